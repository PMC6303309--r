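# Shared constants; this file must collate before the modules that use them.

MODEL_VARIANTS <- c("regulated", "unregulated", "full", "ideal")

EXPERIMENT_KINDS <- c("simulate", "step", "robustness", "sweep", "qic-check",
                      "silencing")

PARAM_KEYS <- c("T_rate", "D", "kappa_gfp", "kappa_ecf", "k", "Ts", "delta",
                "lam", "beta", "R", "gamma", "actuator_saturation")

`%||%` <- function(a, b) if (is.null(a)) b else a
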