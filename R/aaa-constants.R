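# Shared controlled vocabularies. Loaded first (file name ordering).

BASELINE_FLAGS <- c("age_truncated", "geographic_subset",
                    "other_nonbaseline")
MISCLASS_FLAGS <- c("modern_inflated", "traditional_inflated",
                    "methods_combined")
SOURCE_TYPES <- c("DHS", "MICS", "RHS", "WFS", "PMA", "national", "other")
MARITAL_GROUPS <- c("married", "unmarried")
PARAM_NAMES <- c("la_any", "lr_any", "m_any",
                 "la_ratio", "lr_ratio", "m_ratio", "u_int")
GLOBAL_NAMES <- c("slope", "rho_any", "rho_ratio", "sd_any", "sd_ratio")
BIAS_PAR_NAMES <- c(paste0("shift_any.", BASELINE_FLAGS),
                    paste0("shift_u.", BASELINE_FLAGS),
                    paste0("misclass.", MISCLASS_FLAGS))
COMP_NAMES <- c("modern", "traditional", "unmet", "no_need")
INDICATORS <- c("use_any", "use_modern", "use_traditional", "unmet",
                "need", "no_need", "need_satisfied_modern")
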