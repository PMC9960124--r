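# Shared vocabulary for the clinical metadata model.

VALID_GROUPS       <- c("cancer", "healthy")
VALID_TREATMENT    <- c("before", "under", "none")
VALID_HISTOLOGY    <- c("squamous", "adeno", "small_cell", "non_differentiated", "none")
VALID_LOCALIZATION <- c("central", "peripheral", "none")
COMORBIDITIES      <- c("chf", "hypertension", "anemia", "cva", "obesity", "diabetes")
METADATA_COLUMNS   <- c("sample_id", "group", "age", "sex", "smoker",
                        "treatment_status", COMORBIDITIES,
                        "tnm_t", "tnm_n", "tnm_m", "histology", "localization")
FACTOR_NAMES <- c("disease", "treatment", COMORBIDITIES,
                  "tnm", "histology", "localization", "age")
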