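# Small constructed fixtures shared across test files.

# 4-sample, 6-VOC toy table exercising the detection rule (breath at least
# 20% above ambient and positive) and the strict >50% occurrence filter:
#   A detected 4/4 (retained), B 3/4 (retained), C 2/4 (exactly 50%,
#   dropped by the strict inequality), D 1/4 (dropped), E 0/4 (dropped),
#   F breath 1 over ambient 0 in all samples (retained: any positive area
#   exceeds a zero background).
toy_filter_tables <- function() {
  vocs <- c("A", "B", "C", "D", "E", "F")
  ids <- paste0("s", 1:4)
  breath <- matrix(c(
    # A    B    C    D    E   F
    130, 130, 130, 130, 119, 1,
    130, 130, 130, 119, 119, 1,
    130, 130, 100, 100, 119, 1,
    130, 119,   0, 100, 119, 1), 4, 6, byrow = TRUE,
    dimnames = list(ids, vocs))
  ambient <- matrix(100, 4, 6, dimnames = list(ids, vocs))
  ambient[, "F"] <- 0
  list(breath = peak_table(breath, "breath"),
       ambient = peak_table(ambient, "ambient"),
       retained_expected = c("A", "B", "F"))
}

# Occurrence report (fractions) for the package's default 40-VOC panel,
# in the shape produced by filter_vocs().
default_occurrence_report <- function() {
  specs <- default_voc_specs()
  data.frame(voc = vapply(specs, `[[`, "", "name"),
             cancer = vapply(specs, `[[`, 0, "occurrence_cancer"),
             healthy = vapply(specs, `[[`, 0, "occurrence_healthy"),
             stringsAsFactors = FALSE)
}

# A fully-detected, background-free VOC panel for effect-recovery work:
# effects are measured on the breath areas themselves, so censoring and
# ambient noise are switched off.
clean_voc_panel <- function(names, ...) {
  lapply(names, function(nm) voc_spec(nm, 1, 1, ambient_fraction = 0, ...))
}

# Minimal valid metadata for n samples split cancer/healthy.
tiny_meta <- function(n_cancer, n_healthy) {
  generate_cohort(cohort_config(n_cancer, n_healthy,
                                voc_specs = clean_voc_panel("X"),
                                seed = 99))$meta
}

# Fisher-z interval check for a Spearman estimate against a known target,
# using the rank-correlation variance 1.06/(n-3).
fisher_z_covers <- function(rho_hat, target, n, level_z = 1.96) {
  half <- level_z * sqrt(1.06 / (n - 3))
  abs(atanh(rho_hat) - atanh(target)) <= half
}
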