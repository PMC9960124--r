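# Synthetic breath-study cohort generator.
#
# Emulates a two-group (lung cancer / healthy) TD-GC-MS breath study: per-VOC
# detection frequencies per group, heavy-tailed positive peak areas
# (log-normal, censored to 0 on a non-detection draw), paired ambient-air
# backgrounds, a clinical covariate model (age, sex, smoking, treatment,
# comorbidities, TNM, histology, localization), and injectable rank-correlation
# effects between VOCs and clinical factors so that downstream screening and
# modelling can be validated against known truth.

#' Specification of one synthetic VOC
#'
#' @param name VOC name.
#' @param occurrence_cancer,occurrence_healthy detection probability (fraction
#'   of samples with area > 0) in each group, in `[0, 1]`.
#' @param log_mean,log_sd location and scale of the log peak-area distribution
#'   (`log_sd > 0`).
#' @param ambient_fraction mean ambient-air area as a fraction of the mean
#'   breath area, in `[0, 1)`; 0 means the compound never appears in room air.
#' @return a `voc_spec` list.
#' @export
voc_spec <- function(name, occurrence_cancer, occurrence_healthy,
                     log_mean = 13, log_sd = 0.8, ambient_fraction = 0.15) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("voc_spec: 'name' must be a non-empty string")
  for (p in c(occurrence_cancer = occurrence_cancer,
              occurrence_healthy = occurrence_healthy)) {
    if (!is.finite(p) || p < 0 || p > 1)
      stop("voc_spec '", name, "': occurrence probabilities must be in [0, 1]")
  }
  if (!is.finite(log_sd) || log_sd <= 0)
    stop("voc_spec '", name, "': log_sd must be > 0")
  if (!is.finite(ambient_fraction) || ambient_fraction < 0 || ambient_fraction >= 1)
    stop("voc_spec '", name, "': ambient_fraction must be in [0, 1)")
  structure(list(name = name, occurrence_cancer = occurrence_cancer,
                 occurrence_healthy = occurrence_healthy, log_mean = log_mean,
                 log_sd = log_sd, ambient_fraction = ambient_fraction),
            class = "voc_spec")
}

#' Specification of one injected feature-factor effect
#'
#' @param feature VOC name (or a ratio id `"num/den"`, in which case the
#'   effect is injected into the numerator VOC).
#' @param factor one of `"disease"`, `"treatment"`, a comorbidity name
#'   (`"chf"`, `"hypertension"`, `"anemia"`, `"cva"`, `"obesity"`,
#'   `"diabetes"`), `"tnm"`, `"histology"`, `"localization"`, `"age"`.
#' @param target_rho signed target Spearman correlation, `|rho| < 1`.
#' @return an `effect_spec` list.
#' @export
effect_spec <- function(feature, factor, target_rho) {
  if (!factor %in% FACTOR_NAMES)
    stop("effect_spec: unknown factor '", factor, "' (valid: ",
         paste(FACTOR_NAMES, collapse = ", "), ")")
  if (!is.finite(target_rho) || abs(target_rho) >= 1)
    stop("effect_spec: |target_rho| must be < 1")
  structure(list(feature = feature, factor = factor, target_rho = target_rho),
            class = "effect_spec")
}

#' Default VOC panel: the 40 most frequently occurring breath VOCs
#'
#' Occurrence frequencies (fraction of samples with a detection, per group)
#' for the 40 compounds most often seen in exhaled breath of lung cancer
#' patients and healthy volunteers in TD-GC-MS studies of this design; these
#' drive the generator's censoring draws and are also the package's reference
#' input for denominator selection. Log-area locations are staggered over
#' typical EIC peak-area magnitudes (more frequent compounds tend to be more
#' abundant); scale and ambient fraction are uniform defaults.
#'
#' @return a list of [voc_spec()] objects.
#' @export
default_voc_specs <- function() {
  occ <- list(
    # name, cancer %, healthy %
    list("Isoprene",            100, 100), list("Acetone",             100, 100),
    list("Dimethylsulfide",     100, 100), list("1-Methylthiopropene", 100,  92),
    list("Allyl methyl sulfide", 98,  97), list("1-Methylthiopropane",  98,  95),
    list("2-Pentanone",          97,  99), list("Dimethyl disulfide",   97,  93),
    list("2.3-Butandione",       88,  92), list("Acetonitrile",         87,  88),
    list("2-Butanone",           76,  86), list("Dimethyl trisulfide",  71,  55),
    list("Benzaldehyde",         58,  57), list("1-Pentanol",           56,  59),
    list("2-Heptanone",          54,  51), list("Heptane",              53,  73),
    list("Nonanal",              53,  56), list("Hexane",               51,  62),
    list("3-Heptanone",          51,  52), list("Octanal",              51,  52),
    list("Octane",               51,  50), list("Toluene",              51,  32),
    list("Pentanal",             50,  72), list("Hexanal",              49,  49),
    list("Decane",               49,  48), list("Dodecane",             46,  49),
    list("Undecane",             45,  49), list("Propylbenzene",        45,  13),
    list("Decanal",              42,  49), list("Heptanal",             39,  48),
    list("Butanal",              37,  48), list("Nonane",               37,  46),
    list("Benzene",              31,  22), list("1.3-Pentadiene",       25,  15),
    list("Ethylbenzene",         25,  12), list("1-Butanol",            24,  49),
    list("1.4-Pentadiene",       22,  10), list("Butyl acetate",        21,  48),
    list("o-Xylene",             20,  13), list("m+p-Xylene",           20,  12))
  n <- length(occ)
  log_means <- seq(15, 11, length.out = n)   # abundant compounds first
  lapply(seq_len(n), function(i)
    voc_spec(occ[[i]][[1]], occ[[i]][[2]] / 100, occ[[i]][[3]] / 100,
             log_mean = log_means[i], log_sd = 0.8, ambient_fraction = 0.15))
}

#' Default clinical covariate model
#'
#' Count-based covariate model for a reference cohort of 112 lung cancer
#' patients and 120 healthy volunteers: sex and smoker counts per group, age
#' medians/ranges, treatment status, per-comorbidity counts, TNM code
#' frequencies, histology and tumor localization counts. Counts are scaled
#' proportionally when a different group size is requested.
#'
#' @return a named list used by [cohort_config()].
#' @export
default_covariate_model <- function() {
  list(
    ref_n_cancer = 112, ref_n_healthy = 120,
    male_cancer = 88, male_healthy = 36,
    smokers_cancer = 22, smokers_healthy = 17,
    age_cancer = list(median = 63, min = 21, max = 77),
    age_healthy = list(median = 21, min = 21, max = 67),
    treatment_under = 96,              # chemo 88 + immuno 7 + target 1
    comorbidity_counts = c(chf = 19, hypertension = 18, anemia = 8,
                           cva = 5, obesity = 4, diabetes = 4),
    histology_counts = c(adeno = 50, squamous = 38, small_cell = 12,
                         non_differentiated = 12),
    localization_counts = c(central = 59, peripheral = 53),
    tnm_counts = c(T1N0M1 = 1, T2N0M0 = 8, T2N0M1 = 5, T2N1M0 = 8, T2N1M1 = 1,
                   T2N2M0 = 2, T2N2M1 = 6, T2N3M0 = 1, T2N3M1 = 2, T3N0M0 = 6,
                   T3N0M1 = 2, T3N1M0 = 7, T3N1M1 = 1, T3N2M0 = 15, T3N2M1 = 4,
                   T3N3M0 = 1, T4N0M0 = 5, T4N0M1 = 5, T4N1M0 = 8, T4N1M1 = 1,
                   T4N2M0 = 10, T4N2M1 = 10, T4N3M0 = 2, T4N3M1 = 1))
}

#' Cohort generator configuration
#'
#' @param n_cancer,n_healthy group sizes.
#' @param voc_specs list of [voc_spec()] (default: [default_voc_specs()]).
#' @param effects list of [effect_spec()] to inject (default: none).
#' @param covariate_model covariate count model
#'   (default: [default_covariate_model()]).
#' @param seed integer seed; a fixed seed reproduces the cohort exactly.
#' @return a `cohort_config` list, validated.
#' @export
cohort_config <- function(n_cancer = 112, n_healthy = 120,
                          voc_specs = default_voc_specs(),
                          effects = list(),
                          covariate_model = default_covariate_model(),
                          seed = 1L) {
  if (!is.numeric(n_cancer) || n_cancer < 0 || n_cancer != round(n_cancer))
    stop("cohort_config: n_cancer must be a non-negative integer")
  if (!is.numeric(n_healthy) || n_healthy < 0 || n_healthy != round(n_healthy))
    stop("cohort_config: n_healthy must be a non-negative integer")
  if (length(voc_specs) == 0) stop("cohort_config: voc_specs must be non-empty")
  for (v in voc_specs)
    if (!inherits(v, "voc_spec")) stop("cohort_config: voc_specs must be voc_spec objects")
  nm <- vapply(voc_specs, `[[`, "", "name")
  if (anyDuplicated(nm))
    stop("cohort_config: duplicate VOC name '", nm[duplicated(nm)][1], "'")
  for (e in effects) {
    if (!inherits(e, "effect_spec")) stop("cohort_config: effects must be effect_spec objects")
    voc <- sub("/.*$", "", e$feature)
    if (!voc %in% nm)
      stop("cohort_config: effect targets unknown VOC '", voc, "'")
  }
  if (!is.numeric(seed) || length(seed) != 1L)
    stop("cohort_config: seed must be a single integer")
  structure(list(n_cancer = as.integer(n_cancer), n_healthy = as.integer(n_healthy),
                 voc_specs = voc_specs, effects = effects,
                 covariate_model = covariate_model, seed = as.integer(seed)),
            class = "cohort_config")
}

# Scale a reference count to a different group size (never exceeding it).
.scale_count <- function(count, ref_n, n) {
  out <- round(count * n / ref_n)
  out[out > n] <- n
  out
}

# Assign exactly `counts[k]` samples to level names(counts)[k], the remainder
# (if any) to `rest`. Used for histology, localization, TNM.
.assign_levels <- function(n, counts, rest = NULL) {
  counts[counts < 0] <- 0
  if (sum(counts) > n) {           # trim largest classes first to fit
    while (sum(counts) > n) counts[which.max(counts)] <- counts[which.max(counts)] - 1
  }
  lev <- rep(names(counts), counts)
  if (length(lev) < n) {
    pr <- if (sum(counts) > 0) counts / sum(counts)
          else rep(1 / length(counts), length(counts))
    if (is.null(rest)) lev <- c(lev, sample(names(counts), n - length(lev),
                                            replace = TRUE, prob = pr))
    else lev <- c(lev, rep(rest, n - length(lev)))
  }
  sample(lev, n)
}

.flag_count <- function(n, k) {
  f <- rep(FALSE, n)
  if (k > 0) f[sample.int(n, min(k, n))] <- TRUE
  f
}

# Ages: cancer group unimodal around the median; healthy group median pinned
# at the young end (student volunteers) with a decaying older tail.
.draw_ages <- function(n, model, young_heavy) {
  if (n == 0) return(numeric(0))
  md <- model$median; lo <- model$min; hi <- model$max
  if (young_heavy) {
    young <- stats::runif(n) < 0.55
    age <- ifelse(young, lo, lo + 1 + floor(stats::rexp(n, rate = 1 / 12)))
  } else {
    age <- round(stats::rnorm(n, md, 9))
  }
  pmin(hi, pmax(lo, age))
}

#' Generate a synthetic breath-study cohort
#'
#' Produces a paired breath/ambient peak-table pair plus a clinical metadata
#' table with the statistical structure requested by the configuration:
#' per-group VOC detection frequencies, log-normal positive areas, ambient
#' backgrounds at a configurable fraction of breath levels (one paired
#' ambient row per sample by default), covariates drawn from the count model
#' (comorbidity flags and tumor descriptors in the cancer group only), and
#' rank-correlation effects injected through a Gaussian copula on latent
#' log-area scores (see [inject_effect()]) so that Spearman screening
#' recovers each `target_rho` asymptotically. Effects on factors that apply
#' only to patients (treatment, comorbidities, TNM, histology, localization)
#' shift areas within the cancer group only. With a fixed seed the output is
#' reproducible bit for bit.
#'
#' @param config a [cohort_config()].
#' @return list with `breath` and `ambient` [peak_table()]s and `meta`
#'   (validated metadata), samples ordered cancer first.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) config <- do.call(cohort_config, config)
  set.seed(config$seed)
  n1 <- config$n_cancer; n0 <- config$n_healthy; n <- n1 + n0
  cm <- config$covariate_model
  ids <- c(sprintf("LC%03d", seq_len(n1)), sprintf("HV%03d", seq_len(n0)))
  group <- rep(c("cancer", "healthy"), c(n1, n0))

  sc1 <- function(k) .scale_count(k, cm$ref_n_cancer, n1)
  sc0 <- function(k) .scale_count(k, cm$ref_n_healthy, n0)

  sex <- c(ifelse(.flag_count(n1, sc1(cm$male_cancer)), "m", "f"),
           ifelse(.flag_count(n0, sc0(cm$male_healthy)), "m", "f"))
  smoker <- c(.flag_count(n1, sc1(cm$smokers_cancer)),
              .flag_count(n0, sc0(cm$smokers_healthy)))
  age <- c(.draw_ages(n1, cm$age_cancer, young_heavy = FALSE),
           .draw_ages(n0, cm$age_healthy, young_heavy = TRUE))
  treatment <- c(ifelse(.flag_count(n1, sc1(cm$treatment_under)), "under", "before"),
                 rep("none", n0))
  comorb <- sapply(COMORBIDITIES, function(cc)
    c(.flag_count(n1, sc1(cm$comorbidity_counts[[cc]])), rep(FALSE, n0)))
  histology <- c(if (n1 > 0) .assign_levels(n1, sc1(cm$histology_counts)) else character(0),
                 rep("none", n0))
  localization <- c(if (n1 > 0) .assign_levels(n1, sc1(cm$localization_counts)) else character(0),
                    rep("none", n0))
  tnm_code <- c(if (n1 > 0) .assign_levels(n1, sc1(cm$tnm_counts)) else character(0),
                rep("T0N0M0", n0))
  tnm <- parse_tnm(tnm_code)

  meta <- data.frame(sample_id = ids, group = group, age = age, sex = sex,
                     smoker = smoker, treatment_status = treatment,
                     as.data.frame(comorb),
                     tnm_t = tnm[, "t"], tnm_n = tnm[, "n"], tnm_m = tnm[, "m"],
                     histology = histology, localization = localization,
                     stringsAsFactors = FALSE)
  meta <- validate_metadata(meta)

  # group effects by target VOC (ratio effects act on the numerator VOC)
  eff_by_voc <- split(config$effects,
                      vapply(config$effects, function(e) sub("/.*$", "", e$feature), ""))

  vocs <- vapply(config$voc_specs, `[[`, "", "name")
  breath <- matrix(0, n, length(vocs), dimnames = list(ids, vocs))
  ambient <- matrix(0, n, length(vocs), dimnames = list(ids, vocs))

  for (j in seq_along(config$voc_specs)) {
    vs <- config$voc_specs[[j]]
    effs <- eff_by_voc[[vs$name]]
    z <- stats::rnorm(n)
    if (!is.null(effs) && length(effs) > 0) {
      lam2 <- 0
      drive <- numeric(n)
      for (e in effs) {
        enc <- encode_factor(meta, e$factor)
        ok <- !is.na(enc)
        lambda <- .spearman_lambda(enc[ok], e$target_rho)
        s <- numeric(n)
        s[ok] <- .factor_score(enc[ok])$obs_score
        drive <- drive + lambda * s
        lam2 <- lam2 + lambda^2
      }
      if (lam2 >= 1)
        stop("effects on VOC '", vs$name, "' are jointly too strong (sum of lambda^2 >= 1)")
      z <- drive + sqrt(1 - lam2) * z
    }
    area <- exp(vs$log_mean + vs$log_sd * z)
    occ <- ifelse(group == "cancer", vs$occurrence_cancer, vs$occurrence_healthy)
    detected <- stats::runif(n) < occ
    area[!detected] <- 0
    breath[, j] <- area
    if (vs$ambient_fraction > 0)
      ambient[, j] <- stats::rlnorm(n, vs$log_mean + log(vs$ambient_fraction), vs$log_sd)
  }

  list(breath = peak_table(breath, "breath"),
       ambient = peak_table(ambient, "ambient"),
       meta = meta)
}
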