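# Spearman rank-correlation screening of breath features against clinical
# factors, confounder exclusion, top-feature selection and correlation power
# analysis.
#
# The screen is deliberately nonparametric: GC-MS peak areas and their ratios
# are heavy-tailed and non-normal, so associations are measured on ranks.

#' Spearman rank correlation with t-approximation p-value
#'
#' Computes Spearman's rho as the Pearson correlation of average-tie ranks
#' over pairwise-complete observations, with a two-sided p-value from the
#' t approximation \eqn{t = \rho \sqrt{(n-2)/(1-\rho^2)}} on \eqn{n-2}
#' degrees of freedom (\eqn{p = 0} when \eqn{|\rho| = 1}). For very small
#' samples an exact permutation p-value is available.
#'
#' @param x,y numeric vectors of equal length; `NA`s are removed pairwise.
#' @param exact if `TRUE`, compute the p-value by full enumeration of all
#'   `n!` rank permutations (supported for `n <= 8`).
#' @return list with `rho`, `p_value`, `n`. When fewer than 3 complete pairs
#'   remain or either vector has zero rank variance, `rho` and `p_value` are
#'   `NA` (an undefined result, not an error).
#' @examples
#' spearman_rho(c(1, 2, 3, 4), c(1, 3, 2, 4))$rho  # 0.8
#' @export
spearman_rho <- function(x, y, exact = FALSE) {
  if (length(x) != length(y)) stop("x and y must have the same length")
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  undefined <- list(rho = NA_real_, p_value = NA_real_, n = n)
  if (n < 3) return(undefined)
  rx <- rank(x); ry <- rank(y)
  if (stats::var(rx) == 0 || stats::var(ry) == 0) return(undefined)
  rho <- stats::cor(rx, ry)
  rho <- max(-1, min(1, rho))
  if (exact) {
    if (n > 8) stop("exact permutation p-value is supported for n <= 8")
    perms <- .permutations(n)
    rhos <- apply(perms, 1, function(p) stats::cor(rx, ry[p]))
    p_value <- mean(abs(rhos) >= abs(rho) - 1e-12)
  } else if (abs(rho) == 1) {
    p_value <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p_value <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p_value = p_value, n = n)
}

.permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i)
    cbind(i, sub + (sub >= i))))
}

#' Encode a clinical factor as a numeric vector for rank correlation
#'
#' Returns one numeric value per sample, with `NA` marking samples the factor
#' does not apply to (those are excluded from the screen). Encodings:
#' \describe{
#'   \item{disease}{healthy 0, cancer 1 (all samples).}
#'   \item{treatment}{before 0, under 1 (cancer only).}
#'   \item{chf, hypertension, anemia, cva, obesity, diabetes}{flag 0/1
#'     (cancer only).}
#'   \item{localization}{peripheral 0, central 1 by default (cancer only);
#'     flip with `central_high = FALSE`.}
#'   \item{histology}{malignant-course rank: squamous 1, adeno 2,
#'     small_cell 3; non-differentiated tumors are not on this ordinal scale
#'     and are masked out (cancer only).}
#'   \item{tnm}{ordinal score of the detailed (T, N, M) code in lexicographic
#'     T-then-N-then-M order (cancer only).}
#'   \item{age}{years (all samples).}
#' }
#'
#' @param meta validated metadata.
#' @param factor factor name.
#' @param central_high orientation of the localization encoding.
#' @return numeric vector aligned with `meta` rows, `NA` = not applicable.
#' @export
encode_factor <- function(meta, factor, central_high = TRUE) {
  if (!factor %in% FACTOR_NAMES)
    stop("unknown factor '", factor, "' (valid: ",
         paste(FACTOR_NAMES, collapse = ", "), ")")
  n <- nrow(meta)
  cancer <- meta$group == "cancer"
  enc <- rep(NA_real_, n)
  switch(factor,
    disease = { enc <- as.numeric(cancer) },
    age = { enc <- meta$age },
    treatment = {
      enc[cancer] <- ifelse(meta$treatment_status[cancer] == "under", 1, 0)
    },
    localization = {
      loc <- meta$localization
      known <- cancer & loc %in% c("central", "peripheral")
      enc[known] <- if (central_high) as.numeric(loc[known] == "central")
                    else as.numeric(loc[known] == "peripheral")
    },
    histology = {
      ranks <- c(squamous = 1, adeno = 2, small_cell = 3)
      h <- meta$histology
      known <- cancer & h %in% names(ranks)
      enc[known] <- ranks[h[known]]
    },
    tnm = {
      # lexicographic (T, N, M): T dominates N dominates M
      enc[cancer] <- meta$tnm_t[cancer] * 100 + meta$tnm_n[cancer] * 10 +
        meta$tnm_m[cancer]
    },
    { # comorbidity flags
      enc[cancer] <- as.numeric(meta[[factor]][cancer])
    })
  enc
}

#' Screening configuration
#' @param alpha significance level for flagging (default 0.05).
#' @param factors factor names screened by the pipeline.
#' @param top_k number of features selected for modelling (default 12).
#' @export
screen_config <- function(alpha = 0.05,
                          factors = c("disease", "treatment", COMORBIDITIES,
                                      "tnm", "histology", "localization", "age"),
                          top_k = 12) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("screen_config: alpha must be in (0, 1)")
  if (!is.numeric(top_k) || top_k < 1)
    stop("screen_config: top_k must be >= 1")
  bad <- setdiff(factors, FACTOR_NAMES)
  if (length(bad) > 0) stop("screen_config: unknown factor(s): ",
                            paste(bad, collapse = ", "))
  structure(list(alpha = alpha, factors = factors, top_k = as.integer(top_k)),
            class = "screen_config")
}

#' Screen all features against one clinical factor
#'
#' Runs [spearman_rho()] of every feature column against the encoded factor,
#' with pairwise-complete deletion of masked ratio values and non-applicable
#' samples.
#'
#' @param features numeric matrix (samples x features; `NA` = undefined
#'   ratio), rownames matching `meta$sample_id`.
#' @param meta validated metadata.
#' @param factor factor name (see [encode_factor()]).
#' @param alpha significance level for the `significant` flag.
#' @param central_high passed to [encode_factor()].
#' @return data.frame `feature_id`, `factor`, `rho`, `p_value`, `n`,
#'   `significant`. Undefined results (constant factor, too few pairs) carry
#'   `NA` rho/p and `significant = FALSE`.
#' @export
screen_features <- function(features, meta, factor, alpha = 0.05,
                            central_high = TRUE) {
  features <- as.matrix(features)
  if (!is.null(rownames(features)) &&
      !identical(rownames(features), as.character(meta$sample_id))) {
    idx <- match(rownames(features), meta$sample_id)
    if (anyNA(idx)) stop("features and metadata sample ids do not match")
    meta <- meta[idx, , drop = FALSE]
  }
  enc <- encode_factor(meta, factor, central_high)
  res <- lapply(seq_len(ncol(features)), function(j) {
    r <- spearman_rho(features[, j], enc)
    data.frame(feature_id = colnames(features)[j], factor = factor,
               rho = r$rho, p_value = r$p_value, n = r$n,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$significant <- !is.na(out$p_value) & out$p_value < alpha
  out
}

#' Exclude features confounded by treatment or comorbidities
#'
#' A feature significantly associated (at `alpha`) with treatment status or
#' with any comorbidity is not a credible disease biomarker candidate: its
#' disease association may reflect the nuisance factor instead. Such features
#' are removed before model-feature selection, and each removal is recorded
#' with the factor(s) that triggered it.
#'
#' @param disease_screen screen result for the disease factor.
#' @param nuisance_screens list of screen results (treatment, comorbidities).
#' @param alpha exclusion significance level.
#' @return list with `surviving` (disease screen rows for retained features)
#'   and `ledger` (data.frame `feature_id`, `excluded_by`).
#' @export
exclude_confounded <- function(disease_screen, nuisance_screens, alpha = 0.05) {
  reasons <- list()
  for (sc in nuisance_screens) {
    sig <- sc[!is.na(sc$p_value) & sc$p_value < alpha, , drop = FALSE]
    for (i in seq_len(nrow(sig)))
      reasons[[sig$feature_id[i]]] <- c(reasons[[sig$feature_id[i]]],
                                        sig$factor[i])
  }
  excluded <- names(reasons)
  ledger <- data.frame(
    feature_id = excluded,
    excluded_by = vapply(reasons, paste, "", collapse = ";"),
    stringsAsFactors = FALSE, row.names = NULL)
  list(surviving = disease_screen[!disease_screen$feature_id %in% excluded, ,
                                  drop = FALSE],
       ledger = ledger)
}

#' Check selected features for age association within each group
#'
#' Because case and control groups often differ in age, a credible feature
#' set must be age-independent within each group separately. Computes the
#' Spearman correlation of each selected feature with age among cancer
#' patients and among healthy volunteers and flags significant entries.
#'
#' @param selected character vector of selected feature ids.
#' @param features feature matrix.
#' @param meta validated metadata.
#' @param alpha significance level.
#' @return data.frame `feature_id`, `group`, `rho`, `p_value`, `n`,
#'   `flagged` (undefined results have `NA` rho/p and are not flagged).
#' @export
check_age_independence <- function(selected, features, meta, alpha = 0.05) {
  features <- as.matrix(features)
  out <- list()
  for (g in c("cancer", "healthy")) {
    in_g <- meta$group == g
    for (f in selected) {
      r <- spearman_rho(features[in_g, f], meta$age[in_g])
      out[[length(out) + 1L]] <- data.frame(
        feature_id = f, group = g, rho = r$rho, p_value = r$p_value, n = r$n,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, out)
  out$flagged <- !is.na(out$p_value) & out$p_value < alpha
  out
}

#' Select the top features by absolute disease correlation
#'
#' @param surviving disease-screen rows that survived confounder exclusion.
#' @param top_k number of features to keep.
#' @return character vector of feature ids ordered by decreasing `|rho|`
#'   (ties broken lexicographically by feature id). If fewer than `top_k`
#'   features survive, all are returned with a warning.
#' @export
select_top_features <- function(surviving, top_k = 12) {
  sv <- surviving[!is.na(surviving$rho), , drop = FALSE]
  ord <- order(-abs(sv$rho), sv$feature_id)
  ids <- sv$feature_id[ord]
  if (length(ids) < top_k) {
    warning("only ", length(ids), " features survive; requested top ", top_k)
    return(ids)
  }
  ids[seq_len(top_k)]
}

#' Required sample size for detecting a rank correlation
#'
#' Closed-form power calculation for a correlation test via the Fisher
#' z-transform: \deqn{n = \left(\frac{z_{1-\alpha/2} + z_{power}}
#' {\operatorname{atanh}(\rho_0)}\right)^2 + 3,} rounded to the nearest
#' integer and floored at 4.
#'
#' @param rho0 smallest correlation magnitude to detect, in (0, 1).
#' @param alpha two-sided significance level.
#' @param power desired power.
#' @return integer sample size.
#' @examples
#' required_sample_size(0.2, 0.05, 0.85)  # 221
#' @export
required_sample_size <- function(rho0, alpha = 0.05, power = 0.85) {
  if (!is.finite(rho0) || rho0 <= 0 || rho0 >= 1)
    stop("rho0 must be in (0, 1); a vanishing detectable correlation needs an unbounded sample")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (power <= 0 || power >= 1) stop("power must be in (0, 1)")
  n <- ((stats::qnorm(1 - alpha / 2) + stats::qnorm(power)) / atanh(rho0))^2 + 3
  max(4L, as.integer(round(n)))
}
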