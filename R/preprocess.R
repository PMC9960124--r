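# Peak-table preprocessing: ambient-air correction, detection and occurrence
# filtering, denominator selection and ratio-feature construction.
#
# The pipeline follows the standard breathomics conventions for this study
# design: room-air background is removed by per-sample subtraction (negatives
# equated to zero); a VOC counts as detected in a sample only when its breath
# area exceeds the paired ambient area by a margin (20% by default) and is
# positive; only VOCs detected in more than half of all samples are analysed;
# and ratio features are formed against "main" denominators — compounds
# present in at least 86% of samples of both groups — so that division by
# zero is rare by construction.

#' Preprocessing configuration
#'
#' @param min_excess detection margin: a VOC is detected in a sample when its
#'   breath area is at least `(1 + min_excess)` times the paired ambient area
#'   (default 0.20) and positive.
#' @param min_occurrence strict occurrence threshold: a VOC is retained when
#'   detected in *more than* this fraction of all samples (default 0.50).
#' @param denominator_occurrence a VOC qualifies as a ratio denominator when
#'   its detection frequency in *each* group is at least this fraction
#'   (default 0.86).
#' @param always_denominators VOC names always admitted as denominators in
#'   addition to those qualifying by frequency.
#' @param blocklist VOC names excluded outright; defaults to the known
#'   Tedlar-bag storage contaminants phenol and N,N-dimethylacetamide, whose
#'   levels grow with storage time in the bag.
#' @export
preprocess_config <- function(min_excess = 0.20, min_occurrence = 0.50,
                              denominator_occurrence = 0.86,
                              always_denominators = character(0),
                              blocklist = c("Phenol", "N,N-dimethylacetamide")) {
  for (f in c(min_occurrence = min_occurrence,
              denominator_occurrence = denominator_occurrence)) {
    if (!is.finite(f) || f < 0 || f > 1)
      stop("preprocess_config: occurrence fractions must be in [0, 1]")
  }
  if (!is.finite(min_excess) || min_excess < 0)
    stop("preprocess_config: min_excess must be >= 0")
  structure(list(min_excess = min_excess, min_occurrence = min_occurrence,
                 denominator_occurrence = denominator_occurrence,
                 always_denominators = always_denominators,
                 blocklist = blocklist),
            class = "preprocess_config")
}

.check_aligned_pair <- function(breath, ambient) {
  if (!identical(dim(breath), dim(ambient)) ||
      !identical(rownames(breath), rownames(ambient)) ||
      !identical(colnames(breath), colnames(ambient)))
    stop("breath and ambient tables are not aligned (run align_cohort() first)")
}

#' Subtract ambient-air background from breath peak areas
#'
#' `out[i, v] = max(breath[i, v] - ambient[i, v], 0)`: the room-air influence
#' is removed sample-wise and negative results are equated to zero.
#'
#' @param breath,ambient aligned [peak_table()]s.
#' @return corrected breath [peak_table()].
#' @export
subtract_ambient <- function(breath, ambient) {
  .check_aligned_pair(breath, ambient)
  peak_table(pmax(unclass(breath) - unclass(ambient), 0), "breath")
}

#' Per-sample VOC detection flags
#'
#' A VOC is flagged detected in a sample iff its breath area is positive and
#' at least `(1 + min_excess)` times the paired ambient area.
#'
#' @param breath,ambient aligned [peak_table()]s.
#' @param min_excess detection margin (default 0.20).
#' @return logical matrix, samples x VOCs.
#' @export
detect_flags <- function(breath, ambient, min_excess = 0.20) {
  .check_aligned_pair(breath, ambient)
  b <- unclass(breath); a <- unclass(ambient)
  b > 0 & b >= (1 + min_excess) * a
}

#' Occurrence filter: retain VOCs detected in more than a fraction of samples
#'
#' @param flags detection matrix from [detect_flags()].
#' @param groups character vector of group labels per sample (for the
#'   per-group frequencies in the report); optional.
#' @param min_occurrence strict threshold (default 0.50): retained iff the
#'   overall detection fraction is `> min_occurrence`.
#' @param blocklist VOC names dropped regardless of frequency.
#' @return list with `retained` (VOC names) and `occurrence` (data.frame
#'   `voc`, `overall`, and one column per group).
#' @export
filter_vocs <- function(flags, groups = NULL, min_occurrence = 0.50,
                        blocklist = character(0)) {
  if (nrow(flags) == 0 || ncol(flags) == 0)
    stop("empty detection matrix")
  overall <- colMeans(flags)
  occurrence <- data.frame(voc = colnames(flags), overall = as.numeric(overall),
                           stringsAsFactors = FALSE)
  if (!is.null(groups)) {
    for (g in unique(groups))
      occurrence[[g]] <- as.numeric(colMeans(flags[groups == g, , drop = FALSE]))
  }
  keep <- overall > min_occurrence & !(colnames(flags) %in% blocklist)
  list(retained = colnames(flags)[keep], occurrence = occurrence)
}

#' Select ratio denominators from per-group occurrence frequencies
#'
#' Denominators are the "main" VOCs: those whose detection frequency in each
#' group is at least `denominator_occurrence` (so that a zero denominator is
#' rare), plus any names in `always_denominators`. The list is ordered by
#' decreasing minimum per-group frequency (ties by decreasing mean frequency,
#' then name).
#'
#' @param occurrence data.frame with columns `voc` and one frequency column
#'   per group (fractions in `[0, 1]`), as produced by [filter_vocs()].
#' @param denominator_occurrence qualifying threshold (default 0.86).
#' @param always_denominators names to force-include.
#' @param groups which columns of `occurrence` hold group frequencies
#'   (default: all columns except `voc` and `overall`).
#' @return character vector of denominator VOC names.
#' @export
select_denominators <- function(occurrence, denominator_occurrence = 0.86,
                                always_denominators = character(0),
                                groups = NULL) {
  if (is.null(groups))
    groups <- setdiff(names(occurrence), c("voc", "overall"))
  if (length(groups) == 0)
    stop("occurrence report has no per-group frequency columns")
  freq <- as.matrix(occurrence[, groups, drop = FALSE])
  minf <- apply(freq, 1, min)
  qualify <- minf >= denominator_occurrence
  dens <- occurrence$voc[qualify]
  if (length(dens) == 0 && length(always_denominators) == 0)
    stop("no VOC reaches the denominator occurrence threshold of ",
         denominator_occurrence, "; lower the threshold or force denominators")
  ord <- order(-minf[qualify], -rowMeans(freq)[qualify], occurrence$voc[qualify])
  unique(c(dens[ord], always_denominators))
}

#' Build the ratio + raw feature matrix
#'
#' Features are all retained raw VOC areas plus every ratio
#' `numerator/denominator` with the numerator ranging over retained VOCs and
#' the denominator over the selected denominators (self-ratios skipped).
#' A zero numerator yields ratio 0; a zero (undetected) denominator yields a
#' masked missing value (`NA`), excluded pairwise downstream rather than
#' stored as an arbitrary number.
#'
#' @param corrected ambient-corrected [peak_table()].
#' @param retained retained VOC names.
#' @param denominators denominator VOC names (must be a subset of
#'   `retained`).
#' @return numeric matrix samples x features with feature ids `"VOC"` and
#'   `"num/den"` as column names.
#' @export
build_ratio_features <- function(corrected, retained, denominators) {
  if (!all(denominators %in% retained))
    stop("denominators must be a subset of the retained VOCs: ",
         paste(setdiff(denominators, retained), collapse = ", "))
  m <- unclass(corrected)[, retained, drop = FALSE]
  feats <- list()
  for (v in retained) feats[[v]] <- m[, v]
  for (den in denominators) {
    d <- m[, den]
    d[d == 0] <- NA_real_
    for (num in retained) {
      if (num == den) next
      feats[[paste0(num, "/", den)]] <- m[, num] / d
    }
  }
  out <- do.call(cbind, feats)
  rownames(out) <- rownames(corrected)
  out
}

#' Run the full preprocessing chain on an aligned cohort
#'
#' Ambient subtraction, detection flags, occurrence filter, denominator
#' selection and ratio-feature construction in one call.
#'
#' @param aligned an `aligned_cohort` from [align_cohort()].
#' @param config a [preprocess_config()].
#' @return list with `features` (matrix), `occurrence` (report data.frame,
#'   fractions), `retained`, `denominators`, and `corrected` (ambient-
#'   corrected [peak_table()]).
#' @export
preprocess_cohort <- function(aligned, config = preprocess_config()) {
  stopifnot(inherits(aligned, "aligned_cohort"))
  corrected <- subtract_ambient(aligned$breath, aligned$ambient)
  flags <- detect_flags(aligned$breath, aligned$ambient, config$min_excess)
  filt <- filter_vocs(flags, groups = aligned$meta$group,
                      min_occurrence = config$min_occurrence,
                      blocklist = config$blocklist)
  if (length(filt$retained) == 0)
    stop("no VOCs survive the occurrence filter (> ",
         config$min_occurrence, " of samples); no features survive")
  occ_retained <- filt$occurrence[filt$occurrence$voc %in% filt$retained, ,
                                  drop = FALSE]
  denominators <- select_denominators(
    occ_retained, config$denominator_occurrence,
    intersect(config$always_denominators, filt$retained))
  list(features = build_ratio_features(corrected, filt$retained, denominators),
       occurrence = filt$occurrence,
       retained = filt$retained,
       denominators = denominators,
       corrected = corrected)
}
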