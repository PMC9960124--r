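# Peak-table and metadata containers + CSV I/O.
#
# A peak table is a samples x VOCs matrix of non-negative EIC peak areas with
# unique sample ids (rownames) and VOC names (colnames); `kind` distinguishes
# exhaled-breath tables from paired ambient-air (room background) tables.
# Non-detection is encoded as area 0, never NA.

#' Construct and validate a peak table
#'
#' @param areas numeric matrix, samples in rows (rownames = sample ids),
#'   VOCs in columns (colnames = VOC names). Areas must be non-negative;
#'   zero means not detected.
#' @param kind `"breath"` or `"ambient"`.
#' @return an object of class `peak_table` (a matrix with a `kind` attribute).
#' @export
peak_table <- function(areas, kind = c("breath", "ambient")) {
  kind <- match.arg(kind)
  areas <- as.matrix(areas)
  storage.mode(areas) <- "double"
  if (is.null(rownames(areas)) || is.null(colnames(areas)))
    stop("peak table needs sample ids as rownames and VOC names as colnames")
  if (anyDuplicated(rownames(areas)))
    stop("duplicate sample ids: ",
         paste(unique(rownames(areas)[duplicated(rownames(areas))]), collapse = ", "))
  if (anyDuplicated(colnames(areas)))
    stop("duplicate VOC names: ",
         paste(unique(colnames(areas)[duplicated(colnames(areas))]), collapse = ", "))
  if (anyNA(areas)) areas[is.na(areas)] <- 0
  neg <- which(areas < 0, arr.ind = TRUE)
  if (nrow(neg) > 0)
    stop(sprintf("negative peak area at sample '%s', VOC '%s'",
                 rownames(areas)[neg[1, 1]], colnames(areas)[neg[1, 2]]))
  structure(areas, kind = kind, class = c("peak_table", "matrix", "array"))
}

#' @export
print.peak_table <- function(x, ...) {
  cat(sprintf("<peak_table: %s> %d samples x %d VOCs\n",
              attr(x, "kind"), nrow(x), ncol(x)))
  cat("VOCs:", paste(utils::head(colnames(x), 8), collapse = ", "),
      if (ncol(x) > 8) "..." else "", "\n")
  invisible(x)
}

#' Read a peak table from CSV
#'
#' Expects a header row with `sample_id` followed by one column per VOC;
#' comma separators, dot decimals, UTF-8. Empty cells are read as area 0
#' (non-detection). Files ending in `.gz` are decompressed transparently.
#'
#' @param path CSV file path.
#' @param kind `"breath"` or `"ambient"`.
#' @return a [peak_table()].
#' @export
read_peak_table <- function(path, kind = c("breath", "ambient")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        colClasses = NA)
  if (ncol(df) < 2 || names(df)[1] != "sample_id")
    stop("peak table CSV must start with a 'sample_id' column: ", path)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(matrix(as.numeric(m), nrow(m)))) & !is.na(m) & m != "",
                 arr.ind = TRUE)
    if (nrow(bad) > 0)
      stop(sprintf("non-numeric area at row %d, column '%s' in %s",
                   bad[1, 1], colnames(m)[bad[1, 2]], path))
    m <- matrix(suppressWarnings(as.numeric(m)), nrow(m), dimnames = dimnames(m))
  }
  rownames(m) <- ids
  neg <- which(m < 0, arr.ind = TRUE)
  if (nrow(neg) > 0)
    stop(sprintf("negative peak area at sample '%s', VOC '%s' in %s",
                 ids[neg[1, 1]], colnames(m)[neg[1, 2]], path))
  peak_table(m, kind)
}

#' Write a peak table to CSV
#' @param x a [peak_table()].
#' @param path output file path.
#' @export
write_peak_table <- function(x, path) {
  stopifnot(inherits(x, "peak_table"))
  df <- data.frame(sample_id = rownames(x), as.data.frame(unclass(x)[, , drop = FALSE]),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

.check_enum <- function(x, valid, column, path) {
  bad <- which(!(x %in% valid))
  if (length(bad) > 0)
    stop(sprintf("unknown %s label '%s' at row %d%s (valid: %s)",
                 column, x[bad[1]], bad[1],
                 if (is.null(path)) "" else paste0(" in ", path),
                 paste(valid, collapse = ", ")))
}

#' Validate a clinical metadata table
#'
#' Checks column presence, category labels, and the structural rules of a
#' case-control breath study: healthy volunteers carry no tumor descriptors
#' (histology, localization and TNM fields are `none`/0) and no comorbidity
#' flags; treatment status is `before`/`under` for patients, `none` for
#' healthy volunteers.
#'
#' @param meta data.frame with the columns listed in `METADATA_COLUMNS`.
#' @param path optional source path used in error messages.
#' @return the validated data.frame, classed `breath_metadata`.
#' @export
validate_metadata <- function(meta, path = NULL) {
  missing <- setdiff(METADATA_COLUMNS, names(meta))
  if (length(missing) > 0)
    stop("metadata is missing columns: ", paste(missing, collapse = ", "))
  meta <- meta[, METADATA_COLUMNS]
  meta$sample_id <- as.character(meta$sample_id)
  if (anyDuplicated(meta$sample_id))
    stop("duplicate sample ids in metadata: ",
         paste(unique(meta$sample_id[duplicated(meta$sample_id)]), collapse = ", "))
  .check_enum(meta$group, VALID_GROUPS, "group", path)
  .check_enum(meta$treatment_status, VALID_TREATMENT, "treatment_status", path)
  .check_enum(meta$histology, VALID_HISTOLOGY, "histology", path)
  .check_enum(meta$localization, VALID_LOCALIZATION, "localization", path)
  .check_enum(tolower(as.character(meta$sex)), c("m", "f"), "sex", path)
  meta$sex <- tolower(as.character(meta$sex))
  for (cc in c("smoker", COMORBIDITIES)) {
    v <- meta[[cc]]
    if (is.character(v)) v <- as.logical(toupper(v))
    if (!is.logical(v) || anyNA(v))
      stop("metadata column '", cc, "' must be TRUE/FALSE with no missing values")
    meta[[cc]] <- v
  }
  for (cc in c("age", "tnm_t", "tnm_n", "tnm_m")) {
    v <- suppressWarnings(as.numeric(meta[[cc]]))
    if (anyNA(v) || any(v < 0))
      stop("metadata column '", cc, "' must be non-negative numeric")
    meta[[cc]] <- v
  }
  healthy <- meta$group == "healthy"
  if (any(healthy & meta$histology != "none"))
    stop("healthy sample '", meta$sample_id[which(healthy & meta$histology != "none")[1]],
         "' has a histology label; healthy rows must use 'none'")
  if (any(healthy & meta$localization != "none"))
    stop("healthy sample '", meta$sample_id[which(healthy & meta$localization != "none")[1]],
         "' has a tumor localization; healthy rows must use 'none'")
  if (any(healthy & meta$treatment_status != "none"))
    stop("healthy sample '", meta$sample_id[which(healthy & meta$treatment_status != "none")[1]],
         "' has a treatment status; healthy rows must use 'none'")
  if (any(healthy & (meta$tnm_t > 0 | meta$tnm_n > 0 | meta$tnm_m > 0)))
    stop("healthy samples must have TNM fields 0")
  comorb <- as.matrix(meta[, COMORBIDITIES])
  if (any(healthy & rowSums(comorb) > 0))
    stop("comorbidity flags are recorded for lung cancer patients only; healthy sample '",
         meta$sample_id[which(healthy & rowSums(comorb) > 0)[1]], "' has a flag set")
  class(meta) <- c("breath_metadata", "data.frame")
  meta
}

#' Read a clinical metadata table from CSV
#' @param path CSV file path (gzip accepted).
#' @return validated metadata data.frame.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_metadata(df, path)
}

#' Write a clinical metadata table to CSV
#' @param meta validated metadata.
#' @param path output file path.
#' @export
write_metadata <- function(meta, path) {
  utils::write.csv(as.data.frame(meta), path, row.names = FALSE)
  invisible(path)
}

#' Parse a TNM staging code
#'
#' @param code character vector of codes like `"T3N2M0"`.
#' @return integer matrix with columns `t`, `n`, `m`.
#' @examples parse_tnm("T3N2M0")
#' @export
parse_tnm <- function(code) {
  m <- regmatches(code, regexec("^T([0-9]+)N([0-9]+)M([0-9]+)$", code))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad)) stop("malformed TNM code: ", code[which(bad)[1]])
  out <- t(vapply(m, function(g) as.integer(g[2:4]), integer(3)))
  colnames(out) <- c("t", "n", "m")
  out
}

#' Align breath, ambient and metadata tables
#'
#' Orders the ambient table and metadata to match the breath table sample
#' order. Each breath sample must map to exactly one ambient row — by
#' `sample_id` by default, or through a `mapping` data.frame
#' (`sample_id`, `ambient_id`) when one room-air sample served several
#' breath samples (e.g. one per sampling day). VOC columns are reconciled:
#' a breath VOC absent from the ambient table is retained with ambient area
#' 0 (with a warning); ambient-only VOCs are dropped (with a warning).
#'
#' @param breath breath [peak_table()].
#' @param ambient ambient [peak_table()].
#' @param meta validated metadata covering every breath sample.
#' @param mapping optional data.frame mapping breath `sample_id` to
#'   `ambient_id`.
#' @return list with elements `breath`, `ambient`, `meta`, all in breath
#'   sample order and with identical VOC columns; class `aligned_cohort`.
#' @export
align_cohort <- function(breath, ambient, meta, mapping = NULL) {
  stopifnot(inherits(breath, "peak_table"), inherits(ambient, "peak_table"))
  meta <- validate_metadata(as.data.frame(meta))
  ids <- rownames(breath)
  if (is.null(mapping)) {
    amb_ids <- ids
  } else {
    stopifnot(all(c("sample_id", "ambient_id") %in% names(mapping)))
    idx <- match(ids, mapping$sample_id)
    if (anyNA(idx))
      stop("no ambient mapping for breath sample '", ids[which(is.na(idx))[1]], "'")
    amb_ids <- as.character(mapping$ambient_id[idx])
  }
  amb_idx <- match(amb_ids, rownames(ambient))
  if (anyNA(amb_idx))
    stop("no ambient sample for breath sample '", ids[which(is.na(amb_idx))[1]], "'")
  meta_idx <- match(ids, meta$sample_id)
  if (anyNA(meta_idx))
    stop("no metadata for breath sample '", ids[which(is.na(meta_idx))[1]], "'")

  vocs <- colnames(breath)
  only_breath <- setdiff(vocs, colnames(ambient))
  only_amb <- setdiff(colnames(ambient), vocs)
  if (length(only_breath) > 0)
    warning("VOC(s) absent from ambient table, ambient area set to 0: ",
            paste(only_breath, collapse = ", "))
  if (length(only_amb) > 0)
    warning("ambient-only VOC(s) dropped: ", paste(only_amb, collapse = ", "))
  amb <- matrix(0, length(ids), length(vocs), dimnames = list(ids, vocs))
  common <- intersect(vocs, colnames(ambient))
  amb[, common] <- unclass(ambient)[amb_idx, common, drop = FALSE]

  out <- list(breath = peak_table(unclass(breath)[, vocs, drop = FALSE], "breath"),
              ambient = peak_table(amb, "ambient"),
              meta = meta[meta_idx, , drop = FALSE])
  rownames(out$meta) <- NULL
  class(out) <- "aligned_cohort"
  out
}

#' @export
print.aligned_cohort <- function(x, ...) {
  cat(sprintf("<aligned_cohort> %d samples (%d cancer / %d healthy), %d VOCs\n",
              nrow(x$breath), sum(x$meta$group == "cancer"),
              sum(x$meta$group == "healthy"), ncol(x$breath)))
  invisible(x)
}
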