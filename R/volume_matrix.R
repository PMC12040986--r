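#' Subject-by-observer volume matrix
#'
#' The complete-design container for a multi-observer volumetry study:
#' `n` subjects (rows) by `m` observers (columns), volumes in mm^3, no
#' missing cells, all volumes strictly positive.
#'
#' @param volumes numeric matrix (n x m) of volumes in mm^3.
#' @param subject_ids,observer_ids optional identifiers; default to the
#'   dimnames or `S1..Sn` / `O1..Om`.
#' @return An object of class `"volume_matrix"` (a numeric matrix with
#'   dimnames and class attribute).
#' @export
volume_matrix <- function(volumes, subject_ids = NULL, observer_ids = NULL) {
  volumes <- as.matrix(volumes)
  if (nrow(volumes) < 2L || ncol(volumes) < 2L)
    stop("insufficient data: need at least 2 subjects and 2 observers")
  if (any(!is.finite(volumes)))
    stop("invalid input: volume matrix must be complete (no missing cells)")
  if (any(volumes <= 0))
    stop("invalid input: all volumes must be > 0 mm^3")
  if (is.null(subject_ids))
    subject_ids <- rownames(volumes) %||% paste0("S", seq_len(nrow(volumes)))
  if (is.null(observer_ids))
    observer_ids <- colnames(volumes) %||% paste0("O", seq_len(ncol(volumes)))
  dimnames(volumes) <- list(as.character(subject_ids),
                            as.character(observer_ids))
  class(volumes) <- c("volume_matrix", "matrix")
  volumes
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @export
print.volume_matrix <- function(x, ...) {
  cat(sprintf("<volume_matrix> %d subjects x %d observers (mm^3)\n",
              nrow(x), ncol(x)))
  print(utils::head(unclass(x)), ...)
  if (nrow(x) > 6) cat(sprintf("... %d more subjects\n", nrow(x) - 6))
  invisible(x)
}

#' Read a volume matrix from CSV
#'
#' Expects a `subject_id` column plus one column per observer, volumes in
#' mm^3.
#'
#' @param file CSV path.
#' @return A [volume_matrix()].
#' @export
read_volume_matrix <- function(file) {
  df <- read.csv(file, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"subject_id" %in% names(df))
    stop("invalid input: CSV must have a 'subject_id' column")
  obs <- setdiff(names(df), "subject_id")
  m <- as.matrix(df[, obs, drop = FALSE])
  volume_matrix(m, subject_ids = df$subject_id, observer_ids = obs)
}

#' Write a volume matrix to CSV
#'
#' @param vm a [volume_matrix()].
#' @param file output CSV path.
#' @return `file`, invisibly.
#' @export
write_volume_matrix <- function(vm, file) {
  df <- data.frame(subject_id = rownames(vm), unclass(vm),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' Relative deviations from the per-subject observer mean
#'
#' For each subject the observers' mean volume is taken as the consensus,
#' and each observer's volume is expressed as a percent deviation from
#' it: `d_ij = 100 * (V_ij - Vbar_i) / Vbar_i`. By construction the
#' deviations of each subject sum to zero.
#'
#' @param vm a [volume_matrix()] (or coercible matrix).
#' @return An object of class `"deviation_table"`: list with
#'   `mean_volume` (named, mm^3), `deviations` (n x m percent matrix),
#'   `subject_ids`, `observer_ids`.
#' @export
relative_deviations <- function(vm) {
  if (!inherits(vm, "volume_matrix")) vm <- volume_matrix(vm)
  vbar <- rowMeans(vm)
  dev <- 100 * sweep(unclass(vm), 1, vbar, "/") - 100
  structure(
    list(mean_volume = setNames(vbar, rownames(vm)),
         deviations = dev,
         subject_ids = rownames(vm), observer_ids = colnames(vm)),
    class = "deviation_table")
}

#' @export
print.deviation_table <- function(x, ...) {
  cat(sprintf(
    "<deviation_table> %d subjects x %d observers; mean volume %.4g mm^3 (range %.4g-%.4g)\n",
    length(x$mean_volume), ncol(x$deviations), median(x$mean_volume),
    min(x$mean_volume), max(x$mean_volume)))
  invisible(x)
}

# Subset a deviation table to a set of subjects (rows), keeping structure.
subset_deviations <- function(dev, idx) {
  structure(
    list(mean_volume = dev$mean_volume[idx],
         deviations = dev$deviations[idx, , drop = FALSE],
         subject_ids = dev$subject_ids[idx], observer_ids = dev$observer_ids),
    class = "deviation_table")
}
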