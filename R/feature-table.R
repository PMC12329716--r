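# Container for an untargeted LC-MS feature table: a nonnegative intensity
# matrix (features x samples) plus per-feature metadata (m/z, retention
# time, MS2 fragment list, optional predicted formula and annotation level).

#' Construct a feature table
#'
#' @param intensities numeric matrix, features x samples, nonnegative, with
#'   rownames (feature ids) and colnames (sample ids).
#' @param meta data frame with columns `feature_id`, `mz`, `rt`, optionally
#'   `formula` (character, NA when no predicted composition), `ms2` (list
#'   column of numeric fragment m/z vectors, or semicolon-joined strings)
#'   and `annotation_level` (integer 1-3 or NA).
#' @return an object of class `feature_table`.
#' @export
feature_table <- function(intensities, meta) {
  stopifnot(is.matrix(intensities), is.numeric(intensities),
            !is.null(rownames(intensities)), !is.null(colnames(intensities)),
            is.data.frame(meta), all(c("feature_id", "mz", "rt") %in% names(meta)))
  if (anyDuplicated(rownames(intensities))) stop("duplicate feature ids")
  if (any(intensities < 0)) stop("intensities must be nonnegative")
  if (!setequal(meta$feature_id, rownames(intensities))) {
    stop("meta feature ids do not match intensity rownames")
  }
  if (any(meta$mz <= 0)) stop("m/z must be positive")
  meta <- meta[match(rownames(intensities), meta$feature_id), , drop = FALSE]
  rownames(meta) <- NULL
  if (is.null(meta$formula)) meta$formula <- NA_character_
  if (is.null(meta$annotation_level)) meta$annotation_level <- NA_integer_
  if (is.null(meta$ms2)) meta$ms2 <- replicate(nrow(meta), numeric(0),
                                               simplify = FALSE)
  if (is.character(meta$ms2)) meta$ms2 <- parse_ms2_strings(meta$ms2)
  lv <- meta$annotation_level
  if (any(!is.na(lv) & !(lv %in% 1:3))) {
    stop("annotation_level must be 1, 2 or 3 when present")
  }
  structure(list(intensities = intensities, meta = meta),
            class = "feature_table")
}

parse_ms2_strings <- function(x) {
  lapply(x, function(s) {
    if (is.na(s) || !nzchar(s)) return(numeric(0))
    as.numeric(strsplit(s, ";", fixed = TRUE)[[1]])
  })
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d features x %d samples\n",
              nrow(x$intensities), ncol(x$intensities)))
  n_f <- sum(!is.na(x$meta$formula))
  cat(sprintf("  %d features with predicted formula, %d with MS2 fragments\n",
              n_f, sum(lengths(x$meta$ms2) > 0)))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$intensities)

feature_ids <- function(ft) rownames(ft$intensities)

sample_ids <- function(ft) colnames(ft$intensities)

#' Subset a feature table by feature id
#'
#' @param ft a [feature_table()].
#' @param ids feature ids to keep, in the table's original order.
#' @return a `feature_table` restricted to `ids`.
#' @export
subset_features <- function(ft, ids) {
  keep <- feature_ids(ft)[feature_ids(ft) %in% ids]
  feature_table(ft$intensities[keep, , drop = FALSE],
                ft$meta[ft$meta$feature_id %in% keep, , drop = FALSE])
}
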