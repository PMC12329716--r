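# In-source fragment and halogen-artifact removal for untargeted LC-MS
# feature tables. The procedure: bin features by retention time, find
# co-eluting features whose raw intensities correlate near-perfectly,
# take the heaviest ion of each correlated group as the parent, and remove
# lighter group members whose m/z matches a parent MS2 fragment within a
# ppm tolerance; finally drop features whose predicted composition
# contains a halogen (implausible in natural peat organic matter).

#' Cleaning parameters
#'
#' @param rt_tolerance retention-time gap (same units as the RT column)
#'   joining features into one co-elution bin; default 0.005.
#' @param correlation_threshold minimum Pearson correlation (strict `>`) of
#'   raw intensities for two co-eluting features to be grouped; default 0.98.
#' @param ppm_tolerance maximum relative mass error (ppm) for a candidate
#'   fragment to match a parent MS2 fragment; default 5.
#' @param drop_halogens drop features whose predicted formula contains
#'   F, Cl, Br or I; default TRUE.
#' @return a `cleaning_params` list.
#' @export
cleaning_params <- function(rt_tolerance = 0.005,
                            correlation_threshold = 0.98,
                            ppm_tolerance = 5,
                            drop_halogens = TRUE) {
  stopifnot(rt_tolerance > 0,
            correlation_threshold > 0, correlation_threshold <= 1,
            ppm_tolerance > 0, is.logical(drop_halogens))
  structure(list(rt_tolerance = rt_tolerance,
                 correlation_threshold = correlation_threshold,
                 ppm_tolerance = ppm_tolerance,
                 drop_halogens = drop_halogens),
            class = "cleaning_params")
}

#' Bin features by retention time
#'
#' Single-linkage clustering on the RT axis: features are sorted by RT and a
#' new bin starts wherever the gap to the previous feature exceeds `tol`
#' (a gap equal to `tol` still joins). Bins partition the input and do not
#' depend on input order; RT ties are ordered by feature id.
#'
#' @param meta data frame with `feature_id` and `rt` columns.
#' @param tol positive RT tolerance.
#' @return list of character vectors of feature ids, one per bin.
#' @export
bin_by_rt <- function(meta, tol) {
  stopifnot(tol > 0)
  if (nrow(meta) == 0L) return(list())
  ord <- order(meta$rt, meta$feature_id)
  rt <- meta$rt[ord]
  ids <- meta$feature_id[ord]
  new_bin <- c(TRUE, diff(rt) > tol)
  split(ids, cumsum(new_bin))
}

#' Co-eluting feature pairs by intensity correlation
#'
#' All unordered pairs within one RT bin whose Pearson correlation of raw
#' intensities across all samples strictly exceeds `threshold`. Pairs
#' involving a zero-variance (constant) feature are excluded, since their
#' correlation is undefined.
#'
#' @param ids feature ids in the bin.
#' @param ft a [feature_table()] containing those features.
#' @param threshold correlation threshold (strict `>`).
#' @return data frame with columns `a`, `b`, `r` (possibly 0 rows).
#' @export
coeluting_pairs <- function(ids, ft, threshold) {
  stopifnot(all(ids %in% feature_ids(ft)))
  if (ncol(ft$intensities) < 3L) {
    stop("correlation grouping needs at least 3 samples")
  }
  ids <- sort(ids)
  out <- data.frame(a = character(0), b = character(0), r = numeric(0))
  if (length(ids) < 2L) return(out)
  x <- ft$intensities[ids, , drop = FALSE]
  ok <- apply(x, 1L, stats::sd) > 0
  ids <- ids[ok]
  if (length(ids) < 2L) return(out)
  cm <- stats::cor(t(ft$intensities[ids, , drop = FALSE]))
  hit <- which(upper.tri(cm) & cm > threshold, arr.ind = TRUE)
  if (nrow(hit)) {
    out <- data.frame(a = ids[hit[, 1L]], b = ids[hit[, 2L]],
                      r = cm[hit])
    out <- out[order(out$a, out$b), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Match a candidate fragment ion against a parent's MS2 spectrum
#'
#' Finds the parent MS2 fragment m/z closest in relative terms to the
#' candidate ion's m/z; a match is returned when that relative difference is
#' at most `ppm` (computed as |delta m| / fragment m/z * 1e6).
#'
#' @param candidate list/row with `mz` (the candidate fragment ion).
#' @param parent list/row with `mz` and `ms2` (numeric fragment m/z vector).
#' @param ppm ppm tolerance.
#' @return `NULL` if no fragment qualifies (or the parent has no MS2),
#'   otherwise a list with `fragment_mz` and `ppm_error`.
#' @export
match_fragment_to_parent <- function(candidate, parent, ppm) {
  if (candidate$mz >= parent$mz) {
    stop("candidate m/z must be strictly below the parent m/z")
  }
  frags <- parent$ms2
  if (is.list(frags)) frags <- frags[[1L]]
  if (length(frags) == 0L) return(NULL)
  err <- abs(frags - candidate$mz) / frags * 1e6
  i <- which.min(err)
  if (err[i] > ppm) return(NULL)
  list(fragment_mz = frags[i], ppm_error = err[i])
}

#' Remove features with halogen-containing predicted formulas
#'
#' Features whose predicted composition contains F, Cl, Br or I are flagged
#' for removal; features without a predicted formula are kept (absence of a
#' prediction is not evidence of halogens).
#'
#' @param meta data frame with `feature_id` and `formula` columns.
#' @return list with `kept` and `removed` feature-id vectors.
#' @export
remove_halogen_features <- function(meta) {
  halo <- vapply(meta$formula, function(f) {
    if (is.na(f) || !nzchar(f)) FALSE else contains_halogen(f)
  }, logical(1))
  list(kept = meta$feature_id[!halo], removed = meta$feature_id[halo])
}

# Connected components of an undirected graph given as an edge data frame
# over the node ids; returns list of node-id vectors.
connected_components <- function(nodes, edges) {
  comp <- stats::setNames(seq_along(nodes), nodes)
  find <- function(i) {
    while (comp[[i]] != i) i <- comp[[i]]
    i
  }
  for (k in seq_len(nrow(edges))) {
    i <- find(match(edges$a[k], nodes))
    j <- find(match(edges$b[k], nodes))
    if (i != j) comp[j] <- i
  }
  roots <- vapply(seq_along(nodes), find, integer(1))
  unname(split(nodes, roots))
}

#' Clean a feature table of in-source fragments and halogen artifacts
#'
#' Full artifact-removal procedure: RT binning ([bin_by_rt()]), co-elution
#' correlation grouping ([coeluting_pairs()], correlated groups taken as
#' connected components), parent = heaviest ion of each group (m/z ties
#' broken by feature id), removal of lighter group members whose m/z
#' matches a parent MS2 fragment within the ppm tolerance
#' ([match_fragment_to_parent()]), then halogen-formula removal
#' ([remove_halogen_features()]). Every input feature is accounted for
#' exactly once in the report.
#'
#' @param ft a [feature_table()].
#' @param params a [cleaning_params()].
#' @return list with `table` (the cleaned `feature_table`) and `report`, a
#'   `cleaning_report` with `removed_as_fragment` (data frame: fragment_id,
#'   parent_id, r, ppm_error), `removed_as_halogen` and `retained` id
#'   vectors.
#' @export
clean_features <- function(ft, params = cleaning_params()) {
  stopifnot(inherits(ft, "feature_table"))
  meta <- ft$meta
  frag_rows <- list()
  for (bin in bin_by_rt(meta, params$rt_tolerance)) {
    if (length(bin) < 2L) next
    pairs <- coeluting_pairs(bin, ft, params$correlation_threshold)
    if (nrow(pairs) == 0L) next
    nodes <- sort(unique(c(pairs$a, pairs$b)))
    for (grp in connected_components(nodes, pairs)) {
      gm <- meta[match(grp, meta$feature_id), , drop = FALSE]
      gm <- gm[order(-gm$mz, gm$feature_id), , drop = FALSE]
      parent <- list(feature_id = gm$feature_id[1L], mz = gm$mz[1L],
                     ms2 = gm$ms2[[1L]])
      for (i in seq_len(nrow(gm))[-1L]) {
        if (gm$mz[i] >= parent$mz) next
        hit <- match_fragment_to_parent(list(mz = gm$mz[i]), parent,
                                        params$ppm_tolerance)
        if (is.null(hit)) next
        r <- stats::cor(ft$intensities[gm$feature_id[i], ],
                        ft$intensities[parent$feature_id, ])
        frag_rows[[length(frag_rows) + 1L]] <-
          data.frame(fragment_id = gm$feature_id[i],
                     parent_id = parent$feature_id,
                     r = r, ppm_error = hit$ppm_error)
      }
    }
  }
  removed_as_fragment <- if (length(frag_rows)) {
    do.call(rbind, frag_rows)
  } else {
    data.frame(fragment_id = character(0), parent_id = character(0),
               r = numeric(0), ppm_error = numeric(0))
  }
  removed_as_fragment <-
    removed_as_fragment[order(removed_as_fragment$fragment_id), ,
                        drop = FALSE]
  rownames(removed_as_fragment) <- NULL

  left <- setdiff(meta$feature_id, removed_as_fragment$fragment_id)
  if (params$drop_halogens) {
    halo <- remove_halogen_features(meta[meta$feature_id %in% left, ,
                                         drop = FALSE])
    removed_as_halogen <- sort(halo$removed)
  } else {
    removed_as_halogen <- character(0)
  }
  retained <- setdiff(left, removed_as_halogen)
  retained <- feature_ids(ft)[feature_ids(ft) %in% retained]

  report <- structure(list(removed_as_fragment = removed_as_fragment,
                           removed_as_halogen = removed_as_halogen,
                           retained = retained),
                      class = "cleaning_report")
  list(table = subset_features(ft, retained), report = report)
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat(sprintf(paste0("<cleaning_report> %d retained, %d removed as ",
                     "in-source fragments, %d removed as halogen artifacts\n"),
              length(x$retained), nrow(x$removed_as_fragment),
              length(x$removed_as_halogen)))
  invisible(x)
}
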