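# Simplified signed weighted co-expression network analysis relating
# metabolite features to methane production: signed adjacency raised to a
# soft-thresholding power (default 14), topological overlap, average-
# linkage module detection with a static tree cut, module eigengenes, and
# eigengene-methane Pearson correlation with top-feature retention.

#' Network parameters
#'
#' @param beta soft-thresholding power (positive integer, default 14).
#' @param min_module_size smallest cluster kept as a module (default 30);
#'   smaller clusters are left unassigned ("grey").
#' @param cut_height flat-cut height on the 1-TOM dendrogram, in (0, 1]
#'   (default 0.995).
#' @param top_n number of members retained from each of the most
#'   positively and most negatively methane-correlated modules (default
#'   100).
#' @param require_annotation drop features without MS2 annotation before
#'   retention (default TRUE).
#' @param rank_by `"gas_spearman"` (default: per-feature Spearman with
#'   methane) or `"kme"` (member-eigengene correlation) for retention
#'   ranking.
#' @return a `network_params` list.
#' @export
network_params <- function(beta = 14L, min_module_size = 30L,
                           cut_height = 0.995, top_n = 100L,
                           require_annotation = TRUE,
                           rank_by = c("gas_spearman", "kme")) {
  rank_by <- match.arg(rank_by)
  stopifnot(beta >= 1, min_module_size >= 1, cut_height > 0,
            cut_height <= 1, top_n >= 1)
  structure(list(beta = as.integer(beta),
                 min_module_size = as.integer(min_module_size),
                 cut_height = cut_height, top_n = as.integer(top_n),
                 require_annotation = require_annotation,
                 rank_by = rank_by),
            class = "network_params")
}

#' Signed soft-thresholded adjacency
#'
#' a_ij = ((1 + r_ij) / 2)^beta, so anticorrelated features get near-zero
#' adjacency (the "signed" network convention); the diagonal is set to 0
#' for connectivity computations.
#'
#' @param corr symmetric feature x feature Pearson correlation matrix with
#'   unit diagonal.
#' @param beta soft-thresholding power.
#' @return adjacency matrix in `[0, 1]` with zero diagonal.
#' @export
signed_adjacency <- function(corr, beta = 14L) {
  stopifnot(is.matrix(corr), nrow(corr) == ncol(corr))
  if (any(abs(corr) > 1 + 1e-12)) stop("correlations must lie in [-1, 1]")
  corr <- pmin(pmax(corr, -1), 1)
  a <- ((1 + corr) / 2)^beta
  diag(a) <- 0
  a
}

#' Topological overlap matrix
#'
#' TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij), with
#' k the row sums of the adjacency and TOM_ii = 1; a similarity that
#' rewards shared neighbourhoods on top of direct adjacency.
#'
#' @param a symmetric adjacency with zero diagonal and entries in [0, 1].
#' @return TOM similarity matrix in `[0, 1]`.
#' @export
topological_overlap <- function(a) {
  stopifnot(is.matrix(a), nrow(a) == ncol(a), all(a >= 0), all(a <= 1),
            all(diag(a) == 0))
  k <- rowSums(a)
  num <- a %*% a + a
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  diag(tom) <- 1
  tom
}

#' Detect modules by average-linkage clustering of 1-TOM
#'
#' Average-linkage hierarchical clustering on dissimilarity 1-TOM with a
#' flat cut at `cut_height`; clusters smaller than `min_module_size` are
#' left unassigned (`"grey"`). Module labels (`"M1"`, `"M2"`, ...) are
#' deterministic: ordered by decreasing size, ties by the
#' lexicographically smallest member id.
#'
#' @param tom TOM similarity matrix with feature ids as dimnames.
#' @param params a [network_params()].
#' @return named character vector: feature id -> module label.
#' @export
detect_modules <- function(tom, params = network_params()) {
  ids <- rownames(tom)
  if (is.null(ids)) ids <- paste0("F", seq_len(nrow(tom)))
  hc <- stats::hclust(stats::as.dist(1 - tom), method = "average")
  cl <- stats::cutree(hc, h = params$cut_height)
  names(cl) <- ids
  sizes <- table(cl)
  keep <- names(sizes)[sizes >= params$min_module_size]
  first_member <- vapply(keep, function(k) min(ids[cl == k]), character(1))
  keep <- keep[order(-as.integer(sizes[keep]), first_member)]
  labels <- stats::setNames(rep("grey", length(ids)), ids)
  for (i in seq_along(keep)) {
    labels[cl == keep[i]] <- paste0("M", i)
  }
  labels
}

#' Module eigengene
#'
#' First principal component scores of the standardized member submatrix
#' (samples x members), sign-oriented so that the mean member-eigengene
#' correlation is positive.
#'
#' @param x transformed feature x sample matrix (or [feature_table()]).
#' @param members feature ids of the module (>= 2).
#' @return numeric per-sample eigengene vector.
#' @export
module_eigengene <- function(x, members) {
  if (inherits(x, "feature_table")) x <- x$intensities
  if (length(members) < 2L) stop("a module eigengene needs >= 2 members")
  sub <- t(x[members, , drop = FALSE])          # samples x members
  sub <- scale(sub)
  sub[, apply(sub, 2L, function(v) any(!is.finite(v)))] <- 0
  sv <- svd(sub, nu = 1L, nv = 1L)
  eg <- drop(sv$u * sv$d[1L])
  mc <- mean(apply(sub, 2L, function(v) {
    if (stats::sd(v) == 0 || stats::sd(eg) == 0) 0 else stats::cor(v, eg)
  }))
  if (mc < 0) eg <- -eg
  stats::setNames(eg, colnames(x))
}

#' Correlate modules with methane and retain top features
#'
#' Computes each module's eigengene and its Pearson correlation with the
#' per-sample methane totals; for the most positively and most negatively
#' correlated modules, retains the `top_n` members ranked by absolute
#' feature-methane Spearman correlation (or kME), after optionally
#' dropping features without MS2 annotation. Ties are broken by feature
#' id.
#'
#' @param x transformed feature x sample matrix or [feature_table()] (a
#'   feature table also supplies annotation levels for the filter).
#' @param modules named module assignment from [detect_modules()].
#' @param gas per-sample methane totals aligned to the columns of `x`.
#' @param params a [network_params()].
#' @return list of `module_result` entries (one per non-grey module):
#'   `module_id`, `members`, `eigengene`, `gas_correlation`,
#'   `member_gas_rho`, and `retained` (non-NULL only for the extreme
#'   modules).
#' @export
correlate_modules_with_gas <- function(x, modules, gas,
                                       params = network_params()) {
  ft <- NULL
  if (inherits(x, "feature_table")) {
    ft <- x
    x <- x$intensities
  }
  stopifnot(length(gas) == ncol(x))
  if (stats::sd(gas) == 0) {
    warning("gas vector is constant; module-gas correlations undefined")
  }
  mods <- sort(setdiff(unique(modules), "grey"))
  res <- lapply(mods, function(m) {
    members <- sort(names(modules)[modules == m])
    eg <- module_eigengene(x, members)
    r <- if (stats::sd(gas) > 0 && stats::sd(eg) > 0) stats::cor(eg, gas)
         else NA_real_
    # the constant-gas case is warned once above, not per module
    rho <- suppressWarnings(
      spearman_gas_correlation(x[members, , drop = FALSE], gas))
    structure(list(module_id = m, members = members, eigengene = eg,
                   gas_correlation = r, member_gas_rho = rho,
                   retained = NULL),
              class = "module_result")
  })
  names(res) <- mods
  rs <- vapply(res, function(m) m$gas_correlation, numeric(1))
  if (length(res) && any(!is.na(rs))) {
    extremes <- unique(c(names(res)[which.max(rs)],
                         names(res)[which.min(rs)]))
    for (m in extremes) {
      cand <- res[[m]]$members
      if (params$require_annotation && !is.null(ft)) {
        # MS2-based annotation = confidence level 1 or 2 (level 3 is
        # formula-only, no MS2 identity)
        lv <- ft$meta$annotation_level[match(cand, ft$meta$feature_id)]
        cand <- cand[!is.na(lv) & lv <= 2L]
      }
      score <- if (params$rank_by == "kme") {
        vapply(cand, function(f) {
          abs(stats::cor(x[f, ], res[[m]]$eigengene))
        }, numeric(1))
      } else {
        abs(res[[m]]$member_gas_rho[cand])
      }
      ord <- order(-score, cand)
      res[[m]]$retained <- cand[ord][seq_len(min(params$top_n,
                                                 length(cand)))]
    }
  }
  res
}

#' End-to-end module analysis of a transformed feature table
#'
#' Pearson correlation across samples, signed adjacency at `beta`,
#' topological overlap, static-cut module detection, and module-methane
#' correlation with top-feature retention.
#'
#' @param x transformed feature x sample matrix or [feature_table()].
#' @param gas per-sample methane totals.
#' @param params a [network_params()].
#' @return list with `modules` (assignment vector) and `results` (from
#'   [correlate_modules_with_gas()]).
#' @export
methane_module_analysis <- function(x, gas, params = network_params()) {
  m <- if (inherits(x, "feature_table")) x$intensities else x
  keep <- apply(m, 1L, stats::sd) > 0
  m_use <- m[keep, , drop = FALSE]
  corr <- stats::cor(t(m_use))
  tom <- topological_overlap(signed_adjacency(corr, params$beta))
  modules <- detect_modules(tom, params)
  all_mod <- stats::setNames(rep("grey", nrow(m)), rownames(m))
  all_mod[names(modules)] <- modules
  results <- correlate_modules_with_gas(x, all_mod, gas, params)
  list(modules = all_mod, results = results)
}
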