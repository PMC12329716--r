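# Normalization and per-feature statistics for cleaned LC-MS intensities:
# generalized log transform, Pareto scaling, per-feature linear models with
# per-timepoint habitat contrasts and BH correction, PCA, and Spearman
# correlation of raw intensities with methane totals.

#' Generalized log transform
#'
#' Transforms nonnegative intensities so that zeros are handled and
#' heteroscedasticity is tamed. Two modes:
#' \describe{
#'   \item{standard}{x' = log2((x + sqrt(x^2 + a^2)) / 2), the usual
#'     generalized logarithm (default).}
#'   \item{literal}{x' = sqrt(x^2 + a^2) / 2, an offset-magnitude variant
#'     retained for auditing pipelines that applied it verbatim; note it is
#'     not logarithmic.}
#' }
#' The offset `a` ("lambda") defaults to the minimum nonzero intensity
#' across the whole dataset.
#'
#' @param ft a [feature_table()] or numeric matrix of intensities.
#' @param a transform offset; `NULL` (default) auto-derives the dataset
#'   minimum nonzero value.
#' @param mode `"standard"` or `"literal"`.
#' @return object of the same type with transformed intensities.
#' @export
glog_transform <- function(ft, a = NULL, mode = c("standard", "literal")) {
  mode <- match.arg(mode)
  x <- if (inherits(ft, "feature_table")) ft$intensities else ft
  stopifnot(is.numeric(x), all(x >= 0))
  if (is.null(a)) {
    nz <- x[x > 0]
    if (length(nz) == 0L) stop("all intensities are zero; cannot derive a")
    a <- min(nz)
  }
  stopifnot(a >= 0)
  if (mode == "standard" && a == 0 && any(x == 0)) {
    stop("a = 0 with zero intensities present: log of 0 undefined")
  }
  y <- switch(mode,
              standard = log2((x + sqrt(x^2 + a^2)) / 2),
              literal = sqrt(x^2 + a^2) / 2)
  if (inherits(ft, "feature_table")) {
    ft$intensities <- y
    ft
  } else {
    y
  }
}

#' Pareto scaling
#'
#' Divides each feature row by the square root of its standard deviation
#' (n-1 denominator) across all samples, down-weighting large-intensity
#' features less aggressively than unit-variance scaling. Zero-variance
#' rows pass through unchanged.
#'
#' @param ft a [feature_table()] or numeric matrix (features x samples).
#' @return object of the same type, Pareto-scaled.
#' @export
pareto_scale <- function(ft) {
  x <- if (inherits(ft, "feature_table")) ft$intensities else ft
  if (ncol(x) < 2L) stop("Pareto scaling needs at least 2 samples")
  s <- apply(x, 1L, stats::sd)
  div <- ifelse(s > 0, sqrt(s), 1)
  y <- x / div
  if (inherits(ft, "feature_table")) {
    ft$intensities <- y
    ft
  } else {
    y
  }
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate control with monotonicity enforcement,
#' mapped back to input positions. A thin validating wrapper over
#' `stats::p.adjust(method = "BH")`.
#'
#' @param p vector of p-values in `[0, 1]`.
#' @return vector of q-values, same length and order.
#' @export
bh_adjust <- function(p) {
  stopifnot(is.numeric(p))
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' PCA scores on a feature table
#'
#' Column-mean-centred SVD principal component analysis of the
#' samples-by-features matrix. The sign of each component is fixed so that
#' its largest-magnitude loading is positive, making results reproducible
#' across platforms.
#'
#' @param ft a [feature_table()] or numeric matrix (features x samples).
#' @param n_components number of components to return.
#' @return list with `scores` (samples x PC), `loadings` (features x PC)
#'   and `explained_variance` (fractions, summing to <= 1).
#' @export
pca_scores <- function(ft, n_components = 2L) {
  x <- if (inherits(ft, "feature_table")) ft$intensities else ft
  xm <- t(x)                       # samples x features
  if (n_components > min(dim(xm))) {
    stop("n_components exceeds matrix rank bound min(samples, features)")
  }
  xc <- scale(xm, center = TRUE, scale = FALSE)
  sv <- svd(xc, nu = n_components, nv = n_components)
  d <- sv$d[seq_len(n_components)]
  flip <- vapply(seq_len(n_components), function(j) {
    v <- sv$v[, j]
    if (v[which.max(abs(v))] < 0) -1 else 1
  }, numeric(1))
  scores <- sweep(sv$u %*% diag(d, n_components), 2L, flip, `*`)
  loadings <- sweep(sv$v, 2L, flip, `*`)
  rownames(scores) <- rownames(xm)
  rownames(loadings) <- colnames(xm)
  colnames(scores) <- colnames(loadings) <-
    paste0("PC", seq_len(n_components))
  tot <- sum(xc^2)
  ev <- if (tot > 0) d^2 / tot else rep(0, n_components)
  list(scores = scores, loadings = loadings, explained_variance = ev)
}

#' Spearman correlation of features with methane totals
#'
#' Rank correlation (average ranks for ties) between each feature's raw
#' intensity and the per-sample methane totals, used to validate network
#' module relationships against the untransformed data.
#'
#' @param ft a [feature_table()] or numeric matrix (features x samples).
#' @param gas numeric vector of per-sample gas totals, aligned to samples.
#' @return named numeric vector of rho per feature; all-`NA` with a warning
#'   if `gas` is constant (rank correlation undefined).
#' @export
spearman_gas_correlation <- function(ft, gas) {
  x <- if (inherits(ft, "feature_table")) ft$intensities else ft
  stopifnot(length(gas) == ncol(x))
  if (length(gas) < 3L) stop("need at least 3 paired observations")
  out <- stats::setNames(rep(NA_real_, nrow(x)), rownames(x))
  if (stats::sd(gas) == 0) {
    warning("gas vector is constant; Spearman correlation undefined")
    return(out)
  }
  rg <- rank(gas)
  for (i in seq_len(nrow(x))) {
    xi <- x[i, ]
    if (stats::sd(xi) > 0) out[i] <- stats::cor(rank(xi), rg)
  }
  out
}

# Relabel each habitat's final sampling day as one shared "final" level so
# habitats harvested on different days (e.g. bog day 28, fen day 35) are
# contrasted at a common endpoint.
align_final_day <- function(design) {
  day <- as.character(design$day)
  for (h in unique(design$habitat)) {
    sel <- design$habitat == h
    dnum <- suppressWarnings(as.numeric(day[sel]))
    if (all(!is.na(dnum))) day[sel][dnum == max(dnum)] <- "final"
  }
  day
}

#' Per-feature linear models with per-timepoint habitat contrasts
#'
#' Fits, for every feature, an ordinary least squares model of transformed
#' intensity on day (categorical), habitat, and their interaction, then
#' estimates the between-habitat difference at each timepoint with t-based
#' p-values and Benjamini-Hochberg correction applied across features
#' within each timepoint (optionally pooled across all timepoints).
#'
#' @param ft a [feature_table()] or matrix of transformed, scaled
#'   intensities (features x samples).
#' @param design data frame with `sample_id`, `habitat` (two levels) and
#'   `day` columns, one row per sample, in sample order.
#' @param align_final relabel each habitat's last day as a shared `"final"`
#'   level (default TRUE); needed when habitats end on different days.
#' @param bh_family `"per_timepoint"` (default) or `"pooled"`: the family
#'   within which BH correction is applied.
#' @return data frame with columns `feature_id`, `timepoint`, `estimate`
#'   (habitat difference, second level minus first, on the transformed
#'   scale), `p_value`, `q_value`.
#' @export
fit_feature_models <- function(ft, design, align_final = TRUE,
                               bh_family = c("per_timepoint", "pooled")) {
  bh_family <- match.arg(bh_family)
  x <- if (inherits(ft, "feature_table")) ft$intensities else ft
  stopifnot(ncol(x) == nrow(design),
            all(c("sample_id", "habitat", "day") %in% names(design)))
  hab <- factor(design$habitat)
  if (nlevels(hab) != 2L) stop("design must contain exactly two habitats")
  day <- if (align_final) align_final_day(design) else as.character(design$day)
  dnum <- suppressWarnings(as.numeric(day))
  lev <- if (all(!is.na(dnum))) as.character(sort(unique(dnum))) else {
    num <- sort(unique(dnum[!is.na(dnum)]))
    c(as.character(num), sort(setdiff(unique(day), as.character(num))))
  }
  day <- factor(day, levels = lev)

  cell <- table(day, hab)
  if (any(cell == 0L)) {
    bad <- which(cell == 0L, arr.ind = TRUE)[1L, ]
    stop(sprintf("design cell empty: day %s, habitat %s",
                 rownames(cell)[bad[1L]], colnames(cell)[bad[2L]]))
  }

  X <- stats::model.matrix(~ day * hab)
  XtXi <- solve(crossprod(X))
  df_res <- nrow(X) - ncol(X)
  if (df_res < 1L) stop("no residual degrees of freedom")
  H <- XtXi %*% t(X)
  Y <- t(x)                                # samples x features
  B <- H %*% Y                             # coef x features
  E <- Y - X %*% B
  sigma2 <- colSums(E^2) / df_res

  # contrast vector for (habitat level 2 - level 1) at each timepoint
  contrasts <- lapply(levels(day), function(d) {
    grid2 <- data.frame(day = factor(d, levels = levels(day)),
                        hab = factor(levels(hab)[2], levels = levels(hab)))
    grid1 <- data.frame(day = factor(d, levels = levels(day)),
                        hab = factor(levels(hab)[1], levels = levels(hab)))
    drop(stats::model.matrix(~ day * hab, grid2) -
           stats::model.matrix(~ day * hab, grid1))
  })
  names(contrasts) <- levels(day)

  flat <- apply(x, 1L, stats::sd) == 0  # no contrast information
  res <- lapply(names(contrasts), function(d) {
    cv <- contrasts[[d]]
    est <- drop(crossprod(cv, B))
    se <- sqrt(sigma2 * drop(crossprod(cv, XtXi %*% cv)))
    tt <- ifelse(se > 0, est / se, 0)
    p <- 2 * stats::pt(-abs(tt), df_res)
    est[flat] <- 0
    p[flat] <- 1
    data.frame(feature_id = rownames(x), timepoint = d,
               estimate = est, p_value = p, row.names = NULL)
  })
  out <- do.call(rbind, res)
  if (bh_family == "per_timepoint") {
    out$q_value <- stats::ave(out$p_value, out$timepoint,
                              FUN = bh_adjust)
  } else {
    out$q_value <- bh_adjust(out$p_value)
  }
  out
}
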