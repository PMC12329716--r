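# MAG (metagenome-assembled genome) activity and pathway-encoding rules:
# a MAG is active in a sample when its summed transcript count exceeds a
# threshold (default 15, strict), and an active MAG encodes a pathway when
# its gene catalog covers at least 60% of the pathway's steps.

#' Curation parameters
#'
#' @param activity_threshold transcript-count threshold; a MAG is active
#'   when its total in a sample is strictly greater (default 15).
#' @param encoding_fraction minimum fraction of pathway steps covered for
#'   a MAG to encode the pathway, inclusive (default 0.60).
#' @param complex_mode `"all"` (default: a complex step requires every
#'   subunit) or `"any"` (any one subunit suffices).
#' @return a `curation_params` list.
#' @export
curation_params <- function(activity_threshold = 15L,
                            encoding_fraction = 0.60,
                            complex_mode = c("all", "any")) {
  complex_mode <- match.arg(complex_mode)
  stopifnot(activity_threshold >= 0, encoding_fraction > 0,
            encoding_fraction <= 1)
  structure(list(activity_threshold = activity_threshold,
                 encoding_fraction = encoding_fraction,
                 complex_mode = complex_mode),
            class = "curation_params")
}

#' Active MAGs per sample
#'
#' A MAG is active in a sample iff the total transcript count over all its
#' genes in that sample is strictly greater than the threshold.
#'
#' @param counts gene x sample count matrix.
#' @param catalog data frame with `gene_id`, `mag_id` covering every gene.
#' @param params a [curation_params()].
#' @return named list: sample id -> character vector of active MAG ids.
#' @export
active_mags <- function(counts, catalog, params = curation_params()) {
  mag <- catalog$mag_id[match(rownames(counts), catalog$gene_id)]
  if (any(is.na(mag))) {
    stop("gene(s) without MAG assignment: ",
         paste(utils::head(rownames(counts)[is.na(mag)]), collapse = ", "))
  }
  totals <- rowsum(counts, group = mag)       # mag x sample
  lapply(stats::setNames(seq_len(ncol(totals)), colnames(totals)),
         function(j) {
           sort(rownames(totals)[totals[, j] > params$activity_threshold])
         })
}

# Is an AST node satisfied by a KO set?  Steps need any one alternative;
# complexes need all subunits ("all" mode) or any ("any"); a nested
# parenthesised expression needs all of its steps.
node_satisfied <- function(node, ko_set, complex_mode) {
  switch(node$type,
         ko = node$ko %in% ko_set,
         complex = {
           s <- vapply(node$members, node_satisfied, logical(1),
                       ko_set = ko_set, complex_mode = complex_mode)
           if (complex_mode == "all") all(s) else any(s)
         },
         step = any(vapply(node$alts, node_satisfied, logical(1),
                           ko_set = ko_set, complex_mode = complex_mode)),
         expr = all(vapply(node$steps, node_satisfied, logical(1),
                           ko_set = ko_set, complex_mode = complex_mode)))
}

#' Is a pathway encoded by a MAG's KO set?
#'
#' Counts the pathway steps satisfied by the KO set and flags the pathway
#' encoded when satisfied steps / total steps >= `fraction` (inclusive).
#' Encoding is genomic potential: it depends on annotation only, not on
#' expression level.
#'
#' @param ko_set character vector of KO ids annotated in the MAG.
#' @param ast a `pathway_ast`.
#' @param fraction minimum encoded-step fraction (default 0.60).
#' @param complex_mode `"all"` or `"any"` subunit rule for complexes.
#' @return list with `encoded` (flag), `encoded_steps`, `total_steps`.
#' @export
pathway_encoded <- function(ko_set, ast, fraction = 0.60,
                            complex_mode = c("all", "any")) {
  complex_mode <- match.arg(complex_mode)
  ast <- unclass(ast)
  sat <- vapply(ast$steps, node_satisfied, logical(1),
                ko_set = ko_set, complex_mode = complex_mode)
  list(encoded = sum(sat) / length(sat) >= fraction,
       encoded_steps = sum(sat), total_steps = length(sat))
}

#' Per-MAG activity, encoding and pathway-expression profiles
#'
#' Applies the activity rule, evaluates pathway encoding for every MAG
#' active in at least one sample, and computes per-MAG pathway expression
#' from geTMM-normalized counts.
#'
#' @param counts gene x sample count matrix.
#' @param catalog data frame with `gene_id`, `mag_id`, `ko`, `length_bp`.
#' @param defs pathway definitions with `pathway_id` and `ast` columns.
#' @param params a [curation_params()].
#' @param normalized optional precomputed gene x sample normalized matrix;
#'   default runs [getmm_normalize()].
#' @return list of `mag_profile` objects, one per active MAG: `mag_id`,
#'   `active_in`, `encoded` (named logical), `expression` (pathway x
#'   sample matrix).
#' @export
mag_profiles <- function(counts, catalog, defs,
                         params = curation_params(), normalized = NULL) {
  act <- active_mags(counts, catalog, params)
  mags <- sort(unique(unlist(act)))
  if (is.null(normalized)) {
    normalized <- getmm_normalize(counts, catalog)$normalized
  }
  lapply(stats::setNames(mags, mags), function(m) {
    kos <- unique(catalog$ko[catalog$mag_id == m & !is.na(catalog$ko) &
                               nzchar(catalog$ko)])
    enc <- vapply(defs$ast, function(a) {
      pathway_encoded(kos, a, params$encoding_fraction,
                      params$complex_mode)$encoded
    }, logical(1))
    names(enc) <- defs$pathway_id
    kom <- ko_expression(normalized, catalog, scope = m)
    expr <- pathway_scores(defs, kom)
    structure(list(mag_id = m,
                   active_in = names(act)[vapply(act, function(s) m %in% s,
                                                 logical(1))],
                   encoded = enc, expression = expr),
              class = "mag_profile")
  })
}

#' Proportion of active MAGs encoding a pathway
#'
#' Encoded-and-active count over active count. The denominator is the set
#' of MAGs active in at least one sample of the group under study (all
#' profiles passed in).
#'
#' @param profiles list of `mag_profile` objects (e.g. restricted to one
#'   habitat's samples).
#' @param pathway_id pathway to evaluate.
#' @return fraction in `[0, 1]`; `NA` with a warning when no MAG is
#'   active.
#' @export
encoding_proportion <- function(profiles, pathway_id) {
  active <- vapply(profiles, function(p) length(p$active_in) > 0,
                   logical(1))
  if (!any(active)) {
    warning("no active MAGs: encoding proportion undefined")
    return(NA_real_)
  }
  enc <- vapply(profiles[active], function(p) {
    isTRUE(p$encoded[[pathway_id]])
  }, logical(1))
  sum(enc) / sum(active)
}

#' Two-group Wilcoxon rank-sum comparison
#'
#' Two-sided Mann-Whitney/Wilcoxon rank-sum test, exact when the combined
#' sample size is at most 20 and there are no ties, otherwise the normal
#' approximation with tie and continuity corrections.
#'
#' @param values_a,values_b numeric vectors (both nonempty).
#' @return list with `statistic` (U for the first group) and `p_value`.
#' @export
wilcoxon_habitat_test <- function(values_a, values_b) {
  stopifnot(length(values_a) > 0, length(values_b) > 0)
  ties <- anyDuplicated(c(values_a, values_b)) > 0
  exact <- (length(values_a) + length(values_b)) <= 20 && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(values_a, values_b, alternative = "two.sided",
                       exact = exact, correct = TRUE)
  )
  list(statistic = unname(wt$statistic), p_value = wt$p.value)
}

#' Per-timepoint coupling of oxidative and fermentative expression
#'
#' For each MAG at a timepoint: x = summed expression of the oxidative
#' pathways (e.g. ED + EMP glycolysis), y = summed fermentation-pathway
#' expression; the statistic is the Pearson correlation over MAGs,
#' capturing how tightly electron-generating and electron-consuming
#' metabolism are coupled within genomes.
#'
#' @param profiles list of `mag_profile` objects.
#' @param oxidative_ids,fermentation_ids pathway id vectors.
#' @param design data frame with `sample_id` and `day` describing the
#'   columns of the profile expression matrices.
#' @return data frame with `day`, `n_mags`, `r` (`NA` with a warning when
#'   fewer than 3 MAGs are active at a timepoint).
#' @export
mag_redox_coupling <- function(profiles, oxidative_ids, fermentation_ids,
                               design) {
  days <- unique(design$day)
  out <- lapply(days, function(d) {
    smp <- design$sample_id[design$day == d]
    use <- Filter(function(p) any(p$active_in %in% smp), profiles)
    if (length(use) < 3L) {
      warning(sprintf("day %s: fewer than 3 active MAGs, r undefined", d))
      return(data.frame(day = d, n_mags = length(use), r = NA_real_))
    }
    x <- vapply(use, function(p) {
      sum(p$expression[oxidative_ids, smp, drop = FALSE])
    }, numeric(1))
    y <- vapply(use, function(p) {
      sum(p$expression[fermentation_ids, smp, drop = FALSE])
    }, numeric(1))
    r <- if (stats::sd(x) > 0 && stats::sd(y) > 0) stats::cor(x, y)
         else NA_real_
    data.frame(day = d, n_mags = length(use), r = r)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
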