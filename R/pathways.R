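# KEGG-style pathway logical expressions and pathway-level expression.
#
# Grammar (loosest to tightest binding): whitespace separates sequential
# steps; ',' separates alternative enzymes within a step; '+' joins the
# subunits of a complex; parentheses group. Scoring: alternatives are
# summed (substitutable routes add up), complex subunits are averaged
# (a complex is limited by its average subunit expression), and the
# pathway score is the mean over its steps.

pw_token_re <- "[A-Za-z][A-Za-z0-9_.:]*"

tokenize_pathway <- function(expression) {
  toks <- list()
  i <- 1L
  n <- nchar(expression)
  while (i <= n) {
    ch <- substr(expression, i, i)
    if (grepl("^\\s$", ch)) {
      j <- i
      while (j <= n && grepl("^\\s$", substr(expression, j, j))) j <- j + 1L
      toks[[length(toks) + 1L]] <- list(type = "ws", pos = i)
      i <- j
    } else if (ch %in% c("(", ")", ",", "+")) {
      toks[[length(toks) + 1L]] <- list(type = ch, pos = i)
      i <- i + 1L
    } else if (ch == "-") {
      # KEGG optional-component ('-K...') and gap ('--') markers: not part
      # of the plus/comma/step semantics; stripped with a warning.
      j <- i
      while (j <= n && substr(expression, j, j) == "-") j <- j + 1L
      m <- regmatches(substr(expression, j, n),
                      regexpr(paste0("^", pw_token_re), substr(expression, j, n)))
      warning("stripping non-essential component marker at position ", i,
              call. = FALSE)
      i <- j + if (length(m)) nchar(m) else 0L
    } else {
      rest <- substr(expression, i, n)
      m <- regmatches(rest, regexpr(paste0("^", pw_token_re), rest))
      if (!length(m)) {
        stop(sprintf("pathway expression parse error: unknown token at position %d", i))
      }
      toks[[length(toks) + 1L]] <- list(type = "ko", ko = m, pos = i)
      i <- i + nchar(m)
    }
  }
  toks
}

#' Parse a KEGG-style pathway logical expression
#'
#' Parses an expression over KO identifiers into an abstract syntax tree:
#' whitespace-separated sequential steps, comma-separated alternatives
#' within a step, plus-joined complex subunits, and parenthesised
#' sub-expressions. KEGG's `-K`/`--` non-essential markers are stripped
#' with a warning.
#'
#' @param expression nonempty expression string, e.g.
#'   `"K00001,K00002 K00003+K00004"`.
#' @return a `pathway_ast` object.
#' @examples
#' ast <- parse_pathway_logic("K00001,K00002 K00003+K00004")
#' serialize_pathway(ast)
#' @export
parse_pathway_logic <- function(expression) {
  stopifnot(is.character(expression), length(expression) == 1L)
  if (!nzchar(trimws(expression))) stop("pathway expression is empty")
  toks <- tokenize_pathway(expression)
  env <- new.env()
  env$toks <- toks
  env$i <- 1L
  peek <- function() if (env$i <= length(env$toks)) env$toks[[env$i]] else NULL
  advance <- function() env$i <- env$i + 1L
  err <- function(msg, tok = peek()) {
    pos <- if (is.null(tok)) nchar(expression) + 1L else tok$pos
    stop(sprintf("pathway expression parse error: %s at position %d", msg, pos))
  }
  skip_ws <- function() while (!is.null(peek()) && peek()$type == "ws") advance()

  parse_unit <- function() {
    tok <- peek()
    if (is.null(tok)) err("unexpected end of expression")
    if (tok$type == "ko") {
      advance()
      list(type = "ko", ko = tok$ko)
    } else if (tok$type == "(") {
      advance()
      node <- parse_expr()
      skip_ws()
      tok <- peek()
      if (is.null(tok) || tok$type != ")") err("unbalanced parenthesis", tok)
      advance()
      node
    } else {
      err(sprintf("expected KO or '(' but found '%s'", tok$type), tok)
    }
  }
  parse_alt <- function() {
    members <- list(parse_unit())
    while (!is.null(peek()) && peek()$type == "+") {
      advance()
      skip_ws()
      members[[length(members) + 1L]] <- parse_unit()
    }
    if (length(members) == 1L) members[[1L]]
    else list(type = "complex", members = members)
  }
  parse_step <- function() {
    alts <- list(parse_alt())
    while (!is.null(peek()) && peek()$type == ",") {
      advance()
      skip_ws()
      if (is.null(peek()) || peek()$type %in% c(",", ")")) {
        err("empty alternative")
      }
      alts[[length(alts) + 1L]] <- parse_alt()
    }
    list(type = "step", alts = alts)
  }
  parse_expr <- function() {
    skip_ws()
    steps <- list(parse_step())
    repeat {
      saw_ws <- !is.null(peek()) && peek()$type == "ws"
      skip_ws()
      tok <- peek()
      if (is.null(tok) || tok$type == ")") break
      if (!saw_ws) err(sprintf("unexpected '%s'", tok$type), tok)
      steps[[length(steps) + 1L]] <- parse_step()
    }
    list(type = "expr", steps = steps)
  }

  ast <- parse_expr()
  if (!is.null(peek())) err("trailing input")
  structure(ast, class = "pathway_ast")
}

#' Serialize a pathway AST back to expression text
#'
#' `parse_pathway_logic(serialize_pathway(ast))` is parse-equivalent to
#' `ast` (nested expressions are parenthesised).
#'
#' @param ast a `pathway_ast` or internal AST node.
#' @return expression string.
#' @export
serialize_pathway <- function(ast) {
  ser <- function(node, top = FALSE) {
    switch(node$type,
           ko = node$ko,
           complex = paste(vapply(node$members, ser, character(1)),
                           collapse = "+"),
           step = paste(vapply(node$alts, ser, character(1)),
                        collapse = ","),
           expr = {
             body <- paste(vapply(node$steps, ser, character(1)),
                           collapse = " ")
             if (top) body else paste0("(", body, ")")
           })
  }
  ser(unclass(ast), top = TRUE)
}

#' @export
print.pathway_ast <- function(x, ...) {
  cat("<pathway_ast> ", serialize_pathway(x), "\n", sep = "")
  cat("  steps:", length(x$steps), " KOs:",
      length(pathway_kos(x)), "\n")
  invisible(x)
}

#' All KO identifiers referenced by a pathway AST
#'
#' @param ast a `pathway_ast`.
#' @return character vector of unique KO ids, sorted.
#' @export
pathway_kos <- function(ast) {
  walk <- function(node) {
    switch(node$type,
           ko = node$ko,
           complex = unlist(lapply(node$members, walk)),
           step = unlist(lapply(node$alts, walk)),
           expr = unlist(lapply(node$steps, walk)))
  }
  sort(unique(walk(unclass(ast))))
}

#' Score a pathway from KO expression values
#'
#' Evaluates the AST against a KO -> expression map: a KO leaf takes its
#' value (0 when absent), a complex is the arithmetic mean of its
#' subunits, a step sums its alternatives, and the pathway is the mean
#' over steps (nested parenthesised expressions likewise average their
#' steps). With `skip_empty_steps = TRUE`, steps none of whose KOs appear
#' in `ko_values` are excluded from the step mean.
#'
#' @param ast a `pathway_ast` from [parse_pathway_logic()].
#' @param ko_values named numeric vector (or 1-row-per-KO map) of KO
#'   expression values.
#' @param skip_empty_steps exclude steps with no measured KO from the mean
#'   (default FALSE: such steps score 0).
#' @return single numeric pathway score.
#' @examples
#' ast <- parse_pathway_logic("K1,K2 K3+K4")
#' score_pathway(ast, c(K1 = 2, K2 = 3, K3 = 4, K4 = 6)) # 5
#' @export
score_pathway <- function(ast, ko_values, skip_empty_steps = FALSE) {
  val <- function(node) {
    switch(node$type,
           ko = {
             v <- ko_values[node$ko]
             if (is.na(v) || is.null(v)) 0 else unname(v)
           },
           complex = mean(vapply(node$members, val, numeric(1))),
           step = sum(vapply(node$alts, val, numeric(1))),
           expr = {
             steps <- node$steps
             if (skip_empty_steps) {
               has <- vapply(steps, function(s) {
                 any(unlist(lapply(s$alts, ko_in_map)) )
               }, logical(1))
               if (any(has)) steps <- steps[has]
             }
             mean(vapply(steps, val, numeric(1)))
           })
  }
  ko_in_map <- function(node) {
    switch(node$type,
           ko = !is.na(ko_values[node$ko]) && node$ko %in% names(ko_values),
           complex = any(vapply(node$members, ko_in_map, logical(1))),
           step = any(vapply(node$alts, ko_in_map, logical(1))),
           expr = any(vapply(node$steps, ko_in_map, logical(1))))
  }
  val(unclass(ast))
}

#' Read pathway definitions from TSV
#'
#' Dialect: columns `pathway_id`, `name`, `category` (oxidative, reductive,
#' TEA, other), `expression`.
#'
#' @param path TSV file path.
#' @return data frame with a parsed `ast` list-column.
#' @export
read_pathway_definitions <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("pathway_id", "name", "category", "expression")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("pathway definition TSV missing columns: ",
                         paste(miss, collapse = ", "))
  df$ast <- lapply(df$expression, parse_pathway_logic)
  df
}

#' geTMM normalization
#'
#' Gene-length-corrected trimmed mean of M-values: counts are converted to
#' reads per kilobase (RPK), TMM scale factors are computed on the RPK
#' matrix (reference sample = the one whose upper quartile is closest to
#' the mean upper quartile; per-sample factor = doubly trimmed weighted
#' mean of M-values with 30\%/5\% two-sided trims on M and A and inverse
#' asymptotic binomial-variance weights; factors normalised to geometric
#' mean 1) and RPK is scaled to per-million by the effective library size
#' (RPK library size times factor).
#'
#' @param counts gene x sample count matrix with rownames/colnames.
#' @param catalog data frame with `gene_id` and `length_bp` (and usually
#'   `mag_id`, `ko`) covering every row of `counts`.
#' @param logratio_trim two-sided trim fraction on M-values (default 0.3).
#' @param sum_trim two-sided trim fraction on A-values (default 0.05).
#' @param do_weighting inverse-variance weights (default TRUE).
#' @param ref_column optional reference sample (name or index); default
#'   chooses by the upper-quartile rule.
#' @return list with `normalized` (gene x sample matrix, per-million
#'   scale), `factors` (named scale factors) and `ref` (reference sample).
#' @export
getmm_normalize <- function(counts, catalog, logratio_trim = 0.3,
                            sum_trim = 0.05, do_weighting = TRUE,
                            ref_column = NULL) {
  stopifnot(is.matrix(counts), all(counts >= 0))
  len <- catalog$length_bp[match(rownames(counts), catalog$gene_id)]
  if (any(is.na(len))) {
    stop("gene length missing for: ",
         paste(utils::head(rownames(counts)[is.na(len)]), collapse = ", "))
  }
  if (any(len <= 0)) stop("gene lengths must be positive")
  rpk <- counts / (len / 1000)
  lib <- colSums(rpk)
  if (any(lib == 0)) {
    stop("all-zero sample(s): ", paste(colnames(counts)[lib == 0],
                                       collapse = ", "))
  }
  # factors are computed on the per-million scale so that rescaling one
  # sample's counts by any constant cannot move its factor
  cpm_rpk <- sweep(rpk, 2L, lib, `/`) * 1e6
  cpm_lib <- colSums(cpm_rpk)
  if (is.null(ref_column)) {
    f75 <- apply(cpm_rpk, 2L, stats::quantile, probs = 0.75) / cpm_lib
    ref <- which.min(abs(f75 - mean(f75)))
  } else {
    ref <- if (is.character(ref_column)) match(ref_column, colnames(rpk))
           else ref_column
  }
  f <- vapply(seq_len(ncol(rpk)), function(j) {
    tmm_pair_factor(cpm_rpk[, j], cpm_rpk[, ref], cpm_lib[j], cpm_lib[ref],
                    logratio_trim, sum_trim, do_weighting)
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(counts)
  normalized <- sweep(rpk, 2L, lib * f, `/`) * 1e6
  list(normalized = normalized, factors = f, ref = colnames(counts)[ref])
}

# One pairwise TMM factor (obs vs ref), canonical doubly trimmed weighted
# mean of M-values on the log2 scale.
tmm_pair_factor <- function(obs, ref, n_obs, n_ref, logratio_trim,
                            sum_trim, do_weighting) {
  keep0 <- obs > 0 & ref > 0
  obs <- obs[keep0]
  ref <- ref[keep0]
  logR <- log2((obs / n_obs) / (ref / n_ref))
  absE <- (log2(obs / n_obs) + log2(ref / n_ref)) / 2
  v <- (n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref)
  if (length(logR) == 0L || max(abs(logR)) < 1e-6) return(1)
  n <- length(logR)
  loL <- floor(n * logratio_trim) + 1
  hiL <- n + 1 - loL
  loS <- floor(n * sum_trim) + 1
  hiS <- n + 1 - loS
  keep <- rank(logR) >= loL & rank(logR) <= hiL &
    rank(absE) >= loS & rank(absE) <= hiS
  f <- if (do_weighting) {
    sum(logR[keep] / v[keep], na.rm = TRUE) / sum(1 / v[keep], na.rm = TRUE)
  } else {
    mean(logR[keep], na.rm = TRUE)
  }
  if (!is.finite(f)) f <- 0
  2^f
}

#' Aggregate normalized gene expression to KO level
#'
#' KO value = sum of normalized expression over genes annotated with that
#' KO (total transcript output of the function), optionally restricted to
#' a subset of MAGs. KOs in `kos` with no contributing gene get 0.
#'
#' @param normalized gene x sample numeric matrix (e.g. from
#'   [getmm_normalize()]).
#' @param catalog data frame with `gene_id`, `mag_id`, `ko`.
#' @param scope optional character vector of MAG ids to restrict to.
#' @param kos optional KO ids that must appear in the output (zero rows
#'   added when unobserved).
#' @return KO x sample numeric matrix.
#' @export
ko_expression <- function(normalized, catalog, scope = NULL, kos = NULL) {
  cat_use <- catalog[!is.na(catalog$ko) & nzchar(catalog$ko), , drop = FALSE]
  if (!is.null(scope)) {
    cat_use <- cat_use[cat_use$mag_id %in% scope, , drop = FALSE]
  }
  cat_use <- cat_use[cat_use$gene_id %in% rownames(normalized), ,
                     drop = FALSE]
  all_kos <- sort(unique(c(cat_use$ko, kos)))
  out <- matrix(0, nrow = length(all_kos), ncol = ncol(normalized),
                dimnames = list(all_kos, colnames(normalized)))
  if (nrow(cat_use)) {
    sub <- normalized[cat_use$gene_id, , drop = FALSE]
    agg <- rowsum(sub, group = cat_use$ko)
    out[rownames(agg), ] <- agg
  }
  out
}

#' Score all pathways across samples
#'
#' @param defs pathway definition data frame from
#'   [read_pathway_definitions()] (or with an `ast` list-column and
#'   `pathway_id`).
#' @param ko_matrix KO x sample matrix from [ko_expression()].
#' @param skip_empty_steps passed to [score_pathway()].
#' @return pathway x sample numeric matrix.
#' @export
pathway_scores <- function(defs, ko_matrix, skip_empty_steps = FALSE) {
  out <- matrix(0, nrow = nrow(defs), ncol = ncol(ko_matrix),
                dimnames = list(defs$pathway_id, colnames(ko_matrix)))
  for (i in seq_len(nrow(defs))) {
    for (j in seq_len(ncol(ko_matrix))) {
      out[i, j] <- score_pathway(defs$ast[[i]], ko_matrix[, j],
                                 skip_empty_steps = skip_empty_steps)
    }
  }
  out
}

#' Pathway time series with replicate summaries and z-scoring
#'
#' Per pathway and timepoint: mean over replicates with standard error;
#' plus a centred/scaled (z-scored across timepoint means, n-1 sd) series
#' for cross-pathway comparison. Constant series z-score to 0.
#'
#' @param scores pathway x sample matrix (e.g. [pathway_scores()]).
#' @param design data frame with `sample_id` and `day`, one row per sample
#'   in column order; an optional `habitat` column is carried through and
#'   summaries are computed within habitat.
#' @return data frame with `pathway_id`, (`habitat`,) `day`, `mean`, `se`,
#'   `n`, `z`.
#' @export
pathway_timeseries <- function(scores, design) {
  stopifnot(ncol(scores) == nrow(design), "day" %in% names(design))
  grp <- if ("habitat" %in% names(design)) {
    interaction(design$habitat, design$day, drop = TRUE, sep = "\r")
  } else {
    factor(design$day)
  }
  if (length(unique(design$day)) < 2L) {
    warning("single timepoint: centred/scaled series undefined, z set to NA")
  }
  rows <- list()
  for (p in rownames(scores)) {
    m <- tapply(scores[p, ], grp, mean)
    s <- tapply(scores[p, ], grp, stats::sd)
    n <- tapply(scores[p, ], grp, length)
    se <- ifelse(n > 1, s / sqrt(n), NA_real_)
    if ("habitat" %in% names(design)) {
      parts <- do.call(rbind, strsplit(names(m), "\r", fixed = TRUE))
      df <- data.frame(pathway_id = p, habitat = parts[, 1L],
                       day = parts[, 2L], mean = as.numeric(m),
                       se = as.numeric(se), n = as.integer(n))
      df$z <- stats::ave(df$mean, df$habitat, FUN = zscore_guarded)
    } else {
      df <- data.frame(pathway_id = p, day = names(m),
                       mean = as.numeric(m), se = as.numeric(se),
                       n = as.integer(n))
      df$z <- zscore_guarded(df$mean)
    }
    rows[[p]] <- df
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

zscore_guarded <- function(x) {
  if (length(x) < 2L) return(rep(NA_real_, length(x)))
  s <- stats::sd(x)
  if (s == 0) rep(0, length(x)) else (x - mean(x)) / s
}
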