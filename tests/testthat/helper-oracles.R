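# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute-force loops, enumeration, and direct
# formula evaluation.

# Brute-force topological overlap via triple loop.
oracle_tom <- function(a) {
  n <- nrow(a)
  k <- rowSums(a)
  tom <- diag(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      shared <- 0
      for (u in seq_len(n)) shared <- shared + a[i, u] * a[u, j]
      tom[i, j] <- (shared + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
    }
  }
  dimnames(tom) <- dimnames(a)
  tom
}

# Step-up Benjamini-Hochberg computed from the definition.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q_sorted <- p[o] * n / seq_len(n)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(n)
  q[o] <- pmin(q_sorted, 1)
  q
}

# Exact two-sided Mann-Whitney p by full enumeration of rank assignments.
oracle_wilcoxon_p <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  u_stat <- function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - na * (na + 1) / 2
  }
  u_obs <- u_stat(seq_len(na))
  all_u <- apply(utils::combn(length(pooled), na), 2L, u_stat)
  p_low <- mean(all_u <= u_obs)
  p_high <- mean(all_u >= u_obs)
  min(1, 2 * min(p_low, p_high))
}

# Random pathway AST of bounded depth over a KO pool, built as plain
# nested lists (the same node shapes the parser emits, constructed
# directly), plus an independent recursive evaluator of the
# sum-alternatives / average-complex / average-steps semantics.
random_ast <- function(depth, ko_pool) {
  random_unit <- function(d) {
    if (d > 0 && runif(1) < 0.25) random_expr(d - 1)
    else list(type = "ko", ko = sample(ko_pool, 1))
  }
  random_alt <- function(d) {
    if (runif(1) < 0.3) {
      list(type = "complex",
           members = lapply(seq_len(sample(2:3, 1)),
                            function(i) random_unit(d)))
    } else {
      random_unit(d)
    }
  }
  random_step <- function(d) {
    list(type = "step",
         alts = lapply(seq_len(sample(1:3, 1)), function(i) random_alt(d)))
  }
  random_expr <- function(d) {
    list(type = "expr",
         steps = lapply(seq_len(sample(1:3, 1)),
                        function(i) random_step(d)))
  }
  structure(random_expr(depth), class = "pathway_ast")
}

oracle_score <- function(node, vals) {
  if (node$type == "ko") {
    if (node$ko %in% names(vals)) return(vals[[node$ko]])
    return(0)
  }
  if (node$type == "complex") {
    s <- 0
    for (m in node$members) s <- s + oracle_score(m, vals)
    return(s / length(node$members))
  }
  if (node$type == "step") {
    s <- 0
    for (alt in node$alts) s <- s + oracle_score(alt, vals)
    return(s)
  }
  s <- 0
  for (st in node$steps) s <- s + oracle_score(st, vals)
  s / length(node$steps)
}

# Small feature table built from an intensity matrix and optional metadata.
make_feature_table <- function(x, rt = NULL, mz = NULL, ms2 = NULL,
                               formula = NULL, annotation_level = NULL) {
  n <- nrow(x)
  if (is.null(rownames(x))) rownames(x) <- sprintf("f%02d", seq_len(n))
  if (is.null(colnames(x))) colnames(x) <- sprintf("s%02d", seq_len(ncol(x)))
  meta <- data.frame(feature_id = rownames(x),
                     mz = if (is.null(mz)) seq_len(n) + 100 else mz,
                     rt = if (is.null(rt)) seq_len(n) else rt,
                     stringsAsFactors = FALSE)
  if (!is.null(formula)) meta$formula <- formula
  if (!is.null(annotation_level)) meta$annotation_level <- annotation_level
  if (!is.null(ms2)) meta$ms2 <- ms2
  feature_table(x, meta)
}
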