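test_that("pathway grammar: steps, alternatives, complexes, parentheses", {
  a1 <- parse_pathway_logic("K00001")
  expect_length(a1$steps, 1L)
  expect_equal(a1$steps[[1]]$alts[[1]]$ko, "K00001")

  a2 <- parse_pathway_logic("K00001,K00002 K00003+K00004")
  expect_length(a2$steps, 2L)
  expect_length(a2$steps[[1]]$alts, 2L)
  expect_equal(a2$steps[[2]]$alts[[1]]$type, "complex")

  # parenthesis neutrality: same score under any expression map
  set.seed(81)
  for (i in 1:10) {
    vals <- setNames(runif(3, 0, 10), c("K1", "K2", "K3"))
    expect_equal(score_pathway(parse_pathway_logic("((K1,K2) K3)"), vals),
                 score_pathway(parse_pathway_logic("K1,K2 K3"), vals))
  }
})

test_that("parse errors carry positions; KEGG '-' markers are stripped", {
  expect_error(parse_pathway_logic("K1,(K2 K3"), "position")
  expect_error(parse_pathway_logic("K1,,K2"), "empty alternative")
  expect_error(parse_pathway_logic(""), "empty")
  expect_error(parse_pathway_logic("K1 & K2"), "position")
  expect_warning(a <- parse_pathway_logic("K1+K2 -K3 K4"), "non-essential")
  expect_equal(pathway_kos(a), c("K1", "K2", "K4"))
})

test_that("scoring follows sum-alternatives / mean-complex / mean-steps", {
  vals <- c(K1 = 2, K2 = 3, K3 = 4, K4 = 6)
  expect_equal(score_pathway(parse_pathway_logic("K1,K2 K3+K4"), vals), 5.0)
  expect_equal(score_pathway(parse_pathway_logic("K1 K2 K9"), numeric(0)), 0)
  expect_equal(score_pathway(parse_pathway_logic("K1"), c(K1 = 7)), 7)
})

test_that("random ASTs round-trip through text and match the brute-force evaluator", {
  set.seed(91)
  ko_pool <- sprintf("K%05d", 1:12)
  for (i in 1:300) {
    ast <- random_ast(depth = 2, ko_pool = ko_pool)
    txt <- serialize_pathway(ast)
    reparsed <- parse_pathway_logic(txt)
    vals <- setNames(runif(length(ko_pool), 0, 100), ko_pool)
    vals <- vals[runif(12) < 0.7]           # some KOs unmeasured
    expect_equal(score_pathway(reparsed, vals),
                 oracle_score(ast, vals), tolerance = 1e-12)
    expect_identical(serialize_pathway(reparsed), txt)
  }
})

test_that("score_pathway is linear in the expression values", {
  set.seed(101)
  for (i in 1:20) {
    ast <- random_ast(2, sprintf("K%d", 1:8))
    vals <- setNames(runif(8), sprintf("K%d", 1:8))
    alpha <- runif(1, 0.1, 10)
    expect_equal(score_pathway(ast, alpha * vals),
                 alpha * score_pathway(ast, vals))
  }
})

test_that("geTMM: identical samples get unit factors", {
  set.seed(111)
  base <- rnbinom(100, mu = 40, size = 5) + 1L
  counts <- cbind(s1 = base, s2 = base, s3 = base)
  rownames(counts) <- sprintf("g%03d", 1:100)
  catalog <- data.frame(gene_id = rownames(counts), mag_id = "M1",
                        ko = NA, length_bp = sample(500:2000, 100, TRUE))
  res <- getmm_normalize(counts, catalog)
  expect_equal(unname(res$factors), rep(1, 3))
})

test_that("geTMM normalized output is invariant to scaling one sample", {
  set.seed(112)
  counts <- matrix(rnbinom(200 * 4, mu = 50, size = 5), 200,
                   dimnames = list(sprintf("g%03d", 1:200),
                                   paste0("s", 1:4)))
  catalog <- data.frame(gene_id = rownames(counts), mag_id = "M1",
                        ko = NA, length_bp = sample(300:3000, 200, TRUE))
  res <- getmm_normalize(counts, catalog)
  scaled <- counts
  scaled[, 2] <- counts[, 2] * 3
  res3 <- getmm_normalize(scaled, catalog)
  expect_lt(max(abs(res3$normalized - res$normalized)), 1e-9)
  expect_error(getmm_normalize(cbind(counts, z = 0L), catalog),
               "all-zero")
})

test_that("geTMM factors agree with edgeR's TMM on the same scale", {
  skip_if_not_installed("edgeR")
  set.seed(113)
  counts <- matrix(rnbinom(300 * 5, mu = 60, size = 3), 300,
                   dimnames = list(sprintf("g%03d", 1:300),
                                   paste0("s", 1:5)))
  catalog <- data.frame(gene_id = rownames(counts), mag_id = "M1",
                        ko = NA, length_bp = sample(300:3000, 300, TRUE))
  res <- getmm_normalize(counts, catalog)
  rpk <- counts / (catalog$length_bp / 1000)
  cpm <- sweep(rpk, 2, colSums(rpk), `/`) * 1e6
  f_ref <- edgeR::calcNormFactors(cpm, lib.size = colSums(cpm))
  expect_equal(unname(res$factors), unname(f_ref), tolerance = 1e-12)
})

test_that("toy doubled-gene factor equals a brute-force trimmed weighted mean", {
  set.seed(114)
  a <- sort(round(exp(runif(20, log(20), log(2000)))))  # distinct counts
  counts <- cbind(sA = a, sB = a)
  counts[5, "sB"] <- counts[5, "sB"] * 2     # double one high-count gene
  rownames(counts) <- sprintf("g%02d", 1:20)
  catalog <- data.frame(gene_id = rownames(counts), mag_id = "M1",
                        ko = NA, length_bp = 1000)
  res <- getmm_normalize(counts, catalog)

  # oracle on the per-million scale: quantile-based double trim + inverse
  # binomial-variance weights, reference = sample A (upper-quartile rule)
  cpm <- sweep(counts, 2, colSums(counts), `/`) * 1e6
  obs <- cpm[, "sB"]; ref <- cpm[, "sA"]
  nO <- sum(obs); nR <- sum(ref)
  M <- log2((obs / nO) / (ref / nR))
  A <- (log2(obs / nO) + log2(ref / nR)) / 2
  keep <- M >= quantile(M, 0.3) & M <= quantile(M, 0.7) &
    A >= quantile(A, 0.05) & A <= quantile(A, 0.95)
  w <- 1 / ((nO - obs) / (nO * obs) + (nR - ref) / (nR * ref))
  f_b <- 2^(sum((M * w)[keep]) / sum(w[keep]))
  expected <- c(1, f_b) / exp(mean(log(c(1, f_b))))
  expect_equal(unname(res$factors), unname(expected))
  expect_equal(res$ref, "sA")
})

test_that("KO aggregation sums genes and respects MAG scope", {
  norm <- rbind(g1 = c(1.5, 1), g2 = c(2.5, 2), g3 = c(10, 20))
  colnames(norm) <- c("s1", "s2")
  catalog <- data.frame(gene_id = c("g1", "g2", "g3"),
                        mag_id = c("A", "A", "B"),
                        ko = c("K1", "K1", "K2"))
  kom <- ko_expression(norm, catalog)
  expect_equal(kom["K1", ], c(s1 = 4.0, s2 = 3.0))
  empty <- ko_expression(norm, catalog, scope = character(0),
                         kos = c("K1", "K2"))
  expect_equal(max(abs(empty)), 0)   # empty scope: all zeros
  # restriction consistency: scope = one MAG equals whole-matrix result
  # restricted to that MAG's genes
  komA <- ko_expression(norm, catalog, scope = "A")
  expect_equal(komA["K1", ],
               ko_expression(norm[c("g1", "g2"), ], catalog)["K1", ])
  expect_equal(unname(ko_expression(norm, catalog, kos = "K9")["K9", ]),
               c(0, 0))
})

test_that("pathway/gene permutation invariance of scores", {
  set.seed(121)
  counts <- matrix(rnbinom(50 * 4, mu = 30, size = 5), 50,
                   dimnames = list(sprintf("g%02d", 1:50),
                                   paste0("s", 1:4)))
  catalog <- data.frame(gene_id = rownames(counts), mag_id = "M1",
                        ko = sample(sprintf("K%d", 1:10), 50, TRUE),
                        length_bp = sample(300:3000, 50, TRUE))
  defs <- data.frame(pathway_id = "p1", stringsAsFactors = FALSE)
  defs$ast <- list(parse_pathway_logic("K1,K2 K3+K4 K5"))
  s1 <- pathway_scores(defs,
                       ko_expression(getmm_normalize(counts, catalog)$normalized,
                                     catalog))
  perm <- sample(nrow(counts))
  s2 <- pathway_scores(defs,
                       ko_expression(getmm_normalize(counts[perm, ], catalog)$normalized,
                                     catalog))
  expect_equal(s1, s2)
})

test_that("pathway time series averages replicates and z-scores guarded", {
  scores <- matrix(c(1, 1, 2, 2, 3, 3,   # pathway p1 over 3 days x 2 reps
                     5, 5, 5, 5, 5, 5),  # constant pathway p2
                   nrow = 2, byrow = TRUE,
                   dimnames = list(c("p1", "p2"), paste0("s", 1:6)))
  design <- data.frame(sample_id = paste0("s", 1:6),
                       day = rep(c(0, 7, 14), each = 2))
  ts <- pathway_timeseries(scores, design)
  p1 <- ts[ts$pathway_id == "p1", ]
  expect_equal(p1$mean, c(1, 2, 3))
  expect_equal(p1$z, c(-1, 0, 1))
  expect_equal(ts$z[ts$pathway_id == "p2"], rep(0, 3))
  # replicate SE = sd/sqrt(n) for triplicates
  s3 <- matrix(c(1, 2, 3, 7, 8, 9), nrow = 1,
               dimnames = list("p", paste0("s", 1:6)))
  d3 <- data.frame(sample_id = paste0("s", 1:6), day = rep(c(0, 7), each = 3))
  ts3 <- pathway_timeseries(s3, d3)
  expect_equal(ts3$se, c(sd(1:3) / sqrt(3), sd(7:9) / sqrt(3)))
  expect_warning(pathway_timeseries(s3[, 1:3, drop = FALSE],
                                    d3[1:3, ]), "single timepoint")
})
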