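test_that("RT binning is single-linkage with inclusive gap", {
  meta <- data.frame(feature_id = c("a", "b", "c"),
                     rt = c(1.000, 1.004, 1.009))
  bins <- bin_by_rt(meta, 0.005)   # gaps 0.004 and 0.005 both join
  expect_length(bins, 1L)
  expect_setequal(bins[[1]], c("a", "b", "c"))

  meta2 <- data.frame(feature_id = c("a", "b"), rt = c(1.000, 1.010))
  expect_length(bin_by_rt(meta2, 0.005), 2L)

  expect_length(bin_by_rt(data.frame(feature_id = "x", rt = 5), 0.005), 1L)
  expect_length(bin_by_rt(meta[0, ], 0.005), 0L)
})

test_that("RT binning is invariant to input order", {
  set.seed(21)
  meta <- data.frame(feature_id = sprintf("f%02d", 1:40),
                     rt = round(runif(40, 0, 1), 3))
  bins <- bin_by_rt(meta, 0.02)
  perm <- meta[sample(nrow(meta)), ]
  bins_p <- bin_by_rt(perm, 0.02)
  norm <- function(b) unname(lapply(b, sort))
  expect_equal(norm(bins), norm(bins_p))
  expect_setequal(unlist(bins), meta$feature_id)  # partition
})

test_that("co-elution pairing applies a strict Pearson threshold", {
  x <- rbind(a = c(1, 2, 3, 4, 5, 6),
             b = c(1, 2, 3, 4, 5, 6),
             c = c(6, 5, 4, 3, 2, 1),
             d = c(1.0, 2.1, 2.9, 4.0, 5.2, 5.9),
             e = rep(2, 6))
  ft <- make_feature_table(x, rt = rep(1, 5))
  pairs <- coeluting_pairs(rownames(x), ft, 0.98)
  # identical vectors pair at r = 1; anticorrelated and constant excluded
  expect_true(any(pairs$a == "a" & pairs$b == "b"))
  expect_false(any(pairs$a == "c" | pairs$b == "c"))
  expect_false(any(pairs$a == "e" | pairs$b == "e"))
  r_ad <- cor(x["a", ], x["d", ])
  expect_equal(any(pairs$a == "a" & pairs$b == "d"), r_ad > 0.98)

  ft2 <- make_feature_table(x[, 1:2])
  expect_error(coeluting_pairs(rownames(x), ft2, 0.98), "3 samples")
})

test_that("fragment-parent MS2 matching uses relative ppm error", {
  parent <- list(mz = 325.1, ms2 = c(101.2, 163.0601, 200.5))
  hit <- match_fragment_to_parent(list(mz = 163.0605), parent, 5)
  expect_equal(hit$fragment_mz, 163.0601)
  expect_equal(hit$ppm_error, (163.0605 - 163.0601) / 163.0601 * 1e6)
  expect_lt(abs(hit$ppm_error - 2.45), 0.01)

  expect_null(match_fragment_to_parent(list(mz = 163.0621),
                                       list(mz = 325.1, ms2 = 163.0601), 5))
  expect_null(match_fragment_to_parent(list(mz = 150),
                                       list(mz = 325.1, ms2 = numeric(0)), 5))
  expect_error(match_fragment_to_parent(list(mz = 400), parent, 5),
               "strictly below")
})

test_that("halogen removal targets predicted compositions only", {
  meta <- data.frame(feature_id = c("w", "x", "y", "z"),
                     formula = c("C6H5Cl1", "C6H12O6", NA, "C4H2F3"))
  out <- remove_halogen_features(meta)
  expect_setequal(out$removed, c("w", "z"))
  expect_setequal(out$kept, c("x", "y"))   # missing formula is kept
})

test_that("clean() removes every planted artifact and no true feature", {
  fg <- generate_feature_table(synth_config(seed = 1))
  res <- clean_features(fg$table)
  rep <- res$report
  expect_setequal(rep$removed_as_fragment$fragment_id,
                  fg$truth$fragment_ids)                  # recall 1
  expect_setequal(rep$removed_as_halogen, fg$truth$halogen_ids)
  expect_length(intersect(rep$retained, fg$truth$artifact_feature_ids), 0L)
  # each removed fragment is attributed to its true parent
  expect_equal(
    rep$removed_as_fragment$parent_id,
    unname(fg$truth$fragment_parents[rep$removed_as_fragment$fragment_id]))
  expect_true(all(rep$removed_as_fragment$r > 0.98))
  expect_true(all(rep$removed_as_fragment$ppm_error <= 5))
})

test_that("cleaning report partitions the input features", {
  fg <- generate_feature_table(synth_config(seed = 5, n_true_features = 80,
                                            n_fragment_artifacts = 10,
                                            n_halogen_artifacts = 5))
  rep <- clean_features(fg$table)$report
  ids <- c(rep$removed_as_fragment$fragment_id, rep$removed_as_halogen,
           rep$retained)
  expect_length(ids, nrow(fg$table$intensities))
  expect_setequal(ids, rownames(fg$table$intensities))
})

test_that("cleaning is idempotent and order-invariant", {
  fg <- generate_feature_table(synth_config(seed = 7, n_true_features = 60,
                                            n_fragment_artifacts = 8,
                                            n_halogen_artifacts = 3))
  once <- clean_features(fg$table)
  twice <- clean_features(once$table)
  expect_equal(twice$report$retained, once$report$retained)
  expect_equal(nrow(twice$report$removed_as_fragment), 0L)

  set.seed(1)
  perm <- sample(nrow(fg$table$intensities))
  ft_p <- feature_table(fg$table$intensities[perm, , drop = FALSE],
                        fg$table$meta[perm, , drop = FALSE])
  rep_p <- clean_features(ft_p)$report
  expect_setequal(rep_p$removed_as_fragment$fragment_id,
                  once$report$removed_as_fragment$fragment_id)
  expect_setequal(rep_p$retained, once$report$retained)
})

test_that("no MS2 anywhere means no fragment removals; halogen flag works", {
  set.seed(31)
  x <- matrix(runif(5 * 6, 1, 10), 5,
              dimnames = list(letters[1:5], paste0("s", 1:6)))
  x[2, ] <- x[1, ] * 0.5         # correlated pair, but no MS2 evidence
  ft <- make_feature_table(x, rt = rep(1, 5),
                           ms2 = replicate(5, numeric(0), simplify = FALSE),
                           formula = c(NA, NA, "C2H4Cl2", NA, NA))
  res <- clean_features(ft)
  expect_equal(nrow(res$report$removed_as_fragment), 0L)
  expect_equal(res$report$removed_as_halogen, "c")

  res2 <- clean_features(ft, cleaning_params(drop_halogens = FALSE))
  expect_length(res2$report$removed_as_halogen, 0L)
  expect_setequal(res2$report$retained, letters[1:5])
})

test_that("group decisions match a brute-force pass on small bins", {
  # one bin of <= 8 co-eluting features; oracle: enumerate all pairs, build
  # the correlated component, take the heaviest ion, test lighter members
  set.seed(41)
  for (rep_i in 1:5) {
    n <- sample(4:8, 1)
    base <- runif(12, 1, 100)
    x <- matrix(0, n, 12, dimnames = list(sprintf("q%02d", 1:n),
                                          sprintf("s%02d", 1:12)))
    mzs <- sort(runif(n, 100, 500), decreasing = TRUE)
    ms2 <- vector("list", n)
    for (i in seq_len(n)) {
      x[i, ] <- if (i > 1 && runif(1) < 0.5) {
        x[i - 1, ] * runif(1, 0.2, 0.8) * exp(rnorm(12, 0, 0.002))
      } else {
        runif(1, 10, 1000) * exp(rnorm(12, 0, 0.5))
      }
      ms2[[i]] <- if (i < n) mzs[(i + 1):n] else numeric(0)
    }
    ft <- make_feature_table(x, rt = rep(2, n), mz = mzs, ms2 = ms2)
    got <- clean_features(ft)$report$removed_as_fragment

    cm <- cor(t(x))
    adj <- cm > 0.98 & upper.tri(cm)
    comp <- rep(seq_len(n), 1)
    for (i in 1:n) for (j in 1:n) {
      if (i < j && adj[i, j]) comp[comp == comp[j]] <- comp[i]
    }
    removed <- character(0)
    for (cc in unique(comp)) {
      members <- which(comp == cc)
      if (length(members) < 2) next
      parent <- members[which.max(mzs[members])]
      for (m in setdiff(members, parent)) {
        if (mzs[m] < mzs[parent] &&
              any(abs(ms2[[parent]] - mzs[m]) / ms2[[parent]] * 1e6 <= 5)) {
          removed <- c(removed, rownames(x)[m])
        }
      }
    }
    expect_setequal(got$fragment_id, removed)
  }
})
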