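test_that("identical configurations give identical outputs", {
  cfg <- synth_config(seed = 42, n_true_features = 60,
                      n_fragment_artifacts = 6, n_halogen_artifacts = 3,
                      n_mags = 4, genes_per_mag = 40)
  defs <- demo_pathway_definitions()
  expect_identical(generate_feature_table(cfg), generate_feature_table(cfg))
  expect_identical(generate_transcript_counts(cfg, defs),
                   generate_transcript_counts(cfg, defs))
  expect_identical(generate_gas_series(cfg, noise_sd = 0.02),
                   generate_gas_series(cfg, noise_sd = 0.02))
  expect_identical(generate_methane_module_data(cfg),
                   generate_methane_module_data(cfg))
  cfg2 <- synth_config(seed = 43, n_true_features = 60,
                       n_fragment_artifacts = 6, n_halogen_artifacts = 3,
                       n_mags = 4, genes_per_mag = 40)
  expect_false(identical(generate_feature_table(cfg),
                         generate_feature_table(cfg2)))
})

test_that("config invariants are enforced", {
  expect_error(synth_config(n_samples = 0), "n_samples")
  expect_error(synth_config(planted_module_gas_correlation = 1.5),
               "\\[-1, 1\\]")
  expect_error(synth_config(n_fragment_artifacts = 10,
                            n_true_features = 5), "more fragments")
  expect_error(generate_transcript_counts(synth_config(), list()),
               "nonempty")
})

test_that("planted fragments satisfy the published artifact signature", {
  fg <- generate_feature_table(synth_config(seed = 1, n_samples = 24))
  meta <- fg$table$meta
  x <- fg$table$intensities
  for (fid in fg$truth$fragment_ids) {
    pid <- fg$truth$fragment_parents[[fid]]
    fm <- meta[meta$feature_id == fid, ]
    pm <- meta[meta$feature_id == pid, ]
    expect_lte(abs(fm$rt - pm$rt), 0.002)               # co-elution
    expect_gt(cor(x[fid, ], x[pid, ]), 0.98)            # intensity tie
    expect_lt(fm$mz, pm$mz)                             # lighter ion
    expect_lte(min(abs(pm$ms2[[1]] - fm$mz) / pm$ms2[[1]]) * 1e6, 5)
  }
  # halogen artifacts carry halogenated formulas
  halo_meta <- meta[meta$feature_id %in% fg$truth$halogen_ids, ]
  expect_true(all(vapply(halo_meta$formula, contains_halogen, logical(1))))
  # no fragments requested -> only halogen artifacts labeled
  fg0 <- generate_feature_table(synth_config(seed = 2,
                                             n_fragment_artifacts = 0,
                                             n_true_features = 40,
                                             n_halogen_artifacts = 4))
  expect_setequal(fg0$truth$artifact_feature_ids, fg0$truth$halogen_ids)
})

test_that("transcript truth labels are re-verifiable from the data", {
  defs <- demo_pathway_definitions()
  cfg <- synth_config(seed = 6, n_mags = 10, genes_per_mag = 40)
  tc <- generate_transcript_counts(cfg, defs)
  mag <- tc$catalog$mag_id[match(rownames(tc$counts), tc$catalog$gene_id)]
  totals <- rowsum(tc$counts, mag)
  bog_samples <- tc$design$sample_id[tc$design$habitat == "bog"]
  for (m in tc$truth$inactive_mags) {
    expect_true(all(totals[m, bog_samples] <= 15))
  }
  for (s in colnames(totals)) {
    expect_setequal(rownames(totals)[totals[, s] > 15],
                    tc$truth$active_mag_ids[[s]])
  }
  # encoded MAGs cover >= 60% of steps; non-encoded fewer
  for (m in rownames(tc$truth$encoded)) {
    kos <- unique(stats::na.omit(tc$catalog$ko[tc$catalog$mag_id == m]))
    for (p in seq_len(nrow(defs))) {
      enc <- pathway_encoded(kos, defs$ast[[p]])
      expect_equal(enc$encoded, tc$truth$encoded[m, defs$pathway_id[p]])
    }
  }
})

test_that("negative binomial counts approach Poisson as dispersion -> 0", {
  cfg <- synth_config(seed = 8, nb_dispersion = 1e-8, n_mags = 2,
                      genes_per_mag = 20, n_samples = 8)
  defs <- demo_pathway_definitions()[3, ]   # small pathway
  # replicate draws of one gene's count under near-zero dispersion
  set.seed(77)
  mu <- 20
  draws <- rnbinom(1000, mu = mu, size = 1 / 1e-8)
  expect_lt(abs(var(draws) / mean(draws) - 1), 0.15)  # Poisson limit
  # and the generator accepts the limit without error
  tc <- generate_transcript_counts(cfg, defs)
  expect_true(all(tc$counts >= 0))
})

test_that("planted module factor carries the requested gas correlation", {
  for (rho in c(-0.8, 0, 0.8)) {
    md <- generate_methane_module_data(
      synth_config(seed = 15, n_samples = 12,
                   planted_module_gas_correlation = rho))
    expect_equal(cor(md$truth$latent_factor, md$gas), rho)
  }
  # membership partitions exactly planted_module_size features
  md <- generate_methane_module_data(synth_config(seed = 16, n_samples = 12,
                                                  planted_module_size = 25))
  expect_equal(sum(md$truth$module_membership == "M1"), 25L)
  expect_setequal(names(md$truth$module_membership),
                  rownames(md$intensities))
  # zero-noise, rho = 1: members are monotone in gas
  md1 <- generate_methane_module_data(
    synth_config(seed = 17, n_samples = 12,
                 planted_module_gas_correlation = 1),
    feature_noise_sd = 0)
  expect_equal(unname(spearman_gas_correlation(
    md1$intensities[md1$truth$module_membership == "M1", ], md1$gas)),
    rep(1, sum(md1$truth$module_membership == "M1")))
})

test_that("serialized synthetic datasets round-trip through the readers", {
  dir <- withr::local_tempdir()
  cfg <- synth_config(seed = 18, n_true_features = 30,
                      n_fragment_artifacts = 4, n_halogen_artifacts = 2,
                      n_mags = 3, genes_per_mag = 40)
  fg <- generate_feature_table(cfg)
  p <- write_feature_table(fg$table, file.path(dir, "f.tsv"))
  back <- read_feature_table(p)
  expect_equal(back$intensities, fg$table$intensities)
  expect_equal(back$meta$ms2, fg$table$meta$ms2)
  expect_equal(back$meta$formula, fg$table$meta$formula)

  defs <- demo_pathway_definitions()
  tc <- generate_transcript_counts(cfg, defs)
  cp <- write_counts(tc$counts, file.path(dir, "c.tsv"))
  expect_equal(read_counts(cp), tc$counts)
  gp <- write_gene_catalog(tc$catalog, file.path(dir, "g.tsv"))
  expect_equal(read_gene_catalog(gp), tc$catalog)

  dp <- write_pathway_definitions(defs, file.path(dir, "p.tsv"))
  defs2 <- read_pathway_definitions(dp)
  expect_equal(defs2$expression, defs$expression)
  expect_equal(lapply(defs2$ast, serialize_pathway),
               lapply(defs$ast, serialize_pathway))

  gs <- generate_gas_series(cfg)
  sp <- write_gas_series(gs$samples, file.path(dir, "gas.csv"))
  expect_equal(read_gas_series(sp), gs$samples, tolerance = 1e-12)
})
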