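# Synthetic-data generators emulating every input of the pipeline with
# ground-truth labels: LC-MS feature tables with planted in-source
# fragments and halogen artifacts, MAG-structured negative-binomial
# transcript counts with known active/inactive MAGs and encoded pathways,
# headspace gas time series with known total production, and
# single-factor metabolite modules with a planted methane correlation.

#' Synthetic-data configuration
#'
#' Defaults are the study-like conditions the generators emulate: 24
#' samples (two habitats x four timepoints x triplicates), 500 genuine
#' LC-MS features with 50 planted in-source fragments and 10 halogen
#' artifacts, 20 MAGs of 50 genes with RNA-seq-like overdispersion
#' (variance mu + alpha mu^2, alpha = 0.1), and a 30-feature methane
#' module at planted correlation 0.9.
#'
#' @param seed RNG seed; identical configs give identical outputs.
#' @param n_samples number of samples.
#' @param n_true_features genuine LC-MS features.
#' @param n_fragment_artifacts planted in-source fragment ions.
#' @param n_halogen_artifacts planted halogen-formula features.
#' @param fragment_rt_jitter max |RT offset| of a fragment from its parent.
#' @param fragment_intensity_noise_sd multiplicative (log-scale) noise sd
#'   of a fragment around its fixed parent fraction.
#' @param n_mags,genes_per_mag MAG count and genes per MAG.
#' @param nb_dispersion negative-binomial dispersion alpha.
#' @param habitat_effect log2 fold change applied to habitat-responsive
#'   genes/features.
#' @param planted_module_size features in the planted methane module.
#' @param planted_module_gas_correlation latent-factor vs methane Pearson
#'   correlation, in [-1, 1].
#' @return a `synth_config` list.
#' @export
synth_config <- function(seed = 1L, n_samples = 24L,
                         n_true_features = 500L,
                         n_fragment_artifacts = 50L,
                         n_halogen_artifacts = 10L,
                         fragment_rt_jitter = 0.002,
                         fragment_intensity_noise_sd = 0.005,
                         n_mags = 20L, genes_per_mag = 50L,
                         nb_dispersion = 0.1, habitat_effect = 1,
                         planted_module_size = 30L,
                         planted_module_gas_correlation = 0.9) {
  stopifnot(n_samples > 0, n_true_features > 0, n_fragment_artifacts >= 0,
            n_halogen_artifacts >= 0, fragment_rt_jitter > 0,
            fragment_intensity_noise_sd >= 0, n_mags > 0,
            genes_per_mag > 0, nb_dispersion >= 0,
            planted_module_size >= 3)
  if (abs(planted_module_gas_correlation) > 1) {
    stop("planted_module_gas_correlation must lie in [-1, 1]")
  }
  if (n_fragment_artifacts > n_true_features) {
    stop("cannot plant more fragments than true parent features")
  }
  structure(as.list(environment()), class = "synth_config")
}

#' Two-habitat, four-timepoint replicated sample design
#'
#' Bog and fen sampled at days 0, 7, 14 and a habitat-specific final day
#' (bog 28, fen 35), filled with replicates up to `n_samples`.
#'
#' @param n_samples number of samples.
#' @return data frame with `sample_id`, `habitat`, `day`.
#' @export
synth_design <- function(n_samples) {
  habitats <- c("bog", "fen")
  days <- c(0, 7, 14, 28)
  grid <- expand.grid(rep = seq_len(ceiling(n_samples / 8)),
                      day = days, habitat = habitats,
                      stringsAsFactors = FALSE)
  grid <- grid[seq_len(n_samples), , drop = FALSE]
  # the two habitats end on different days, as in field incubations
  grid$day[grid$habitat == "fen" & grid$day == 28] <- 35
  data.frame(sample_id = sprintf("S%02d", seq_len(n_samples)),
             habitat = grid$habitat, day = grid$day,
             stringsAsFactors = FALSE)
}

#' Generate a synthetic LC-MS feature table with planted artifacts
#'
#' Genuine features get independent log-normal intensities (a subset
#' carries a habitat effect), random retention times, CHNO formulas and
#' random MS2 fragment lists. Each planted in-source fragment co-elutes
#' with its parent (RT within `fragment_rt_jitter`), has intensity =
#' parent x fixed fraction x small multiplicative noise (so the
#' parent-fragment Pearson correlation across samples exceeds 0.98), has
#' m/z strictly below the parent's and exactly matching one of the
#' parent's MS2 fragments. Halogen artifacts carry F/Cl/Br/I-containing
#' formulas.
#'
#' @param config a [synth_config()].
#' @return list with `table` (a [feature_table()]), `design` (sample
#'   design data frame) and `truth` (list with `artifact_feature_ids`,
#'   `fragment_parents` named vector, `halogen_ids`, `fragment_ids`).
#' @export
generate_feature_table <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  design <- synth_design(config$n_samples)
  n_t <- config$n_true_features
  n_f <- config$n_fragment_artifacts
  n_h <- config$n_halogen_artifacts

  true_ids <- sprintf("FT%04d", seq_len(n_t))
  mz <- round(stats::runif(n_t, 120, 800), 4)
  rt <- round(stats::runif(n_t, 0.5, 20), 3)
  ms2 <- lapply(mz, function(m) {
    k <- sample(3:8, 1)
    sort(round(stats::runif(k, 50, m - 1), 4))
  })
  formulas <- vapply(seq_len(n_t), function(i) {
    if (stats::runif(1) < 0.2) return(NA_character_)  # no predicted composition
    C <- sample(4:30, 1)
    sprintf("C%dH%dN%dO%d", C, sample(c(ceiling(C / 2), 2 * C + 2), 1),
            sample(0:3, 1), sample(1:10, 1))
  }, character(1))

  base <- exp(stats::runif(n_t, log(1e4), log(1e7)))
  hab_feature <- stats::runif(n_t) < 0.2
  hab_mult <- ifelse(design$habitat == "fen", 2^config$habitat_effect, 1)
  intens <- matrix(0, nrow = n_t, ncol = config$n_samples,
                   dimnames = list(true_ids, design$sample_id))
  for (i in seq_len(n_t)) {
    mult <- if (hab_feature[i]) hab_mult else rep(1, config$n_samples)
    intens[i, ] <- base[i] * mult * exp(stats::rnorm(config$n_samples, 0, 0.5))
  }

  # planted in-source fragments
  frag_ids <- character(0)
  frag_parent <- character(0)
  if (n_f > 0) {
    frag_ids <- sprintf("FRAG%03d", seq_len(n_f))
    parents <- sample(seq_len(n_t), n_f)
    frag_parent <- stats::setNames(true_ids[parents], frag_ids)
    frac <- stats::runif(n_f, 0.1, 0.6)
    f_int <- matrix(0, nrow = n_f, ncol = config$n_samples,
                    dimnames = list(frag_ids, design$sample_id))
    f_mz <- f_rt <- numeric(n_f)
    f_ms2 <- vector("list", n_f)
    for (k in seq_len(n_f)) {
      p <- parents[k]
      f_int[k, ] <- intens[p, ] * frac[k] *
        exp(stats::rnorm(config$n_samples, 0,
                         config$fragment_intensity_noise_sd))
      f_mz[k] <- sample(ms2[[p]], 1)  # exact MS2 match, m/z < parent
      f_rt[k] <- rt[p] + stats::runif(1, -config$fragment_rt_jitter,
                                      config$fragment_rt_jitter)
      f_ms2[[k]] <- sort(round(stats::runif(2, 20, f_mz[k] - 1), 4))
    }
  }

  # halogen artifacts: independent intensities, halogenated formulas
  halo_ids <- character(0)
  if (n_h > 0) {
    halo_ids <- sprintf("HALO%03d", seq_len(n_h))
    halo <- sample(c("F", "Cl", "Br", "I"), n_h, replace = TRUE)
    h_formula <- sprintf("C%dH%d%s%d", sample(4:20, n_h, TRUE),
                         sample(3:30, n_h, TRUE), halo,
                         sample(1:3, n_h, TRUE))
    h_int <- matrix(exp(stats::runif(n_h, log(1e4), log(1e6))) *
                      exp(stats::rnorm(n_h * config$n_samples, 0, 0.5)),
                    nrow = n_h, dimnames = list(halo_ids, design$sample_id))
    h_mz <- round(stats::runif(n_h, 120, 800), 4)
    h_rt <- round(stats::runif(n_h, 0.5, 20), 3)
  }

  meta <- data.frame(
    feature_id = c(true_ids, frag_ids, halo_ids),
    mz = c(mz, if (n_f) f_mz, if (n_h) h_mz),
    rt = c(rt, if (n_f) f_rt, if (n_h) h_rt),
    formula = c(formulas, rep(NA_character_, n_f),
                if (n_h) h_formula),
    annotation_level = c(sample(c(1L, 2L, 3L, NA), n_t, TRUE,
                                prob = c(0.2, 0.3, 0.3, 0.2)),
                         rep(NA_integer_, n_f + n_h)),
    stringsAsFactors = FALSE
  )
  meta$ms2 <- c(ms2, if (n_f) f_ms2 else NULL,
                if (n_h) replicate(n_h, numeric(0), simplify = FALSE))
  all_int <- rbind(intens,
                   if (n_f) f_int else NULL,
                   if (n_h) h_int else NULL)

  truth <- list(artifact_feature_ids = c(frag_ids, halo_ids),
                fragment_ids = frag_ids,
                halogen_ids = halo_ids,
                fragment_parents = frag_parent)
  list(table = feature_table(all_int, meta), design = design,
       truth = truth)
}

#' Generate MAG-structured transcript counts with known truth
#'
#' Counts are negative binomial with variance mu + alpha mu^2. Each MAG is
#' flagged encoded for each pathway with probability `p_encoded`; encoded
#' MAGs receive genes covering every step of the pathway (one alternative
#' per step, all subunits of a complex), non-encoded MAGs cover fewer than
#' 60\% of the steps. A fraction of MAGs is inactive in the samples of one
#' habitat: their per-sample totals there are drawn between 0 and 15
#' (never above the activity threshold), while active MAG-sample totals
#' are guaranteed above it.
#'
#' @param config a [synth_config()].
#' @param pathways list (or definition data frame) of parsed
#'   `pathway_ast` objects with nonempty KO sets; a character vector of
#'   expressions is also accepted.
#' @param p_encoded probability a MAG encodes a pathway (default 0.5).
#' @param p_inactive fraction of MAGs inactive in the bog samples
#'   (default 0.25).
#' @return list with `counts` (gene x sample matrix), `catalog`
#'   (gene_id, mag_id, ko, length_bp), `design`, and `truth` (list with
#'   `active_mag_ids` per sample, `encoded` MAG x pathway logical matrix,
#'   `inactive_mags`).
#' @export
generate_transcript_counts <- function(config = synth_config(), pathways,
                                       p_encoded = 0.5,
                                       p_inactive = 0.25) {
  stopifnot(inherits(config, "synth_config"))
  if (is.character(pathways)) {
    pathways <- lapply(pathways, parse_pathway_logic)
  }
  if (is.data.frame(pathways)) {
    asts <- pathways$ast
    pw_ids <- pathways$pathway_id
  } else {
    asts <- pathways
    pw_ids <- if (!is.null(names(pathways))) names(pathways)
              else paste0("PW", seq_along(pathways))
  }
  if (length(asts) == 0L) stop("pathway list must be nonempty")
  if (any(vapply(asts, function(a) length(pathway_kos(a)) == 0L,
                 logical(1)))) {
    stop("every pathway must reference at least one KO")
  }
  set.seed(config$seed + 1L)
  design <- synth_design(config$n_samples)
  n_g <- config$n_mags * config$genes_per_mag
  gene_id <- sprintf("G%05d", seq_len(n_g))
  mag_id <- rep(sprintf("MAG%03d", seq_len(config$n_mags)),
                each = config$genes_per_mag)
  mags <- unique(mag_id)

  # encoding truth and KO assignment
  encoded <- matrix(stats::runif(config$n_mags * length(asts)) < p_encoded,
                    nrow = config$n_mags,
                    dimnames = list(mags, pw_ids))
  ko <- rep(NA_character_, n_g)
  for (m in seq_along(mags)) {
    gpool <- which(mag_id == mags[m])
    gi <- 1L
    take_gene <- function() {
      if (gi > length(gpool)) {
        stop("genes_per_mag too small to cover the supplied pathways")
      }
      g <- gpool[gi]
      gi <<- gi + 1L
      g
    }
    for (p in seq_along(asts)) {
      steps <- unclass(asts[[p]])$steps
      cover <- if (encoded[m, p]) seq_along(steps) else {
        n_cov <- max(0L, ceiling(0.6 * length(steps)) - 1L)
        if (n_cov > 0) sort(sample(seq_along(steps), n_cov)) else integer(0)
      }
      for (s in cover) {
        alt <- steps[[s]]$alts[[1L]]
        for (k in alt_kos(alt)) ko[take_gene()] <- k
      }
    }
  }
  catalog <- data.frame(gene_id = gene_id, mag_id = mag_id, ko = ko,
                        length_bp = sample(300:3000, n_g, replace = TRUE),
                        stringsAsFactors = FALSE)

  inactive_mags <- mags[stats::runif(config$n_mags) < p_inactive]
  inactive_samples <- design$sample_id[design$habitat == "bog"]

  mu_gene <- exp(stats::runif(n_g, log(2), log(50)))
  hab_gene <- stats::runif(n_g) < 0.2
  day_f <- as.numeric(factor(design$day))
  counts <- matrix(0L, nrow = n_g, ncol = config$n_samples,
                   dimnames = list(gene_id, design$sample_id))
  for (j in seq_len(config$n_samples)) {
    mu <- mu_gene * ifelse(hab_gene & design$habitat[j] == "fen",
                           2^config$habitat_effect, 1) *
      1.1^(day_f[j] - 1)
    counts[, j] <- if (config$nb_dispersion > 0) {
      stats::rnbinom(n_g, mu = mu, size = 1 / config$nb_dispersion)
    } else {
      stats::rpois(n_g, mu)
    }
  }
  # enforce the activity truth exactly
  for (m in mags) {
    rows <- which(mag_id == m)
    for (j in seq_len(config$n_samples)) {
      tot <- sum(counts[rows, j])
      if (m %in% inactive_mags &&
            design$sample_id[j] %in% inactive_samples) {
        target <- sample(0:15, 1)
        counts[rows, j] <- 0L
        if (target > 0) {
          pick <- sample(rows, min(target, length(rows)))
          counts[pick, j] <- counts[pick, j] +
            as.integer(stats::rmultinom(1, target, rep(1, length(pick))))
        }
      } else if (tot <= 15) {
        counts[rows[1], j] <- counts[rows[1], j] + (16L - as.integer(tot))
      }
    }
  }
  active <- lapply(stats::setNames(design$sample_id, design$sample_id),
                   function(s) {
                     if (s %in% inactive_samples) {
                       sort(setdiff(mags, inactive_mags))
                     } else {
                       sort(mags)
                     }
                   })
  list(counts = counts, catalog = catalog, design = design,
       truth = list(active_mag_ids = active, encoded = encoded,
                    inactive_mags = inactive_mags))
}

# KOs needed to satisfy one alternative (all subunits of a complex; for a
# nested expression, every step's first alternative).
alt_kos <- function(node) {
  switch(node$type,
         ko = node$ko,
         complex = unlist(lapply(node$members, alt_kos)),
         step = alt_kos(node$alts[[1L]]),
         expr = unlist(lapply(node$steps, alt_kos)))
}

#' Generate headspace gas time series with known totals
#'
#' Monotone production trajectories for CO2 and CH4 in two habitats
#' (triplicate tubes), converted to headspace ppm by inverting the
#' headspace+dissolved accounting so that [total_gas_table()] on the
#' noiseless series recovers the true totals exactly. Fen CH4 production
#' exceeds bog by `ch4_habitat_ratio`. Multiplicative noise is applied on
#' the ppm scale; a running maximum keeps each tube's series monotone
#' nondecreasing.
#'
#' @param config a [synth_config()] (supplies the seed).
#' @param days measurement days.
#' @param ch4_habitat_ratio fen:bog CH4 total-production ratio (default 40).
#' @param noise_sd multiplicative (log-scale) ppm noise sd (default 0:
#'   noiseless).
#' @param production_scale global multiplier on production (0 gives a
#'   zero-production scenario with constant ppm).
#' @param constants a [henry_constants()] object.
#' @return list with `samples` (gas CSV dialect data frame: sample_id,
#'   day, gas, ppm, temp_C, pH, headspace_mL, liquid_mL) and `truth`
#'   (habitat, gas, day, rep, true_total_mol).
#' @export
generate_gas_series <- function(config = synth_config(),
                                days = c(0, 7, 14, 21, 28, 35),
                                ch4_habitat_ratio = 40, noise_sd = 0,
                                production_scale = 1,
                                constants = henry_constants()) {
  stopifnot(inherits(config, "synth_config"), all(days >= 0),
            max(days) > 0, ch4_habitat_ratio > 0, noise_sd >= 0,
            production_scale >= 0)
  set.seed(config$seed + 2L)
  geom <- balch_tube_preset()
  temp_C <- geom$temperature_K - 273.15
  pH <- c(bog = 4.2, fen = 5.6)
  finals <- list(
    bog = c(CO2 = 5e-5, CH4 = 2e-6),
    fen = c(CO2 = 8e-5, CH4 = 2e-6 * ch4_habitat_ratio)
  )
  rows <- list()
  truth <- list()
  for (h in names(finals)) {
    for (g in c("CO2", "CH4")) {
      coeff <- 1e-6 * geom$headspace_volume_L /
        (GAS_CONSTANT_L_ATM * geom$temperature_K) +
        dissolved_concentration(g, 1e-6, pH[[h]], geom$temperature_K,
                                constants) * geom$liquid_volume_L
      for (rep_i in 1:3) {
        tot <- production_scale * finals[[h]][[g]] * (days / max(days))^1.5
        ppm <- tot / coeff
        if (noise_sd > 0) {
          ppm <- cummax(ppm * exp(stats::rnorm(length(ppm), 0, noise_sd)))
        }
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sprintf("%s_%s_r%d", h, g, rep_i),
          day = days, gas = g, ppm = ppm, temp_C = temp_C,
          pH = pH[[h]], headspace_mL = geom$headspace_volume_L * 1000,
          liquid_mL = geom$liquid_volume_L * 1000,
          stringsAsFactors = FALSE)
        truth[[length(truth) + 1L]] <- data.frame(
          habitat = h, gas = g, day = days, rep = rep_i,
          true_total_mol = tot, stringsAsFactors = FALSE)
      }
    }
  }
  list(samples = do.call(rbind, rows), truth = do.call(rbind, truth))
}

#' Generate a planted methane-correlated metabolite module
#'
#' A latent factor is constructed whose sample Pearson correlation with
#' the methane vector equals `planted_module_gas_correlation` exactly
#' (before feature-level noise). Module members are the factor plus
#' independent Gaussian noise; background features are independent of the
#' gas.
#'
#' @param config a [synth_config()].
#' @param n_background number of background features (default: same as
#'   the module size).
#' @param feature_noise_sd feature-level noise sd relative to the
#'   unit-variance factor (default 0.3).
#' @return list with `intensities` (feature x sample matrix), `gas`
#'   (per-sample methane vector), and `truth` (`module_membership` named
#'   vector: `"M1"` for members, `"grey"` for background; `latent_factor`).
#' @export
generate_methane_module_data <- function(config = synth_config(),
                                         n_background = NULL,
                                         feature_noise_sd = 0.3) {
  stopifnot(inherits(config, "synth_config"))
  rho <- config$planted_module_gas_correlation
  n <- config$n_samples
  m <- config$planted_module_size
  if (is.null(n_background)) n_background <- m
  set.seed(config$seed + 3L)
  gas <- stats::rnorm(n, mean = 10, sd = 2)
  gs <- drop(scale(gas))
  e <- stats::rnorm(n)
  e_perp <- stats::residuals(stats::lm(e ~ gs))
  f <- if (abs(rho) == 1) {
    sign(rho) * gs
  } else {
    rho * gs + sqrt(1 - rho^2) * drop(scale(e_perp))
  }
  ids <- c(sprintf("MOD%03d", seq_len(m)),
           sprintf("BG%03d", seq_len(n_background)))
  x <- matrix(0, nrow = length(ids), ncol = n,
              dimnames = list(ids, sprintf("S%02d", seq_len(n))))
  for (i in seq_len(m)) {
    x[i, ] <- f + stats::rnorm(n, 0, feature_noise_sd)
  }
  for (i in seq_len(n_background)) {
    x[m + i, ] <- stats::rnorm(n)
  }
  membership <- stats::setNames(c(rep("M1", m),
                                  rep("grey", n_background)), ids)
  list(intensities = x, gas = stats::setNames(gas, colnames(x)),
       truth = list(module_membership = membership, latent_factor = f))
}
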