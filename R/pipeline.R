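# End-to-end orchestration: simulate inputs (optional), clean the feature
# table, transform, fit per-feature contrasts, account total gas,
# normalize and score pathway expression, curate MAGs, and detect
# methane-correlated modules; every stage writes a fresh artifact under
# the run directory and the run is summarized in a JSON manifest with
# parameter values, input checksums and stage row counts.

#' Demo pathway definitions
#'
#' A small set of redox pathway definitions in the KEGG logical-expression
#' dialect, used by the pipeline demo and the simulator. These are
#' synthetic stand-ins with the structural shapes that matter
#' (alternatives, complexes, multi-step chains), not curated KEGG content.
#'
#' @return data frame with `pathway_id`, `name`, `category`,
#'   `expression`, and parsed `ast`.
#' @export
demo_pathway_definitions <- function() {
  df <- data.frame(
    pathway_id = c("emp_glycolysis", "ed_glycolysis", "acetate_ferm",
                   "ethanol_ferm", "hydro_methanogenesis"),
    name = c("EMP glycolysis", "ED glycolysis",
             "acetate fermentation", "ethanol fermentation",
             "hydrogenotrophic methanogenesis"),
    category = c("oxidative", "oxidative", "reductive", "reductive",
                 "reductive"),
    expression = c(
      "K00844,K00845 K01810 K00850 K01623,K01624 K00134 K00927",
      "K00036 K01057 K00033 K02446",
      "K00625 K00925",
      "K00016,K00101 K04072",
      "K00200+K00201+K00202 K00577+K00578+K00579 K00399+K00401"),
    stringsAsFactors = FALSE)
  df$ast <- lapply(df$expression, parse_pathway_logic)
  df
}

#' Analysis configuration
#'
#' @param out_dir run output directory (created if absent).
#' @param seed RNG seed for the simulate stage.
#' @param simulate generate inputs with the synthetic-data module
#'   (default TRUE); otherwise `features`, `counts`, `catalog`, `defs`,
#'   `design`, `gas` must point to existing files.
#' @param features,counts,catalog,defs,design,gas input file paths
#'   (ignored when `simulate = TRUE`).
#' @param synth a [synth_config()] used by the simulate stage.
#' @param cleaning a [cleaning_params()].
#' @param network a [network_params()].
#' @param curation a [curation_params()].
#' @param henry a [henry_constants()].
#' @return an `analysis_config` list.
#' @export
analysis_config <- function(out_dir, seed = 1L, simulate = TRUE,
                            features = NULL, counts = NULL,
                            catalog = NULL, defs = NULL, design = NULL,
                            gas = NULL,
                            synth = synth_config(seed = seed),
                            cleaning = cleaning_params(),
                            network = network_params(),
                            curation = curation_params(),
                            henry = henry_constants()) {
  structure(list(out_dir = out_dir, seed = seed, simulate = simulate,
                 features = features, counts = counts, catalog = catalog,
                 defs = defs, design = design, gas = gas, synth = synth,
                 cleaning = cleaning, network = network,
                 curation = curation, henry = henry),
            class = "analysis_config")
}

#' Validate pipeline inputs
#'
#' Schema checks on every input file named by the configuration. Each
#' finding is a row with a severity (`"fatal"` or `"warning"`); fatal
#' findings prevent [run_pipeline()] from starting.
#'
#' @param config an [analysis_config()].
#' @return data frame with `severity` and `message` (0 rows when clean).
#' @export
validate_inputs <- function(config) {
  findings <- list()
  add <- function(severity, message) {
    findings[[length(findings) + 1L]] <<-
      data.frame(severity = severity, message = message,
                 stringsAsFactors = FALSE)
  }
  if (!config$simulate) {
    paths <- c(features = config$features, counts = config$counts,
               catalog = config$catalog, defs = config$defs,
               design = config$design, gas = config$gas)
    for (nm in names(paths)) {
      if (is.null(paths[[nm]]) || !file.exists(paths[[nm]])) {
        add("fatal", sprintf("input '%s' missing: %s", nm,
                             if (is.null(paths[[nm]])) "(not set)"
                             else paths[[nm]]))
      }
    }
    if (nrow(do.call(rbind, c(findings,
                              list(data.frame(severity = character(0),
                                              message = character(0))))))) {
      return(do.call(rbind, findings))
    }
    ft <- tryCatch(read_feature_table(config$features), error = identity)
    if (inherits(ft, "error")) {
      add("fatal", paste("feature table unreadable:",
                         conditionMessage(ft)))
    } else if (any(lengths(ft$meta$ms2) == 0)) {
      add("warning", sprintf("%d features have empty MS2 lists",
                             sum(lengths(ft$meta$ms2) == 0)))
    }
    counts <- tryCatch(read_counts(config$counts), error = identity)
    catalog <- tryCatch(read_gene_catalog(config$catalog),
                        error = identity)
    if (inherits(counts, "error")) {
      add("fatal", paste("counts unreadable:", conditionMessage(counts)))
    } else if (!inherits(catalog, "error")) {
      orphan <- setdiff(rownames(counts), catalog$gene_id)
      if (length(orphan)) {
        add("fatal", sprintf("%d genes in counts absent from catalog (e.g. %s)",
                             length(orphan), orphan[1]))
      }
    }
    if (inherits(catalog, "error")) {
      add("fatal", paste("catalog unreadable:",
                         conditionMessage(catalog)))
    }
    defs <- tryCatch(read_pathway_definitions(config$defs),
                     error = identity)
    if (inherits(defs, "error")) {
      add("fatal", paste("pathway definitions unreadable:",
                         conditionMessage(defs)))
    }
  }
  if (length(findings)) do.call(rbind, findings)
  else data.frame(severity = character(0), message = character(0))
}

pipeline_log <- function(con, ...) {
  msg <- sprintf(...)
  message("[redoxomics] ", msg)
  if (!is.null(con)) writeLines(paste0("[redoxomics] ", msg), con)
}

#' Run the full pipeline
#'
#' Stages: simulate (optional) -> clean -> transform -> stats -> gas
#' totals -> pathway expression -> MAG curation -> methane modules.
#' Every intermediate artifact is written under `config$out_dir`;
#' `manifest.json` records parameter values (including every
#' literature-stated default: RT tolerance 0.005, correlation 0.98,
#' 5 ppm, power 14, activity threshold 15, encoding fraction 0.6,
#' top 100), input checksums and stage row counts. Identical config and
#' seed give identical manifest checksums.
#'
#' @param config an [analysis_config()].
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  findings <- validate_inputs(config)
  if (any(findings$severity == "fatal")) {
    stop("input validation failed:\n  ",
         paste(findings$message[findings$severity == "fatal"],
               collapse = "\n  "))
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  logfile <- file.path(config$out_dir, "run.log")
  con <- file(logfile, open = "wt")
  on.exit(close(con))
  stages <- list()
  stage <- function(name, fn) {
    pipeline_log(con, "stage %s", name)
    out <- tryCatch(fn(), error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    stages[[name]] <<- out
    out
  }
  path_of <- function(name) file.path(config$out_dir, name)

  # 1. simulate or load
  if (config$simulate) {
    stage("simulate", function() {
      defs <- demo_pathway_definitions()
      fg <- generate_feature_table(config$synth)
      tc <- generate_transcript_counts(config$synth, defs)
      gs <- generate_gas_series(config$synth, noise_sd = 0.01)
      write_feature_table(fg$table, path_of("features.tsv"))
      write_design(fg$design, path_of("design.csv"))
      write_counts(tc$counts, path_of("counts.tsv"))
      write_gene_catalog(tc$catalog, path_of("catalog.tsv"))
      write_pathway_definitions(defs, path_of("pathways.tsv"))
      write_gas_series(gs$samples, path_of("gas.csv"))
      write_truth_labels(list(
        artifact_feature_ids = fg$truth$artifact_feature_ids,
        inactive_mags = tc$truth$inactive_mags),
        path_of("truth.json"))
      list(rows = nrow(fg$table$intensities))
    })
    in_paths <- c(features = path_of("features.tsv"),
                  counts = path_of("counts.tsv"),
                  catalog = path_of("catalog.tsv"),
                  defs = path_of("pathways.tsv"),
                  design = path_of("design.csv"),
                  gas = path_of("gas.csv"))
  } else {
    in_paths <- c(features = config$features, counts = config$counts,
                  catalog = config$catalog, defs = config$defs,
                  design = config$design, gas = config$gas)
  }
  ft <- read_feature_table(in_paths[["features"]])
  design <- read_design(in_paths[["design"]])
  counts <- read_counts(in_paths[["counts"]])
  catalog <- read_gene_catalog(in_paths[["catalog"]])
  defs <- read_pathway_definitions(in_paths[["defs"]])
  gas <- read_gas_series(in_paths[["gas"]])

  # 2. clean
  cleaned <- stage("clean", function() {
    out <- clean_features(ft, config$cleaning)
    write_feature_table(out$table, path_of("cleaned.tsv"))
    jsonlite::write_json(
      list(removed_as_fragment = out$report$removed_as_fragment,
           removed_as_halogen = out$report$removed_as_halogen,
           retained = out$report$retained),
      path_of("cleaning_report.json"), digits = NA, pretty = TRUE)
    c(out, rows = length(out$report$retained))
  })

  # 3. transform
  transformed <- stage("transform", function() {
    tr <- pareto_scale(glog_transform(cleaned$table))
    write_feature_table(tr, path_of("transformed.tsv"))
    list(table = tr, rows = nrow(tr$intensities))
  })

  # 4. per-feature stats
  stats_out <- stage("stats", function() {
    res <- fit_feature_models(transformed$table, design)
    utils::write.table(res, path_of("contrasts.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    list(result = res, rows = nrow(res))
  })

  # 5. gas totals
  gas_out <- stage("gas_totals", function() {
    tot <- total_gas_table(gas, config$henry)
    write_gas_series(tot, path_of("gas_totals.csv"))
    list(result = tot, rows = nrow(tot))
  })

  # 6. pathway expression
  pw_out <- stage("pathway_expression", function() {
    norm <- getmm_normalize(counts, catalog)
    kom <- ko_expression(norm$normalized, catalog)
    scores <- pathway_scores(defs, kom)
    utils::write.table(
      data.frame(pathway_id = rownames(scores), scores,
                 check.names = FALSE),
      path_of("pathway_scores.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    list(normalized = norm, scores = scores, rows = nrow(scores))
  })

  # 7. MAG curation
  mag_out <- stage("mag_curation", function() {
    profiles <- mag_profiles(counts, catalog, defs, config$curation,
                             normalized = pw_out$normalized$normalized)
    enc <- vapply(defs$pathway_id, function(p) {
      encoding_proportion(profiles, p)
    }, numeric(1))
    df <- data.frame(pathway_id = defs$pathway_id,
                     encoding_proportion = enc)
    utils::write.table(df, path_of("mag_encoding.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    list(profiles = profiles, rows = length(profiles))
  })

  # 8. methane modules
  mod_out <- stage("methane_modules", function() {
    # per-sample methane totals aligned to the metabolite samples: the
    # simulated gas series is per tube; collapse CH4 finals per habitat/day
    ch4 <- gas_out$result[gas_out$result$gas == "CH4", , drop = FALSE]
    gas_by_sample <- vapply(seq_len(nrow(design)), function(i) {
      sel <- grepl(design$habitat[i], ch4$sample_id) &
        ch4$day <= design$day[i]
      if (!any(sel)) 0 else max(ch4$total_mol[sel])
    }, numeric(1))
    ana <- methane_module_analysis(transformed$table, gas_by_sample,
                                   config$network)
    utils::write.table(
      data.frame(feature_id = names(ana$modules), module = ana$modules),
      path_of("modules.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    list(analysis = ana, rows = length(ana$modules))
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("redoxomics")),
    seed = config$seed,
    parameters = list(
      rt_tolerance = config$cleaning$rt_tolerance,
      correlation_threshold = config$cleaning$correlation_threshold,
      ppm_tolerance = config$cleaning$ppm_tolerance,
      soft_threshold_beta = config$network$beta,
      min_module_size = config$network$min_module_size,
      top_n = config$network$top_n,
      activity_threshold = config$curation$activity_threshold,
      encoding_fraction = config$curation$encoding_fraction
    ),
    input_checksums = as.list(tools::md5sum(unname(in_paths))),
    stage_rows = list(
      simulate = if (config$simulate) stages$simulate$rows else NA,
      clean = stages$clean$rows,
      transform = stages$transform$rows,
      stats = stages$stats$rows,
      gas_totals = stages$gas_totals$rows,
      pathway_expression = stages$pathway_expression$rows,
      mag_curation = stages$mag_curation$rows,
      methane_modules = stages$methane_modules$rows
    )
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  pipeline_log(con, "done: %d stages", length(manifest$stage_rows))
  invisible(manifest)
}
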