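#' Pipeline configuration
#'
#' One configuration object drives every stage of the analysis pipeline.
#' Any element can be overridden; unspecified elements keep their defaults.
#'
#' @param generator Named list of overrides for [generator_config()].
#' @param rf Named list: `grid` (hyperparameter data frame),
#'   `train_fraction`, `n_tuning_folds`.
#' @param effects Named list: `radius_km` for the control/impact comparison.
#' @param inference Named list: `threshold`, `delta_max`, `n_perm`.
#' @param seed Master seed; stages derive their streams from it.
#' @return List of class `reef_pipeline_config`.
#' @export
pipeline_config <- function(generator = list(), rf = list(),
                            effects = list(), inference = list(),
                            seed = 1L) {
  cfg <- list(
    generator = utils::modifyList(list(), generator),
    rf = utils::modifyList(
      list(grid = default_rf_grid(), train_fraction = 0.75,
           n_tuning_folds = 5),
      rf
    ),
    effects = utils::modifyList(list(radius_km = 20), effects),
    inference = utils::modifyList(
      list(threshold = 0.9, delta_max = 4, n_perm = 999),
      inference
    ),
    seed = as.integer(seed)
  )
  structure(cfg, class = "reef_pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path Path to a YAML file whose top-level keys match the arguments
#'   of [pipeline_config()].
#' @return A `reef_pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  rf <- raw$rf %||% list()
  if (!is.null(rf$grid)) rf$grid <- as.data.frame(rf$grid)
  pipeline_config(
    generator = raw$generator %||% list(),
    rf = rf,
    effects = raw$effects %||% list(),
    inference = raw$inference %||% list(),
    seed = raw$seed %||% 1L
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

pipeline_files <- function(outdir) {
  file.path(outdir, c(
    sites = "sites.csv", fish = "fish.csv", habitat = "habitat.csv",
    species = "species.csv", category_map = "category_map.csv",
    truth = "truth.csv", config = "config.json",
    biomass = "biomass_by_site.csv", habitat_site = "habitat_by_site.csv",
    counterfactual = "counterfactual.csv", model_card = "model_card.json",
    summary = "protection_summary.csv", pairs = "mpa_effect_pairs.csv",
    model_set = "model_set_global.csv", top_model = "top_model.json",
    report = "report.md", manifest = "manifest.json"
  )) |> setNames(c("sites", "fish", "habitat", "species", "category_map",
                   "truth", "config", "biomass", "habitat_site",
                   "counterfactual", "model_card", "summary", "pairs",
                   "model_set", "top_model", "report", "manifest"))
}

require_file <- function(path, produced_by) {
  if (!file.exists(path)) {
    stop(sprintf("missing intermediate '%s'; run the '%s' stage first",
                 basename(path), produced_by), call. = FALSE)
  }
  path
}

read_csv_quiet <- function(path) {
  tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
}

#' Run the reef MPA analysis pipeline
#'
#' Executes the requested stages in dependency order, reading and writing
#' plain CSV/JSON artifacts under `outdir` so that partial runs can resume
#' from existing intermediates. Stages: `simulate` (synthetic data with
#' ground truth), `process` (biomass reconstruction + habitat
#' harmonization), `counterfactual` (fished-site random forest and response
#' ratios), `effects` (protection-level summaries and control/impact
#' comparison), `infer` (two-stage multi-model mixed-effects inference) and
#' `report` (run summary). A manifest with file digests is written at the
#' end of every invocation.
#'
#' @param outdir Output directory (created if needed).
#' @param stages Character vector of stages to execute.
#' @param config A [pipeline_config()].
#' @param seed Optional master-seed override.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a named list of artifact paths.
#' @export
run_pipeline <- function(outdir,
                         stages = c("simulate", "process", "counterfactual",
                                    "effects", "infer", "report"),
                         config = pipeline_config(), seed = NULL,
                         quiet = FALSE) {
  stages <- match.arg(stages, c("simulate", "process", "counterfactual",
                                "effects", "infer", "report"),
                      several.ok = TRUE)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- pipeline_files(outdir)
  say <- function(...) if (!quiet) message(sprintf(...))

  if ("simulate" %in% stages) {
    say("stage simulate: generating synthetic survey data")
    gen_args <- utils::modifyList(config$generator, list(seed = config$seed),
                                  keep.null = TRUE)
    gcfg <- do.call(generator_config, gen_args)
    sim <- simulate_reef_data(gcfg)
    sites_out <- sim$sites[, !grepl("^true_cover_", names(sim$sites))]
    write.csv(sites_out, paths["sites"], row.names = FALSE)
    write.csv(sim$surveys, paths["fish"], row.names = FALSE)
    habitat_wide <- sim$habitat |>
      tidyr::pivot_wider(names_from = "category", values_from = "value",
                         values_fill = 0)
    write.csv(habitat_wide, paths["habitat"], row.names = FALSE)
    write.csv(sim$pool, paths["species"], row.names = FALSE)
    write.csv(default_category_map(), paths["category_map"], row.names = FALSE)
    truth_out <- dplyr::bind_cols(
      sim$truth,
      sim$sites[, grepl("^true_cover_", names(sim$sites))]
    )
    write.csv(truth_out, paths["truth"], row.names = FALSE)
    jsonlite::write_json(unclass(gcfg), paths["config"], auto_unbox = TRUE,
                         digits = NA)
  }

  if ("process" %in% stages) {
    say("stage process: reconstructing biomass and harmonizing habitat")
    fish <- read_csv_quiet(require_file(paths["fish"], "simulate"))
    pool <- read_csv_quiet(require_file(paths["species"], "simulate"))
    map <- read_csv_quiet(require_file(paths["category_map"], "simulate"))
    habitat_wide <- read_csv_quiet(require_file(paths["habitat"], "simulate"))
    keys <- c("site_id", "survey_date", "transect_id", "dialect", "layer")
    habitat <- habitat_wide |>
      tidyr::pivot_longer(cols = -dplyr::all_of(keys),
                          names_to = "category", values_to = "value") |>
      dplyr::filter(.data$value > 0 | .data$dialect == "photo_quadrat")
    processed <- suppressMessages(
      process_surveys(fish, pool, habitat, category_map = map)
    )
    write.csv(processed$biomass_by_site, paths["biomass"], row.names = FALSE)
    write.csv(processed$habitat_by_site, paths["habitat_site"],
              row.names = FALSE)
  }

  if ("counterfactual" %in% stages) {
    say("stage counterfactual: training fished-site forest")
    biomass <- read_csv_quiet(require_file(paths["biomass"], "process"))
    sites <- read_csv_quiet(require_file(paths["sites"], "simulate"))
    settings <- rf_settings(train_fraction = config$rf$train_fraction,
                            n_tuning_folds = config$rf$n_tuning_folds,
                            seed = config$seed)
    stage <- counterfactual_stage(biomass, sites,
                                  grid = config$rf$grid, settings = settings)
    write.csv(stage$ratios, paths["counterfactual"], row.names = FALSE)
    jsonlite::write_json(stage$model_card, paths["model_card"],
                         auto_unbox = TRUE, digits = NA)
  }

  if ("effects" %in% stages) {
    say("stage effects: protection-level summaries")
    ratios <- read_csv_quiet(require_file(paths["counterfactual"],
                                          "counterfactual"))
    sites <- read_csv_quiet(require_file(paths["sites"], "simulate"))
    summary <- summarize_by_protection(ratios)
    write.csv(summary, paths["summary"], row.names = FALSE)
    pairs <- tryCatch(
      suppressMessages(control_impact_effects(ratios, sites,
                                              config$effects$radius_km)),
      error = function(e) NULL
    )
    if (!is.null(pairs)) {
      pairs$pearson_r <- attr(pairs, "pearson_r")
      write.csv(pairs, paths["pairs"], row.names = FALSE)
    }
  }

  if ("infer" %in% stages) {
    say("stage infer: two-stage multi-model inference")
    ratios <- read_csv_quiet(require_file(paths["counterfactual"],
                                          "counterfactual"))
    sites <- read_csv_quiet(require_file(paths["sites"], "simulate"))
    habitat_site <- read_csv_quiet(require_file(paths["habitat_site"],
                                                "process"))
    inf <- suppressWarnings(suppressMessages(run_inference(
      ratios, sites, habitat_site,
      threshold = config$inference$threshold,
      delta_max = config$inference$delta_max,
      n_perm = config$inference$n_perm,
      seed = config$seed
    )))
    for (s in names(inf$importance)) {
      write.csv(inf$importance[[s]],
                file.path(outdir, sprintf("importance_%s.csv", s)),
                row.names = FALSE)
    }
    global <- inf$global_records
    global$terms <- vapply(global$terms, paste, character(1), collapse = " + ")
    write.csv(global, paths["model_set"], row.names = FALSE)
    jsonlite::write_json(list(
      terms = inf$top_model$terms[[1]],
      k = inf$top_model$k, aicc = inf$top_model$aicc,
      weight = inf$top_model$weight,
      estimates = as.list(setNames(inf$partial_effects$estimate,
                                   inf$partial_effects$term)),
      ci_low = as.list(setNames(inf$partial_effects$ci_low,
                                inf$partial_effects$term)),
      ci_high = as.list(setNames(inf$partial_effects$ci_high,
                                 inf$partial_effects$term)),
      r2_marginal = inf$r2[["marginal"]],
      r2_conditional = inf$r2[["conditional"]],
      morans_i = inf$morans$observed,
      morans_p = inf$morans$p_value,
      reduced_terms = inf$reduced_terms
    ), paths["top_model"], auto_unbox = TRUE, digits = NA)
  }

  if ("report" %in% stages) {
    say("stage report: writing run summary")
    write_report(outdir, paths)
  }

  write_manifest(outdir, paths, config)
  invisible(as.list(paths))
}

write_report <- function(outdir, paths) {
  lines <- c("# Pipeline run summary", "")
  if (file.exists(paths["summary"])) {
    s <- read_csv_quiet(paths["summary"])
    lines <- c(lines, "## Observed biomass relative to the fished counterfactual",
               "")
    for (i in seq_len(nrow(s))) {
      lines <- c(lines, sprintf(
        "- %s: %.1f%% of predicted (mean lnrr %.4f +/- %.4f SEM, n = %d)",
        s$protection[i], s$percent_of_predicted[i], s$mean_lnrr[i],
        s$sem[i], s$n_sites[i]))
    }
    lines <- c(lines, "")
  }
  if (file.exists(paths["top_model"])) {
    tm <- jsonlite::read_json(paths["top_model"], simplifyVector = TRUE)
    lines <- c(lines, "## Top mixed model",
               sprintf("- terms: %s", paste(tm$terms, collapse = ", ")),
               sprintf("- marginal R2 %.3f, conditional R2 %.3f",
                       tm$r2_marginal, tm$r2_conditional),
               sprintf("- Moran's I on residuals: %.4f (p = %.3f)",
                       tm$morans_i, tm$morans_p), "")
  }
  writeLines(lines, paths["report"])
}

write_manifest <- function(outdir, paths, config) {
  existing <- paths[file.exists(paths)]
  existing <- existing[names(existing) != "manifest"]
  extra <- list.files(outdir, pattern = "^importance_.*\\.csv$",
                      full.names = TRUE)
  files <- c(unname(existing), extra)
  digests <- as.character(tools::md5sum(files))
  cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                               force = TRUE, digits = NA)
  tmp <- tempfile(); writeLines(cfg_json, tmp)
  manifest <- list(
    package_version = as.character(utils::packageVersion("reefmpa")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    config_md5 = as.character(tools::md5sum(tmp)),
    files = setNames(as.list(digests), basename(files))
  )
  unlink(tmp)
  jsonlite::write_json(manifest, paths["manifest"], auto_unbox = TRUE)
}

#' Validate pipeline input files
#'
#' Schema and range checks on the raw input CSVs: required columns, legal
#' size categories, non-negative counts, percent-cover bounds by dialect,
#' in-situ layer limits, protection vocabulary and depth range. Returns a
#' tibble of problems (zero rows when everything passes).
#'
#' @param outdir Directory holding `fish.csv`, `habitat.csv`, `sites.csv`
#'   (any subset; missing files are reported).
#' @return Tibble with columns `file`, `problem`; attribute `ok` is TRUE
#'   when no problems were found.
#' @export
validate_inputs <- function(outdir) {
  paths <- pipeline_files(outdir)
  problems <- list()
  note <- function(file, problem) {
    problems[[length(problems) + 1L]] <<- tibble::tibble(file = file,
                                                         problem = problem)
  }

  if (file.exists(paths["fish"])) {
    fish <- read_csv_quiet(paths["fish"])
    need <- c("site_id", "survey_date", "transect_id", "species", "family",
              "size_class_cm", "count")
    miss <- setdiff(need, names(fish))
    if (length(miss) > 0) {
      note("fish.csv", paste("missing column(s):", paste(miss, collapse = ", ")))
    } else {
      legal <- legal_size_categories(max(fish$size_class_cm, 15))
      bad <- which(!fish$size_class_cm %in% legal)
      if (length(bad) > 0) {
        note("fish.csv", sprintf("illegal size category %g in row %d",
                                 fish$size_class_cm[bad[1]], bad[1]))
      }
      if (any(fish$count < 0)) note("fish.csv", "negative count")
    }
  } else note("fish.csv", "file not found")

  if (file.exists(paths["habitat"])) {
    hab <- read_csv_quiet(paths["habitat"])
    keys <- c("site_id", "survey_date", "transect_id", "dialect", "layer")
    miss <- setdiff(keys, names(hab))
    if (length(miss) > 0) {
      note("habitat.csv", paste("missing column(s):",
                                paste(miss, collapse = ", ")))
    } else {
      vals <- as.matrix(hab[, setdiff(names(hab), keys), drop = FALSE])
      if (any(!hab$dialect %in% c("photo_quadrat", "in_situ"))) {
        note("habitat.csv", "unknown dialect value")
      }
      pq <- hab$dialect == "photo_quadrat"
      if (any(pq) && any(rowSums(vals[pq, , drop = FALSE]) > 100 + 1e-8)) {
        note("habitat.csv", "photo-quadrat covers sum to more than 100%")
      }
      ins <- hab$dialect == "in_situ"
      if (any(ins) && any(rowSums(vals[ins, , drop = FALSE]) > 50)) {
        note("habitat.csv", "in-situ layer exceeds 50 points")
      }
    }
  } else note("habitat.csv", "file not found")

  if (file.exists(paths["sites"])) {
    sites <- read_csv_quiet(paths["sites"])
    if ("protection" %in% names(sites)) {
      bad <- setdiff(unique(sites$protection),
                     c("fished", "partially_protected", "fully_protected"))
      if (length(bad) > 0) {
        note("sites.csv", paste("unknown protection level:",
                                paste(bad, collapse = ", ")))
      }
    } else note("sites.csv", "missing column(s): protection")
    if ("depth_m" %in% names(sites) &&
        any(sites$depth_m < 1 | sites$depth_m > 25)) {
      note("sites.csv", "depth outside the 1-25 m survey range")
    }
  } else note("sites.csv", "file not found")

  out <- if (length(problems) > 0) dplyr::bind_rows(problems) else {
    tibble::tibble(file = character(), problem = character())
  }
  attr(out, "ok") <- nrow(out) == 0
  out
}
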