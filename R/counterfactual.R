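#' Names of the broad-scale environmental predictor columns
#'
#' The counterfactual random forest uses exactly 13 predictors: site
#' latitude and longitude plus 11 ocean covariates (mean SST and ten
#' additional surface variables).
#' @return Character vector of 13 column names.
#' @export
env_feature_names <- function() {
  c("latitude", "longitude", "mean_sst", sprintf("env_%02d", 1:10))
}

#' Assemble the broad-scale environmental feature table
#'
#' Builds one row per site with the 13 predictors used by the counterfactual
#' model. If a daily SST series is supplied, the site-level mean SST is
#' computed over the two calendar years preceding (and excluding) the year
#' of the site's latest survey; otherwise a pre-computed `mean_sst` column
#' on `sites` is passed through. All other covariates are long-term means
#' taken directly from `sites`.
#'
#' @param sites Site table with `site_id`, `latitude`, `longitude`,
#'   `env_01`..`env_10`, and either `mean_sst` or a daily series.
#' @param sst_daily Optional tibble `site_id`, `date`, `sst` of daily SST.
#' @return Tibble `site_id` + the 13 predictor columns, no missing values.
#' @export
assemble_features <- function(sites, sst_daily = NULL) {
  needed <- setdiff(env_feature_names(), "mean_sst")
  if (!is.null(sst_daily)) {
    stopifnot(all(c("site_id", "date", "sst") %in% names(sst_daily)),
              "survey_date" %in% names(sites))
    sst_daily <- dplyr::mutate(sst_daily, year = as.integer(format(as.Date(.data$date), "%Y")))
    ref_year <- sites |>
      dplyr::transmute(.data$site_id,
                       survey_year = as.integer(format(as.Date(.data$survey_date), "%Y")))
    means <- sst_daily |>
      dplyr::inner_join(ref_year, by = "site_id") |>
      dplyr::filter(.data$year == .data$survey_year - 1 |
                      .data$year == .data$survey_year - 2) |>
      dplyr::group_by(.data$site_id) |>
      dplyr::summarise(mean_sst = mean(.data$sst), .groups = "drop")
    sites <- sites |>
      dplyr::select(-dplyr::any_of("mean_sst")) |>
      dplyr::left_join(means, by = "site_id")
  }
  missing_cols <- setdiff(c("site_id", env_feature_names()), names(sites))
  if (length(missing_cols) > 0) {
    stop("missing covariate columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  out <- sites[, c("site_id", env_feature_names())]
  bad <- !complete.cases(out)
  if (any(bad)) {
    stop("missing covariate values for site(s): ",
         paste(out$site_id[bad], collapse = ", "), call. = FALSE)
  }
  tibble::as_tibble(out)
}

#' Random-forest settings
#'
#' @param ntrees Number of trees (>= 100).
#' @param mtry Predictors sampled per split (1..13); `NULL` lets tuning pick.
#' @param min_node_size Minimal node size (>= 1); `NULL` lets tuning pick.
#' @param n_tuning_folds Cross-validation folds for RMSE tuning.
#' @param train_fraction Fraction of fished sites used for training.
#' @param seed RNG seed for splitting, fold assignment and forests.
#' @return List of class `reef_rf_settings`.
#' @export
rf_settings <- function(ntrees = 500, mtry = NULL, min_node_size = NULL,
                        n_tuning_folds = 5, train_fraction = 0.75, seed = 1L) {
  stopifnot(ntrees >= 100, n_tuning_folds >= 2,
            train_fraction > 0, train_fraction <= 1)
  if (!is.null(mtry)) stopifnot(mtry >= 1, mtry <= 13)
  if (!is.null(min_node_size)) stopifnot(min_node_size >= 1)
  structure(list(ntrees = ntrees, mtry = mtry, min_node_size = min_node_size,
                 n_tuning_folds = n_tuning_folds,
                 train_fraction = train_fraction, seed = as.integer(seed)),
            class = "reef_rf_settings")
}

#' Default hyperparameter grid for forest tuning
#' @return Data frame of candidate (ntrees, mtry, min_node_size) combinations.
#' @export
default_rf_grid <- function() {
  expand.grid(ntrees = 500, mtry = c(3, 6, 13), min_node_size = c(5, 15, 30))
}

#' Split fished-site data into training and test sets
#'
#' Only openly fished sites may enter the counterfactual model; any protected
#' site in the input is an error (leakage guard). The split is random,
#' disjoint, and reproducible under the seed.
#'
#' @param data Tibble of fished sites with a `protection` column.
#' @param train_fraction Training fraction (default 0.75).
#' @param seed Integer seed.
#' @return List with disjoint tibbles `train` and `test`.
#' @export
split_fished_train_test <- function(data, train_fraction = 0.75, seed = 1L) {
  if (any(as.character(data$protection) != "fished")) {
    stop("protected sites must not enter counterfactual training", call. = FALSE)
  }
  n <- nrow(data)
  n_train <- round(n * train_fraction)
  idx <- with_local_seed(seed, sample(n, n_train))
  list(train = data[sort(idx), , drop = FALSE],
       test = data[setdiff(seq_len(n), idx), , drop = FALSE])
}

#' Tune and fit the counterfactual random forest
#'
#' Grid search over (ntrees, mtry, min_node_size) by k-fold cross-validated
#' RMSE on the training set, refit of the winning combination on the full
#' training data, and diagnostics: out-of-bag (OOB) error, optional test-set
#' R-squared, and permutation variable importance.
#'
#' @param train Training tibble containing `observed_log10` and the 13
#'   predictor columns of [env_feature_names()].
#' @param test Optional held-out tibble with the same columns.
#' @param grid Hyperparameter grid, default [default_rf_grid()].
#' @param settings [rf_settings()] controlling folds and seed.
#' @return List of class `reef_rf`: `model` (ranger fit), `best`
#'   (chosen hyperparameters), `cv_results`, `oob_mse`, `oob_rmse`,
#'   `test_r2`, `importance` (sorted permutation importance), `n_train`.
#' @export
tune_and_fit_rf <- function(train, test = NULL, grid = default_rf_grid(),
                            settings = rf_settings()) {
  feats <- env_feature_names()
  stopifnot(all(c("observed_log10", feats) %in% names(train)))
  if (nrow(train) < 50) stop("need at least 50 training rows", call. = FALSE)
  if (sd(train$observed_log10) == 0) {
    stop("degenerate (constant) response", call. = FALSE)
  }
  grid$mtry <- pmin(grid$mtry, length(feats))

  with_local_seed(settings$seed + 101L, {
    folds <- sample(rep(seq_len(settings$n_tuning_folds), length.out = nrow(train)))
    cv_rmse <- vapply(seq_len(nrow(grid)), function(g) {
      errs <- vapply(seq_len(settings$n_tuning_folds), function(f) {
        tr <- train[folds != f, , drop = FALSE]
        ho <- train[folds == f, , drop = FALSE]
        fit <- ranger::ranger(
          x = tr[, feats], y = tr$observed_log10,
          num.trees = grid$ntrees[g], mtry = grid$mtry[g],
          min.node.size = grid$min_node_size[g],
          replace = TRUE, seed = settings$seed + f,
          num.threads = 1
        )
        pred <- predict(fit, data = ho[, feats])$predictions
        sqrt(mean((ho$observed_log10 - pred)^2))
      }, numeric(1))
      mean(errs)
    }, numeric(1))

    best <- grid[which.min(cv_rmse), , drop = FALSE]
    model <- ranger::ranger(
      x = train[, feats], y = train$observed_log10,
      num.trees = best$ntrees, mtry = best$mtry,
      min.node.size = best$min_node_size,
      replace = TRUE, importance = "permutation",
      seed = settings$seed, num.threads = 1
    )
    test_r2 <- NA_real_
    if (!is.null(test) && nrow(test) > 1) {
      pred <- predict(model, data = test[, feats])$predictions
      test_r2 <- 1 - sum((test$observed_log10 - pred)^2) /
        sum((test$observed_log10 - mean(test$observed_log10))^2)
    }
    structure(list(
      model = model,
      best = best,
      cv_results = cbind(grid, cv_rmse = cv_rmse),
      oob_mse = model$prediction.error,
      oob_rmse = sqrt(model$prediction.error),
      test_r2 = test_r2,
      importance = sort(ranger::importance(model), decreasing = TRUE),
      n_train = nrow(train),
      features = feats
    ), class = "reef_rf")
  })
}

#' @export
print.reef_rf <- function(x, ...) {
  cat("<reef_rf> counterfactual random forest\n")
  cat(sprintf("  n_train %d | ntrees %d, mtry %d, min.node %d\n",
              x$n_train, x$best$ntrees, x$best$mtry, x$best$min_node_size))
  cat(sprintf("  OOB MSE %.4f | test R2 %s\n", x$oob_mse,
              ifelse(is.na(x$test_r2), "NA", sprintf("%.3f", x$test_r2))))
  cat("  top predictors:", paste(names(head(x$importance, 3)), collapse = ", "),
      "\n")
  invisible(x)
}

#' Predict counterfactual (fished-baseline) log biomass at all sites
#'
#' Applies the fished-trained forest to every site, including protected
#' ones; the prediction is the biomass expected had the site been openly
#' fished. Predictions for sites that were in the training set are in-sample
#' (the same model benchmarks its own training sites) and therefore
#' optimistic; this is surfaced in the model card diagnostics.
#'
#' @param fit A `reef_rf` object from [tune_and_fit_rf()].
#' @param features Feature table from [assemble_features()] (any sites).
#' @return Tibble `site_id`, `predicted_log10`.
#' @export
predict_counterfactual <- function(fit, features) {
  stopifnot(inherits(fit, "reef_rf"))
  missing_cols <- setdiff(fit$features, names(features))
  if (length(missing_cols) > 0) {
    stop("feature schema mismatch; missing: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  pred <- predict(fit$model, data = features[, fit$features])$predictions
  tibble::tibble(site_id = features$site_id, predicted_log10 = as.numeric(pred))
}

#' Log response ratios of observed to predicted biomass
#'
#' lnrr = observed_log10 - predicted_log10, so 10^lnrr is the ratio of
#' observed to counterfactual-predicted biomass; `ratio_percent` expresses
#' it as a percentage of predicted biomass (100 means exactly as predicted).
#'
#' @param observed Tibble `site_id`, `survey_date`, `observed_log10`
#'   (and optionally `protection`).
#' @param predicted Tibble `site_id`, `predicted_log10`.
#' @return ResponseRatio tibble: keys, `observed_log10`, `predicted_log10`,
#'   `lnrr`, `ratio_percent`, and `protection` when supplied.
#' @examples
#' log_response_ratio(
#'   tibble::tibble(site_id = "s", survey_date = "2020-01-01",
#'                  observed_log10 = 1.50),
#'   tibble::tibble(site_id = "s", predicted_log10 = 1.44)
#' )
#' @export
log_response_ratio <- function(observed, predicted) {
  unmatched <- setdiff(observed$site_id, predicted$site_id)
  if (length(unmatched) > 0) {
    stop("no prediction for site(s): ", paste(head(unmatched, 5), collapse = ", "),
         call. = FALSE)
  }
  out <- observed |>
    dplyr::inner_join(predicted[, c("site_id", "predicted_log10")],
                      by = "site_id") |>
    dplyr::mutate(lnrr = .data$observed_log10 - .data$predicted_log10,
                  ratio_percent = 100 * 10^.data$lnrr)
  if (any(!is.finite(out$lnrr))) stop("non-finite lnrr produced", call. = FALSE)
  out
}

#' Fit the full counterfactual stage on processed site data
#'
#' Convenience wrapper: enforces the fished-only training rule, performs the
#' train/test split, tunes and fits the forest, predicts the fished baseline
#' everywhere and returns the response ratios together with a model card.
#'
#' @param biomass_by_site Site/date observed biomass
#'   (from [observed_log_biomass()]).
#' @param sites Site table with `protection` and environmental covariates.
#' @param grid,settings Passed to [tune_and_fit_rf()].
#' @return List: `ratios` (ResponseRatio tibble), `fit` (`reef_rf`),
#'   `model_card` (plain list for JSON serialization).
#' @export
counterfactual_stage <- function(biomass_by_site, sites,
                                 grid = default_rf_grid(),
                                 settings = rf_settings()) {
  features <- assemble_features(sites)
  data <- biomass_by_site |>
    dplyr::inner_join(sites[, c("site_id", "protection")], by = "site_id") |>
    dplyr::inner_join(features, by = "site_id")
  # latest survey per site only
  data <- data |>
    dplyr::group_by(.data$site_id) |>
    dplyr::slice_max(.data$survey_date, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()

  fished <- data |> dplyr::filter(as.character(.data$protection) == "fished")
  split <- split_fished_train_test(fished, settings$train_fraction, settings$seed)
  fit <- tune_and_fit_rf(split$train, split$test, grid, settings)
  predicted <- predict_counterfactual(fit, data)
  ratios <- log_response_ratio(
    data[, c("site_id", "survey_date", "observed_log10", "protection")],
    predicted
  )
  model_card <- list(
    hyperparameters = as.list(fit$best),
    n_train = fit$n_train,
    n_test = nrow(split$test),
    oob_mse = fit$oob_mse,
    test_r2 = fit$test_r2,
    importance_ranking = as.list(fit$importance),
    note = "predictions at training sites are in-sample and optimistic"
  )
  list(ratios = ratios, fit = fit, model_card = model_card)
}
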