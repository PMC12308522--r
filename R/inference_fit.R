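#' Deterministic spatial grid-cell identifiers
#'
#' Assigns each site to a square grid cell (default 100 x 100 km) by
#' floor-division of planar coordinates. Coordinates are projected with an
#' equirectangular approximation about a fixed reference latitude (-36.5
#' degrees, the centre of the temperate Australian domain), so the mapping
#' is deterministic, idempotent and independent of the input order or of
#' which sites are present.
#'
#' @param lat,lon Numeric vectors of coordinates (degrees).
#' @param cell_km Cell size in km (default 100).
#' @return Character vector of cell IDs like `"gx_gy"`.
#' @export
assign_grid_cell <- function(lat, lon, cell_km = 100) {
  stopifnot(all(is.finite(lat)), all(is.finite(lon)), cell_km > 0)
  ref_lat <- -36.5
  x_km <- lon * 111.32 * cos(ref_lat * pi / 180)
  y_km <- lat * 110.574
  sprintf("%d_%d", floor(x_km / cell_km), floor(y_km / cell_km))
}

#' Prepare the standardized predictor matrix for mixed-model inference
#'
#' Joins site-level habitat covers with site metadata, log10-transforms human
#' gravity and distance from shore, standardizes every continuous predictor
#' to mean 0 / SD 1 (ordinal physical scores are treated as numeric graded
#' intensities), encodes protection as a factor with `fished` as reference,
#' and runs a Pearson correlation screen: any predictor pair with |r| >= 0.5
#' is reported with a warning (flagged, not dropped).
#'
#' @param sites Site table (coordinates, depth, scores, gravity, distance,
#'   protection, grid_cell_id).
#' @param habitat_by_site Site/date mean broad covers from
#'   [site_date_habitat()].
#' @return Tibble with standardized predictors, `protection`,
#'   `grid_cell_id`, coordinates and keys. The correlation matrix is
#'   attached as attribute `correlation_screen` and flagged pairs as
#'   attribute `flagged_pairs`.
#' @export
prepare_predictors <- function(sites, habitat_by_site) {
  data <- habitat_by_site |>
    dplyr::inner_join(
      sites[, c("site_id", "latitude", "longitude", "depth_m",
                "wave_exposure", "slope", "relief", "currents",
                "human_gravity", "distance_shore_m", "protection",
                "grid_cell_id")],
      by = "site_id"
    ) |>
    dplyr::mutate(
      depth = .data$depth_m,
      human_gravity = log10(.data$human_gravity),
      distance_shore = log10(.data$distance_shore_m)
    )
  continuous <- c(broad_habitat_categories(), "depth", "wave_exposure",
                  "slope", "relief", "currents", "human_gravity",
                  "distance_shore")
  for (v in continuous) {
    s <- sd(data[[v]])
    if (!is.finite(s) || s == 0) {
      stop("predictor column is constant: ", v, call. = FALSE)
    }
    data[[v]] <- (data[[v]] - mean(data[[v]])) / s
  }
  data$protection <- factor(as.character(data$protection),
                            levels = c("fished", "partially_protected",
                                       "fully_protected"))

  cors <- cor(as.matrix(data[, continuous]))
  flags <- which(abs(cors) >= 0.5 & upper.tri(cors), arr.ind = TRUE)
  flagged <- tibble::tibble(
    var1 = rownames(cors)[flags[, 1]],
    var2 = colnames(cors)[flags[, 2]],
    r = cors[flags]
  )
  if (nrow(flagged) > 0) {
    warning("correlated predictor pair(s) with |r| >= 0.5: ",
            paste(sprintf("%s~%s (r=%.2f)", flagged$var1, flagged$var2,
                          flagged$r), collapse = "; "),
            call. = FALSE)
  }
  out <- data[, c("site_id", "survey_date", continuous, "protection",
                  "grid_cell_id", "latitude", "longitude")]
  attr(out, "correlation_screen") <- cors
  attr(out, "flagged_pairs") <- flagged
  out
}

#' Fit one linear mixed model with a spatial grid random intercept
#'
#' Fits `response ~ terms + (1 | grid_cell_id)` by maximum likelihood
#' (REML optional for final refits). The parameter count `k` includes all
#' fixed-effect coefficients (factor levels expand to their contrasts) plus
#' the random-intercept and residual variances. Singular fits are flagged
#' but retained.
#'
#' @param data Prepared predictor tibble containing the response.
#' @param terms Character vector of fixed-effect terms (possibly empty for
#'   the intercept-only model); interactions written `"a:b"`.
#' @param response Response column name (default `"lnrr"`).
#' @param group Grouping column for the random intercept.
#' @param reml Use REML instead of ML (default FALSE; AICc comparisons
#'   require ML).
#' @return List: `fit` (merMod), `terms`, `formula`, `loglik`, `k`, `n`,
#'   `singular`.
#' @export
fit_lmm <- function(data, terms = character(), response = "lnrr",
                    group = "grid_cell_id", reml = FALSE) {
  if (length(unique(data[[group]])) < 2) {
    stop("need at least 2 grid cells for the random intercept", call. = FALSE)
  }
  rhs <- if (length(terms) == 0) "1" else paste(terms, collapse = " + ")
  fml <- as.formula(sprintf("%s ~ %s + (1 | %s)", response, rhs, group))
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(fml, data = data, REML = reml,
               control = lme4::lmerControl(check.conv.singular = "ignore",
                                           calc.derivs = FALSE))
  ))
  k <- length(lme4::fixef(fit)) + 2L
  if (nrow(data) <= k + 2) stop("too few observations for the model size",
                                call. = FALSE)
  list(fit = fit, terms = terms, formula = deparse(fml),
       loglik = as.numeric(logLik(fit)), k = k, n = nrow(data),
       singular = lme4::isSingular(fit))
}

#' Fit every model of a suite and rank by AICc
#'
#' Enumerates all additive combinations of `mains` (plus hierarchical
#' interaction terms), fits each by ML with the grid random intercept, and
#' returns the ranked model records with AICc, delta-AICc and Akaike
#' weights normalized within the suite.
#'
#' @param data Prepared predictor tibble with the response column.
#' @param mains,interactions Term sets passed to [enumerate_models()].
#' @param response,group See [fit_lmm()].
#' @return Tibble of ModelRecords: `terms` (list-column), `formula`, `k`,
#'   `loglik`, `aicc`, `delta_aicc`, `weight`, `singular`, sorted by AICc.
#' @export
fit_model_suite <- function(data, mains, interactions = character(),
                            response = "lnrr", group = "grid_cell_id") {
  term_sets <- enumerate_models(mains, interactions)
  fits <- purrr::map(term_sets, function(ts) {
    f <- fit_lmm(data, ts, response, group, reml = FALSE)
    tibble::tibble(terms = list(f$terms), formula = f$formula, k = f$k,
                   loglik = f$loglik, singular = f$singular)
  })
  records <- dplyr::bind_rows(fits)
  records$aicc <- aicc(records$loglik, records$k, nrow(data))
  records$delta_aicc <- records$aicc - min(records$aicc)
  records$weight <- akaike_weights(records$aicc)
  if (any(records$singular)) {
    message(sprintf("fit_model_suite: %d of %d fits singular (retained)",
                    sum(records$singular), nrow(records)))
  }
  dplyr::arrange(records, .data$aicc)
}

#' Marginal and conditional R-squared for a mixed model
#'
#' Variance-partition goodness of fit: marginal R2 is the variance explained
#' by fixed effects alone, conditional R2 by fixed plus random effects,
#' relative to the total of fixed-effect, random-intercept and residual
#' variances.
#'
#' @param fit A merMod object (or a list with `$fit` as returned by
#'   [fit_lmm()]).
#' @return Named numeric vector `c(marginal = , conditional = )`.
#' @seealso [nakagawa_components()] for the bare-variance form.
#' @export
nakagawa_r2 <- function(fit) {
  if (is.list(fit) && !inherits(fit, "merMod") && !is.null(fit$fit)) {
    fit <- fit$fit
  }
  stopifnot(inherits(fit, "merMod"))
  fixed_pred <- predict(fit, re.form = NA)
  var_fixed <- var(fixed_pred)
  vc <- lme4::VarCorr(fit)
  var_random <- sum(vapply(vc, function(m) sum(diag(m)), numeric(1)))
  var_resid <- attr(vc, "sc")^2
  nakagawa_components(var_fixed, var_random, var_resid)
}

#' Mixed-model R-squared from variance components
#'
#' @param var_fixed Variance of the fixed-effect predictions.
#' @param var_random Summed random-effect variance.
#' @param var_resid Residual variance.
#' @return Named numeric vector `c(marginal = , conditional = )`.
#' @examples
#' nakagawa_components(1, 1, 2)  # marginal 0.25, conditional 0.50
#' @export
nakagawa_components <- function(var_fixed, var_random, var_resid) {
  total <- var_fixed + var_random + var_resid
  c(marginal = var_fixed / total,
    conditional = (var_fixed + var_random) / total)
}

#' Moran's I spatial autocorrelation with a permutation test
#'
#' Computes Moran's I for site-level values under inverse great-circle
#' distance weights (or k-nearest-neighbour binary weights) and a seeded
#' permutation test. The null expectation is -1/(n-1).
#'
#' @param values Numeric vector (e.g. model residuals), length >= 10.
#' @param lat,lon Site coordinates (degrees).
#' @param scheme `"inverse_distance"` (default) or `"knn"`.
#' @param k Number of neighbours for the knn scheme.
#' @param row_standardize Normalize each row of the weight matrix to sum to 1
#'   (W-style weights) before computing the statistic; default `FALSE`
#'   (B-style raw weights).
#' @param n_perm Number of permutations (default 999).
#' @param seed RNG seed for the permutations.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return List: `observed`, `expected`, `p_value`, `n`, `n_perm`, `scheme`.
#' @export
morans_i <- function(values, lat, lon,
                     scheme = c("inverse_distance", "knn"), k = 8,
                     row_standardize = FALSE,
                     n_perm = 999, seed = 1L,
                     alternative = c("two.sided", "greater", "less")) {
  scheme <- match.arg(scheme)
  alternative <- match.arg(alternative)
  n <- length(values)
  if (n < 10) stop("need at least 10 sites for Moran's I", call. = FALSE)
  stopifnot(length(lat) == n, length(lon) == n)

  d <- geosphere::distm(cbind(lon, lat), fun = geosphere::distHaversine)
  if (scheme == "inverse_distance") {
    pos_min <- min(d[d > 0])
    d[d == 0] <- pos_min / 2  # coincident sites: strongest finite weight
    w <- 1 / d
    diag(w) <- 0
  } else {
    w <- matrix(0, n, n)
    for (i in seq_len(n)) {
      nb <- order(d[i, ])[2:(k + 1)]
      w[i, nb] <- 1
    }
  }
  if (row_standardize) {
    rs <- rowSums(w)
    rs[rs == 0] <- 1
    w <- w / rs
  }
  s0 <- sum(w)
  moran_stat <- function(z) {
    zc <- z - mean(z)
    (n / s0) * as.numeric(zc %*% w %*% zc) / sum(zc^2)
  }
  observed <- moran_stat(values)
  expected <- -1 / (n - 1)

  perms <- with_local_seed(seed, {
    vapply(seq_len(n_perm), function(i) moran_stat(sample(values)), numeric(1))
  })
  p_hi <- (1 + sum(perms >= observed)) / (n_perm + 1)
  p_lo <- (1 + sum(perms <= observed)) / (n_perm + 1)
  p <- switch(alternative,
              two.sided = min(1, 2 * min(p_hi, p_lo)),
              greater = p_hi,
              less = p_lo)
  list(observed = observed, expected = expected, p_value = p, n = n,
       n_perm = n_perm, scheme = scheme)
}

#' Standardized partial effects of the top model
#'
#' Refits the chosen term set by REML and reports each fixed-effect
#' coefficient with its standard error, Wald 95% CI and a significance flag
#' (CI excluding zero). Protection contrasts are reported against the
#' `fished` reference level. Rows are ordered by decreasing |estimate| for
#' coefficient plots.
#'
#' @param data Prepared predictor tibble with the response.
#' @param terms Term set of the selected model.
#' @param response,group See [fit_lmm()].
#' @return Tibble: `term`, `estimate`, `se`, `ci_low`, `ci_high`,
#'   `significant`; the REML fit is attached as attribute `fit`.
#' @export
partial_effects <- function(data, terms, response = "lnrr",
                            group = "grid_cell_id") {
  refit <- fit_lmm(data, terms, response, group, reml = TRUE)
  est <- lme4::fixef(refit$fit)
  se <- sqrt(diag(as.matrix(vcov(refit$fit))))
  out <- tibble::tibble(
    term = names(est),
    estimate = as.numeric(est),
    se = as.numeric(se),
    ci_low = .data$estimate - 1.96 * .data$se,
    ci_high = .data$estimate + 1.96 * .data$se
  ) |>
    dplyr::filter(.data$term != "(Intercept)") |>
    dplyr::mutate(significant = .data$ci_low > 0 | .data$ci_high < 0) |>
    dplyr::arrange(dplyr::desc(abs(.data$estimate)))
  attr(out, "fit") <- refit$fit
  out
}

#' Coefficient plot of standardized partial effects
#'
#' @param effects Output of [partial_effects()].
#' @return A ggplot object (dot and 95% CI per term, reference at zero).
#' @export
plot_partial_effects <- function(effects) {
  df <- effects
  df$term <- factor(df$term, levels = rev(df$term))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_low,
                                          xmax = .data$ci_high)) +
    ggplot2::labs(x = "standardized estimate", y = NULL) +
    ggplot2::theme_minimal()
}

#' Default model suites for the two-stage inference
#'
#' Protection is available as a main effect in every suite (its interactions
#' require it), with interactions between each local covariate and
#' protection.
#' @return Named list of suites, each with `mains` and `interactions`.
#' @export
default_suites <- function() {
  biogenic_covs <- broad_habitat_categories()
  physical_covs <- c("depth", "wave_exposure", "slope", "relief", "currents")
  anthro_covs <- c("human_gravity", "distance_shore")
  list(
    biogenic = list(
      mains = c(biogenic_covs, "protection"),
      interactions = paste0(biogenic_covs, ":protection")
    ),
    physical = list(
      mains = c(physical_covs, "protection"),
      interactions = paste0(physical_covs, ":protection")
    ),
    anthropogenic = list(
      mains = c("protection", anthro_covs),
      interactions = paste0(anthro_covs, ":protection")
    )
  )
}

#' Two-stage multi-model inference on response ratios
#'
#' Stage one fits three model suites (biogenic habitat, physical
#' environment, anthropogenic) of all additive term combinations, computes
#' per-term variable importance as summed Akaike weights, and retains terms
#' with importance >= `threshold`. Stage two fits all additive combinations
#' of the reduced predictor set, selects the most parsimonious model within
#' `delta_max` AICc of the best, refits it by REML, and reports partial
#' effects, marginal/conditional R2 and Moran's I on its residuals.
#'
#' @param ratios ResponseRatio tibble (`site_id`, `lnrr`).
#' @param sites Site table.
#' @param habitat_by_site Site/date broad covers.
#' @param suites Model suites, default [default_suites()].
#' @param threshold Importance cutoff for the reduction (default 0.9).
#' @param delta_max Top-model-set width on the AICc scale (default 4).
#' @param n_perm Permutations for Moran's I (default 999).
#' @param seed Seed for the permutation test.
#' @return List: `data`, `suite_records`, `importance` (per suite),
#'   `reduced_terms`, `global_records`, `top_model` (record row),
#'   `partial_effects`, `r2` (marginal/conditional), `morans`
#'   (residual autocorrelation test).
#' @export
run_inference <- function(ratios, sites, habitat_by_site,
                          suites = default_suites(), threshold = 0.9,
                          delta_max = 4, n_perm = 999, seed = 1L) {
  predictors <- prepare_predictors(sites, habitat_by_site)
  data <- predictors |>
    dplyr::inner_join(ratios[, c("site_id", "lnrr")], by = "site_id")

  suite_records <- purrr::map(
    suites,
    function(s) fit_model_suite(data, s$mains, s$interactions)
  )
  importance <- purrr::map(suite_records, variable_importance)
  reduced <- reduce_predictor_set(importance, threshold)

  red_ints <- reduced[grepl(":", reduced, fixed = TRUE)]
  red_mains <- setdiff(reduced, red_ints)
  global_records <- fit_model_suite(data, red_mains, red_ints)
  top <- select_top_model(global_records, delta_max)
  top_terms <- top$terms[[1]]

  effects <- partial_effects(data, top_terms)
  reml_fit <- attr(effects, "fit")
  r2 <- nakagawa_r2(reml_fit)
  resid_vals <- stats::residuals(reml_fit)
  morans <- morans_i(as.numeric(resid_vals), data$latitude, data$longitude,
                     n_perm = n_perm, seed = seed)

  list(data = data, suite_records = suite_records, importance = importance,
       reduced_terms = reduced, global_records = global_records,
       top_model = top, partial_effects = effects, r2 = r2, morans = morans)
}
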