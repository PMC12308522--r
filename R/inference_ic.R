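#' Small-sample corrected Akaike information criterion
#'
#' AICc = -2 logLik + 2k + 2k(k+1)/(n-k-1). `k` counts every estimated
#' parameter: fixed effects including the intercept plus both variance
#' components of the mixed model (random-intercept and residual variance).
#'
#' @param loglik Maximized log-likelihood.
#' @param k Number of estimated parameters.
#' @param n Number of observations (must exceed k + 1).
#' @return AICc value (vectorized over its arguments).
#' @examples
#' aicc(-100, 3, 50)  # 206 + 24/46
#' @export
aicc <- function(loglik, k, n) {
  if (any(n <= k + 1)) {
    stop("AICc undefined: need n > k + 1", call. = FALSE)
  }
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Akaike weights from a set of AICc scores
#'
#' w_i = exp(-Delta_i / 2) / sum_j exp(-Delta_j / 2), with Delta relative to
#' the minimum AICc in the set; weights sum to 1.
#'
#' @param aicc_values Numeric vector of AICc scores (length >= 1).
#' @return Numeric vector of weights.
#' @examples
#' akaike_weights(c(100, 102))  # 0.731, 0.269
#' @export
akaike_weights <- function(aicc_values) {
  if (length(aicc_values) < 1) stop("need at least one model", call. = FALSE)
  delta <- aicc_values - min(aicc_values)
  w <- exp(-delta / 2)
  w / sum(w)
}

#' Enumerate candidate model term sets
#'
#' All additive combinations of the main effects, optionally crossed with
#' interaction terms (written `"a:b"`), obeying marginality: an interaction
#' may only appear in a model that contains both of its main effects. The
#' intercept-only model (empty term set) is always included.
#'
#' @param mains Character vector of main-effect names.
#' @param interactions Character vector of `"a:b"` interaction names whose
#'   parents appear in `mains`.
#' @return List of character vectors (term sets).
#' @examples
#' length(enumerate_models(c("a", "b", "c")))  # 8
#' @export
enumerate_models <- function(mains, interactions = character()) {
  parents <- lapply(strsplit(interactions, ":", fixed = TRUE), identity)
  bad <- vapply(parents, function(p) !all(p %in% mains) || length(p) != 2,
                logical(1))
  if (any(bad)) {
    stop("interaction parents must be listed in `mains`: ",
         paste(interactions[bad], collapse = ", "), call. = FALSE)
  }
  models <- list()
  n_m <- length(mains)
  for (mask in 0:(2^n_m - 1)) {
    subset <- mains[bitwAnd(mask, 2^(seq_len(n_m) - 1)) > 0]
    ok_int <- interactions[vapply(parents, function(p) all(p %in% subset),
                                  logical(1))]
    n_i <- length(ok_int)
    for (imask in 0:(2^n_i - 1)) {
      ints <- if (n_i > 0) ok_int[bitwAnd(imask, 2^(seq_len(n_i) - 1)) > 0]
              else character()
      models[[length(models) + 1L]] <- c(subset, ints)
    }
  }
  models
}

#' Per-term variable importance as the sum of Akaike weights
#'
#' Each term's importance is the sum of the Akaike weights of all models in
#' which it appears; with normalized weights it lies between 0 and 1.
#'
#' @param records Model-record tibble with a list-column `terms` and a
#'   numeric `weight` column (see [fit_model_suite()]).
#' @return Tibble `term`, `importance`, sorted decreasing.
#' @export
variable_importance <- function(records) {
  all_terms <- unique(unlist(records$terms))
  imp <- vapply(all_terms, function(tm) {
    sum(records$weight[vapply(records$terms, function(ts) tm %in% ts,
                              logical(1))])
  }, numeric(1))
  tibble::tibble(term = all_terms, importance = as.numeric(imp)) |>
    dplyr::arrange(dplyr::desc(.data$importance))
}

#' Reduce the predictor set by an importance threshold
#'
#' Keeps every term whose variable importance is greater than or equal to
#' `threshold` in any of the supplied importance tables (strict `>=`, so an
#' importance of exactly 0.9 is retained and 0.89 is not), then enforces
#' marginality: a retained interaction pulls in both of its main effects.
#'
#' @param importance_tables A single importance tibble or a list of them
#'   (one per model suite).
#' @param threshold Importance cutoff (default 0.9).
#' @return Character vector of retained terms (mains first, then
#'   interactions).
#' @export
reduce_predictor_set <- function(importance_tables, threshold = 0.9) {
  if (is.data.frame(importance_tables)) {
    importance_tables <- list(importance_tables)
  }
  combined <- dplyr::bind_rows(importance_tables)
  kept <- unique(combined$term[combined$importance >= threshold])
  ints <- kept[grepl(":", kept, fixed = TRUE)]
  mains <- setdiff(kept, ints)
  pulled <- unique(unlist(strsplit(ints, ":", fixed = TRUE)))
  mains <- union(mains, pulled)
  c(mains, ints)
}

#' Select the top model from a candidate set
#'
#' Among all models within `delta_max` AICc of the best, the most
#' parsimonious model (fewest parameters `k`) is chosen; ties on `k` are
#' broken by the lowest AICc. The choice is invariant to the input order.
#'
#' @param records Model-record tibble with `k` and `aicc` columns.
#' @param delta_max Width of the top model set on the AICc scale (default 4).
#' @return The selected row of `records` (one-row tibble).
#' @export
select_top_model <- function(records, delta_max = 4) {
  if (nrow(records) < 1) stop("need at least one model", call. = FALSE)
  delta <- records$aicc - min(records$aicc)
  cand <- records[delta <= delta_max, , drop = FALSE]
  cand <- cand[order(cand$k, cand$aicc,
                     vapply(cand$terms, function(ts) paste(sort(ts), collapse = "+"),
                            character(1))), , drop = FALSE]
  cand[1, , drop = FALSE]
}

#' Published variable-importance values for the reduction-rule example
#'
#' Variable-importance tables (sum of Akaike weights) from a published
#' temperate-Australia analysis of reef-fish biomass response ratios, in the
#' three-suite layout produced by this package (biogenic habitat, physical
#' environment, anthropogenic). Useful for demonstrating and testing the
#' importance-threshold reduction rule on fixed, well-known inputs.
#'
#' @return Named list of three importance tibbles.
#' @export
reference_importance_tables <- function() {
  list(
    biogenic = tibble::tribble(
      ~term, ~importance,
      "turfing_algae", 1.00,
      "sand", 0.99,
      "sessile_invertebrates", 0.96,
      "sessile_invertebrates:protection", 0.69,
      "understorey_algae", 0.36,
      "sand:protection", 0.35,
      "canopy_algae", 0.31,
      "turfing_algae:protection", 0.16,
      "understorey_algae:protection", 0.13,
      "canopy_algae:protection", 0.04
    ),
    physical = tibble::tribble(
      ~term, ~importance,
      "depth", 1.00,
      "currents", 0.89,
      "relief", 0.78,
      "currents:protection", 0.47,
      "wave_exposure", 0.44,
      "slope", 0.38,
      "relief:protection", 0.28,
      "wave_exposure:protection", 0.23,
      "depth:protection", 0.20,
      "slope:protection", 0.14
    ),
    anthropogenic = tibble::tribble(
      ~term, ~importance,
      "protection", 1.00,
      "human_gravity", 0.93,
      "human_gravity:protection", 0.90,
      "distance_shore", 0.59,
      "distance_shore:protection", 0.34
    )
  )
}
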