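# small spatially grouped dataset with a known generative structure
lmm_data <- function(n = 120, beta_x = 0.3, grid_sd = 0.2, resid_sd = 0.1,
                     seed = 1) {
  withr::with_seed(seed, {
    cell <- sample(sprintf("c%d", 1:6), n, replace = TRUE)
    cell_eff <- setNames(rnorm(6, 0, grid_sd), sprintf("c%d", 1:6))
    x <- rnorm(n); z <- rnorm(n); w <- rnorm(n)
    tibble::tibble(
      x = x, z = z, w = w,
      grid_cell_id = cell,
      lnrr = beta_x * x + cell_eff[cell] + rnorm(n, 0, resid_sd)
    )
  })
}

test_that("AICc matches the closed form and its limits", {
  expect_equal(aicc(-100, 3, 50), 206 + 24 / 46, tolerance = 1e-12)
  # large-n limit is plain AIC
  expect_equal(aicc(-100, 3, 1e9), 206, tolerance = 1e-6)
  # heavier parameterization at equal fit is penalized
  expect_gt(aicc(-100, 5, 50), aicc(-100, 3, 50))
  expect_error(aicc(-100, 10, 11), "n > k")
})

test_that("Akaike weights normalize exp(-delta/2)", {
  w <- akaike_weights(c(100, 102))
  expect_equal(w, c(1, exp(-1)) / (1 + exp(-1)), tolerance = 1e-12)
  expect_equal(sum(akaike_weights(c(3, 9, 4, 7))), 1)
  expect_equal(akaike_weights(rep(5, 4)), rep(0.25, 4))
})

test_that("model enumeration obeys the marginality hierarchy", {
  expect_length(enumerate_models(c("a", "b", "c")), 8)
  ms <- enumerate_models(c("a", "protection"), "a:protection")
  with_int <- Filter(function(ts) "a:protection" %in% ts, ms)
  expect_true(all(vapply(with_int,
                         function(ts) all(c("a", "protection") %in% ts),
                         logical(1))))
  expect_length(ms, 5)  # {}, a, p, a+p, a+p+a:p
  expect_true(any(vapply(ms, length, integer(1)) == 0))
  expect_error(enumerate_models("a", "a:b"), "parents")
  # every biogenic-suite term shows up in at least one candidate model
  s <- default_suites()$biogenic
  all_terms <- unique(unlist(enumerate_models(s$mains, s$interactions)))
  expect_setequal(all_terms, c(s$mains, s$interactions))
})

test_that("suite fitting agrees exactly with brute-force recomputation", {
  d <- lmm_data(n = 90, seed = 4)
  mains <- c("x", "z", "w")
  records <- fit_model_suite(d, mains, response = "lnrr")
  expect_equal(nrow(records), 8)

  # independent route: explicit formulas, direct lme4 fits, hand AICc
  brute <- list()
  idx <- 1
  for (i in 0:1) for (j in 0:1) for (k in 0:1) {
    ts <- c("x", "z", "w")[c(i, j, k) == 1]
    rhs <- if (length(ts) == 0) "1" else paste(ts, collapse = " + ")
    fit <- lme4::lmer(as.formula(paste("lnrr ~", rhs, "+ (1 | grid_cell_id)")),
                      data = d, REML = FALSE)
    ll <- as.numeric(logLik(fit))
    kk <- length(lme4::fixef(fit)) + 2
    brute[[idx]] <- data.frame(
      key = paste(sort(ts), collapse = "+"), loglik = ll, k = kk,
      aicc = -2 * ll + 2 * kk + 2 * kk * (kk + 1) / (nrow(d) - kk - 1)
    )
    idx <- idx + 1
  }
  brute <- do.call(rbind, brute)
  brute$weight <- {
    delta <- brute$aicc - min(brute$aicc)
    exp(-delta / 2) / sum(exp(-delta / 2))
  }

  key <- vapply(records$terms, function(ts) paste(sort(ts), collapse = "+"),
                character(1))
  m <- match(key, brute$key)
  expect_equal(records$loglik, brute$loglik[m], tolerance = 1e-8)
  expect_equal(records$aicc, brute$aicc[m], tolerance = 1e-8)
  expect_equal(records$weight, brute$weight[m], tolerance = 1e-8)

  # importance: independent recomputation by summing weights per term
  imp <- variable_importance(records)
  for (tm in c("x", "z", "w")) {
    ref <- sum(brute$weight[grepl(tm, brute$key)])
    expect_equal(imp$importance[imp$term == tm], ref, tolerance = 1e-8)
  }
  expect_equal(sum(records$weight), 1, tolerance = 1e-12)
  expect_true(all(imp$importance >= 0 & imp$importance <= 1))

  # top-model rule agrees with a hand application on the same records
  top <- select_top_model(records)
  cand <- records[records$aicc - min(records$aicc) <= 4, ]
  cand <- cand[order(cand$k, cand$aicc), ]
  expect_equal(top$aicc, cand$aicc[1])
  expect_equal(top$k, cand$k[1])
})

test_that("variable importance sums weights of containing models", {
  records <- tibble::tibble(
    terms = list("a", c("a", "b"), "b", character()),
    weight = c(0.4, 0.3, 0.2, 0.1)
  )
  imp <- variable_importance(records)
  expect_equal(imp$importance[imp$term == "a"], 0.7)
  expect_equal(imp$importance[imp$term == "b"], 0.5)
  # a term in every model scores 1
  all_in <- tibble::tibble(terms = list("a", c("a", "b")), weight = c(0.5, 0.5))
  expect_equal(variable_importance(all_in)$importance[1], 1)
})

test_that("importance-threshold reduction keeps >= 0.9 terms with hierarchy", {
  tabs <- reference_importance_tables()
  reduced <- reduce_predictor_set(tabs, threshold = 0.9)
  expect_setequal(reduced, c("turfing_algae", "sand", "sessile_invertebrates",
                             "depth", "protection", "human_gravity",
                             "human_gravity:protection"))
  # currents at 0.89 misses the strict >= 0.9 boundary
  expect_false("currents" %in% reduced)
  # threshold 0 keeps everything
  all_terms <- unique(unlist(lapply(tabs, function(t) t$term)))
  expect_setequal(reduce_predictor_set(tabs, 0), all_terms)
  # monotone in the threshold
  r_low <- reduce_predictor_set(tabs, 0.3)
  expect_true(all(reduced %in% r_low))
  # a retained interaction pulls in absent mains
  solo <- tibble::tibble(term = c("a:b"), importance = 0.95)
  expect_setequal(reduce_predictor_set(solo), c("a", "b", "a:b"))
})

test_that("top-model selection is parsimony-first within the AICc window", {
  recs <- tibble::tibble(
    terms = list(c("a", "b", "c"), c("a", "b"), "a", character()),
    k = c(5, 3, 2, 1),
    aicc = c(100.0, 100.5, 103.9, 104.5)
  )
  top <- select_top_model(recs)
  expect_equal(top$k, 2)
  expect_equal(top$aicc, 103.9)
  # invariant to input order
  top2 <- select_top_model(recs[c(3, 1, 4, 2), ])
  expect_equal(top2$aicc, top$aicc)
  # k-ties broken by the lower AICc
  ties <- tibble::tibble(terms = list("a", "b"), k = c(2, 2),
                         aicc = c(102, 101))
  expect_equal(select_top_model(ties)$aicc, 101)
  expect_equal(select_top_model(recs[1, ])$k, 5)
})

test_that("grid-cell assignment is deterministic and distance-faithful", {
  lat <- c(-35, -35.005)
  lon <- c(140, 140.005)
  cells <- assign_grid_cell(lat, lon)
  # ~1 km apart: same or edge-adjacent cells
  parts <- do.call(rbind, strsplit(cells, "_"))
  expect_true(all(abs(as.numeric(parts[1, ]) - as.numeric(parts[2, ])) <= 1))
  # 200 km east is a different cell
  far <- assign_grid_cell(-35, 140 + 200 / (111.32 * cos(-36.5 * pi / 180)))
  expect_false(far == cells[1])
  # idempotent and order-independent
  expect_equal(assign_grid_cell(rev(lat), rev(lon)), rev(cells))
})

test_that("mixed-model fits recover variance structure", {
  # response driven by grid shifts: random-intercept variance dominates
  d <- lmm_data(n = 150, beta_x = 0, grid_sd = 0.5, resid_sd = 0.05, seed = 6)
  f <- fit_lmm(d, character())
  vc <- lme4::VarCorr(f$fit)
  expect_gt(vc$grid_cell_id[1, 1], 10 * attr(vc, "sc")^2)
  expect_equal(f$k, 3)

  # adding a decoy never lowers the maximized log-likelihood
  f0 <- fit_lmm(d, "x")
  f1 <- fit_lmm(d, c("x", "z"))
  expect_gte(f1$loglik, f0$loglik - 1e-6)

  # no true grid effect: variance component collapses towards zero
  d0 <- lmm_data(n = 150, beta_x = 0.3, grid_sd = 0, resid_sd = 0.1, seed = 7)
  fit0 <- fit_lmm(d0, "x")
  vc0 <- lme4::VarCorr(fit0$fit)
  expect_lt(vc0$grid_cell_id[1, 1], 0.002)

  expect_error(fit_lmm(dplyr::mutate(d, grid_cell_id = "one"), "x"),
               "grid cells")
})

test_that("Nakagawa R2 matches hand-computed components and limits", {
  expect_equal(nakagawa_components(1, 1, 2),
               c(marginal = 0.25, conditional = 0.50), tolerance = 1e-9)
  expect_equal(nakagawa_components(0, 1, 3)[["marginal"]], 0)
  nr <- nakagawa_components(2, 0, 1)
  expect_equal(nr[["marginal"]], nr[["conditional"]], tolerance = 1e-9)

  # merMod route: strong fixed effect, sane ordering
  d <- lmm_data(n = 200, beta_x = 0.5, grid_sd = 0.2, resid_sd = 0.1, seed = 8)
  f <- fit_lmm(d, "x")
  r2 <- nakagawa_r2(f)
  expect_gt(r2[["marginal"]], 0.4)
  expect_gte(r2[["conditional"]], r2[["marginal"]])
  expect_lte(r2[["conditional"]], 1)
})

test_that("Moran's I flags planted gradients but not white noise", {
  withr::with_seed(31, {
    n <- 60
    lat <- runif(n, -40, -30)
    lon <- runif(n, 115, 150)
    noise <- rnorm(n)
  })
  m_noise <- morans_i(noise, lat, lon, n_perm = 199, seed = 5)
  expect_equal(m_noise$expected, -1 / (n - 1))
  expect_gt(m_noise$p_value, 0.05)

  gradient <- scale(lon + lat)[, 1]
  m_grad <- morans_i(gradient, lat, lon, n_perm = 199, seed = 5)
  expect_gt(m_grad$observed, 0)
  expect_lt(m_grad$p_value, 0.05)

  # permutation p reproducible under a fixed seed; knn scheme also works
  m2 <- morans_i(noise, lat, lon, n_perm = 199, seed = 5)
  expect_identical(m_noise$p_value, m2$p_value)
  m_knn <- morans_i(gradient, lat, lon, scheme = "knn", n_perm = 99, seed = 5)
  expect_lt(m_knn$p_value, 0.05)

  # observed statistic agrees with an independent implementation
  # (ape row-standardizes its weights internally)
  skip_if_not_installed("ape")
  d <- geosphere::distm(cbind(lon, lat), fun = geosphere::distHaversine)
  w <- 1 / d; diag(w) <- 0
  ref <- ape::Moran.I(as.numeric(gradient), w)
  m_std <- morans_i(gradient, lat, lon, row_standardize = TRUE,
                    n_perm = 99, seed = 5)
  expect_equal(m_std$observed, ref$observed, tolerance = 1e-8)
  expect_equal(m_std$expected, ref$expected, tolerance = 1e-12)
})

test_that("predictor preparation standardizes, screens and transforms", {
  sim <- small_sim()
  hb <- small_processed()$habitat_by_site
  pred <- suppressWarnings(prepare_predictors(sim$sites, hb))
  for (v in c("turfing_algae", "depth", "human_gravity")) {
    expect_equal(mean(pred[[v]]), 0, tolerance = 1e-9)
    expect_equal(sd(pred[[v]]), 1, tolerance = 1e-9)
  }
  expect_s3_class(pred$protection, "factor")
  expect_equal(levels(pred$protection)[1], "fished")
  expect_true(all(c("grid_cell_id", "latitude") %in% names(pred)))

  # a duplicated predictor is flagged r = 1 by the correlation screen
  sim2 <- sim$sites
  sim2$human_gravity <- sim2$distance_shore_m  # same column twice
  expect_warning(prepare_predictors(sim2, hb), "r=1.00")

  sim3 <- sim$sites
  sim3$depth_m <- 5
  expect_error(prepare_predictors(sim3, hb), "depth")
})

test_that("planted effects surface in the global model on synthetic data", {
  sim <- small_sim()
  proc <- small_processed()
  run <- counterfactual_stage(
    proc$biomass_by_site, sim$sites,
    grid = expand.grid(ntrees = 300, mtry = 4, min_node_size = 10),
    settings = rf_settings(seed = 1)
  )
  pred <- suppressWarnings(prepare_predictors(sim$sites, proc$habitat_by_site))
  data <- dplyr::inner_join(pred, run$ratios[, c("site_id", "lnrr")],
                            by = "site_id")
  # fit the reduced global suite directly (protection + planted covariates)
  records <- fit_model_suite(data, c("protection", "turfing_algae", "sand",
                                     "depth"))
  imp <- variable_importance(records)
  expect_gt(imp$importance[imp$term == "protection"], 0.9)
  top <- select_top_model(records)
  expect_true("protection" %in% top$terms[[1]])
  eff <- partial_effects(data, top$terms[[1]])
  full_row <- eff[eff$term == "protectionfully_protected", ]
  expect_gt(full_row$estimate, 0)
  expect_true(full_row$significant)
})
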