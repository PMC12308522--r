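test_that("generator config validates its invariants", {
  expect_error(generator_config(prop_fully_protected = 0.7,
                                prop_partially_protected = 0.4), "sum")
  expect_error(generator_config(protection_multiplier_full = 0), "> 0")
  expect_error(generator_config(resid_sd = -0.1), ">= 0")
  expect_error(generator_config(n_sites = 10), "n_sites")
  expect_s3_class(generator_config(), "reef_generator_config")
})

test_that("site generation honours ranges, fractions and spatial extent", {
  cfg <- generator_config(n_sites = 100, prop_fully_protected = 0.2,
                          prop_partially_protected = 0.2, seed = 1)
  sites <- generate_sites(cfg)
  expect_equal(nrow(sites), 100)
  expect_equal(sum(sites$protection == "fully_protected"), 20)
  expect_equal(sum(sites$protection == "partially_protected"), 20)
  expect_true(all(sites$depth_m >= 1 & sites$depth_m <= 25))
  expect_true(all(sites$human_gravity >= 0.57 & sites$human_gravity <= 34856))
  expect_true(all(sites$distance_shore_m >= 1 & sites$distance_shore_m <= 60447))
  expect_true(all(sites$wave_exposure %in% 1:4))

  # coordinate extent over 1000 km
  span_km <- geosphere::distHaversine(
    c(min(sites$longitude), sites$latitude[which.min(sites$longitude)]),
    c(max(sites$longitude), sites$latitude[which.max(sites$longitude)])
  ) / 1000
  expect_gt(span_km, 1000)

  # protected sites come in contiguous MPA blocks of more than one site
  blocks <- table(sites$mpa_id)
  expect_gt(mean(blocks), 1.5)
})

test_that("generation is deterministic under a fixed seed", {
  cfg <- generator_config(n_sites = 60, seed = 42)
  s1 <- simulate_reef_data(cfg)
  s2 <- simulate_reef_data(cfg)
  expect_identical(s1$sites, s2$sites)
  expect_identical(s1$surveys, s2$surveys)
  expect_identical(s1$habitat, s2$habitat)
  s3 <- simulate_reef_data(generator_config(n_sites = 60, seed = 43))
  expect_false(identical(s1$surveys, s3$surveys))
})

test_that("true response ratios carry the planted protection multipliers", {
  cfg <- generator_config(n_sites = 900, seed = 5)
  sites <- generate_sites(cfg)
  sv <- generate_surveys(sites, species_pool(cfg), cfg)
  tr <- sv$truth
  gap_full <- mean(tr$true_lnrr[tr$protection == "fully_protected"]) -
    mean(tr$true_lnrr[tr$protection == "fished"])
  expect_lt(abs(gap_full - log10(1.34)), 0.05)
  gap_part <- mean(tr$true_lnrr[tr$protection == "partially_protected"]) -
    mean(tr$true_lnrr[tr$protection == "fished"])
  expect_lt(abs(gap_part - log10(1.10)), 0.05)
})

test_that("a null configuration plants no protection or habitat effects", {
  cfg <- generator_config(n_sites = 400,
                          protection_multiplier_full = 1,
                          protection_multiplier_partial = 1,
                          beta_turf = 0, beta_sand = 0, beta_depth = 0,
                          seed = 9)
  sites <- generate_sites(cfg)
  sv <- generate_surveys(sites, species_pool(cfg), cfg)
  tr <- sv$truth
  expect_true(all(tr$protection_effect == 0))
  expect_true(all(tr$planted_local_effect == 0))
  gap <- mean(tr$true_lnrr[tr$protection == "fully_protected"]) -
    mean(tr$true_lnrr[tr$protection == "fished"])
  expect_lt(abs(gap), 0.05)
})

test_that("surveys have the configured transect structure and species pool", {
  sim <- small_sim()
  per_site <- sim$surveys |>
    dplyr::group_by(site_id, survey_date) |>
    dplyr::summarise(n_tr = dplyr::n_distinct(transect_id), .groups = "drop")
  expect_true(all(per_site$n_tr == sim$config$transects_per_site))
  expect_true(all(sim$surveys$species %in% sim$pool$species))
  expect_true(any(sim$surveys$family %in% excluded_families()))
  expect_true(all(sim$surveys$count >= 1))
  expect_error(generate_surveys(sim$sites, sim$pool[0, ], sim$config), "empty")
})

test_that("habitat output respects each dialect's constraints", {
  sim <- small_sim()
  hab <- sim$habitat
  expect_setequal(unique(hab$dialect), c("photo_quadrat", "in_situ"))
  # one dialect per site
  per_site <- hab |>
    dplyr::group_by(site_id) |>
    dplyr::summarise(n_dialects = dplyr::n_distinct(dialect))
  expect_true(all(per_site$n_dialects == 1))

  pq_tot <- hab |>
    dplyr::filter(dialect == "photo_quadrat") |>
    dplyr::group_by(site_id, transect_id) |>
    dplyr::summarise(total = sum(value), .groups = "drop")
  expect_true(all(pq_tot$total <= 100))

  layer_tot <- hab |>
    dplyr::filter(dialect == "in_situ") |>
    dplyr::group_by(site_id, transect_id, layer) |>
    dplyr::summarise(total = sum(value), .groups = "drop")
  expect_true(all(layer_tot$total <= 50))
  # layered scoring can exceed 100% equivalent cover on some transects
  quad_tot <- layer_tot |>
    dplyr::group_by(site_id, transect_id) |>
    dplyr::summarise(total = sum(total), .groups = "drop")
  expect_gt(max(quad_tot$total), 50)
  expect_true(all(hab$category %in% default_category_map()$fine))
})
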