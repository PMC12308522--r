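quadrat <- function(canopy = 0, subcanopy = 0, substrate = 0) {
  tibble::tibble(
    layer = c("canopy", "subcanopy", "substrate"),
    category = c("laminarian_kelp", "foliose_red", "sand"),
    value = c(canopy, subcanopy, substrate)
  )
}

pct <- function(out, cat) {
  v <- out$percent[out$category == cat]
  if (length(v) == 0) 0 else v
}

test_that("top-down scaling truncates lower layers at 100% cover", {
  out <- scale_insitu_quadrat(quadrat(30, 20, 40))
  expect_equal(pct(out, "laminarian_kelp"), 60)
  expect_equal(pct(out, "foliose_red"), 40)
  expect_equal(pct(out, "sand"), 0)
  expect_equal(sum(out$percent), 100)
})

test_that("quadrats within 50 points pass through doubled", {
  out <- scale_insitu_quadrat(quadrat(10, 10, 10))
  expect_equal(sort(out$percent), c(20, 20, 20))
  out2 <- scale_insitu_quadrat(quadrat(canopy = 50))
  expect_equal(pct(out2, "laminarian_kelp"), 100)
  expect_error(scale_insitu_quadrat(quadrat(51, 0, 0)), "50-point")
})

test_that("top-down scaling never inflates a layer and respects the bound", {
  # randomized property check, including multi-category layers
  withr::with_seed(7, {
    for (i in 1:50) {
      q <- tibble::tibble(
        layer = sample(c("canopy", "subcanopy", "substrate"), 6, replace = TRUE),
        category = sprintf("cat_%d", 1:6),
        value = sample(0:25, 6, replace = TRUE)
      )
      q <- q |>
        dplyr::group_by(layer) |>
        dplyr::mutate(value = value * min(1, 50 / max(sum(value), 1))) |>
        dplyr::ungroup()
      out <- scale_insitu_quadrat(q)
      expect_lte(sum(out$percent), 100 + 1e-9)
      inp <- q |>
        dplyr::group_by(category) |>
        dplyr::summarise(v = 2 * sum(value))
      m <- dplyr::inner_join(out, inp, by = "category")
      expect_true(all(m$percent <= m$v + 1e-9))
      if (sum(q$value) >= 50) expect_equal(sum(out$percent), 100)
      if (sum(q$value) <= 50) {
        expect_equal(sort(out$percent), sort(2 * q$value))
      }
    }
  })
})

test_that("harmonization leaves photo-quadrat rows untouched", {
  sim <- small_sim()
  pq <- sim$habitat[sim$habitat$dialect == "photo_quadrat", ]
  harm <- harmonize_habitat(pq)
  joined <- dplyr::inner_join(
    harm,
    dplyr::rename(pq, original = "value"),
    by = c("site_id", "survey_date", "transect_id", "category")
  )
  expect_equal(joined$percent, joined$original)
})

test_that("vectorized harmonization matches the single-quadrat rule", {
  sim <- small_sim()
  ins <- sim$habitat[sim$habitat$dialect == "in_situ", ]
  harm <- harmonize_habitat(ins)
  keys <- unique(ins[, c("site_id", "survey_date", "transect_id")])
  for (i in sample(nrow(keys), 5)) {
    k <- keys[i, ]
    q <- dplyr::semi_join(ins, k, by = names(k))
    ref <- scale_insitu_quadrat(q[, c("layer", "category", "value")])
    got <- dplyr::semi_join(harm, k, by = names(k))
    m <- dplyr::full_join(ref, got, by = "category",
                          suffix = c("_ref", "_vec"))
    expect_equal(m$percent_vec, m$percent_ref, tolerance = 1e-9)
  }
})

test_that("aggregation maps fine categories onto exactly the five groups", {
  covers <- tibble::tibble(
    site_id = "S1", survey_date = "2021-06-01", transect_id = "T1",
    category = c("laminarian_kelp", "foliose_red", "turf_mat", "sand"),
    percent = c(20, 10, 30, 40)
  )
  out <- suppressMessages(aggregate_habitat(covers))
  expect_equal(names(out)[-(1:3)], broad_habitat_categories())
  expect_equal(out$canopy_algae, 20)
  expect_equal(out$understorey_algae, 10)
  expect_equal(out$turfing_algae, 30)
  expect_equal(out$sand, 40)

  # abiotic cover is dropped with a logged total
  covers2 <- dplyr::add_row(covers, site_id = "S1",
                            survey_date = "2021-06-01", transect_id = "T1",
                            category = "bare_rock", percent = 5)
  expect_message(out2 <- aggregate_habitat(covers2), "abiotic")
  expect_equal(attr(out2, "dropped_percent_total"), 5)

  expect_error(
    suppressMessages(aggregate_habitat(
      dplyr::mutate(covers, category = dplyr::if_else(category == "sand",
                                                      "mystery_cat", category))
    )),
    "mystery_cat"
  )

  zero <- suppressMessages(aggregate_habitat(dplyr::mutate(covers, percent = 0)))
  expect_true(all(as.matrix(zero[, broad_habitat_categories()]) == 0))
})

test_that("site/date habitat means preserve the 100% bound", {
  sim <- small_sim()
  per_transect <- suppressMessages(
    aggregate_habitat(harmonize_habitat(sim$habitat))
  )
  by_site <- site_date_habitat(per_transect)
  totals <- rowSums(as.matrix(by_site[, broad_habitat_categories()]))
  expect_true(all(totals <= 100 + 1e-9))
  # two-transect hand case
  tc <- tibble::tibble(site_id = "S1", survey_date = "d",
                       transect_id = c("T1", "T2"),
                       turfing_algae = c(10, 30), sessile_invertebrates = 0,
                       sand = 0, canopy_algae = 0, understorey_algae = 0)
  expect_equal(site_date_habitat(tc)$turfing_algae, 20)
})
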