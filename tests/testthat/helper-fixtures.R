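# Shared fixtures: tiny hand-built tables plus a lazily cached synthetic run.

tiny_pool <- function() {
  tibble::tibble(
    species = c("wrasse", "leatherjacket", "ray"),
    family = c("Labridae", "Monacanthidae", "Urolophidae"),
    a = c(0.01, 0.02, 0.012),
    b = c(3, 3, 3),
    mean_length_cm = c(20, 15, 35),
    length_sdlog = 0.2,
    biomass_share = c(0.6, 0.4, 0.05),
    excluded = c(FALSE, FALSE, TRUE)
  )
}

tiny_records <- function() {
  tibble::tibble(
    site_id = "S1",
    survey_date = "2021-06-01",
    transect_id = c("T1", "T1", "T2"),
    species = c("wrasse", "leatherjacket", "wrasse"),
    family = c("Labridae", "Monacanthidae", "Labridae"),
    size_class_cm = c(20, 15, 25),
    count = c(2L, 3L, 1L)
  )
}

small_config <- function(...) {
  generator_config(n_sites = 120, transects_per_site = 2, seed = 101, ...)
}

# One small simulated dataset reused across test files (built once).
.fixture_env <- new.env(parent = emptyenv())

small_sim <- function() {
  if (is.null(.fixture_env$sim)) {
    .fixture_env$sim <- simulate_reef_data(small_config())
  }
  .fixture_env$sim
}

small_processed <- function() {
  if (is.null(.fixture_env$proc)) {
    sim <- small_sim()
    .fixture_env$proc <- suppressMessages(
      process_surveys(sim$surveys, sim$pool, sim$habitat)
    )
  }
  .fixture_env$proc
}

# Full-size default run used by the end-to-end recovery checks; cached so
# several tests can share the single expensive computation.
default_run <- function(seed = 1) {
  key <- paste0("run_", seed)
  if (is.null(.fixture_env[[key]])) {
    cfg <- generator_config(seed = seed)
    sim <- simulate_reef_data(cfg)
    proc <- suppressMessages(process_surveys(sim$surveys, sim$pool, sim$habitat))
    stage <- counterfactual_stage(proc$biomass_by_site, sim$sites,
                                  settings = rf_settings(seed = seed))
    .fixture_env[[key]] <- list(sim = sim, proc = proc, stage = stage,
                                summary = summarize_by_protection(stage$ratios))
  }
  .fixture_env[[key]]
}
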