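#' Configuration for the synthetic reef-survey generator
#'
#' Bundles every knob of the synthetic data generator into a validated list.
#' Defaults emulate a temperate-Australia-scale survey campaign: ~1000 sites
#' along a >3000 km coastline, protection assigned in contiguous MPA blocks,
#' and multiplicative planted protection effects of x1.34 (fully protected)
#' and x1.10 (partially protected) on total fish biomass, so the downstream
#' pipeline has a known ground truth to recover.
#'
#' @param n_sites Number of survey sites (>= 20).
#' @param prop_fully_protected,prop_partially_protected Fractions of sites
#'   inside fully / partially protected MPA zones; must sum to < 1.
#' @param protection_multiplier_full,protection_multiplier_partial
#'   Multiplicative effect of protection on true biomass (> 0). The default
#'   1.34 corresponds to biomass 34% above the fished counterfactual.
#' @param beta_turf,beta_sand,beta_depth Planted effects on log10 biomass per
#'   standard deviation of turf cover, sand cover and depth.
#' @param env_effect_sst Slope of log10 biomass on mean SST (per degree C).
#' @param beta_aux Length-2 numeric: minor planted effects (per SD) of the
#'   first two auxiliary ocean covariates; the remaining covariates are
#'   decoys that carry no signal.
#' @param grid_sd Standard deviation of 100 x 100 km grid-cell random
#'   intercepts (log10 units).
#' @param resid_sd Residual site-level standard deviation (log10 units).
#'   Within-site transect variability in real campaigns is not published;
#'   this default is a free choice of the generator.
#' @param n_species Number of (non-excluded) teleost species in the pool;
#'   two elasmobranch species from excluded families are always appended so
#'   the family-exclusion filter is exercised.
#' @param transects_per_site Transects surveyed per site and date.
#' @param sites_per_mpa Mean number of contiguous sites per protected block.
#' @param baseline_log10 Grand mean of log10 biomass (kg per 500 m2) before
#'   covariate and protection effects.
#' @param length_sdlog Log-scale SD of individual fish lengths around the
#'   species mean (lognormal lengths).
#' @param max_size_cm Upper end of the legal size-category labels.
#' @param seed Integer seed; every generator stage derives its RNG stream
#'   from it, so identical configs yield identical data.
#' @return A list of class `reef_generator_config`.
#' @examples
#' cfg <- generator_config(n_sites = 100, seed = 1)
#' @export
generator_config <- function(n_sites = 1000,
                             prop_fully_protected = 0.2,
                             prop_partially_protected = 0.2,
                             protection_multiplier_full = 1.34,
                             protection_multiplier_partial = 1.10,
                             beta_turf = 0.05,
                             beta_sand = -0.05,
                             beta_depth = 0.05,
                             env_effect_sst = 0.04,
                             beta_aux = c(0.05, -0.05),
                             grid_sd = 0.05,
                             resid_sd = 0.15,
                             n_species = 12,
                             transects_per_site = 2,
                             sites_per_mpa = 6,
                             baseline_log10 = 1.1,
                             length_sdlog = 0.2,
                             max_size_cm = 200,
                             seed = 1L) {
  cfg <- list(
    n_sites = as.integer(n_sites),
    prop_fully_protected = prop_fully_protected,
    prop_partially_protected = prop_partially_protected,
    protection_multiplier_full = protection_multiplier_full,
    protection_multiplier_partial = protection_multiplier_partial,
    beta_turf = beta_turf, beta_sand = beta_sand, beta_depth = beta_depth,
    env_effect_sst = env_effect_sst,
    beta_aux = beta_aux,
    grid_sd = grid_sd, resid_sd = resid_sd,
    n_species = as.integer(n_species),
    transects_per_site = as.integer(transects_per_site),
    sites_per_mpa = sites_per_mpa,
    baseline_log10 = baseline_log10,
    length_sdlog = length_sdlog,
    max_size_cm = max_size_cm,
    seed = as.integer(seed)
  )
  validate_generator_config(cfg)
  structure(cfg, class = "reef_generator_config")
}

validate_generator_config <- function(cfg) {
  fr <- c(cfg$prop_fully_protected, cfg$prop_partially_protected)
  if (any(!is.finite(fr)) || any(fr < 0) || any(fr > 1) || sum(fr) >= 1) {
    stop("protection fractions must lie in [0, 1] and sum to < 1", call. = FALSE)
  }
  if (cfg$protection_multiplier_full <= 0 || cfg$protection_multiplier_partial <= 0) {
    stop("protection multipliers must be > 0", call. = FALSE)
  }
  if (cfg$grid_sd < 0 || cfg$resid_sd < 0 || cfg$length_sdlog < 0) {
    stop("standard deviations must be >= 0", call. = FALSE)
  }
  if (cfg$n_sites < 20) stop("n_sites must be >= 20", call. = FALSE)
  if (cfg$n_species < 1) stop("n_species must be >= 1", call. = FALSE)
  if (cfg$transects_per_site < 1) stop("transects_per_site must be >= 1", call. = FALSE)
  if (length(cfg$beta_aux) != 2) stop("beta_aux must have length 2", call. = FALSE)
  invisible(cfg)
}

#' @export
print.reef_generator_config <- function(x, ...) {
  cat("<reef_generator_config>\n")
  cat(sprintf("  sites: %d (%.0f%% full, %.0f%% partial protection)\n",
              x$n_sites, 100 * x$prop_fully_protected,
              100 * x$prop_partially_protected))
  cat(sprintf("  planted multipliers: full x%.2f, partial x%.2f\n",
              x$protection_multiplier_full, x$protection_multiplier_partial))
  cat(sprintf("  habitat betas (per SD): turf %+0.2f, sand %+0.2f, depth %+0.2f\n",
              x$beta_turf, x$beta_sand, x$beta_depth))
  cat(sprintf("  grid_sd %.3f, resid_sd %.3f, seed %d\n",
              x$grid_sd, x$resid_sd, x$seed))
  invisible(x)
}

# Evaluate `expr` under `seed` without disturbing the caller's RNG state.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}

# Smooth spatially autocorrelated surface via random Fourier features.
# Returns a vector with roughly zero mean and unit SD; correlation length
# is controlled by `range_km`. Consumes RNG state.
spatial_field <- function(x_km, y_km, range_km = 250, n_basis = 40) {
  freq <- matrix(rnorm(2 * n_basis, sd = 1 / range_km), ncol = 2)
  phase <- runif(n_basis, 0, 2 * pi)
  proj <- cbind(x_km, y_km) %*% t(freq)
  proj <- sweep(proj, 2, phase, "+")
  as.numeric(sqrt(2 / n_basis) * rowSums(cos(proj)))
}

#' Species pool with length-weight allometry
#'
#' Draws a deterministic pool of `n_species` teleost species (weight in grams
#' from W = a L^b, lognormal lengths around a species mean) plus two
#' elasmobranch species from families conventionally excluded from biomass
#' reconstruction (skates and rays), so the exclusion filter always has work
#' to do. Relative expected biomass shares are drawn once per pool.
#'
#' @param config A [generator_config()].
#' @return Tibble with columns `species`, `family`, `a`, `b`,
#'   `mean_length_cm`, `length_sdlog`, `biomass_share`, `excluded`.
#' @export
species_pool <- function(config) {
  stopifnot(inherits(config, "reef_generator_config"))
  n <- config$n_species
  with_local_seed(config$seed + 11L, {
    families <- c("Labridae", "Monacanthidae", "Scorpididae", "Cheilodactylidae",
                  "Sparidae", "Serranidae", "Mullidae", "Pomacentridae")
    pool <- tibble::tibble(
      species = sprintf("species_%02d", seq_len(n)),
      family = sample(families, n, replace = TRUE),
      a = exp(runif(n, log(0.008), log(0.03))),
      b = runif(n, 2.8, 3.2),
      mean_length_cm = exp(runif(n, log(8), log(45))),
      length_sdlog = config$length_sdlog,
      biomass_share = NA_real_,
      excluded = FALSE
    )
    shares <- rgamma(n, shape = 2)
    pool$biomass_share <- shares / sum(shares)
    rays <- tibble::tibble(
      species = c("ray_01", "skate_01"),
      family = c("Urolophidae", "Rajidae"),
      a = c(0.012, 0.010),
      b = c(3.0, 3.05),
      mean_length_cm = c(35, 50),
      length_sdlog = config$length_sdlog,
      biomass_share = c(0.04, 0.04),  # relative to total teleost biomass
      excluded = TRUE
    )
    dplyr::bind_rows(pool, rays)
  })
}

#' Families excluded from biomass reconstruction
#'
#' Skate and ray families whose biomass estimates from visual surveys are
#' considered too uncertain; records from these families are dropped before
#' biomass is reconstructed.
#' @return Character vector of family names.
#' @export
excluded_families <- function() {
  c("Rajidae", "Urolophidae", "Dasyatidae", "Myliobatidae", "Rhinobatidae")
}

# ---------------------------------------------------------------------------

#' Generate site metadata with spatially structured covariates
#'
#' Places `n_sites` along a synthetic temperate coastline spanning well over
#' 1000 km, draws spatially autocorrelated mean SST and ten auxiliary ocean
#' covariates (random smooth surfaces; only the first two carry planted
#' signal), depth, ordinal physical scores, human gravity, distance from
#' shore, latent benthic covers, and assigns protection levels in contiguous
#' MPA blocks according to the configured fractions.
#'
#' @param config A [generator_config()].
#' @return Tibble with one row per site: identifiers, coordinates,
#'   `survey_date`, environmental covariates (`mean_sst`, `env_01` ..
#'   `env_10`), `depth_m`, physical scores, `human_gravity`,
#'   `distance_shore_m`, `protection`, `mpa_id`, `grid_cell_id`, and latent
#'   habitat covers (`true_cover_*`, percent).
#' @export
generate_sites <- function(config) {
  stopifnot(inherits(config, "reef_generator_config"))
  n <- config$n_sites
  with_local_seed(config$seed, {
    pos <- sort(runif(n))  # position along the coastline, west to east
    lon <- 114 + 39.5 * pos + rnorm(n, 0, 0.15)
    # monotone southward drift with a gentle meander: latitude coverage stays
    # near-uniform so no single temperature band dominates the site density
    lat <- -29.5 - 14 * pos + 0.6 * sin(3 * pi * pos) + rnorm(n, 0, 0.1)
    lat <- pmin(pmax(lat, -43.8), -29.0)
    x_km <- lon * 111.32 * cos(-36.5 * pi / 180)
    y_km <- lat * 110.574

    mean_sst <- 21.5 + 0.55 * (lat + 29.5) + 0.8 * spatial_field(x_km, y_km, 300)
    aux <- vapply(seq_len(10), function(i) {
      spatial_field(x_km, y_km, range_km = runif(1, 150, 400))
    }, numeric(n))
    colnames(aux) <- sprintf("env_%02d", seq_len(10))

    depth_m <- pmin(pmax(1 + rgamma(n, shape = 2.2, scale = 2.5), 1), 25)
    scores <- function() sample(1:4, n, replace = TRUE, prob = c(0.3, 0.3, 0.25, 0.15))

    prot <- assign_protection_clusters(
      n, config$prop_fully_protected, config$prop_partially_protected,
      config$sites_per_mpa
    )

    covers <- latent_covers(x_km, y_km, n)

    sites <- tibble::tibble(
      site_id = sprintf("S%04d", seq_len(n)),
      latitude = lat,
      longitude = lon,
      survey_date = as.character(as.Date("2020-01-01") + sample(0:1095, n, replace = TRUE)),
      mean_sst = mean_sst,
      depth_m = depth_m,
      wave_exposure = scores(),
      slope = scores(),
      relief = scores(),
      currents = scores(),
      human_gravity = exp(runif(n, log(0.57), log(34856))),
      distance_shore_m = exp(runif(n, log(1), log(60447))),
      protection = prot$level,
      mpa_id = prot$mpa_id,
      grid_cell_id = assign_grid_cell(lat, lon)
    )
    dplyr::bind_cols(sites, tibble::as_tibble(aux), covers)
  })
}

# Contiguous blocks of protected sites along the coastline ordering;
# quotas are met exactly by trimming the final block of each level.
assign_protection_clusters <- function(n, prop_full, prop_partial, sites_per_mpa) {
  n_full <- round(n * prop_full)
  n_partial <- round(n * prop_partial)
  level <- rep("fished", n)
  mpa_id <- rep(NA_character_, n)

  sizes <- pmax(2, rpois(ceiling(2 * n / sites_per_mpa) + 4, sites_per_mpa))
  starts <- cumsum(c(1, sizes))
  blocks <- purrr::map2(starts[-length(starts)], sizes,
                        function(s, sz) seq(s, min(s + sz - 1, n)))
  blocks <- blocks[vapply(blocks, function(b) length(b) > 0 && b[1] <= n, logical(1))]
  order_blocks <- sample(seq_along(blocks))

  counter <- 0L
  take <- function(target, label, level, mpa_id, counter) {
    assigned <- 0L
    for (bi in order_blocks) {
      if (assigned >= target) break
      b <- blocks[[bi]]
      if (any(level[b] != "fished")) next
      b <- b[seq_len(min(length(b), target - assigned))]
      counter <- counter + 1L
      level[b] <- label
      mpa_id[b] <- sprintf("MPA_%03d", counter)
      assigned <- assigned + length(b)
    }
    list(level = level, mpa_id = mpa_id, counter = counter)
  }
  res <- take(n_full, "fully_protected", level, mpa_id, counter)
  res <- take(n_partial, "partially_protected", res$level, res$mpa_id, res$counter)
  list(level = factor(res$level,
                      levels = c("fished", "partially_protected", "fully_protected")),
       mpa_id = res$mpa_id)
}

# Latent per-site benthic covers (percent, summing to 100 across six broad
# groups incl. bare substrate) with spatial structure in turf/sand/canopy.
latent_covers <- function(x_km, y_km, n) {
  base <- c(canopy_algae = 3, understorey_algae = 2.5, turfing_algae = 3,
            sessile_invertebrates = 2, sand = 2.5, bare = 2)
  f_turf <- spatial_field(x_km, y_km, 250)
  f_sand <- spatial_field(x_km, y_km, 250)
  f_canopy <- spatial_field(x_km, y_km, 250)
  alpha <- cbind(
    canopy_algae = base["canopy_algae"] * exp(0.4 * f_canopy),
    understorey_algae = rep(base["understorey_algae"], n),
    turfing_algae = base["turfing_algae"] * exp(0.4 * f_turf),
    sessile_invertebrates = rep(base["sessile_invertebrates"], n),
    sand = base["sand"] * exp(0.4 * f_sand),
    bare = rep(base["bare"], n)
  )
  draws <- matrix(rgamma(length(alpha), shape = as.numeric(alpha)), nrow = n)
  covers <- 100 * draws / rowSums(draws)
  colnames(covers) <- paste0("true_cover_", colnames(alpha))
  tibble::as_tibble(covers)
}

# ---------------------------------------------------------------------------

#' Generate size-binned fish survey records with known true biomass
#'
#' Computes each site's true log10 biomass from the generative model
#' (environmental baseline + planted habitat/depth effects + log10 protection
#' multiplier + grid-cell random intercept + residual noise), then simulates
#' the observation process: per transect and species, Poisson fish counts
#' with lognormal individual lengths snapped to the legal size categories.
#' Species from excluded families are simulated on top of the true teleost
#' biomass so that the downstream exclusion filter is exercised.
#'
#' @param sites Output of [generate_sites()].
#' @param pool Output of [species_pool()].
#' @param config The same [generator_config()].
#' @return List with `surveys` (site_id, survey_date, transect_id, species,
#'   family, size_class_cm, count) and `truth` (per site: true and
#'   environmental-baseline log10 biomass, true lnrr, planted components).
#' @export
generate_surveys <- function(sites, pool, config) {
  stopifnot(inherits(config, "reef_generator_config"))
  if (nrow(pool) == 0) stop("species pool is empty", call. = FALSE)
  n <- nrow(sites)
  with_local_seed(config$seed + 1L, {
    zs <- function(x) (x - mean(x)) / sd(x)
    cells <- unique(sites$grid_cell_id)
    cell_int <- setNames(rnorm(length(cells), 0, config$grid_sd), cells)

    env_baseline <- config$baseline_log10 +
      config$env_effect_sst * (sites$mean_sst - mean(sites$mean_sst)) +
      config$beta_aux[1] * zs(sites$env_01) +
      config$beta_aux[2] * zs(sites$env_02)
    planted_local <- config$beta_turf * zs(sites$true_cover_turfing_algae) +
      config$beta_sand * zs(sites$true_cover_sand) +
      config$beta_depth * zs(sites$depth_m)
    mult <- c(fished = 1,
              partially_protected = config$protection_multiplier_partial,
              fully_protected = config$protection_multiplier_full)
    protection_effect <- log10(mult[as.character(sites$protection)])
    grid_effect <- cell_int[sites$grid_cell_id]
    resid <- rnorm(n, 0, config$resid_sd)
    true_log10 <- env_baseline + planted_local + protection_effect +
      grid_effect + resid

    truth <- tibble::tibble(
      site_id = sites$site_id,
      survey_date = sites$survey_date,
      protection = sites$protection,
      true_log10_biomass = true_log10,
      env_baseline_log10 = env_baseline,
      true_lnrr = true_log10 - env_baseline,
      planted_local_effect = planted_local,
      protection_effect = as.numeric(protection_effect),
      grid_effect = as.numeric(grid_effect)
    )

    surveys <- simulate_observation(sites, pool, config, true_log10)
    list(surveys = surveys, truth = truth)
  })
}

# Observation process: expected counts from target biomass and species
# shares, Poisson counts, lognormal lengths, nearest-size-category binning.
simulate_observation <- function(sites, pool, config, true_log10) {
  tps <- config$transects_per_site
  target_g <- 1000 * 10^true_log10  # grams per 500 m2 transect

  # lognormal length parameters per species; mean weight from moments
  mu_log <- log(pool$mean_length_cm) - pool$length_sdlog^2 / 2
  mean_w <- pool$a * exp(pool$b * mu_log + (pool$b * pool$length_sdlog)^2 / 2)

  grid <- expand.grid(site = seq_len(nrow(sites)), transect = seq_len(tps),
                      sp = seq_len(nrow(pool)))
  lambda <- target_g[grid$site] * pool$biomass_share[grid$sp] / mean_w[grid$sp]
  counts <- rpois(nrow(grid), lambda)
  keep <- counts > 0
  grid <- grid[keep, , drop = FALSE]
  counts <- counts[keep]

  sp_idx <- rep(grid$sp, counts)
  lengths <- rlnorm(length(sp_idx), mu_log[sp_idx], pool$length_sdlog[sp_idx])
  cats <- legal_size_categories(config$max_size_cm)
  bins <- nearest_size_category(lengths, cats)

  obs <- tibble::tibble(
    row = rep(seq_len(nrow(grid)), counts),
    size_class_cm = bins
  )
  agg <- dplyr::count(obs, .data$row, .data$size_class_cm, name = "count")
  tibble::tibble(
    site_id = sites$site_id[grid$site[agg$row]],
    survey_date = sites$survey_date[grid$site[agg$row]],
    transect_id = sprintf("T%d", grid$transect[agg$row]),
    species = pool$species[grid$sp[agg$row]],
    family = pool$family[grid$sp[agg$row]],
    size_class_cm = agg$size_class_cm,
    count = as.integer(agg$count)
  ) |>
    dplyr::arrange(.data$site_id, .data$transect_id, .data$species,
                   .data$size_class_cm)
}

# ---------------------------------------------------------------------------

#' Generate benthic cover records in both survey dialects
#'
#' A random half of sites is scored photo-quadrat style (100 points per
#' transect over 16 fine categories; percent covers sum to exactly 100),
#' the other half as layered in-situ point counts (canopy / subcanopy /
#' substrate, each a 50-point quadrat, so totals may exceed 50 points and the
#' top-down harmonization path is exercised).
#'
#' @param sites Output of [generate_sites()].
#' @param config The same [generator_config()].
#' @return Long tibble: `site_id`, `survey_date`, `transect_id`, `dialect`
#'   (`photo_quadrat` / `in_situ`), `layer` (NA for photo-quadrats),
#'   `category` (fine category), `value` (percent for photo-quadrats, points
#'   in 0..50 for in-situ layers).
#' @export
generate_habitat <- function(sites, config) {
  stopifnot(inherits(config, "reef_generator_config"))
  n <- nrow(sites)
  map <- default_category_map()
  with_local_seed(config$seed + 2L, {
    pq_sites <- sample(c(TRUE, FALSE), n, replace = TRUE)
    tps <- config$transects_per_site

    broad <- c("canopy_algae", "understorey_algae", "turfing_algae",
               "sessile_invertebrates", "sand", "bare")
    cover_mat <- as.matrix(sites[paste0("true_cover_", broad)])
    colnames(cover_mat) <- broad

    # per-site probability over the 16 fine categories: broad cover fraction
    # times a per-site gamma split within each group
    fine_prob <- matrix(0, n, nrow(map),
                        dimnames = list(NULL, map$fine))
    for (g in broad) {
      fines <- map$fine[map$group == g]
      w <- matrix(rgamma(n * length(fines), shape = 2), nrow = n)
      w <- w / rowSums(w)
      fine_prob[, fines] <- (cover_mat[, g] / 100) * w
    }

    # expand to transects
    site_idx <- rep(seq_len(n), each = tps)
    transect <- sprintf("T%d", rep(seq_len(tps), times = n))
    is_pq <- pq_sites[site_idx]

    out <- vector("list", 4)

    # photo-quadrat transects: 100 scored points over the fine categories
    pq_rows <- which(is_pq)
    if (length(pq_rows) > 0) {
      pts <- vapply(pq_rows, function(r) {
        as.integer(rmultinom(1, 100, fine_prob[site_idx[r], ]))
      }, integer(nrow(map)))
      out[[1]] <- melt_counts(pts, pq_rows, site_idx, transect, sites,
                              map$fine, dialect = "photo_quadrat",
                              layer = NA_character_)
    }

    # in-situ transects: one 50-point quadrat per structural layer; the
    # understorey extends beneath canopy and the substrate beneath both, so
    # the quadrat total can exceed 50 points (100% equivalent cover)
    ins_rows <- which(!is_pq)
    if (length(ins_rows) > 0) {
      inflate <- c(canopy = 1, subcanopy = 1.4, substrate = 1.8)
      li <- 2
      for (ly in names(inflate)) {
        fines <- map$fine[map$layer == ly]
        p_layer <- pmin(1, rowSums(fine_prob[, fines, drop = FALSE]) *
                          inflate[[ly]])
        totals <- rbinom(length(ins_rows), 50, p_layer[site_idx[ins_rows]])
        pts <- vapply(seq_along(ins_rows), function(j) {
          if (totals[j] == 0) return(integer(length(fines)))
          p <- fine_prob[site_idx[ins_rows[j]], fines]
          if (sum(p) == 0) return(integer(length(fines)))
          as.integer(rmultinom(1, totals[j], p))
        }, integer(length(fines)))
        out[[li]] <- melt_counts(pts, ins_rows, site_idx, transect, sites,
                                 fines, dialect = "in_situ", layer = ly)
        li <- li + 1
      }
    }

    dplyr::bind_rows(out) |>
      dplyr::arrange(.data$site_id, .data$transect_id, .data$layer,
                     .data$category)
  })
}

# counts: categories x transect-subset matrix -> long tibble of nonzero rows
melt_counts <- function(counts, rows, site_idx, transect, sites, fine,
                        dialect, layer) {
  counts <- matrix(counts, nrow = length(fine))
  nz <- which(counts > 0, arr.ind = TRUE)
  if (nrow(nz) == 0) return(NULL)
  r <- rows[nz[, 2]]
  tibble::tibble(
    site_id = sites$site_id[site_idx[r]],
    survey_date = sites$survey_date[site_idx[r]],
    transect_id = transect[r],
    dialect = dialect,
    layer = layer,
    category = fine[nz[, 1]],
    value = as.numeric(counts[nz])
  )
}

# ---------------------------------------------------------------------------

#' Simulate a complete synthetic reef-survey dataset
#'
#' Convenience wrapper running [generate_sites()], [species_pool()],
#' [generate_surveys()] and [generate_habitat()] under one configuration.
#'
#' @param config A [generator_config()].
#' @return List: `config`, `sites`, `pool`, `surveys`, `truth`, `habitat`.
#' @examples
#' sim <- simulate_reef_data(generator_config(n_sites = 40, seed = 7))
#' names(sim)
#' @export
simulate_reef_data <- function(config = generator_config()) {
  sites <- generate_sites(config)
  pool <- species_pool(config)
  sv <- generate_surveys(sites, pool, config)
  habitat <- generate_habitat(sites, config)
  list(config = config, sites = sites, pool = pool,
       surveys = sv$surveys, truth = sv$truth, habitat = habitat)
}
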