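#' Default fine-to-broad benthic category mapping
#'
#' Maps the 16 fine benthic categories scored on transects to the five broad
#' groups used in the analysis (turfing algae, sessile invertebrates, sand,
#' canopy algae, understorey algae). Abiotic categories (bare rock, cobble)
#' have no broad group and are dropped, with their total logged, during
#' aggregation. The `layer` column records which structural layer each fine
#' category occupies in layered in-situ quadrats.
#'
#' @return Tibble with columns `fine`, `coarse16`, `broad5` (NA for abiotic),
#'   `group` and `layer`.
#' @export
default_category_map <- function() {
  tibble::tribble(
    ~fine,                   ~group,                  ~layer,
    "laminarian_kelp",       "canopy_algae",          "canopy",
    "fucoid_canopy",         "canopy_algae",          "canopy",
    "foliose_brown",         "understorey_algae",     "subcanopy",
    "foliose_red",           "understorey_algae",     "subcanopy",
    "foliose_green",         "understorey_algae",     "subcanopy",
    "calcified_algae",       "understorey_algae",     "subcanopy",
    "turf_mat",              "turfing_algae",         "substrate",
    "filamentous_algae",     "turfing_algae",         "substrate",
    "sponges",               "sessile_invertebrates", "substrate",
    "ascidians",             "sessile_invertebrates", "substrate",
    "hard_corals_bryozoans", "sessile_invertebrates", "substrate",
    "other_sessile_inverts", "sessile_invertebrates", "substrate",
    "sand",                  "sand",                  "substrate",
    "shell_grit",            "sand",                  "substrate",
    "bare_rock",             "bare",                  "substrate",
    "cobble",                "bare",                  "substrate"
  ) |>
    dplyr::mutate(coarse16 = .data$fine,
                  broad5 = ifelse(.data$group == "bare", NA_character_,
                                  .data$group)) |>
    dplyr::select(dplyr::all_of(c("fine", "coarse16", "broad5", "group",
                                  "layer")))
}

#' Names of the five broad habitat categories
#' @return Character vector of the five broad cover groups.
#' @export
broad_habitat_categories <- function() {
  c("turfing_algae", "sessile_invertebrates", "sand",
    "canopy_algae", "understorey_algae")
}

#' Remove records from excluded families
#'
#' Drops all survey records whose family appears in the exclusion list
#' (by default skates and rays, whose visual biomass estimates are too
#' uncertain) and reports how many records were removed.
#'
#' @param records Survey-record tibble with a `family` column.
#' @param families Character vector of families to exclude
#'   (default [excluded_families()]).
#' @return Filtered tibble; the number of removed records is attached as
#'   attribute `n_removed` and reported via `message()`.
#' @export
exclude_families <- function(records, families = excluded_families()) {
  if (!"family" %in% names(records)) {
    stop("`records` must contain a `family` column", call. = FALSE)
  }
  keep <- !(records$family %in% families)
  out <- records[keep, , drop = FALSE]
  n_removed <- sum(!keep)
  if (n_removed > 0) {
    message(sprintf("exclude_families: removed %d record(s) from excluded families",
                    n_removed))
  }
  attr(out, "n_removed") <- n_removed
  out
}

#' Reconstruct biomass per transect from size-binned counts
#'
#' Converts each record's size-category label to weight through the species'
#' length-weight relationship W = a L'^b (grams), where L' is the recorded
#' bin label after an optional diver-bias correction, and sums count-weighted
#' biomass over each transect. The bin label itself is used as the length
#' (sizes are recorded to the nearest category; no midpoint rule applies).
#'
#' @param records Filtered survey records (`site_id`, `survey_date`,
#'   `transect_id`, `species`, `size_class_cm`, `count`).
#' @param pool Species pool with `species`, `a`, `b` columns.
#' @param bias_correction Optional `function(species, length_cm)` returning
#'   corrected lengths; `NULL` (default) applies the identity correction.
#' @return Tibble: `site_id`, `survey_date`, `transect_id`, `biomass_kg`
#'   (kg per 500 m2). Transects present in `records` with zero total count
#'   get 0 kg.
#' @examples
#' pool <- tibble::tibble(species = "sp", a = 0.01, b = 3)
#' rec <- tibble::tibble(site_id = "s", survey_date = "2020-01-01",
#'                       transect_id = "T1", species = "sp",
#'                       size_class_cm = 20, count = 2)
#' transect_biomass(rec, pool)  # 2 * 0.01 * 20^3 g = 0.16 kg
#' @export
transect_biomass <- function(records, pool, bias_correction = NULL) {
  missing_sp <- setdiff(unique(records$species), pool$species)
  if (length(missing_sp) > 0) {
    stop("species missing length-weight parameters: ",
         paste(missing_sp, collapse = ", "), call. = FALSE)
  }
  if (any(records$count < 0)) stop("counts must be >= 0", call. = FALSE)
  lw <- pool[match(records$species, pool$species), c("a", "b")]
  len <- records$size_class_cm
  if (!is.null(bias_correction)) {
    len <- bias_correction(records$species, len)
  }
  weight_g <- lw$a * len^lw$b
  records |>
    dplyr::mutate(.biomass_g = .data$count * weight_g) |>
    dplyr::group_by(.data$site_id, .data$survey_date, .data$transect_id) |>
    dplyr::summarise(biomass_kg = sum(.data$.biomass_g) / 1000,
                     .groups = "drop")
}

#' Observed log biomass per site and date
#'
#' Averages transect biomass (raw kg scale) over all transects of each
#' site/date combination, then applies the log10(X + 0.001) transform used
#' to stabilize extremely high biomass values.
#'
#' @param transects Output of [transect_biomass()].
#' @return Tibble: `site_id`, `survey_date`, `observed_biomass` (kg per
#'   500 m2, mean over transects), `observed_log10`.
#' @export
observed_log_biomass <- function(transects) {
  transects |>
    dplyr::group_by(.data$site_id, .data$survey_date) |>
    dplyr::summarise(observed_biomass = mean(.data$biomass_kg),
                     .groups = "drop") |>
    dplyr::mutate(observed_log10 = log10(.data$observed_biomass + 0.001))
}

#' Harmonize one layered in-situ quadrat to 2-D equivalent percent cover
#'
#' Layered in-situ quadrats score up to 50 points per structural layer
#' (canopy, subcanopy, substrate), so totals can exceed 50 points (100%
#' cover). To mimic a two-dimensional photo-quadrat the layers are scaled
#' from the top down: the canopy is retained in full, then the subcanopy and
#' finally the substrate are truncated to the remaining capacity, with
#' categories inside a truncated layer reduced proportionally, until 50
#' points (100% cover) is reached. Quadrats totalling at most 50 points pass
#' through unchanged (doubled into percent).
#'
#' @param quadrat Tibble with columns `layer` (canopy/subcanopy/substrate),
#'   `category` and `value` (points, 0..50 per layer).
#' @return Tibble `category`, `percent`; sums to exactly 100 when the input
#'   total is >= 50 points, and to `2 * total` otherwise.
#' @examples
#' q <- tibble::tibble(layer = c("canopy", "subcanopy", "substrate"),
#'                     category = c("kelp", "foliose_red", "sand"),
#'                     value = c(30, 20, 40))
#' scale_insitu_quadrat(q)  # kelp 60%, foliose_red 40%, sand 0%
#' @export
scale_insitu_quadrat <- function(quadrat) {
  layers <- c("canopy", "subcanopy", "substrate")
  if (!all(quadrat$layer %in% layers)) {
    stop("unknown layer: ",
         paste(setdiff(quadrat$layer, layers), collapse = ", "), call. = FALSE)
  }
  layer_totals <- vapply(layers, function(l) sum(quadrat$value[quadrat$layer == l]),
                         numeric(1))
  if (any(layer_totals > 50 + 1e-8)) {
    stop("layer point count exceeds the 50-point quadrat", call. = FALSE)
  }
  if (any(quadrat$value < 0)) stop("point counts must be >= 0", call. = FALSE)

  capacity <- 50
  out <- quadrat
  out$scaled <- 0
  for (l in layers) {
    idx <- out$layer == l
    tot <- sum(out$value[idx])
    if (tot == 0) next
    keep <- min(tot, capacity)
    out$scaled[idx] <- out$value[idx] * keep / tot
    capacity <- capacity - keep
  }
  out |>
    dplyr::group_by(.data$category) |>
    dplyr::summarise(percent = 2 * sum(.data$scaled), .groups = "drop")
}

#' Harmonize mixed-dialect habitat records to per-transect percent covers
#'
#' Photo-quadrat rows pass through unchanged (their values are already 2-D
#' percent covers); layered in-situ transects are collapsed with
#' [scale_insitu_quadrat()].
#'
#' @param habitat Long habitat tibble (`site_id`, `survey_date`,
#'   `transect_id`, `dialect`, `layer`, `category`, `value`).
#' @return Tibble: `site_id`, `survey_date`, `transect_id`, `category`,
#'   `percent`.
#' @export
harmonize_habitat <- function(habitat) {
  pq <- habitat |>
    dplyr::filter(.data$dialect == "photo_quadrat") |>
    dplyr::group_by(.data$site_id, .data$survey_date, .data$transect_id,
                    .data$category) |>
    dplyr::summarise(percent = sum(.data$value), .groups = "drop")

  insitu <- habitat |> dplyr::filter(.data$dialect == "in_situ")
  if (nrow(insitu) > 0) {
    # vectorized top-down scaling (same rule as scale_insitu_quadrat):
    # canopy kept in full, lower layers truncated to remaining capacity
    layer_rank <- c(canopy = 1, subcanopy = 2, substrate = 3)
    if (!all(insitu$layer %in% names(layer_rank))) {
      stop("unknown layer: ",
           paste(setdiff(insitu$layer, names(layer_rank)), collapse = ", "),
           call. = FALSE)
    }
    totals <- insitu |>
      dplyr::group_by(.data$site_id, .data$survey_date, .data$transect_id,
                      .data$layer) |>
      dplyr::summarise(layer_total = sum(.data$value), .groups = "drop")
    if (any(totals$layer_total > 50 + 1e-8)) {
      stop("layer point count exceeds the 50-point quadrat", call. = FALSE)
    }
    caps <- totals |>
      dplyr::group_by(.data$site_id, .data$survey_date, .data$transect_id) |>
      dplyr::arrange(layer_rank[.data$layer], .by_group = TRUE) |>
      dplyr::mutate(
        used_above = cumsum(.data$layer_total) - .data$layer_total,
        kept = pmin(.data$layer_total, pmax(50 - .data$used_above, 0)),
        factor = ifelse(.data$layer_total > 0, .data$kept / .data$layer_total, 0)
      ) |>
      dplyr::ungroup()
    insitu <- insitu |>
      dplyr::left_join(
        caps[, c("site_id", "survey_date", "transect_id", "layer", "factor")],
        by = c("site_id", "survey_date", "transect_id", "layer")
      ) |>
      dplyr::group_by(.data$site_id, .data$survey_date, .data$transect_id,
                      .data$category) |>
      dplyr::summarise(percent = 2 * sum(.data$value * .data$factor),
                       .groups = "drop")
  } else {
    insitu <- pq[0, ]
  }
  dplyr::bind_rows(pq, insitu)
}

#' Aggregate fine benthic categories to the five broad groups
#'
#' Sums fine-category percent covers within each of the five broad analysis
#' groups (see [broad_habitat_categories()]). Abiotic fine categories that
#' map to no broad group are dropped; their total is reported as a message
#' and attached as attribute `dropped_percent_total`.
#'
#' @param covers Per-transect fine covers (`site_id`, `survey_date`,
#'   `transect_id`, `category`, `percent`).
#' @param category_map Mapping tibble, default [default_category_map()].
#' @return Wide tibble: keys + one column per broad category (all five
#'   always present, zero-filled).
#' @export
aggregate_habitat <- function(covers, category_map = default_category_map()) {
  unmapped <- setdiff(unique(covers$category), category_map$fine)
  if (length(unmapped) > 0) {
    stop("fine categories absent from the mapping: ",
         paste(unmapped, collapse = ", "), call. = FALSE)
  }
  covers$broad <- category_map$broad5[match(covers$category, category_map$fine)]
  dropped <- sum(covers$percent[is.na(covers$broad)])
  if (dropped > 0) {
    message(sprintf("aggregate_habitat: dropped %.1f total %% of abiotic cover",
                    dropped))
  }
  out <- covers |>
    dplyr::filter(!is.na(.data$broad)) |>
    dplyr::group_by(.data$site_id, .data$survey_date, .data$transect_id,
                    .data$broad) |>
    dplyr::summarise(percent = sum(.data$percent), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "broad", values_from = "percent",
                       values_fill = 0)
  for (b in broad_habitat_categories()) {
    if (!b %in% names(out)) out[[b]] <- 0
  }
  out <- out[, c("site_id", "survey_date", "transect_id",
                 broad_habitat_categories())]
  attr(out, "dropped_percent_total") <- dropped
  out
}

#' Average habitat covers over transects of each site and date
#'
#' @param transect_covers Wide per-transect broad covers from
#'   [aggregate_habitat()].
#' @return Tibble keyed by `site_id`, `survey_date` with mean percent cover
#'   per broad category.
#' @export
site_date_habitat <- function(transect_covers) {
  transect_covers |>
    dplyr::group_by(.data$site_id, .data$survey_date) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(broad_habitat_categories()),
                                   mean),
                     .groups = "drop")
}

#' Process raw survey and habitat records into site-level observations
#'
#' Full survey-processing stage: family exclusion, transect biomass
#' reconstruction, site/date averaging with the log10(X + 0.001) transform,
#' habitat harmonization and aggregation to the five broad categories.
#'
#' @param surveys Raw fish survey records.
#' @param pool Species pool (length-weight parameters).
#' @param habitat Long habitat records (both dialects).
#' @param category_map Fine-to-broad mapping, default
#'   [default_category_map()].
#' @param exclusion Families to drop, default [excluded_families()].
#' @param bias_correction Optional diver-bias length correction (see
#'   [transect_biomass()]).
#' @return List: `biomass_by_site` (site/date observed biomass and log10),
#'   `habitat_by_site` (site/date mean broad covers).
#' @export
process_surveys <- function(surveys, pool, habitat,
                            category_map = default_category_map(),
                            exclusion = excluded_families(),
                            bias_correction = NULL) {
  filtered <- exclude_families(surveys, exclusion)
  biomass <- transect_biomass(filtered, pool, bias_correction) |>
    observed_log_biomass()
  covers <- harmonize_habitat(habitat) |>
    aggregate_habitat(category_map) |>
    site_date_habitat()
  list(biomass_by_site = biomass, habitat_by_site = covers)
}
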