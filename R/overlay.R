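# Conservation overlays: top-quartile classification, PA filtering and
# zone/country reports, all in exact cell arithmetic on the shared grid.

cells_to_mask <- function(grid, cells) {
  m <- matrix(FALSE, grid$n_rows, grid$n_cols)
  m[cells] <- TRUE
  m
}

#' Buffer the current range outward
#'
#' Morphological dilation of the range's cell mask by a disc: a cell joins
#' the buffered range if any range cell centre lies within `buffer_km` of
#' its centre. Optional exclusion zones (e.g. countries where the species
#' is extinct) are subtracted afterwards.
#'
#' @param range_zone A zone (from a `zone_set`) or logical mask matrix.
#' @param grid A [grid_spec()].
#' @param buffer_km Outward buffer distance in km (0 = identity).
#' @param exclude Optional list of zones (or masks) to subtract.
#' @return Logical mask matrix of the buffered range.
#' @export
buffer_current_range <- function(range_zone, grid, buffer_km = 100, exclude = NULL) {
  mask <- if (is.matrix(range_zone)) range_zone else cells_to_mask(grid, range_zone$cells)
  stopifnot(buffer_km >= 0)
  if (buffer_km > 0) {
    r_px <- buffer_km * 1000 / grid$resolution
    rr <- ceiling(r_px)
    off <- (-rr):rr
    disc <- (outer(off^2, off^2, "+") <= r_px^2) + 0
    mask <- conv2_same(mask + 0, disc) > 0.5
  }
  if (!is.null(exclude)) {
    for (z in exclude) {
      em <- if (is.matrix(z)) z else cells_to_mask(grid, z$cells)
      mask <- mask & !em
    }
  }
  mask
}

#' Filter protected areas for the assessment
#'
#' Adjacent protected areas (cell masks touching, 8-neighbourhood) within
#' the same country are first merged into blocks; a block is retained only
#' if it is larger than `min_area_km2`, lies below `max_elev_m` (zone-level
#' maximum elevation), and intersects the buffered current range.
#'
#' @param pas A `zone_set` (only its `"PA"` zones are used).
#' @param buffered_range Logical mask matrix from [buffer_current_range()].
#' @param min_area_km2 Minimum block area, exclusive (default 100).
#' @param max_elev_m Elevation ceiling (default 3000).
#' @return A `zone_set` of surviving PA blocks; each block's attrs carry
#'   `members`, the ids of the merged source PAs.
#' @export
filter_protected_areas <- function(pas, buffered_range, min_area_km2 = 100,
                                   max_elev_m = 3000) {
  grid <- pas$grid
  pa_zones <- Filter(function(z) z$zone_type == "PA", pas$zones)
  if (!length(pa_zones)) return(zone_set(grid, list()))
  n <- length(pa_zones)
  # adjacency: masks touch when one dilated by 1 cell overlaps the other
  dil <- lapply(pa_zones, function(z) {
    m <- cells_to_mask(grid, z$cells)
    conv2_same(m + 0, matrix(1, 3, 3)) > 0.5
  })
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    same_country <- identical(pa_zones[[i]]$attrs$country, pa_zones[[j]]$attrs$country)
    if (same_country && any(dil[[i]][pa_zones[[j]]$cells])) {
      parent[find(j)] <- find(i)
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  blocks <- lapply(unique(comp), function(cid) {
    members <- pa_zones[comp == cid]
    cells <- sort(unique(unlist(lapply(members, `[[`, "cells"))))
    zone(paste0("pablock_", members[[1]]$zone_id), "PA",
         paste(vapply(members, `[[`, character(1), "name"), collapse = "+"),
         cells, grid,
         max_elevation_m = max(vapply(members, function(z) z$attrs$max_elevation_m,
                                      numeric(1))),
         country = members[[1]]$attrs$country,
         members = vapply(members, `[[`, character(1), "zone_id"))
  })
  keep <- vapply(blocks, function(b) {
    b$attrs$area_km2 > min_area_km2 &&
      (is.na(b$attrs$max_elevation_m) || b$attrs$max_elevation_m < max_elev_m) &&
      any(buffered_range[b$cells])
  }, logical(1))
  if (!any(keep)) message("no protected-area block passed the filters")
  zone_set(grid, blocks[keep])
}

#' Share of total suitability held by each zone
#'
#' `share(z) = 100 * sum(w over cells of z) / sum(w over the current
#' range)`, treating the suitability surface as continuous mass.
#'
#' @param surface A `suitability_surface`.
#' @param zones A `zone_set` (zones to report; a `current_range` zone in
#'   the set defines the denominator, else all valid cells do).
#' @return Tibble `zone_id`, `zone_type`, `share_pct`.
#' @export
summed_share <- function(surface, zones) {
  stop_if_grid_mismatch(surface$grid, zones$grid)
  w <- surface$w
  rng <- Filter(function(z) z$zone_type == "current_range", zones$zones)
  total <- if (length(rng)) sum(w[rng[[1]]$cells], na.rm = TRUE) else sum(w, na.rm = TRUE)
  rows <- lapply(zones$zones, function(z) {
    tibble::tibble(zone_id = z$zone_id, zone_type = z$zone_type,
                   share_pct = 100 * sum(w[z$cells], na.rm = TRUE) / total)
  })
  do.call(rbind, rows)
}

#' Classify highly suitable habitat (top quartile)
#'
#' Flags cells in the upper quartile of suitability. In the range-based
#' scenario the 75th-percentile threshold is taken over all valid cells at
#' once; in the ecoregion-based scenario it is taken separately within
#' each ecoregion, so every ecoregion contributes its own best quarter.
#' Cells equal to the threshold are flagged (exactly 25% when values are
#' distinct); a constant stratum flags everything with a warning; strata
#' with fewer than 4 valid cells are skipped.
#'
#' @param surface A `suitability_surface`.
#' @param scenario `"range_based"` or `"ecoregion_based"`.
#' @param ecoregions A `zone_set` holding the ecoregion partition
#'   (required for the ecoregion scenario).
#' @param quartile Flagged upper fraction (default 0.25).
#' @return A `high_suitability_mask`: logical `mask` matrix, `scenario`,
#'   and a tibble of per-stratum `threshold`s.
#' @export
classify_high <- function(surface, scenario = c("range_based", "ecoregion_based"),
                          ecoregions = NULL, quartile = 0.25) {
  scenario <- match.arg(scenario)
  w <- surface$w
  mask <- matrix(FALSE, nrow(w), ncol(w))
  flag_stratum <- function(cells, label) {
    v <- w[cells]
    cells <- cells[!is.na(v)]
    v <- v[!is.na(v)]
    if (length(v) < 4) {
      warning("stratum '", label, "' has fewer than 4 valid cells; skipped")
      return(NULL)
    }
    thr <- sort(v, decreasing = TRUE)[ceiling(quartile * length(v))]
    if (thr == min(v)) warning("stratum '", label, "' is (near-)constant: ",
                               "ties flag the whole stratum")
    mask[cells[v >= thr]] <<- TRUE
    tibble::tibble(stratum = label, threshold = thr, n_valid = length(v))
  }
  thresholds <- if (scenario == "range_based") {
    flag_stratum(which(!is.na(w)), "range")
  } else {
    if (is.null(ecoregions)) {
      stop("ecoregion_based scenario requires an ecoregion zone_set", call. = FALSE)
    }
    eco <- Filter(function(z) z$zone_type == "ecoregion", ecoregions$zones)
    if (!length(eco)) stop("no ecoregion zones supplied", call. = FALSE)
    do.call(rbind, Filter(Negate(is.null),
                          lapply(eco, function(z) flag_stratum(z$cells, z$zone_id))))
  }
  structure(list(mask = mask, scenario = scenario, thresholds = thresholds),
            class = "high_suitability_mask")
}

high_category <- function(prop_pct) {
  stopifnot(all(prop_pct >= 0 & prop_pct <= 100))
  out <- character(length(prop_pct))
  out[prop_pct == 0] <- "0%"
  out[prop_pct > 0 & prop_pct < 25] <- "25-0%"
  out[prop_pct >= 25 & prop_pct < 50] <- "50-25%"
  out[prop_pct >= 50 & prop_pct < 75] <- "75-50%"
  out[prop_pct >= 75] <- "100-75%"
  out
}

#' Per-zone report of highly suitable habitat
#'
#' For each zone and scenario mask: zone area, summed-suitability share,
#' highly suitable area inside the zone, the proportion of the zone that
#' is highly suitable, and its five-class category (`100-75%`, `75-50%`,
#' `50-25%`, `25-0%`, `0%`; boundary values go to the upper class, exact
#' zero to `0%`).
#'
#' @param masks A `high_suitability_mask` or named list of them.
#' @param surface A `suitability_surface`.
#' @param zones A `zone_set` of the zones to report.
#' @return Tibble with one row per zone x scenario.
#' @export
zone_report <- function(masks, surface, zones) {
  if (inherits(masks, "high_suitability_mask")) masks <- list(masks)
  shares <- summed_share(surface, zones)
  grid <- zones$grid
  rows <- lapply(masks, function(mk) {
    per_zone <- lapply(zones$zones, function(z) {
      nhigh <- sum(mk$mask[z$cells])
      prop <- 100 * nhigh / length(z$cells)
      tibble::tibble(zone_id = z$zone_id, zone_type = z$zone_type,
                     scenario = mk$scenario,
                     area_km2 = z$attrs$area_km2,
                     share_pct = shares$share_pct[shares$zone_id == z$zone_id],
                     high_area_km2 = nhigh * cell_area_km2(grid),
                     high_prop_pct = prop,
                     category = high_category(prop))
    })
    do.call(rbind, per_zone)
  })
  do.call(rbind, rows)
}

#' Country-wise assessment of highly suitable habitat
#'
#' For each country and scenario: range area inside the country, highly
#' suitable area and its percentage of the country's range, and the
#' percentage of that highly suitable habitat lying inside filtered
#' protected-area blocks.
#'
#' @param masks A `high_suitability_mask` or named list of them.
#' @param surface A `suitability_surface`.
#' @param countries A `zone_set` of `"country"` zones.
#' @param pas A `zone_set` of (filtered) PA blocks, or `NULL`.
#' @return Tibble with one row per country x scenario.
#' @export
country_report <- function(masks, surface, countries, pas = NULL) {
  if (inherits(masks, "high_suitability_mask")) masks <- list(masks)
  grid <- countries$grid
  pa_mask <- matrix(FALSE, grid$n_rows, grid$n_cols)
  if (!is.null(pas)) for (z in pas$zones) pa_mask[z$cells] <- TRUE
  ctry <- Filter(function(z) z$zone_type == "country", countries$zones)
  rows <- lapply(masks, function(mk) {
    per <- lapply(ctry, function(z) {
      valid <- z$cells[!is.na(surface$w[z$cells])]
      nhigh <- sum(mk$mask[valid])
      nprot <- sum(mk$mask[valid] & pa_mask[valid])
      tibble::tibble(country = z$zone_id, scenario = mk$scenario,
                     range_area_km2 = length(valid) * cell_area_km2(grid),
                     high_area_km2 = nhigh * cell_area_km2(grid),
                     high_pct = if (length(valid)) 100 * nhigh / length(valid) else 0,
                     protected_high_pct = if (nhigh) 100 * nprot / nhigh else 0)
    })
    do.call(rbind, per)
  })
  do.call(rbind, rows)
}
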