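#' Zone sets: raster-native conservation geographies
#'
#' Zones (current range, ecoregions, protected areas, countries, priority
#' units, non-designated lands) are represented natively on the analysis
#' grid: each zone is the set of cells whose centres it contains, following
#' the half-open pixel rule used everywhere in the pipeline. This makes all
#' overlay arithmetic (areas, shares, partition checks) exact cell counts.
#'
#' @param grid A [grid_spec()].
#' @param zones List of zones created with [zone()].
#' @return A `zone_set`.
#' @export
zone_set <- function(grid, zones) {
  stopifnot(is.list(zones))
  ids <- vapply(zones, function(z) z$zone_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate zone_id in zone_set", call. = FALSE)
  structure(list(grid = grid, zones = zones), class = "zone_set")
}

#' Create a single zone from its member cells
#'
#' @param zone_id Unique identifier.
#' @param zone_type One of `"PA"`, `"JCU"`, `"ecoregion"`, `"country"`,
#'   `"non_designated"`, `"current_range"`.
#' @param name Human-readable name.
#' @param cells Integer cell indices (column-major) of the zone's members.
#' @param grid The shared `grid_spec` (used for the area attribute).
#' @param max_elevation_m Highest elevation inside the zone (PA filter input).
#' @param country Country label the zone belongs to (used when merging PAs).
#' @param ... Further attributes stored verbatim.
#' @return A zone (plain list) for use in [zone_set()].
#' @export
zone <- function(zone_id, zone_type, name, cells, grid,
                 max_elevation_m = NA_real_, country = NA_character_, ...) {
  zone_type <- match.arg(zone_type, c("PA", "JCU", "ecoregion", "country",
                                      "non_designated", "current_range"))
  cells <- sort(unique(as.integer(cells)))
  stopifnot(all(cells >= 1), all(cells <= n_cells(grid)))
  list(zone_id = as.character(zone_id), zone_type = zone_type, name = name,
       cells = cells,
       attrs = c(list(area_km2 = length(cells) * cell_area_km2(grid),
                      max_elevation_m = max_elevation_m, country = country),
                 list(...)))
}

#' @export
print.zone_set <- function(x, ...) {
  tab <- table(vapply(x$zones, function(z) z$zone_type, character(1)))
  cat("<zone_set>", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Subset a zone set by zone type
#' @param zones A `zone_set`.
#' @param type Zone type to keep.
#' @return A `zone_set` with only the matching zones.
#' @export
zones_of_type <- function(zones, type) {
  zone_set(zones$grid, Filter(function(z) z$zone_type == type, zones$zones))
}

#' Generate a synthetic zone geography
#'
#' Builds a `current_range` zone covering the whole grid, `n_ecoregions`
#' ecoregions as the Voronoi partition of seeded points (so they tile the
#' range exactly), `n_countries` countries as an independent Voronoi
#' partition, and `n_pas` protected areas as disjoint random rectangles,
#' each carrying a synthetic `max_elevation_m` attribute and the country of
#' its centroid.
#'
#' @param grid A [grid_spec()].
#' @param n_ecoregions Number of ecoregions (>= 1).
#' @param n_pas Number of protected-area rectangles (>= 0).
#' @param seed Integer seed.
#' @param n_countries Number of countries (default 3; 0 for none).
#' @return A `zone_set`.
#' @export
generate_zone_set <- function(grid, n_ecoregions, n_pas = 0L, seed = 1L,
                              n_countries = 3L) {
  stopifnot(n_ecoregions >= 1, n_pas >= 0, n_countries >= 0)
  all_cells <- seq_len(n_cells(grid))
  ctr <- xy_from_cell(grid, all_cells)
  withr::with_seed(seed, {
    zones <- list(zone("range", "current_range", "current range", all_cells, grid))

    voronoi_partition <- function(n, prefix, type) {
      if (n == 1L) {
        return(list(zone(paste0(prefix, 1), type, paste0(prefix, 1), all_cells, grid)))
      }
      seeds <- cbind(stats::runif(n, grid$origin_x, grid$origin_x + grid$n_cols * grid$resolution),
                     stats::runif(n, grid$origin_y - grid$n_rows * grid$resolution, grid$origin_y))
      d2 <- sapply(seq_len(n), function(k) (ctr[, 1] - seeds[k, 1])^2 + (ctr[, 2] - seeds[k, 2])^2)
      nearest <- max.col(-d2, ties.method = "first")
      lapply(seq_len(n), function(k) {
        zone(paste0(prefix, k), type, paste0(prefix, k), all_cells[nearest == k], grid)
      })
    }

    eco <- voronoi_partition(n_ecoregions, "eco", "ecoregion")
    ctry <- if (n_countries > 0) voronoi_partition(n_countries, "country", "country") else list()
    country_of_cell <- rep(NA_character_, n_cells(grid))
    for (z in ctry) country_of_cell[z$cells] <- z$zone_id

    pas <- list()
    occupied <- rep(FALSE, n_cells(grid))
    attempts <- 0L
    while (length(pas) < n_pas && attempts < 200L * max(1L, n_pas)) {
      attempts <- attempts + 1L
      h <- sample(max(2L, grid$n_rows %/% 20L):max(3L, grid$n_rows %/% 6L), 1)
      w <- sample(max(2L, grid$n_cols %/% 20L):max(3L, grid$n_cols %/% 6L), 1)
      i0 <- sample(seq_len(grid$n_rows - h + 1L), 1)
      j0 <- sample(seq_len(grid$n_cols - w + 1L), 1)
      ii <- i0:(i0 + h - 1L); jj <- j0:(j0 + w - 1L)
      cells <- as.integer(outer(ii, (jj - 1L) * grid$n_rows, "+"))
      if (any(occupied[cells])) next
      occupied[cells] <- TRUE
      k <- length(pas) + 1L
      cen <- round(colMeans(xy_from_cell(grid, cells)))
      ccell <- cell_from_xy(grid, cen[1], cen[2])
      pas[[k]] <- zone(paste0("pa", k), "PA", paste0("pa", k), cells, grid,
                       max_elevation_m = stats::runif(1, 0, 4000),
                       country = if (length(ctry)) country_of_cell[ccell] else NA_character_)
    }
    if (length(pas) < n_pas) {
      warning("placed only ", length(pas), " of ", n_pas,
              " requested protected areas (grid too crowded)")
    }
    zone_set(grid, c(zones, eco, ctry, pas))
  })
}
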