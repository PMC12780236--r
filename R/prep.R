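#' Spatially rarefy telemetry to one fix per pixel
#'
#' Duty cycles differ wildly between collars, so fixes are thinned to at
#' most one per individual per 500 m pixel before any modelling. The
#' chronologically first fix in a pixel is kept (ties broken by input
#' order); row order of the retained fixes is preserved.
#'
#' @param telemetry Telemetry tibble (`individual_id`, `timestamp`, `x`, `y`, ...).
#' @param grid A [grid_spec()].
#' @return The rarefied telemetry tibble.
#' @export
rarefy <- function(telemetry, grid) {
  if (nrow(telemetry) == 0) return(telemetry)
  cells <- cell_from_xy(grid, telemetry$x, telemetry$y)
  if (anyNA(cells)) stop("telemetry contains coordinates outside the grid", call. = FALSE)
  ord <- order(telemetry$individual_id, telemetry$timestamp)
  first <- ord[!duplicated(paste(telemetry$individual_id, cells)[ord])]
  telemetry[sort(first), , drop = FALSE]
}

#' Availability radius from home-range area
#'
#' Median mammalian dispersal distance is approximately isometric with the
#' linear dimension of the home range: radius = `7 * sqrt(area)`.
#'
#' @param home_range_area Home-range area in km^2 (> 0).
#' @return Availability radius in km.
#' @export
availability_radius <- function(home_range_area) {
  if (any(!is.finite(home_range_area)) || any(home_range_area <= 0)) {
    stop("home_range_area must be positive", call. = FALSE)
  }
  7 * sqrt(home_range_area)
}

#' Build an individual's availability domain
#'
#' The domain available to an individual is the union of discs of radius
#' `d` around its retained fixes, clipped to the grid. The domain is held
#' as the set of grid cells whose centres fall inside that union, the same
#' membership rule used for all zonal arithmetic.
#'
#' @param ind_locs Telemetry tibble for one individual (>= 1 row).
#' @param d Disc radius in km (> 0).
#' @param grid A [grid_spec()].
#' @return An `availability_domain`: `individual_id`, `centers` (x/y
#'   matrix), `radius_km`, `cells` (integer cell indices), `grid`.
#' @export
build_availability_domain <- function(ind_locs, d, grid) {
  if (d <= 0) stop("availability radius d must be > 0", call. = FALSE)
  if (nrow(ind_locs) < 1) stop("at least one location is required", call. = FALSE)
  ids <- unique(ind_locs$individual_id)
  if (length(ids) > 1) stop("ind_locs must belong to a single individual", call. = FALSE)
  cells <- unique(unlist(lapply(seq_len(nrow(ind_locs)), function(k) {
    cells_in_disc(grid, ind_locs$x[k], ind_locs$y[k], d * 1000)
  })))
  if (!length(cells)) stop("availability domain is empty after clipping to the grid",
                           call. = FALSE)
  structure(list(individual_id = ids, centers = cbind(x = ind_locs$x, y = ind_locs$y),
                 radius_km = d, cells = sort(cells), grid = grid),
            class = "availability_domain")
}

#' Area of an availability domain
#'
#' Computed by sub-pixel sampling: each grid cell overlapping the domain's
#' bounding box is subdivided `subdiv x subdiv` times and sub-centres are
#' tested against the disc union, so the estimate converges to the exact
#' geometric area.
#'
#' @param domain An `availability_domain`.
#' @param subdiv Sub-pixel sampling factor per cell edge (default 4).
#' @return Area in km^2.
#' @export
domain_area_km2 <- function(domain, subdiv = 4L) {
  g <- domain$grid
  res <- g$resolution
  sub <- res / subdiv
  r_m <- domain$radius_km * 1000
  xs <- range(domain$centers[, 1]); ys <- range(domain$centers[, 2])
  ext <- grid_extent(g)
  gx <- seq(max(ext["xmin"], xs[1] - r_m) + sub / 2, min(ext["xmax"], xs[2] + r_m), by = sub)
  gy <- seq(max(ext["ymin"], ys[1] - r_m) + sub / 2, min(ext["ymax"], ys[2] + r_m), by = sub)
  inside <- matrix(FALSE, length(gy), length(gx))
  for (k in seq_len(nrow(domain$centers))) {
    d2 <- outer((gy - domain$centers[k, 2])^2, (gx - domain$centers[k, 1])^2, "+")
    inside <- inside | (d2 <= r_m^2)
  }
  sum(inside) * (sub / 1000)^2
}

#' Sample temporally matched background points
#'
#' Draws `ratio` background (available) points per used point, uniformly
#' over the individual's availability domain, with the constraint that no
#' two rows of the design - used or available - share a 500 m pixel within
#' an individual. Each background point inherits the calendar month of the
#' used point it is matched to, so covariate extraction sees the same
#' season/year for both sides of a pair.
#'
#' @param used Rarefied telemetry tibble for one individual.
#' @param domain The individual's [build_availability_domain()].
#' @param ratio Background points per used point (default 10).
#' @param grid A [grid_spec()].
#' @param seed Integer seed.
#' @return A use/available tibble: `case` (1 used / 0 available),
#'   `individual_id`, `month`, `x`, `y`, `pair_id` (row id of the matched
#'   used fix; a used row is its own pair).
#' @export
sample_background <- function(used, domain, ratio = 10L, grid, seed = 1L) {
  stopifnot(ratio >= 1, nrow(used) >= 1)
  used_cells <- cell_from_xy(grid, used$x, used$y)
  if (anyNA(used_cells)) stop("used locations outside grid", call. = FALSE)
  if (anyDuplicated(used_cells)) {
    stop("used locations must be rarefied (one per pixel) before background sampling",
         call. = FALSE)
  }
  free <- setdiff(domain$cells, used_cells)
  need <- ratio * nrow(used)
  if (length(free) < need) {
    stop("availability domain has only ", length(free),
         " free pixels but ", need, " background points are required (deficit ",
         need - length(free), ")", call. = FALSE)
  }
  month <- month_label(used$timestamp)
  withr::with_seed(seed, {
    bg_cells <- sample(free, need, replace = FALSE)
    xy <- xy_from_cell(grid, bg_cells)
    used_xy <- xy_from_cell(grid, used_cells) # snap used rows to cell centres
    pair <- sprintf("%s.%04d", domain$individual_id, seq_len(nrow(used)))
    tibble::tibble(
      case = rep(c(1L, 0L), c(nrow(used), need)),
      individual_id = domain$individual_id,
      month = c(month, rep(month, each = ratio)),
      x = c(used_xy[, 1], xy[, 1]),
      y = c(used_xy[, 2], xy[, 2]),
      pair_id = c(pair, rep(pair, each = ratio))
    )
  })
}

#' Assemble the full used/available design for a population
#'
#' Convenience wrapper: rarefies the telemetry, builds each individual's
#' availability domain from its fixes and radius, and samples matched
#' background points, returning one combined table.
#'
#' @param telemetry Telemetry tibble for all individuals.
#' @param individuals Population tibble with `individual_id` and `radius_km`.
#' @param grid A [grid_spec()].
#' @param ratio Background points per used point (default 10).
#' @param seed Integer seed (per-individual child seeds are derived from it).
#' @return A use/available tibble as from [sample_background()].
#' @export
build_use_available <- function(telemetry, individuals, grid, ratio = 10L, seed = 1L) {
  telemetry <- rarefy(telemetry, grid)
  parts <- lapply(seq_len(nrow(individuals)), function(i) {
    ind <- individuals[i, ]
    locs <- telemetry[telemetry$individual_id == ind$individual_id, , drop = FALSE]
    if (nrow(locs) == 0) return(NULL)
    dom <- build_availability_domain(locs, ind$radius_km, grid)
    sample_background(locs, dom, ratio = ratio, grid = grid,
                      seed = child_seed(seed, ind$individual_id))
  })
  do.call(rbind, Filter(Negate(is.null), parts))
}

#' Split presences into training and validation sets
#'
#' Only used rows are randomly partitioned, stratified by individual so
#' every individual contributes to training; each available row follows
#' its matched used row, keeping pairs intact.
#'
#' @param table Use/available tibble with `pair_id`.
#' @param train_fraction Fraction of presences for training, in (0, 1),
#'   default 0.80.
#' @param seed Integer seed.
#' @return The table with an added `split` column (`"train"`/`"validate"`).
#' @export
split_train_validate <- function(table, train_fraction = 0.8, seed = 1L) {
  if (!(train_fraction > 0 && train_fraction < 1)) {
    stop("train_fraction must be strictly between 0 and 1", call. = FALSE)
  }
  used <- table[table$case == 1L, ]
  if (nrow(used) < 5) stop("need at least 5 used rows to split", call. = FALSE)
  lookup <- withr::with_seed(seed, {
    unlist(unname(lapply(split(used$pair_id, used$individual_id), function(p) {
      n_tr <- round(length(p) * train_fraction)
      tr <- sample(p, n_tr)
      stats::setNames(ifelse(p %in% tr, "train", "validate"), p)
    })))
  })
  table$split <- unname(lookup[table$pair_id])
  table
}
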