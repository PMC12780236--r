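#' Simulate a collared population
#'
#' Draws individuals with sex- and region-specific home-range areas and
#' uniform activity centres. The availability radius of each individual is
#' the isometric dispersal approximation `7 * sqrt(home-range area)` used
#' throughout the used/available design. Sexes are allocated
#' deterministically by rounding (`n_f = round(n * sex_ratio)`), regions
#' cyclically from the home-range table.
#'
#' @param n_individuals Number of individuals (0 allowed, returns empty).
#' @param sex_ratio Fraction of females in `[0, 1]`.
#' @param hr_by_region_sex Data frame with columns `region`, `sex`
#'   (`"F"`/`"M"`) and `hr_km2` (mean home-range area, km^2, > 0).
#' @param grid A [grid_spec()].
#' @param seed Integer seed.
#' @return A tibble with columns `individual_id`, `sex`, `region`,
#'   `hr_km2`, `radius_km`, `center_x`, `center_y`.
#' @export
simulate_population <- function(n_individuals, sex_ratio, hr_by_region_sex,
                                grid, seed = 1L) {
  stopifnot(is.data.frame(hr_by_region_sex),
            all(c("region", "sex", "hr_km2") %in% names(hr_by_region_sex)),
            all(hr_by_region_sex$hr_km2 > 0),
            sex_ratio >= 0, sex_ratio <= 1)
  if (n_individuals == 0) {
    return(tibble::tibble(individual_id = character(0), sex = character(0),
                          region = character(0), hr_km2 = numeric(0),
                          radius_km = numeric(0), center_x = numeric(0),
                          center_y = numeric(0)))
  }
  n_f <- round(n_individuals * sex_ratio)
  sex <- rep(c("F", "M"), c(n_f, n_individuals - n_f))
  regions <- unique(hr_by_region_sex$region)
  region <- rep_len(regions, n_individuals)
  hr <- mapply(function(r, s) {
    row <- hr_by_region_sex$region == r & hr_by_region_sex$sex == s
    if (!any(row)) stop("no home-range entry for region '", r, "', sex '", s, "'",
                        call. = FALSE)
    hr_by_region_sex$hr_km2[row][1]
  }, region, sex)
  radius_km <- availability_radius(hr)
  ext <- grid_extent(grid)
  withr::with_seed(seed, {
    cx <- numeric(n_individuals); cy <- numeric(n_individuals)
    for (i in seq_len(n_individuals)) {
      buf <- radius_km[i] * 1000
      # edge-buffer the centre when the grid allows it, else fall back to the
      # full interior (availability discs are then clipped downstream)
      if (ext["xmax"] - ext["xmin"] > 2 * buf && ext["ymax"] - ext["ymin"] > 2 * buf) {
        cx[i] <- stats::runif(1, ext["xmin"] + buf, ext["xmax"] - buf)
        cy[i] <- stats::runif(1, ext["ymin"] + buf, ext["ymax"] - buf)
      } else {
        cx[i] <- stats::runif(1, ext["xmin"], ext["xmax"])
        cy[i] <- stats::runif(1, ext["ymin"], ext["ymax"])
      }
    }
    tibble::tibble(
      individual_id = sprintf("ind%03d", seq_len(n_individuals)),
      sex = sex, region = region, hr_km2 = as.numeric(hr),
      radius_km = radius_km, center_x = cx, center_y = cy
    )
  })
}

#' Ground-truth selection coefficients and scales
#'
#' Bundles the true selection coefficients and the true scale of effect per
#' covariate, the recovery target for the whole pipeline.
#'
#' @param beta Named numeric vector of selection coefficients, one per
#'   covariate acting on the kernel-smoothed layer.
#' @param scale_km Named numeric vector of true scales (km), same names.
#' @param seed Seed recorded for provenance.
#' @return A `truth_bundle`.
#' @export
truth_bundle <- function(beta, scale_km, seed = NA_integer_) {
  stopifnot(!is.null(names(beta)), !is.null(names(scale_km)),
            setequal(names(beta), names(scale_km)))
  structure(list(beta = beta, scale_km = scale_km[names(beta)], seed = seed),
            class = "truth_bundle")
}

#' Simulate RSF-driven telemetry
#'
#' For each individual, cells inside its availability disc (clipped to the
#' grid) are drawn independently with probability proportional to
#' `exp(sum_c beta_c * z_{c,s(c)}(x))`, where `z_{c,s}` is covariate `c`
#' smoothed with a Gaussian kernel at its true scale `s(c)`. Locations are
#' placed at cell centres and stamped with consecutive days starting at
#' `start_date`, so month labels advance naturally.
#'
#' @param stack A `covariate_stack` containing every covariate named in
#'   `truth`.
#' @param individuals Tibble from [simulate_population()].
#' @param truth A [truth_bundle()].
#' @param n_locs_per_individual Fixes to draw per individual (>= 1).
#' @param seed Integer seed.
#' @param start_date First fix date (ISO string), default `"2020-01-01"`.
#' @return A telemetry tibble: `individual_id`, `sex`, `region`,
#'   `timestamp` (Date), `x`, `y`.
#' @export
simulate_telemetry <- function(stack, individuals, truth,
                               n_locs_per_individual, seed = 1L,
                               start_date = "2020-01-01") {
  stopifnot(inherits(truth, "truth_bundle"), n_locs_per_individual >= 1)
  missing <- setdiff(names(truth$beta), names(stack$layers))
  if (length(missing)) {
    stop("truth covariates not in stack: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  grid <- stack$grid
  # smooth each active covariate once at its true scale; standardize the
  # smoothed layer so every coefficient expresses the same selection
  # strength per sd regardless of how much smoothing shrinks the variance
  zs <- lapply(names(truth$beta), function(cv) {
    z <- smooth_covariate(stack$layers[[cv]],
                          build_gaussian_kernel(truth$scale_km[[cv]], grid$resolution))
    (z - mean(z, na.rm = TRUE)) / stats::sd(z, na.rm = TRUE)
  })
  names(zs) <- names(truth$beta)
  lp <- matrix(0, grid$n_rows, grid$n_cols)
  for (cv in names(truth$beta)) lp <- lp + truth$beta[[cv]] * zs[[cv]]

  withr::with_seed(seed, {
    out <- lapply(seq_len(nrow(individuals)), function(i) {
      ind <- individuals[i, ]
      cells <- cells_in_disc(grid, ind$center_x, ind$center_y, ind$radius_km * 1000)
      cells <- cells[!is.na(lp[cells])]
      if (!length(cells)) {
        stop("availability disc of ", ind$individual_id,
             " is empty after clipping to the grid", call. = FALSE)
      }
      w <- exp(lp[cells] - max(lp[cells]))
      picked <- sample(cells, n_locs_per_individual, replace = TRUE, prob = w)
      xy <- xy_from_cell(grid, picked)
      tibble::tibble(
        individual_id = ind$individual_id, sex = ind$sex, region = ind$region,
        timestamp = as.Date(start_date) + seq_len(n_locs_per_individual) - 1L,
        x = xy[, 1], y = xy[, 2]
      )
    })
    do.call(rbind, out)
  })
}
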