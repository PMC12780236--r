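#' Simulate a stack of spatially autocorrelated covariate layers
#'
#' Generates stationary Gaussian random fields by the convolution method:
#' white noise is smoothed with a Gaussian kernel on the torus (periodic
#' boundary, so the field is stationary across the whole grid) and each
#' layer is then standardized to mean 0, sd 1 over valid cells. The fields
#' stand in for gridded environmental covariates (forest cover, water
#' surface, human density, ...) whose "scale of effect" the pipeline later
#' estimates.
#'
#' @param grid A [grid_spec()].
#' @param n_covariates Number of layers to generate (>= 1).
#' @param autocorr_range Autocorrelation range in metres: the convolution
#'   kernel has sigma = `autocorr_range / 2`, giving correlation ~0.6 at
#'   half the range and near 0 beyond it. Must be at least one pixel and at
#'   most a quarter of the shorter grid side.
#' @param seed Integer seed; output is a pure function of the arguments.
#' @param names Optional layer names (default `cov01`, `cov02`, ...).
#' @param times Optional numeric time label (e.g. a year) per layer.
#' @return A `covariate_stack`: list with `grid`, `layers` (named list of
#'   matrices, `NA` = nodata) and `times` (named numeric, `NA` if untimed).
#' @export
generate_covariate_stack <- function(grid, n_covariates, autocorr_range = 4 * grid$resolution,
                                     seed = 1L, names = NULL, times = NULL) {
  stopifnot(n_covariates >= 1, autocorr_range >= grid$resolution)
  min_side_m <- min(grid$n_rows, grid$n_cols) * grid$resolution
  if (autocorr_range > min_side_m / 4) {
    stop("grid too small for autocorr_range = ", autocorr_range,
         " m (must be <= ", min_side_m / 4, " m for this grid)", call. = FALSE)
  }
  if (is.null(names)) names <- sprintf("cov%02d", seq_len(n_covariates))
  stopifnot(length(names) == n_covariates, !anyDuplicated(names))
  sigma_px <- (autocorr_range / 2) / grid$resolution
  r <- ceiling(3 * sigma_px)
  off <- (-r):r
  k <- exp(-outer(off^2, off^2, "+") / (2 * sigma_px^2))
  k <- k / sum(k)
  layers <- withr::with_seed(seed, {
    lapply(seq_len(n_covariates), function(i) {
      z <- matrix(stats::rnorm(n_cells(grid)), grid$n_rows, grid$n_cols)
      f <- conv2_wrap(z, k)
      (f - mean(f)) / stats::sd(f)
    })
  })
  names(layers) <- names
  tt <- rep(NA_real_, n_covariates)
  if (!is.null(times)) {
    stopifnot(length(times) == n_covariates)
    tt <- as.numeric(times)
  }
  names(tt) <- names
  covariate_stack(grid, layers, times = tt)
}

#' @export
print.covariate_stack <- function(x, ...) {
  cat(sprintf("<covariate_stack> %d layer(s) on %d x %d grid: %s\n",
              length(x$layers), x$grid$n_rows, x$grid$n_cols,
              paste(names(x$layers), collapse = ", ")))
  invisible(x)
}

#' Construct a covariate stack from existing matrices
#'
#' @param grid A [grid_spec()].
#' @param layers Named list of matrices matching the grid shape (`NA` = nodata).
#' @param times Optional numeric time label (e.g. year) per layer.
#' @param covariates Optional logical covariate name per layer; several
#'   layers may map to the same covariate when they are snapshots of it at
#'   different times (defaults to the layer names).
#' @return A `covariate_stack`.
#' @export
covariate_stack <- function(grid, layers, times = NULL, covariates = NULL) {
  stopifnot(is.list(layers), length(layers) >= 1, !is.null(names(layers)),
            !anyDuplicated(names(layers)))
  for (nm in names(layers)) {
    l <- layers[[nm]]
    if (!is.matrix(l) || nrow(l) != grid$n_rows || ncol(l) != grid$n_cols) {
      stop("layer '", nm, "' does not match the grid shape", call. = FALSE)
    }
  }
  tt <- rep(NA_real_, length(layers))
  if (!is.null(times)) {
    stopifnot(length(times) == length(layers))
    tt <- as.numeric(times)
  }
  names(tt) <- names(layers)
  cv <- covariates %||% names(layers)
  stopifnot(length(cv) == length(layers))
  names(cv) <- names(layers)
  dup <- duplicated(cv) & is.na(tt)
  if (any(dup)) stop("layers sharing a covariate must carry time labels", call. = FALSE)
  structure(list(grid = grid, layers = layers, times = tt, covariates = cv),
            class = "covariate_stack")
}

# Empirical correlogram along rows at given cell lags (internal diagnostic,
# used by tests to verify autocorrelation decay).
lag_correlation <- function(layer, lag) {
  a <- layer[, seq_len(ncol(layer) - lag)]
  b <- layer[, seq_len(ncol(layer) - lag) + lag]
  stats::cor(as.vector(a), as.vector(b), use = "complete.obs")
}
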