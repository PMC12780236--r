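#' Project a fitted RSF onto the landscape
#'
#' Evaluates the fixed-effect linear predictor cellwise on the smoothed
#' covariate layers at their chosen scales (random intercept at its mean,
#' 0) and maps it through the inverse logit. Because a use/availability
#' RSF estimates relative selection strength, the surface is meaningful up
#' to any monotone transform; the inverse logit keeps values in (0, 1)
#' and leaves every rank-based downstream step (bins, Boyce, quartiles)
#' invariant. The 10 equal-frequency bins are attached via
#' [quantile_bins()].
#'
#' @param model A `fitted_rsf` from [fit_final_model()] (standardization
#'   record required).
#' @param smoothed A [build_smoothed_stack()] result holding every
#'   selected `(covariate, scale)` layer. When a covariate has several
#'   time labels, the most recent layer is used.
#' @param n_bins Number of equal-frequency bins (default 10).
#' @return A `suitability_surface`: `grid`, continuous `w` matrix in
#'   (0, 1) (`NA` = nodata), integer `bins` matrix, and the bin cut values.
#' @export
predict_surface <- function(model, smoothed, n_bins = 10L) {
  if (is.null(model$standardization)) {
    stop("model carries no standardization record; fit it with fit_final_model()",
         call. = FALSE)
  }
  std <- model$standardization
  co <- model$coefficients
  b0 <- co$beta[co$term == "(Intercept)"]
  lp <- matrix(b0, smoothed$grid$n_rows, smoothed$grid$n_cols)
  idx <- smoothed$index
  for (r in seq_len(nrow(std))) {
    col <- std$column[r]
    beta <- co$beta[co$term == col]
    if (!length(beta)) next # column dropped in the fit
    cv <- sub("__[0-9.]+km$", "", col)
    sc <- as.numeric(sub("km$", "", sub("^.*__", "", col)))
    cand <- idx[idx$covariate == cv & idx$scale_km == sc, ]
    if (nrow(cand) == 0) {
      stop("smoothed stack lacks covariate '", cv, "' at scale ", sc, " km",
           call. = FALSE)
    }
    key <- if (all(is.na(cand$time))) cand$key[1] else cand$key[which.max(cand$time)]
    lp <- lp + beta * (smoothed$layers[[key]] - std$mean[r]) / std$sd[r]
  }
  w <- stats::plogis(lp)
  structure(c(list(grid = smoothed$grid, w = w),
              quantile_bins(w, n_bins = n_bins, as_list = TRUE)),
            class = "suitability_surface")
}

#' @export
print.suitability_surface <- function(x, ...) {
  v <- x$w[!is.na(x$w)]
  cat(sprintf("<suitability_surface> %d x %d, %d valid cells, w in [%.3f, %.3f], %d bins\n",
              x$grid$n_rows, x$grid$n_cols, length(v), min(v), max(v),
              max(x$bins, na.rm = TRUE)))
  invisible(x)
}

#' Equal-frequency (quantile) bins of a raster
#'
#' Cut values are the sorted cell values at ranks `ceiling(n * k / n_bins)`;
#' a cell equal to a cut value is assigned to the lower bin, so counts are
#' equal up to ties. An all-tied (constant) layer degenerates to a single
#' bin and is flagged with a warning.
#'
#' @param layer Numeric matrix (`NA` = nodata).
#' @param n_bins Number of bins (default 10).
#' @param as_list Internal: return `list(bins, bin_breaks)` instead of the
#'   bin matrix alone.
#' @return Integer matrix of bin numbers 1..n_bins (`NA` where input is
#'   nodata), with the cut values in attribute `breaks` (or as a list).
#' @export
quantile_bins <- function(layer, n_bins = 10L, as_list = FALSE) {
  v <- layer[!is.na(layer)]
  if (length(v) < n_bins) {
    stop("fewer valid cells (", length(v), ") than bins (", n_bins, ")", call. = FALSE)
  }
  s <- sort(v)
  cuts <- s[ceiling(length(s) * seq_len(n_bins - 1) / n_bins)]
  bins <- matrix(NA_integer_, nrow(layer), ncol(layer))
  ok <- !is.na(layer)
  bins[ok] <- 1L + findInterval(layer[ok], cuts, left.open = TRUE)
  if (length(unique(bins[ok])) == 1L) {
    warning("degenerate binning: ties collapse all cells into one bin")
  }
  if (as_list) list(bins = bins, bin_breaks = cuts)
  else structure(bins, breaks = cuts)
}

#' Boyce index of a suitability surface
#'
#' Presence-only evaluation: the valid cells are split into equal-frequency
#' suitability bins; for each bin the predicted frequency `P_i` (share of
#' evaluation presences falling in bin i) is compared with the expected
#' frequency `E_i` (share of valid cells in bin i) and the index is the
#' Spearman rank correlation (average ranks on ties) between the ratio
#' `F_i = P_i / E_i` and bin rank. 1 means presences pile up monotonically
#' in the most suitable bins, 0 a random model, negative values counter
#' prediction.
#'
#' @param surface A `suitability_surface`.
#' @param eval_points Tibble/data frame with `x`, `y` of evaluation
#'   presences (>= 10 on valid cells).
#' @return A `boyce_result`: per-bin tibble (`bin`, `predicted`,
#'   `expected`, `ratio`) and the index `boyce`.
#' @export
boyce_index <- function(surface, eval_points) {
  cells <- cell_from_xy(surface$grid, eval_points$x, eval_points$y)
  binv <- surface$bins[cells[!is.na(cells)]]
  binv <- binv[!is.na(binv)]
  if (length(binv) < 10) {
    stop("need at least 10 evaluation points on valid cells", call. = FALSE)
  }
  nb <- max(surface$bins, na.rm = TRUE)
  pred <- tabulate(binv, nbins = nb) / length(binv)
  expd <- tabulate(surface$bins[!is.na(surface$bins)], nbins = nb)
  expd <- expd / sum(expd)
  ratio <- ifelse(expd > 0, pred / expd, NA_real_)
  ok <- !is.na(ratio)
  b <- suppressWarnings(stats::cor(ratio[ok], seq_len(nb)[ok], method = "spearman"))
  structure(list(table = tibble::tibble(bin = seq_len(nb), predicted = pred,
                                        expected = expd, ratio = ratio),
                 boyce = b),
            class = "boyce_result")
}

#' @export
print.boyce_result <- function(x, ...) {
  cat(sprintf("<boyce_result> B = %.3f over %d bins\n", x$boyce, nrow(x$table)))
  invisible(x)
}

#' ROC metrics of a suitability surface against presence/absence points
#'
#' AUC (trapezoidal, via pROC) plus the optimal classification threshold
#' at the ROC point closest to the top-left corner, i.e. minimizing
#' `(1 - sensitivity)^2 + (1 - specificity)^2`, with the sensitivity and
#' specificity achieved there.
#'
#' @param surface A `suitability_surface`.
#' @param labelled_points Tibble with `x`, `y` and `presence` (0/1); both
#'   classes must be represented on valid cells.
#' @return A `roc_result`: `auc`, `threshold`, `sensitivity`, `specificity`,
#'   `n_presence`, `n_absence`.
#' @export
roc_metrics <- function(surface, labelled_points) {
  cells <- cell_from_xy(surface$grid, labelled_points$x, labelled_points$y)
  score <- surface$w[cells]
  ok <- !is.na(score)
  score <- score[ok]
  lab <- labelled_points$presence[ok]
  if (length(unique(lab)) < 2) {
    stop("both presences and absences are required on valid cells", call. = FALSE)
  }
  r <- pROC::roc(response = lab, predictor = score, quiet = TRUE,
                 direction = "<", levels = c(0, 1))
  best <- pROC::coords(r, x = "best", best.method = "closest.topleft",
                       ret = c("threshold", "sensitivity", "specificity"),
                       transpose = FALSE)
  best <- best[1, , drop = FALSE]
  structure(list(auc = as.numeric(pROC::auc(r)),
                 threshold = best$threshold,
                 sensitivity = best$sensitivity,
                 specificity = best$specificity,
                 n_presence = sum(lab == 1), n_absence = sum(lab == 0)),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.3f; tau* = %.3f (sens %.3f, spec %.3f)\n",
              x$auc, x$threshold, x$sensitivity, x$specificity))
  invisible(x)
}

#' Radius of the 100 km^2 density buffer, in km
#'
#' Density estimates are referenced to a 100 km^2 circular footprint;
#' the matching radius is `sqrt(100 / pi)` km (about 5.642 km).
#'
#' @param area_km2 Buffer area (default 100).
#' @return Radius in km.
#' @export
density_buffer_radius_km <- function(area_km2 = 100) sqrt(area_km2 / pi)

#' Regress observed densities on buffered mean suitability
#'
#' For each density record, the mean suitability over valid cells within a
#' circular buffer of 100 km^2 around the record is the predictor in an
#' ordinary least-squares regression of density.
#'
#' @param surface A `suitability_surface`.
#' @param density_records Tibble with `x`, `y`, `density` (>= 3 usable rows).
#' @param buffer_area_km2 Buffer area (default 100).
#' @return A `density_regression_result`: `slope`, `se`, `t`, `p`,
#'   `ci` (95% for the slope), `r_squared`, `n`, `radius_km`.
#' @export
density_regression <- function(surface, density_records, buffer_area_km2 = 100) {
  radius_km <- density_buffer_radius_km(buffer_area_km2)
  ms <- vapply(seq_len(nrow(density_records)), function(i) {
    cells <- cells_in_disc(surface$grid, density_records$x[i],
                           density_records$y[i], radius_km * 1000)
    mean(surface$w[cells], na.rm = TRUE)
  }, numeric(1))
  ok <- is.finite(ms)
  ms <- ms[ok]
  dens <- density_records$density[ok]
  if (length(ms) < 3) stop("need at least 3 density records on valid cells", call. = FALSE)
  if (stats::sd(ms) == 0) stop("buffered suitability has zero variance", call. = FALSE)
  fit <- stats::lm(dens ~ ms)
  sm <- summary(fit)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 se = sm$coefficients[2, 2],
                 t = sm$coefficients[2, 3],
                 p = sm$coefficients[2, 4],
                 ci = unname(stats::confint(fit)[2, ]),
                 r_squared = sm$r.squared,
                 n = length(ms), radius_km = radius_km),
            class = "density_regression_result")
}

#' @export
print.density_regression_result <- function(x, ...) {
  cat(sprintf("<density_regression> beta = %.3f (SE %.3f, t = %.2f, p = %.3g), R2 = %.3f, n = %d\n",
              x$slope, x$se, x$t, x$p, x$r_squared, x$n))
  invisible(x)
}

#' Pearson correlation between two co-registered rasters
#'
#' @param a,b Numeric matrices of equal shape (`NA` = nodata).
#' @return Pearson r over jointly valid cells (>= 3 required).
#' @export
raster_correlation <- function(a, b) {
  stopifnot(is.matrix(a), is.matrix(b), all(dim(a) == dim(b)))
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 3) stop("fewer than 3 jointly valid cells", call. = FALSE)
  stats::cor(a[ok], b[ok])
}
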