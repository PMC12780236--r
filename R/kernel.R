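#' The default candidate scale set
#'
#' Seven candidate scales of effect, in km, spanning local (one native
#' pixel) to broad landscape context, doubling at each step.
#'
#' @return Numeric vector `c(0.5, 1, 2, 4, 8, 16, 32)`.
#' @export
default_scales <- function() c(0.5, 1, 2, 4, 8, 16, 32)

#' Build an isotropic Gaussian smoothing kernel
#'
#' The kernel bandwidth is the scale itself: sigma = `scale` km, truncated
#' at radius 3 sigma and renormalized to sum 1, so the 0.5 km scale is
#' approximately the native 500 m pixel.
#'
#' @param scale Scale of effect in km (> 0).
#' @param resolution Grid resolution in metres (> 0).
#' @return A `kernel_matrix`: `scale_km`, `resolution`, `sigma_px`, and the
#'   odd-sided weight matrix `w` (non-negative, sums to 1).
#' @export
build_gaussian_kernel <- function(scale, resolution) {
  stopifnot(scale > 0, resolution > 0)
  sigma_px <- scale * 1000 / resolution
  r <- ceiling(3 * sigma_px)
  off <- (-r):r
  w <- exp(-outer(off^2, off^2, "+") / (2 * sigma_px^2))
  w <- w / sum(w)
  structure(list(scale_km = scale, resolution = resolution,
                 sigma_px = sigma_px, w = w),
            class = "kernel_matrix")
}

#' Gaussian focal mean of a raster layer
#'
#' Computes the kernel-weighted focal mean with the kernel renormalized
#' over valid cells near edges and nodata: the output at a cell is the
#' weighted mean of the valid in-grid cells under the kernel. A cell is set
#' to nodata when less than `min_valid_mass` of the kernel mass falling
#' inside the grid lies on valid cells. With `boundary = "wrap"` the layer
#' is treated as periodic (used for stationary diagnostics); nodata is not
#' supported on the torus.
#'
#' @param layer Numeric matrix (`NA` = nodata).
#' @param kernel A [build_gaussian_kernel()] result.
#' @param boundary `"valid"` (default, edge-renormalized) or `"wrap"`.
#' @param min_valid_mass Minimum fraction of in-grid kernel mass that must
#'   be valid (default 0.5).
#' @return Matrix of the same shape; `NA` where the layer cannot be smoothed.
#' @export
smooth_covariate <- function(layer, kernel, boundary = c("valid", "wrap"),
                             min_valid_mass = 0.5) {
  boundary <- match.arg(boundary)
  stopifnot(is.matrix(layer))
  k <- kernel$w
  if (nrow(k) > 4 * nrow(layer) || ncol(k) > 4 * ncol(layer)) {
    warning("kernel much larger than the grid; smoothing approaches the global mean")
  }
  if (boundary == "wrap") {
    if (anyNA(layer)) stop("nodata is not supported with wrap boundary", call. = FALSE)
    return(conv2_wrap(layer, k))
  }
  valid <- !is.na(layer)
  if (!any(valid)) return(layer)
  x0 <- layer
  x0[!valid] <- 0
  num <- conv2_same(x0, k)
  den_valid <- conv2_same(valid + 0, k)
  den_ingrid <- conv2_same(matrix(1, nrow(layer), ncol(layer)), k)
  out <- num / den_valid
  out[den_valid / den_ingrid < min_valid_mass] <- NA_real_
  out[den_valid <= 0] <- NA_real_
  out
}

#' Column/layer key of a covariate at a scale
#'
#' Design-matrix columns and smoothed-stack layers are keyed
#' `"<covariate>__<scale>km"`; this helper builds those keys.
#'
#' @param covariate Covariate name(s).
#' @param scale Scale(s) in km.
#' @return Character vector of keys.
#' @export
smoothed_key <- function(covariate, scale) sprintf("%s__%gkm", covariate, scale)

#' Smooth every covariate at every candidate scale
#'
#' @param stack A `covariate_stack`.
#' @param scales Strictly increasing positive scales in km
#'   (default [default_scales()]).
#' @return A `smoothed_stack`: `grid`, `layers` (named
#'   `"<covariate>__<scale>km"`), and an `index` tibble
#'   (`key`, `covariate`, `scale_km`, `time`).
#' @export
build_smoothed_stack <- function(stack, scales = default_scales()) {
  stopifnot(length(scales) >= 1, all(scales > 0), !is.unsorted(scales, strictly = TRUE))
  grid <- stack$grid
  cov_of <- stack$covariates %||% stats::setNames(names(stack$layers), names(stack$layers))
  idx <- expand.grid(layer = names(stack$layers), scale_km = scales,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  idx <- idx[order(match(idx$layer, names(stack$layers)), idx$scale_km), ]
  layers <- vector("list", nrow(idx))
  keys <- sprintf("%s__%gkm", idx$layer, idx$scale_km)
  kernels <- lapply(scales, build_gaussian_kernel, resolution = grid$resolution)
  names(kernels) <- as.character(scales)
  # batched FFT smoothing: one forward transform per source layer and per
  # kernel on a shared padded size, instead of one full convolution per
  # (layer, scale) pair; numerically identical to smooth_covariate()
  na_ <- grid$n_rows; ma <- grid$n_cols
  kmax <- max(vapply(kernels, function(k) nrow(k$w), integer(1)))
  nr <- na_ + kmax - 1L; nc <- ma + kmax - 1L
  padk <- function(k) { p <- matrix(0, nr, nc); p[1:nrow(k), 1:ncol(k)] <- k; stats::fft(p) }
  FK <- lapply(kernels, function(k) padk(k$w))
  ones <- matrix(0, nr, nc); ones[1:na_, 1:ma] <- 1
  FO <- stats::fft(ones)
  crop <- function(full, side) {
    r0 <- (side - 1L) %/% 2L
    full[(r0 + 1L):(r0 + na_), (r0 + 1L):(r0 + ma), drop = FALSE]
  }
  den_ingrid <- lapply(names(kernels), function(s) {
    crop(Re(stats::fft(FO * FK[[s]], inverse = TRUE)) / (nr * nc), nrow(kernels[[s]]$w))
  })
  names(den_ingrid) <- names(kernels)
  for (lname in unique(idx$layer)) {
    lay <- stack$layers[[lname]]
    valid <- !is.na(lay)
    has_na <- !all(valid)
    x0 <- lay; x0[!valid] <- 0
    px <- matrix(0, nr, nc); px[1:na_, 1:ma] <- x0
    FA <- stats::fft(px)
    FV <- if (has_na) {
      pv <- matrix(0, nr, nc); pv[1:na_, 1:ma] <- valid + 0
      stats::fft(pv)
    } else FO
    for (s in as.character(scales)) {
      side <- nrow(kernels[[s]]$w)
      num <- crop(Re(stats::fft(FA * FK[[s]], inverse = TRUE)) / (nr * nc), side)
      den <- if (has_na) {
        crop(Re(stats::fft(FV * FK[[s]], inverse = TRUE)) / (nr * nc), side)
      } else den_ingrid[[s]]
      out <- num / den
      out[den / den_ingrid[[s]] < 0.5] <- NA_real_
      out[den <= 0] <- NA_real_
      r <- which(idx$layer == lname & idx$scale_km == as.numeric(s))
      layers[[r]] <- out
    }
  }
  names(layers) <- keys
  index <- tibble::tibble(key = keys, layer = idx$layer,
                          covariate = unname(cov_of[idx$layer]),
                          scale_km = idx$scale_km,
                          time = unname(stack$times[idx$layer]))
  structure(list(grid = grid, layers = layers, index = index),
            class = "smoothed_stack")
}

#' @export
print.smoothed_stack <- function(x, ...) {
  cat(sprintf("<smoothed_stack> %d layer(s): %d covariate(s) x scales {%s} km\n",
              length(x$layers), length(unique(x$index$covariate)),
              paste(sort(unique(x$index$scale_km)), collapse = ", ")))
  invisible(x)
}

#' Extract smoothed covariate values at design rows
#'
#' Samples the containing pixel (no interpolation: the 500 m pixel is the
#' analysis unit) of each smoothed layer at each row. When a covariate is
#' available at several time labels, the layer nearest in time to the
#' row's month is used, ties resolved toward the earlier label. Rows that
#' hit nodata in any required layer are dropped with a message.
#'
#' @param points Use/available tibble with `x`, `y` and (if any layer is
#'   timed) `month` (`"YYYY-MM"`).
#' @param smoothed A [build_smoothed_stack()] result.
#' @return The input rows (minus nodata drops) with one numeric column per
#'   `(covariate, scale)` key.
#' @export
extract_covariates <- function(points, smoothed) {
  cells <- cell_from_xy(smoothed$grid, points$x, points$y)
  if (anyNA(cells)) {
    stop("points outside grid at rows: ",
         paste(utils::head(which(is.na(cells)), 10), collapse = ", "), call. = FALSE)
  }
  idx <- smoothed$index
  out <- points
  combos <- unique(idx[, c("covariate", "scale_km")])
  for (r in seq_len(nrow(combos))) {
    cv <- combos$covariate[r]; sc <- combos$scale_km[r]
    cand <- idx[idx$covariate == cv & idx$scale_km == sc, ]
    if (nrow(cand) == 1 || all(is.na(cand$time))) {
      vals <- smoothed$layers[[cand$key[1]]][cells]
    } else {
      # nearest time label per row; ties -> earlier label
      rt <- month_to_time(points$month)
      cand <- cand[order(cand$time), ]
      vals <- rep(NA_real_, length(cells))
      pick <- vapply(rt, function(t) {
        d <- abs(cand$time - t)
        which(d == min(d))[1]
      }, integer(1))
      for (k in unique(pick)) {
        sel <- pick == k
        vals[sel] <- smoothed$layers[[cand$key[k]]][cells[sel]]
      }
    }
    out[[smoothed_key(cv, sc)]] <- vals
  }
  val_cols <- setdiff(names(out), names(points))
  drop <- rowSums(is.na(as.matrix(out[, val_cols, drop = FALSE]))) > 0
  if (any(drop)) {
    message(sum(drop), " row(s) dropped: nodata in at least one smoothed layer")
    out <- out[!drop, , drop = FALSE]
  }
  out
}
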