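# Shared fixtures: small synthetic worlds built in code at test time.

small_grid <- function(n = 40, res = 500) grid_spec(n_rows = n, n_cols = n, resolution = res)

# One-region population with equal F/M home ranges.
hr_table <- function(hr_km2 = 4) {
  data.frame(region = "synthetic", sex = c("F", "M"), hr_km2 = hr_km2)
}

# A small but complete synthetic world: landscape, population, truth,
# telemetry. Sized so a full design fits in well under a second.
make_world <- function(seed = 1, n = 120, n_cov = 2, n_ind = 6, n_locs = 80,
                       beta = c(cov01 = 1.5, cov02 = -1),
                       scale_km = c(cov01 = 2, cov02 = 1),
                       hr_km2 = 4, autocorr = 1500) {
  g <- grid_spec(n_rows = n, n_cols = n)
  st <- generate_covariate_stack(g, n_cov, autocorr_range = autocorr,
                                 seed = seed)
  pop <- simulate_population(n_ind, 0.5, hr_table(hr_km2), g, seed = seed + 1)
  tr <- truth_bundle(beta, scale_km, seed)
  te <- simulate_telemetry(st, pop, tr, n_locs, seed = seed + 2)
  list(grid = g, stack = st, population = pop, truth = tr, telemetry = te)
}

# Deterministic surface with all-distinct values for binning tests.
distinct_surface <- function(n = 40, n_bins = 10) {
  g <- grid_spec(n_rows = n, n_cols = n)
  w <- matrix(seq(0.001, 0.999, length.out = n * n), n, n)
  structure(c(list(grid = g, w = w),
              quantile_bins(w, n_bins = n_bins, as_list = TRUE)),
            class = "suitability_surface")
}

# Evaluation points hitting bin i exactly count[i] times (cell centres).
points_by_bin <- function(surface, counts) {
  cells <- unlist(lapply(seq_along(counts), function(b) {
    avail <- which(surface$bins == b)
    avail[seq_len(counts[b])]
  }))
  xy <- xy_from_cell(surface$grid, cells)
  tibble::tibble(x = xy[, 1], y = xy[, 2])
}

# Brute-force focal weighted mean with valid-mass renormalization; the
# independent oracle for the FFT smoothing engine.
naive_smooth <- function(layer, kernel, min_valid_mass = 0.5) {
  k <- kernel$w
  r <- (nrow(k) - 1L) %/% 2L
  n <- nrow(layer); m <- ncol(layer)
  out <- matrix(NA_real_, n, m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    num <- 0; den <- 0; den_ingrid <- 0
    for (di in -r:r) for (dj in -r:r) {
      ii <- i + di; jj <- j + dj
      if (ii < 1 || ii > n || jj < 1 || jj > m) next
      wgt <- k[di + r + 1L, dj + r + 1L]
      den_ingrid <- den_ingrid + wgt
      if (!is.na(layer[ii, jj])) {
        den <- den + wgt
        num <- num + wgt * layer[ii, jj]
      }
    }
    if (den > 0 && den / den_ingrid >= min_valid_mass) out[i, j] <- num / den
  }
  out
}
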