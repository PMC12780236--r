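# A deterministic surface + zone fixture for overlay arithmetic.
overlay_fixture <- function(n = 40) {
  g <- grid_spec(n_rows = n, n_cols = n)
  w <- matrix(seq(0, 1, length.out = n * n), n, n)
  surf <- structure(c(list(grid = g, w = w),
                      quantile_bins(w, 10, as_list = TRUE)),
                    class = "suitability_surface")
  list(grid = g, surf = surf)
}

test_that("range buffering matches the rounded-rectangle formula", {
  # 100x100 km square on a 300x300 km grid, buffered by 100 km
  g <- grid_spec(n_rows = 600, n_cols = 600)
  sq <- matrix(FALSE, 600, 600)
  sq[201:400, 201:400] <- TRUE
  buf <- buffer_current_range(sq, g, buffer_km = 100)
  area <- sum(buf) * cell_area_km2(g)
  expected <- 10000 + 4 * 100 * 100 + pi * 100^2
  expect_lt(abs(area - expected) / expected, 0.01)
  # buffer 0 is the identity
  expect_identical(buffer_current_range(sq, g, buffer_km = 0), sq)
  # exclusions are subtracted
  excl <- matrix(FALSE, 600, 600); excl[1:600, 1:50] <- TRUE
  buf2 <- buffer_current_range(sq, g, buffer_km = 100, exclude = list(excl))
  expect_true(!any(buf2 & excl))
  expect_identical(buf2 | (buf & excl), buf)
})

test_that("protected-area filtering merges adjacent same-country blocks then filters", {
  g <- grid_spec(n_rows = 60, n_cols = 60)
  rect_cells <- function(i0, i1, j0, j1) {
    as.integer(outer(i0:i1, (j0:j1 - 1L) * 60L, "+"))
  }
  # two touching 60 km^2 PAs in the same country -> merged 120 km^2 block
  paA <- zone("A", "PA", "A", rect_cells(1, 10, 1, 24), g,
              max_elevation_m = 500, country = "X")   # 10x24 cells = 60 km2
  paB <- zone("B", "PA", "B", rect_cells(11, 20, 1, 24), g,
              max_elevation_m = 700, country = "X")
  # same geometry, different countries -> NOT merged, each 60 km2 -> dropped
  paC <- zone("C", "PA", "C", rect_cells(1, 10, 31, 54), g,
              max_elevation_m = 500, country = "X")
  paD <- zone("D", "PA", "D", rect_cells(11, 20, 31, 54), g,
              max_elevation_m = 500, country = "Y")
  # big enough but above the elevation ceiling -> dropped
  paE <- zone("E", "PA", "E", rect_cells(31, 55, 1, 24), g,
              max_elevation_m = 3500, country = "X")  # 25x24 = 150 km2
  # big, low, in range -> kept alone
  paF <- zone("F", "PA", "F", rect_cells(31, 55, 31, 54), g,
              max_elevation_m = 900, country = "Y")
  zs <- zone_set(g, list(paA, paB, paC, paD, paE, paF))
  rng <- matrix(TRUE, 60, 60)
  kept <- filter_protected_areas(zs, rng)
  expect_equal(length(kept$zones), 2)
  areas <- sort(vapply(kept$zones, function(z) z$attrs$area_km2, numeric(1)))
  expect_equal(areas, c(120, 150))
  merged <- kept$zones[[which(vapply(kept$zones, function(z)
    z$attrs$area_km2, numeric(1)) == 120)]]
  expect_setequal(merged$attrs$members, c("A", "B"))
  expect_equal(merged$attrs$max_elevation_m, 700)

  # a 99 km^2 block fails the strict >100 km^2 rule
  pa99 <- zone("G", "PA", "G", rect_cells(1, 18, 1, 22), g,
               max_elevation_m = 100, country = "Z") # 18*22*0.25 = 99
  expect_equal(length(filter_protected_areas(zone_set(g, list(pa99)), rng)$zones), 0)
  # out-of-range block dropped
  norange <- matrix(FALSE, 60, 60)
  expect_equal(length(filter_protected_areas(zone_set(g, list(paF)), norange)$zones), 0)
})

test_that("summed shares conserve mass over a partition", {
  fx <- overlay_fixture(40)
  zs <- generate_zone_set(fx$grid, n_ecoregions = 5, n_pas = 0, seed = 9,
                          n_countries = 0)
  shares <- summed_share(fx$surf, zs)
  expect_equal(shares$share_pct[shares$zone_type == "current_range"], 100)
  eco <- shares[shares$zone_type == "ecoregion", ]
  expect_equal(sum(eco$share_pct), 100, tolerance = 1e-6)
  # uniform surface: share equals the cell-count fraction
  uni <- fx$surf; uni$w[] <- 0.5
  su <- summed_share(uni, zs)
  eco_zones <- Filter(function(z) z$zone_type == "ecoregion", zs$zones)
  for (z in eco_zones) {
    expect_equal(su$share_pct[su$zone_id == z$zone_id],
                 100 * length(z$cells) / n_cells(fx$grid), tolerance = 1e-9)
  }
})

test_that("top-quartile classification flags exactly 25% of distinct cells", {
  fx <- overlay_fixture(40)
  hs <- classify_high(fx$surf, "range_based")
  expect_equal(sum(hs$mask), 400) # 25% of 1600 distinct values
  expect_true(all(fx$surf$w[hs$mask] >= hs$thresholds$threshold))

  # two ecoregions with disjoint value ranges
  g <- grid_spec(n_rows = 20, n_cols = 40)
  w <- matrix(NA_real_, 20, 40)
  w[, 1:20] <- seq(0, 0.4, length.out = 400)       # low stratum
  w[, 21:40] <- seq(0.5, 0.9, length.out = 400)    # high stratum
  surf <- structure(c(list(grid = g, w = w), quantile_bins(w, 10, as_list = TRUE)),
                    class = "suitability_surface")
  lo <- zone("lo", "ecoregion", "lo", which(col(w) <= 20), g)
  hi <- zone("hi", "ecoregion", "hi", which(col(w) > 20), g)
  eco <- zone_set(g, list(lo, hi))
  ehs <- classify_high(surf, "ecoregion_based", ecoregions = eco)
  expect_equal(sum(ehs$mask[lo$cells]), 100) # 25% of each stratum
  expect_equal(sum(ehs$mask[hi$cells]), 100)
  rhs <- classify_high(surf, "range_based")
  expect_equal(sum(rhs$mask[lo$cells]), 0)   # range-based: 50% of high, 0% of low
  expect_equal(sum(rhs$mask[hi$cells]), 200)

  cst <- surf; cst$w[] <- 0.3
  expect_warning(chs <- classify_high(cst, "range_based"), "constant")
  expect_true(all(chs$mask))
  expect_error(classify_high(surf, "ecoregion_based"), "requires")
})

test_that("raising a cell's suitability never unflags it", {
  fx <- overlay_fixture(20)
  hs <- classify_high(fx$surf, "range_based")
  flagged <- which(hs$mask)[1:5]
  bumped <- fx$surf
  bumped$w[flagged] <- bumped$w[flagged] + 0.05
  hs2 <- classify_high(bumped, "range_based")
  expect_true(all(hs2$mask[flagged]))
})

test_that("zone reports categorize proportions with upper-boundary rule", {
  g <- grid_spec(n_rows = 20, n_cols = 20)
  w <- matrix(seq(0, 1, length.out = 400), 20, 20)
  surf <- structure(c(list(grid = g, w = w), quantile_bins(w, 10, as_list = TRUE)),
                    class = "suitability_surface")
  hs <- classify_high(surf, "range_based") # flags top 100 cells
  flagged <- which(hs$mask)
  unflagged <- which(!hs$mask)
  zfull <- zone("full", "JCU", "full", flagged[1:40], g)
  znone <- zone("none", "JCU", "none", unflagged[1:40], g)
  zhalf <- zone("half", "JCU", "half", c(flagged[41:60], unflagged[41:60]), g)
  zs <- zone_set(g, list(zfull, znone, zhalf,
                         zone("range", "current_range", "range", 1:400, g)))
  rep <- zone_report(hs, surf, zs)
  expect_equal(rep$category[rep$zone_id == "full"], "100-75%")
  expect_equal(rep$high_prop_pct[rep$zone_id == "full"], 100)
  expect_equal(rep$category[rep$zone_id == "none"], "0%")
  expect_equal(rep$category[rep$zone_id == "half"], "75-50%") # boundary up
  expect_equal(rep$high_area_km2[rep$zone_id == "half"], 20 * 0.25)
})

test_that("country report equals a per-cell oracle on a 3-country fixture", {
  fx <- overlay_fixture(30)
  g <- fx$grid
  # three vertical country strips
  strips <- list(1:10, 11:20, 21:30)
  ctr <- lapply(1:3, function(k) {
    zone(paste0("c", k), "country", paste0("c", k),
         which(matrix(col(fx$surf$w) %in% strips[[k]], 30, 30)), g)
  })
  countries <- zone_set(g, ctr)
  hs <- classify_high(fx$surf, "range_based")
  pa <- zone("p", "PA", "p", which(hs$mask)[seq(1, sum(hs$mask), by = 2)], g,
             max_elevation_m = 100, country = "c3")
  pas <- zone_set(g, list(pa))
  cr <- country_report(hs, fx$surf, countries, pas)
  # oracle: direct cell-by-cell tabulation
  for (k in 1:3) {
    cells <- ctr[[k]]$cells
    nhigh <- sum(hs$mask[cells])
    expect_equal(cr$high_area_km2[cr$country == paste0("c", k)], nhigh * 0.25)
    expect_equal(cr$high_pct[cr$country == paste0("c", k)],
                 100 * nhigh / length(cells))
    prot <- sum(hs$mask[cells] & cells %in% pa$cells)
    expect_equal(cr$protected_high_pct[cr$country == paste0("c", k)],
                 if (nhigh) 100 * prot / nhigh else 0)
  }
  # partition conservation: per-country high areas sum to the total
  expect_equal(sum(cr$high_area_km2), sum(hs$mask) * 0.25)
  # single country covering all, PAs covering all flagged cells
  all_c <- zone_set(g, list(zone("all", "country", "all", 1:900, g)))
  all_pa <- zone_set(g, list(zone("pp", "PA", "pp", which(hs$mask), g,
                                  max_elevation_m = 1, country = "all")))
  cr2 <- country_report(hs, fx$surf, all_c, all_pa)
  expect_equal(cr2$range_area_km2, 900 * 0.25)
  expect_equal(cr2$protected_high_pct, 100)
})

test_that("scenario masks agree in expectation for exchangeable ecoregions", {
  diffs <- vapply(1:20, function(r) {
    withr::with_seed(900 + r, {
      g <- grid_spec(n_rows = 40, n_cols = 40)
      w <- matrix(runif(1600), 40, 40)
      surf <- structure(c(list(grid = g, w = w),
                          quantile_bins(w, 10, as_list = TRUE)),
                        class = "suitability_surface")
      zs <- generate_zone_set(g, n_ecoregions = 4, n_pas = 0,
                              seed = 900 + r, n_countries = 0)
      a <- classify_high(surf, "range_based")
      b <- classify_high(surf, "ecoregion_based", ecoregions = zs)
      abs(mean(a$mask) - mean(b$mask))
    })
  }, numeric(1))
  expect_lt(mean(diffs), 0.02)
})
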