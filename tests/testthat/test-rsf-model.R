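# Direct GLMM simulation (no landscape): binomial responses from a logistic
# model with known fixed effects and random-intercept variance.
simulate_glmm_design <- function(n_ind, n_per, beta, sigma2_id, seed) {
  withr::with_seed(seed, {
    id <- rep(sprintf("i%02d", seq_len(n_ind)), each = n_per)
    u <- rep(rnorm(n_ind, 0, sqrt(sigma2_id)), each = n_per)
    X <- matrix(rnorm(n_ind * n_per * length(beta)), ncol = length(beta))
    eta <- drop(X %*% beta) + u - 2 # rare-ish outcome like a 10:1 design
    d <- tibble::tibble(case = rbinom(length(id), 1, plogis(eta)),
                        individual_id = id)
    for (k in seq_along(beta)) d[[paste0("x", k)]] <- X[, k]
    d
  })
}

test_that("aicc matches the closed form and its limits", {
  expect_equal(aicc(-100, 3, 100), 206.25)
  expect_equal(aicc(-50, 0, 10), 100)
  expect_lt(abs(aicc(-100, 3, 1e7) - (200 + 6)), 1e-3) # -> AIC
  expect_error(aicc(-100, 3, 4), "exceed")
  # AICc >= AIC always
  for (k in 1:4) expect_gte(aicc(-10, k, 30), -2 * -10 + 2 * k)
})

test_that("glmm recovery: fixed effects unbiased at the design size", {
  errs <- vapply(1:50, function(r) {
    d <- simulate_glmm_design(30, 200, c(1, -0.5), 0.5, seed = 100 + r)
    fit <- fit_rsf_glmm(d, c("x1", "x2"))
    fit$coefficients$beta[2:3] - c(1, -0.5)
  }, numeric(2))
  expect_lt(abs(mean(errs[1, ])), 0.1)
  expect_lt(abs(mean(errs[2, ])), 0.1)
})

test_that("with no between-individual variance the GLMM matches plain logistic", {
  d <- simulate_glmm_design(30, 200, c(1, -0.5), 0, seed = 42)
  fit <- fit_rsf_glmm(d, c("x1", "x2"))
  glm_fit <- glm(case ~ x1 + x2, data = d, family = binomial())
  expect_lt(max(abs(fit$coefficients$beta - coef(glm_fit))), 0.05)
})

test_that("glmm guards: few individuals, degenerate columns, k bookkeeping", {
  d <- simulate_glmm_design(10, 50, c(1), 0.3, seed = 7)
  d$flat <- 0
  expect_warning(fit <- fit_rsf_glmm(d, c("x1", "flat")), "degenerate")
  expect_equal(fit$coefficients$term, c("(Intercept)", "x1"))
  expect_equal(fit$k, 3) # intercept + slope + random-intercept variance
  expect_equal(fit$aicc, aicc(fit$loglik, fit$k, fit$n))
  expect_error(suppressWarnings(fit_rsf_glmm(d, "flat")), "no non-degenerate")
  d1 <- d[d$individual_id == "i01", ]
  expect_error(fit_rsf_glmm(d1, "x1"), "2 individuals")
})

test_that("spearman matrix is rank-invariant and matches a hand oracle", {
  d <- tibble::tibble(case = c(1, 0, 1, 0, 1),
                      a = c(3, 1, 4, 1.5, 5),
                      b = c(10, 2, 30, 4, 50))
  sp <- spearman_matrix(d, c("a", "b"))
  expect_equal(unname(diag(sp$rho)), c(1, 1))
  expect_equal(sp$rho["a", "b"], sp$rho["b", "a"])
  # hand-computed rank correlation
  hand <- cor(rank(d$a), rank(d$b))
  expect_equal(unname(sp$rho["a", "b"]), hand)
  # monotone transform invariance
  d$c <- exp(d$a)
  sp2 <- spearman_matrix(d, c("a", "c"))
  expect_equal(unname(sp2$rho["a", "c"]), 1)
  d$k <- 1
  expect_warning(sp3 <- spearman_matrix(d, c("a", "k")), "constant")
  expect_equal(unname(sp3$rho["a", "k"]), 0)
})

test_that("mrmr selection penalizes redundancy and matches exhaustive greedy", {
  set.seed(30)
  n <- 200
  sig <- rnorm(n)
  d <- tibble::tibble(case = as.integer(plogis(2 * sig) > runif(n)),
                      dup1 = sig, dup2 = sig,
                      weak = sig * 0.3 + rnorm(n),
                      noise1 = rnorm(n), noise2 = rnorm(n))
  sp <- spearman_matrix(d, c("dup1", "dup2", "weak", "noise1", "noise2"))
  mr <- mrmr_select(sp, 3)
  # the most relevant column leads, and its identical twin is penalized
  # out of the immediately following pick
  expect_true(mr$selected[1] %in% c("dup1", "dup2"))
  expect_false(mr$selected[2] %in% c("dup1", "dup2"))
  expect_error(mrmr_select(sp, 6), "exceeds")
})

test_that("mrmr equals an independent step-by-step oracle on 6 candidates", {
  set.seed(31)
  n <- 150
  d <- tibble::tibble(case = rbinom(n, 1, 0.3))
  for (k in 1:6) d[[paste0("c", k)]] <- rnorm(n) + d$case * k / 6
  cols <- paste0("c", 1:6)
  sp <- spearman_matrix(d, cols)
  mr <- mrmr_select(sp, 3)
  # oracle: recompute the greedy criterion from raw Spearman calls
  rel <- vapply(cols, function(cv) abs(cor(d[[cv]], d$case, method = "spearman")),
                numeric(1))
  sel <- character(0)
  for (step in 1:3) {
    avail <- sort(setdiff(cols, sel))
    score <- vapply(avail, function(cv) {
      red <- if (length(sel)) mean(vapply(sel, function(s2)
        abs(cor(d[[cv]], d[[s2]], method = "spearman")), numeric(1))) else 0
      rel[cv] - red
    }, numeric(1))
    sel <- c(sel, avail[order(-score, avail)][1])
  }
  expect_identical(mr$selected, sel)
})

test_that("mrmr is deterministic and invariant to candidate order", {
  set.seed(32)
  d <- tibble::tibble(case = rbinom(100, 1, 0.4))
  for (k in 1:5) d[[paste0("v", k)]] <- rnorm(100)
  cols <- paste0("v", 1:5)
  s1 <- mrmr_select(spearman_matrix(d, cols), 4)$selected
  s2 <- mrmr_select(spearman_matrix(d, rev(cols)), 4)$selected
  expect_identical(s1, s2)
})

test_that("univariate scale optimization recovers a known scale of effect", {
  hits <- integer(0)
  for (r in 1:10) {
    w <- make_world(seed = 400 + r, n = 160, n_cov = 1, n_ind = 12,
                    n_locs = 100, beta = c(cov01 = 1.5),
                    scale_km = c(cov01 = 4))
    ua <- build_use_available(w$telemetry, w$population, w$grid, 10,
                              seed = 500 + r)
    sm <- build_smoothed_stack(w$stack)
    des <- extract_covariates(ua, sm)
    ss <- optimize_scales(des, "cov01")
    expect_true(all(is.finite(ss$aicc_table$aicc)))
    hits <- c(hits, ss$chosen[["cov01"]])
  }
  expect_gte(mean(hits == 4), 0.6)                       # exact recovery
  expect_gte(mean(abs(log2(hits / 4)) <= 1), 0.9)        # within one step
})

test_that("single-scale sets and tie-breaking behave as documented", {
  w <- make_world(seed = 77, n = 80, n_cov = 1, n_ind = 4, n_locs = 40,
                  beta = c(cov01 = 1), scale_km = c(cov01 = 1))
  ua <- build_use_available(w$telemetry, w$population, w$grid, 5, seed = 78)
  sm <- build_smoothed_stack(w$stack, 2)
  des <- extract_covariates(ua, sm)
  ss <- optimize_scales(des, "cov01", scales = 2)
  expect_equal(unname(ss$chosen["cov01"]), 2)
})

test_that("final model standardizes on training rows and reports the schema", {
  w <- make_world(seed = 90, n = 120, n_cov = 2, n_ind = 8, n_locs = 80)
  ua <- split_train_validate(
    build_use_available(w$telemetry, w$population, w$grid, 10, seed = 91),
    0.8, seed = 92)
  sm <- build_smoothed_stack(w$stack, c(1, 2))
  des <- extract_covariates(ua, sm)
  ss <- optimize_scales(des[des$split == "train", ], c("cov01", "cov02"),
                        scales = c(1, 2))
  cols <- smoothed_key(names(ss$chosen), unname(ss$chosen))
  fit <- fit_final_model(des, cols, ss)
  # standardization recorded from training rows
  tr <- des[des$split == "train", ]
  expect_equal(fit$standardization$mean,
               vapply(cols, function(cv) mean(tr[[cv]]), numeric(1)),
               ignore_attr = TRUE)
  ct <- coefficient_table(fit)
  expect_named(ct, c("covariate", "scale_km", "beta", "se", "z", "p"))
  expect_equal(nrow(ct), 2)
  expect_true(all(ct$se > 0))
  # deterministic refit
  fit2 <- fit_final_model(des, cols, ss)
  expect_equal(fit$coefficients, fit2$coefficients)
  # multivariable likelihood at least the intercept-only likelihood
  null_ll <- as.numeric(logLik(suppressMessages(
    lme4::glmer(case ~ 1 + (1 | individual_id),
                data = des[des$split == "train", ], family = binomial()))))
  expect_gte(fit$loglik, null_ll)
})
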