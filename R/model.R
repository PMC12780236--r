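#' Small-sample corrected Akaike Information Criterion
#'
#' @param loglik Maximized log-likelihood.
#' @param k Number of estimated parameters.
#' @param n Number of observations; must exceed `k + 1`.
#' @return `-2*loglik + 2k + 2k(k+1)/(n-k-1)`.
#' @export
aicc <- function(loglik, k, n) {
  if (n <= k + 1) stop("AICc undefined: n must exceed k + 1", call. = FALSE)
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Fit a mixed-effect used/available logistic model
#'
#' The workhorse RSF fit: a binomial logit GLMM of `case` (1 used,
#' 0 available) on the given covariate columns with a random intercept per
#' individual, which absorbs between-animal differences in overall use
#' intensity. Fitted with `lme4::glmer`; `nAGQ = 1` is the Laplace
#' approximation (default), `nAGQ = 0` a faster marginal approximation
#' used for the many univariate scale-screening fits.
#'
#' Zero-variance covariate columns cannot be estimated and are dropped
#' with a warning (an error if nothing remains). The parameter count for
#' AICc is the fixed effects (intercept included) plus one for the
#' random-intercept variance.
#'
#' @param design Design tibble with `case`, `individual_id` and covariate
#'   columns.
#' @param covariates Character vector of covariate column names.
#' @param nAGQ Integrating quadrature points passed to `lme4::glmer`.
#' @return A `fitted_rsf`: `coefficients` tibble (`term`, `beta`, `se`,
#'   `z`, `p`), `sigma2_id`, `loglik`, `k`, `n`, `aicc`, `converged`, plus
#'   empty `standardization`/`scale_km` slots filled by [fit_final_model()].
#' @export
fit_rsf_glmm <- function(design, covariates, nAGQ = 1L) {
  stopifnot(all(covariates %in% names(design)),
            all(c("case", "individual_id") %in% names(design)))
  if (length(unique(design$individual_id)) < 2) {
    stop("mixed fit requires at least 2 individuals", call. = FALSE)
  }
  sds <- vapply(covariates, function(cv) stats::sd(design[[cv]]), numeric(1))
  degen <- covariates[sds == 0 | !is.finite(sds)]
  if (length(degen)) {
    warning("dropping degenerate (constant) covariate column(s): ",
            paste(degen, collapse = ", "))
    covariates <- setdiff(covariates, degen)
  }
  if (!length(covariates)) stop("no non-degenerate covariates to fit", call. = FALSE)
  dat <- as.data.frame(design[, c("case", "individual_id", covariates)])
  names(dat) <- c("case", "individual_id", sprintf("V%d", seq_along(covariates)))
  fml <- stats::as.formula(paste(
    "case ~", paste(sprintf("V%d", seq_along(covariates)), collapse = " + "),
    "+ (1 | individual_id)"))
  fit <- suppressMessages(suppressWarnings(
    lme4::glmer(fml, data = dat, family = stats::binomial(), nAGQ = nAGQ)
  ))
  converged <- length(fit@optinfo$conv$lme4) == 0 && fit@optinfo$conv$opt == 0
  sm <- summary(fit)$coefficients
  terms <- c("(Intercept)", covariates)
  coefs <- tibble::tibble(term = terms,
                          beta = unname(sm[, "Estimate"]),
                          se = unname(sm[, "Std. Error"]),
                          z = unname(sm[, "z value"]),
                          p = unname(sm[, "Pr(>|z|)"]))
  ll <- as.numeric(stats::logLik(fit))
  n <- nrow(dat)
  k <- nrow(coefs) + 1L # fixed effects + random-intercept variance
  structure(list(coefficients = coefs,
                 sigma2_id = unname(lme4::VarCorr(fit)$individual_id[1, 1]),
                 loglik = ll, k = k, n = n, aicc = aicc(ll, k, n),
                 converged = converged,
                 standardization = NULL, scale_km = NULL),
            class = "fitted_rsf")
}

#' @export
print.fitted_rsf <- function(x, ...) {
  cat(sprintf("<fitted_rsf> %d fixed effect(s), n = %d, logLik = %.2f, AICc = %.2f%s\n",
              nrow(x$coefficients), x$n, x$loglik, x$aicc,
              if (x$converged) "" else " [NOT CONVERGED]"))
  print(x$coefficients)
  invisible(x)
}

#' Optimize the scale of effect of each covariate
#'
#' For each covariate independently, fits the univariate mixed model
#' (intercept + covariate + random intercept) at every candidate scale and
#' retains the scale with the lowest AICc; ties resolve to the smaller
#' scale. Covariates whose fits all fail are excluded with a warning.
#'
#' @param design Design tibble containing a `<covariate>__<scale>km` column
#'   for every covariate at every scale.
#' @param covariates Covariate base names.
#' @param scales Candidate scales in km.
#' @param nAGQ Quadrature setting for the screening fits (default 0: fast
#'   marginal approximation; the final model uses Laplace). Screening fits
#'   skip standard-error derivatives since only the likelihood is compared.
#' @return A `scale_selection`: tibble `aicc_table` (`covariate`,
#'   `scale_km`, `aicc`) and named vector `chosen` of optimal scales.
#' @export
optimize_scales <- function(design, covariates, scales = default_scales(),
                            nAGQ = 0L) {
  rows <- list()
  chosen <- stats::setNames(rep(NA_real_, length(covariates)), covariates)
  # likelihood-only univariate mixed fit: intercept + covariate + random
  # intercept, no vcov derivatives (not needed for AICc screening)
  screen_aicc <- function(col) {
    dat <- data.frame(case = design$case, individual_id = design$individual_id,
                      V1 = design[[col]])
    if (stats::sd(dat$V1) == 0 || !is.finite(stats::sd(dat$V1))) return(NA_real_)
    fit <- suppressMessages(suppressWarnings(
      lme4::glmer(case ~ V1 + (1 | individual_id), data = dat,
                  family = stats::binomial(), nAGQ = nAGQ,
                  control = lme4::glmerControl(calc.derivs = FALSE))
    ))
    aicc(as.numeric(stats::logLik(fit)), 3L, nrow(dat))
  }
  for (cv in covariates) {
    aiccs <- rep(NA_real_, length(scales))
    for (s in seq_along(scales)) {
      col <- smoothed_key(cv, scales[s])
      if (!col %in% names(design)) {
        stop("design lacks column ", col, " needed for scale optimization",
             call. = FALSE)
      }
      a <- tryCatch(screen_aicc(col), error = function(e) NA_real_)
      if (is.finite(a)) aiccs[s] <- a
    }
    rows[[cv]] <- tibble::tibble(covariate = cv, scale_km = scales, aicc = aiccs)
    if (all(is.na(aiccs))) {
      warning("all scale fits failed for covariate '", cv, "'; excluded")
    } else {
      # which.min returns the first (smallest-scale) minimiser; scales ascend
      chosen[cv] <- scales[which.min(aiccs)]
    }
  }
  structure(list(aicc_table = do.call(rbind, rows),
                 chosen = chosen[!is.na(chosen)]),
            class = "scale_selection")
}

#' @export
print.scale_selection <- function(x, ...) {
  cat("<scale_selection>\n")
  print(tibble::tibble(covariate = names(x$chosen), scale_km = unname(x$chosen)))
  invisible(x)
}

#' Spearman correlation structure of a design
#'
#' Rank correlations among candidate columns and between each column and
#' the binary response, the inputs to minimum-redundancy maximum-relevance
#' selection. Constant columns get correlation 0 with a warning.
#'
#' @param design Design tibble with `case` and the candidate columns.
#' @param columns Candidate column names.
#' @return A `spearman_matrix`: symmetric `rho` among columns and
#'   `rho_response`, the signed rank correlation of each column with the
#'   response.
#' @export
spearman_matrix <- function(design, columns) {
  stopifnot(nrow(design) >= 3, all(columns %in% names(design)))
  m <- as.matrix(design[, columns, drop = FALSE])
  const <- apply(m, 2, function(v) stats::sd(v) == 0 || !is.finite(stats::sd(v)))
  if (any(const)) warning("constant column(s), correlation recorded as 0: ",
                          paste(columns[const], collapse = ", "))
  full <- suppressWarnings(stats::cor(cbind(m, .case = design$case),
                                      method = "spearman"))
  full[!is.finite(full)] <- 0
  rho <- full[columns, columns, drop = FALSE]
  diag(rho) <- 1
  structure(list(rho = rho, rho_response = full[columns, ".case"]),
            class = "spearman_matrix")
}

#' Greedy minimum-redundancy maximum-relevance selection
#'
#' Step 1 picks the column most rank-correlated (in absolute value) with
#' the response; each later step maximizes
#' `|rho(x, case)| - mean(|rho(x, selected)|)`. Deterministic: ties break
#' alphabetically by column name, and the result is invariant to the input
#' order of candidates.
#'
#' @param sp A [spearman_matrix()].
#' @param n_keep Number of columns to keep (default 15).
#' @return An `mrmr_result`: `selected` (ordered names) and a `trace`
#'   tibble (`step`, `column`, `relevance`, `redundancy`, `score`).
#' @export
mrmr_select <- function(sp, n_keep = 15L) {
  cand <- sort(rownames(sp$rho))
  if (n_keep > length(cand)) {
    stop("n_keep exceeds the number of candidates", call. = FALSE)
  }
  relevance <- abs(sp$rho_response)[cand]
  selected <- character(0)
  trace <- list()
  for (step in seq_len(n_keep)) {
    avail <- setdiff(cand, selected)
    red <- if (length(selected)) {
      rowMeans(abs(sp$rho[avail, selected, drop = FALSE]))
    } else {
      stats::setNames(rep(0, length(avail)), avail)
    }
    score <- relevance[avail] - red
    best <- avail[order(-score, avail)][1] # ties -> alphabetical
    trace[[step]] <- tibble::tibble(step = step, column = best,
                                    relevance = unname(relevance[best]),
                                    redundancy = unname(red[best]),
                                    score = unname(score[best]))
    selected <- c(selected, best)
  }
  structure(list(selected = selected, trace = do.call(rbind, trace)),
            class = "mrmr_result")
}

#' Fit the final standardized multivariable RSF
#'
#' Standardizes the selected covariate columns to training mean 0 / sd 1,
#' fits the multivariable mixed model on the training rows (Laplace), and
#' records the standardization constants and chosen scales needed to
#' project the model onto rasters. The coefficient table mirrors the
#' conventional report layout: covariate, scale (km), beta, SE, z, p.
#'
#' @param design Design tibble (with `split` column if only training rows
#'   should be used; rows with `split == "validate"` are excluded from the
#'   fit but standardization constants still come from training rows only).
#' @param selection An [mrmr_select()] result (or character vector of
#'   design column names).
#' @param scales A [optimize_scales()] result (used to annotate the
#'   coefficient table with each covariate's scale).
#' @param nAGQ Quadrature setting (default 1, Laplace).
#' @return A `fitted_rsf` with `standardization` and `scale_km` filled.
#' @export
fit_final_model <- function(design, selection, scales = NULL, nAGQ = 1L) {
  cols <- if (inherits(selection, "mrmr_result")) selection$selected else selection
  stopifnot(all(cols %in% names(design)))
  train <- if ("split" %in% names(design)) design[design$split == "train", ] else design
  std <- tibble::tibble(
    column = cols,
    mean = vapply(cols, function(cv) mean(train[[cv]]), numeric(1)),
    sd = vapply(cols, function(cv) stats::sd(train[[cv]]), numeric(1))
  )
  if (any(std$sd == 0)) {
    stop("zero-variance column(s) in training rows: ",
         paste(std$column[std$sd == 0], collapse = ", "), call. = FALSE)
  }
  zdes <- train
  for (r in seq_len(nrow(std))) {
    zdes[[std$column[r]]] <- (train[[std$column[r]]] - std$mean[r]) / std$sd[r]
  }
  fit <- fit_rsf_glmm(zdes, cols, nAGQ = nAGQ)
  fit$standardization <- std
  if (!is.null(scales)) {
    ch <- if (inherits(scales, "scale_selection")) scales$chosen else scales
    cov_of_col <- sub("__[0-9.]+km$", "", cols)
    fit$scale_km <- stats::setNames(unname(ch[cov_of_col]), cols)
  }
  fit
}

#' Coefficient report of a final model
#'
#' @param fit A `fitted_rsf` from [fit_final_model()].
#' @return Tibble with `covariate`, `scale_km`, `beta`, `se`, `z`, `p`
#'   (covariate rows only, intercept excluded).
#' @export
coefficient_table <- function(fit) {
  co <- fit$coefficients[fit$coefficients$term != "(Intercept)", ]
  tibble::tibble(
    covariate = sub("__[0-9.]+km$", "", co$term),
    scale_km = if (!is.null(fit$scale_km)) unname(fit$scale_km[co$term]) else NA_real_,
    beta = co$beta, se = co$se, z = co$z, p = co$p
  )
}
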