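#' The 13-model family
#'
#' One baseline-only model (B), six damage-only models (one per measure) and
#' six combination models (baseline plus one measure). The six damage
#' measures never co-occur in a model because of their multicollinearity;
#' age, sex and hemispheric motor dominance enter every model as confounding
#' covariates.
#'
#' @return data frame with columns `label`, `baseline` (logical), `measure`
#'   (measure column name or `NA`); 13 rows.
#' @export
enumerate_models <- function() {
  codes <- damage_measure_codes()
  rbind(
    data.frame(label = "B", baseline = TRUE, measure = NA_character_,
               stringsAsFactors = FALSE),
    data.frame(label = names(codes), baseline = FALSE,
               measure = unname(codes), stringsAsFactors = FALSE),
    data.frame(label = paste("B +", names(codes)), baseline = TRUE,
               measure = unname(codes), stringsAsFactors = FALSE))
}

#' Ordinary least squares fit with CV and information statistics
#'
#' Fits `response ~ 1 + x` by least squares (no regularisation) and returns
#' the fit statistics used for model comparison: residual sum of squares,
#' R-squared, AICc, in-sample MSE (`rss / n`) and leave-one-out
#' cross-validated MSE (computed by the exact hat-matrix identity, equal to
#' refitting with each observation left out).
#'
#' @param x numeric matrix or data frame of predictors and covariates (no
#'   intercept column; one is added).
#' @param y numeric response vector.
#' @param label optional model label carried into the result.
#' @return object of class `model_fit`: list with `label`, `coefficients`,
#'   `se` (coefficient standard errors), `n`, `k` (estimated parameters,
#'   counting the intercept and the error variance), `rss`, `r_squared`,
#'   `aicc`, `in_sample_mse`, `loocv_mse`, plus `x`, `y`, `terms` for
#'   refitting.
#' @export
fit_ols <- function(x, y, label = NULL) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  y <- as.numeric(y)
  n <- length(y)
  if (nrow(x) != n) stop("nrow(x) must equal length(y)", call. = FALSE)
  X <- cbind(`(Intercept)` = 1, x)
  p <- ncol(X)
  if (n <= p)
    stop("insufficient sample: n = ", n, " <= ", p, " parameters",
         call. = FALSE)
  qx <- qr(X)
  if (qx$rank < p)
    stop("singular design: rank ", qx$rank, " < ", p, " columns",
         call. = FALSE)
  beta <- qr.coef(qx, y)
  resid <- as.numeric(y - X %*% beta)
  rss <- sum(resid^2)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - rss / tss else 0
  h <- rowSums(qr.Q(qx)[, seq_len(p), drop = FALSE]^2)
  k <- p + 1L  # + error variance
  sigma2 <- rss / (n - p)
  se <- sqrt(diag(chol2inv(qr.R(qx))) * sigma2)
  names(se) <- colnames(X)
  fit <- structure(list(label = label, coefficients = beta, se = se,
                        n = n, k = k,
                        rss = rss, r_squared = r2,
                        in_sample_mse = rss / n,
                        loocv_mse = loocv_from_hat(resid, h),
                        x = x, y = y, terms = colnames(X)),
                   class = "model_fit")
  fit$aicc <- aicc(fit)
  fit
}

loocv_from_hat <- function(resid, h) {
  bad <- which(1 - h < 1e-10)
  if (length(bad))
    stop("LOOCV fold ", bad[1], " is singular (leverage 1)", call. = FALSE)
  mean((resid / (1 - h))^2)
}

#' Leave-one-out cross-validated MSE
#'
#' `mean_i (y_i - yhat_i^(-i))^2`, via the hat-matrix identity
#' `e_i / (1 - h_ii)`; identical to refitting per fold.
#'
#' @inheritParams fit_ols
#' @return LOOCV mean squared error (score-squared units).
#' @export
loocv_mse <- function(x, y) fit_ols(x, y)$loocv_mse

#' Corrected Akaike information criterion
#'
#' Gaussian-likelihood convention with all constants retained:
#' `n log(rss / n) + n log(2 pi) + n + 2 k + 2 k (k + 1) / (n - k - 1)`,
#' where `k` counts every estimated parameter including the intercept and
#' the error variance. Any shared-constant convention preserves ranking
#' across models fitted to the same data.
#'
#' @param fit a [model_fit], or a list with elements `n`, `k`, `rss`.
#' @return AICc value.
#' @export
aicc <- function(fit) {
  n <- fit$n; k <- fit$k; rss <- fit$rss
  if (n - k - 1 <= 0)
    stop("AICc undefined: n - k - 1 = ", n - k - 1, call. = FALSE)
  n * log(rss / n) + n * log(2 * pi) + n + 2 * k +
    2 * k * (k + 1) / (n - k - 1)
}

#' Likelihood-ratio test between nested OLS models
#'
#' `chi2 = n log(rss_reduced / rss_extended)` with degrees of freedom equal
#' to the parameter-count difference; upper-tail chi-squared p-value. The
#' reduced model's terms must be a subset of the extended model's.
#'
#' @param reduced,extended [model_fit] objects on the same response.
#' @return list with `chi2`, `df`, `p_value` (class `lr_test`); `p_fdr` is
#'   `NA` until a family is adjusted with [fdr_adjust].
#' @export
likelihood_ratio_test <- function(reduced, extended) {
  if (!all(reduced$terms %in% extended$terms))
    stop("models are not nested: reduced terms must be a subset",
         call. = FALSE)
  if (reduced$n != extended$n ||
      !isTRUE(all.equal(reduced$y, extended$y)))
    stop("models were fitted to different data", call. = FALSE)
  df <- extended$k - reduced$k
  chi2 <- max(0, reduced$n * log(reduced$rss / extended$rss))
  # identical specifications (df = 0) carry no evidence: p = 1
  p <- if (df < 1L) 1 else stats::pchisq(chi2, df, lower.tail = FALSE)
  structure(list(chi2 = chi2, df = df, p_value = p, p_fdr = NA_real_),
            class = "lr_test")
}

#' Fit the 13-model family to one stratum
#'
#' Builds the design of each model from the merged cohort/measures table
#' (response `fma_3m`; baseline `fma_2w`; covariates `age`, `sex`,
#' `dominance`), fits by OLS, and runs the likelihood-ratio test of each
#' combination model against the baseline-only model, with
#' Benjamini-Hochberg adjustment across the stratum's comparisons. Strata
#' smaller than `k + 3` for a model yield a skipped row for that model
#' rather than an error.
#'
#' @param data data frame with `fma_3m`, `fma_2w`, `age`, `sex`,
#'   `dominance` and the six measure columns (see [damage_measure_codes]).
#' @param models model table from [enumerate_models].
#' @return list with `results` (one row per model: label, n, k, rss,
#'   r_squared, aicc, in_sample_mse, loocv_mse, lr_chi2, lr_df, lr_p,
#'   lr_p_fdr, skipped) and `fits` (named list of [model_fit]).
#' @export
fit_stratum_models <- function(data, models = enumerate_models()) {
  covars <- c("age", "sex", "dominance")
  y <- data$fma_3m
  n <- nrow(data)
  fits <- list()
  rows <- vector("list", nrow(models))
  for (i in seq_len(nrow(models))) {
    m <- models[i, ]
    pred_cols <- c(if (m$baseline) "fma_2w",
                   if (!is.na(m$measure)) m$measure, covars)
    k <- length(pred_cols) + 2L  # + intercept + error variance
    if (n < k + 3L) {
      rows[[i]] <- data.frame(label = m$label, n = n, k = k, rss = NA_real_,
                              r_squared = NA_real_, aicc = NA_real_,
                              in_sample_mse = NA_real_,
                              loocv_mse = NA_real_, lr_chi2 = NA_real_,
                              lr_df = NA_integer_, lr_p = NA_real_,
                              lr_p_fdr = NA_real_, skipped = TRUE,
                              stringsAsFactors = FALSE)
      next
    }
    fit <- tryCatch(
      fit_ols(as.matrix(data[, pred_cols, drop = FALSE]), y,
              label = m$label),
      error = function(e) e)
    if (inherits(fit, "error")) {
      # degenerate stratum for this model (singular design or leverage-1
      # CV fold): record it as skipped rather than aborting the stratum
      rows[[i]] <- data.frame(label = m$label, n = n, k = k, rss = NA_real_,
                              r_squared = NA_real_, aicc = NA_real_,
                              in_sample_mse = NA_real_,
                              loocv_mse = NA_real_, lr_chi2 = NA_real_,
                              lr_df = NA_integer_, lr_p = NA_real_,
                              lr_p_fdr = NA_real_, skipped = TRUE,
                              stringsAsFactors = FALSE)
      next
    }
    fits[[m$label]] <- fit
    rows[[i]] <- data.frame(label = m$label, n = fit$n, k = fit$k,
                            rss = fit$rss, r_squared = fit$r_squared,
                            aicc = fit$aicc,
                            in_sample_mse = fit$in_sample_mse,
                            loocv_mse = fit$loocv_mse, lr_chi2 = NA_real_,
                            lr_df = NA_integer_, lr_p = NA_real_,
                            lr_p_fdr = NA_real_, skipped = FALSE,
                            stringsAsFactors = FALSE)
  }
  results <- do.call(rbind, rows)

  # LR tests: each combination model vs the baseline-only model, one
  # FDR family per stratum
  if ("B" %in% names(fits)) {
    combo <- grep("^B \\+ ", results$label, value = TRUE)
    combo <- combo[combo %in% names(fits)]
    ps <- numeric(0)
    for (lab in combo) {
      lr <- likelihood_ratio_test(fits[["B"]], fits[[lab]])
      j <- match(lab, results$label)
      results$lr_chi2[j] <- lr$chi2
      results$lr_df[j] <- lr$df
      results$lr_p[j] <- lr$p_value
      ps <- c(ps, lr$p_value)
    }
    if (length(ps))
      results$lr_p_fdr[match(combo, results$label)] <- fdr_adjust(ps)
  }
  list(results = results, fits = fits)
}
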