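#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p-values (via [stats::p.adjust]); monotone and never
#' smaller than the raw values.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values, same length and order.
#' @export
fdr_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p_values, method = "BH")
}

#' Best model of a stratum, per error type
#'
#' Picks the model with the smallest LOOCV MSE (generalisation-best) and,
#' independently, the smallest in-sample MSE. Ties are broken by fewer
#' estimated parameters, then by label order as listed.
#'
#' @param results per-model results table of one stratum (from
#'   [fit_stratum_models]); skipped models are ignored.
#' @return list with `generalization` and `in_sample`, each a one-row slice
#'   of `results`.
#' @export
select_best <- function(results) {
  ok <- results[!results$skipped, , drop = FALSE]
  if (nrow(ok) == 0L)
    stop("empty stratum: no model could be fitted", call. = FALSE)
  pick <- function(crit) {
    o <- order(ok[[crit]], ok$k, seq_len(nrow(ok)))
    ok[o[1], , drop = FALSE]
  }
  list(generalization = pick("loocv_mse"), in_sample = pick("in_sample_mse"))
}

#' Size-weighted overall MSE across strata
#'
#' `sum(n_g * mse_g) / sum(n_g)`: each stratum's best-model MSE weighted by
#' the number of individuals in the stratum.
#'
#' @param stratum_mses numeric vector of per-stratum MSEs.
#' @param stratum_sizes corresponding subgroup sizes (all > 0).
#' @return overall MSE (score-squared units).
#' @export
overall_weighted_mse <- function(stratum_mses, stratum_sizes) {
  if (length(stratum_mses) != length(stratum_sizes) ||
      length(stratum_mses) == 0L)
    stop("MSE and size vectors must be nonempty and of equal length",
         call. = FALSE)
  if (any(stratum_sizes <= 0))
    stop("stratum sizes must be positive", call. = FALSE)
  sum(stratum_sizes * stratum_mses) / sum(stratum_sizes)
}

#' Overall MSE as a percentage of the whole-group MSE
#'
#' With the whole-group best model set at 100%.
#'
#' @param overall_mse stratified overall MSE.
#' @param whole_group_mse whole-group reference MSE (> 0).
#' @param digits rounding of the reported percentage (1 decimal place, as
#'   conventionally printed); use `NA` for no rounding.
#' @return percentage.
#' @export
relative_percentage <- function(overall_mse, whole_group_mse, digits = 1) {
  if (!is.finite(whole_group_mse) || whole_group_mse <= 0)
    stop("whole-group MSE must be positive", call. = FALSE)
  pct <- 100 * overall_mse / whole_group_mse
  if (is.na(digits)) pct else round(pct, digits)
}

#' Compare the goodness of fit of combination models
#'
#' Pairwise differences in R-squared between model fits on the same
#' stratum, with significance assessed by a nonparametric bootstrap of the
#' difference (subjects resampled with replacement, both models refitted per
#' resample; percentile interval at `1 - alpha`).
#'
#' @param fits list of at least two [model_fit] objects fitted to the same
#'   subjects.
#' @param n_boot bootstrap replicates (default 1000).
#' @param alpha significance level for the percentile interval.
#' @param seed integer seed for the resampling.
#' @return data frame: one row per pair, with `model_a`, `model_b`,
#'   `r2_diff`, `ci_lower`, `ci_upper`, `significant`.
#' @export
compare_r_squared <- function(fits, n_boot = 1000, alpha = 0.05,
                              seed = 1L) {
  if (length(fits) < 2L)
    stop("need at least two fits to compare", call. = FALSE)
  ns <- vapply(fits, function(f) f$n, numeric(1))
  if (length(unique(ns)) != 1L ||
      !all(vapply(fits[-1], function(f)
        isTRUE(all.equal(f$y, fits[[1]]$y)), logical(1))))
    stop("fits are not comparable: different strata", call. = FALSE)
  labs <- vapply(seq_along(fits), function(i) {
    if (is.null(fits[[i]]$label)) paste0("model", i) else fits[[i]]$label
  }, character(1))
  n <- ns[1]
  pairs <- utils::combn(seq_along(fits), 2)
  set.seed(seed)
  idx_mat <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
  r2_boot <- function(fit, idx) {
    xb <- fit$x[idx, , drop = FALSE]
    yb <- fit$y[idx]
    tryCatch(fit_ols(xb, yb)$r_squared, error = function(e) NA_real_)
  }
  out <- vector("list", ncol(pairs))
  for (p in seq_len(ncol(pairs))) {
    i <- pairs[1, p]; j <- pairs[2, p]
    d0 <- fits[[i]]$r_squared - fits[[j]]$r_squared
    if (identical(labs[i], labs[j]) &&
        isTRUE(all.equal(fits[[i]]$x, fits[[j]]$x))) {
      ci <- c(0, 0)
    } else {
      db <- vapply(seq_len(n_boot), function(b) {
        idx <- idx_mat[, b]
        r2_boot(fits[[i]], idx) - r2_boot(fits[[j]], idx)
      }, numeric(1))
      ci <- stats::quantile(db, c(alpha / 2, 1 - alpha / 2), na.rm = TRUE,
                            names = FALSE)
    }
    out[[p]] <- data.frame(model_a = labs[i], model_b = labs[j],
                           r2_diff = d0, ci_lower = ci[1], ci_upper = ci[2],
                           significant = (ci[1] > 0 | ci[2] < 0),
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Best-model summary table across stratification strategies
#'
#' For each strategy, selects per-stratum best models (per error type),
#' computes the size-weighted overall MSE, and expresses it as a percentage
#' of the whole-group best model's MSE (set at 100%): the stratified
#' predictive-ability summary.
#'
#' @param strategy_results named list; element `whole` holds the whole-group
#'   [fit_stratum_models] results table, every other element is a named list
#'   of per-stratum results tables (with the stratum's n implied by the
#'   table's `n` column).
#' @param mep_denominator for strategies that do not cover the full cohort
#'   (MEP status unmeasured in some subjects): `"measured"` (default)
#'   aggregates over the measured strata only; `"whole"` additionally counts
#'   unmeasured subjects under the whole-group model's MSE.
#' @return list with `table` (one row per stratum: strategy, stratum, n,
#'   best model and MSE per error type) and `aggregates` (one row per
#'   strategy: overall and percentage per error type).
#' @export
build_table3 <- function(strategy_results, mep_denominator = c("measured",
                                                               "whole")) {
  mep_denominator <- match.arg(mep_denominator)
  if (!"whole" %in% names(strategy_results))
    stop("missing whole-group reference results", call. = FALSE)
  whole_best <- select_best(strategy_results$whole)
  ref_gen <- whole_best$generalization$loocv_mse
  ref_ins <- whole_best$in_sample$in_sample_mse

  rows <- list(data.frame(
    strategy = "whole", stratum = "all", n = whole_best$generalization$n,
    best_gen = whole_best$generalization$label, mse_gen = ref_gen,
    best_ins = whole_best$in_sample$label, mse_ins = ref_ins,
    stringsAsFactors = FALSE))
  aggs <- list(data.frame(
    strategy = "whole", overall_gen = ref_gen, pct_gen = 100,
    overall_ins = ref_ins, pct_ins = 100, stringsAsFactors = FALSE))

  for (strat in setdiff(names(strategy_results), "whole")) {
    per_stratum <- strategy_results[[strat]]
    ns <- mg <- mi <- numeric(0)
    unfittable <- FALSE
    for (lv in names(per_stratum)) {
      best <- tryCatch(select_best(per_stratum[[lv]]),
                       error = function(e) NULL)
      if (is.null(best)) {
        # no model could be fitted in this stratum (degenerate design):
        # record it explicitly and mark the strategy's aggregate undefined
        warning("strategy '", strat, "', stratum '", lv,
                "': no fittable model; aggregate set to NA")
        rows[[length(rows) + 1L]] <- data.frame(
          strategy = strat, stratum = lv,
          n = per_stratum[[lv]]$n[1], best_gen = NA_character_,
          mse_gen = NA_real_, best_ins = NA_character_,
          mse_ins = NA_real_, stringsAsFactors = FALSE)
        unfittable <- TRUE
        next
      }
      n_lv <- best$generalization$n
      rows[[length(rows) + 1L]] <- data.frame(
        strategy = strat, stratum = lv, n = n_lv,
        best_gen = best$generalization$label,
        mse_gen = best$generalization$loocv_mse,
        best_ins = best$in_sample$label,
        mse_ins = best$in_sample$in_sample_mse,
        stringsAsFactors = FALSE)
      ns <- c(ns, n_lv)
      mg <- c(mg, best$generalization$loocv_mse)
      mi <- c(mi, best$in_sample$in_sample_mse)
    }
    if (strat == "neurophysiological" && mep_denominator == "whole") {
      n_unmeas <- whole_best$generalization$n - sum(ns)
      if (n_unmeas > 0) {
        ns <- c(ns, n_unmeas); mg <- c(mg, ref_gen); mi <- c(mi, ref_ins)
      }
    }
    if (unfittable) {
      aggs[[length(aggs) + 1L]] <- data.frame(
        strategy = strat, overall_gen = NA_real_, pct_gen = NA_real_,
        overall_ins = NA_real_, pct_ins = NA_real_,
        stringsAsFactors = FALSE)
      next
    }
    og <- overall_weighted_mse(mg, ns)
    oi <- overall_weighted_mse(mi, ns)
    aggs[[length(aggs) + 1L]] <- data.frame(
      strategy = strat, overall_gen = og,
      pct_gen = relative_percentage(og, ref_gen),
      overall_ins = oi, pct_ins = relative_percentage(oi, ref_ins),
      stringsAsFactors = FALSE)
  }
  list(table = do.call(rbind, rows), aggregates = do.call(rbind, aggs))
}
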