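#' Proportional recovery rule parameters
#'
#' The rule predicts a score change of `proportion * (ceiling - baseline)`;
#' subjects whose model residual (predicted minus observed change) is at
#' least `residual_threshold` are classed non-fitted. `severity_threshold`
#' separates severe from non-severe baseline impairment. Both thresholds
#' are inclusive.
#'
#' @param ceiling maximal UE-FMA score (66).
#' @param proportion recovery proportion, in (0, 1\]; 0.7 by default.
#' @param residual_threshold score points; non-fitted if residual >= this.
#' @param severity_threshold score points; severe if baseline <= this.
#' @return object of class `prr_parameters`.
#' @export
prr_parameters <- function(ceiling = 66, proportion = 0.7,
                           residual_threshold = 20,
                           severity_threshold = 20) {
  if (!(proportion > 0 && proportion <= 1))
    stop("'proportion' must lie in (0, 1]", call. = FALSE)
  structure(list(ceiling = ceiling, proportion = proportion,
                 residual_threshold = residual_threshold,
                 severity_threshold = severity_threshold),
            class = "prr_parameters")
}

#' Proportional-recovery model residual
#'
#' `(ceiling - fma_2w) * proportion - (fma_3m - fma_2w)`: the predicted
#' change under the proportional recovery rule minus the observed change.
#' Positive values mean poorer recovery than predicted.
#'
#' @param fma_2w baseline (2-week) UE-FMA score(s), in \[0, 66\].
#' @param fma_3m outcome (3-month) UE-FMA score(s), in \[0, 66\].
#' @param params a [prr_parameters].
#' @return residual(s) in score points.
#' @export
prr_residual <- function(fma_2w, fma_3m, params = prr_parameters()) {
  if (any(fma_2w < 0 | fma_2w > params$ceiling, na.rm = TRUE) ||
      any(fma_3m < 0 | fma_3m > params$ceiling, na.rm = TRUE))
    stop("UE-FMA scores must lie in [0, ", params$ceiling, "]",
         call. = FALSE)
  (params$ceiling - fma_2w) * params$proportion - (fma_3m - fma_2w)
}

#' Assign stratification labels
#'
#' Applies the four stratification strategies to each record: initial
#' impairment (severe iff `fma_2w <= severity_threshold`), lesion location
#' (cortical iff the cortical-involvement flag is set), neurophysiological
#' status (MEP-negative / MEP-positive, or unmeasured) and proportional
#' recovery (non-fitted iff the model residual is `>= residual_threshold`).
#'
#' @param records data frame with columns `subject_id`, `fma_2w`, `fma_3m`,
#'   `mep_status` (`"positive"`, `"negative"`, `"unmeasured"`) and
#'   `cortical_flag` (0/1 or logical).
#' @param params a [prr_parameters].
#' @return data frame: `subject_id`, `prr_residual`, and factors
#'   `initial_impairment` (severe/non-severe), `lesion_location`
#'   (cortical/non-cortical), `neurophysiological`
#'   (MEP-negative/MEP-positive/unmeasured), `proportional_recovery`
#'   (non-fitted/fitted).
#' @export
assign_strata <- function(records, params = prr_parameters()) {
  res <- prr_residual(records$fma_2w, records$fma_3m, params)
  data.frame(
    subject_id = records$subject_id,
    prr_residual = res,
    initial_impairment = factor(
      ifelse(records$fma_2w <= params$severity_threshold,
             "severe", "non-severe"),
      levels = c("severe", "non-severe")),
    lesion_location = factor(
      ifelse(as.logical(records$cortical_flag), "cortical", "non-cortical"),
      levels = c("cortical", "non-cortical")),
    neurophysiological = factor(
      ifelse(records$mep_status == "unmeasured", "unmeasured",
             ifelse(records$mep_status == "negative",
                    "MEP-negative", "MEP-positive")),
      levels = c("MEP-negative", "MEP-positive", "unmeasured")),
    proportional_recovery = factor(
      ifelse(res >= params$residual_threshold, "non-fitted", "fitted"),
      levels = c("non-fitted", "fitted")),
    stringsAsFactors = FALSE)
}

#' Subgroup counts per stratification strategy
#'
#' @param assignments output of [assign_strata].
#' @return named list of label-count tables, one per strategy. The
#'   neurophysiological table covers measured subjects only.
#' @export
stratum_counts <- function(assignments) {
  if (nrow(assignments) == 0L)
    stop("empty assignment collection", call. = FALSE)
  meas <- assignments$neurophysiological != "unmeasured"
  list(
    initial_impairment = table(assignments$initial_impairment),
    lesion_location = table(assignments$lesion_location),
    neurophysiological =
      table(droplevels(assignments$neurophysiological[meas],
                       exclude = "unmeasured")),
    proportional_recovery = table(assignments$proportional_recovery))
}
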