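# Sum of distance-weighted contributions (SDC) applicability domain.
# SDC = sum_i exp(-3 * TD_i / (1 - TD_i)), where TD_i is the Tanimoto
# distance (1 - similarity) between the query and the i-th training
# molecule. Every term lies in [0, 1]: an exact structural match contributes
# 1, a molecule at maximal distance contributes 0 (the continuous limit of
# the weight as TD -> 1). High SDC means the query sits in well-covered
# chemical space and the model's prediction is considered reliable.

sdc_term <- function(td) {
  out <- ifelse(td >= 1, 0, exp(-3 * td / (1 - td)))
  out[td < 0] <- NA_real_
  out
}

#' SDC applicability-domain score
#'
#' @param query_fp A single fingerprint ([morgan_fp()]).
#' @param training_fps List of training-set fingerprints.
#' @return Non-negative SDC score, bounded above by `length(training_fps)`.
#' @examples
#' fps <- lapply(c("CCO", "CCN", "CCC"), morgan_fp)
#' sdc_score(fps[[1]], fps)
#' @export
sdc_score <- function(query_fp, training_fps) {
  if (length(training_fps) == 0L) abort("empty training set")
  td <- vapply(training_fps, function(f) 1 - tanimoto(query_fp, f), numeric(1))
  sum(sdc_term(td))
}

#' Calibrate an SDC in-domain threshold from the training set
#'
#' Each training molecule is scored against the other `n - 1` by
#' leave-one-out SDC; the returned threshold is the requested percentile of
#' that distribution (default the 5th), so roughly `1 - percentile` of the
#' training chemistry itself would be called in-domain.
#'
#' @param training_fps List of at least 3 training fingerprints.
#' @param percentile Quantile of the leave-one-out SDC distribution in
#'   `[0, 1]` (default 0.05).
#' @return Non-negative threshold.
#' @export
calibrate_sdc_threshold <- function(training_fps, percentile = 0.05) {
  n <- length(training_fps)
  if (n < 3L) abort("insufficient training set: need at least 3 molecules")
  stopifnot(percentile >= 0, percentile <= 1)
  loo <- vapply(seq_len(n), function(i) {
    sdc_score(training_fps[[i]], training_fps[-i])
  }, numeric(1))
  unname(quantile(loo, probs = percentile, type = 7))
}

#' Applicability-domain assessment for a batch of queries
#'
#' @param queries Dataset tibble with `record_id` and `fingerprint` columns
#'   (see [add_fingerprints()]).
#' @param training_fps List of training-set fingerprints the model was
#'   built from.
#' @param threshold In-domain cutoff: `in_domain` is `sdc >= threshold`.
#'   Defaults to [calibrate_sdc_threshold()] of the training set.
#' @return Tibble with `record_id`, `sdc`, `n_training`, `threshold`,
#'   `in_domain`.
#' @export
assess_domain <- function(queries, training_fps,
                          threshold = calibrate_sdc_threshold(training_fps)) {
  stopifnot(is.data.frame(queries), "fingerprint" %in% names(queries))
  if (length(training_fps) == 0L) abort("empty training set")
  stopifnot(is.numeric(threshold), threshold >= 0)
  sdc <- vapply(queries$fingerprint, sdc_score, numeric(1),
                training_fps = training_fps)
  tibble(
    record_id = queries$record_id,
    sdc = sdc,
    n_training = length(training_fps),
    threshold = threshold,
    in_domain = sdc >= threshold
  )
}
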