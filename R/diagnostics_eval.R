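# Diagnostic-evaluation statistics: 2x2 metrics, ROC AUC (Mann--Whitney),
# the DeLong structural-components test for paired AUCs, Bland--Altman
# agreement, correlation, and per-patient aggregation.
#
# Orientation is explicit everywhere: FFR-like indexes flag disease at LOW
# values, diameter-stenosis-like indexes at HIGH values. Silent
# mis-orientation is the classic field bug, so `positive_low` is a required
# argument and never inferred from the data.

#' 2x2 diagnostic metrics
#'
#' @param calls Logical vector of index-positive calls.
#' @param truth Logical vector of reference-positive states (both classes
#'   must be present).
#' @return Object of class `diagnostic_summary`: accuracy, sensitivity,
#'   specificity, ppv, npv, lr_pos, lr_neg, counts. `lr_pos` is `Inf` when
#'   specificity is 1; `lr_neg` is 0 when sensitivity is 1.
#' @export
confusion_metrics <- function(calls, truth) {
  stopifnot(length(calls) == length(truth))
  calls <- as.logical(calls); truth <- as.logical(truth)
  if (!any(truth)) stop("truth contains no positive cases")
  if (all(truth)) stop("truth contains no negative cases")
  tp <- sum(calls & truth); fn <- sum(!calls & truth)
  tn <- sum(!calls & !truth); fp <- sum(calls & !truth)
  sens <- tp / (tp + fn); spec <- tn / (tn + fp)
  structure(list(
    accuracy = (tp + tn) / length(truth),
    sensitivity = sens, specificity = spec,
    ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
    lr_pos = if (spec < 1) sens / (1 - spec) else Inf,
    lr_neg = if (spec > 0) (1 - sens) / spec else Inf,
    n_pos = tp + fn, n_neg = tn + fp,
    tp = tp, fp = fp, tn = tn, fn = fn), class = "diagnostic_summary")
}

# orient scores so that HIGHER means more disease-positive
orient_scores <- function(scores, positive_low) {
  stopifnot(is.logical(positive_low), length(positive_low) == 1L)
  if (positive_low) -scores else scores
}

#' ROC area under the curve
#'
#' Mann--Whitney estimator with tie correction (tied pairs count 1/2),
#' computed from average ranks.
#'
#' @param scores Continuous index values.
#' @param truth Logical reference states (both classes present).
#' @param positive_low `TRUE` if low scores indicate disease (FFR-like),
#'   `FALSE` if high scores do (stenosis-like). Required.
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(scores, truth, positive_low) {
  stopifnot(length(scores) == length(truth))
  truth <- as.logical(truth)
  if (!any(truth) || all(truth)) stop("truth must contain both classes")
  x <- orient_scores(scores, positive_low)
  r <- rank(x)
  n_pos <- sum(truth); n_neg <- sum(!truth)
  (sum(r[truth]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# DeLong structural components for one oriented marker:
# V10_i = mean_j psi(X_i, Y_j), V01_j = mean_i psi(X_i, Y_j)
delong_components <- function(x_oriented, truth) {
  X <- x_oriented[truth]; Y <- x_oriented[!truth]
  m <- length(X); n <- length(Y)
  psi <- outer(X, Y, function(a, b) (a > b) + 0.5 * (a == b))
  list(auc = mean(psi), v10 = rowMeans(psi), v01 = colMeans(psi),
       m = m, n = n)
}

#' DeLong test for two correlated ROC AUCs
#'
#' Nonparametric comparison of two AUCs measured on the same cases, using
#' the DeLong structural-components variance estimator and a two-sided
#' normal reference for the AUC difference. Also returns each AUC's 95%
#' confidence interval from the same estimator.
#'
#' @param scores_a,scores_b Paired continuous indexes on identical cases.
#' @param truth Logical reference states (both classes present).
#' @param positive_low_a,positive_low_b Orientation of each index (see
#'   [roc_auc()]).
#' @param conf_level Confidence level for the per-AUC intervals.
#' @return List: `auc_a`, `auc_b`, `var_a`, `var_b`, `cov_ab`, `var_diff`,
#'   `z`, `p`, `ci_a`, `ci_b`.
#' @export
delong_test <- function(scores_a, scores_b, truth, positive_low_a,
                        positive_low_b, conf_level = 0.95) {
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(truth))
    stop("scores_a, scores_b and truth must be paired (equal lengths)")
  truth <- as.logical(truth)
  if (!any(truth) || all(truth)) stop("truth must contain both classes")
  ca <- delong_components(orient_scores(scores_a, positive_low_a), truth)
  cb <- delong_components(orient_scores(scores_b, positive_low_b), truth)
  m <- ca$m; n <- ca$n
  s10 <- stats::cov(cbind(ca$v10, cb$v10))
  s01 <- stats::cov(cbind(ca$v01, cb$v01))
  var_a <- s10[1, 1] / m + s01[1, 1] / n
  var_b <- s10[2, 2] / m + s01[2, 2] / n
  cov_ab <- s10[1, 2] / m + s01[1, 2] / n
  var_diff <- var_a + var_b - 2 * cov_ab
  d <- ca$auc - cb$auc
  z <- if (var_diff <= 0) 0 else d / sqrt(var_diff)
  p <- 2 * stats::pnorm(-abs(z))
  zc <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- function(auc, v) c(max(0, auc - zc * sqrt(max(v, 0))),
                           min(1, auc + zc * sqrt(max(v, 0))))
  list(auc_a = ca$auc, auc_b = cb$auc, var_a = var_a, var_b = var_b,
       cov_ab = cov_ab, var_diff = var_diff, z = z, p = p,
       ci_a = ci(ca$auc, var_a), ci_b = ci(cb$auc, var_b))
}

#' Bland--Altman agreement
#'
#' @param x,y Paired measurements (n >= 2).
#' @param k Limits-of-agreement multiplier (default 1.96).
#' @return List: `bias` (= mean(y - x)), `sd` of differences, `loa`
#'   (bias -/+ k sd), `n`.
#' @export
bland_altman <- function(x, y, k = 1.96) {
  if (length(x) != length(y)) stop("x and y must be paired")
  if (length(x) < 2L) stop("need at least 2 pairs")
  d <- y - x
  b <- mean(d); s <- stats::sd(d)
  list(bias = b, sd = s, loa = c(b - k * s, b + k * s), n = length(d))
}

#' Pearson correlation
#'
#' @param x,y Paired values, n >= 3, each with nonzero variance.
#' @return Sample correlation coefficient r.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired")
  if (length(x) < 3L) stop("need at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in x or y")
  stats::cor(x, y)
}

#' Aggregate vessel-level records to patient level
#'
#' A patient is reference-positive if any vessel has invasive FFR at or
#' below the threshold; each continuous index is summarized by its worst
#' vessel (minimum for FFR-like indexes, maximum for stenosis-like ones),
#' including the invasive FFR itself.
#'
#' @param records data.frame with columns `patient_id`, `ffr_invasive`, and
#'   the index columns named in `positive_low`.
#' @param positive_low Named logical: orientation per index column.
#' @param threshold Ischemia threshold on invasive FFR (default 0.80).
#' @return data.frame with one row per patient: `patient_id`, `truth`,
#'   `ffr_invasive` (worst), and the worst-vessel value of each index.
#' @export
aggregate_per_patient <- function(records, positive_low, threshold = 0.8) {
  stopifnot(is.data.frame(records), "patient_id" %in% names(records),
            "ffr_invasive" %in% names(records))
  idx <- names(positive_low)
  stopifnot(all(idx %in% names(records)))
  pieces <- lapply(split(records, records$patient_id), function(d) {
    row <- data.frame(patient_id = d$patient_id[1],
                      truth = any(d$ffr_invasive <= threshold),
                      ffr_invasive = min(d$ffr_invasive),
                      stringsAsFactors = FALSE)
    for (ix in idx)
      row[[ix]] <- if (positive_low[[ix]]) min(d[[ix]]) else max(d[[ix]])
    row
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Tidy diagnostic-performance report
#'
#' Builds one row per index/threshold/level combination, shaped like a
#' clinical diagnostic-performance table: accuracy, sensitivity,
#' specificity, likelihood ratios, predictive values, AUC with 95% CI.
#' Binary calls use the index's threshold with its orientation (`<=` for
#' FFR-like indexes, `>=` for stenosis-like). Also returns DeLong p-values
#' for every index pair at each level.
#'
#' @param records data.frame with `vessel_id`, optional `patient_id`,
#'   `ffr_invasive`, and index columns.
#' @param indexes Named logical: orientation per index (`TRUE` = low is
#'   positive). Defaults cover `ffr_am`, `ffr_b`, `ds_ctca`, `ds_ica`;
#'   missing columns are skipped.
#' @param ffr_threshold Ischemia threshold on FFR-like indexes and on the
#'   invasive reference.
#' @param ds_thresholds Diameter-stenosis call thresholds (default 0.5, 0.7).
#' @return List with data.frames `metrics` and `delong`.
#' @export
eval_report <- function(records,
                        indexes = c(ffr_am = TRUE, ffr_b = TRUE,
                                    ds_ctca = FALSE, ds_ica = FALSE),
                        ffr_threshold = 0.8,
                        ds_thresholds = c(0.5, 0.7)) {
  stopifnot("ffr_invasive" %in% names(records))
  indexes <- indexes[names(indexes) %in% names(records)]
  if (!length(indexes)) stop("no index columns found in records")
  vr <- records
  vr$truth <- vr$ffr_invasive <= ffr_threshold
  levels <- list(vessel = vr)
  if ("patient_id" %in% names(records)) {
    levels$patient <- aggregate_per_patient(records, indexes,
                                            threshold = ffr_threshold)
  } else {
    warning("no patient_id column; per-patient rows skipped")
  }
  mrows <- list(); drows <- list()
  for (lev in names(levels)) {
    d <- levels[[lev]]
    for (ix in names(indexes)) {
      thr <- if (indexes[[ix]]) ffr_threshold else ds_thresholds
      for (t in thr) {
        calls <- if (indexes[[ix]]) d[[ix]] <= t else d[[ix]] >= t
        cm <- confusion_metrics(calls, d$truth)
        dl <- delong_test(d[[ix]], d[[ix]], d$truth,
                          indexes[[ix]], indexes[[ix]])
        mrows[[length(mrows) + 1L]] <- data.frame(
          index = ix, threshold = t, level = lev,
          accuracy = cm$accuracy, sens = cm$sensitivity,
          spec = cm$specificity, lr_pos = cm$lr_pos, lr_neg = cm$lr_neg,
          ppv = cm$ppv, npv = cm$npv, auc = dl$auc_a,
          ci_lo = dl$ci_a[1], ci_hi = dl$ci_a[2],
          n_pos = cm$n_pos, n_neg = cm$n_neg, stringsAsFactors = FALSE)
      }
    }
    ixn <- names(indexes)
    if (length(ixn) > 1L) for (i in seq_len(length(ixn) - 1L))
      for (j in (i + 1L):length(ixn)) {
        dl <- delong_test(d[[ixn[i]]], d[[ixn[j]]], d$truth,
                          indexes[[ixn[i]]], indexes[[ixn[j]]])
        drows[[length(drows) + 1L]] <- data.frame(
          level = lev, index_a = ixn[i], index_b = ixn[j],
          auc_a = dl$auc_a, auc_b = dl$auc_b, z = dl$z, p = dl$p,
          stringsAsFactors = FALSE)
      }
  }
  list(metrics = do.call(rbind, mrows),
       delong = if (length(drows)) do.call(rbind, drows) else NULL)
}
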