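# brute-force AUC oracle: pairwise concordance with ties counting 1/2
auc_brute <- function(scores, truth, positive_low) {
  x <- if (positive_low) -scores else scores
  pos <- x[truth]; neg <- x[!truth]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

test_that("confusion metrics match hand arithmetic and identities", {
  truth <- c(rep(TRUE, 12), rep(FALSE, 8))
  calls <- c(rep(TRUE, 9), rep(FALSE, 3), rep(TRUE, 1), rep(FALSE, 7))
  cm <- confusion_metrics(calls, truth)
  expect_equal(cm$sensitivity, 0.75)
  expect_equal(cm$specificity, 0.875)
  expect_equal(cm$accuracy, 0.80)
  expect_equal(cm$ppv, 0.90)
  expect_equal(cm$npv, 0.70)
  expect_equal(cm$lr_pos, 6.0)
  # identity: acc = (sens n_pos + spec n_neg) / n
  expect_equal(cm$accuracy,
               (cm$sensitivity * cm$n_pos + cm$specificity * cm$n_neg) / 20)
  # ppv consistent with Bayes at sample prevalence
  prev <- cm$n_pos / 20
  expect_equal(cm$ppv, cm$sensitivity * prev /
                 (cm$sensitivity * prev + (1 - cm$specificity) * (1 - prev)))

  # perfect calls
  cp <- confusion_metrics(truth, truth)
  expect_equal(cp$accuracy, 1); expect_equal(cp$lr_neg, 0)
  expect_equal(cp$lr_pos, Inf)
  # inverted calls swap sens/spec with complement
  ci <- confusion_metrics(!calls, truth)
  expect_equal(ci$sensitivity, 1 - cm$sensitivity)
  expect_equal(ci$specificity, 1 - cm$specificity)
  expect_error(confusion_metrics(calls[truth], truth[truth]), "negative")
})

test_that("ROC AUC equals brute-force concordance, handles ties and orientation", {
  # 4-pair hand example: positives {0.8, 0.4}, negatives {0.6, 0.2}
  truth <- c(TRUE, TRUE, FALSE, FALSE)
  sc <- c(0.8, 0.4, 0.6, 0.2)
  expect_equal(roc_auc(sc, truth, positive_low = FALSE), 0.75)
  # perfectly separated and all-tied cases
  expect_equal(roc_auc(c(2, 3, 0, 1), c(TRUE, TRUE, FALSE, FALSE), FALSE), 1)
  expect_equal(roc_auc(rep(1, 6), rep(c(TRUE, FALSE), 3), FALSE), 0.5)
  # orientation flip complements the AUC
  expect_equal(roc_auc(sc, truth, TRUE), 0.25)
  # brute-force equality on random instances with ties, n <= 50
  set.seed(31)
  for (i in 1:25) {
    n <- sample(5:50, 1)
    truth <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(truth)) truth[1] <- TRUE
    if (all(truth)) truth[1] <- FALSE
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # many ties
    lowpos <- i %% 2 == 0
    expect_equal(roc_auc(scores, truth, lowpos),
                 auc_brute(scores, truth, lowpos), tolerance = 1e-12)
  }
  expect_error(roc_auc(1:4, rep(TRUE, 4), FALSE), "both classes")
})

test_that("DeLong test agrees with pROC and behaves in degenerate cases", {
  set.seed(5)
  truth <- rep(c(TRUE, FALSE), 20)
  a <- truth + rnorm(40); b <- 0.3 * truth + rnorm(40)
  # identical scores: zero difference, p = 1
  dl0 <- delong_test(a, a, truth, FALSE, FALSE)
  expect_equal(dl0$auc_a, dl0$auc_b)
  expect_equal(dl0$p, 1)
  dl <- delong_test(a, b, truth, FALSE, FALSE)
  expect_gt(dl$var_a, 0); expect_gt(dl$var_b, 0)
  expect_true(dl$ci_a[1] < dl$auc_a && dl$auc_a < dl$ci_a[2])
  skip_if_not_installed("pROC")
  ra <- pROC::roc(truth, a, quiet = TRUE, direction = "<")
  rb <- pROC::roc(truth, b, quiet = TRUE, direction = "<")
  ref <- pROC::roc.test(ra, rb, method = "delong")
  expect_equal(dl$p, ref$p.value, tolerance = 1e-9)
  expect_equal(dl$auc_a, as.numeric(pROC::auc(ra)), tolerance = 1e-12)
  ci_ref <- as.numeric(pROC::ci.auc(ra, method = "delong"))
  expect_equal(dl$ci_a, ci_ref[c(1, 3)], tolerance = 1e-9)
  # mixed orientation: comparing an index against its own negation is a null
  dmix <- delong_test(a, -a, truth, FALSE, TRUE)
  expect_equal(dmix$auc_a, dmix$auc_b)
  expect_equal(dmix$p, 1)
  expect_error(delong_test(a, b[-1], truth, FALSE, FALSE), "paired")
})

test_that("Bland-Altman and Pearson r basics", {
  ba <- bland_altman(c(0.8, 0.6), c(0.7, 0.7))
  expect_equal(ba$bias, 0)
  expect_equal(ba$sd, 0.1414, tolerance = 1e-3)
  ba2 <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ba2$bias, 0); expect_equal(ba2$sd, 0)
  # shift property: adding c to y shifts bias by c, sd unchanged
  set.seed(9)
  x <- rnorm(50); y <- x + rnorm(50, 0, 0.1)
  b1 <- bland_altman(x, y); b2 <- bland_altman(x, y + 0.3)
  expect_equal(b2$bias, b1$bias + 0.3); expect_equal(b2$sd, b1$sd)
  # reorder invariance
  o <- sample(50)
  b3 <- bland_altman(x[o], y[o])
  expect_equal(b3$bias, b1$bias); expect_equal(b3$sd, b1$sd)
  expect_equal(b1$loa, c(b1$bias - 1.96 * b1$sd, b1$bias + 1.96 * b1$sd))

  expect_equal(pearson_r(1:10, 2 * (1:10) + 1), 1)
  expect_equal(pearson_r(1:10, -(1:10)), -1)
  set.seed(13)
  expect_lt(abs(pearson_r(rnorm(10000), rnorm(10000))), 0.05)
  expect_error(pearson_r(rep(1, 5), 1:5), "zero variance")
})

test_that("per-patient aggregation takes the worst vessel per index", {
  rec <- data.frame(
    vessel_id = c("v1", "v2", "v3", "v4"),
    patient_id = c("p1", "p1", "p2", "p3"),
    ffr_invasive = c(0.9, 0.7, 0.85, 0.95),
    ffr_am = c(0.88, 0.75, 0.9, 0.97),
    ds_ctca = c(0.4, 0.6, 0.3, 0.2))
  agg <- aggregate_per_patient(rec, c(ffr_am = TRUE, ds_ctca = FALSE))
  expect_identical(nrow(agg), 3L)
  p1 <- agg[agg$patient_id == "p1", ]
  expect_true(p1$truth)               # one vessel at 0.7 <= 0.8
  expect_equal(p1$ffr_am, 0.75)       # worst = minimum for FFR-like
  expect_equal(p1$ds_ctca, 0.6)       # worst = maximum for DS-like
  expect_equal(p1$ffr_invasive, 0.7)
  # single-vessel patients are identical to per-vessel
  p2 <- agg[agg$patient_id == "p2", ]
  expect_false(p2$truth); expect_equal(p2$ffr_am, 0.9)
})

test_that("evaluation report produces the tidy metrics table", {
  set.seed(21)
  n <- 80
  truth_lat <- rnorm(n)
  rec <- data.frame(
    vessel_id = sprintf("v%03d", 1:n),
    patient_id = sprintf("p%03d", rep(1:40, each = 2)),
    ffr_invasive = pmin(1, pmax(0.3, 0.8 - 0.1 * truth_lat + rnorm(n, 0, 0.05))),
    ffr_am = pmin(1, pmax(0.2, 0.8 - 0.1 * truth_lat + rnorm(n, 0, 0.08))),
    ds_ctca = pmin(1, pmax(0, 0.5 + 0.15 * truth_lat + rnorm(n, 0, 0.1))))
  rep <- eval_report(rec)
  m <- rep$metrics
  # ffr index gets 1 threshold, ds gets 2, at both levels
  expect_identical(nrow(m[m$index == "ffr_am", ]), 2L)
  expect_identical(nrow(m[m$index == "ds_ctca", ]), 4L)
  expect_true(all(m$auc >= 0 & m$auc <= 1))
  expect_true(all(m$ci_lo <= m$auc & m$auc <= m$ci_hi))
  expect_identical(nrow(rep$delong), 2L)  # one pair x two levels
  # scoring a cohort by its own truth index yields AUC 1
  rec2 <- rec; rec2$ffr_am <- rec2$ffr_invasive
  m2 <- eval_report(rec2)$metrics
  expect_equal(m2$auc[m2$index == "ffr_am" & m2$level == "vessel"], 1)
  # missing patient_id: per-patient rows skipped with a warning
  expect_warning(r3 <- eval_report(rec[, names(rec) != "patient_id"]),
                 "patient_id")
  expect_true(all(r3$metrics$level == "vessel"))
})
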