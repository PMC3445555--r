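test_that("the published exemplar ratios classify as their histopathology", {
  expect_false(classify_site(0.08))   # HPV effect exemplar
  expect_true(classify_site(0.22))    # CIN 3 exemplar
  expect_false(classify_site(0.163))  # strict inequality at the cutoff
  expect_error(classify_site(-0.1), "non-negative")
})

test_that("confusion counts reproduce the published per-category tally", {
  cm <- confusion(tally_ledger())
  expect_equal(unclass(cm)[c("tp", "fn", "tn", "fp")],
               list(tp = 12L, fn = 2L, tn = 26L, fp = 4L))
})

test_that("confusion matches a brute-force per-site recount", {
  set.seed(81)
  for (rep in 1:5) {
    nc <- round(runif(44, 0, 0.4), 3)
    lab <- runif(44) < 0.3
    df <- data.frame(nc_ratio = nc, neoplastic = lab)
    cm <- confusion(df, cutoff = 0.163)
    tp <- 0; fn <- 0; tn <- 0; fp <- 0
    for (i in 1:44) {
      call <- nc[i] > 0.163
      if (lab[i] && call) tp <- tp + 1
      if (lab[i] && !call) fn <- fn + 1
      if (!lab[i] && !call) tn <- tn + 1
      if (!lab[i] && call) fp <- fp + 1
    }
    expect_equal(unclass(cm)[c("tp", "fn", "tn", "fp")],
                 list(tp = tp, fn = fn, tn = tn, fp = fp))
    expect_equal(cm$tp + cm$fn + cm$tn + cm$fp, 44)
  }
})

test_that("missing labels are reported by site", {
  df <- data.frame(site_id = c("A", "B"), nc_ratio = c(0.1, 0.2),
                   neoplastic = c(TRUE, NA))
  expect_error(confusion(df), "B")
})

test_that("sensitivity and specificity round to the headline percentages", {
  ss <- sens_spec(list(tp = 12, fn = 2, tn = 26, fp = 4))
  expect_equal(ss$sensitivity, 100 * 12 / 14)
  expect_equal(ss$specificity, 100 * 26 / 30)
  expect_equal(ss$sensitivity_pct, 86)
  expect_equal(ss$specificity_pct, 87)
  perfect <- sens_spec(list(tp = 5, fn = 0, tn = 9, fp = 0))
  expect_equal(c(perfect$sensitivity, perfect$specificity), c(100, 100))
  expect_error(sens_spec(list(tp = 0, fn = 0, tn = 3, fp = 1)),
               "positive")
})

test_that("ROC endpoints, AUC extremes and one-class errors behave", {
  roc <- roc_curve(c(0.05, 0.1, 0.3, 0.4), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(roc$auc, 1)
  pts <- roc$points
  expect_true(any(pts$sensitivity == 1 & pts$specificity == 0))
  expect_true(any(pts$sensitivity == 0 & pts$specificity == 1))
  expect_error(roc_curve(c(0.1, 0.2), c(TRUE, TRUE)), "both")
})

test_that("AUC equals the brute-force Mann-Whitney statistic", {
  set.seed(82)
  for (rep in 1:10) {
    n <- sample(6:16, 1)
    scores <- round(runif(n, 0, 0.4), 2)  # rounding induces ties
    labels <- c(TRUE, FALSE, runif(n - 2) < 0.4)
    expect_equal(roc_curve(scores, labels)$auc, mw_auc(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("AUC is invariant under strictly increasing score transforms", {
  set.seed(83)
  scores <- runif(30, 0, 0.4)
  labels <- c(TRUE, FALSE, runif(28) < 0.5)
  a <- roc_curve(scores, labels)$auc
  b <- roc_curve(exp(3 * scores), labels)$auc
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("uninformative scores give AUC near one half", {
  set.seed(84)
  scores <- runif(400)
  labels <- rep(c(TRUE, FALSE), 200)
  expect_lt(abs(roc_curve(scores, labels)$auc - 0.5), 0.05)
})

test_that("ROC is monotone along the cutoff axis", {
  set.seed(85)
  scores <- runif(50, 0, 0.4)
  labels <- c(TRUE, FALSE, runif(48) < 0.3)
  pts <- roc_curve(scores, labels)$points
  expect_true(all(diff(pts$sensitivity) <= 0))
  expect_true(all(diff(pts$specificity) >= 0))
})

test_that("the Q-point takes perfect points and breaks ties upward", {
  roc <- roc_curve(c(0.05, 0.1, 0.3, 0.4), c(FALSE, FALSE, TRUE, TRUE))
  q <- roc$q_point
  expect_equal(c(q$sensitivity, q$specificity), c(1, 1))
  # two equidistant points: prefer the higher-sensitivity one
  fake <- structure(list(points = data.frame(
    cutoff = c(0.1, 0.2),
    tp = c(9, 8), fn = c(1, 2), tn = c(8, 9), fp = c(2, 1),
    sensitivity = c(0.9, 0.8), specificity = c(0.8, 0.9))),
    class = "roc_curve")
  expect_equal(q_point(fake)$sensitivity, 0.9)
})

test_that("a cohort mimicking the published separability yields 86/87", {
  led <- tally_ledger()
  roc <- roc_curve(led$nc_ratio, led$neoplastic)
  q <- roc$q_point
  expect_equal(round_half_up(100 * q$sensitivity), 86)
  expect_equal(round_half_up(100 * q$specificity), 87)
  # self-consistency: confusion at the Q-point cutoff reproduces the
  # stored operating point exactly
  cm <- confusion(led, cutoff = q$cutoff)
  ss <- sens_spec(cm)
  expect_equal(ss$sensitivity / 100, q$sensitivity)
  expect_equal(ss$specificity / 100, q$specificity)
})

test_that("Youden selection is available and reports a valid point", {
  led <- tally_ledger()
  roc <- roc_curve(led$nc_ratio, led$neoplastic)
  qy <- q_point(roc, method = "youden")
  expect_true(qy$sensitivity + qy$specificity - 1 >=
                max(roc$points$sensitivity + roc$points$specificity - 1) -
                1e-12)
})
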