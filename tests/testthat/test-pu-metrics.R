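test_that("confusion counts follow the standard definitions", {
  c1 <- confusion_from_labels(rep("positive", 3),
                              c("inlier", "inlier", "outlier"))
  expect_equal(c1$tp, 2)
  expect_equal(c1$fn, 1)
  expect_true(is.na(c1$fp))   # PU mode: no negatives observable

  c2 <- confusion_from_labels(c("positive", "negative"),
                              c("inlier", "outlier"))
  expect_equal(c(c2$tp, c2$fn, c2$fp, c2$tn), c(1, 0, 0, 1))

  c3 <- confusion_from_labels(rep("unlabeled", 4), rep("inlier", 4))
  expect_true(c3$degenerate)
  expect_equal(c3$tp + c3$fn, 0)

  expect_error(confusion_from_labels(rep("positive", 2), "inlier"),
               "length")
})

test_that("recall and positive-rate estimators are plain proportions", {
  expect_equal(estimate_recall(rep(c("inlier", "outlier"), c(8, 2))), 0.8)
  expect_equal(estimate_recall(rep("inlier", 5)), 1)
  expect_equal(estimate_recall(rep("outlier", 5)), 0)
  expect_error(estimate_recall(character(0)), "empty")

  expect_equal(estimate_positive_rate(rep(c("inlier", "outlier"),
                                          c(10, 10))), 0.5)
  expect_equal(estimate_positive_rate(rep("outlier", 3)), 0)
  expect_error(estimate_positive_rate(character(0)), "empty")
})

test_that("precision Bayes inversion reproduces hand arithmetic", {
  expect_equal(estimate_precision(0.8, 0.5, 0.5), 0.8)
  expect_equal(estimate_precision(1.0, 0.3, 0.6), 0.5)
  # perfect classifier on an uncontaminated pool: rate = prior, r = 1
  expect_equal(estimate_precision(1, 0.25, 0.25), 1)
  # sampling noise above 1 is clipped (and reported)
  expect_message(p <- estimate_precision(1, 0.5, 0.4), "clipped")
  expect_equal(p, 1)
  expect_error(estimate_precision(0.8, 0.5, 0), "undefined")
  expect_error(estimate_precision(0.8, 1.5, 0.5), "prior")
})

test_that("precision equals recall exactly when rate equals prior", {
  # the identity behind published even-break-point tables: r * prior /
  # rate = r whenever the predicted-positive rate matches the prior
  for (r in c(0.3, 0.9961)) {
    for (prior in c(0.2, 0.5)) {
      m <- pu_metrics(r, positive_rate_hat = prior, class_prior = prior)
      expect_equal(m$precision_hat, r)
      expect_equal(m$f_measure, r)
    }
  }
})

test_that("F-measure matches published table arithmetic", {
  expect_equal(f_measure(0.9961, 0.9961), 0.9961)
  # harmonic mean of 93.70 / 82.33 prints as 87.64
  expect_equal(f_measure(0.9370, 0.8233), 0.8764, tolerance = 1e-4)
  expect_equal(f_measure(0, 0), 0)
  for (p in c(0.2, 0.7)) for (r in c(0.4, 0.9)) {
    expect_equal(f_measure(p, r), f_measure(r, p))
    expect_lte(f_measure(p, r), max(p, r))
    expect_lte(f_measure(p, r), (p + r) / 2)
  }
})

test_that("the positives-only criterion is r^2 over the rate", {
  expect_equal(pu_criterion(1, 0.5), 2)
  expect_equal(pu_criterion(0, 0.3), 0)
  rates <- pu_criterion(c(0.2, 0.5, 0.9), 0.4)
  expect_true(all(diff(rates) > 0))   # increasing in r at fixed rate
  expect_error(pu_criterion(0.5, 0), "undefined")
})

test_that("metrics reports round-trip through text and JSON", {
  m <- pu_metrics(0.9, 0.45, 0.4)
  base <- tempfile()
  write_metrics_report(m, base)
  txt <- readLines(paste0(base, ".txt"))
  expect_true(any(grepl("^recall_hat\t0.9", txt)))
  expect_true(any(grepl("^recall_pct\t90.00", txt)))
  j <- jsonlite::read_json(paste0(base, ".json"), simplifyVector = TRUE)
  expect_equal(j$recall_hat, 0.9)
  expect_equal(j$precision_hat, m$precision_hat)
})
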