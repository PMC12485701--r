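test_that("expression tiers partition TPM with the documented boundaries", {
  th <- ExpressionThresholds()
  expect_identical(expressionTier(10, th), "expressed")
  expect_identical(expressionTier(1, th), "not_expressed")
  expect_identical(expressionTier(5, th), "low")
  expect_identical(expressionTier(0, th), "not_expressed")
  # exactly one tier for any tpm, monotone in tpm
  tpm <- sort(c(0, 0.5, 1, 1 + 1e-12, 5, 10 - 1e-12, 10, 100))
  tiers <- expressionTier(tpm, th)
  expect_true(all(tiers %in% c("expressed", "low", "not_expressed")))
  ord <- c(not_expressed = 1L, low = 2L, expressed = 3L)
  expect_true(all(diff(ord[tiers]) >= 0))
  expect_error(expressionTier(-1, th), "validation error")
  expect_error(expressionTier(Inf, th), "validation error")
})

test_that("thresholds and panels validate their invariants", {
  expect_error(ExpressionThresholds(1, 10), "must be <")
  expect_error(ExpressionThresholds(10, -1), "positive")
  expect_error(MarkerPanel(y_genes = character(0)), "non-empty")
  expect_error(MarkerPanel(min_y_expressed = 9L), "1..length")
})

test_that("Y presence requires the configured number of expressed markers", {
  expect_equal(yPresence(yMarkers(0.1, RPS4Y1 = 50, DDX3Y = 12)),
               list(present = TRUE, n_expressed = 2L, n_low = 0L),
               ignore_attr = TRUE)
  expect_equal(yPresence(yMarkers(0.1, RPS4Y1 = 50)),
               list(present = FALSE, n_expressed = 1L, n_low = 0L),
               ignore_attr = TRUE)
  expect_equal(yPresence(yMarkers(0)),
               list(present = FALSE, n_expressed = 0L, n_low = 0L),
               ignore_attr = TRUE)
  expect_error(yPresence(c(RPS4Y1 = 50)), "marker-missing error.*DDX3Y")
})

test_that("the decision table maps every evidence combination to one call", {
  on <- yMarkers(0.1, DDX3Y = 30, KDM5D = 15)
  off <- yMarkers(0.1)
  cases <- expand.grid(xist = c(55, 0.2), y = c(TRUE, FALSE),
                       sex = c("female", "male", "unknown"),
                       ploidy = c("1", "2", "unknown"),
                       stringsAsFactors = FALSE)
  expected_call <- function(xp, yp, sex, ploidy) {
    if (sex == "female") {
      if (xp && !yp) "XaXi"
      else if (!xp && !yp) switch(ploidy, "2" = "XaXa", "1" = "X0_LOX", "X0_ambiguous")
      else if (xp && yp) "XXY_like" else "XY_unexpected"
    } else if (sex == "male") {
      if (!xp && yp) "XY" else if (!xp && !yp) "X0_LOY"
      else if (xp && !yp) "XX_unexpected" else "XXY_like"
    } else {
      if (xp && !yp) "XaXi" else if (!xp && yp) "XY"
      else if (!xp && !yp) "X0_ambiguous" else "XXY_like"
    }
  }
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    call <- suppressWarnings(
      inferSCC(cs$xist, if (cs$y) on else off, cs$sex, cs$ploidy))$call
    expect_identical(call, expected_call(cs$xist >= 10, cs$y, cs$sex, cs$ploidy),
                     label = paste(unlist(cs), collapse = "/"))
  }
})

test_that("spec exemplar calls and the ploidy-inconsistency flag hold", {
  off <- yMarkers(0.8)
  expect_identical(inferSCC(55, off, "female", "2")$call, "XaXi")
  expect_identical(inferSCC(0.2, off, "female", "1")$call, "X0_LOX")
  expect_identical(inferSCC(0.2, off, "female", "2")$call, "XaXa")
  expect_identical(
    inferSCC(40, yMarkers(0.1, DDX3Y = 30, KDM5D = 15), "male")$call,
    "XXY_like")
  expect_identical(inferSCC(40, yMarkers(0.5), "unknown")$call, "XaXi")
  # XIST expressed with single-X ploidy: flagged, still XaXi
  expect_warning(res <- inferSCC(55, off, "female", "1"), "inconsistent")
  expect_identical(res$call, "XaXi")
  expect_identical(res$flags, "ploidy_inconsistent")
  # male ploidy is ignored
  expect_identical(inferSCC(0.2, yMarkers(30), "male", "1")$call, "XY")
})

test_that("raising the expressed threshold never flips X0 calls back to XaXi/XY", {
  set.seed(11)
  violations <- 0L; n_x0 <- 0L
  for (i in 1:50) {
    xist <- runif(1, 0, 20)
    mk <- yMarkers(runif(7, 0, 12))
    sex <- sample(c("female", "male"), 1)
    lo <- suppressWarnings(
      inferSCC(xist, mk, sex, "1", thresholds = ExpressionThresholds(10, 1)))
    hi <- suppressWarnings(
      inferSCC(xist, mk, sex, "1", thresholds = ExpressionThresholds(25, 1)))
    if (lo$call %in% c("X0_LOX", "X0_LOY")) {
      n_x0 <- n_x0 + 1L
      if (hi$call %in% c("XaXi", "XY")) violations <- violations + 1L
    }
  }
  expect_gt(n_x0, 0L)
  expect_identical(violations, 0L)
})

test_that("batch calls match hand-built samples and proportions sum to one", {
  se <- handCohort()
  batch <- inferSCCBatch(se)
  expect_identical(batch$calls$call, c("XaXi", "X0_LOX", "XY", "X0_LOY"))
  sums <- tapply(batch$proportions$proportion,
                 paste(batch$proportions$tissue, batch$proportions$reported_sex),
                 sum)
  expect_true(all(abs(sums - 1) < 1e-12))
})

test_that("low-signal tissues are flagged by within-sex median thresholds", {
  genes <- c("XIST", names(yMarkers()))
  blood <- cbind(b1 = c(1, rep(2, 7)), b2 = c(2, rep(3, 7)), b3 = c(3, rep(1, 7)),
                 b4 = c(2, rep(2, 7)))
  liver <- cbind(l1 = c(80, rep(0.1, 7)), l2 = c(90, rep(0.1, 7)),
                 l3 = c(0.1, rep(30, 7)), l4 = c(0.2, rep(40, 7)))
  values <- cbind(blood, liver); rownames(values) <- genes
  se <- tinySE(values, chromosome = c("X", rep("Y", 7)))
  ann <- DataFrame(sample_id = colnames(values),
                   tissue = rep(c("blood", "liver"), each = 4),
                   reported_sex = rep(c("female", "female", "male", "male"), 2),
                   row.names = colnames(values))
  res <- flagLowSignalTissues(alignSamples(se, ann))
  expect_identical(res$flagged, "blood")
  expect_false("liver" %in% res$flagged)

  # tissue with no female samples: skipped with a warning, not flagged on XIST
  ann2 <- ann; ann2$reported_sex <- rep("male", 8)
  ws <- capture_warnings(res2 <- flagLowSignalTissues(alignSamples(se, ann2)))
  expect_match(ws, "no female samples", all = TRUE)
  expect_true(is.na(res2$medians$median_female_xist[1]))
})

test_that("age association recovers a planted offset and degenerates safely", {
  # identical ages -> difference 0, p = 1
  calls <- DataFrame(sample_id = paste0("s", 1:8),
                     call = rep(c("XY", "X0_LOY"), each = 4),
                     reported_sex = "male",
                     xist_tpm = rep(0.1, 8),
                     y_mean_tpm = rep(c(30, 0.2), each = 4))
  ann <- DataFrame(sample_id = paste0("s", 1:8), age_years = rep(50, 8))
  res <- ageAssociation(calls, ann)
  expect_equal(res$age_diff, 0)
  expect_equal(res$p, 1)
  expect_true(all(is.na(res$correlations$rho)))  # zero-variance age

  # Monte Carlo: planted +4.6y offset at n = 500/group lies inside the CI
  set.seed(101)
  n <- 500
  age <- c(rnorm(n, 64.6, 10), rnorm(n, 60, 10))
  calls2 <- DataFrame(sample_id = paste0("m", seq_len(2 * n)),
                      call = rep(c("X0_LOY", "XY"), each = n),
                      reported_sex = "male",
                      xist_tpm = runif(2 * n, 0, 1),
                      y_mean_tpm = c(runif(n, 0, 1), runif(n, 20, 40)))
  ann2 <- DataFrame(sample_id = calls2$sample_id, age_years = age)
  res2 <- ageAssociation(calls2, ann2)
  expect_lt(res2$p, 1e-4)
  expect_gt(4.6, res2$ci_low)
  expect_lt(4.6, res2$ci_high + 1e-9)
  expect_equal(res2$age_diff, 4.6, tolerance = 0.3)
})

test_that("paired tumor/adjacent deltas are computed per subject and marker", {
  # direct arithmetic: tumor 5 vs normal 20 with c = 0.5
  expect_equal(log2((5 + 0.5) / (20 + 0.5)), -1.898, tolerance = 1e-3)
  genes <- c("XIST", names(yMarkers()))
  values <- cbind(t1 = c(0.2, rep(5, 7)), n1 = c(0.2, rep(20, 7)),
                  t2 = c(0.2, rep(8, 7)))
  rownames(values) <- genes
  se <- tinySE(values, chromosome = c("X", rep("Y", 7)))
  ann <- DataFrame(sample_id = colnames(values),
                   subject_id = c("p1", "p1", "p2"),
                   tissue = "T1", reported_sex = "male",
                   sample_type = c("primary_tumor", "adjacent_normal",
                                   "primary_tumor"),
                   row.names = colnames(values))
  res <- pairedMarkerDelta(alignSamples(se, ann))
  expect_identical(unique(res$subject_id), "p1")   # p2 has no pair
  ddx <- res[res$gene == "DDX3Y", ]
  expect_equal(ddx$log2_ratio, log2(5.5 / 20.5))
  # tumor == normal -> delta 0
  expect_equal(res$log2_ratio[res$gene == "XIST"], 0)

  ann$sample_type <- "primary_tumor"
  expect_warning(empty <- pairedMarkerDelta(alignSamples(se, ann)), "no.*pairs")
  expect_identical(nrow(empty), 0L)
})
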