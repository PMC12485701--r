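# Synthetic cohort generator: determinism, marker separation, planted truth.

small_cfg <- function(...) simConfig(n_tissues = 2L,
                                     n_per_group = rep(8L, 5),
                                     n_genes = 300L,
                                     n_de = c(lox = 10L, xaxa = 10L,
                                              loy = 10L, sex = 30L),
                                     n_convergence = 20L, ...)

test_that("identical seeds reproduce the cohort exactly; seeds differ otherwise", {
  a <- simulateCohort(small_cfg(seed = 5))
  b <- simulateCohort(small_cfg(seed = 5))
  expect_identical(assay(a$se, "tpm"), assay(b$se, "tpm"))
  expect_identical(as.data.frame(colData(a$se)), as.data.frame(colData(b$se)))
  expect_identical(a$truth, b$truth)
  c_ <- simulateCohort(small_cfg(seed = 6))
  expect_false(identical(assay(a$se, "tpm"), assay(c_$se, "tpm")))
})

test_that("marker distributions separate SCC states by more than 10x", {
  sim <- simulateCohort(small_cfg(seed = 9))
  cd <- colData(sim$se)
  truth <- sim$truth$scc
  xist <- assay(sim$se, "tpm")["XIST", ]
  grp <- truth$group[match(colnames(sim$se), truth$sample_id)]
  expect_gt(mean(xist[grp == "female_XaXi"]),
            10 * mean(xist[grp == "female_X0"]))
  ddx <- assay(sim$se, "tpm")["DDX3Y", ]
  expect_gt(mean(ddx[grp == "male_XY"]), 10 * mean(ddx[grp == "male_X0"]))
})

test_that("planted fold changes are recovered in the empirical means", {
  sim <- simulateCohort(simConfig(seed = 12, n_tissues = 4L,
                                  n_per_group = rep(20L, 5)))
  tpm <- assay(sim$se, "tpm")
  grp <- sim$truth$scc$group[match(colnames(sim$se), sim$truth$scc$sample_id)]
  lox <- sim$truth$de$lox
  direct <- lox[abs(abs(lox$log_effect) - log(2)) < 1e-9, ]
  lfc <- log2(rowMeans(tpm[direct$gene, grp == "female_X0"]) /
                rowMeans(tpm[direct$gene, grp == "female_XaXi"]))
  signed <- ifelse(direct$direction == "up", lfc, -lfc)
  expect_equal(mean(signed), 1, tolerance = 0.15)
})

test_that("per-contrast truth is derived from the planted effect matrix", {
  sim <- simulateCohort(small_cfg(seed = 10))
  E <- sim$truth$effects
  for (cn in c("lox", "xaxa", "loy", "sex")) {
    pair <- switch(cn,
                   lox = c("female_XaXi", "female_X0"),
                   xaxa = c("female_XaXi", "female_XaXa"),
                   loy = c("male_XY", "male_X0"),
                   sex = c("male_XY", "female_XaXi"))
    d <- E[, pair[2]] - E[, pair[1]]
    expect_setequal(sim$truth$de[[cn]]$gene, rownames(E)[d != 0])
  }
  # sex-difference genes planted in Xi-retaining groups appear in the lox truth
  expect_gt(nrow(sim$truth$de$lox), 10)
})

test_that("classifier recovery is exact at default separation and degrades with noise", {
  sim <- simulateCohort(small_cfg(seed = 14))
  batch <- inferSCCBatch(sim$se)
  truth <- sim$truth$scc$call[match(batch$calls$sample_id,
                                    sim$truth$scc$sample_id)]
  expect_identical(unname(batch$calls$call), truth)

  acc_at <- function(noise) {
    cor_ <- corruptCohort(sim$se, boundary_noise = noise, seed = 3)
    b <- inferSCCBatch(cor_$se)
    mean(b$calls$call == truth)
  }
  accs <- vapply(c(0, 0.2, 0.5), acc_at, numeric(1))
  expect_equal(accs[1], 1)
  expect_true(all(diff(accs) <= 0))
})

test_that("corruption is recorded and forces the documented downstream calls", {
  sim <- simulateCohort(small_cfg(seed = 15))
  none <- corruptCohort(sim$se, swap_labels = 0, boundary_noise = 0)
  expect_identical(assay(none$se, "tpm"), assay(sim$se, "tpm"))
  expect_identical(nrow(none$manifest), 0L)

  # swap one male XY sample to female -> XY_unexpected
  truth <- sim$truth$scc
  xy_id <- truth$sample_id[truth$group == "male_XY"][1]
  se2 <- sim$se
  cd <- colData(se2)
  cd$reported_sex[colnames(se2) == xy_id] <- "female"
  colData(se2) <- cd
  b <- inferSCCBatch(se2)
  expect_identical(b$calls[xy_id, "call"], "XY_unexpected")

  # boundary noise on an XaXi female with unknown ploidy -> X0_ambiguous
  xaxi_id <- truth$sample_id[truth$group == "female_XaXi"][1]
  se3 <- sim$se
  tpm <- assay(se3, "tpm"); tpm["XIST", xaxi_id] <- 5
  SummarizedExperiment::assay(se3, "tpm") <- tpm
  cd3 <- colData(se3); cd3$x_ploidy[colnames(se3) == xaxi_id] <- "unknown"
  colData(se3) <- cd3
  b3 <- inferSCCBatch(se3)
  expect_identical(b3$calls[xaxi_id, "call"], "X0_ambiguous")

  cor_ <- corruptCohort(sim$se, swap_labels = 0.1, seed = 8)
  expect_identical(sort(unique(cor_$manifest$change)), "swap_label")
  expect_equal(nrow(cor_$manifest), round(0.1 * ncol(sim$se)))
})

test_that("survival and age generators hit their planted parameters", {
  # KM medians per group, averaged over seeded replicates to keep the Monte
  # Carlo error of the check well inside the 10% band
  meds <- vapply(16:19, function(s) {
    sim <- simulateCohort(simConfig(seed = s, n_tissues = 1L,
                                    n_per_group = rep(500L, 5),
                                    n_genes = 10L, n_de = c(lox = 0L, xaxa = 0L,
                                                            loy = 0L, sex = 0L),
                                    n_convergence = 0L, censor_frac = 0))
    cd <- colData(sim$se)
    grp <- sim$truth$scc$group[match(colnames(sim$se), sim$truth$scc$sample_id)]
    vapply(c("female_XaXi", "male_XY", "male_X0"), function(g)
      medianSurvival(kmEstimate(cd$survival_days[grp == g],
                                cd$event[grp == g])), numeric(1))
  }, numeric(3))
  planted <- c(female_XaXi = 4445, male_XY = 3200, male_X0 = 1900)
  expect_true(all(abs(rowMeans(meds) - planted) / planted < 0.10))

  # age offsets
  sim <- simulateCohort(simConfig(seed = 16, n_tissues = 1L,
                                  n_per_group = rep(500L, 5), n_genes = 10L,
                                  n_de = c(lox = 0L, xaxa = 0L, loy = 0L,
                                           sex = 0L), n_convergence = 0L))
  cd <- colData(sim$se)
  grp <- sim$truth$scc$group[match(colnames(sim$se), sim$truth$scc$sample_id)]
  expect_equal(mean(cd$age_years[grp == "male_X0"]) -
                 mean(cd$age_years[grp == "male_XY"]), 4.6, tolerance = 1.5)
})

test_that("paired subjects receive adjacent-normal samples with typical markers", {
  sim <- simulateCohort(small_cfg(seed = 17, n_paired = 4L))
  cd <- colData(sim$se)
  expect_equal(sum(cd$sample_type == "adjacent_normal"), 4L)
  delta <- pairedMarkerDelta(sim$se)
  # male X0 tumors lost Y expression relative to their adjacent normal
  male_subj <- cd$subject_id[cd$sample_type == "adjacent_normal" &
                               cd$reported_sex == "male"]
  ddx <- delta[delta$gene == "DDX3Y" & delta$subject_id %in% male_subj, ]
  expect_true(all(ddx$log2_ratio < 0))
})

test_that("invalid generator configurations are rejected", {
  expect_error(simConfig(bogus_field = 1), "unknown field")
  expect_error(simulateCohort(simConfig(n_per_group = rep(0L, 5))))
})
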