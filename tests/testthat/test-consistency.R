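# Cross-tissue consistency rule, hypergeometric overlap, set relations.

fake_de <- function(genes, log2FC, p) {
  data.frame(gene = genes, log2FC = log2FC, p = p, stringsAsFactors = FALSE)
}

# independent exhaustive-scan implementation of the consistency rule
oracle_profile <- function(tabs, f = 0.6, alpha = 0.05) {
  genes <- Reduce(intersect, lapply(tabs, `[[`, "gene"))
  up <- character(); down <- character()
  for (g in genes) {
    fcs <- sapply(tabs, function(d) d$log2FC[d$gene == g])
    ps <- sapply(tabs, function(d) d$p[d$gene == g])
    if (all(fcs > 0) && mean(ps < alpha) >= f) up <- c(up, g)
    if (all(fcs < 0) && mean(ps < alpha) >= f) down <- c(down, g)
  }
  list(up = up, down = down)
}

test_that("the documented boundary cases of the 60%/same-direction rule hold", {
  g <- "gene1"
  tabs5 <- function(fcs, ps) lapply(1:5, function(i) fake_de(g, fcs[i], ps[i]))
  # up in 5/5, significant in exactly 3/5 -> included (0.60 >= 0.60)
  p1 <- buildConsistentProfile(tabs5(rep(1, 5), c(0.01, 0.01, 0.01, 0.5, 0.5)))
  expect_identical(upGenes(p1), g)
  # up in 4/5 but down in 1 -> excluded regardless of significance
  p2 <- buildConsistentProfile(tabs5(c(1, 1, 1, 1, -1), rep(0.001, 5)))
  expect_length(profileGenes(p2), 0)
  # up in 5/5, significant in 2/5 -> excluded (0.40 < 0.60)
  p3 <- buildConsistentProfile(tabs5(rep(1, 5), c(0.01, 0.01, 0.5, 0.5, 0.5)))
  expect_length(profileGenes(p3), 0)
  # zero fold change cannot match any direction
  p4 <- buildConsistentProfile(tabs5(c(1, 1, 1, 1, 0), rep(0.001, 5)))
  expect_length(profileGenes(p4), 0)
  expect_error(buildConsistentProfile(list()), "empty")
})

test_that("profiles equal the exhaustive-scan oracle on random tables", {
  set.seed(31)
  for (rep_i in 1:5) {
    genes <- sprintf("g%02d", 1:50)
    tabs <- lapply(1:6, function(i)
      fake_de(genes, log2FC = round(rnorm(50), 2) ,
              p = runif(50)))
    prof <- buildConsistentProfile(tabs)
    orc <- oracle_profile(tabs)
    expect_setequal(upGenes(prof), orc$up)
    expect_setequal(downGenes(prof), orc$down)
  }
})

test_that("criteria behave monotonically and reduce correctly at f=1, p=1", {
  set.seed(32)
  genes <- sprintf("g%02d", 1:50)
  tabs <- lapply(1:6, function(i) fake_de(genes, rnorm(50), runif(50)))
  base <- profileGenes(buildConsistentProfile(tabs, ConsistencyCriteria(0.5, 0.1)))
  tighter_f <- profileGenes(buildConsistentProfile(tabs, ConsistencyCriteria(0.9, 0.1)))
  tighter_p <- profileGenes(buildConsistentProfile(tabs, ConsistencyCriteria(0.5, 0.01)))
  expect_true(all(tighter_f %in% base))
  expect_true(all(tighter_p %in% base))
  # f = 1 with per-tissue p = 1 is exactly the same-direction-in-all rule
  reduced <- buildConsistentProfile(tabs, ConsistencyCriteria(1, 1))
  sgn <- sapply(tabs, `[[`, "log2FC")
  all_same <- apply(sign(sgn), 1, function(s) all(s == s[1]) && s[1] != 0)
  expect_setequal(profileGenes(reduced), genes[all_same])
})

test_that("hypergeometric overlap matches full enumeration and is monotone", {
  universe <- letters[1:10]
  res <- hypergeometricOverlap(letters[1:5], letters[1:5], universe)
  # oracle: enumerate all C(10,5) draws of B and count overlap-5 outcomes
  draws <- combn(10, 5)
  k5 <- mean(apply(draws, 2, function(b) length(intersect(b, 1:5))) >= 5)
  expect_equal(res$p, k5)
  expect_equal(res$p, 1 / 252)
  expect_equal(res$expected, 2.5)

  # full-enumeration check across all k for a second configuration
  resA <- hypergeometricOverlap(letters[1:4], letters[3:8], universe)
  kk <- apply(combn(10, 6), 2, function(b) length(intersect(b, 1:4)))
  expect_equal(resA$p, mean(kk >= resA$k))

  # k = 0 -> p = P(X >= 0) = 1; B = universe -> k = |A|, p = 1
  disjoint <- hypergeometricOverlap(letters[1:3], letters[4:6], universe)
  expect_equal(disjoint$k, 0)
  expect_equal(disjoint$p, 1)
  full <- hypergeometricOverlap(letters[1:4], universe, universe)
  expect_equal(full$k, 4)
  expect_equal(full$p, 1)

  # monotone non-increasing in k at fixed (N, K, n)
  pk <- sapply(0:5, function(k) stats::phyper(k - 1, 5, 5, 5, lower.tail = FALSE))
  expect_true(all(diff(pk) <= 0))

  expect_error(hypergeometricOverlap(c("zz"), letters[1:3], universe),
               "containment error")
})

test_that("set relations enumerate exclusive membership patterns exactly", {
  rel <- profileSetRelations(list(A = c("a", "b"), B = "c"))
  expect_equal(rel$n[rel$pattern == "A"], 2L)
  expect_equal(rel$n[rel$pattern == "B"], 1L)
  expect_equal(rel$n[rel$pattern == "A&B"], 0L)
  expect_equal(sum(rel$n), 3L)

  ident <- profileSetRelations(list(A = c("x", "y"), B = c("x", "y")))
  expect_equal(ident$n[ident$pattern == "A&B"], 2L)
  expect_equal(sum(ident$n), 2L)

  # oracle: brute-force membership scan on random sets
  set.seed(44)
  sets <- list(P = sample(letters, 8), Q = sample(letters, 12),
               R = sample(letters, 5))
  rel3 <- profileSetRelations(sets)
  uni <- unique(unlist(sets))
  for (i in seq_len(nrow(rel3))) {
    pat <- as.logical(rel3[i, names(sets)])
    n_oracle <- sum(sapply(uni, function(el)
      all(sapply(seq_along(sets), function(j) (el %in% sets[[j]]) == pat[j]))))
    expect_equal(rel3$n[i], n_oracle)
  }
  expect_equal(sum(rel3$n), length(uni))
})

test_that("sex-difference DE collapses between X0 groups on planted signal", {
  set.seed(55)
  n_per <- 8; G <- 120
  groups <- rep(c("female_XaXi", "female_X0", "male_XY", "male_X0"), each = n_per)
  genes <- sprintf("g%03d", 1:G)
  chrom <- rep("1", G); chrom[1:10] <- "X"; chrom[11:15] <- "Y"
  base <- matrix(rlnorm(G * length(groups), 2.5, 0.4), G, length(groups),
                 dimnames = list(genes, paste0("s", seq_along(groups))))
  # 20 autosomal genes 4-fold higher in female-XaXi only
  planted <- 21:40
  base[planted, groups == "female_XaXi"] <- base[planted, groups == "female_XaXi"] * 4
  se <- tinySE(base, chromosome = chrom)
  calls <- DataFrame(sample_id = colnames(base),
                     call = rep(c("XaXi", "X0_LOX", "XY", "X0_LOY"), each = n_per),
                     reported_sex = rep(c("female", "female", "male", "male"),
                                        each = n_per))
  cfg <- DEConfig(low_expr_filter = 0, covariates = character(0))
  ref <- sexDiffDE(se, calls, "XaXi", "XY", cfg)
  expect_setequal(ref$significant, genes[planted])
  expect_equal(ref$counts$n[ref$counts$class == "autosomal"], 20L)

  collapsed <- sexDiffDE(se, calls, "X0_LOX", "X0_LOY", cfg,
                         reference_genes = ref$significant)
  expect_length(intersect(collapsed$significant, genes[planted]), 0)

  # all-null contrast: nothing significant at FDR + fold-change cut
  null_de <- sexDiffDE(se[-planted, ], calls, "XaXi", "XY", cfg)
  expect_length(null_de$significant, 0)
})
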