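# Group structure across the four sex-by-SCC groups: per-gene one-way ANOVA,
# top-gene selection, PLS-DA projection (NIPALS PLS2 on one-hot groups), and
# the X0-convergence centroid ratio.

#' Standard four-group labels for group-structure analysis
#' @return character vector of the four sex-by-SCC group labels.
#' @export
groupStructureGroups <- function()
  c("female_XaXi", "female_X0", "male_XY", "male_X0")

# Calls excluded before ANOVA/PLS-DA: ambiguous or unexpected complements.
.EXCLUDED_CALLS <- c("XXY_like", "XX_unexpected", "XY_unexpected", "X0_ambiguous")

#' Map SCC calls to sex-by-SCC analysis groups
#'
#' Produces the five-level grouping used for group-structure and survival
#' analyses; ambiguous/unexpected calls map to `NA`.
#'
#' @param calls calls DataFrame from [inferSCCBatch()].
#' @return character vector in `{female_XaXi, female_XaXa, female_X0,
#'   male_XY, male_X0}` or `NA`.
#' @export
sccGroup <- function(calls) {
  out <- rep(NA_character_, nrow(calls))
  out[calls$reported_sex == "female" & calls$call == "XaXi"] <- "female_XaXi"
  out[calls$reported_sex == "female" & calls$call == "XaXa"] <- "female_XaXa"
  out[calls$reported_sex == "female" & calls$call == "X0_LOX"] <- "female_X0"
  out[calls$reported_sex == "male" & calls$call == "XY"] <- "male_XY"
  out[calls$reported_sex == "male" & calls$call == "X0_LOY"] <- "male_X0"
  out
}

#' Per-gene one-way ANOVA across groups
#'
#' Classical one-way F statistic per gene computed from between/within sums
#' of squares on log2(TPM + c); p from `F(k-1, n-k)`.  Genes with zero
#' between- and within-group variance are reported as missing.
#'
#' @param tpm genes x samples TPM matrix.
#' @param group factor/character of group labels (>= 2 groups, each >= 2
#'   samples).
#' @param pseudocount c in log2(TPM + c); set `NULL` to analyse the matrix
#'   as-is (already log-scale).
#' @return data.frame (gene, F, p).
#' @export
anovaPerGene <- function(tpm, group, pseudocount = 0.5) {
  y <- as.matrix(tpm)
  if (!is.null(pseudocount)) y <- log2(y + pseudocount)
  group <- factor(as.character(group))
  k <- nlevels(group)
  if (k < 2L) stop("anovaPerGene: need at least 2 groups", call. = FALSE)
  sizes <- table(group)
  if (any(sizes < 2L))
    stop("anovaPerGene: group(s) with < 2 samples: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "), call. = FALSE)
  n <- ncol(y)
  gm <- vapply(levels(group), function(l) rowMeans(y[, group == l, drop = FALSE]),
               numeric(nrow(y)))
  gm <- matrix(gm, nrow = nrow(y))
  grand <- rowMeans(y)
  ssb <- as.vector(gm^2 %*% as.numeric(sizes)) - n * grand^2
  sst <- rowSums(y^2) - n * grand^2
  ssw <- pmax(sst - ssb, 0)
  Fstat <- (ssb / (k - 1L)) / (ssw / (n - k))
  p <- stats::pf(Fstat, k - 1L, n - k, lower.tail = FALSE)
  degenerate <- sst < 1e-12
  Fstat[degenerate] <- NA_real_
  p[degenerate] <- NA_real_
  data.frame(gene = rownames(y) %||% as.character(seq_len(nrow(y))),
             F = Fstat, p = p, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Select top genes by ANOVA p-value
#'
#' Sorts ascending by p (ties broken by descending F, then lexical gene id)
#' and truncates to `n_top`.  When `exclude_sex_chromosomes` is set, chrX and
#' chrY genes are removed before truncation.
#'
#' @param anova_table data.frame from [anovaPerGene()].
#' @param n_top number of genes to keep (default 3000).
#' @param exclude_sex_chromosomes drop X/Y genes first.
#' @param chromosome chromosome label per row of `anova_table` (required when
#'   excluding sex chromosomes).
#' @return character vector of gene ids, deterministically ordered.
#' @export
selectTopGenes <- function(anova_table, n_top = 3000,
                           exclude_sex_chromosomes = FALSE,
                           chromosome = NULL) {
  if (!nrow(anova_table)) stop("selectTopGenes: empty table", call. = FALSE)
  tab <- anova_table
  if (exclude_sex_chromosomes) {
    if (is.null(chromosome))
      stop("selectTopGenes: chromosome labels required to exclude sex ",
           "chromosomes", call. = FALSE)
    keep <- !(normalizeChromosome(chromosome) %in% c("X", "Y"))
    tab <- tab[keep, , drop = FALSE]
  }
  tab <- tab[!is.na(tab$p), , drop = FALSE]
  ord <- order(tab$p, -tab$F, tab$gene)
  tab <- tab[ord, , drop = FALSE]
  if (n_top > nrow(tab)) {
    warning("selectTopGenes: n_top (", n_top, ") exceeds available genes (",
            nrow(tab), "); returning all", call. = FALSE)
    n_top <- nrow(tab)
  }
  tab$gene[seq_len(n_top)]
}

#' PLS-DA projection (two-component score map)
#'
#' @slot scores samples x components matrix.
#' @slot loadings genes x components matrix of unit-norm weight vectors.
#' @slot centroids groups x components matrix of group score means.
#' @slot groups character vector of group labels per sample.
#' @export
setClass("PLSProjection",
         representation(scores = "matrix", loadings = "matrix",
                        centroids = "matrix", groups = "character"))

setMethod("show", "PLSProjection", function(object) {
  cat("PLSProjection: ", nrow(object@scores), " samples x ",
      ncol(object@scores), " components over ", nrow(object@loadings),
      " genes; groups: ", paste(rownames(object@centroids), collapse = ", "),
      "\n", sep = "")
})

#' Partial least squares discriminant analysis
#'
#' NIPALS PLS2 of gene expression against one-hot-encoded group membership.
#' Genes are centered (and unit-scaled unless `scale_genes = FALSE`;
#' constant genes are dropped with a warning), components are extracted with
#' X-loading deflation so successive score vectors are orthogonal, and each
#' component's sign is fixed so its largest-magnitude loading is positive,
#' making projections reproducible.
#'
#' @param tpm genes x samples TPM matrix restricted to the selected genes.
#' @param group character/factor of group labels per sample.
#' @param n_components number of latent components (default 2).
#' @param scale_genes unit-variance scale genes (default TRUE).
#' @param pseudocount c in log2(TPM + c); `NULL` for already-log input.
#' @param max_iter,tol NIPALS iteration controls.
#' @return a [PLSProjection].
#' @export
plsdaProject <- function(tpm, group, n_components = 2L, scale_genes = TRUE,
                         pseudocount = 0.5, max_iter = 500L, tol = 1e-10) {
  y <- as.matrix(tpm)
  if (!is.null(pseudocount)) y <- log2(y + pseudocount)
  group <- factor(as.character(group))
  X <- t(y)                                  # samples x genes
  if (n_components > min(ncol(X), nrow(X) - 1L))
    stop("plsdaProject: n_components exceeds min(#genes, #samples - 1)",
         call. = FALSE)
  sds <- apply(X, 2L, stats::sd)
  if (scale_genes && any(sds == 0)) {
    warning("plsdaProject: dropping ", sum(sds == 0), " constant gene(s)",
            call. = FALSE)
    X <- X[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  X <- scale(X, center = TRUE, scale = if (scale_genes) sds else FALSE)
  Y <- stats::model.matrix(~ 0 + group)
  colnames(Y) <- levels(group)
  Y <- scale(Y, center = TRUE, scale = FALSE)

  n <- nrow(X); G <- ncol(X); k <- ncol(Y)
  scores <- matrix(0, n, n_components)
  loadings <- matrix(0, G, n_components,
                     dimnames = list(colnames(X), NULL))
  Xd <- X; Yd <- Y
  for (comp in seq_len(n_components)) {
    u <- Yd[, which.max(apply(Yd, 2L, stats::var))]
    t_old <- rep(Inf, n)
    for (it in seq_len(max_iter)) {
      w <- crossprod(Xd, u) / sum(u^2)
      w <- w / sqrt(sum(w^2))
      t_ <- Xd %*% w
      q <- crossprod(Yd, t_) / sum(t_^2)
      u <- Yd %*% q / sum(q^2)
      if (sum((t_ - t_old)^2) < tol * sum(t_^2)) break
      t_old <- t_
    }
    p_ <- crossprod(Xd, t_) / sum(t_^2)
    # deterministic sign: largest |loading| entry positive
    flip <- sign(w[which.max(abs(w))])
    if (flip < 0) { w <- -w; t_ <- -t_; p_ <- -p_; q <- -q }
    scores[, comp] <- t_
    loadings[, comp] <- w
    Xd <- Xd - t_ %*% t(p_)
    Yd <- Yd - t_ %*% t(q)
  }
  rownames(scores) <- rownames(X)
  centroids <- vapply(levels(group), function(l)
    colMeans(scores[group == l, , drop = FALSE]), numeric(n_components))
  centroids <- t(matrix(centroids, nrow = n_components,
                        dimnames = list(NULL, levels(group))))
  new("PLSProjection", scores = scores, loadings = loadings,
      centroids = centroids, groups = as.character(group))
}

#' @describeIn PLSProjection-class sample scores matrix.
#' @param x a `PLSProjection`.
#' @export
plsScores <- function(x) x@scores

#' @describeIn PLSProjection-class gene loading (weight) matrix.
#' @export
plsLoadings <- function(x) x@loadings

#' @describeIn PLSProjection-class group centroid matrix.
#' @export
plsCentroids <- function(x) x@centroids

#' X0 convergence ratio in PLS-DA score space
#'
#' Ratio of the Euclidean distance between the female-X0 and male-X0 group
#' centroids to the distance between the typical female-XaXi and male-XY
#' centroids.  `r < 1` indicates that sex-chromosome-loss tumors converge
#' toward a common X0 expression state.
#'
#' @param projection a [PLSProjection] whose groups include all four labels of
#'   [groupStructureGroups()].
#' @return numeric ratio r.
#' @export
x0Convergence <- function(projection) {
  cen <- plsCentroids(projection)
  need <- groupStructureGroups()
  if (!all(need %in% rownames(cen)))
    stop("x0Convergence: missing group(s): ",
         paste(setdiff(need, rownames(cen)), collapse = ", "), call. = FALSE)
  d <- function(a, b) sqrt(sum((cen[a, ] - cen[b, ])^2))
  d("female_X0", "male_X0") / d("female_XaXi", "male_XY")
}
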