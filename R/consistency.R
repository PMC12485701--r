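# Cross-tissue consistent gene profiles and set-overlap statistics.

#' Consistency criteria for cross-tissue profiles
#'
#' A gene enters a consistent profile when its fold change has the same sign
#' in every eligible tissue and its per-tissue DE p-value is below
#' `per_tissue_p` in at least a fraction `min_frac_significant` of them.
#'
#' @slot min_frac_significant numeric in (0,1], default 0.60.
#' @slot per_tissue_p numeric, default 0.05.
#' @export
setClass("ConsistencyCriteria",
         representation(min_frac_significant = "numeric",
                        per_tissue_p = "numeric"),
         prototype(min_frac_significant = 0.60, per_tissue_p = 0.05),
         validity = function(object) {
           if (object@min_frac_significant <= 0 || object@min_frac_significant > 1)
             return("min_frac_significant must be in (0,1]")
           if (object@per_tissue_p <= 0 || object@per_tissue_p > 1)
             return("per_tissue_p must be in (0,1]")
           TRUE
         })

#' @rdname ConsistencyCriteria-class
#' @param min_frac_significant,per_tissue_p see slots.
#' @return a `ConsistencyCriteria` object.
#' @export
ConsistencyCriteria <- function(min_frac_significant = 0.60,
                                per_tissue_p = 0.05) {
  new("ConsistencyCriteria", min_frac_significant = min_frac_significant,
      per_tissue_p = per_tissue_p)
}

#' Cross-tissue consistent gene profile
#'
#' @slot contrast character label of the contrast.
#' @slot up_genes,down_genes character vectors (disjoint).
#' @slot tissues_used character vector of contributing tissues.
#' @slot support data.frame (gene, direction, n_tissues, n_significant).
#' @slot criteria the [ConsistencyCriteria] applied.
#' @export
setClass("ConsistentProfile",
         representation(contrast = "character", up_genes = "character",
                        down_genes = "character", tissues_used = "character",
                        support = "data.frame", criteria = "ConsistencyCriteria"),
         validity = function(object) {
           if (length(intersect(object@up_genes, object@down_genes)))
             return("up_genes and down_genes must be disjoint")
           TRUE
         })

setMethod("show", "ConsistentProfile", function(object) {
  cat("ConsistentProfile '", object@contrast, "': ",
      length(object@up_genes), " up, ", length(object@down_genes),
      " down across ", length(object@tissues_used), " tissue(s) ",
      "(same direction in all; p < ", object@criteria@per_tissue_p,
      " in >= ", 100 * object@criteria@min_frac_significant, "% of tissues)\n",
      sep = "")
})

#' @describeIn ConsistentProfile-class genes in the profile (up then down).
#' @param object,x a `ConsistentProfile`.
#' @export
profileGenes <- function(x) c(x@up_genes, x@down_genes)

#' @describeIn ConsistentProfile-class up-regulated member genes.
#' @export
upGenes <- function(x) x@up_genes

#' @describeIn ConsistentProfile-class down-regulated member genes.
#' @export
downGenes <- function(x) x@down_genes

#' Build a cross-tissue consistent gene profile
#'
#' Genes are evaluated over the intersection of the gene universes of all
#' per-tissue DE tables: a gene is included iff its log2FC sign is identical
#' (and nonzero) in every tissue and `p < per_tissue_p` in at least
#' `min_frac_significant` of the tissues.
#'
#' @param de_tables named list of per-tissue DE tables from [fitDE()] (need
#'   columns gene, log2FC, p).
#' @param criteria a [ConsistencyCriteria].
#' @param contrast label stored on the profile.
#' @return a [ConsistentProfile].
#' @export
buildConsistentProfile <- function(de_tables,
                                   criteria = ConsistencyCriteria(),
                                   contrast = "contrast") {
  if (!length(de_tables))
    stop("buildConsistentProfile: empty tissue list", call. = FALSE)
  if (is.null(names(de_tables)))
    names(de_tables) <- paste0("tissue", seq_along(de_tables))
  genes <- Reduce(intersect, lapply(de_tables, `[[`, "gene"))
  n_tis <- length(de_tables)
  fc <- vapply(de_tables, function(d) d$log2FC[match(genes, d$gene)],
               numeric(length(genes)))
  pv <- vapply(de_tables, function(d) d$p[match(genes, d$gene)],
               numeric(length(genes)))
  fc <- matrix(fc, ncol = n_tis); pv <- matrix(pv, ncol = n_tis)
  sgn <- sign(fc)
  same_dir <- apply(sgn, 1L, function(s) all(s == s[1L]) && s[1L] != 0)
  n_sig <- rowSums(pv < criteria@per_tissue_p)
  pass <- same_dir & (n_sig / n_tis >= criteria@min_frac_significant)
  direction <- ifelse(sgn[, 1L] > 0, "up", ifelse(sgn[, 1L] < 0, "down", "zero"))
  support <- data.frame(gene = genes[pass], direction = direction[pass],
                        n_tissues = rep(n_tis, sum(pass)),
                        n_significant = n_sig[pass],
                        stringsAsFactors = FALSE)
  new("ConsistentProfile", contrast = contrast,
      up_genes = support$gene[support$direction == "up"],
      down_genes = support$gene[support$direction == "down"],
      tissues_used = names(de_tables), support = support, criteria = criteria)
}

#' Upper-tail hypergeometric overlap test
#'
#' For two gene sets drawn from a common universe of size N, tests whether
#' their observed overlap k is larger than expected under independent draws:
#' `p = P(X >= k)` with `X ~ Hypergeometric(N, |A|, |B|)`.
#'
#' @param setA,setB character vectors, subsets of `universe`.
#' @param universe character vector of all eligible genes.
#' @return list with `k` (overlap), `expected` (`|A||B|/N`) and `p`.
#' @examples
#' hypergeometricOverlap(letters[1:5], letters[1:5], letters[1:10])
#' @export
hypergeometricOverlap <- function(setA, setB, universe) {
  setA <- unique(setA); setB <- unique(setB); universe <- unique(universe)
  if (length(setdiff(setA, universe)) || length(setdiff(setB, universe)))
    stop("containment error: sets must be subsets of the universe",
         call. = FALSE)
  N <- length(universe)
  k <- length(intersect(setA, setB))
  list(k = k,
       expected = length(setA) * length(setB) / N,
       p = stats::phyper(k - 1L, length(setA), N - length(setA),
                         length(setB), lower.tail = FALSE))
}

#' Exclusive membership pattern counts across profiles
#'
#' Upset-style summary: for every non-empty combination of the input sets,
#' counts the elements belonging to exactly that combination.  Counts sum to
#' the size of the union.
#'
#' @param sets named list (length >= 2) of character vectors, or of
#'   [ConsistentProfile] objects (their member genes are used).
#' @return data.frame with `pattern` (e.g. `"A&B"`), one logical column per
#'   set, and `n`.
#' @export
profileSetRelations <- function(sets) {
  if (length(sets) < 2L)
    stop("profileSetRelations: need at least 2 profiles", call. = FALSE)
  sets <- lapply(sets, function(s)
    if (is(s, "ConsistentProfile")) profileGenes(s) else as.character(s))
  if (is.null(names(sets)) || any(names(sets) == ""))
    names(sets) <- paste0("set", seq_along(sets))
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  member <- matrix(member, ncol = length(sets),
                   dimnames = list(universe, names(sets)))
  k <- length(sets)
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), k))[-1L, , drop = FALSE]
  names(combos) <- names(sets)
  n <- apply(combos, 1L, function(pat) {
    if (length(universe) == 0L) return(0L)
    sum(apply(member, 1L, function(m) all(m == as.logical(pat))))
  })
  data.frame(pattern = apply(combos, 1L, function(pat)
    paste(names(sets)[as.logical(pat)], collapse = "&")),
    combos, n = as.integer(n), row.names = NULL,
    stringsAsFactors = FALSE)
}

#' Sex-difference DE under alternative SCC groupings
#'
#' Differential expression between a female-side and male-side SCC group in
#' one tissue, with counts of significant genes (BH-adjusted p below
#' `config@p_threshold` and |log2FC| above `config@abs_log2fc_threshold`)
#' partitioned by chromosome class and, optionally, by overlap with a
#' reference contrast's significant gene list.
#'
#' @param se aligned SummarizedExperiment (one tissue, or pre-subset).
#' @param calls calls DataFrame from [inferSCCBatch()] for the same samples.
#' @param female_calls,male_calls SCC call labels selecting the two groups
#'   (e.g. `"XaXi"` vs `"XY"`, or `"X0_LOX"` vs `"X0_LOY"`).
#' @param config a [DEConfig].
#' @param reference_genes optional character vector of significant genes from
#'   a reference contrast for shared/unique partitioning.
#' @return list with `de` (full table), `significant` (gene vector), and
#'   `counts` (data.frame by chromosome class with total/shared/unique).
#' @export
sexDiffDE <- function(se, calls, female_calls = "XaXi", male_calls = "XY",
                      config = DEConfig(), reference_genes = NULL) {
  cd <- colData(se)
  tpm <- assay(se, "tpm")
  sel_f <- calls$reported_sex == "female" & calls$call %in% female_calls
  sel_m <- calls$reported_sex == "male" & calls$call %in% male_calls
  if (sum(sel_f) < config@min_group_size || sum(sel_m) < config@min_group_size)
    stop("group-size error: selectors resolve to fewer than min_group_size ",
         "samples", call. = FALSE)
  # male side is the reference level, so log2FC = female minus male
  jj <- c(which(sel_m), which(sel_f))
  grp <- factor(rep(c("g_male", "g_female"), c(sum(sel_m), sum(sel_f))),
                levels = c("g_male", "g_female"))
  age <- if ("age_years" %in% colnames(cd) &&
             "age_years" %in% config@covariates) cd$age_years[jj] else NULL
  de <- fitDE(tpm[, jj, drop = FALSE], grp, age, config,
              chromosome = rowData(se)$chromosome)
  sig <- de$adj_p < config@p_threshold &
    abs(de$log2FC) > config@abs_log2fc_threshold
  sig[is.na(sig)] <- FALSE
  sig_genes <- de$gene[sig]
  chrom_class <- ifelse(de$chromosome == "X", "chrX",
                        ifelse(de$chromosome == "Y", "chrY", "autosomal"))
  cls <- factor(chrom_class[sig], levels = c("autosomal", "chrX", "chrY"))
  counts <- data.frame(class = levels(cls), n = as.integer(table(cls)),
                       stringsAsFactors = FALSE)
  if (!is.null(reference_genes)) {
    shared <- sig_genes %in% reference_genes
    counts$shared <- as.integer(table(cls[shared]))
    counts$unique <- counts$n - counts$shared
  }
  list(de = de, significant = sig_genes, counts = counts)
}
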