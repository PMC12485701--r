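# Functional sex chromosome complement (SCC) inference.
#
# The classifier is a fixed decision table over three pieces of evidence:
#   X+  : XIST expression tier == "expressed" (>= expressed_min_tpm)
#   Y+  : at least min_y_expressed Y-panel genes in the "expressed" tier
#   ploidy : optional DNA-level X copy number (females / unknown sex only)
# stratified by reported sex.  Low (1-10 TPM) XIST counts as X- for calls but
# is retained in the evidence fields for descriptive tables.

.SCC_CALLS <- c("XaXi", "XaXa", "X0_LOX", "XY", "X0_LOY", "X0_ambiguous",
                "XXY_like", "XX_unexpected", "XY_unexpected")

#' Expression tier thresholds
#'
#' TPM cutpoints defining the three expression tiers used by the classifier:
#' expressed (>= `expressed_min_tpm`, default 10 TPM), not expressed
#' (<= `not_expressed_max_tpm`, default 1 TPM), and low in between.
#'
#' @slot expressed_min_tpm numeric, lower bound (inclusive) of "expressed".
#' @slot not_expressed_max_tpm numeric, upper bound (inclusive) of
#'   "not_expressed".
#' @export
setClass("ExpressionThresholds",
         representation(expressed_min_tpm = "numeric",
                        not_expressed_max_tpm = "numeric"),
         prototype(expressed_min_tpm = 10, not_expressed_max_tpm = 1),
         validity = function(object) {
           if (length(object@expressed_min_tpm) != 1L ||
               length(object@not_expressed_max_tpm) != 1L)
             return("thresholds must be scalar")
           if (!is.finite(object@expressed_min_tpm) ||
               !is.finite(object@not_expressed_max_tpm))
             return("thresholds must be finite")
           if (object@expressed_min_tpm <= 0 || object@not_expressed_max_tpm <= 0)
             return("thresholds must be positive")
           if (object@not_expressed_max_tpm >= object@expressed_min_tpm)
             return("not_expressed_max_tpm must be < expressed_min_tpm")
           TRUE
         })

#' @rdname ExpressionThresholds-class
#' @param expressed_min_tpm,not_expressed_max_tpm tier cutpoints in TPM.
#' @return an `ExpressionThresholds` object.
#' @export
ExpressionThresholds <- function(expressed_min_tpm = 10,
                                 not_expressed_max_tpm = 1) {
  new("ExpressionThresholds",
      expressed_min_tpm = as.numeric(expressed_min_tpm),
      not_expressed_max_tpm = as.numeric(not_expressed_max_tpm))
}

setMethod("show", "ExpressionThresholds", function(object) {
  cat("ExpressionThresholds: expressed >= ", object@expressed_min_tpm,
      " TPM, not expressed <= ", object@not_expressed_max_tpm,
      " TPM, low in between\n", sep = "")
})

#' Marker gene panel for SCC inference
#'
#' XIST marks the presence of an inactive X; the Y panel defaults to the
#' seven broadly expressed, non-pseudoautosomal Y-linked genes DDX3Y, EIF1AY,
#' KDM5D, RPS4Y1, USP9Y, ZFY and UTY.  Presence of an active Y requires at
#' least `min_y_expressed` (default 2) panel genes in the expressed tier.
#'
#' @slot xist_gene character, id/symbol of the XIST gene.
#' @slot y_genes character vector of Y marker gene symbols.
#' @slot min_y_expressed integer, Y genes required for Y presence.
#' @export
setClass("MarkerPanel",
         representation(xist_gene = "character", y_genes = "character",
                        min_y_expressed = "integer"),
         prototype(xist_gene = "XIST",
                   y_genes = c("DDX3Y", "EIF1AY", "KDM5D", "RPS4Y1",
                               "USP9Y", "ZFY", "UTY"),
                   min_y_expressed = 2L),
         validity = function(object) {
           if (!length(object@y_genes)) return("y_genes must be non-empty")
           if (anyDuplicated(object@y_genes)) return("y_genes must be unique")
           if (object@min_y_expressed < 1L ||
               object@min_y_expressed > length(object@y_genes))
             return("min_y_expressed must be in 1..length(y_genes)")
           TRUE
         })

#' @rdname MarkerPanel-class
#' @param xist_gene,y_genes,min_y_expressed see slots.
#' @return a `MarkerPanel` object.
#' @export
MarkerPanel <- function(xist_gene = "XIST",
                        y_genes = c("DDX3Y", "EIF1AY", "KDM5D", "RPS4Y1",
                                    "USP9Y", "ZFY", "UTY"),
                        min_y_expressed = 2L) {
  new("MarkerPanel", xist_gene = xist_gene, y_genes = y_genes,
      min_y_expressed = as.integer(min_y_expressed))
}

setMethod("show", "MarkerPanel", function(object) {
  cat("MarkerPanel: XIST = ", object@xist_gene, "; Y panel (",
      length(object@y_genes), "): ",
      paste(object@y_genes, collapse = ", "),
      "; Y presence requires >= ", object@min_y_expressed,
      " expressed\n", sep = "")
})

#' Assign an expression tier to TPM values
#'
#' @param tpm numeric vector of non-negative finite TPM values.
#' @param thresholds an [ExpressionThresholds] object.
#' @return character vector in `{"expressed","low","not_expressed"}`.
#' @examples
#' expressionTier(c(0, 1, 5, 10, 50), ExpressionThresholds())
#' @export
expressionTier <- function(tpm, thresholds = ExpressionThresholds()) {
  if (!is.numeric(tpm) || any(!is.finite(tpm)) || any(tpm < 0))
    stop("validation error: tpm must be finite and non-negative", call. = FALSE)
  ifelse(tpm >= thresholds@expressed_min_tpm, "expressed",
         ifelse(tpm <= thresholds@not_expressed_max_tpm, "not_expressed", "low"))
}

#' Decide chromosome-Y presence from the marker panel
#'
#' @param marker_tpms named numeric vector of TPM covering every panel Y gene.
#' @param panel a [MarkerPanel].
#' @param thresholds an [ExpressionThresholds].
#' @return list with `present` (logical), `n_expressed`, `n_low`.
#' @export
yPresence <- function(marker_tpms, panel = MarkerPanel(),
                      thresholds = ExpressionThresholds()) {
  missing_genes <- setdiff(panel@y_genes, names(marker_tpms))
  if (length(missing_genes))
    stop("marker-missing error: Y marker gene(s) absent: ",
         paste(missing_genes, collapse = ", "), call. = FALSE)
  tiers <- expressionTier(unname(marker_tpms[panel@y_genes]), thresholds)
  n_expressed <- sum(tiers == "expressed")
  n_low <- sum(tiers == "low")
  list(present = n_expressed >= panel@min_y_expressed,
       n_expressed = n_expressed, n_low = n_low)
}

# The decision table proper.  xplus/yplus are logicals, sex in
# {female, male, unknown}, ploidy in {"1","2","unknown"}.
.sccDecision <- function(xplus, yplus, sex, ploidy) {
  flag <- ""
  call <- if (sex == "female") {
    if (xplus && !yplus) {
      if (ploidy == "1") flag <- "ploidy_inconsistent"
      "XaXi"
    } else if (!xplus && !yplus) {
      switch(ploidy, "2" = "XaXa", "1" = "X0_LOX", "X0_ambiguous")
    } else if (xplus && yplus) "XXY_like" else "XY_unexpected"
  } else if (sex == "male") {
    if (!xplus && yplus) "XY"
    else if (!xplus && !yplus) "X0_LOY"
    else if (xplus && !yplus) "XX_unexpected"
    else "XXY_like"
  } else {
    if (xplus && !yplus) {
      if (ploidy == "1") flag <- "ploidy_inconsistent"
      "XaXi"
    } else if (!xplus && yplus) "XY"
    else if (!xplus && !yplus) "X0_ambiguous"
    else "XXY_like"
  }
  list(call = call, flag = flag)
}

#' Infer the SCC of a single sample
#'
#' Applies the fixed decision table over the XIST tier, Y-panel presence,
#' reported sex, and (for female/unknown sex) X DNA ploidy.  XIST in the low
#' tier counts as not-expressed for the call.  A female sample with expressed
#' XIST but single-X ploidy is called XaXi with a `ploidy_inconsistent` flag
#' and a warning.
#'
#' @param xist_tpm XIST expression in TPM.
#' @param marker_tpms named numeric vector covering the Y panel.
#' @param reported_sex `"female"`, `"male"` or `"unknown"`.
#' @param x_ploidy `"1"`, `"2"` or `"unknown"` (numeric accepted).
#' @param panel a [MarkerPanel].
#' @param thresholds an [ExpressionThresholds].
#' @return one-row [S4Vectors::DataFrame] with the call and evidence fields
#'   (`xist_tpm`, `xist_tier`, `n_y_expressed`, `n_y_low`, `y_mean_tpm`,
#'   `x_ploidy_used`, `reported_sex`, `flags`).
#' @export
inferSCC <- function(xist_tpm, marker_tpms, reported_sex = "unknown",
                     x_ploidy = "unknown", panel = MarkerPanel(),
                     thresholds = ExpressionThresholds()) {
  reported_sex <- match.arg(reported_sex, .SEX_LEVELS)
  x_ploidy <- as.character(x_ploidy)
  if (!(x_ploidy %in% c("1", "2"))) x_ploidy <- "unknown"
  xist_tier <- expressionTier(xist_tpm, thresholds)
  ypr <- yPresence(marker_tpms, panel, thresholds)
  ploidy_used <- if (reported_sex == "male") "unknown" else x_ploidy
  dec <- .sccDecision(xist_tier == "expressed", ypr$present,
                      reported_sex, ploidy_used)
  if (dec$flag == "ploidy_inconsistent")
    warning("inconsistent evidence: XIST expressed with single-X ploidy; ",
            "calling XaXi with flag", call. = FALSE)
  DataFrame(call = dec$call, xist_tpm = as.numeric(xist_tpm),
            xist_tier = xist_tier,
            n_y_expressed = as.integer(ypr$n_expressed),
            n_y_low = as.integer(ypr$n_low),
            y_mean_tpm = mean(unname(marker_tpms[panel@y_genes])),
            x_ploidy_used = ploidy_used, reported_sex = reported_sex,
            flags = dec$flag)
}

# Locate panel genes in a SummarizedExperiment by gene_id or symbol.
.markerRows <- function(se, genes) {
  rd <- rowData(se)
  idx <- match(genes, rd$gene_id)
  miss <- is.na(idx)
  idx[miss] <- match(genes[miss], rd$symbol)
  if (anyNA(idx))
    stop("marker-missing error: marker gene(s) absent from matrix: ",
         paste(genes[is.na(idx)], collapse = ", "), call. = FALSE)
  setNames(idx, genes)
}

#' Infer SCC for every sample of a cohort
#'
#' @param se aligned SummarizedExperiment (see [alignSamples()]) whose colData
#'   carries `reported_sex`, `x_ploidy` and `tissue`.
#' @param panel a [MarkerPanel].
#' @param thresholds an [ExpressionThresholds].
#' @return list with `calls` (DataFrame, one row per sample) and
#'   `proportions` (data.frame of call proportions per tissue x reported sex;
#'   rows for one tissue/sex sum to 1).
#' @export
inferSCCBatch <- function(se, panel = MarkerPanel(),
                          thresholds = ExpressionThresholds()) {
  cd <- colData(se)
  stopifnot(all(c("reported_sex", "tissue") %in% colnames(cd)))
  ploidy <- if ("x_ploidy" %in% colnames(cd)) as.character(cd$x_ploidy)
            else rep("unknown", ncol(se))
  tpm <- assay(se, "tpm")
  xist_idx <- .markerRows(se, panel@xist_gene)
  y_idx <- .markerRows(se, panel@y_genes)
  y_tpm <- tpm[y_idx, , drop = FALSE]
  rownames(y_tpm) <- panel@y_genes
  xist_tpm <- as.numeric(tpm[xist_idx, ])
  xist_tier <- expressionTier(xist_tpm, thresholds)
  y_tiers <- matrix(expressionTier(as.vector(y_tpm), thresholds),
                    nrow = nrow(y_tpm))
  n_y_expressed <- colSums(y_tiers == "expressed")
  n_y_low <- colSums(y_tiers == "low")
  sex <- as.character(cd$reported_sex)
  sex[!(sex %in% c("female", "male"))] <- "unknown"
  ploidy[!(ploidy %in% c("1", "2"))] <- "unknown"
  ploidy_used <- ifelse(sex == "male", "unknown", ploidy)
  dec <- mapply(.sccDecision, xist_tier == "expressed",
                n_y_expressed >= panel@min_y_expressed, sex, ploidy_used,
                SIMPLIFY = FALSE)
  calls <- DataFrame(
    sample_id = colnames(se), tissue = cd$tissue,
    call = vapply(dec, `[[`, character(1), "call"),
    xist_tpm = xist_tpm, xist_tier = xist_tier,
    n_y_expressed = as.integer(n_y_expressed),
    n_y_low = as.integer(n_y_low),
    y_mean_tpm = colMeans(y_tpm),
    x_ploidy_used = ploidy_used, reported_sex = sex,
    flags = vapply(dec, `[[`, character(1), "flag"),
    row.names = colnames(se))

  tab <- table(tissue = calls$tissue, reported_sex = calls$reported_sex,
               call = factor(calls$call, levels = .SCC_CALLS))
  props <- as.data.frame(tab, responseName = "n", stringsAsFactors = FALSE)
  totals <- tapply(props$n, paste(props$tissue, props$reported_sex), sum)
  props$proportion <- props$n / totals[paste(props$tissue, props$reported_sex)]
  props <- props[totals[paste(props$tissue, props$reported_sex)] > 0, ]
  list(calls = calls, proportions = props)
}

#' Flag tissues with low overall sex-chromosome marker signal
#'
#' A tissue is flagged when the median XIST TPM among reported-female samples
#' falls below the expressed threshold, or the median of the mean Y-panel TPM
#' among reported-male samples does.  Such tissues (whole blood and most brain
#' regions in real data) are poor substrates for threshold-based SCC calls.
#'
#' @inheritParams inferSCCBatch
#' @return list with `flagged` (character vector of tissue labels) and
#'   `medians` (data.frame: tissue, median_female_xist, median_male_y,
#'   flagged).
#' @export
flagLowSignalTissues <- function(se, panel = MarkerPanel(),
                                 thresholds = ExpressionThresholds()) {
  cd <- colData(se)
  tpm <- assay(se, "tpm")
  xist <- tpm[.markerRows(se, panel@xist_gene), ]
  ymean <- colMeans(tpm[.markerRows(se, panel@y_genes), , drop = FALSE])
  tissues <- unique(as.character(cd$tissue))
  rows <- lapply(tissues, function(tis) {
    f <- cd$tissue == tis & cd$reported_sex == "female"
    m <- cd$tissue == tis & cd$reported_sex == "male"
    if (!any(f))
      warning("flagLowSignalTissues: no female samples in tissue '", tis,
              "'; XIST criterion skipped", call. = FALSE)
    if (!any(m))
      warning("flagLowSignalTissues: no male samples in tissue '", tis,
              "'; Y criterion skipped", call. = FALSE)
    med_f <- if (any(f)) median(xist[f]) else NA_real_
    med_m <- if (any(m)) median(ymean[m]) else NA_real_
    flagged <- isTRUE(med_f < thresholds@expressed_min_tpm) ||
      isTRUE(med_m < thresholds@expressed_min_tpm)
    data.frame(tissue = tis, median_female_xist = med_f,
               median_male_y = med_m, flagged = flagged,
               stringsAsFactors = FALSE)
  })
  medians <- do.call(rbind, rows)
  list(flagged = medians$tissue[medians$flagged], medians = medians)
}

#' Age association of atypical SCC
#'
#' Two-sided two-sample t-test of age between an atypical SCC group (e.g.
#' X0_LOY) and its typical counterpart (e.g. XY), plus rank correlation of age
#' with XIST TPM and mean Y-panel TPM across the samples of the relevant sex.
#'
#' @param calls calls DataFrame from [inferSCCBatch()].
#' @param annotations sample sheet DataFrame (must include `age_years`).
#' @param sex which reported sex the contrast lives in.
#' @param atypical,typical SCC call labels defining the two groups.
#' @param var_equal use the pooled-variance (classical Student) t-test instead
#'   of the Welch default.
#' @param cor_method correlation method for age vs marker expression.
#' @return list with `age_diff` (atypical minus typical mean age), `t`, `p`,
#'   the 95% confidence interval (`ci_low`, `ci_high`), group sizes,
#'   dropped-missing-age count, and `correlations` (data.frame
#'   with rho and p for XIST and mean-Y expression vs age; NA when degenerate).
#' @export
ageAssociation <- function(calls, annotations, sex = "male",
                           atypical = "X0_LOY", typical = "XY",
                           var_equal = FALSE, cor_method = c("spearman", "pearson")) {
  cor_method <- match.arg(cor_method)
  ann <- as(annotations, "DataFrame")
  age <- ann$age_years[match(calls$sample_id, ann$sample_id)]
  sel <- calls$reported_sex == sex
  grp_a <- sel & calls$call %in% atypical
  grp_t <- sel & calls$call %in% typical
  n_missing <- sum((grp_a | grp_t) & is.na(age))
  a <- age[grp_a & !is.na(age)]
  t_ <- age[grp_t & !is.na(age)]
  if (length(a) < 2L || length(t_) < 2L) {
    warning("ageAssociation: a group has < 2 non-missing ages; test skipped",
            call. = FALSE)
    test <- list(diff = NA_real_, t = NA_real_, p = NA_real_,
                 ci = c(NA_real_, NA_real_))
  } else if (sd(a) == 0 && sd(t_) == 0) {
    # degenerate: no variance; difference is exact, p is 1 iff means equal
    d <- mean(a) - mean(t_)
    test <- list(diff = d, t = if (d == 0) 0 else NA_real_,
                 p = if (d == 0) 1 else NA_real_, ci = c(d, d))
  } else {
    ht <- stats::t.test(a, t_, var.equal = var_equal)
    test <- list(diff = unname(diff(rev(ht$estimate))), t = unname(ht$statistic),
                 p = ht$p.value, ci = as.numeric(ht$conf.int))
  }
  safe_cor <- function(x, y) {
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 3L || sd(x[ok]) == 0 || sd(y[ok]) == 0)
      return(c(rho = NA_real_, p = NA_real_))
    ct <- suppressWarnings(stats::cor.test(x[ok], y[ok], method = cor_method))
    c(rho = unname(ct$estimate), p = ct$p.value)
  }
  cx <- safe_cor(age[sel], calls$xist_tpm[sel])
  cy <- safe_cor(age[sel], calls$y_mean_tpm[sel])
  list(age_diff = test$diff, t = test$t, p = test$p,
       ci_low = test$ci[1L], ci_high = test$ci[2L],
       n_atypical = length(a), n_typical = length(t_),
       n_missing_age = n_missing,
       correlations = data.frame(
         marker = c("xist_tpm", "y_mean_tpm"),
         rho = c(cx[["rho"]], cy[["rho"]]),
         p = c(cx[["p"]], cy[["p"]]),
         stringsAsFactors = FALSE))
}

#' Per-subject tumor vs adjacent-normal marker deltas
#'
#' For every subject contributing both a primary tumor and an adjacent-normal
#' sample, reports `log2((tumor TPM + c) / (adjacent TPM + c))` for XIST and
#' each Y panel gene.
#'
#' @param se aligned SummarizedExperiment with `subject_id` and `sample_type`
#'   in colData.
#' @param panel a [MarkerPanel].
#' @param pseudocount c added to both numerator and denominator TPM.
#' @return data.frame with subject_id, gene, tumor_tpm, normal_tpm,
#'   log2_ratio; empty (with a warning) when no pairs exist.
#' @export
pairedMarkerDelta <- function(se, panel = MarkerPanel(), pseudocount = 0.5) {
  cd <- colData(se)
  stopifnot(all(c("subject_id", "sample_type") %in% colnames(cd)))
  genes <- c(panel@xist_gene, panel@y_genes)
  tpm <- assay(se, "tpm")[.markerRows(se, genes), , drop = FALSE]
  rownames(tpm) <- genes
  tum <- cd$sample_type %in% "primary_tumor"
  adj <- cd$sample_type %in% "adjacent_normal"
  subjects <- intersect(unique(cd$subject_id[tum]), unique(cd$subject_id[adj]))
  if (!length(subjects)) {
    warning("pairedMarkerDelta: no tumor/adjacent-normal pairs found",
            call. = FALSE)
    return(data.frame(subject_id = character(), gene = character(),
                      tumor_tpm = numeric(), normal_tpm = numeric(),
                      log2_ratio = numeric(), stringsAsFactors = FALSE))
  }
  rows <- lapply(subjects, function(s) {
    jt <- which(tum & cd$subject_id == s)[1L]
    ja <- which(adj & cd$subject_id == s)[1L]
    data.frame(subject_id = s, gene = genes,
               tumor_tpm = tpm[, jt], normal_tpm = tpm[, ja],
               log2_ratio = log2((tpm[, jt] + pseudocount) /
                                 (tpm[, ja] + pseudocount)),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, rows)
}
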