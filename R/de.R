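# Differential expression on log2(TPM + c) with voom-style precision weights
# and empirical-Bayes variance moderation.
#
# The model per gene g is weighted least squares
#   y_gj = b0 + b1 * group_j + b2 * age_j + e_gj,  Var(e_gj) = sigma_g^2 / w_gj
# with observation weights w_gj from a fitted mean-variance trend, and the
# per-gene residual variance shrunk toward a pooled prior s0^2 with d0 prior
# degrees of freedom estimated by moment-matching the scaled-F distribution of
# the residual variances (on the log scale).  The moderated statistic is
#   t_g = b1_g / (se_unit_g * s_tilde_g),  df = d0 + d_g.

#' Differential expression configuration
#'
#' @slot pseudocount numeric, c in log2(TPM + c) (default 0.5).
#' @slot covariates character, covariate columns (default "age_years").
#' @slot min_group_size integer, minimum samples per group (default 3).
#' @slot p_threshold numeric, per-tissue significance level (default 0.05).
#' @slot adjust_method character, multiple-testing method ("BH").
#' @slot abs_log2fc_threshold numeric, fold-change cut for sex-difference
#'   counting (default 1, i.e. 2-fold).
#' @slot low_expr_filter numeric, minimum fraction of samples with TPM > 1
#'   for a gene to be tested (default 0.2).
#' @slot variance_moderation logical, empirical-Bayes shrinkage on/off.
#' @slot weights character, "voom" or "unit".
#' @slot trend_span numeric, lowess span of the mean-variance trend.
#' @slot d0_cap_factor numeric, cap on prior df as a multiple of the median
#'   residual df (default 10; guards against infinite shrinkage).
#' @export
setClass("DEConfig",
         representation(pseudocount = "numeric", covariates = "character",
                        min_group_size = "integer", p_threshold = "numeric",
                        adjust_method = "character",
                        abs_log2fc_threshold = "numeric",
                        low_expr_filter = "numeric",
                        variance_moderation = "logical",
                        weights = "character", trend_span = "numeric",
                        d0_cap_factor = "numeric"),
         prototype(pseudocount = 0.5, covariates = "age_years",
                   min_group_size = 3L, p_threshold = 0.05,
                   adjust_method = "BH", abs_log2fc_threshold = 1,
                   low_expr_filter = 0.2, variance_moderation = TRUE,
                   weights = "voom", trend_span = 0.5, d0_cap_factor = 10),
         validity = function(object) {
           if (object@pseudocount <= 0) return("pseudocount must be > 0")
           if (object@min_group_size < 2L) return("min_group_size must be >= 2")
           if (object@p_threshold <= 0 || object@p_threshold >= 1)
             return("p_threshold must be in (0,1)")
           if (!object@adjust_method %in% "BH")
             return("adjust_method must be 'BH'")
           if (!object@weights %in% c("voom", "unit"))
             return("weights must be 'voom' or 'unit'")
           if (object@low_expr_filter < 0 || object@low_expr_filter > 1)
             return("low_expr_filter must be in [0,1]")
           TRUE
         })

#' @rdname DEConfig-class
#' @param ... slot values overriding the defaults (see slots).
#' @return a `DEConfig` object.
#' @export
DEConfig <- function(...) {
  args <- list(...)
  if ("min_group_size" %in% names(args))
    args$min_group_size <- as.integer(args$min_group_size)
  do.call(new, c(list(Class = "DEConfig"), args))
}

setMethod("show", "DEConfig", function(object) {
  cat("DEConfig: log2(TPM + ", object@pseudocount, "), weights = ",
      object@weights, ", moderation = ",
      if (object@variance_moderation) "on" else "off",
      ", min group size = ", object@min_group_size, "\n", sep = "")
})

#' Voom-style precision weights from a mean-variance trend
#'
#' Fits the design to every gene by ordinary least squares, smooths
#' sqrt(residual sd) against mean log-expression with lowess, predicts the sd
#' at each observation's fitted value, and returns weights
#' `predicted sd^-4` (genes x samples).
#'
#' @param logexpr genes x samples matrix of log2(TPM + c).
#' @param design samples x p design matrix (no gene-specific columns).
#' @param span lowess span.
#' @return genes x samples matrix of finite positive weights.
#' @export
precisionWeights <- function(logexpr, design, span = 0.5) {
  logexpr <- as.matrix(logexpr)
  n <- ncol(logexpr)
  p <- ncol(design)
  if (nrow(logexpr) < 2L)
    stop("precisionWeights: need at least 2 genes to fit a trend", call. = FALSE)
  if (n <= p)
    stop("rank error: fewer samples than design columns leaves no residual df",
         call. = FALSE)
  fit <- stats::lm.fit(design, t(logexpr))
  res <- fit$residuals                      # samples x genes
  df <- n - fit$rank
  if (df < 2L)
    stop("rank error: fewer than 2 residual degrees of freedom", call. = FALSE)
  sg <- sqrt(colSums(res^2) / df)
  mean_log <- rowMeans(logexpr)
  lo <- stats::lowess(mean_log, sqrt(sg), f = span)
  fitted <- t(fit$fitted.values)            # genes x samples
  pred_sqrt_sd <- stats::approx(lo$x, lo$y, xout = as.vector(fitted),
                                rule = 2, ties = mean)$y
  pred_sqrt_sd <- pmax(pred_sqrt_sd, 1e-6)
  w <- matrix(pred_sqrt_sd^-4, nrow = nrow(logexpr))
  dimnames(w) <- dimnames(logexpr)
  w
}

# Newton inversion of trigamma, as used for moment-matching the scaled-F
# distribution of residual variances on the log scale.
.trigammaInverse <- function(x) {
  vapply(x, function(xi) {
    if (!is.finite(xi) || xi <= 0) return(Inf)
    if (xi > 1e7) return(1 / sqrt(xi))
    y <- 0.5 + 1 / xi
    for (i in 1:50) {
      tri <- trigamma(y)
      dif <- tri * (1 - tri / xi) / psigamma(y, 2L)
      y <- y + dif
      if (abs(dif) < 1e-8 * y) break
    }
    y
  }, numeric(1))
}

# Moment-matching estimate of (d0, s0^2) from per-gene variances s2 with
# common residual df d.  Returns d0 possibly Inf (caller caps it).
.estimatePrior <- function(s2, d) {
  ok <- is.finite(s2) & s2 > 0
  z <- log(s2[ok])
  e <- z - digamma(d / 2) + log(d / 2)
  evar <- var(e) - trigamma(d / 2)
  if (!is.finite(evar) || evar <= 0) {
    d0 <- Inf
    s02 <- exp(mean(e))
  } else {
    d0 <- 2 * .trigammaInverse(evar)
    s02 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  }
  list(d0 = d0, s02 = s02)
}

#' Fit per-gene differential expression for one tissue
#'
#' Weighted least squares of log2(TPM + c) on a two-level group indicator
#' plus covariates, with voom-style precision weights and empirical-Bayes
#' variance moderation (both optional via `config`).  P-values are two-sided
#' from the moderated t with `d0 + d_g` degrees of freedom and BH-adjusted
#' across tested genes.
#'
#' @param tpm genes x samples TPM matrix (rownames = gene ids).
#' @param group factor/character with exactly 2 levels; the reported log2 fold
#'   change is level 2 minus level 1.
#' @param age optional numeric covariate (dropped with a warning when any
#'   value is missing).
#' @param config a [DEConfig].
#' @param chromosome optional character vector of chromosome labels per gene,
#'   carried into the result.
#' @return data.frame with gene, log2FC, se, s2, df, t, p, adj_p, direction,
#'   mean_log_expr (and chromosome when given); attribute `n_filtered` counts
#'   genes removed by the low-expression filter.
#' @export
fitDE <- function(tpm, group, age = NULL, config = DEConfig(),
                  chromosome = NULL) {
  tpm <- as.matrix(tpm)
  group <- factor(group)
  if (nlevels(group) != 2L)
    stop("fitDE: group must have exactly 2 levels", call. = FALSE)
  sizes <- table(group)
  if (any(sizes < config@min_group_size))
    stop("group-size error: group(s) below min_group_size (",
         config@min_group_size, "): ",
         paste(names(sizes)[sizes < config@min_group_size], collapse = ", "),
         call. = FALSE)
  if (!is.null(age) && anyNA(age)) {
    warning("fitDE: missing ages; age covariate dropped", call. = FALSE)
    age <- NULL
  }
  keep <- rowMeans(tpm > 1) >= config@low_expr_filter
  n_filtered <- sum(!keep)
  if (!any(keep)) stop("fitDE: no genes pass the expression filter", call. = FALSE)
  if (!is.null(chromosome)) chromosome <- chromosome[keep]
  tpm <- tpm[keep, , drop = FALSE]

  y <- log2(tpm + config@pseudocount)
  design <- cbind(`(Intercept)` = 1, group = as.numeric(group == levels(group)[2L]))
  if (!is.null(age)) design <- cbind(design, age = as.numeric(age))
  n <- ncol(y); p <- ncol(design)
  if (n <= p) stop("rank error: not enough samples for the design", call. = FALSE)

  w <- if (config@weights == "voom" && nrow(y) >= 2L)
    precisionWeights(y, design, span = config@trend_span)
  else matrix(1, nrow(y), n)

  G <- nrow(y)
  b1 <- se_unit <- s2 <- numeric(G)
  for (g in seq_len(G)) {
    fg <- stats::lm.wfit(design, y[g, ], w[g, ])
    dfres <- n - fg$rank
    rss <- sum(w[g, ] * fg$residuals^2)
    s2[g] <- rss / dfres
    XtWX <- crossprod(design * w[g, ], design)
    cov_unit <- tryCatch(solve(XtWX), error = function(e) NULL)
    if (is.null(cov_unit)) { b1[g] <- NA; se_unit[g] <- NA; next }
    b1[g] <- fg$coefficients[["group"]]
    se_unit[g] <- sqrt(cov_unit["group", "group"])
  }
  dg <- n - p

  # genes numerically constant within the fit: effect and variance are both
  # floating-point dust; report a null result rather than 0/0 artifacts
  scale_y <- pmax(1, abs(rowMeans(y)))
  tiny <- sqrt(s2) < 1e-10 * scale_y & abs(b1) < 1e-10 * scale_y
  b1[tiny] <- 0
  s2[tiny] <- 0

  if (config@variance_moderation) {
    prior <- .estimatePrior(s2, dg)
    d0 <- min(prior$d0, config@d0_cap_factor * dg)
    s2_tilde <- (d0 * prior$s02 + dg * s2) / (d0 + dg)
    tval <- b1 / (se_unit * sqrt(s2_tilde))
    df_total <- d0 + dg
  } else {
    s2_tilde <- s2
    tval <- b1 / (se_unit * sqrt(s2))
    df_total <- dg
  }
  # genes with zero residual variance and zero effect are undefined (0/0)
  tval[!is.finite(tval) & b1 == 0] <- 0
  pval <- 2 * stats::pt(-abs(tval), df_total)
  pval[s2_tilde == 0 & b1 == 0] <- 1
  adj <- stats::p.adjust(pval, method = config@adjust_method)
  out <- data.frame(gene = rownames(y), log2FC = b1,
                    se = se_unit * sqrt(s2_tilde), s2 = s2, df = dg,
                    t = tval, p = pval, adj_p = adj,
                    direction = c("down", "zero", "up")[sign(b1) + 2],
                    mean_log_expr = rowMeans(y),
                    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(chromosome)) out$chromosome <- chromosome
  attr(out, "n_filtered") <- n_filtered
  attr(out, "df_prior") <- if (config@variance_moderation) df_total - dg else 0
  out
}

#' Per-tissue DE for an SCC contrast across a cohort
#'
#' Runs [fitDE()] within each tissue between two SCC call groups, skipping
#' (and recording) tissues where either group has fewer than
#' `config@min_group_size` samples.
#'
#' @param se aligned SummarizedExperiment.
#' @param calls calls DataFrame from [inferSCCBatch()].
#' @param group1,group2 character vectors of SCC call labels; log2FC is
#'   group2 minus group1.
#' @param sex1,sex2 reported sex required for each group (defaults derive
#'   from typical usage; pass `NULL` to skip the sex filter).
#' @param config a [DEConfig].
#' @return named list of per-tissue DE tables; attribute `skipped` lists
#'   tissues without enough samples.
#' @export
fitDEPerTissue <- function(se, calls, group1, group2, sex1 = NULL, sex2 = NULL,
                           config = DEConfig()) {
  cd <- colData(se)
  tpm <- assay(se, "tpm")
  chrom <- rowData(se)$chromosome
  sel1 <- calls$call %in% group1 & (if (is.null(sex1)) TRUE else calls$reported_sex %in% sex1)
  sel2 <- calls$call %in% group2 & (if (is.null(sex2)) TRUE else calls$reported_sex %in% sex2)
  tissues <- unique(as.character(cd$tissue))
  out <- list(); skipped <- character()
  for (tis in tissues) {
    in_tis <- cd$tissue == tis
    j1 <- which(in_tis & sel1); j2 <- which(in_tis & sel2)
    if (length(j1) < config@min_group_size || length(j2) < config@min_group_size) {
      skipped <- c(skipped, tis); next
    }
    jj <- c(j1, j2)
    grp <- factor(rep(c("g1", "g2"), c(length(j1), length(j2))),
                  levels = c("g1", "g2"))
    age <- if ("age_years" %in% colnames(cd) &&
               "age_years" %in% config@covariates) cd$age_years[jj] else NULL
    out[[tis]] <- fitDE(tpm[, jj, drop = FALSE], grp, age, config,
                        chromosome = chrom)
  }
  if (length(skipped))
    message("fitDEPerTissue: skipped tissue(s) with undersized groups: ",
            paste(skipped, collapse = ", "))
  attr(out, "skipped") <- skipped
  out
}
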