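# Kaplan-Meier estimation, median survival, and log-rank tests across SCC
# groups.  The estimator and tests are computed by the survival package
# (survfit/survdiff); this module fixes the conventions (tie aggregation,
# median definition, BH-adjusted pairwise tests) and the KMCurve container.

#' Kaplan-Meier curve
#'
#' Product-limit estimate for one group: all distinct observed times with
#' at-risk counts, event counts, censoring counts and the survival step
#' function.  `S(0) = 1`; S is non-increasing and steps only at event times.
#'
#' @slot time numeric, increasing distinct observed times.
#' @slot surv numeric, S(t) at each time.
#' @slot n_risk,n_event,n_censor integer counts per time.
#' @slot n integer, subjects entering.
#' @export
setClass("KMCurve",
         representation(time = "numeric", surv = "numeric",
                        n_risk = "integer", n_event = "integer",
                        n_censor = "integer", n = "integer"),
         validity = function(object) {
           if (is.unsorted(object@time, strictly = TRUE))
             return("times must be strictly increasing")
           if (any(object@surv < 0 | object@surv > 1))
             return("survival must lie in [0,1]")
           if (is.unsorted(rev(object@surv)))
             return("survival must be non-increasing")
           TRUE
         })

setMethod("show", "KMCurve", function(object) {
  med <- medianSurvival(object)
  cat("KMCurve: n = ", object@n, ", events = ", sum(object@n_event),
      ", median = ", if (is.na(med)) "not reached" else med, "\n", sep = "")
})

#' @describeIn KMCurve-class event times (times with at least one event).
#' @param x a `KMCurve`.
#' @export
eventTimes <- function(x) x@time[x@n_event > 0L]

#' Kaplan-Meier estimate for one group
#'
#' Ties are aggregated exactly (censoring at an event time is processed after
#' the events); censored-only times reduce the at-risk count without a step.
#'
#' @param time positive survival times (days).
#' @param event event indicator: 1/TRUE = death, 0/FALSE = censored.
#' @return a [KMCurve].
#' @examples
#' kmEstimate(c(1, 2, 3, 4), c(1, 1, 1, 1))
#' @export
kmEstimate <- function(time, event) {
  if (any(!is.finite(time)) || any(time <= 0))
    stop("validation error: survival times must be positive and finite",
         call. = FALSE)
  event <- as.integer(as.logical(event))
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  new("KMCurve", time = as.numeric(fit$time), surv = as.numeric(fit$surv),
      n_risk = as.integer(fit$n.risk), n_event = as.integer(fit$n.event),
      n_censor = as.integer(fit$n.censor), n = as.integer(fit$n))
}

#' Median survival from a KM curve
#'
#' The smallest event time at which the survival estimate is <= 0.5 (the
#' convention of the survival package); with `strict = TRUE`, requires
#' S(t) strictly below 0.5.  `NA` when the curve never reaches the cut
#' (median not reached).
#'
#' @param curve a [KMCurve].
#' @param strict require S(t) < 0.5 instead of <= 0.5.
#' @return numeric time, or `NA` when not reached.
#' @export
medianSurvival <- function(curve, strict = FALSE) {
  ev <- curve@n_event > 0L
  hit <- if (strict) curve@surv < 0.5 else curve@surv <= 0.5
  idx <- which(ev & hit)
  if (!length(idx)) return(NA_real_)
  curve@time[idx[1L]]
}

#' Global k-sample log-rank test
#'
#' @param time positive survival times.
#' @param event event indicator (1 = death, 0 = censored).
#' @param group group labels (k >= 2).
#' @return list with `chisq`, `df` (= k-1), `p`, and per-group `observed` /
#'   `expected` event counts.
#' @export
logrankGlobal <- function(time, event, group) {
  group <- factor(as.character(group))
  if (nlevels(group) < 2L)
    stop("logrankGlobal: need at least 2 groups", call. = FALSE)
  if (any(time <= 0) || any(!is.finite(time)))
    stop("validation error: survival times must be positive and finite",
         call. = FALSE)
  sd_ <- survival::survdiff(
    survival::Surv(time, as.integer(as.logical(event))) ~ group)
  df <- nlevels(group) - 1L
  obs <- setNames(as.numeric(sd_$obs), levels(group))
  expd <- setNames(as.numeric(sd_$exp), levels(group))
  list(chisq = unname(sd_$chisq), df = df,
       p = stats::pchisq(sd_$chisq, df, lower.tail = FALSE),
       observed = obs, expected = expd)
}

#' Pairwise log-rank tests with multiplicity adjustment
#'
#' Two-sample log-rank for every unordered pair of groups, adjusted across
#' the `choose(k, 2)` tests (BH by default).  Pairs with no events are
#' reported as missing.
#'
#' @inheritParams logrankGlobal
#' @param adjust_method method for [stats::p.adjust()] (default "BH").
#' @return data.frame (group1, group2, chisq, p, adj_p).
#' @export
logrankPairwise <- function(time, event, group, adjust_method = "BH") {
  group <- factor(as.character(group))
  if (nlevels(group) < 2L)
    stop("logrankPairwise: need at least 2 groups", call. = FALSE)
  event <- as.integer(as.logical(event))
  pairs <- utils::combn(levels(group), 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    g1 <- pairs[1L, i]; g2 <- pairs[2L, i]
    sel <- group %in% c(g1, g2)
    if (sum(event[sel]) == 0L)
      return(data.frame(group1 = g1, group2 = g2, chisq = NA_real_,
                        p = NA_real_, stringsAsFactors = FALSE))
    sd_ <- survival::survdiff(
      survival::Surv(time[sel], event[sel]) ~ droplevels(group[sel]))
    data.frame(group1 = g1, group2 = g2, chisq = unname(sd_$chisq),
               p = stats::pchisq(sd_$chisq, 1L, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$adj_p <- stats::p.adjust(out$p, method = adjust_method)
  out
}

#' SCC-stratified survival analysis
#'
#' Builds the five sex-by-SCC groups from calls and clinical annotations
#' (ambiguous/unexpected calls excluded), estimates a KM curve and median per
#' group, and runs the global and BH-adjusted pairwise log-rank tests.
#'
#' @param calls calls DataFrame from [inferSCCBatch()].
#' @param annotations sample sheet DataFrame with `survival_days` and `event`.
#' @param min_group_size groups smaller than this are dropped (default 2).
#' @return list with `curves` (named list of [KMCurve]), `medians`
#'   (data.frame), `global` (from [logrankGlobal()]), `pairwise` (from
#'   [logrankPairwise()]), and `records` (the analysis table).
#' @export
survivalBySCC <- function(calls, annotations, min_group_size = 2L) {
  ann <- as(annotations, "DataFrame")
  idx <- match(calls$sample_id, ann$sample_id)
  rec <- data.frame(sample_id = calls$sample_id,
                    group = sccGroup(calls),
                    time = ann$survival_days[idx],
                    event = ann$event[idx],
                    stringsAsFactors = FALSE)
  rec <- rec[!is.na(rec$group) & !is.na(rec$time) & !is.na(rec$event) &
               rec$time > 0, ]
  keep <- names(which(table(rec$group) >= min_group_size))
  rec <- rec[rec$group %in% keep, ]
  if (length(unique(rec$group)) < 2L)
    stop("survivalBySCC: fewer than 2 usable groups", call. = FALSE)
  curves <- lapply(split(rec, rec$group),
                   function(d) kmEstimate(d$time, d$event))
  medians <- data.frame(group = names(curves),
                        n = as.integer(table(rec$group)[names(curves)]),
                        events = vapply(split(rec, rec$group),
                                        function(d) sum(d$event), numeric(1)),
                        median_days = vapply(curves, medianSurvival, numeric(1)),
                        row.names = NULL, stringsAsFactors = FALSE)
  list(curves = curves, medians = medians,
       global = logrankGlobal(rec$time, rec$event, rec$group),
       pairwise = logrankPairwise(rec$time, rec$event, rec$group),
       records = rec)
}
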