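# Survival analysis primitives: the product-limit (Kaplan-Meier)
# estimator, the k-group log-rank test with hypergeometric variance, the
# strict OS < 1 month exclusion, and a maximally-selected two-group
# cutpoint search. Implemented directly (no dependency on the survival
# package, which serves only as a test oracle). Time unit is months
# throughout; convert days with /30.44 at the I/O layer.

#' Remove cases with short follow-up
#'
#' Rows with `os_months` strictly below `min_months` are removed before
#' survival analysis.
#'
#' @param clinical a `ClinicalTable`.
#' @param min_months strict threshold in months (default 1).
#' @return the filtered table, original order preserved.
#' @export
filter_min_followup <- function(clinical, min_months = 1) {
  out <- clinical[clinical$os_months >= min_months, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Kaplan-Meier product-limit estimate
#'
#' `S(t) = prod over event times t_i <= t of (1 - d_i / n_i)`; subjects
#' censored at a time leave the risk set after that time.
#'
#' @param times non-negative follow-up times.
#' @param events 0/1 event indicators (1 = death).
#' @return object of class `SurvivalCurve`: list with `time` (distinct
#'   event times, sorted), `surv`, `n_risk`, `n_event`, and `n` (sample
#'   size). `S(0) = 1` implicitly; see [km_surv_at()].
#' @export
km_estimate <- function(times, events) {
  if (length(times) < 1L) stop("need at least one subject")
  if (any(times < 0)) stop("negative survival time")
  if (!all(events %in% c(0, 1))) stop("events must be 0/1")
  et <- sort(unique(times[events == 1]))
  n_risk <- vapply(et, function(t) sum(times >= t), numeric(1))
  n_event <- vapply(et, function(t) sum(times == t & events == 1), numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  structure(list(time = et, surv = surv, n_risk = n_risk,
                 n_event = n_event, n = length(times)),
            class = "SurvivalCurve")
}

#' Evaluate a survival curve at given times
#' @param curve a `SurvivalCurve`.
#' @param t numeric vector of times.
#' @return `S(t)` (right-continuous step function, `S(0) = 1`).
#' @export
km_surv_at <- function(curve, t) {
  idx <- findInterval(t, curve$time)
  c(1, curve$surv)[idx + 1L]
}

#' Median survival of a curve
#' @param curve a `SurvivalCurve`.
#' @return smallest event time with `S(t) <= 0.5`, or NA if never reached.
#' @export
km_median <- function(curve) {
  i <- which(curve$surv <= 0.5)
  if (length(i)) curve$time[i[1]] else NA_real_
}

#' @export
print.SurvivalCurve <- function(x, ...) {
  cat(sprintf("SurvivalCurve: n = %d, %d event time(s), median = %s\n",
              x$n, length(x$time), format(km_median(x))))
  invisible(x)
}

#' k-group log-rank test
#'
#' At each distinct event time the expected events per group are
#' `d_t * n_gt / n_t`; the statistic is the (k-1)-dimensional quadratic
#' form with the hypergeometric covariance, referred to a chi-square
#' distribution with k-1 degrees of freedom. Ties are handled by the
#' standard hypergeometric variance.
#'
#' @param groups list of length >= 2; each element a list/data.frame with
#'   numeric `times` and 0/1 `events`.
#' @return object of class `LogRankResult`: `statistic`, `df`, `p_value`,
#'   `observed`, `expected` (per group), `n` (per group).
#' @export
logrank_test <- function(groups) {
  if (length(groups) < 2L) stop("need >= 2 groups")
  ns <- vapply(groups, function(g) length(g$times), integer(1))
  if (any(ns == 0L)) stop("group with 0 subjects")
  k <- length(groups)
  times <- unlist(lapply(groups, function(g) g$times))
  events <- unlist(lapply(groups, function(g) g$events))
  grp <- rep(seq_len(k), ns)
  if (any(times < 0)) stop("negative survival time")
  if (!all(events %in% c(0, 1))) stop("events must be 0/1")
  if (sum(events) == 0) stop("no events in any group")

  td <- sort(unique(times[events == 1]))
  nt <- length(td)
  # at-risk counts: per group, number with time >= td
  n_gt <- matrix(0, k, nt)
  d_gt <- matrix(0, k, nt)
  for (g in seq_len(k)) {
    tg <- times[grp == g]; eg <- events[grp == g]
    st <- sort(tg)
    n_gt[g, ] <- length(tg) - findInterval(td, st, left.open = TRUE)
    de <- tg[eg == 1]
    if (length(de)) d_gt[g, ] <- vapply(td, function(t) sum(de == t), numeric(1))
  }
  n_t <- colSums(n_gt)
  d_t <- colSums(d_gt)

  O <- rowSums(d_gt)
  E <- rowSums(sweep(n_gt, 2, d_t / n_t, "*"))
  # covariance: sum_t c_t (diag(p_t) - p_t p_t'), c_t = d_t (n_t - d_t)/(n_t - 1)
  c_t <- ifelse(n_t > 1, d_t * (n_t - d_t) / (n_t - 1), 0)
  P <- sweep(n_gt, 2, n_t, "/")
  V <- diag(as.vector(P %*% c_t), k) - (P %*% (c_t * t(P)))

  u <- (O - E)[-k]
  Vs <- V[-k, -k, drop = FALSE]
  stat <- tryCatch(drop(t(u) %*% solve(Vs, u)),
                   error = function(e) {
                     sv <- svd(Vs)
                     pos <- sv$d > max(sv$d) * 1e-10
                     ginv <- sv$v[, pos, drop = FALSE] %*%
                       (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
                     drop(t(u) %*% ginv %*% u)
                   })
  df <- k - 1L
  structure(list(statistic = stat, df = df,
                 p_value = stats::pchisq(stat, df, lower.tail = FALSE),
                 observed = O, expected = E, n = ns),
            class = "LogRankResult")
}

#' @export
print.LogRankResult <- function(x, ...) {
  cat(sprintf("Log-rank: chi-square = %.4g on %d df, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Log-rank test from a grouping vector
#' @param times,events follow-up times and 0/1 indicators.
#' @param group grouping vector (>= 2 levels present).
#' @return a `LogRankResult`.
#' @export
logrank_test_by <- function(times, events, group) {
  group <- as.character(group)
  lv <- unique(group)
  logrank_test(lapply(lv, function(g)
    list(times = times[group == g], events = events[group == g])))
}

#' Maximally selected survival cutpoint
#'
#' Scans candidate thresholds at observed values of a continuous marker;
#' a threshold splits samples into `value <= threshold` vs `>`; only
#' splits leaving both groups with at least `minprop` of the samples are
#' admissible. Returns the threshold maximizing the two-group log-rank
#' statistic (ties broken toward the lower threshold). No selection-bias
#' correction is applied to the reported p-value: the scan is exploratory.
#'
#' @param values named numeric vector, sample id -> marker value.
#' @param clinical a `ClinicalTable` covering those samples.
#' @param minprop minimum group fraction (default 0.1).
#' @return object of class `CutpointResult`: `threshold`,
#'   `max_statistic`, `p_value` (uncorrected, exploratory),
#'   `group_sizes`, and the full `scan` data.frame.
#' @export
optimal_cutpoint <- function(values, clinical, minprop = 0.1) {
  ids <- intersect(names(values), clinical$sample_id)
  if (length(ids) < 10L) stop("need >= 10 samples with follow-up")
  v <- values[ids]
  cl <- clinical[match(ids, clinical$sample_id), ]
  cand <- sort(unique(v))
  cand <- cand[-length(cand)]  # top value would leave an empty group
  n <- length(v)
  ok <- vapply(cand, function(th) {
    nl <- sum(v <= th)
    nl >= minprop * n && (n - nl) >= minprop * n
  }, logical(1))
  cand <- cand[ok]
  if (!length(cand)) stop("no admissible threshold")
  stats_ <- vapply(cand, function(th) {
    logrank_test_by(cl$os_months, cl$os_event, v <= th)$statistic
  }, numeric(1))
  best <- which.max(stats_)  # first max -> lowest threshold on ties
  th <- cand[best]
  structure(list(threshold = th, max_statistic = stats_[best],
                 p_value = stats::pchisq(stats_[best], 1, lower.tail = FALSE),
                 group_sizes = c(low = sum(v <= th), high = sum(v > th)),
                 scan = data.frame(threshold = cand, statistic = stats_)),
            class = "CutpointResult")
}
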