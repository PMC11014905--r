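# Kaplan-Meier machinery, written from first principles: product-limit
# estimate, Greenwood variance, log-log pointwise intervals.

#' Kaplan-Meier product-limit fit
#'
#' Estimates the survival function at each distinct event time, with the
#' Greenwood variance and pointwise confidence intervals on the
#' complementary log-log scale (which keeps the bounds inside \[0, 1\]).
#'
#' @param time Follow-up times in months (nonnegative).
#' @param event Logical or 0/1 event indicators.
#' @param conf_level Pointwise confidence level; default 0.95.
#' @return Object of class `km_curve`: data.frame `steps` with columns
#'   `time`, `n_risk`, `n_event`, `surv`, `se`, `lower`, `upper` (one row per
#'   distinct event time), plus `n`, `max_time`, `conf_level`.
#' @export
km_fit <- function(time, event, conf_level = 0.95) {
  event <- as.logical(event)
  if (length(time) < 1L || all(!is.finite(time)))
    stop("no usable survival times", call. = FALSE)
  stopifnot(length(time) == length(event), all(is.finite(time)), all(time >= 0))
  ord <- order(time)
  time <- time[ord]; event <- event[ord]
  n <- length(time)
  ut <- sort(unique(time[event]))
  n_risk <- n_event <- integer(length(ut))
  for (i in seq_along(ut)) {
    n_risk[i] <- sum(time >= ut[i])
    n_event[i] <- sum(time == ut[i] & event)
  }
  frac <- 1 - n_event / n_risk
  surv <- cumprod(frac)
  # Greenwood: var(S) = S^2 * sum d / (n (n - d))
  gw <- cumsum(n_event / (n_risk * pmax(n_risk - n_event, 0)))
  gw[!is.finite(gw)] <- Inf
  se <- surv * sqrt(gw)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  lower <- upper <- rep(NA_real_, length(ut))
  pos <- surv > 0 & surv < 1 & is.finite(gw)
  # CI on log(-log S): se_cll = se(S) / |S log S|
  se_cll <- se[pos] / abs(surv[pos] * log(surv[pos]))
  lower[pos] <- surv[pos]^exp(z * se_cll)
  upper[pos] <- surv[pos]^exp(-z * se_cll)
  zero <- surv == 0
  lower[zero] <- 0; upper[zero] <- 0
  structure(list(steps = data.frame(time = ut, n_risk = n_risk,
                                    n_event = n_event, surv = surv, se = se,
                                    lower = lower, upper = upper),
                 n = n, max_time = max(time), conf_level = conf_level),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("km_curve: n = %d, %d event times, max follow-up %.1f\n",
              x$n, nrow(x$steps), x$max_time))
  invisible(x)
}

#' Evaluate a Kaplan-Meier curve at a time point
#'
#' Step-function evaluation with the pointwise interval carried from the
#' last event time at or before `t`. Evaluation beyond the last observed
#' follow-up returns the last estimate with `truncated = TRUE`.
#'
#' @param curve A `km_curve`.
#' @param t Time in months, `t >= 0`.
#' @return List with `estimate`, `lower`, `upper`, `truncated`.
#' @export
survival_at <- function(curve, t) {
  stopifnot(inherits(curve, "km_curve"), is.finite(t), t >= 0)
  st <- curve$steps
  i <- findInterval(t, st$time)
  if (i == 0L) return(list(estimate = 1, lower = 1, upper = 1, truncated = FALSE))
  list(estimate = st$surv[i], lower = st$lower[i], upper = st$upper[i],
       truncated = t > curve$max_time)
}

#' Median follow-up by the reverse Kaplan-Meier method
#'
#' Applies the product-limit estimator to the censoring distribution (event
#' indicator inverted) and reads off its median: the smallest time at which
#' the censoring-survival estimate drops to 0.5 or below.
#'
#' @param time Follow-up times in months.
#' @param event Event indicators (deaths); censorings are the "events" of the
#'   reversed fit.
#' @return List with `median` (months; NA when not reached) and `reached`.
#' @export
reverse_km_median_followup <- function(time, event) {
  fit <- km_fit(time, !as.logical(event))
  st <- fit$steps
  hit <- which(st$surv <= 0.5)
  if (length(hit) == 0L) return(list(median = NA_real_, reached = FALSE))
  list(median = st$time[hit[1]], reached = TRUE)
}

#' Log-rank test for two or more groups
#'
#' The standard (unweighted) log-rank statistic: at each distinct event time
#' the observed events per group are compared with their hypergeometric
#' expectation given the risk sets, and the accumulated differences are
#' combined through the estimated covariance matrix. With `pairwise = TRUE`
#' and three or more groups, the three two-group tests are also returned,
#' unadjusted for multiplicity (a Holm adjustment is available via
#' `p_adjust`).
#'
#' @param time Follow-up times.
#' @param event Event indicators.
#' @param group Group labels (two or more levels, each nonempty).
#' @param pairwise Also compute all two-group comparisons.
#' @param p_adjust Adjustment for the pairwise p-values as in
#'   [stats::p.adjust()]; default `"none"`.
#' @return List with `chisq`, `df`, `p`, `observed`, `expected` and, when
#'   requested, `pairwise` (data.frame `group1`, `group2`, `chisq`, `p`).
#' @export
logrank_test <- function(time, event, group, pairwise = FALSE,
                         p_adjust = "none") {
  event <- as.logical(event)
  group <- as.factor(droplevels(as.factor(group)))
  if (nlevels(group) < 2L) stop("need at least two groups", call. = FALSE)
  if (any(table(group) == 0L)) stop("every group needs at least one subject",
                                    call. = FALSE)
  res <- logrank_core(time, event, group)
  if (pairwise) {
    lv <- levels(group)
    pairs <- utils::combn(lv, 2, simplify = FALSE)
    pw <- do.call(rbind, lapply(pairs, function(pr) {
      sel <- group %in% pr
      r <- logrank_core(time[sel], event[sel], droplevels(group[sel]))
      data.frame(group1 = pr[1], group2 = pr[2], chisq = r$chisq, p = r$p,
                 stringsAsFactors = FALSE)
    }))
    pw$p <- stats::p.adjust(pw$p, method = p_adjust)
    res$pairwise <- pw
  }
  res
}

logrank_core <- function(time, event, group) {
  lv <- levels(group)
  k <- length(lv)
  ut <- sort(unique(time[event]))
  O <- E <- stats::setNames(numeric(k), lv)
  V <- matrix(0, k, k, dimnames = list(lv, lv))
  for (t in ut) {
    at_risk <- time >= t
    n_t <- sum(at_risk)
    d_t <- sum(time == t & event)
    n_g <- vapply(lv, function(g) sum(at_risk & group == g), numeric(1))
    d_g <- vapply(lv, function(g) sum(time == t & event & group == g), numeric(1))
    O <- O + d_g
    E <- E + d_t * n_g / n_t
    if (n_t > 1L) {
      c_t <- d_t * (n_t - d_t) / (n_t - 1)
      p_g <- n_g / n_t
      V <- V + c_t * (diag(p_g, k) - tcrossprod(p_g))
    }
  }
  u <- (O - E)[-k]
  vi <- V[-k, -k, drop = FALSE]
  chisq <- if (all(abs(u) < 1e-12)) 0 else
    as.numeric(t(u) %*% solve(vi, u))
  list(chisq = chisq, df = k - 1L,
       p = stats::pchisq(chisq, df = k - 1L, lower.tail = FALSE),
       observed = O, expected = E)
}

#' Censor follow-up at an intervening event
#'
#' Replaces each subject's observation by the intervening-event time (as a
#' censoring) whenever that event precedes, or ties with, the observed
#' endpoint. A tie is resolved toward censoring: the subject did reach the
#' intervening event. Never increases a time and never creates events.
#'
#' @param time Observed follow-up times.
#' @param event Event indicators.
#' @param intervening_time Per-subject intervening-event times; NA when no
#'   intervening event occurred.
#' @return List with adjusted `time` and `event` vectors.
#' @export
censor_at_event <- function(time, event, intervening_time) {
  event <- as.logical(event)
  stopifnot(length(time) == length(event),
            length(intervening_time) == length(time))
  bad <- which(!is.na(intervening_time) & intervening_time > time + 1e-9)
  if (length(bad))
    stop("intervening_time exceeds observed time for subject ", bad[1],
         call. = FALSE)
  hit <- !is.na(intervening_time)
  time[hit] <- intervening_time[hit]
  event[hit] <- FALSE
  list(time = time, event = event)
}
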