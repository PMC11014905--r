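# Harrell's concordance for censored data and the paired comparison of two
# correlated concordance indices via a leave-one-out jackknife.

# pairwise contribution matrices: comp[i, j] = 1 when subject i's event
# makes the pair (i, j) usable (t_i < t_j, or t_i == t_j with j censored);
# conc[i, j] = 1 / 0.5 / 0 as the score orders the pair correctly / ties /
# inverts it (higher score must mean earlier event)
concordance_pairs <- function(score, time, event) {
  event <- as.logical(event)
  n <- length(time)
  ti <- matrix(time, n, n)
  tj <- t(ti)
  ei <- matrix(event, n, n)
  ej <- t(ei)
  comp <- ei & (ti < tj | (ti == tj & !ej))
  diag(comp) <- FALSE
  si <- matrix(score, n, n)
  sj <- t(si)
  conc <- (si > sj) + 0.5 * (si == sj)
  list(comp = comp, conc = conc * comp)
}

#' Harrell's concordance index
#'
#' The proportion of usable subject pairs ordered correctly by a risk score:
#' a pair is usable when the subject with the shorter follow-up had the
#' event; it is concordant when that subject also carries the higher score.
#' Ties in the score count one half. Invariant to strictly monotone
#' transformations of the score.
#'
#' @param score Risk score per subject (higher = higher risk).
#' @param time Follow-up times.
#' @param event Event indicators.
#' @return List with `c` (index in \[0, 1\]), `concordant` (weighted count)
#'   and `comparable` (usable-pair count).
#' @export
harrell_c <- function(score, time, event) {
  stopifnot(length(score) == length(time), length(time) == length(event))
  pr <- concordance_pairs(score, time, event)
  m <- sum(pr$comp)
  if (m == 0L) stop("no comparable pairs under censoring", call. = FALSE)
  list(c = sum(pr$conc) / m, concordant = sum(pr$conc), comparable = m)
}

#' Compare two correlated concordance indices
#'
#' Paired comparison of the concordance of two risk scores evaluated on the
#' same subjects: reports the difference `delta = C_b - C_a`, a leave-one-out
#' jackknife standard error of the difference, and a two-sided
#' normal-approximation p-value.
#'
#' @param score_a,score_b Risk scores per subject, same subjects.
#' @param time Follow-up times.
#' @param event Event indicators.
#' @return List with `c_a`, `c_b`, `delta`, `se`, `p`.
#' @export
compare_c <- function(score_a, score_b, time, event) {
  stopifnot(length(score_a) == length(score_b))
  pa <- concordance_pairs(score_a, time, event)
  pb <- concordance_pairs(score_b, time, event)
  m <- sum(pa$comp)
  if (m == 0L) stop("no comparable pairs under censoring", call. = FALSE)
  c_a <- sum(pa$conc) / m
  c_b <- sum(pb$conc) / m
  delta <- c_b - c_a
  n <- length(time)
  # pair totals lost when subject k is removed (row + column involvement)
  inv_comp <- rowSums(pa$comp) + colSums(pa$comp)
  inv_ca <- rowSums(pa$conc) + colSums(pa$conc)
  inv_cb <- rowSums(pb$conc) + colSums(pb$conc)
  m_k <- m - inv_comp
  ok <- m_k > 0
  d_k <- (sum(pb$conc) - inv_cb[ok]) / m_k[ok] -
         (sum(pa$conc) - inv_ca[ok]) / m_k[ok]
  nk <- sum(ok)
  se <- sqrt((nk - 1) / nk * sum((d_k - mean(d_k))^2))
  p <- if (se == 0) {
    if (delta == 0) 1 else 0
  } else 2 * stats::pnorm(-abs(delta) / se)
  list(c_a = c_a, c_b = c_b, delta = delta, se = se, p = p)
}
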