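#' Kaplan-Meier product-limit estimate
#'
#' `S(t) = prod_{t_i <= t} (1 - d_i / n_i)` over distinct death times, with
#' Greenwood standard errors. At tied times deaths precede censorings: an
#' animal censored at `t` is still at risk for deaths at `t`.
#'
#' @param time positive follow-up times (days)
#' @param event 1/TRUE = died, 0/FALSE = censored
#' @return an object of class `km_curve`: data.frame-backed list with
#'   per-death-time `time`, `n_risk`, `n_event`, `surv` and Greenwood `se`,
#'   plus totals `n` and `n_events`
#' @export
kaplan_meier <- function(time, event) {
  stopifnot(length(time) == length(event))
  if (any(time <= 0)) stop("times must be positive")
  event <- as.integer(as.logical(event))
  dt <- sort(unique(time[event == 1L]))
  n_risk <- vapply(dt, function(t) sum(time >= t), 0L)
  n_event <- vapply(dt, function(t) sum(time == t & event == 1L), 0L)
  surv <- cumprod(1 - n_event / n_risk)
  gw <- cumsum(n_event / (n_risk * (n_risk - n_event)))
  se <- surv * sqrt(gw)
  structure(list(table = data.frame(time = dt, n_risk = n_risk,
                                    n_event = n_event, surv = surv,
                                    se = se),
                 n = length(time), n_events = sum(event)),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("km_curve: %d subjects, %d events, %d death times\n",
              x$n, x$n_events, nrow(x$table)))
  if (nrow(x$table))
    cat(sprintf("  final S(%g) = %.4f (se %.4f)\n",
                max(x$table$time), x$table$surv[nrow(x$table)],
                x$table$se[nrow(x$table)]))
  invisible(x)
}

#' Evaluate a Kaplan-Meier curve at a time point
#'
#' Right-continuous step evaluation; before the first death the survival
#' is 1.
#'
#' @param curve a [kaplan_meier()] result
#' @param t time (days)
#' @return the survival estimate at `t`
#' @export
km_survival_at <- function(curve, t) {
  tab <- curve$table
  vapply(t, function(tt) {
    i <- which(tab$time <= tt)
    if (!length(i)) 1 else tab$surv[max(i)]
  }, 0)
}

#' Survival and mortality at a grid of days
#'
#' @param curve a [kaplan_meier()] result
#' @param days positive day grid (default: the registry reporting grid
#'   6, 10, 20, 50, 102, 202, 300)
#' @return data.frame with `day`, `surv` and `mortality` (= 1 - surv)
#' @export
mortality_table <- function(curve, days = c(6, 10, 20, 50, 102, 202, 300)) {
  stopifnot(all(days > 0))
  s <- km_survival_at(curve, days)
  data.frame(day = days, surv = s, mortality = 1 - s)
}

#' Log-rank test between two groups
#'
#' Standard (unweighted) log-rank: at each distinct death time the observed
#' deaths in group A are compared with the hypergeometric expectation;
#' the statistic `U^2 / V` is referred to chi-square with 1 df. With no
#' events at all the statistic is 0 and p = 1. P-values below the double
#' precision floor are reported as that floor, never 0.
#'
#' @param a,b data.frames with columns `time` and `event`
#' @return list with `statistic`, `p`, `df = 1`, and per-group observed and
#'   expected event counts
#' @export
logrank_test <- function(a, b) {
  stopifnot(nrow(a) >= 1, nrow(b) >= 1)
  time <- c(a$time, b$time)
  event <- as.integer(as.logical(c(a$event, b$event)))
  grp <- rep(c(1L, 2L), c(nrow(a), nrow(b)))
  if (any(time <= 0)) stop("times must be positive")
  dt <- sort(unique(time[event == 1L]))
  U <- 0; V <- 0; oA <- 0; eA <- 0
  for (t in dt) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & grp == 1L)
    d <- sum(time == t & event == 1L)
    d1 <- sum(time == t & event == 1L & grp == 1L)
    e1 <- d * n1 / n
    U <- U + (d1 - e1)
    if (n > 1)
      V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    oA <- oA + d1; eA <- eA + e1
  }
  if (V <= 0) return(list(statistic = 0, p = 1, df = 1L,
                          observed = c(oA, sum(event) - oA),
                          expected = c(eA, sum(event) - eA)))
  stat <- U^2 / V
  p <- max(stats::pchisq(stat, df = 1, lower.tail = FALSE),
           .Machine$double.xmin)
  list(statistic = stat, p = p, df = 1L,
       observed = c(oA, sum(event) - oA),
       expected = c(eA, sum(event) - eA))
}

#' Kaplan-Meier curves and log-rank contrast by mating-type group
#'
#' Convenience wrapper for survival records carrying a `group` column with
#' exactly two levels.
#'
#' @param records data.frame with `time`, `event`, `group`
#' @param days reporting grid for [mortality_table()]
#' @return list with per-group `curves`, `tables` and the `logrank` result
#' @export
survival_contrast <- function(records,
                              days = c(6, 10, 20, 50, 102, 202, 300)) {
  lv <- unique(records$group)
  if (length(lv) != 2) stop("records must contain exactly two groups")
  parts <- split(records, records$group)
  curves <- lapply(parts, function(r) kaplan_meier(r$time, r$event))
  list(curves = curves,
       tables = lapply(curves, mortality_table, days = days),
       logrank = logrank_test(parts[[lv[1]]], parts[[lv[2]]]))
}
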