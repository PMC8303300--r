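#' Validate a table of survival records
#'
#' @param df Data frame with columns `sample`, `time` (months, > 0), `event`
#'   (1 = event observed, 0 = censored) and optionally `group`.
#' @return The validated data frame (class `survival_records`).
#' @export
survival_records <- function(df) {
  need <- c("sample", "time", "event")
  if (!all(need %in% names(df)))
    stop("survival records need columns: ", paste(need, collapse = ", "))
  if (any(!is.finite(df$time)) || any(df$time <= 0))
    stop("times must be finite and positive")
  if (!all(df$event %in% c(0, 1)))
    stop("event must be 0 (censored) or 1 (event)")
  if (anyDuplicated(df$sample)) stop("duplicate sample IDs")
  df <- as.data.frame(df)
  class(df) <- c("survival_records", "data.frame")
  df
}

#' Kaplan-Meier product-limit estimator
#'
#' Censored observations tied with events at the same time are treated as
#' still at risk at that time (events first), the standard convention.
#'
#' @param time Positive follow-up times (months).
#' @param event Event indicators (1 = event, 0 = censored).
#' @return An object of class `km_curve`: list with `time` (ascending
#'   distinct observed times), `surv` (survival probability just after each
#'   time), `n.risk`, `n.event`, `n.censor`.
#' @export
km_estimate <- function(time, event) {
  if (length(time) < 1L) stop("need at least 1 record")
  if (any(!is.finite(time)) || any(time <= 0))
    stop("times must be finite and positive")
  if (!all(event %in% c(0, 1))) stop("event must be 0/1")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  structure(list(time = fit$time, surv = fit$surv, n.risk = fit$n.risk,
                 n.event = fit$n.event, n.censor = fit$n.censor),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("km_curve: %d time points, %d events, final S = %.3f\n",
              length(x$time), sum(x$n.event), min(x$surv)))
  invisible(x)
}

#' Median survival from a Kaplan-Meier curve
#'
#' The smallest event time at which the survival probability drops to 0.5 or
#' below; `NA` ("not reached") when the curve stays above 0.5.
#'
#' @param c A [km_estimate()] curve.
#' @return Median time in months, or `NA_real_` when not reached.
#' @export
median_survival <- function(c) {
  stopifnot(inherits(c, "km_curve"))
  hit <- c$n.event > 0 & c$surv <= 0.5
  if (!any(hit)) return(NA_real_)
  min(c$time[hit])
}

#' Two-group log-rank test
#'
#' At each distinct event time the observed number of events in group `a` is
#' compared with its hypergeometric expectation given the at-risk counts;
#' the summed difference squared over the summed variance is referred to a
#' 1-df chi-square upper tail.
#'
#' @param a,b Data frames with columns `time` and `event` (one group each).
#' @return List with `statistic` (chi-square), `df` (= 1), `p.value`.
#' @export
logrank_test <- function(a, b) {
  for (d in list(a, b))
    if (!all(c("time", "event") %in% names(d)) || nrow(d) == 0L)
      stop("each group needs non-empty 'time' and 'event' columns")
  if (sum(a$event) + sum(b$event) == 0) stop("no events in either group")
  time <- c(a$time, b$time)
  event <- c(a$event, b$event)
  grp <- rep(c("a", "b"), c(nrow(a), nrow(b)))
  sd <- survival::survdiff(survival::Surv(time, event) ~ grp, rho = 0)
  list(statistic = unname(sd$chisq), df = 1L,
       p.value = stats::pchisq(sd$chisq, df = 1L, lower.tail = FALSE))
}

#' Compare survival between two groups
#'
#' Bundles the per-group Kaplan-Meier curves, median survival, restricted
#' mean survival (horizon = largest observed time over both groups) and the
#' log-rank test.
#'
#' @param records A [survival_records()] data frame with exactly two
#'   distinct `group` labels.
#' @return An object of class `survival_comparison`: list with `groups`,
#'   `curves`, `medians`, `rmeans`, `logrank` (list with `statistic`,
#'   `p.value`) and `n` per group.
#' @export
compare_groups <- function(records) {
  records <- survival_records(records)
  if (!"group" %in% names(records)) stop("records need a 'group' column")
  groups <- sort(unique(as.character(records$group)))
  if (length(groups) != 2L)
    stop("need exactly 2 groups, got ", length(groups))
  split_rec <- split(records, as.character(records$group))[groups]
  curves <- lapply(split_rec, function(d) km_estimate(d$time, d$event))
  medians <- vapply(curves, median_survival, 0)
  horizon <- max(records$time)
  fit <- survival::survfit(
    survival::Surv(time, event) ~ group, data = records)
  tab <- summary(fit, rmean = horizon)$table
  rmeans <- stats::setNames(tab[, "rmean"], groups)
  lr <- logrank_test(split_rec[[1L]][, c("time", "event")],
                     split_rec[[2L]][, c("time", "event")])
  structure(list(groups = groups, curves = curves, medians = medians,
                 rmeans = rmeans, logrank = lr,
                 n = vapply(split_rec, nrow, 0L)),
            class = "survival_comparison")
}

#' @export
print.survival_comparison <- function(x, ...) {
  for (g in x$groups)
    cat(sprintf("  %s: n = %d, median = %s months, rmean = %.1f\n", g,
                x$n[[g]],
                if (is.na(x$medians[[g]])) "not reached"
                else format(x$medians[[g]]),
                x$rmeans[[g]]))
  cat(sprintf("  log-rank chi-square = %.3f, p = %.4g\n",
              x$logrank$statistic, x$logrank$p.value))
  invisible(x)
}
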