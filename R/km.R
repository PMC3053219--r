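#' Kaplan-Meier product-limit estimator
#'
#' Estimates the survivor function \eqn{S(t)} from right-censored
#' observation times by the product-limit formula
#' \deqn{\hat S(t) = \prod_{t_i \le t} \left(1 - d_i/n_i\right),}
#' where \eqn{d_i} is the number of events and \eqn{n_i} the number at risk
#' just before the distinct time \eqn{t_i}. At tied times events are
#' processed before censorings, the standard product-limit convention.
#' The variance follows Greenwood's formula
#' \deqn{\widehat{Var}[\hat S(t)] = \hat S(t)^2 \sum_{t_i \le t}
#'   \frac{d_i}{n_i (n_i - d_i)},}
#' and pointwise confidence limits are built on a transformed scale
#' (log by default) and clipped to \eqn{[0,1]}.
#'
#' @param x numeric vector of non-negative observation times, or a data
#'   frame of survival records (see [build_records()]), in which case
#'   `endpoint` selects the time/event pair.
#' @param event 0/1 event indicators (1 = event, 0 = censored); ignored for
#'   the data-frame method.
#' @param conf_level confidence level for the pointwise interval
#'   (default 0.95).
#' @param conf_type transform for the confidence interval: `"log"`
#'   (symmetric normal error on \eqn{\log S}, the common default),
#'   `"log-log"` (on \eqn{\log(-\log S)}), `"plain"` (linear), or
#'   `"none"`.
#' @param endpoint for the data-frame method: `"os"` (observation time /
#'   `os_event`) or `"efs"` (`efs_time_years` / `efs_event`).
#' @param ... passed between methods.
#' @return an object of class `km_fit`: a list with `time` / `event`
#'   (the input data), `times` (distinct observed times), `n_risk`,
#'   `n_event`, `n_censor`, `survival`, `variance` (Greenwood), `ci_low`,
#'   `ci_high`, `conf_level`, `conf_type`, `endpoint`, `n`.
#' @examples
#' fit <- km_fit(c(1, 2, 3, 4), c(1, 0, 1, 0))
#' summary(fit)
#' median(fit)
#' survival_at(fit, c(0, 2, 5))
#' @seealso [survival_at()], [median_survival()], [numbers_at_risk()],
#'   [logrank_test()]
#' @export
km_fit <- function(x, ...) UseMethod("km_fit")

#' @rdname km_fit
#' @export
km_fit.default <- function(x, event, conf_level = 0.95,
                           conf_type = c("log", "log-log", "plain", "none"),
                           endpoint = NULL, ...) {
  conf_type <- match.arg(conf_type)
  time <- as.numeric(x)
  event <- as.integer(event)
  if (length(time) == 0L) stop("no observations", call. = FALSE)
  if (length(event) != length(time))
    stop("time and event must have the same length", call. = FALSE)
  keep <- !is.na(time) & !is.na(event)
  time <- time[keep]; event <- event[keep]
  if (length(time) == 0L) stop("no complete observations", call. = FALSE)
  if (any(time < 0)) stop("negative observation times", call. = FALSE)
  if (!all(event %in% 0:1)) stop("event must be 0 or 1", call. = FALSE)
  if (!(conf_level > 0 && conf_level < 1))
    stop("conf_level must be in (0, 1)", call. = FALSE)

  n <- length(time)
  times <- sort(unique(time))
  f <- factor(match(time, times), levels = seq_along(times))
  d <- as.integer(vapply(split(event, f), sum, 0L))        # events per time
  c_ <- as.integer(vapply(split(1L - event, f), sum, 0L))  # censorings
  n_risk <- n - c(0L, cumsum(d + c_)[-length(times)])

  frac <- ifelse(n_risk > 0, 1 - d / n_risk, 1)
  surv <- cumprod(frac)
  # Greenwood accumulator; a time where d == n_risk drives S to 0 and the
  # variance term is undefined -> propagate NA beyond that point
  term <- ifelse(d > 0,
                 ifelse(n_risk > d, d / (n_risk * (n_risk - d)), NA_real_),
                 0)
  gsum <- cumsum(term)
  variance <- surv^2 * gsum
  variance[surv == 0] <- 0

  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  se_log <- sqrt(gsum)
  ci <- switch(conf_type,
    "log" = {
      lo <- exp(log(surv) - z * se_log)
      hi <- exp(log(surv) + z * se_log)
      list(lo, hi)
    },
    "log-log" = {
      # symmetric on log(-log S); undefined at S = 1 or 0
      th <- suppressWarnings(log(-log(surv)))
      se_ll <- se_log / abs(log(surv))
      list(exp(-exp(th + z * se_ll)), exp(-exp(th - z * se_ll)))
    },
    "plain" = {
      se <- sqrt(variance)
      list(surv - z * se, surv + z * se)
    },
    "none" = list(rep(NA_real_, length(surv)), rep(NA_real_, length(surv))))
  ci_low <- pmax(0, pmin(1, ci[[1]]))
  ci_high <- pmax(0, pmin(1, ci[[2]]))
  # degenerate boundaries: the interval collapses where S hits 0
  ci_low[surv == 0] <- 0
  ci_high[surv == 0 & !is.finite(ci_high)] <- 0
  if (conf_type == "log-log") {        # transform undefined at S = 1
    ci_low[surv == 1] <- 1
    ci_high[surv == 1] <- 1
  }

  structure(list(time = time, event = event, n = n,
                 times = times, n_risk = n_risk, n_event = d, n_censor = c_,
                 survival = surv, variance = variance,
                 ci_low = ci_low, ci_high = ci_high,
                 conf_level = conf_level, conf_type = conf_type,
                 endpoint = endpoint, call = match.call()),
            class = "km_fit")
}

#' @rdname km_fit
#' @export
km_fit.data.frame <- function(x, endpoint = c("os", "efs"),
                              conf_level = 0.95, conf_type = "log", ...) {
  endpoint <- match.arg(endpoint)
  if (endpoint == "os")
    km_fit(x$time_years, x$os_event, conf_level = conf_level,
           conf_type = conf_type, endpoint = "os", ...)
  else
    km_fit(x$efs_time_years, x$efs_event, conf_level = conf_level,
           conf_type = conf_type, endpoint = "efs", ...)
}

#' @export
print.km_fit <- function(x, ...) {
  med <- median_survival(x)
  cat("Kaplan-Meier estimate",
      if (!is.null(x$endpoint)) paste0(" (", toupper(x$endpoint), ")"),
      "\n", sep = "")
  cat("  n = ", x$n, ", events = ", sum(x$n_event),
      ", censored = ", sum(x$n_censor), "\n", sep = "")
  cat("  median survival: ",
      if (is.na(med)) "not reached" else format(med, digits = 4), "\n",
      sep = "")
  invisible(x)
}

#' @export
summary.km_fit <- function(object, times = NULL, ...) {
  tab <- data.frame(time = object$times, n_risk = object$n_risk,
                    n_event = object$n_event, n_censor = object$n_censor,
                    survival = object$survival,
                    std_err = sqrt(object$variance),
                    ci_low = object$ci_low, ci_high = object$ci_high)
  if (!is.null(times)) tab <- survival_at(object, times)
  structure(list(table = tab, n = object$n, events = sum(object$n_event),
                 median = median_survival(object),
                 conf_level = object$conf_level, endpoint = object$endpoint),
            class = "summary.km_fit")
}

#' @export
print.summary.km_fit <- function(x, ...) {
  cat("Kaplan-Meier estimate",
      if (!is.null(x$endpoint)) paste0(" (", toupper(x$endpoint), ")"),
      ": n = ", x$n, ", events = ", x$events, "\n", sep = "")
  cat("Median survival:",
      if (is.na(x$median)) "not reached" else format(x$median, digits = 4),
      "\n\n")
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @param x a `km_fit`.
#' @param ... passed to [render_km_plot()] (e.g. `risk_times`, `main`).
#' @describeIn km_fit plot the curve with confidence band and numbers at
#'   risk.
#' @export
plot.km_fit <- function(x, ...) {
  render_km_plot(x, ...)
}

#' @describeIn km_fit add the step curve to an existing plot.
#' @param col line colour.
#' @export
lines.km_fit <- function(x, col = "#00468B", ...) {
  st <- km_steps(x$times, x$survival)
  graphics::lines(st$x, st$y, col = col, ...)
}

#' Evaluate a Kaplan-Meier curve at given times
#'
#' The product-limit estimate is a right-continuous step function: the
#' value at `t` is the estimate at the largest event time not exceeding
#' `t`, 1 before the first observed time, and the last estimate beyond the
#' data.
#'
#' @param fit a `km_fit`.
#' @param times numeric vector of non-negative times.
#' @return data frame with `time`, `survival`, `ci_low`, `ci_high`.
#' @export
survival_at <- function(fit, times) {
  stopifnot(inherits(fit, "km_fit"))
  times <- as.numeric(times)
  if (any(is.na(times) | times < 0))
    stop("times must be non-negative", call. = FALSE)
  idx <- findInterval(times, fit$times)
  pick <- function(v, default) ifelse(idx == 0L, default, v[pmax(idx, 1L)])
  data.frame(time = times,
             survival = pick(fit$survival, 1),
             ci_low = pick(fit$ci_low, 1),
             ci_high = pick(fit$ci_high, 1))
}

#' @export
predict.km_fit <- function(object, times = object$times, ...) {
  survival_at(object, times)
}

#' Median survival time
#'
#' The smallest observed time at which the product-limit estimate drops to
#' 0.5 or below. When the curve never reaches 0.5 the median is not
#' reached and `NA` is returned.
#'
#' @param fit a `km_fit`.
#' @return numeric median time, or `NA` when not reached.
#' @export
median_survival <- function(fit) {
  stopifnot(inherits(fit, "km_fit"))
  i <- which(fit$survival <= 0.5)
  if (!length(i)) NA_real_ else fit$times[min(i)]
}

#' @export
median.km_fit <- function(x, na.rm = FALSE, ...) median_survival(x)

#' Numbers at risk at given times
#'
#' The number of subjects still under observation just before each
#' requested time: the count of observation times greater than or equal to
#' `t`. Conventionally tabulated beneath survival plots.
#'
#' @param x a `km_fit`, a numeric vector of observation times, or a data
#'   frame of survival records.
#' @param at_times numeric vector of non-negative times.
#' @param endpoint for the data-frame input: `"os"` or `"efs"`.
#' @return integer vector of counts, one per requested time.
#' @export
numbers_at_risk <- function(x, at_times, endpoint = "os") {
  times <- if (inherits(x, "km_fit")) x$time
           else if (is.data.frame(x)) {
             if (endpoint == "os") x$time_years else x$efs_time_years
           } else as.numeric(x)
  at_times <- as.numeric(at_times)
  if (any(is.na(at_times) | at_times < 0))
    stop("at_times must be non-negative", call. = FALSE)
  vapply(at_times, function(t) sum(times >= t), integer(1))
}

#' Curve table of a Kaplan-Meier fit
#'
#' @param fit a `km_fit`.
#' @param path optional CSV output path.
#' @return data frame `time, n_risk, n_event, n_censor, survival, ci_low,
#'   ci_high` (written to `path` when given).
#' @export
km_table <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "km_fit"))
  tab <- data.frame(time = fit$times, n_risk = fit$n_risk,
                    n_event = fit$n_event, n_censor = fit$n_censor,
                    survival = fit$survival,
                    ci_low = fit$ci_low, ci_high = fit$ci_high)
  if (!is.null(path)) {
    out <- tab
    for (col in c("time", "survival", "ci_low", "ci_high"))
      out[[col]] <- sprintf("%.12g", out[[col]])
    utils::write.csv(out, path, row.names = FALSE, na = "")
    return(invisible(tab))
  }
  tab
}
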