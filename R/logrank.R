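#' Log-rank test for equality of survival distributions
#'
#' Compares the survival experience of two or more groups. At each distinct
#' event time \eqn{t_j} the expected number of events in group \eqn{g}
#' under the null hypothesis follows the hypergeometric model
#' \deqn{e_{gj} = n_{gj} d_j / n_j,}
#' with the multivariate hypergeometric covariance
#' \deqn{v_{ghj} = \frac{d_j (n_j - d_j)}{n_j - 1}
#'   \left(\delta_{gh} \frac{n_{gj}}{n_j} -
#'         \frac{n_{gj} n_{hj}}{n_j^2}\right).}
#' The statistic is \eqn{(O-E)^\top V^- (O-E)} over the first \eqn{g-1}
#' groups, using a generalized inverse of the covariance block for
#' numerical safety, and is referred to the chi-square distribution with
#' \eqn{g-1} degrees of freedom.
#'
#' @param x numeric vector of observation times, or a data frame of
#'   survival records (then `group_col`/`endpoint` select the columns).
#' @param event 0/1 event indicators.
#' @param group group labels, one per observation; at least two non-empty
#'   groups are required.
#' @param group_col column holding the group label (data-frame method).
#' @param endpoint `"os"` or `"efs"` (data-frame method).
#' @param ... passed between methods.
#' @return object of class `logrank_test`: `groups`, `n`, `observed`,
#'   `expected`, `statistic`, `df`, `p_value`.
#' @examples
#' lr <- logrank_test(c(1, 2, 3, 4), c(1, 1, 1, 1), c("A", "A", "B", "B"))
#' lr$statistic
#' @export
logrank_test <- function(x, ...) UseMethod("logrank_test")

#' @rdname logrank_test
#' @export
logrank_test.default <- function(x, event, group, ...) {
  time <- as.numeric(x)
  event <- as.integer(event)
  group <- as.character(group)
  keep <- !is.na(time) & !is.na(event) & !is.na(group)
  time <- time[keep]; event <- event[keep]; group <- group[keep]
  if (any(time < 0)) stop("negative observation times", call. = FALSE)
  if (!all(event %in% 0:1)) stop("event must be 0 or 1", call. = FALSE)
  groups <- sort(unique(group))
  g <- length(groups)
  if (g < 2L) stop("at least two non-empty groups are required", call. = FALSE)
  gi <- match(group, groups)

  etimes <- sort(unique(time[event == 1L]))
  O <- E <- stats::setNames(numeric(g), groups)
  V <- matrix(0, g, g, dimnames = list(groups, groups))
  risk_seen <- numeric(g)
  for (g0 in seq_len(g)) O[g0] <- sum(event[gi == g0])
  for (tj in etimes) {
    at_risk <- time >= tj
    nj <- sum(at_risk)
    dj <- sum(event[time == tj])
    ngj <- vapply(seq_len(g), function(k) sum(at_risk & gi == k), 0L)
    risk_seen <- risk_seen + ngj
    E <- E + ngj * dj / nj
    if (nj > 1) {
      p <- ngj / nj
      V <- V + dj * (nj - dj) / (nj - 1) * (diag(p, g) - outer(p, p))
    }
  }
  idx <- seq_len(g - 1L)
  diff <- (O - E)[idx]
  Vb <- V[idx, idx, drop = FALSE]
  stat <- as.numeric(t(diff) %*% MASS::ginv(Vb) %*% diff)
  df <- g - 1L
  if (length(etimes) && any(risk_seen == 0))
    warning("group(s) never at risk at an event time contribute nothing: ",
            paste(groups[risk_seen == 0], collapse = ", "), call. = FALSE)
  structure(list(groups = groups,
                 n = as.integer(tabulate(gi, g)),
                 observed = O, expected = E, covariance = V,
                 statistic = stat, df = df,
                 p_value = stats::pchisq(stat, df, lower.tail = FALSE)),
            class = "logrank_test")
}

#' @rdname logrank_test
#' @export
logrank_test.data.frame <- function(x, group_col = "group",
                                    endpoint = c("os", "efs"), ...) {
  endpoint <- match.arg(endpoint)
  if (endpoint == "os")
    logrank_test(x$time_years, x$os_event, x[[group_col]], ...)
  else
    logrank_test(x$efs_time_years, x$efs_event, x[[group_col]], ...)
}

#' @export
print.logrank_test <- function(x, ...) {
  cat("Log-rank test:", length(x$groups), "groups\n\n")
  print(data.frame(group = x$groups, n = x$n,
                   observed = x$observed, expected = round(x$expected, 2),
                   row.names = NULL))
  cat("\n  chi-square = ", format(x$statistic, digits = 4),
      " on ", x$df, " df, p = ", format.pval(x$p_value, digits = 3),
      "\n", sep = "")
  invisible(x)
}
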