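# Disproportionality statistics on 2x2 contingency tables: chi-squared,
# RRR, PRR, ROR, information component, Woolf-type confidence intervals,
# and the Evans positive-signal rule.

cells_of <- function(t) {
  stopifnot(inherits(t, "contingency_table"))
  list(a = t$a, b = t$b, c = t$c, d = t$d)
}

apply_haldane <- function(x, haldane) {
  if (haldane && any(c(x$a, x$b, x$c, x$d) == 0)) {
    x <- lapply(x, function(v) v + 0.5)
  }
  x
}

#' Pearson chi-squared statistic of a 2x2 table
#'
#' Evaluates `(ad - bc)^2 N / ((a+b)(c+d)(a+c)(b+d))`. By default no
#' continuity correction is applied; `correct = TRUE` uses the Yates
#' correction `(|ad - bc| - N/2)^2` (floored at zero), which is what
#' several pharmacovigilance extraction tools report.
#'
#' @param t A [contingency_table()].
#' @param correct Apply the Yates continuity correction?
#' @return The chi-squared statistic (non-negative scalar). All four
#'   margins must be positive, otherwise an undefined-statistic error is
#'   raised.
#' @export
chi_squared <- function(t, correct = FALSE) {
  x <- cells_of(t)
  n <- x$a + x$b + x$c + x$d
  margins <- c(x$a + x$b, x$c + x$d, x$a + x$c, x$b + x$d)
  if (any(margins == 0)) {
    stop_undefined("chi-squared", cell = "margin")
  }
  num <- abs(x$a * x$d - x$b * x$c)
  if (correct) num <- max(num - n / 2, 0)
  num^2 * n / prod(margins)
}

#' Relative reporting ratio (RRR)
#'
#' Two conventions are in circulation and both are supported:
#' * `"rate_ratio"` (default): the ratio of reporting rates
#'   `(a/(a+b)) / (c/(c+d))` -- the share of event-of-interest reports
#'   that involve the drug, relative to the same share among all other
#'   reports. This is the formula most published analyses display.
#' * `"observed_expected"`: the observed count over its expectation under
#'   independence, `a N / ((a+b)(a+c))`, the form used by BCPNN-style
#'   screening tools.
#'
#' The two agree when the drug and the event are both rare in the
#' database. `ic()` is `log2` of whichever convention is requested.
#'
#' @param t A [contingency_table()].
#' @param method RRR convention, see Details.
#' @param haldane Add 0.5 to every cell when any cell is zero
#'   (Haldane-Anscombe correction). Off by default.
#' @return Positive scalar; an undefined-statistic error if a denominator
#'   is zero.
#' @export
rrr <- function(t, method = c("rate_ratio", "observed_expected"),
                haldane = FALSE) {
  method <- match.arg(method)
  x <- apply_haldane(cells_of(t), haldane)
  if (method == "rate_ratio") {
    if (x$a + x$b == 0 || x$c + x$d == 0) {
      stop_undefined("RRR", cell = "margin")
    }
    if (x$c == 0) stop_undefined("RRR", cell = "c")
    (x$a / (x$a + x$b)) / (x$c / (x$c + x$d))
  } else {
    n <- x$a + x$b + x$c + x$d
    if (x$a + x$b == 0 || x$a + x$c == 0) {
      stop_undefined("RRR", cell = "margin")
    }
    x$a * n / ((x$a + x$b) * (x$a + x$c))
  }
}

#' Proportional reporting ratio (PRR)
#'
#' `(a/(a+c)) / (b/(b+d))`: the proportion of the drug's reports that
#' mention the event, relative to the same proportion among all other
#' drugs' reports.
#'
#' @inheritParams rrr
#' @return Positive scalar; undefined-statistic error when `b = 0`.
#' @export
prr <- function(t, haldane = FALSE) {
  x <- apply_haldane(cells_of(t), haldane)
  if (x$a + x$c == 0 || x$b + x$d == 0) stop_undefined("PRR", cell = "margin")
  if (x$b == 0) stop_undefined("PRR", cell = "b")
  (x$a / (x$a + x$c)) / (x$b / (x$b + x$d))
}

#' Reporting odds ratio (ROR)
#'
#' `(a/c) / (b/d)`: the odds of the event among reports of the drug vs.
#' all other drugs.
#'
#' @inheritParams rrr
#' @return Positive scalar; undefined-statistic error when `b = 0` or
#'   `c = 0`.
#' @export
ror <- function(t, haldane = FALSE) {
  x <- apply_haldane(cells_of(t), haldane)
  if (x$b == 0) stop_undefined("ROR", cell = "b")
  if (x$c == 0) stop_undefined("ROR", cell = "c")
  (x$a / x$c) / (x$b / x$d)
}

#' Information component (IC)
#'
#' `IC = log2(RRR)`: the base-2 logarithm of the relative reporting ratio,
#' the point estimate of the BCPNN-style information component.
#'
#' @inheritParams rrr
#' @return Real scalar (bits).
#' @export
ic <- function(t, method = c("rate_ratio", "observed_expected"),
               haldane = FALSE) {
  r <- rrr(t, method = method, haldane = haldane)
  if (r <= 0) stop_undefined("IC")
  log2(r)
}

woolf_se <- function(statistic, x) {
  se2 <- switch(statistic,
    ror = {
      if (any(c(x$a, x$b, x$c, x$d) == 0)) {
        stop_undefined("ROR interval",
                       cell = c("a", "b", "c", "d")[which(c(x$a, x$b, x$c, x$d) == 0)[1]])
      }
      1 / x$a + 1 / x$b + 1 / x$c + 1 / x$d
    },
    prr = {
      if (x$a == 0 || x$b == 0) {
        stop_undefined("PRR interval", cell = if (x$a == 0) "a" else "b")
      }
      1 / x$a - 1 / (x$a + x$c) + 1 / x$b - 1 / (x$b + x$d)
    },
    rrr = {
      if (x$a == 0 || x$c == 0) {
        stop_undefined("RRR interval", cell = if (x$a == 0) "a" else "c")
      }
      1 / x$a - 1 / (x$a + x$b) + 1 / x$c - 1 / (x$c + x$d)
    }
  )
  sqrt(se2)
}

#' Woolf-type log-normal confidence interval for a ratio statistic
#'
#' `exp(ln(point) +/- z * SE)` with the standard error on the log scale:
#' `SE_ROR = sqrt(1/a + 1/b + 1/c + 1/d)`,
#' `SE_PRR = sqrt(1/a - 1/(a+c) + 1/b - 1/(b+d))`,
#' `SE_RRR = sqrt(1/a - 1/(a+b) + 1/c - 1/(c+d))`.
#'
#' @param t A [contingency_table()].
#' @param statistic One of `"rrr"`, `"prr"`, `"ror"`.
#' @param level Confidence level in (0, 1); default 0.95.
#' @param rrr_method RRR convention used for the point estimate when
#'   `statistic = "rrr"` (the log-scale SE formula is shared).
#' @return Named numeric vector `c(lower, upper)`; the point estimate
#'   always lies inside. Undefined-interval error when a required cell is
#'   zero.
#' @export
confidence_interval <- function(t, statistic = c("ror", "prr", "rrr"),
                                level = 0.95,
                                rrr_method = c("rate_ratio", "observed_expected")) {
  statistic <- match.arg(statistic)
  if (!(is.numeric(level) && length(level) == 1 && level > 0 && level < 1)) {
    stop_config("level must be in (0, 1)")
  }
  x <- cells_of(t)
  point <- switch(statistic,
    ror = ror(t), prr = prr(t),
    rrr = rrr(t, method = match.arg(rrr_method))
  )
  se <- woolf_se(statistic, x)
  z <- stats::qnorm((1 + level) / 2)
  c(lower = point * exp(-z * se), upper = point * exp(z * se))
}

#' Confidence interval for the information component
#'
#' Default method: `log2` of the RRR confidence interval bounds (monotone
#' transform of the Woolf interval). The credible intervals printed by
#' full Bayesian BCPNN implementations are generally asymmetric and are
#' not reproduced by this transform.
#'
#' @inheritParams confidence_interval
#' @return Named numeric vector `c(lower, upper)` in bits.
#' @export
ic_interval <- function(t, level = 0.95,
                        rrr_method = c("rate_ratio", "observed_expected")) {
  ci <- confidence_interval(t, "rrr", level = level,
                            rrr_method = match.arg(rrr_method))
  log2(ci)
}

#' Positive-signal thresholds (Evans rule)
#'
#' The conventional disproportionality screening rule: a signal requires
#' more than `min_n` cases, chi-squared above `min_chi2`, and PRR above
#' `min_prr`. Strictness `"strict_greater"` (default) uses strict
#' inequalities ("more than three ... greater than four ... greater than
#' two"); `"greater_or_equal"` uses the >= form in which the rule is also
#' often quoted.
#'
#' @param min_n,min_chi2,min_prr Positive thresholds (defaults 3, 4, 2).
#' @param strictness `"strict_greater"` or `"greater_or_equal"`.
#' @return An object of class `signal_criteria`.
#' @export
signal_criteria <- function(min_n = 3, min_chi2 = 4, min_prr = 2,
                            strictness = c("strict_greater",
                                           "greater_or_equal")) {
  strictness <- match.arg(strictness)
  if (!all(c(min_n, min_chi2, min_prr) > 0)) {
    stop_config("signal criteria thresholds must be positive")
  }
  structure(list(min_n = min_n, min_chi2 = min_chi2, min_prr = min_prr,
                 strictness = strictness),
            class = "signal_criteria")
}

#' Evaluate the positive-signal rule
#'
#' @param stats A [signal_stats][compute_all()] object, or any list with
#'   elements `n`, `chi2` and `prr`.
#' @param criteria A [signal_criteria()].
#' @return `TRUE` iff all three thresholds are cleared under the configured
#'   strictness. A missing (`NA`, undefined) component fails the rule.
#' @export
evaluate_signal <- function(stats, criteria = signal_criteria()) {
  stopifnot(inherits(criteria, "signal_criteria"))
  cmp <- if (criteria$strictness == "strict_greater") `>` else `>=`
  vals <- c(stats$n, stats$chi2, stats$prr)
  ths <- c(criteria$min_n, criteria$min_chi2, criteria$min_prr)
  if (anyNA(vals)) return(FALSE)
  all(cmp(vals, ths))
}

na_on_undefined <- function(expr) {
  tryCatch(expr, pvsignal_undefined_statistic = function(e) NA_real_)
}

na_pair_on_undefined <- function(expr) {
  tryCatch(expr, pvsignal_undefined_statistic = function(e)
    c(lower = NA_real_, upper = NA_real_))
}

#' Compute all disproportionality statistics for a table
#'
#' Populates the full result row: `n` (cell a), chi-squared, RRR, PRR, ROR,
#' IC and their confidence intervals. A statistic whose denominator is zero
#' is reported as `NA` rather than failing the whole row, so sparse tables
#' still report `n`.
#'
#' @param t A [contingency_table()].
#' @param level Confidence level for the intervals.
#' @param rrr_method RRR convention, see [rrr()].
#' @param haldane Apply the Haldane-Anscombe 0.5 correction to the point
#'   estimates of sparse tables.
#' @return An object of class `signal_stats`: a list with elements `n`,
#'   `chi2`, `rrr`, `prr`, `ror`, `ic`, `ci_rrr`, `ci_prr`, `ci_ror`,
#'   `ci_ic`, `ci_method`, `level`, plus the table's labels.
#' @export
compute_all <- function(t, level = 0.95,
                        rrr_method = c("rate_ratio", "observed_expected"),
                        haldane = FALSE) {
  rrr_method <- match.arg(rrr_method)
  res <- list(
    n = t$a,
    chi2 = na_on_undefined(chi_squared(t)),
    rrr = na_on_undefined(rrr(t, method = rrr_method, haldane = haldane)),
    prr = na_on_undefined(prr(t, haldane = haldane)),
    ror = na_on_undefined(ror(t, haldane = haldane)),
    ci_rrr = na_pair_on_undefined(
      confidence_interval(t, "rrr", level, rrr_method)),
    ci_prr = na_pair_on_undefined(confidence_interval(t, "prr", level)),
    ci_ror = na_pair_on_undefined(confidence_interval(t, "ror", level)),
    ci_method = "woolf_log_normal",
    level = level,
    drug = t$drug, event = t$event, stratum = t$stratum
  )
  res$ic <- if (is.na(res$rrr) || res$rrr <= 0) NA_real_ else log2(res$rrr)
  res$ci_ic <- log2(res$ci_rrr)
  structure(res, class = "signal_stats")
}

#' @export
print.signal_stats <- function(x, digits = 1, ...) {
  fmt <- function(p, ci) {
    if (is.na(p)) return("--")
    sprintf("%s (%s, %s)", format(round_half_up(p, digits)),
            format(round_half_up(ci[[1]], digits)),
            format(round_half_up(ci[[2]], digits)))
  }
  cat(sprintf("%s / %s [%s]\n", x$drug, x$event, x$stratum))
  cat(sprintf("  N    %d\n", as.integer(x$n)))
  cat(sprintf("  chi2 %s\n",
              if (is.na(x$chi2)) "--" else
                format(round_half_up(x$chi2, digits), big.mark = ",")))
  cat(sprintf("  RRR  %s\n", fmt(x$rrr, x$ci_rrr)))
  cat(sprintf("  PRR  %s\n", fmt(x$prr, x$ci_prr)))
  cat(sprintf("  ROR  %s\n", fmt(x$ror, x$ci_ror)))
  cat(sprintf("  IC   %s\n", fmt(x$ic, x$ci_ic)))
  invisible(x)
}

#' One-row data frame view of a signal_stats object
#'
#' @param x A `signal_stats` object.
#' @param ... Unused.
#' @return A one-row tibble with the columns of the results CSV (without
#'   the `signal` flag).
#' @export
as_tibble_row <- function(x, ...) {
  stopifnot(inherits(x, "signal_stats"))
  tibble::tibble(
    drug = x$drug, event = x$event, stratum = x$stratum,
    n = x$n, chi2 = x$chi2,
    rrr = x$rrr, rrr_lo = x$ci_rrr[["lower"]], rrr_hi = x$ci_rrr[["upper"]],
    prr = x$prr, prr_lo = x$ci_prr[["lower"]], prr_hi = x$ci_prr[["upper"]],
    ror = x$ror, ror_lo = x$ci_ror[["lower"]], ror_hi = x$ci_ror[["upper"]],
    ic = x$ic, ic_lo = x$ci_ic[["lower"]], ic_hi = x$ci_ic[["upper"]]
  )
}
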