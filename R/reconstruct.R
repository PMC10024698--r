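# Inverse problem: recover integer contingency cells (b, c, d) from a known
# cell a and published point estimates of RRR, PRR and ROR.
#
# Closed-form elimination: substituting d = ROR * b * c / a into the PRR
# formula gives PRR = (a + ROR c) / (a + c), hence
#     c = a (PRR - 1) / (ROR - PRR),
# independent of b. The RRR formula then pins b:
#   rate-ratio RRR:        b = a (RRR - 1) / (ROR - RRR)
#   observed/expected RRR: b = a (a + c)(RRR - 1) / (a + ROR c - RRR (a + c))
# Because the published targets are rounded, each relation only bounds its
# unknown: integer candidates for c and b are enumerated over the interval
# images of the rounding windows, d is bracketed per (b, c) by the three
# monotone-in-d statistics, and every candidate is verified by forward
# evaluation.

target_window <- function(target, precision, tol) {
  if (!is.null(tol)) {
    c(target * (1 - tol), target * (1 + tol))
  } else {
    h <- 0.5 * 10^(-precision)
    c(target - h, target + h)
  }
}

matches_target <- function(value, target, precision, tol) {
  if (!is.null(tol)) abs(value / target - 1) <= tol
  else round_half_up(value, precision) == target
}

# interval quotient num/den over boxes; NULL marks an unbounded image
# (the denominator window straddles zero), which means the targets do not
# pin the unknown at all
iv_div <- function(num, den) {
  if (den[1] <= 0 && den[2] >= 0) return(NULL)
  range(c(num[1] / den[1], num[1] / den[2],
          num[2] / den[1], num[2] / den[2]))
}

#' Reconstruct contingency cells from published summary statistics
#'
#' Given cell `a` and published point estimates of RRR, PRR and ROR
#' (typically printed to one decimal), finds every integer `(b, c, d)` such
#' that forward evaluation of the three statistics reproduces the targets
#' at the stated precision. The search uses closed-form elimination of two
#' unknowns followed by a bounded integer search on the third (see source
#' header), so it is exact over the implied rounding windows.
#'
#' Published triples are sometimes mutually inconsistent under one RRR
#' convention and consistent under the other (see [rrr()]); try both
#' `rrr_method`s before concluding that a row cannot be reconstructed.
#'
#' @param a Known count of reports with both the drug and the event.
#' @param rrr_target,prr_target,ror_target Published positive point
#'   estimates.
#' @param precision Number of decimals at which the targets are matched
#'   (half-up rounding); default 1, as in typical published tables.
#' @param rrr_method RRR convention used in forward evaluation.
#' @param tol Optional relative tolerance; when given it replaces decimal
#'   matching, accepting tables whose forward statistics are within
#'   `tol * target` of each target.
#' @param max_candidates Search guard: an error is raised if the bounded
#'   search would enumerate more than this many `(b, c)` pairs, which
#'   indicates inconsistent targets or far too coarse a precision.
#' @return A tibble of solutions with columns `a, b, c, d, rrr, prr, ror`
#'   (forward-evaluated, unrounded); zero rows when no integer table
#'   reproduces the targets.
#' @examples
#' t <- contingency_table(20, 5, 5, 20)
#' reconstruct_table(20, rrr(t), prr(t), ror(t))
#' @export
reconstruct_table <- function(a, rrr_target, prr_target, ror_target,
                              precision = 1,
                              rrr_method = c("rate_ratio",
                                             "observed_expected"),
                              tol = NULL, max_candidates = 5e6) {
  rrr_method <- match.arg(rrr_method)
  if (!is_count(a) || a <= 0) stop_config("a must be a positive integer")
  if (any(c(rrr_target, prr_target, ror_target) <= 0)) {
    stop_config("targets must be positive")
  }
  Rw <- target_window(rrr_target, precision, tol)
  Pw <- target_window(prr_target, precision, tol)
  Ow <- target_window(ror_target, precision, tol)

  empty <- tibble::tibble(a = numeric(), b = numeric(), c = numeric(),
                          d = numeric(), rrr = numeric(), prr = numeric(),
                          ror = numeric())

  # c from (PRR, ROR): c = a (P - 1) / (O - P)
  c_rng <- iv_div(a * (Pw - 1), c(Ow[1] - Pw[2], Ow[2] - Pw[1]))
  if (is.null(c_rng)) {
    stop_config("reconstruction search limits exceeded: the PRR and ROR windows overlap, so c is unbounded")
  }
  if (c_rng[2] < 1) return(empty)
  c_lo <- max(1, floor(c_rng[1]) - 1)
  c_hi <- ceiling(c_rng[2]) + 1
  if (c_hi - c_lo + 1 > max_candidates) {
    stop_config("reconstruction search limits exceeded: targets under-determine c")
  }

  b_window <- function(cc) {
    if (rrr_method == "rate_ratio") {
      iv_div(a * (Rw - 1), c(Ow[1] - Rw[2], Ow[2] - Rw[1]))
    } else {
      iv_div(a * (a + cc) * (Rw - 1),
             c(a + Ow[1] * cc - Rw[2] * (a + cc),
               a + Ow[2] * cc - Rw[1] * (a + cc)))
    }
  }

  sols <- vector("list", 64)
  n_sol <- 0
  n_pairs <- 0
  for (cc in seq(c_lo, c_hi)) {
    b_rng <- b_window(cc)
    if (is.null(b_rng)) {
      stop_config("reconstruction search limits exceeded: the RRR and ROR windows overlap, so b is unbounded")
    }
    if (b_rng[2] < 1) next
    b_lo <- max(1, floor(b_rng[1]) - 1)
    b_hi <- ceiling(b_rng[2]) + 1
    n_pairs <- n_pairs + (b_hi - b_lo + 1)
    if (n_pairs > max_candidates) {
      stop_config("reconstruction search limits exceeded: targets may be inconsistent or precision too coarse")
    }
    for (b in seq(b_lo, b_hi)) {
      # every statistic is increasing in d, so each window brackets d
      d_lo <- max(
        Ow[1] * b * cc / a,
        Pw[1] * b * (a + cc) / a - b,
        if (rrr_method == "rate_ratio") Rw[1] * cc * (a + b) / a - cc
        else Rw[1] * (a + b) * (a + cc) / a - (a + b + cc),
        1
      )
      d_hi <- min(
        Ow[2] * b * cc / a,
        Pw[2] * b * (a + cc) / a - b,
        if (rrr_method == "rate_ratio") Rw[2] * cc * (a + b) / a - cc
        else Rw[2] * (a + b) * (a + cc) / a - (a + b + cc)
      )
      if (!is.finite(d_lo) || !is.finite(d_hi) || d_hi < d_lo) next
      d <- seq(ceiling(d_lo), floor(d_hi))
      if (length(d) == 0) next
      rrr_v <- if (rrr_method == "rate_ratio") {
        (a / (a + b)) / (cc / (cc + d))
      } else {
        a * (a + b + cc + d) / ((a + b) * (a + cc))
      }
      prr_v <- (a / (a + cc)) / (b / (b + d))
      ror_v <- (a / cc) / (b / d)
      keep <- matches_target(rrr_v, rrr_target, precision, tol) &
        matches_target(prr_v, prr_target, precision, tol) &
        matches_target(ror_v, ror_target, precision, tol)
      if (any(keep)) {
        n_sol <- n_sol + 1
        if (n_sol > length(sols)) sols <- c(sols, vector("list", length(sols)))
        sols[[n_sol]] <- cbind(b = b, c = cc, d = d[keep],
                               rrr = rrr_v[keep], prr = prr_v[keep],
                               ror = ror_v[keep])
      }
    }
  }
  if (n_sol == 0) return(empty)
  m <- do.call(rbind, sols[seq_len(n_sol)])
  tibble::tibble(a = a, b = m[, "b"], c = m[, "c"], d = m[, "d"],
                 rrr = m[, "rrr"], prr = m[, "prr"], ror = m[, "ror"])
}

#' Pick a representative solution from a reconstruction
#'
#' Deterministic tie-break among reconstructed tables: the solution whose
#' forward statistics have the smallest maximum relative deviation from the
#' targets; remaining ties go to the smallest total count N.
#'
#' @param solutions Tibble returned by [reconstruct_table()].
#' @param rrr_target,prr_target,ror_target The targets used in the search.
#' @return A [contingency_table()] built from the selected row.
#' @export
representative_solution <- function(solutions, rrr_target, prr_target,
                                    ror_target) {
  if (nrow(solutions) == 0) stop_config("no solutions to choose from")
  dev <- pmax(abs(solutions$rrr / rrr_target - 1),
              abs(solutions$prr / prr_target - 1),
              abs(solutions$ror / ror_target - 1))
  n_tot <- solutions$a + solutions$b + solutions$c + solutions$d
  i <- order(dev, n_tot)[1]
  contingency_table(solutions$a[i], solutions$b[i], solutions$c[i],
                    solutions$d[i], drug = "reconstructed",
                    event = "reconstructed")
}
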