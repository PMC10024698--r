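# 2x2 contingency tables for (drug, event) pairs and stratified subsets.
#
# The cells follow the classical disproportionality layout:
#          event of interest | all other events
#   drug          a          |        c
#   other drugs   b          |        d
# so N = a + b + c + d is the number of analyzed reports.

#' Construct a 2x2 contingency table for a drug-event pair
#'
#' @param a Reports with the drug of interest AND the event of interest.
#' @param b Reports with the event of interest and all other drugs.
#' @param c Reports with the drug of interest and all other events.
#' @param d Reports with all other drugs and all other events.
#' @param drug,event,stratum Labels carried along for reporting.
#' @return An object of class `contingency_table`.
#' @examples
#' contingency_table(20, 5, 5, 20)
#' @export
contingency_table <- function(a, b, c, d, drug = "drug", event = "event",
                              stratum = "overall") {
  cells <- c(a = a, b = b, c = c, d = d)
  if (!all(vapply(cells, is_count, TRUE))) {
    stop_format("contingency cells must be non-negative integers")
  }
  if (sum(cells) == 0) {
    stop_format("contingency table must contain at least one report (N > 0)")
  }
  structure(
    list(a = as.numeric(a), b = as.numeric(b), c = as.numeric(c),
         d = as.numeric(d), drug = drug, event = event, stratum = stratum),
    class = "contingency_table"
  )
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("2x2 contingency table: %s / %s [%s], N = %s\n",
              x$drug, x$event, x$stratum,
              format(x$a + x$b + x$c + x$d, big.mark = ",")))
  m <- matrix(c(x$a, x$c, x$b, x$d), nrow = 2, byrow = TRUE,
              dimnames = list(c("drug of interest", "all other drugs"),
                              c("event", "other events")))
  print(m)
  invisible(x)
}

table_n <- function(t) t$a + t$b + t$c + t$d

#' Build the contingency table for a drug-event pair
#'
#' Each report is assigned to exactly one cell by (has-drug, has-event)
#' membership; cells sum to the number of input reports. Reports listing
#' several drugs of interest contribute to cell `a` of each drug's own
#' table (a separate call per drug).
#'
#' @param reports A report tibble, expected deduplicated and normalized.
#' @param drug Canonical drug name of interest.
#' @param event Event preferred term of interest.
#' @param stratum Label stored on the resulting table.
#' @return A [contingency_table()].
#' @export
build_table <- function(reports, drug, event, stratum = "overall") {
  if (nrow(reports) == 0) {
    stop_format("cannot build a contingency table from zero reports")
  }
  has_d <- report_has_drug(reports, drug)
  has_e <- report_has_event(reports, event)
  contingency_table(
    a = sum(has_d & has_e), b = sum(!has_d & has_e),
    c = sum(has_d & !has_e), d = sum(!has_d & !has_e),
    drug = drug, event = event, stratum = stratum
  )
}

#' Build contingency cells for many drug-event pairs at once
#'
#' Computes membership per drug and per event once, then forms every
#' pairwise table, which is much faster than repeated [build_table()] calls
#' when screening a whole drug and event vocabulary.
#'
#' @param reports A report tibble.
#' @param drugs Character vector of canonical drug names.
#' @param events Character vector of event preferred terms.
#' @return A tibble with one row per (drug, event) pair and columns
#'   `drug, event, a, b, c, d`.
#' @export
build_tables <- function(reports, drugs, events) {
  if (nrow(reports) == 0) {
    stop_format("cannot build contingency tables from zero reports")
  }
  n <- nrow(reports)
  D <- vapply(drugs, function(d) report_has_drug(reports, d),
              logical(n))
  E <- vapply(events, function(e) report_has_event(reports, e),
              logical(n))
  a <- crossprod(D, E)                      # drugs x events
  drug_tot <- colSums(D)
  event_tot <- colSums(E)
  grid <- expand.grid(drug = drugs, event = events,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  av <- as.vector(a)
  bv <- unname(rep(event_tot, each = length(drugs)) - av)
  cv <- unname(rep(drug_tot, times = length(events)) - av)
  tibble::tibble(
    drug = grid$drug, event = grid$event,
    a = av, b = bv, c = cv, d = n - av - bv - cv
  )
}

#' Define a stratification of the report set
#'
#' A stratum specification is a named list of predicates over the report
#' table; bins must be mutually exclusive and a report whose stratum
#' variable is missing matches no bin.
#'
#' @param variable Name of the stratified variable (informational).
#' @param bins Named list of functions, each mapping a report tibble to a
#'   logical vector (`NA` treated as no match).
#' @return An object of class `stratum_spec`.
#' @seealso [sex_strata()], [age_strata()] for the conventional subgroup
#'   specifications.
#' @export
stratum_spec <- function(variable, bins) {
  if (length(bins) == 0 || is.null(names(bins)) || any(!nzchar(names(bins)))) {
    stop_config("stratum bins must be a non-empty named list of predicates")
  }
  structure(list(variable = variable, bins = bins), class = "stratum_spec")
}

#' Sex strata (male, female; unknown excluded)
#' @return A [stratum_spec()] with bins `male` and `female`.
#' @export
sex_strata <- function() {
  stratum_spec("sex", list(
    male = function(r) r$sex == "male",
    female = function(r) r$sex == "female"
  ))
}

#' Age strata: under 18, 18-65, over 65
#'
#' The boundary ages 18 and 65 belong to the middle bin (closed interval),
#' consistent with the conventional labels `<18`, `18-65`, `>65`. Reports
#' with missing age match no bin.
#'
#' @return A [stratum_spec()] with the three age bins.
#' @export
age_strata <- function() {
  stratum_spec("age", list(
    "<18" = function(r) !is.na(r$age_years) & r$age_years < 18,
    "18-65" = function(r) !is.na(r$age_years) &
      r$age_years >= 18 & r$age_years <= 65,
    ">65" = function(r) !is.na(r$age_years) & r$age_years > 65
  ))
}

#' Partition reports into strata
#'
#' @param reports A report tibble.
#' @param spec A [stratum_spec()].
#' @return A named list of disjoint report sub-tibbles, one per bin.
#'   Reports matching no bin (missing stratum variable) are excluded, so
#'   the union size is the input size minus the unmatched reports.
#' @export
stratify <- function(reports, spec) {
  stopifnot(inherits(spec, "stratum_spec"))
  ind <- vapply(spec$bins, function(f) {
    m <- f(reports)
    m & !is.na(m)
  }, logical(nrow(reports)))
  if (nrow(reports) == 1) ind <- matrix(ind, nrow = 1,
                                        dimnames = list(NULL, names(spec$bins)))
  if (nrow(reports) > 0 && any(rowSums(ind) > 1)) {
    stop_config(sprintf("stratum bins for '%s' overlap", spec$variable))
  }
  out <- lapply(names(spec$bins), function(b) reports[ind[, b], ])
  stats::setNames(out, names(spec$bins))
}
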