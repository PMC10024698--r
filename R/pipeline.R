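# Orchestration of the full screening analysis: descriptive characteristics
# of the cases behind a drug-event pair, overall disproportionality for each
# drug in a target list, and sex/age subgroup analyses.

#' Analysis configuration
#'
#' @param drugs Canonical names of the drugs of interest. Default: the
#'   five triazole antifungals.
#' @param event Event preferred term of interest.
#' @param strata List of [stratum_spec()]s for subgroup analyses; default
#'   sex (male/female) and the three conventional age bins.
#' @param criteria [signal_criteria()] for flagging positive signals.
#' @param level Confidence level for intervals.
#' @param synonyms [synonym_map()] applied before analysis.
#' @param normalize,dedupe Run [normalize_drugs()] /
#'   [deduplicate_reports()] before analysis (both default `TRUE`; counting
#'   is per case).
#' @param rrr_method RRR convention, see [rrr()].
#' @param year_anchor First year of the 4-year year-band grid used in the
#'   descriptive table.
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(drugs = c("fluconazole", "itraconazole",
                                      "voriconazole", "posaconazole",
                                      "ravuconazole"),
                            event = "Periostitis",
                            strata = list(sex = sex_strata(),
                                          age = age_strata()),
                            criteria = signal_criteria(),
                            level = 0.95,
                            synonyms = synonym_map(),
                            normalize = TRUE, dedupe = TRUE,
                            rrr_method = c("rate_ratio",
                                           "observed_expected"),
                            year_anchor = 2007) {
  if (length(drugs) == 0) stop_config("drug list must be non-empty")
  if (!is_string(event) || !nzchar(event)) {
    stop_config("event must be a non-empty string")
  }
  structure(
    list(drugs = drugs, event = event, strata = strata,
         criteria = criteria, level = level, synonyms = synonyms,
         normalize = normalize, dedupe = dedupe,
         rrr_method = match.arg(rrr_method), year_anchor = year_anchor),
    class = "analysis_config"
  )
}

#' Read an analysis configuration from a YAML file
#'
#' Recognized keys: `drugs` (list), `event`, `level`, `rrr_method`,
#' `year_anchor`, and `criteria` with `min_n`, `min_chi2`, `min_prr`,
#' `strictness`. Missing keys fall back to the [analysis_config()]
#' defaults.
#'
#' @param path YAML file path.
#' @return An [analysis_config()].
#' @export
read_analysis_config <- function(path) {
  if (!file.exists(path)) stop_format(sprintf("file not found: %s", path))
  y <- yaml::read_yaml(path)
  defaults <- analysis_config()
  crit <- y$criteria
  criteria <- if (is.null(crit)) defaults$criteria else
    signal_criteria(
      min_n = crit$min_n %||% 3, min_chi2 = crit$min_chi2 %||% 4,
      min_prr = crit$min_prr %||% 2,
      strictness = crit$strictness %||% "strict_greater"
    )
  analysis_config(
    drugs = unlist(y$drugs) %||% defaults$drugs,
    event = y$event %||% defaults$event,
    criteria = criteria,
    level = y$level %||% defaults$level,
    rrr_method = y$rrr_method %||% defaults$rrr_method,
    year_anchor = y$year_anchor %||% defaults$year_anchor
  )
}

quarter_year <- function(quarter) as.integer(substr(quarter, 1, 4))

year_band <- function(quarter, anchor = 2007, width = 4) {
  year <- quarter_year(quarter)
  start <- anchor + width * floor((year - anchor) / width)
  sprintf("%d-%d", start, start + width - 1)
}

# Outcome shown in the descriptive table: the most serious one reported,
# so every case contributes to exactly one category.
OUTCOME_SEVERITY <- c("death", "life_threatening", "hospitalization",
                      "disability", "other", "unknown")

primary_outcome <- function(outcomes) {
  vapply(outcomes, function(o) {
    OUTCOME_SEVERITY[min(match(o, OUTCOME_SEVERITY))]
  }, "")
}

primary_indication <- function(indications) {
  vapply(indications, function(i) {
    if (length(i) == 0) "Unknown" else i[[1]]
  }, "")
}

count_block <- function(variable, values, total, order_by_count = FALSE,
                        level_order = NULL) {
  tab <- table(values)
  labels <- names(tab)
  if (!is.null(level_order)) {
    labels <- c(intersect(level_order, labels),
                setdiff(labels, level_order))
  } else if (order_by_count) {
    known <- setdiff(labels, "Unknown")
    known <- known[order(-tab[known], known)]
    labels <- c(known, intersect("Unknown", labels))
  } else {
    labels <- sort(labels)
  }
  tibble::tibble(
    variable = variable, category = labels,
    count = as.integer(tab[labels]),
    percent = 100 * as.integer(tab[labels]) / total
  )
}

#' Descriptive characteristics of a report set
#'
#' Counts and percentages by sex, age bin, 4-year year band, reporting
#' country, (most serious) outcome and primary indication, in the layout
#' of a "Table 1" for the cases behind one drug-event pair. Percentages
#' use the overall set size as denominator for every variable, and
#' unknowns are included as their own categories, so each variable's
#' counts sum to the total.
#'
#' @param reports Non-empty report tibble (typically restricted to the
#'   cases reporting the drug and event of interest).
#' @param age_spec [stratum_spec()] for the age bins.
#' @param year_anchor First year of the 4-year band grid.
#' @return A tibble with columns `variable, category, count, percent`
#'   (percent unrounded; conventional display is one decimal).
#' @export
summarize_characteristics <- function(reports, age_spec = age_strata(),
                                      year_anchor = 2007) {
  validate_reports(reports)
  total <- nrow(reports)
  if (total == 0) stop_format("cannot summarize an empty report set")

  sex_label <- c(male = "Male", female = "Female", unknown = "Unknown")
  age_values <- rep("Unknown", total)
  for (b in names(age_spec$bins)) {
    m <- age_spec$bins[[b]](reports)
    age_values[m & !is.na(m)] <- b
  }
  out <- rbind(
    count_block("sex", unname(sex_label[reports$sex]), total,
                level_order = c("Male", "Female", "Unknown")),
    count_block("age", age_values, total,
                level_order = c(names(age_spec$bins), "Unknown")),
    count_block("year", year_band(reports$quarter, year_anchor), total),
    count_block("country",
                ifelse(is.na(reports$country), "Unknown", reports$country),
                total, order_by_count = TRUE),
    count_block("outcome", primary_outcome(reports$outcomes), total,
                level_order = c("death", "hospitalization",
                                "life_threatening", "disability", "other",
                                "unknown")),
    count_block("indication", primary_indication(reports$indications),
                total, order_by_count = TRUE)
  )
  tibble::as_tibble(out)
}

no_data_row <- function(drug, event, stratum) {
  tibble::tibble(
    drug = drug, event = event, stratum = stratum, n = 0, chi2 = NA_real_,
    rrr = NA_real_, rrr_lo = NA_real_, rrr_hi = NA_real_,
    prr = NA_real_, prr_lo = NA_real_, prr_hi = NA_real_,
    ror = NA_real_, ror_lo = NA_real_, ror_hi = NA_real_,
    ic = NA_real_, ic_lo = NA_real_, ic_hi = NA_real_
  )
}

analyze_one <- function(reports, drug, event, stratum, config) {
  t <- build_table(reports, drug, event, stratum = stratum)
  if (t$a == 0) {
    row <- no_data_row(drug, event, stratum)
    row$signal <- FALSE
    return(list(table = t, row = row))
  }
  s <- compute_all(t, level = config$level, rrr_method = config$rrr_method)
  row <- as_tibble_row(s)
  row$signal <- evaluate_signal(s, config$criteria)
  list(table = t, row = row)
}

#' Run the full disproportionality analysis
#'
#' For every drug in the configuration: the overall contingency table and
#' statistics against the event of interest, per-stratum tables and
#' statistics for each configured subgroup specification, and a
#' descriptive characteristics table for the drugs with at least one
#' matching case. Drugs absent from the database yield `n = 0` "no data"
#' rows rather than errors; if the event is absent from the whole database
#' a warning is raised and every `n` is zero.
#'
#' The result rows are a pure function of `(reports, config)`: re-running
#' on the same inputs reproduces them exactly.
#'
#' @param reports A report tibble (raw versions are fine: normalization
#'   and case deduplication run first unless disabled in the config).
#' @param config An [analysis_config()].
#' @return An object of class `disprop_result`: list with `results` (one
#'   tibble row per drug x stratum, including `"overall"`),
#'   `characteristics` (named list of tibbles per drug with cases),
#'   `tables` (the contingency tables), `config` and `n_reports`.
#' @export
run_analysis <- function(reports, config = analysis_config()) {
  stopifnot(inherits(config, "analysis_config"))
  validate_reports(reports)
  if (config$normalize) reports <- normalize_drugs(reports, config$synonyms)
  if (config$dedupe) reports <- deduplicate_reports(reports)
  if (nrow(reports) == 0) stop_format("no reports to analyze")
  if (!any(report_has_event(reports, config$event))) {
    warning(sprintf("event '%s' is absent from the database; all counts are zero",
                    config$event), call. = FALSE)
  }

  subsets_by_spec <- lapply(config$strata, function(spec)
    stratify(reports, spec))

  rows <- list()
  tables <- list()
  for (drug in config$drugs) {
    res <- analyze_one(reports, drug, config$event, "overall", config)
    rows[[length(rows) + 1]] <- res$row
    tables[[paste(drug, "overall", sep = "|")]] <- res$table
    for (spec_name in names(config$strata)) {
      subsets <- subsets_by_spec[[spec_name]]
      for (bin in names(subsets)) {
        sub <- subsets[[bin]]
        if (nrow(sub) == 0) next
        res <- analyze_one(sub, drug, config$event, bin, config)
        rows[[length(rows) + 1]] <- res$row
        tables[[paste(drug, bin, sep = "|")]] <- res$table
      }
    }
  }
  results <- do.call(rbind, rows)

  characteristics <- list()
  for (drug in config$drugs) {
    keep <- report_has_drug(reports, drug) &
      report_has_event(reports, config$event)
    if (any(keep)) {
      characteristics[[drug]] <- summarize_characteristics(
        reports[keep, ], year_anchor = config$year_anchor
      )
    }
  }

  structure(
    list(results = results, characteristics = characteristics,
         tables = tables, config = config, n_reports = nrow(reports)),
    class = "disprop_result"
  )
}

#' @export
print.disprop_result <- function(x, digits = 1, ...) {
  cat(sprintf("Disproportionality analysis: event '%s', %d drug(s), %s deduplicated reports\n",
              x$config$event, length(x$config$drugs),
              format(x$n_reports, big.mark = ",")))
  shown <- x$results
  num <- vapply(shown, is.numeric, TRUE)
  shown[num] <- lapply(shown[num], round_half_up, digits = digits)
  print(shown, n = nrow(shown))
  invisible(x)
}

#' Write analysis results to CSV files
#'
#' Writes `results.csv` (`drug,event,stratum,n,chi2,rrr,rrr_lo,rrr_hi,prr,
#' prr_lo,prr_hi,ror,ror_lo,ror_hi,ic,ic_lo,ic_hi,signal`), one
#' `characteristics_<drug>.csv` per drug with cases
#' (`variable,category,count,percent`), and `run_log.txt` with the run
#' parameters. Output is deterministic: re-running the same analysis
#' reproduces the files byte for byte.
#'
#' @param x A `disprop_result`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_results <- function(x, dir) {
  stopifnot(inherits(x, "disprop_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(x$results, file.path(dir, "results.csv"),
                   row.names = FALSE, quote = FALSE)
  for (drug in names(x$characteristics)) {
    utils::write.csv(x$characteristics[[drug]],
                     file.path(dir, sprintf("characteristics_%s.csv", drug)),
                     row.names = FALSE, quote = FALSE)
  }
  cfg <- x$config
  log_lines <- c(
    "pvsignal run log",
    sprintf("drugs: %s", paste(cfg$drugs, collapse = ", ")),
    sprintf("event: %s", cfg$event),
    sprintf("level: %s", cfg$level),
    sprintf("rrr_method: %s", cfg$rrr_method),
    sprintf("criteria: n > %s, chi2 > %s, prr > %s (%s)",
            cfg$criteria$min_n, cfg$criteria$min_chi2, cfg$criteria$min_prr,
            cfg$criteria$strictness),
    sprintf("n_reports_analyzed: %d", x$n_reports)
  )
  writeLines(log_lines, file.path(dir, "run_log.txt"))
  invisible(dir)
}
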