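# Data model for spontaneous adverse-event reports: a flat, FAERS-like table
# with one row per report version. Multi-valued fields (drugs, reactions,
# outcomes, indications) are list-columns; drugs are named character vectors
# mapping drug name -> role code.

REPORT_COLUMNS <- c(
  "report_id", "case_id", "version", "sex", "age_years", "country",
  "quarter", "drugs", "reactions", "outcomes", "indications"
)

SEX_LEVELS <- c("male", "female", "unknown")
SEX_CODES <- c(M = "male", `F` = "female")

# role precedence: suspect roles outrank concomitant/interacting
ROLE_LEVELS <- c("PS", "SS", "C", "I", "unknown")

OUTCOME_CODES <- c(
  DE = "death", HO = "hospitalization", LT = "life_threatening",
  DS = "disability", OT = "other"
)
OUTCOME_LEVELS <- c(unname(OUTCOME_CODES), "unknown")

AGE_MAX <- 130

#' Construct a table of spontaneous reports
#'
#' Builds the validated tibble used throughout the package: one row per
#' report version, with list-columns for the multi-valued fields.
#'
#' @param report_id Unique report identifiers (character).
#' @param case_id Case identifiers, stable across versions of the same case.
#' @param version Non-negative integer report versions.
#' @param sex One of `"male"`, `"female"`, `"unknown"` per report.
#' @param age_years Age in years (`NA` for missing), in `[0, 130]`.
#' @param country Reporting country (`NA` for missing).
#' @param quarter Receipt quarter as `"YYYYQn"`.
#' @param drugs List of named character vectors: names are drug names,
#'   values are role codes (`"PS"`, `"SS"`, `"C"`, `"I"`, `"unknown"`).
#'   Plain (unnamed) character vectors are given role `"unknown"`.
#' @param reactions List of character vectors of event preferred terms.
#' @param outcomes List of character vectors drawn from
#'   `death, hospitalization, life_threatening, disability, other, unknown`.
#' @param indications List of character vectors (may be empty).
#' @return A tibble with the eleven report columns, validated.
#' @examples
#' report_table(
#'   report_id = "r1", case_id = "c1", version = 0, sex = "male",
#'   age_years = 54, country = "US", quarter = "2019Q1",
#'   drugs = list(c(voriconazole = "PS")), reactions = list("Periostitis")
#' )
#' @export
report_table <- function(report_id, case_id, version = 0L,
                         sex = "unknown", age_years = NA_real_,
                         country = NA_character_, quarter,
                         drugs, reactions,
                         outcomes = NULL, indications = NULL) {
  n <- length(report_id)
  if (!is.list(drugs)) drugs <- list(drugs)
  if (!is.list(reactions)) reactions <- list(reactions)
  drugs <- lapply(drugs, function(d) {
    if (is.null(names(d))) d <- stats::setNames(rep("unknown", length(d)), d)
    stats::setNames(unname(unclass(d)), names(d))
  })
  outcomes <- outcomes %||% rep(list("unknown"), n)
  indications <- indications %||% rep(list(character()), n)
  if (!is.list(outcomes)) outcomes <- list(outcomes)
  if (!is.list(indications)) indications <- list(indications)
  reports <- tibble::tibble(
    report_id = as.character(report_id),
    case_id = as.character(case_id),
    version = as.integer(version),
    sex = as.character(sex),
    age_years = as.numeric(age_years),
    country = as.character(country),
    quarter = as.character(quarter),
    drugs = drugs,
    reactions = reactions,
    outcomes = outcomes,
    indications = indications
  )
  validate_reports(reports)
}

#' Validate a report table
#'
#' Checks the structural invariants of the report data model: required
#' columns, non-empty drug and reaction lists, sex in its three-level
#' enumeration, versions non-negative, and ages (when present) in
#' `[0, 130]`.
#'
#' @param reports A report tibble as returned by [report_table()] or
#'   [read_reports()].
#' @return `reports`, invisibly unchanged, if valid; otherwise an error.
#' @export
validate_reports <- function(reports) {
  missing_cols <- setdiff(REPORT_COLUMNS, names(reports))
  if (length(missing_cols) > 0) {
    stop_format(sprintf(
      "report table is missing column(s): %s",
      paste(missing_cols, collapse = ", ")
    ))
  }
  bad <- which(
    !(reports$sex %in% SEX_LEVELS) |
      is.na(reports$version) | reports$version < 0 |
      (!is.na(reports$age_years) &
         (reports$age_years < 0 | reports$age_years > AGE_MAX)) |
      lengths(reports$drugs) == 0 |
      lengths(reports$reactions) == 0
  )
  if (length(bad) > 0) {
    stop_record(
      sprintf(
        "invalid report record(s) at row(s) %s (check sex, version, age range, non-empty drugs/reactions)",
        paste(utils::head(bad, 10), collapse = ", ")
      ),
      rows = bad
    )
  }
  reports
}

parse_drug_cell <- function(cell) {
  if (is.na(cell) || !nzchar(cell)) {
    return(stats::setNames(character(), character()))
  }
  tokens <- strsplit(cell, "|", fixed = TRUE)[[1]]
  parts <- strsplit(tokens, ":", fixed = TRUE)
  nm <- vapply(parts, `[[`, "", 1L)
  role <- vapply(parts, function(p) if (length(p) >= 2) p[[2]] else "unknown", "")
  role[!(role %in% ROLE_LEVELS)] <- "unknown"
  stats::setNames(role, nm)
}

split_cell <- function(cell) {
  if (is.na(cell) || !nzchar(cell)) character() else
    strsplit(cell, "|", fixed = TRUE)[[1]]
}

parse_outcome_cell <- function(cell) {
  codes <- split_cell(cell)
  if (length(codes) == 0) return("unknown")
  out <- unname(OUTCOME_CODES[codes])
  if (anyNA(out)) return(NULL) # signal invalid code to the caller
  out
}

#' Read spontaneous reports from the flat CSV dialect
#'
#' Reads a UTF-8 comma-separated report table with header
#' `report_id,case_id,version,sex,age_years,country,quarter,drugs,reactions,outcomes,indications`.
#' `drugs` is `name:role|name:role|...`; `reactions`, `outcomes` and
#' `indications` are pipe-delimited; an empty cell means missing. Sex codes
#' are `M`, `F` or empty (unknown); outcome codes are `DE`, `HO`, `LT`,
#' `DS`, `OT` or empty (unknown).
#'
#' @param path Path to the CSV file.
#' @param on_error `"fail"` (default) stops at the first invalid record;
#'   `"skip"` drops invalid rows with a warning naming them.
#' @return A validated report tibble, one row per input row, in file order.
#' @seealso [write_reports()] for the inverse operation.
#' @export
read_reports <- function(path, on_error = c("fail", "skip")) {
  on_error <- match.arg(on_error)
  if (!file.exists(path)) stop_format(sprintf("file not found: %s", path))
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         na.strings = NULL)
  missing_cols <- setdiff(REPORT_COLUMNS, names(raw))
  if (length(missing_cols) > 0) {
    stop_format(sprintf(
      "malformed header: missing column(s) %s",
      paste(missing_cols, collapse = ", ")
    ))
  }
  n <- nrow(raw)
  if (n == 0) {
    return(report_table(
      report_id = character(), case_id = character(), version = integer(),
      sex = character(), age_years = numeric(), country = character(),
      quarter = character(), drugs = list(), reactions = list(),
      outcomes = list(), indications = list()
    ))
  }

  version <- suppressWarnings(as.integer(raw$version))
  sex <- ifelse(raw$sex == "", "unknown",
                unname(SEX_CODES[raw$sex]))
  age <- suppressWarnings(as.numeric(ifelse(raw$age_years == "", NA, raw$age_years)))
  age_given <- raw$age_years != ""
  country <- ifelse(raw$country == "", NA_character_, raw$country)
  quarter_ok <- grepl("^[0-9]{4}Q[1-4]$", raw$quarter)

  drugs <- lapply(raw$drugs, parse_drug_cell)
  reactions <- lapply(raw$reactions, split_cell)
  outcomes <- lapply(raw$outcomes, parse_outcome_cell)
  indications <- lapply(raw$indications, split_cell)

  bad <- which(
    is.na(version) | version < 0 |
      is.na(sex) |
      (age_given & (is.na(age) | age < 0 | age > AGE_MAX)) |
      !quarter_ok |
      lengths(drugs) == 0 |
      lengths(reactions) == 0 |
      vapply(outcomes, is.null, TRUE)
  )
  if (length(bad) > 0) {
    msg <- sprintf(
      "invalid record(s) at data row(s) %s",
      paste(utils::head(bad, 10), collapse = ", ")
    )
    if (on_error == "fail") stop_record(msg, rows = bad)
    warning(paste(msg, "- skipped"), call. = FALSE)
  }
  keep <- if (length(bad) > 0) -bad else seq_len(n)
  reports <- tibble::tibble(
    report_id = raw$report_id, case_id = raw$case_id, version = version,
    sex = sex, age_years = age, country = country, quarter = raw$quarter,
    drugs = drugs, reactions = reactions, outcomes = outcomes,
    indications = indications
  )[keep, ]
  validate_reports(reports)
}

format_drug_cell <- function(d) {
  paste(paste(names(d), unname(d), sep = ":"), collapse = "|")
}

format_outcome_cell <- function(o) {
  if (identical(o, "unknown")) return("")
  codes <- names(OUTCOME_CODES)[match(o, OUTCOME_CODES)]
  paste(codes, collapse = "|")
}

format_age <- function(a) {
  ifelse(is.na(a), "", vapply(a, function(x) {
    if (is.na(x)) "" else format(x, trim = TRUE, scientific = FALSE)
  }, ""))
}

#' Write spontaneous reports to the flat CSV dialect
#'
#' Inverse of [read_reports()]: a valid report table written with
#' `write_reports()` and re-read with `read_reports()` round-trips exactly,
#' and a file in canonical form round-trips byte-identically.
#'
#' @param reports A validated report tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_reports <- function(reports, path) {
  validate_reports(reports)
  sex_code <- c(male = "M", female = "F", unknown = "")
  out <- data.frame(
    report_id = reports$report_id,
    case_id = reports$case_id,
    version = reports$version,
    sex = unname(sex_code[reports$sex]),
    age_years = format_age(reports$age_years),
    country = ifelse(is.na(reports$country), "", reports$country),
    quarter = reports$quarter,
    drugs = vapply(reports$drugs, format_drug_cell, ""),
    reactions = vapply(reports$reactions, paste, "", collapse = "|"),
    outcomes = vapply(reports$outcomes, format_outcome_cell, ""),
    indications = vapply(reports$indications, paste, "", collapse = "|"),
    check.names = FALSE, stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "")
  invisible(path)
}

#' Drug-name synonym map
#'
#' A total, case-insensitive lookup from raw drug strings (generic names,
#' brand names, abbreviations) to canonical names. Strings without an
#' explicit mapping canonicalize to their lower-cased, whitespace-trimmed
#' form, so lookup never fails.
#'
#' @param x A named character vector (`c(raw = "canonical")`), a two-column
#'   data frame with columns `raw` and `canonical`, or `NULL` for the empty
#'   map (pure lower-case/trim normalization).
#' @return An object of class `synonym_map`.
#' @examples
#' m <- synonym_map(c(VFEND = "voriconazole"))
#' canonical_name(c("VFEND", "  DiFLUcan "), m)
#' @export
synonym_map <- function(x = NULL) {
  if (is.null(x)) {
    map <- stats::setNames(character(), character())
  } else if (is.data.frame(x)) {
    if (!all(c("raw", "canonical") %in% names(x))) {
      stop_format("synonym data frame needs columns 'raw' and 'canonical'")
    }
    map <- stats::setNames(as.character(x$canonical), as.character(x$raw))
  } else if (is.character(x) && !is.null(names(x))) {
    map <- x
  } else {
    stop_format("synonym_map() expects a named character vector, a data frame, or NULL")
  }
  names(map) <- tolower(trimws(names(map)))
  structure(map, class = "synonym_map")
}

#' Read a synonym map from a two-column CSV
#'
#' @param path CSV file with header `raw,canonical`.
#' @return A [synonym_map()].
#' @export
read_synonym_map <- function(path) {
  if (!file.exists(path)) stop_format(sprintf("file not found: %s", path))
  synonym_map(utils::read.csv(path, colClasses = "character"))
}

#' Canonicalize raw drug names
#'
#' @param x Character vector of raw drug strings.
#' @param synonyms A [synonym_map()].
#' @return Character vector of canonical names; unmapped strings fall back
#'   to their lower-cased, trimmed form.
#' @export
canonical_name <- function(x, synonyms = synonym_map()) {
  key <- tolower(trimws(x))
  hit <- match(key, names(synonyms))
  ifelse(is.na(hit), key, unname(unclass(synonyms))[hit])
}

#' Normalize drug names within reports
#'
#' Replaces every drug name by its canonical form and collapses duplicate
#' canonical names within a report to a single entry, keeping the
#' highest-precedence role (`PS > SS > C > I > unknown`). Idempotent once
#' all names are canonical.
#'
#' @param reports A report tibble.
#' @param synonyms A [synonym_map()].
#' @return The report tibble with normalized `drugs`.
#' @export
normalize_drugs <- function(reports, synonyms = synonym_map()) {
  validate_reports(reports)
  reports$drugs <- lapply(reports$drugs, function(d) {
    nm <- canonical_name(names(d), synonyms)
    role <- unname(d)
    # order by role precedence, keep first occurrence of each name,
    # then restore first-appearance order of the canonical names
    prec <- match(role, ROLE_LEVELS)
    o <- order(prec)
    keep <- o[!duplicated(nm[o])]
    keep <- keep[order(match(nm[keep], unique(nm)))]
    stats::setNames(role[keep], nm[keep])
  })
  reports
}

#' Deduplicate report versions to one report per case
#'
#' FAERS-style databases carry multiple versions of the same case; counting
#' is done on cases ("patients"). For each `case_id` the retained report is
#' the one with the highest `version`; ties are broken by latest `quarter`,
#' then largest `report_id` (string order). Idempotent; the output has
#' exactly one row per distinct `case_id`, in input order of the retained
#' rows.
#'
#' @param reports A report tibble.
#' @return The deduplicated report tibble.
#' @export
deduplicate_reports <- function(reports) {
  validate_reports(reports)
  if (nrow(reports) == 0) return(reports)
  o <- order(reports$case_id, reports$version, reports$quarter,
             reports$report_id)
  winner_last <- !duplicated(reports$case_id[o], fromLast = TRUE)
  keep <- sort(seq_len(nrow(reports))[o][winner_last])
  reports[keep, ]
}

#' Does each report mention a drug?
#'
#' @param reports A report tibble.
#' @param drug Canonical drug name. A report is exposed if the name appears
#'   in its drug list in any role.
#' @return Logical vector along the rows of `reports`.
#' @export
report_has_drug <- function(reports, drug) {
  # flat scan over the unlisted drug names (names survive unlist because
  # the list column itself is unnamed) -- much faster than a per-row loop
  lens <- lengths(reports$drugs)
  nm <- names(unlist(unname(reports$drugs)))
  out <- logical(nrow(reports))
  out[rep.int(seq_along(lens), lens)[nm == drug]] <- TRUE
  out
}

#' Does each report mention an event?
#'
#' Matching is case-insensitive exact equality on the preferred-term string
#' (no dictionary-hierarchy expansion).
#'
#' @param reports A report tibble.
#' @param event Event preferred term.
#' @return Logical vector along the rows of `reports`.
#' @export
report_has_event <- function(reports, event) {
  lens <- lengths(reports$reactions)
  flat <- unlist(unname(reports$reactions), use.names = FALSE)
  hit <- tolower(flat) == tolower(event)
  out <- logical(nrow(reports))
  out[rep.int(seq_along(lens), lens)[hit]] <- TRUE
  out
}
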