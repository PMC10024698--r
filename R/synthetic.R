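# Seeded generator of synthetic spontaneous-report databases with known
# ground-truth reporting odds ratios.
#
# Signals act multiplicatively on the REPORTING ODDS of an event: for a
# report exposed to a signal drug, odds(event) = baseline_odds * theta.
# Because drug exposures are drawn independently of everything else, theta
# is exactly the asymptotic reporting odds ratio of the (drug, event) pair,
# which is what the parameter-recovery tests target. The at-least-one-drug
# and at-least-one-reaction constraints are enforced by redrawing whole
# rows, which leaves the odds ratio untouched (the conditioning event is
# independent of exposure).

default_drug_probs <- function() c(
  # drugs of interest: plausible exposure rates for systemic antifungals
  voriconazole = 0.004, fluconazole = 0.008, itraconazole = 0.004,
  posaconazole = 0.002, ravuconazole = 0.0002,
  # background co-medication
  paracetamol = 0.10, aspirin = 0.08, ibuprofen = 0.06,
  atorvastatin = 0.05, metformin = 0.05, lisinopril = 0.04,
  omeprazole = 0.04, amoxicillin = 0.03, prednisone = 0.03,
  furosemide = 0.03, warfarin = 0.02, sertraline = 0.02
)

default_event_probs <- function() c(
  # a rare designated event plus common background reactions
  Periostitis = 1e-4,
  Nausea = 0.06, Headache = 0.05, `Drug ineffective` = 0.05,
  Rash = 0.04, Diarrhoea = 0.04, Vomiting = 0.03, Dizziness = 0.03,
  Fatigue = 0.03, Pyrexia = 0.02, Pruritus = 0.02
)

default_country_probs <- function() c(
  US = 0.60, CA = 0.08, GB = 0.05, FR = 0.04, DE = 0.04, AU = 0.03,
  JP = 0.03, other = 0.08, unknown = 0.05
)

default_outcome_probs <- function() c(
  other = 0.40, hospitalization = 0.25, unknown = 0.20, disability = 0.06,
  death = 0.05, life_threatening = 0.04
)

default_indication_probs <- function() c(
  infection = 0.25, prophylaxis = 0.10, hypertension = 0.15,
  diabetes = 0.10, pain = 0.15, depression = 0.05, none = 0.20
)

#' Configuration of the synthetic report generator
#'
#' @param n_reports Number of cases to generate (superseded duplicate
#'   versions come on top).
#' @param seed Integer seed; the same config and seed always produce the
#'   identical database.
#' @param drug_probs Named vector of independent per-report exposure
#'   probabilities.
#' @param event_probs Named vector of baseline reporting probabilities
#'   (converted to odds internally).
#' @param signals Data frame with columns `drug`, `event`, `theta`: each
#'   exposure to `drug` multiplies the reporting odds of `event` by
#'   `theta` (`theta = 1` is the null).
#' @param sex_probs Named probabilities for `male`, `female`, `unknown`.
#' @param age_probs Named probabilities for the age bins `<18`, `18-65`,
#'   `>65` and `unknown` (missing age). Ages are drawn uniformly on the
#'   integers 0-17, 18-65 and 66-95 within the bins.
#' @param country_probs Categorical distribution of reporting country
#'   (`unknown` maps to a missing country).
#' @param outcome_probs Categorical distribution of the single reported
#'   outcome.
#' @param indication_probs Categorical distribution of the primary
#'   indication (`none` maps to an empty indication list).
#' @param duplicate_rate Fraction of cases that also emit a superseded
#'   earlier version (for deduplication testing).
#' @param quarters Character vector of candidate receipt quarters,
#'   sampled uniformly.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_reports = 50000, seed = 1,
                             drug_probs = default_drug_probs(),
                             event_probs = default_event_probs(),
                             signals = data.frame(
                               drug = "voriconazole", event = "Periostitis",
                               theta = 20
                             ),
                             sex_probs = c(male = 0.48, female = 0.41,
                                           unknown = 0.11),
                             age_probs = c(`<18` = 0.05, `18-65` = 0.60,
                                           `>65` = 0.25, unknown = 0.10),
                             country_probs = default_country_probs(),
                             outcome_probs = default_outcome_probs(),
                             indication_probs = default_indication_probs(),
                             duplicate_rate = 0.05,
                             quarters = all_quarters()) {
  if (!is_count(n_reports) || n_reports <= 0) {
    stop_config("n_reports must be a positive integer")
  }
  if (!is_count(abs(seed))) stop_config("seed must be an integer")
  check_prob_vector(drug_probs, "drug_probs")
  check_prob_vector(event_probs, "event_probs")
  check_distribution(sex_probs[c("male", "female", "unknown")], "sex_probs")
  check_distribution(age_probs, "age_probs")
  check_distribution(country_probs, "country_probs")
  check_distribution(outcome_probs[names(default_outcome_probs())],
                     "outcome_probs")
  check_distribution(indication_probs, "indication_probs")
  check_prob_vector(duplicate_rate, "duplicate_rate")
  if (nrow(signals) > 0) {
    if (!all(c("drug", "event", "theta") %in% names(signals))) {
      stop_config("signals needs columns drug, event, theta")
    }
    if (any(signals$theta <= 0)) stop_config("signal theta must be > 0")
    if (!all(signals$drug %in% names(drug_probs))) {
      stop_config("signal drugs must appear in drug_probs")
    }
    if (!all(signals$event %in% names(event_probs))) {
      stop_config("signal events must appear in event_probs")
    }
  }
  structure(
    list(n_reports = n_reports, seed = seed, drug_probs = drug_probs,
         event_probs = event_probs, signals = signals,
         sex_probs = sex_probs, age_probs = age_probs,
         country_probs = country_probs, outcome_probs = outcome_probs,
         indication_probs = indication_probs,
         duplicate_rate = duplicate_rate, quarters = quarters),
    class = "synthetic_config"
  )
}

#' All quarters from 2004Q1 to 2022Q2
#' @return Character vector of `"YYYYQn"` strings.
#' @export
all_quarters <- function() {
  q <- as.vector(outer(1:4, 2004:2022, function(q, y) sprintf("%d{Q}%d", y, q)))
  q <- sub("{Q}", "Q", q, fixed = TRUE)
  q[q >= "2004Q1" & q <= "2022Q2"]
}

sample_cat <- function(n, probs) {
  names(probs)[sample.int(length(probs), n, replace = TRUE, prob = probs)]
}

# Bernoulli matrix (n x length(p)), one column per named probability
bernoulli_matrix <- function(n, p) {
  m <- matrix(stats::runif(n * length(p)) <
                rep(p, each = n), nrow = n)
  colnames(m) <- names(p)
  m
}

# redraw rows of a Bernoulli matrix until each has at least one success
redraw_nonempty <- function(m, p, max_iter = 10000) {
  empty <- which(rowSums(m) == 0)
  iter <- 0
  while (length(empty) > 0) {
    iter <- iter + 1
    if (iter > max_iter) {
      # probabilities so small that redrawing is hopeless: force the most
      # probable column
      m[empty, which.max(p)] <- TRUE
      break
    }
    m[empty, ] <- matrix(stats::runif(length(empty) * length(p)) <
                           rep(p, each = length(empty)),
                         nrow = length(empty))
    empty <- empty[rowSums(m[empty, , drop = FALSE]) == 0]
  }
  m
}

# Split the TRUE entries of an indicator matrix into a per-row list of
# column names. Implemented by accumulating a delimited string per row and
# splitting once, which is much faster than split()/factor() at database
# scale; every row is assumed non-empty (enforced upstream by redraws).
rows_to_list <- function(m) {
  s <- character(nrow(m))
  for (j in seq_len(ncol(m))) {
    sel <- m[, j]
    s[sel] <- paste0(s[sel], "\x1f", colnames(m)[j])
  }
  strsplit(substring(s, 2), "\x1f", fixed = TRUE)
}

#' Generate a synthetic spontaneous-report database
#'
#' Draws, in a fixed documented order (sex; age bin; age; country;
#' quarter; drug exposures with redraw; drug roles; event indicators with
#' redraw; outcome; indication; duplicate-version flags), a database of
#' `config$n_reports` cases plus superseded versions for a
#' `duplicate_rate` fraction of them. All randomness comes from a single
#' seeded Mersenne-Twister stream, so the same config reproduces the same
#' database; the caller's RNG state is restored on exit.
#'
#' @param config A [synthetic_config()].
#' @return A list with `reports` (a validated report tibble) and
#'   `manifest` (a list recording every true parameter and the seed).
#' @export
generate_reports <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(config$seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  n <- config$n_reports

  sex <- sample_cat(n, config$sex_probs[c("male", "female", "unknown")])
  age_bin <- sample_cat(n, config$age_probs)
  age <- rep(NA_real_, n)
  i <- age_bin == "<18"; age[i] <- sample(0:17, sum(i), replace = TRUE)
  i <- age_bin == "18-65"; age[i] <- sample(18:65, sum(i), replace = TRUE)
  i <- age_bin == ">65"; age[i] <- sample(66:95, sum(i), replace = TRUE)
  country <- sample_cat(n, config$country_probs)
  country[country == "unknown"] <- NA_character_
  quarter <- sample(config$quarters, n, replace = TRUE)

  exposure <- bernoulli_matrix(n, config$drug_probs)
  exposure <- redraw_nonempty(exposure, config$drug_probs)
  role_pool <- c("PS", "SS", "C", "I")
  role_probs <- c(0.5, 0.2, 0.25, 0.05)

  # event odds per report: baseline odds times theta per exposed signal drug
  base_odds <- config$event_probs / (1 - config$event_probs)
  event_p <- matrix(rep(config$event_probs, each = n), nrow = n,
                    dimnames = list(NULL, names(config$event_probs)))
  if (nrow(config$signals) > 0) {
    for (k in seq_len(nrow(config$signals))) {
      s <- config$signals[k, ]
      odds <- base_odds[[s$event]] *
        ifelse(exposure[, s$drug], s$theta, 1)
      event_p[, s$event] <- odds / (1 + odds)
    }
  }
  events <- matrix(stats::runif(n * ncol(event_p)) < event_p, nrow = n,
                   dimnames = dimnames(event_p))
  # redraw all-empty reaction rows (row-specific probabilities)
  empty <- which(rowSums(events) == 0)
  iter <- 0
  while (length(empty) > 0 && iter < 10000) {
    iter <- iter + 1
    events[empty, ] <- matrix(
      stats::runif(length(empty) * ncol(event_p)) <
        event_p[empty, , drop = FALSE],
      nrow = length(empty)
    )
    empty <- empty[rowSums(events[empty, , drop = FALSE]) == 0]
  }
  if (length(empty) > 0) {
    events[empty, which.max(config$event_probs)] <- TRUE
  }

  drug_names <- rows_to_list(exposure)
  # roles drawn column by column (same accumulation order as the names)
  role_s <- character(n)
  for (j in seq_len(ncol(exposure))) {
    sel <- exposure[, j]
    role_s[sel] <- paste0(role_s[sel], "\x1f",
                          sample(role_pool, sum(sel), replace = TRUE,
                                 prob = role_probs))
  }
  roles <- strsplit(substring(role_s, 2), "\x1f", fixed = TRUE)
  drugs <- unname(Map(stats::setNames, roles, drug_names))
  reactions <- rows_to_list(events)

  outcome <- sample_cat(n, config$outcome_probs)
  indication <- sample_cat(n, config$indication_probs)
  indications <- as.list(indication)
  indications[indication == "none"] <- list(character())

  dup <- which(stats::runif(n) < config$duplicate_rate)
  idx <- c(seq_len(n), dup)
  ids <- paste0("r", seq_len(n))
  reports <- tibble::tibble(
    report_id = c(ids, if (length(dup) > 0) paste0(ids[dup], "v0")),
    case_id = paste0("c", idx),
    version = rep(c(1L, 0L), c(n, length(dup))),
    sex = sex[idx], age_years = age[idx], country = country[idx],
    quarter = quarter[idx],
    drugs = drugs[idx], reactions = reactions[idx],
    outcomes = as.list(outcome[idx]), indications = indications[idx]
  )
  reports <- validate_reports(reports)

  manifest <- list(
    seed = config$seed, n_reports = n, n_rows = nrow(reports),
    n_superseded = length(dup),
    drug_probs = config$drug_probs, event_probs = config$event_probs,
    signals = config$signals, sex_probs = config$sex_probs,
    age_probs = config$age_probs, country_probs = config$country_probs,
    outcome_probs = config$outcome_probs,
    indication_probs = config$indication_probs,
    duplicate_rate = config$duplicate_rate
  )
  list(reports = reports, manifest = manifest)
}

#' Write a generator manifest as key=value text
#'
#' @param manifest The `manifest` element returned by
#'   [generate_reports()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  fmt <- function(x) {
    if (is.data.frame(x)) {
      paste(apply(x, 1, paste, collapse = ":"), collapse = ";")
    } else if (!is.null(names(x)) && length(x) > 1) {
      paste(paste(names(x), x, sep = "="), collapse = ";")
    } else {
      paste(x, collapse = ";")
    }
  }
  writeLines(sprintf("%s=%s", names(manifest),
                     vapply(manifest, fmt, "")), path)
  invisible(path)
}
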