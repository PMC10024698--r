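# Fixtures built in code: no data files.

# Six reports over drugs {X, Y} and events {E, F}; for the pair (X, E) the
# manual enumeration gives a = 2 (r1, r5), b = 1 (r3), c = 1 (r2), d = 2
# (r4, r6).
fixture_six <- function() {
  report_table(
    report_id = paste0("r", 1:6),
    case_id = paste0("c", 1:6),
    version = 0L,
    sex = c("male", "female", "male", "unknown", "female", "male"),
    age_years = c(54, 33, 17, 70, NA, 18),
    country = c("US", "US", "CA", NA, "FR", "US"),
    quarter = c("2019Q1", "2019Q2", "2020Q1", "2020Q3", "2021Q4", "2022Q1"),
    drugs = list(c(X = "PS"), c(X = "PS"), c(Y = "SS"),
                 c(Y = "C"), c(X = "PS"), c(Y = "unknown")),
    reactions = list("E", "F", "E", "F", "E", "F"),
    outcomes = list("hospitalization", "other", "unknown",
                    "death", "other", "unknown"),
    indications = list("infection", character(), "infection",
                       "prophylaxis", character(), character())
  )
}

# Random report set built independently of the package generator, for
# oracle comparisons (deduplication, stratification).
random_reports <- function(n, n_cases, seed) {
  withr::with_seed(seed, {
    case <- sample(paste0("case", seq_len(n_cases)), n, replace = TRUE)
    report_table(
      report_id = paste0("rr", seq_len(n)),
      case_id = case,
      version = sample(0:5, n, replace = TRUE),
      sex = sample(c("male", "female", "unknown"), n, replace = TRUE),
      age_years = ifelse(runif(n) < 0.15, NA,
                         sample(0:95, n, replace = TRUE)),
      country = sample(c("US", "GB", NA), n, replace = TRUE),
      quarter = sprintf("%dQ%d", sample(2004:2022, n, replace = TRUE),
                        sample(1:4, n, replace = TRUE)),
      drugs = lapply(seq_len(n), function(i) {
        nm <- sample(c("alpha", "beta", "gamma"),
                     sample(1:2, 1))
        stats::setNames(sample(c("PS", "SS", "C"), length(nm),
                               replace = TRUE), nm)
      }),
      reactions = lapply(seq_len(n), function(i) {
        sample(c("E1", "E2", "E3"), sample(1:2, 1))
      })
    )
  })
}

# Descriptive-table fixture: 143 cases of one drug-event pair with the
# category counts used in the characteristics tests.
characteristics_fixture <- function() {
  n <- 143
  sex <- rep(c("male", "female", "unknown"), c(67, 59, 17))
  # ages: 4 under 18, 87 in 18-65, 31 over 65, 21 missing
  age <- c(rep(10, 4), rep(40, 87), rep(70, 31), rep(NA, 21))
  # year bands: 6 / 28 / 47 / 62 across the four 4-year bands from 2007
  year <- rep(c(2008, 2012, 2016, 2020), c(6, 28, 47, 62))
  country <- rep(
    c("United States", "Canada", "Australia", "France", "Denmark",
      "Germany", "Netherlands", "United Kingdom", "India", "Argentina",
      "Belgium", "Spain", "New Zealand", NA),
    c(89, 13, 8, 6, 5, 5, 3, 2, 2, 1, 1, 1, 1, 6)
  )
  outcome <- rep(c("death", "hospitalization", "life_threatening",
                   "disability", "other", "unknown"),
                 c(3, 35, 2, 8, 66, 29))
  indication <- rep(
    c("Infection", "Aspergillosis", "Prophylaxis", "Inflammation",
      "Antifungal treatment", "Mycetoma mycotic", "Immunosuppression",
      "Cystic fibrosis", ""),
    c(52, 39, 17, 6, 2, 1, 1, 1, 24)
  )
  report_table(
    report_id = paste0("p", seq_len(n)),
    case_id = paste0("pc", seq_len(n)),
    version = 0L,
    sex = sex, age_years = age, country = country,
    quarter = sprintf("%dQ1", year),
    drugs = rep(list(c(voriconazole = "PS")), n),
    reactions = rep(list("Periostitis"), n),
    outcomes = as.list(outcome),
    indications = lapply(indication, function(x) {
      if (nzchar(x)) x else character()
    })
  )
}

# Printed overall summary row used across the reconstruction tests.
printed_row <- list(n = 143, chi2 = 82689.0,
                    rrr = 583.6, prr = 1808.9, ror = 1831.7,
                    ror_ci = c(1371.6, 2446.3))
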