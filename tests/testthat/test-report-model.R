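test_that("read_reports parses the flat dialect field by field", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "report_id,case_id,version,sex,age_years,country,quarter,drugs,reactions,outcomes,indications",
    "r1,c1,0,M,54,US,2019Q1,voriconazole:PS,Periostitis,HO,"
  ), path)
  r <- read_reports(path)
  expect_equal(nrow(r), 1)
  expect_equal(r$sex, "male")
  expect_equal(r$age_years, 54)
  expect_equal(r$drugs[[1]], c(voriconazole = "PS"))
  expect_equal(r$reactions[[1]], "Periostitis")
  expect_equal(r$outcomes[[1]], "hospitalization")
  expect_equal(r$indications[[1]], character())
})

test_that("a header-only file yields an empty collection", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(
    "report_id,case_id,version,sex,age_years,country,quarter,drugs,reactions,outcomes,indications",
    path
  )
  r <- read_reports(path)
  expect_equal(nrow(r), 0)
})

test_that("malformed headers and invalid records are reported by name and row", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("report_id,case_id,version", "r1,c1,0"), path)
  expect_error(read_reports(path), "sex", class = "pvsignal_format_error")

  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "report_id,case_id,version,sex,age_years,country,quarter,drugs,reactions,outcomes,indications",
    "r1,c1,0,M,54,US,2019Q1,voriconazole:PS,Periostitis,HO,",
    "r2,c2,0,X,54,US,2019Q1,voriconazole:PS,Periostitis,,",
    "r3,c3,0,F,999,US,2019Q1,voriconazole:PS,Periostitis,,"
  ), path2)
  expect_error(read_reports(path2), "row\\(s\\) 2, 3",
               class = "pvsignal_record_error")
  expect_warning(r <- read_reports(path2, on_error = "skip"), "skipped")
  expect_equal(r$report_id, "r1")
})

test_that("write_reports and read_reports round-trip collections and bytes", {
  reports <- fixture_six()
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_reports(reports, f1)
  back <- read_reports(f1)
  expect_equal(back, reports)
  write_reports(back, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("normalize_drugs maps synonyms, collapses duplicates, falls back to lower-case", {
  m <- synonym_map(c(VFEND = "voriconazole"))
  r <- report_table("r1", "c1", quarter = "2019Q1",
                    drugs = list(c(VFEND = "PS")),
                    reactions = list("Periostitis"))
  expect_equal(normalize_drugs(r, m)$drugs[[1]], c(voriconazole = "PS"))

  r2 <- report_table("r2", "c2", quarter = "2019Q1",
                     drugs = list(c(Vfend = "C", voriconazole = "PS")),
                     reactions = list("Periostitis"))
  expect_equal(normalize_drugs(r2, m)$drugs[[1]], c(voriconazole = "PS"))

  r3 <- report_table("r3", "c3", quarter = "2019Q1",
                     drugs = list(c("  DiFLUcan " = "SS")),
                     reactions = list("Periostitis"))
  expect_equal(normalize_drugs(r3)$drugs[[1]], c(diflucan = "SS"))

  # idempotent once canonical
  once <- normalize_drugs(r2, m)
  expect_equal(normalize_drugs(once, m), once)
})

test_that("role precedence is PS > SS > C > I > unknown when collapsing", {
  r <- report_table("r1", "c1", quarter = "2019Q1",
                    drugs = list(c(a = "I", a = "C", b = "unknown", b = "SS")),
                    reactions = list("E"))
  out <- normalize_drugs(r)$drugs[[1]]
  expect_equal(out, c(a = "C", b = "SS"))
})

test_that("deduplication keeps the latest version of each case", {
  r <- report_table(
    report_id = c("ra", "rb"), case_id = c("c1", "c1"),
    version = c(0L, 1L), quarter = c("2019Q1", "2019Q2"),
    drugs = list(c(X = "PS"), c(X = "PS")),
    reactions = list("E", "E")
  )
  out <- deduplicate_reports(r)
  expect_equal(out$report_id, "rb")

  # all-distinct case ids: identity
  six <- fixture_six()
  expect_equal(deduplicate_reports(six), six)
})

test_that("deduplication matches an independent group-by oracle and is idempotent", {
  r <- random_reports(100, 40, seed = 71)
  out <- deduplicate_reports(r)
  expect_equal(nrow(out), length(unique(r$case_id)))
  # oracle: per case, max version; ties by quarter then report_id
  key <- paste(sprintf("%03d", r$version), r$quarter, r$report_id)
  oracle <- vapply(split(seq_len(nrow(r)), r$case_id),
                   function(i) r$report_id[i][key[i] == max(key[i])][1], "")
  expect_setequal(out$report_id, unname(oracle))
  expect_equal(deduplicate_reports(out), out)
})

test_that("version ties break by quarter then report_id", {
  r <- report_table(
    report_id = c("r1", "r2", "r9"), case_id = rep("c1", 3),
    version = c(2L, 2L, 2L), quarter = c("2020Q4", "2021Q1", "2021Q1"),
    drugs = rep(list(c(X = "PS")), 3), reactions = rep(list("E"), 3)
  )
  expect_equal(deduplicate_reports(r)$report_id, "r9")
})

test_that("report invariants are enforced", {
  expect_error(
    report_table("r1", "c1", quarter = "2019Q1",
                 drugs = list(character()), reactions = list("E")),
    class = "pvsignal_record_error"
  )
  expect_error(
    report_table("r1", "c1", quarter = "2019Q1", age_years = 131,
                 drugs = list(c(X = "PS")), reactions = list("E")),
    class = "pvsignal_record_error"
  )
  expect_error(
    report_table("r1", "c1", quarter = "2019Q1", sex = "m",
                 drugs = list(c(X = "PS")), reactions = list("E")),
    class = "pvsignal_record_error"
  )
})
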