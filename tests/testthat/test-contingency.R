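test_that("build_table matches manual enumeration on the six-report fixture", {
  t <- build_table(fixture_six(), "X", "E")
  expect_equal(c(t$a, t$b, t$c, t$d), c(2, 1, 1, 2))
  expect_equal(t$a + t$b + t$c + t$d, 6)
})

test_that("a drug absent from every report gives a = c = 0", {
  t <- build_table(fixture_six(), "Z", "E")
  expect_equal(t$a, 0)
  expect_equal(t$c, 0)
  expect_equal(t$b + t$d, 6)
})

test_that("a report with two drugs of interest lands in cell a of both tables", {
  r <- report_table(
    report_id = c("r1", "r2"), case_id = c("c1", "c2"),
    quarter = "2019Q1",
    drugs = list(c(X = "PS", Y = "C"), c(W = "PS")),
    reactions = list("E", "F")
  )
  tx <- build_table(r, "X", "E")
  ty <- build_table(r, "Y", "E")
  expect_equal(tx$a, 1)
  expect_equal(ty$a, 1)
  # within one table the report occupies exactly one cell
  expect_equal(tx$a + tx$b + tx$c + tx$d, 2)
})

test_that("event matching is case-insensitive exact equality", {
  r <- report_table("r1", "c1", quarter = "2019Q1",
                    drugs = list(c(X = "PS")),
                    reactions = list("periostitis"))
  expect_equal(build_table(r, "X", "Periostitis")$a, 1)
  expect_equal(build_table(r, "X", "Periostiti")$a, 0)
})

test_that("build_tables agrees with build_table over a drug-event grid", {
  r <- random_reports(200, 150, seed = 5)
  grid <- build_tables(r, c("alpha", "beta"), c("E1", "E2"))
  for (i in seq_len(nrow(grid))) {
    t <- build_table(r, grid$drug[i], grid$event[i])
    expect_equal(c(grid$a[i], grid$b[i], grid$c[i], grid$d[i]),
                 c(t$a, t$b, t$c, t$d))
  }
})

test_that("stratify partitions by sex and excludes missing values", {
  r <- random_reports(60, 60, seed = 9)
  s <- stratify(r, sex_strata())
  expect_named(s, c("male", "female"))
  expect_equal(nrow(s$male), sum(r$sex == "male"))
  expect_equal(nrow(s$female), sum(r$sex == "female"))
  expect_equal(nrow(s$male) + nrow(s$female), sum(r$sex != "unknown"))
})

test_that("age boundaries 18 and 65 belong to the middle bin", {
  r <- report_table(
    report_id = paste0("r", 1:4), case_id = paste0("c", 1:4),
    quarter = "2019Q1", age_years = c(17, 18, 65, 66),
    drugs = rep(list(c(X = "PS")), 4), reactions = rep(list("E"), 4)
  )
  s <- stratify(r, age_strata())
  expect_equal(vapply(s, nrow, 1L), c("<18" = 1L, "18-65" = 2L, ">65" = 1L))
})

test_that("stratification matches a brute-force filter oracle", {
  r <- random_reports(300, 260, seed = 13)
  s <- stratify(r, age_strata())
  expect_equal(nrow(s$"<18"), sum(!is.na(r$age_years) & r$age_years < 18))
  expect_equal(nrow(s$"18-65"),
               sum(!is.na(r$age_years) & r$age_years >= 18 & r$age_years <= 65))
  expect_equal(nrow(s$">65"), sum(!is.na(r$age_years) & r$age_years > 65))
  expect_equal(sum(vapply(s, nrow, 1L)), sum(!is.na(r$age_years)))
})

test_that("overlapping stratum bins raise a configuration error", {
  spec <- stratum_spec("age", list(
    young = function(r) !is.na(r$age_years) & r$age_years <= 30,
    old = function(r) !is.na(r$age_years) & r$age_years >= 30
  ))
  r <- report_table("r1", "c1", quarter = "2019Q1", age_years = 30,
                    drugs = list(c(X = "PS")), reactions = list("E"))
  expect_error(stratify(r, spec), "overlap", class = "pvsignal_config_error")
})

test_that("per-stratum cells sum to the cells of the pooled matched reports", {
  r <- random_reports(400, 350, seed = 17)
  s <- stratify(r, sex_strata())
  pooled <- r[r$sex != "unknown", ]
  t_all <- build_table(pooled, "alpha", "E1")
  t_m <- build_table(s$male, "alpha", "E1")
  t_f <- build_table(s$female, "alpha", "E1")
  for (cell in c("a", "b", "c", "d")) {
    expect_equal(t_m[[cell]] + t_f[[cell]], t_all[[cell]])
  }
})

test_that("swapping drug of interest with the complement permutes cells", {
  t <- contingency_table(7, 3, 11, 19)
  swapped <- contingency_table(t$b, t$a, t$d, t$c)
  expect_equal(c(swapped$a, swapped$b, swapped$c, swapped$d),
               c(3, 7, 19, 11))
  expect_equal(chi_squared(swapped), chi_squared(t))
})

test_that("degenerate tables are rejected", {
  expect_error(contingency_table(0, 0, 0, 0), class = "pvsignal_format_error")
  expect_error(contingency_table(1.5, 0, 0, 1), class = "pvsignal_format_error")
  expect_error(contingency_table(-1, 1, 1, 1), class = "pvsignal_format_error")
  expect_error(build_table(fixture_six()[0, ], "X", "E"),
               class = "pvsignal_format_error")
})
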