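test_that("chi-squared matches hand values and the base-R oracle", {
  expect_equal(chi_squared(contingency_table(10, 10, 10, 10)), 0)
  t <- contingency_table(20, 5, 5, 20)
  expect_equal(chi_squared(t), 18)
  oracle <- unname(stats::chisq.test(matrix(c(20, 5, 5, 20), 2),
                                     correct = FALSE)$statistic)
  expect_equal(chi_squared(t), oracle)
  # transposition symmetry: chi2(a,b,c,d) == chi2(d,c,b,a)
  expect_equal(chi_squared(contingency_table(3, 9, 14, 2)),
               chi_squared(contingency_table(2, 14, 9, 3)))
})

test_that("chi-squared with continuity correction matches chisq.test(correct = TRUE)", {
  t <- contingency_table(12, 7, 9, 31)
  oracle <- unname(stats::chisq.test(matrix(c(12, 9, 7, 31), 2),
                                     correct = TRUE)$statistic)
  expect_equal(chi_squared(t, correct = TRUE), oracle)
})

test_that("zero margins make chi-squared undefined", {
  expect_error(chi_squared(contingency_table(0, 0, 5, 5)),
               class = "pvsignal_undefined_statistic")
})

test_that("RRR, PRR, ROR evaluate their formulas exactly", {
  t <- contingency_table(20, 5, 5, 20)
  expect_equal(rrr(t), 4)
  expect_equal(prr(t), 4)
  expect_equal(ror(t), 16)
  expect_equal(ror(contingency_table(2, 1, 1, 2)), 4)
  # observed/expected convention: a N / ((a+b)(a+c))
  expect_equal(rrr(t, method = "observed_expected"), 20 * 50 / (25 * 25))
})

test_that("independence (ad = bc) gives unit ratios, zero IC and zero chi-squared", {
  t <- contingency_table(6, 9, 4, 6)
  expect_equal(rrr(t), 1)
  expect_equal(prr(t), 1)
  expect_equal(ror(t), 1)
  expect_equal(ic(t), 0)
  expect_equal(chi_squared(t), 0)
})

test_that("IC is exactly log2 of RRR", {
  t <- contingency_table(20, 5, 5, 20)
  expect_identical(ic(t), log2(rrr(t)))
  expect_equal(ic(t), 2)
  withr::with_seed(31, {
    for (i in 1:50) {
      cells <- sample(1:50, 4, replace = TRUE)
      tt <- contingency_table(cells[1], cells[2], cells[3], cells[4])
      expect_identical(ic(tt), log2(rrr(tt)))
      expect_identical(ic(tt, method = "observed_expected"),
                       log2(rrr(tt, method = "observed_expected")))
    }
  })
})

test_that("zero cells raise undefined-statistic errors naming the cell", {
  expect_error(ror(contingency_table(5, 0, 5, 5)), "'b'",
               class = "pvsignal_undefined_statistic")
  expect_error(ror(contingency_table(5, 5, 0, 5)), "'c'",
               class = "pvsignal_undefined_statistic")
  expect_error(prr(contingency_table(5, 0, 5, 5)), "'b'",
               class = "pvsignal_undefined_statistic")
  expect_error(rrr(contingency_table(5, 5, 0, 5)), "'c'",
               class = "pvsignal_undefined_statistic")
})

test_that("the Haldane option rescues sparse tables", {
  t <- contingency_table(5, 0, 5, 5)
  expect_equal(ror(t, haldane = TRUE), (5.5 / 5.5) / (0.5 / 5.5))
})

test_that("Woolf ROR interval reproduces the closed form on (20,5,5,20)", {
  t <- contingency_table(20, 5, 5, 20)
  ci <- confidence_interval(t, "ror", level = 0.95)
  expect_equal(round_half_up(ci[["lower"]], 1), 4.0)
  expect_equal(round_half_up(ci[["upper"]], 1), 64.0)
  # direct closed form: SE = sqrt(1/20 + 1/5 + 1/5 + 1/20) = sqrt(0.5)
  z <- qnorm(0.975)
  expect_equal(unname(ci),
               16 * exp(c(-1, 1) * z * sqrt(0.5)))
})

test_that("Woolf intervals use the stated SE formulas and bracket the point", {
  withr::with_seed(47, {
    for (i in 1:50) {
      cells <- sample(1:60, 4, replace = TRUE)
      a <- cells[1]; b <- cells[2]; c <- cells[3]; d <- cells[4]
      t <- contingency_table(a, b, c, d)
      z <- qnorm(0.975)
      ci_ror <- confidence_interval(t, "ror")
      expect_equal(unname(ci_ror),
                   ror(t) * exp(c(-1, 1) * z * sqrt(1/a + 1/b + 1/c + 1/d)))
      ci_prr <- confidence_interval(t, "prr")
      expect_equal(unname(ci_prr),
                   prr(t) * exp(c(-1, 1) * z *
                                  sqrt(1/a - 1/(a + c) + 1/b - 1/(b + d))))
      ci_rrr <- confidence_interval(t, "rrr")
      expect_equal(unname(ci_rrr),
                   rrr(t) * exp(c(-1, 1) * z *
                                  sqrt(1/a - 1/(a + b) + 1/c - 1/(c + d))))
      expect_true(ci_ror[1] <= ror(t) && ror(t) <= ci_ror[2])
      expect_true(ci_prr[1] <= prr(t) && prr(t) <= ci_prr[2])
      expect_true(ci_rrr[1] <= rrr(t) && rrr(t) <= ci_rrr[2])
    }
  })
})

test_that("IC interval is the log2 image of the RRR interval", {
  t <- contingency_table(24, 9, 13, 37)
  expect_equal(ic_interval(t), log2(confidence_interval(t, "rrr")),
               ignore_attr = TRUE)
  # degenerate: a zero cell in the RRR SE (c = 0) leaves no interval
  expect_error(ic_interval(contingency_table(5, 5, 0, 5)),
               class = "pvsignal_undefined_statistic")
})

test_that("interval level must be a probability", {
  t <- contingency_table(20, 5, 5, 20)
  expect_error(confidence_interval(t, "ror", level = 1.2),
               class = "pvsignal_config_error")
})

test_that("the Evans rule thresholds and strictness behave as stated", {
  expect_true(evaluate_signal(list(n = 143, chi2 = 82689.0, prr = 1808.9)))
  expect_false(evaluate_signal(list(n = 3, chi2 = 100, prr = 50)))
  expect_true(evaluate_signal(
    list(n = 3, chi2 = 100, prr = 50),
    signal_criteria(strictness = "greater_or_equal")
  ))
  expect_false(evaluate_signal(list(n = 10, chi2 = 3.9, prr = 5)))
  expect_false(evaluate_signal(list(n = 10, chi2 = NA_real_, prr = 5)))
  expect_error(signal_criteria(min_n = -1), class = "pvsignal_config_error")
})

test_that("compute_all assembles every field and degrades per field", {
  t <- contingency_table(20, 5, 5, 20)
  s <- compute_all(t)
  expect_s3_class(s, "signal_stats")
  expect_equal(s$n, 20)
  expect_equal(s$chi2, 18)
  expect_equal(s$rrr, 4)
  expect_equal(s$prr, 4)
  expect_equal(s$ror, 16)
  expect_equal(s$ic, 2)
  expect_equal(s$ci_method, "woolf_log_normal")
  expect_equal(unname(s$ci_ic), log2(unname(s$ci_rrr)))

  flat <- compute_all(contingency_table(6, 9, 4, 6))
  expect_equal(c(flat$rrr, flat$prr, flat$ror, flat$ic, flat$chi2),
               c(1, 1, 1, 0, 0))

  sparse <- compute_all(contingency_table(5, 0, 5, 5))
  expect_equal(sparse$n, 5)
  expect_false(is.na(sparse$chi2))
  expect_true(is.na(sparse$ror))
  expect_true(is.na(sparse$prr))
  expect_true(all(is.na(sparse$ci_ror)))
})

test_that("ROR exceeds PRR exactly when a/c > b/d", {
  withr::with_seed(53, {
    for (i in 1:100) {
      cells <- sample(1:40, 4, replace = TRUE)
      t <- contingency_table(cells[1], cells[2], cells[3], cells[4])
      expect_equal(ror(t) > prr(t), t$a / t$c > t$b / t$d)
    }
  })
})
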