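test_that("percentage differences use the second argument as reference", {
  expect_equal(percentage_difference(10, 10), 0)
  expect_equal(percentage_difference(15, 10), 50)
  expect_equal(percentage_difference(0, 10), -100)
  expect_error(percentage_difference(5, 0), "positive")
})

test_that("comparison pairing implements the five scenario contrasts", {
  sc <- fake_scenarios(d_a = 10, d_b = 8, d_c = 9, d_d = 9.5, d_e = 7)
  cmp <- compare_scenarios(sc)
  s <- tidy(cmp)
  get <- function(id) s$mean_pct[s$comparison == id]
  expect_equal(get("C1"), (10 - 8) / 8 * 100)
  expect_equal(get("C2"), (8 - 9.5) / 9.5 * 100)
  expect_equal(get("C3"), (9.5 - 9) / 9 * 100)
  expect_equal(get("C4"), (10 - 9.5) / 9.5 * 100)
  expect_equal(get("C5"), (7 - 9.5) / 9.5 * 100)
  # single-phantom cohorts report SD 0 with a flag
  expect_true(all(s$sd_pct == 0) && all(s$sd_flag))
  expect_error(compare_scenarios(list()), "empty cohort")
})

test_that("missing-volume overestimate follows (1/phi - 1) across coverage levels", {
  phi <- c(1, 0.75, 0.5, 0.25)
  sc <- fake_scenarios(d_a = rep(10, 4), d_b = 10 * phi,
                       d_c = rep(10, 4), d_d = rep(10, 4))
  c1 <- tidy(compare_scenarios(sc, "C1"))
  expect_equal(sort(c1$mean_pct), sort((1 / phi - 1) * 100),
               tolerance = 1e-9)  # 0, 33.3, 100, 300 %
})

test_that("absent organs yield NA for C1 and -100% for C2/C4/C5", {
  sc <- fake_scenarios(d_a = c(10, NA), d_b = c(10, 0), d_c = c(9, 3),
                       d_d = c(9.5, 3.2), d_e = c(10, 0),
                       absent = c(FALSE, TRUE),
                       organ = c("heart", "thyroid"))
  per <- tidy(compare_scenarios(sc), per_phantom = TRUE)
  thy <- function(id) per$pct_diff[per$organ == "thyroid" & per$comparison == id]
  expect_true(is.na(thy("C1")))
  expect_equal(thy("C2"), -100)
  expect_equal(thy("C4"), -100)
  expect_equal(thy("C5"), -100)
  expect_gt(thy("C3"), 0)
})

test_that("cohort summaries use the sample standard deviation over phantoms", {
  cohort <- list(
    fake_scenarios(d_a = 12, d_b = 10, d_c = 10, d_d = 10, organ = "liver"),
    fake_scenarios(d_a = 14, d_b = 10, d_c = 10, d_d = 10, organ = "liver"),
    fake_scenarios(d_a = 10, d_b = 10, d_c = 10, d_d = 10, organ = "liver"))
  s <- tidy(compare_scenarios(cohort, "C1"))
  expect_equal(s$mean_pct, mean(c(20, 40, 0)))
  expect_equal(s$sd_pct, sd(c(20, 40, 0)))
  expect_equal(s$n, 3)
  expect_false(s$sd_flag)
})

test_that("scatter contribution compares whole-body against rescaled truncated dose", {
  sc <- fake_scenarios(d_a = c(10, 10), d_b = c(10, 10),
                       d_c = c(10, 10.6), d_d = c(10, 11),
                       organ = c("a", "b"))
  out <- scatter_contribution(sc)
  expect_equal(out$scatter_pct, c(0, 6), tolerance = 1e-9)

  sc2 <- fake_scenarios(d_a = NA, d_b = 0, d_c = 3, d_d = 3.2,
                        absent = TRUE, organ = "thyroid")
  out2 <- scatter_contribution(sc2)
  expect_true(is.infinite(out2$scatter_pct) && out2$total_scatter)
})

test_that("cohort regressions report OLS slope and R squared", {
  d <- tibble::tibble(x = 1:10, y = 2 * (1:10) + 1)
  r <- regress_cohort(d, "x", "y")
  expect_equal(r$r_squared, 1)
  expect_equal(r$slope, 2)
  expect_equal(r$intercept, 1)

  set.seed(13)
  d2 <- tibble::tibble(x = rnorm(40), y = sample(rnorm(40)))
  expect_lt(regress_cohort(d2, "x", "y")$r_squared, 0.2)

  expect_error(regress_cohort(tibble::tibble(x = 1:2, y = 1:2), "x", "y"),
               "at least 3")
  expect_error(regress_cohort(tibble::tibble(x = rep(1, 5), y = 1:5),
                              "x", "y"), "zero variance")
})

test_that("cohort specs alternate sexes within the population ranges", {
  specs <- cohort_specs(6, seed = 3)
  expect_equal(sapply(specs, `[[`, "sex"),
               rep(c("female", "male"), 3))
  h <- sapply(specs, `[[`, "height")
  w <- sapply(specs, `[[`, "weight")
  expect_true(all(h >= 1.50 & h <= 1.95))
  expect_true(all(w >= 39 & w <= 126))
  # reproducible
  specs2 <- cohort_specs(6, seed = 3)
  expect_identical(sapply(specs2, `[[`, "height"), h)
})
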