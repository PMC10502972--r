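test_that("noiseless simulation reproduces the configured group changes exactly", {
  spec <- cohort_spec(n_dims = 5, n_sv = 5, noise_sd = 0, al_noise_sd = 0,
                      ser_noise_sd = 0, seed = 2)
  rec <- simulate_cohort(spec)
  ch <- change_from_baseline(rec)
  one_week <- dplyr::filter(ch, visit == "1w", group == "DIMS")
  expect_true(all(abs(one_week$sfcht_change - 6.75) < 1e-12))
  sv_12m <- dplyr::filter(ch, visit == "12m", group == "SV")
  expect_true(all(abs(sv_12m$sfcht_change - (-9.46)) < 1e-12))
})

test_that("cohort simulation is reproducible and well-formed", {
  spec <- cohort_spec(n_dims = 10, n_sv = 12, seed = 7)
  a <- simulate_cohort(spec)
  b <- simulate_cohort(spec)
  expect_identical(a, b)
  expect_identical(nrow(a), (10L + 12L) * 8L)
  expect_true(all(table(a$subject) == 8))
  # AL/SER only at baseline and 6-monthly visits
  expect_true(all(is.na(a$axial_length[a$visit %in% c("1w", "1m", "3m")])))
  expect_true(all(!is.na(a$axial_length[a$visit %in% c("baseline", "6m", "12m",
                                                       "18m", "24m")])))
  expect_true(all(a$sfcht > 0))
})

test_that("simulated group means match configuration within Monte-Carlo error", {
  spec <- cohort_spec(seed = 11)  # paper-scale n = 78/80
  rec <- simulate_cohort(spec)
  base <- dplyr::filter(rec, visit == "baseline")
  for (g in c("DIMS", "SV")) {
    m <- mean(base$sfcht[base$group == g])
    se <- spec$baseline_sd[g] / sqrt(sum(base$group == g))
    expect_lt(abs(m - spec$baseline_mean[g]), 2.5 * se)
  }
})

test_that("change_from_baseline subtracts the baseline per subject", {
  rec <- simulate_cohort(cohort_spec(n_dims = 3, n_sv = 3, seed = 4))
  ch <- change_from_baseline(rec)
  one <- dplyr::filter(rec, subject == "S001")
  base <- one$sfcht[one$visit == "baseline"]
  expect_equal(dplyr::filter(ch, subject == "S001", visit == "3m")$sfcht_change,
               one$sfcht[one$visit == "3m"] - base)
  # visit equal to baseline -> zero
  rec0 <- rec
  rec0$sfcht[rec0$subject == "S002" & rec0$visit == "1w"] <-
    rec0$sfcht[rec0$subject == "S002" & rec0$visit == "baseline"]
  ch0 <- change_from_baseline(rec0)
  expect_equal(dplyr::filter(ch0, subject == "S002", visit == "1w")$sfcht_change, 0)
  # missing baseline -> excluded with warning
  rec_m <- dplyr::filter(rec, !(subject == "S003" & visit == "baseline"))
  expect_warning(ch_m <- change_from_baseline(rec_m), "no baseline")
  expect_false("S003" %in% ch_m$subject)
})

test_that("adjusted group change reduces to raw means for balanced baselines", {
  set.seed(9)
  g <- rep(c("DIMS", "SV"), each = 20)
  baseline <- rep(270, 40)                       # identical baselines
  change <- ifelse(g == "DIMS", 6, -3) + rnorm(40, 0, 2)
  adj <- adjusted_group_change(change, baseline, g)
  expect_equal(adj$adjusted_mean[adj$group == "DIMS"],
               mean(change[g == "DIMS"]))
  expect_equal(adj$adjusted_mean[adj$group == "SV"], mean(change[g == "SV"]))
  # swapping labels negates the difference
  g2 <- ifelse(g == "DIMS", "SV", "DIMS")
  adj2 <- adjusted_group_change(change, baseline, g2)
  expect_equal(attr(adj2, "difference"), -attr(adj, "difference"))
})

test_that("adjusted group change recovers the planted difference", {
  spec <- cohort_spec(seed = 19)
  ch <- change_from_baseline(simulate_cohort(spec))
  adj <- adjusted_group_change(ch, visit = "1w")
  planted <- spec$visit_changes["DIMS", "1w"] - spec$visit_changes["SV", "1w"]
  expect_lt(abs(attr(adj, "difference") - planted),
            2 * attr(adj, "difference_se"))
  expect_error(adjusted_group_change(ch), "visit")
  expect_error(adjusted_group_change(c(1, 2), c(1, 2), c("A", "A")),
               "two groups")
})

test_that("percent change reproduces the worked example and validates input", {
  expect_identical(percent_change(6.75, 280.95), 2.4)
  expect_identical(percent_change(0, 123), 0)
  expect_identical(percent_change(10, 200), 5)
  expect_equal(percent_change(6.75, 280.95, digits = NULL),
               100 * 6.75 / 280.95)
  expect_error(percent_change(5, 0), "baseline")
})

test_that("pearson_r matches a hand-computed covariance formula", {
  expect_equal(pearson_r(1:10, 2 * (1:10) + 1), 1)
  expect_equal(pearson_r(1:10, -(1:10)), -1)
  x <- c(1, 2, 3, 4); y <- c(2, 1, 4, 3)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson_r(x, y), r_hand)
  expect_error(pearson_r(c(1, 2), c(3, 4)), "3 complete pairs")
  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)), "degenerate")
})

test_that("hierarchical regression reports nested R² and standardized betas", {
  set.seed(5)
  n <- 60
  d <- tibble::tibble(
    age = rnorm(n, 10, 1.5),
    gender = sample(c("male", "female"), n, TRUE),
    ch_3m = rnorm(n, 0, 12)
  )
  # orthogonalized candidate: no unique contribution
  y <- 0.5 - 0.03 * d$age + rnorm(n, 0, 0.1)
  d$al <- y
  resid_ch <- residuals(lm(ch_3m ~ al + age + gender, data = d))
  d2 <- d; d2$ch_3m <- resid_ch
  hr0 <- hierarchical_regression(d2, outcome = "al", candidate = "ch_3m")
  expect_lt(hr0$delta_r2, 1e-10)

  # exact linear outcome: model 2 explains everything
  d3 <- d
  d3$al <- 0.4 - 0.03 * d3$age - 0.01 * (d3$gender == "male") - 0.004 * d3$ch_3m
  hr1 <- suppressWarnings(  # lm warns about the deliberately perfect fit
    hierarchical_regression(d3, outcome = "al", candidate = "ch_3m"))
  expect_equal(hr1$r2_model2, 1)
  expect_gte(hr1$r2_model2, hr1$r2_model1)

  # planted negative coefficient shows up with the right sign
  d4 <- d
  d4$al <- 0.4 - 0.03 * d4$age - 0.004 * d4$ch_3m + rnorm(n, 0, 0.05)
  hr2 <- hierarchical_regression(d4, outcome = "al", candidate = "ch_3m")
  beta_ch <- dplyr::filter(hr2$coefficients, model == 2, term == "ch_3m")$beta
  expect_lt(beta_ch, 0)

  # collinear design rejected
  d5 <- d4; d5$dup <- d5$ch_3m
  expect_error(
    hierarchical_regression(d5, outcome = "al", base = c("age", "ch_3m"),
                            candidate = "dup"),
    "collinear")
})

test_that("R² never decreases across nested models on simulated cohorts", {
  for (seed in c(3, 14, 25)) {
    rec <- simulate_cohort(cohort_spec(n_dims = 30, n_sv = 30, seed = seed))
    ch <- change_from_baseline(rec)
    d <- dplyr::inner_join(
      dplyr::select(dplyr::filter(ch, visit == "3m"),
                    subject, age, gender, ch_3m = sfcht_change),
      dplyr::select(dplyr::filter(ch, visit == "12m"),
                    subject, al_12m = al_change),
      by = "subject")
    hr <- hierarchical_regression(d, outcome = "al_12m", candidate = "ch_3m")
    expect_gte(hr$r2_model2, hr$r2_model1)
    expect_equal(hr$delta_r2, hr$r2_model2 - hr$r2_model1)
  }
})
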