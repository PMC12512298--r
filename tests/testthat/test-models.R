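# Season assignment, logistic fits, cyclic GAMs, AIC comparison,
# predictions, background OLS.

test_that("assign_season implements the inclusive Apr 1 - Sep 30 window", {
  expect_identical(assign_season(as.Date("2022-04-01")), "breeding")
  expect_identical(assign_season(as.Date("2022-09-30")), "breeding")
  expect_identical(assign_season(as.Date("2022-10-01")), "nonbreeding")
  expect_identical(assign_season(as.Date("2022-03-31")), "nonbreeding")
  expect_identical(assign_season(as.Date(c("2023-01-15", "2023-07-15"))),
                   c("nonbreeding", "breeding"))
})

test_that("week_of_year is continuous, wrapped, and in [0, 52)", {
  expect_equal(week_of_year(as.Date("2022-01-01")), 0)
  expect_equal(week_of_year(as.Date("2022-01-08")), 1)
  expect_equal(week_of_year(as.Date("2022-12-31")), 0) # day 365 closes cycle
  expect_equal(week_of_year(as.Date("2020-12-31")), 0) # leap day 366 -> 365
  w <- week_of_year(as.Date("2022-01-01") + 0:730)
  expect_true(all(w >= 0 & w < 52))
})

mk_2x2 <- function() {
  data.frame(
    label = c(rep("green", 40), rep("brown", 10),
              rep("green", 20), rep("brown", 30)),
    hourly_temp = c(rep(1, 50), rep(0, 50)))
}

test_that("fit_logistic reproduces the closed-form 2x2 log odds ratio", {
  fit <- fit_logistic(mk_2x2(), "temp_only")
  expect_equal(unname(fit$coefficients["hourly_temp"]), log(6),
               tolerance = 1e-6)
  expect_equal(fit$aic, fit$deviance + 2 * 2)
  expect_lte(fit$deviance, fit$null_deviance + 1e-8)
})

test_that("fit_logistic agrees with a brute-force likelihood grid search", {
  for (seed in c(2, 5)) {
    d <- withr::with_seed(seed, {
      x <- runif(40, -2, 2)
      y <- rbinom(40, 1, plogis(0.3 + 0.8 * x))
      data.frame(label = ifelse(y == 1, "green", "brown"), hourly_temp = x)
    })
    fit <- fit_logistic(d, "temp_only")
    oracle <- oracle_logistic_mle(d$hourly_temp,
                                  as.integer(d$label == "green"))
    expect_equal(unname(fit$coefficients), oracle, tolerance = 1e-3)
  }
})

test_that("null covariates give no spurious slopes", {
  d <- withr::with_seed(19, {
    data.frame(label = sample(c("green", "brown"), 2000, TRUE),
               hourly_temp = runif(2000, 5, 35),
               season = sample(c("breeding", "nonbreeding"), 2000, TRUE))
  })
  fit <- fit_logistic(d, "temp_by_season_interaction")
  expect_true(all(abs(fit$season_slopes$z) < 4))
})

test_that("fit_logistic rejects degenerate inputs", {
  d <- mk_2x2()
  d$label <- "green"
  expect_error(fit_logistic(d, "temp_only"), "both labels")
  sep <- data.frame(label = c(rep("green", 30), rep("brown", 30)),
                    hourly_temp = c(rep(10, 30), rep(20, 30)))
  expect_error(fit_logistic(sep, "temp_only"), "separation")
  few <- mk_2x2()
  few$season <- c("breeding", rep("nonbreeding", 99))
  expect_error(fit_logistic(few, "temp_plus_season"), "10 records")
})

test_that("cyclic GAM predictions are periodic in week", {
  cfg <- synth_config(n_records = 3000, seed = 23)
  d <- as_model_table(gen_observation_table(cfg))
  fit <- fit_cyclic_gam(d, "week_by_lat_interaction")
  p0 <- predict_with_ci(fit, data.frame(week = 0, latitude = 30))
  p52 <- predict_with_ci(fit, data.frame(week = 52, latitude = 30))
  expect_equal(p0$linear_predictor, p52$linear_predictor, tolerance = 1e-8)
  # adding whole cycles changes nothing
  pa <- predict_with_ci(fit, data.frame(week = c(8, 20), latitude = 31))
  pb <- predict_with_ci(fit, data.frame(week = c(8, 20) + 52, latitude = 31))
  expect_equal(pa, pb, tolerance = 1e-12)
  expect_equal(fit$aic, fit$deviance + 2 * fit$effective_df)
})

test_that("cyclic GAM warns when weeks do not cover the cycle", {
  d <- withr::with_seed(3, data.frame(
    label = sample(c("green", "brown"), 300, TRUE),
    week = runif(300, 10, 30), latitude = runif(300, 25, 36)))
  expect_warning(fit_cyclic_gam(d, "week_only"), "cycle")
})

test_that("aic_compare selects by AIC with the stated tie-breaks", {
  y0 <- c(0, 1, 1, 0)
  mk <- function(name, dev, edf) {
    structure(list(model_name = name, deviance = dev, effective_df = edf,
                   aic = dev + 2 * edf, y = y0), class = "anole_fit")
  }
  cmp <- aic_compare(list(mk("simple", 100, 2), mk("rich", 90, 4)))
  expect_equal(cmp$table$aic, c(104, 98))
  expect_identical(cmp$best, "rich")
  expect_equal(cmp$delta_aic, -6)
  # tie -> fewest effective df
  tie <- aic_compare(list(mk("fat", 96, 4), mk("lean", 100, 2)))
  expect_identical(tie$best, "lean")
  expect_equal(tie$delta_aic, 0)
  # differing record sets are not comparable
  other <- mk("other", 50, 2)
  other$y <- c(1, 1, 1, 1)
  expect_error(aic_compare(list(mk("a", 100, 2), other)), "differing")
})

test_that("predict_with_ci back-transforms a symmetric logit interval", {
  d <- withr::with_seed(29, data.frame(
    label = ifelse(rbinom(400, 1, 0.5) == 1, "green", "brown"),
    hourly_temp = runif(400, 5, 35)))
  fit <- fit_logistic(d, "temp_only")
  nd <- data.frame(hourly_temp = c(10, 20, 30))
  pr <- predict_with_ci(fit, nd)
  expect_true(all(pr$lower <= pr$probability & pr$probability <= pr$upper))
  expect_true(all(pr$lower > 0 & pr$upper < 1))
  # matches the manual logit-scale construction with z = 1.959964
  link <- predict(fit$fit, nd, type = "link", se.fit = TRUE)
  expect_equal(pr$upper, plogis(as.numeric(link$fit) +
                                  1.959964 * as.numeric(link$se.fit)),
               tolerance = 1e-6)
  expect_error(predict_with_ci(fit, data.frame(bogus = 1)), "lacks")
  expect_warning(predict_with_ci(fit, data.frame(hourly_temp = 90)),
                 "outside")
})

test_that("deviance explained is invariant to swapping the label coding", {
  d <- as_model_table(gen_observation_table(synth_config(n_records = 800,
                                                         seed = 37)))
  f1 <- fit_logistic(d, "temp_plus_season")
  d2 <- d
  d2$label <- ifelse(d$label == "green", "brown", "green")
  f2 <- fit_logistic(d2, "temp_plus_season")
  expect_equal(f1$deviance_explained, f2$deviance_explained,
               tolerance = 1e-9)
  expect_equal(unname(f1$coefficients["hourly_temp"]),
               -unname(f2$coefficients["hourly_temp"]), tolerance = 1e-6)
})

test_that("fit_background_lm matches closed-form least squares", {
  # perfect fit
  d <- data.frame(greenness = c(0.2, 0.3, 0.4, 0.5),
                  bg_greenness = c(0.2, 0.3, 0.4, 0.5))
  f <- suppressWarnings(fit_background_lm(d))
  expect_equal(f$slope, 1, tolerance = 1e-12)
  expect_equal(f$r_squared, 1, tolerance = 1e-12)
  # hand-computed normal equations
  d3 <- data.frame(greenness = c(0.32, 0.41, 0.52),
                   bg_greenness = c(0.30, 0.40, 0.50))
  f3 <- suppressWarnings(fit_background_lm(d3))
  expect_equal(f3$slope, 1.0, tolerance = 1e-10)
  expect_equal(f3$intercept, 1 / 60, tolerance = 1e-10)
  # degenerate predictor
  dz <- data.frame(greenness = c(0.1, 0.2, 0.3), bg_greenness = rep(0.4, 3))
  expect_error(fit_background_lm(dz), "zero variance")
  expect_error(fit_background_lm(d3[1:2, ]), "at least 3")
  # confounder fields are reported when temperature is present
  d$hourly_temp <- c(12, 18, 25, 30)
  fc <- suppressWarnings(fit_background_lm(d))
  expect_true(is.finite(fc$confounder$cor_bg_temp))
  expect_true(is.finite(fc$confounder$p_value_temp_on_bg))
})
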