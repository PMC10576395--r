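test_that("count model: saturated counts give a flat day effect", {
  s <- data.frame(day = rep(200:229, each = 48),
                  n_total = 20L)
  s$n_lake <- s$n_total  # every fish in the lake at every minute
  fit <- fit_count_model(s)
  expect_lt(abs(fit$coef_table$estimate[fit$coef_table$term == "day"]), 1e-8)
})

test_that("count model recovers a known positive trend in the lake rate", {
  set.seed(21)
  day <- rep(200:259, each = 24)
  beta <- 0.015
  total <- rpois(length(day), 25) + 1L
  p <- exp(-2 + beta * (day - 230))
  s <- data.frame(day = day, n_total = total,
                  n_lake = rbinom(length(day), total, pmin(p, 1)))
  fit <- fit_count_model(s)
  row <- fit$coef_table[fit$coef_table$term == "day", ]
  expect_gt(row$z, 0)
  expect_lt(abs(row$estimate - beta), 2 * row$se)
})

test_that("count model drops zero-total minutes and validates counts", {
  s <- data.frame(day = c(1, 2, 3), n_total = c(0L, 5L, 5L),
                  n_lake = c(0L, 2L, 3L))
  fit <- fit_count_model(s)
  expect_equal(fit$n_dropped, 1L)
  s$n_lake[2] <- 9L
  expect_error(fit_count_model(s), "exceeds")
})

test_that("count model is invariant to joint rescaling of counts and totals", {
  set.seed(3)
  s <- data.frame(day = 1:200, n_total = 10L,
                  n_lake = rbinom(200, 10, 0.4))
  f1 <- fit_count_model(s)
  s2 <- transform(s, n_total = n_total * 3L, n_lake = n_lake * 3L)
  f2 <- fit_count_model(s2)
  expect_equal(f2$coef_table$estimate[2], f1$coef_table$estimate[2],
               tolerance = 1e-8)
})

sim_gam_data <- function(n_fish = 8, n_per = 120, rho = 0, seed = 1,
                         two_curves = FALSE) {
  set.seed(seed)
  out <- list()
  for (i in seq_len(n_fish)) {
    day <- seq(200, 300, length.out = n_per)
    hab <- if (two_curves) sample(c("lake", "river"), 1) else "lake"
    f <- if (identical(hab, "lake")) sin(day / 12) * 0.4 else
      cos(day / 18) * 0.3
    e <- as.numeric(stats::arima.sim(list(ar = max(rho, 1e-12)), n_per,
                                     sd = 0.25 * sqrt(1 - rho^2)))
    mu <- exp(-1.2 + f + 0.3 * (i - n_fish / 2) / n_fish)
    y <- mu * exp(e)
    out[[i]] <- data.frame(fish = sprintf("F%02d", i), day = day,
                           habitat = hab, t = seq_len(n_per), y = y,
                           truth = f, stringsAsFactors = FALSE)
  }
  d <- do.call(rbind, out)
  d$fish <- factor(d$fish)
  d$habitat <- factor(d$habitat)
  d
}

test_that("a smooth day effect is recovered from gamma noise", {
  d <- sim_gam_data(n_fish = 6, n_per = 150, seed = 5)
  spec <- model_spec("y", "gamma_log",
                     smooths = list(sm("day", k = 20),
                                    sm("fish", bs = "re")),
                     ar_group = "fish", time_col = "t")
  fit <- fit_additive_model(d, spec)
  grid <- data.frame(day = seq(201, 299, length.out = 80),
                     fish = d$fish[1])
  pred <- predict(fit, newdata = grid, type = "terms")
  sm_col <- grep("s\\(day\\)", colnames(pred))
  expect_gt(stats::cor(pred[, sm_col], sin(grid$day / 12) * 0.4), 0.95)
})

test_that("a flat truth is penalised to roughly one degree of freedom", {
  set.seed(8)
  d <- data.frame(y = rgamma(800, shape = 20, rate = 20),
                  day = runif(800, 0, 100),
                  z = runif(800, 0, 1))
  spec <- model_spec("y", "gamma_log",
                     smooths = list(sm("day", k = 20), sm("z", k = 5)))
  fit <- fit_additive_model(d, spec)
  edf <- sum(summary(fit)$s.table[1, "edf"])
  expect_lt(edf, 2.5)
})

test_that("factor-by smooths recover distinct curves per habitat", {
  d <- sim_gam_data(n_fish = 10, n_per = 150, seed = 9, two_curves = TRUE)
  spec <- model_spec("y", "gamma_log", parametric = "habitat",
                     smooths = list(sm("day", k = 20, by = "habitat"),
                                    sm("fish", bs = "re")))
  fit <- fit_additive_model(d, spec)
  for (hab in levels(d$habitat)) {
    grid <- data.frame(day = seq(201, 299, length.out = 80),
                       habitat = factor(hab, levels(d$habitat)),
                       fish = d$fish[1])
    pred <- predict(fit, newdata = grid, type = "terms")
    sm_col <- grep(paste0("s\\(day\\):habitat", hab), colnames(pred))
    truth <- if (hab == "lake") sin(grid$day / 12) * 0.4 else
      cos(grid$day / 18) * 0.3
    expect_gt(stats::cor(pred[, sm_col], truth), 0.95)
  }
})

test_that("gamma family rejects non-positive responses by row", {
  d <- data.frame(y = c(1, 0, 2, -1), day = 1:4)
  spec <- model_spec("y", "gamma_log", smooths = list(sm("day", k = 3)))
  expect_error(fit_additive_model(d, spec), "strictly positive.*2")
})

test_that("excessive basis dimension is reduced with a warning", {
  d <- data.frame(y = rgamma(60, 10, 10), day = rep(1:6, 10))
  spec <- model_spec("y", "gamma_log", smooths = list(sm("day", k = 20)))
  expect_warning(fit <- fit_additive_model(d, spec), "unique")
  expect_s3_class(fit, "trout_gam")
})

test_that("rho estimation is calibrated and grouping-invariant", {
  # white noise: rho compatible with zero
  set.seed(2)
  e <- rnorm(4000)
  g <- rep(1:40, each = 100)
  expect_lt(abs(estimate_rho(e, groups = g)), 2 / sqrt(4000))

  # AR(1) residuals with rho = 0.6: recovered within 0.05 at n = 5000
  e2 <- as.numeric(stats::arima.sim(list(ar = 0.6), 5000))
  expect_lt(abs(estimate_rho(e2, groups = rep(1:10, each = 500)) - 0.6),
            0.05)

  # permuting whole groups does not change the estimate
  ord <- order(rep(sample(40), each = 100))
  expect_equal(estimate_rho(e[ord], groups = g[ord]),
               estimate_rho(e, groups = g), tolerance = 1e-12)

  expect_error(estimate_rho(rnorm(5), groups = 1:5), "undefined")
})

test_that("the AR(1) refit path matches the two-step procedure", {
  d <- sim_gam_data(n_fish = 6, n_per = 150, rho = 0.6, seed = 11)
  spec0 <- model_spec("y", "gamma_log",
                      smooths = list(sm("day", k = 15),
                                     sm("fish", bs = "re")),
                      ar_group = "fish", time_col = "t")
  fit0 <- fit_additive_model(d, spec0)
  rho <- estimate_rho(fit0)
  expect_lt(abs(rho - 0.6), 0.15)
  spec1 <- model_spec("y", "gamma_log",
                      smooths = list(sm("day", k = 15),
                                     sm("fish", bs = "re")),
                      rho = rho, ar_group = "fish", time_col = "t")
  fit1 <- fit_additive_model(d, spec1)
  cmp <- compare_aic(no_ar = fit0, ar = fit1)
  expect_equal(cmp$model[1], "ar")

  # with rho = 0 the AR-enabled path reproduces the plain fit
  spec00 <- model_spec("y", "gamma_log",
                       smooths = list(sm("day", k = 15),
                                      sm("fish", bs = "re")),
                       rho = 0, ar_group = "fish", time_col = "t")
  fit00 <- fit_additive_model(d, spec00)
  expect_equal(stats::coef(fit00$fit), stats::coef(fit0$fit),
               tolerance = 1e-8)
})

test_that("AIC comparison demands a common response and reports deltas", {
  d <- sim_gam_data(n_fish = 4, n_per = 80, seed = 13)
  spec <- model_spec("y", "gamma_log", smooths = list(sm("day", k = 10),
                                                      sm("fish", bs = "re")))
  f1 <- fit_additive_model(d, spec)
  cmp <- compare_aic(a = f1, b = f1)
  expect_equal(cmp$delta_aic, c(0, 0))
  f2 <- fit_additive_model(d[1:200, ], spec)
  expect_error(compare_aic(a = f1, b = f2), "differing")
})

test_that("worst-case concurvity flags duplicated covariates and not independent ones", {
  set.seed(17)
  n <- 2000
  d <- data.frame(y = rgamma(n, 10, 10), a = runif(n), c = runif(n))
  d$b <- d$a  # a smooth of a copy of a
  dup <- fit_additive_model(d, model_spec("y", "gamma_log",
                                          smooths = list(sm("a", k = 8),
                                                         sm("b", k = 8))))
  w_dup <- concurvity_worst(dup)
  expect_gt(min(w_dup), 0.99)

  ind <- fit_additive_model(d, model_spec("y", "gamma_log",
                                          smooths = list(sm("a", k = 8),
                                                         sm("c", k = 8))))
  w_ind <- concurvity_worst(ind)
  expect_lt(max(w_ind), 0.8)
  expect_true(all(w_dup >= 0 & w_dup <= 1 & w_ind >= 0 & w_ind <= 1))

  # agreement with the reference implementation's pessimistic measure
  ref <- mgcv::concurvity(ind$fit, full = TRUE)["worst", -1]
  expect_equal(unname(w_ind), unname(ref), tolerance = 0.05)
})

test_that("collinearity screening flags strong pairs and constants", {
  set.seed(19)
  n <- 3000
  day <- runif(n, 200, 300)
  d <- data.frame(day = day,
                  discharge = -0.9 * scale(day)[, 1] + rnorm(n, 0, 0.45),
                  temp = rnorm(n))
  rep_ <- screen_collinearity(d)
  row <- rep_[rep_$var_a == "day" & rep_$var_b == "discharge", ]
  expect_true(row$flagged)
  expect_lt(row$r, -0.8)
  expect_false(rep_[rep_$var_a == "day" & rep_$var_b == "temp", "flagged"])
  # x vs -x is perfectly anti-correlated and flagged
  d2 <- data.frame(x = 1:50, y = -(1:50))
  expect_true(screen_collinearity(d2)$flagged)
  d3 <- data.frame(x = 1:50, k = rep(1, 50))
  expect_warning(r3 <- screen_collinearity(d3), "constant")
  expect_true(r3$flagged)
})

test_that("fitted gamma means are strictly positive", {
  d <- sim_gam_data(n_fish = 4, n_per = 80, seed = 23)
  fit <- fit_additive_model(d, model_spec("y", "gamma_log",
                                          smooths = list(sm("day", k = 10),
                                                         sm("fish", bs = "re"))))
  expect_true(all(stats::fitted(fit$fit) > 0))
})
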