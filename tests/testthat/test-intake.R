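mk_events <- function(animal, day, grams, dur_s = 200,
                      start_hour = 9, day0 = as.Date("2016-07-01")) {
  entry <- as.POSIXct(day0, tz = "UTC") + day * 86400 + start_hour * 3600
  data.frame(animal = animal, feeder = "F1",
             entry = entry, exit = entry + dur_s, grams = grams)
}

test_that("daily_intake sums events per animal-day and conserves mass", {
  ev <- rbind(mk_events("A", 0, 100, start_hour = c(8, 12, 16)),
              mk_events("A", 1, 250), mk_events("B", 0, 400))
  expect_warning(di <- daily_intake(ev, days = 0:1), "no feeder events")
  expect_equal(di$grams[di$animal == "A" & di$day == 0], 300)
  expect_equal(di$grams[di$animal == "A" & di$day == 1], 250)
  expect_equal(di$grams[di$animal == "B" & di$day == 1], 0)
  expect_equal(sum(di$grams), sum(ev$grams))  # conservation
})

test_that("events spanning midnight count on the entry day; bad grams rejected", {
  late <- data.frame(animal = "A", feeder = "F1",
                     entry = as.POSIXct("2016-07-01 23:59:00", tz = "UTC"),
                     exit = as.POSIXct("2016-07-02 00:05:00", tz = "UTC"),
                     grams = 120)
  di <- suppressWarnings(daily_intake(late, days = 0:1))
  expect_equal(di$grams[di$day == 0], 120)
  expect_equal(di$grams[di$day == 1], 0)
  neg <- mk_events("A", 0, c(100, -5))
  expect_warning(di2 <- daily_intake(neg, days = 0), "negative")
  expect_equal(di2$grams, 100)
})

test_that("energy intake is the DM-and-ME product of as-fed mass", {
  fs <- feed_spec(dm_frac = 0.93, me_mj_per_kg_dm = 10.9, year = 1)
  expect_equal(energy_intake(0, fs), 0)
  expect_equal(energy_intake(1000, feed_spec(1, 10)), 10)
  expect_equal(energy_intake(2500, fs), 25.3425, tolerance = 1e-12)
})

test_that("growth interpolation passes through observations and summarises growth", {
  g <- interpolate_growth(data.frame(day = c(0, 42), kg = c(50, 54)))
  expect_equal(g$day21_kg, 52)
  expect_equal(g$adg, 4 / 42)
  expect_equal(g$mmwt, 52^0.75)
  # constant weight
  g0 <- interpolate_growth(data.frame(day = c(0, 14, 42), kg = 50))
  expect_equal(g0$adg, 0)
  expect_equal(g0$mmwt, 50^0.75)
  # piecewise: day 21 sits on the flat middle segment
  g2 <- interpolate_growth(data.frame(day = c(0, 14, 28, 42),
                                      kg = c(50, 52, 52, 56)))
  expect_equal(g2$day21_kg, 52)
  obs <- data.frame(day = c(0, 14, 28, 42), kg = c(50, 52, 52, 56))
  expect_equal(g2$daily$kg[g2$daily$day %in% obs$day], obs$kg)
})

test_that("regression growth equals OLS and matches interpolation on linear data", {
  w <- data.frame(day = seq(0, 42, by = 7), kg = 48 + 0.3 * seq(0, 42, by = 7))
  gi <- interpolate_growth(w); gr <- regression_growth(w)
  expect_equal(gr$adg, gi$adg, tolerance = 1e-10)
  expect_equal(gr$mmwt, gi$mmwt, tolerance = 1e-10)
  # outlier: slope must equal the normal-equations solution
  w2 <- w; w2$kg[3] <- w2$kg[3] + 5
  gr2 <- regression_growth(w2)
  X <- cbind(1, w2$day)
  beta <- solve(t(X) %*% X, t(X) %*% w2$kg)
  expect_equal(gr2$adg, beta[2], tolerance = 1e-10)
  expect_equal(gr2$day21_kg, beta[1] + 21 * beta[2], tolerance = 1e-10)
})

test_that("metabolic mid-weight is the 0.75 power", {
  expect_equal(round(metabolic_midweight(57.2), 1), 20.8)
  expect_equal(metabolic_midweight(16), 8)
  expect_equal(metabolic_midweight(1), 1)
  expect_error(metabolic_midweight(0), "positive")
})

test_that("feeding behavior averages per-event rates, not pooled totals", {
  ev <- rbind(mk_events("A", 0, 100, dur_s = 200),
              mk_events("A", 1, 300, dur_s = 100))
  fb <- feeding_behavior(ev, n_days = 42)
  expect_equal(fb$mean_rate_g_s, mean(c(100 / 200, 300 / 100)))  # 1.75, not 400/300
  expect_equal(fb$events_per_day, 2 / 42)
  expect_equal(fb$mean_grams_per_event, 200)
  expect_equal(fb$mean_duration_s, 150)
  # single event
  fb1 <- feeding_behavior(mk_events("A", 0, 100, dur_s = 200), n_days = 1)
  expect_equal(fb1$mean_rate_g_s, 0.5)
  expect_equal(fb1$events_per_day, 1)
  # zero-duration events excluded from the rate but counted
  ev0 <- rbind(mk_events("A", 0, 100, dur_s = 0), mk_events("A", 0, 90, dur_s = 90))
  fb0 <- feeding_behavior(ev0, n_days = 1)
  expect_equal(fb0$mean_rate_g_s, 1)
  expect_equal(fb0$events_per_day, 2)
  expect_warning(feeding_behavior(mk_events("A", 0, 1)[0, ]), "undefined")
})

test_that("fit_rfi recovers injected residuals and honours OLS geometry", {
  set.seed(42)
  n <- 240
  d <- data.frame(animal = sprintf("A%03d", 1:n),
                  mmwt = rnorm(n, 20.8, 2),
                  adg = rnorm(n, 0.35, 0.067),
                  flock = sample(c("F1", "F2", "F3"), n, TRUE),
                  cohort = sample(c("1", "2a", "2b"), n, TRUE),
                  pen = sample(c("A", "B"), n, TRUE))
  # exact model data -> zero residuals
  d$energy_mj <- 3 + 0.8 * d$mmwt + 18 * d$adg +
    c(F1 = 0, F2 = 1, F3 = -1)[d$flock]
  fit0 <- fit_rfi(d)
  expect_lt(max(abs(fit0$rfi)), 1e-9)
  # inject residuals orthogonal to the model columns: recovered exactly
  X <- stats::model.matrix(fit0$lm)
  X <- X[, !is.na(stats::coef(fit0$lm)), drop = FALSE]
  eps_raw <- rnorm(n)
  eps <- eps_raw - X %*% solve(crossprod(X), crossprod(X, eps_raw))
  d$energy_mj <- d$energy_mj + as.vector(eps)
  fit <- fit_rfi(d)
  expect_equal(unname(fit$rfi), as.vector(eps), tolerance = 1e-8)
  expect_lt(abs(sum(fit$rfi)), 1e-8)
  expect_lt(abs(sum(fit$rfi * d$mmwt)), 1e-6)
  expect_lt(abs(sum(fit$rfi * d$adg)), 1e-6)
  expect_equal(unname(fit$fitted + fit$rfi), d$energy_mj)
})
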