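small_cfg <- function(seed = 3, ...) {
  sim_config(seed = seed, n_sires = 10, progeny_per_sire = 10, ...)
}

test_that("simulated pedigree has the configured size, links and known dams", {
  cfg <- sim_config(seed = 1, n_sires = 20, progeny_per_sire = 10,
                    link_fraction = 0.2)
  ped <- simulate_pedigree(cfg)
  prog <- ped[!is.na(ped$cohort), ]
  expect_equal(nrow(prog), 200)
  expect_false(anyNA(prog$dam))
  sire_cohorts <- tapply(prog$cohort, prog$sire, function(x) length(unique(x)))
  expect_gte(mean(sire_cohorts >= 2), 0.2)
  expect_equal(length(unique(prog$flock)), 3)
  # same seed twice -> identical
  expect_identical(ped, simulate_pedigree(cfg))
})

test_that("breeding values follow the pedigree covariance structure", {
  # zero covariance -> all zero
  ped0 <- read_pedigree(data.frame(animal = c("A", "B"), sire = NA, dam = NA))
  expect_true(all(simulate_breeding_values(ped0, matrix(0, 1, 1),
                                           seed = 1) == 0))
  expect_error(simulate_breeding_values(ped0, matrix(c(1, 2, 2, 1), 2),
                                        seed = 1), "PSD")
  # founders: sample variance near the configured variance
  nf <- 5000
  pedf <- read_pedigree(data.frame(animal = sprintf("F%04d", 1:nf),
                                   sire = NA, dam = NA))
  bv <- simulate_breeding_values(pedf, matrix(1, 1, 1), seed = 2)
  expect_lt(abs(stats::var(bv[, 1]) - 1), 0.1)
  # parent-offspring covariance about half the additive variance
  np <- 2000
  pedpo <- read_pedigree(data.frame(
    animal = c(sprintf("P%04d", 1:np), sprintf("O%04d", 1:np)),
    sire = c(rep(NA, np), sprintf("P%04d", 1:np)), dam = NA))
  bv2 <- simulate_breeding_values(pedpo, matrix(1, 1, 1), seed = 3)
  cv <- stats::cov(bv2[1:np, 1], bv2[np + 1:np, 1])
  expect_lt(abs(cv - 0.5), 0.06)
  # bivariate: realized genetic correlation tracks the configured one
  G <- matrix(c(1, 0.5, 0.5, 1), 2)
  bv3 <- simulate_breeding_values(pedf, G, seed = 4)
  expect_lt(abs(stats::cor(bv3[, 1], bv3[, 2]) - 0.5), 0.05)
})

test_that("cohort bundle is deterministic and phenotypes equal their components", {
  cfg <- small_cfg()
  ch <- simulate_cohort(cfg)
  ch2 <- simulate_cohort(cfg)
  expect_identical(ch$truth, ch2$truth)
  expect_identical(ch$feeder_events, ch2$feeder_events)
  expect_identical(ch$pac, ch2$pac)
  cc <- ch$truth$components
  expect_equal(cc$phenotype, cc$mu + cc$fixed + cc$a + cc$m + cc$pe + cc$e)
  # daily feeder sums average exactly to the latent daily intake
  di <- suppressWarnings(daily_intake(ch$feeder_events))
  m <- tapply(di$grams, di$animal, mean)
  lat <- stats::setNames(ch$truth$latents$daily_grams,
                         ch$truth$latents$animal)
  expect_equal(as.numeric(m[names(lat)]), as.numeric(lat), tolerance = 1e-10)
})

test_that("zero weighing noise makes interpolated day-21 weight exact", {
  cfg <- small_cfg(seed = 5, weighing_noise_sd = 0)
  ch <- simulate_cohort(cfg)
  lw <- split(ch$liveweights[, c("day", "kg")], ch$liveweights$animal)
  d21 <- vapply(lw, function(w) interpolate_growth(w)$day21_kg, numeric(1))
  lat <- stats::setNames(ch$truth$latents$lw21, ch$truth$latents$animal)
  expect_equal(d21[names(lat)], lat, tolerance = 1e-10)
})

test_that("gas pipeline inverts the chamber forward model at zero nuisance", {
  cfg <- small_cfg(seed = 6)
  cfg$pac$lot_log_sd <- 0
  cfg$pac$reading_noise_ppm <- c(ch4 = 0, co2 = 0)
  ch <- simulate_cohort(cfg)
  lat <- ch$truth$latents
  bw <- data.frame(animal = rep(lat$animal, 2),
                   round = rep(1:2, each = nrow(lat)),
                   kg = c(lat$bw_r1, lat$bw_r2))
  gt <- derive_gas_traits(ch$pac, bodyweight = bw, scale = FALSE)
  for (r in 1:2) {
    g <- gt[gt$round == r, ]
    g <- g[match(lat$animal, g$animal), ]
    expect_lt(max(abs(g$ch4_g_day / lat[[paste0("ch4_r", r)]] - 1)), 0.02)
    expect_lt(max(abs(g$co2_g_day / lat[[paste0("co2_r", r)]] - 1)), 0.02)
  }
})

test_that("flat concentration profiles arise from zero latent emission", {
  # forward model sanity: a zero emission implies a zero slope
  mins <- c(0, 30, 60)
  molair <- 101.325 * 770 / (8.31446 * 288.15)
  slope <- 0 / (1e-6 * molair * 16.04 * 1440)
  expect_equal(2 + slope * mins, rep(2, 3))
})

test_that("CT stacks integrate back to the latent depot masses", {
  masses <- c(visceral_fat = 5.13, subcutaneous_fat = 5.51,
              intermuscular_fat = 2.29, lean = 19.10, bone = 4.36,
              nonfat_viscera = 10.76)
  hu <- c(visceral_fat = 70, subcutaneous_fat = 80, intermuscular_fat = 90,
          lean = 150, bone = 220, nonfat_viscera = 160)
  st <- simulate_ct_stack(masses, hu, spacing_mm = 30)
  comp <- derive_ct_traits(st, spacing_mm = 30)
  for (dp in names(masses)) {
    expect_lt(abs(comp[[dp]] / masses[[dp]] - 1), 0.05)
  }
  expect_equal(comp$carcass_weight,
               comp$carcass_fat + comp$lean + comp$bone)
})

test_that("write_cohort emits readable CSVs in the pipeline dialects", {
  dir <- withr::local_tempdir()
  ch <- simulate_cohort(small_cfg(seed = 7))
  write_cohort(ch, dir)
  ped <- read_pedigree(file.path(dir, "pedigree.csv"))
  expect_equal(sort(ped$animal), sort(ch$pedigree$animal))
  ev <- utils::read.csv(file.path(dir, "feeder_events.csv"))
  di <- suppressWarnings(daily_intake(ev))
  expect_equal(sum(di$grams), sum(ch$feeder_events$grams), tolerance = 1e-6)
  cfg <- yaml::read_yaml(file.path(dir, "config.yaml"))
  expect_equal(cfg$seed, 7)
})
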