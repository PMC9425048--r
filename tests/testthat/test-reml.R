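small_ped <- function(n = 40, seed = 11) {
  set.seed(seed)
  nf <- 12
  ids <- sprintf("A%02d", seq_len(n))
  sire <- dam <- rep(NA_character_, n)
  for (i in (nf + 1):n) {
    sire[i] <- sample(ids[1:(i - 1)], 1)
    dam[i] <- sample(setdiff(ids[1:(i - 1)], sire[i]), 1)
  }
  read_pedigree(data.frame(animal = ids, sire = sire, dam = dam))
}

test_that("mixed-model equations match a dense GLS solve on a toy pedigree", {
  ped <- read_pedigree(data.frame(
    animal = c("P1", "P2", "P3", "O1", "O2", "O3"),
    sire = c(NA, NA, NA, "P1", "P1", "P3"),
    dam = c(NA, NA, NA, "P2", "P2", "P2")))
  set.seed(5)
  y <- rnorm(6, 10, 2)
  X <- cbind(1, c(0.3, -1, 2, 0.5, 0, 1))
  A <- build_A(ped)
  Z <- diag(6)
  sa <- 1.3; se <- 0.9
  mme <- build_mme(y, X, list(additive = list(Z = Z, Kinv = build_A_inverse(ped))),
                   sigma2 = c(additive = sa, residual = se))
  # dense GLS oracle
  V <- sa * Z %*% A %*% t(Z) + se * diag(6)
  Vi <- solve(V)
  b_gls <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  u_gls <- sa * A %*% t(Z) %*% Vi %*% (y - X %*% b_gls)
  expect_equal(mme$b, as.vector(b_gls), tolerance = 1e-8)
  expect_equal(mme$u$additive, as.vector(u_gls), tolerance = 1e-8)
  # intercept-only fixed part is a column of ones
  mme1 <- build_mme(y, matrix(1, 6, 1),
                    list(additive = list(Z = Z, Kinv = build_A_inverse(ped))),
                    sigma2 = c(additive = sa, residual = se))
  expect_equal(mme1$p, 1)
})

test_that("REML matches the dense profile-likelihood oracle on small pedigrees", {
  for (seed in c(11, 12)) {
    ped <- small_ped(40, seed)
    set.seed(seed + 100)
    bv <- simulate_breeding_values(ped, matrix(0.5, 1, 1))
    d <- data.frame(animal = ped$animal,
                    y = 5 + bv[, 1] + rnorm(nrow(ped), 0, sqrt(0.5)))
    fit <- reml_univariate(d, "y", ped, se = FALSE)
    h2 <- unname(fit$components["additive"] / sum(fit$components))
    h2_oracle <- profile_h2_oracle(d$y, matrix(1, nrow(d), 1), build_A(ped))
    expect_lt(abs(h2 - h2_oracle), 1e-4)
  }
})

test_that("REML equals the balanced half-sib ANOVA estimator when interior", {
  hs <- sim_halfsib(n_sires = 40, k = 10, h2 = 0.4, seed = 21)
  h2_anova <- halfsib_anova_h2(hs$data$y, hs$data$sire)
  expect_gt(h2_anova, 0.05)  # interior
  expect_lt(h2_anova, 0.95)
  fit <- reml_univariate(hs$data, "y", hs$ped, se = FALSE)
  h2 <- unname(fit$components["additive"] / sum(fit$components))
  expect_lt(abs(h2 - h2_anova), 1e-6)
})

test_that("restricted likelihood is invariant to data row permutation", {
  ped <- small_ped(30, seed = 33)
  set.seed(34)
  d <- data.frame(animal = ped$animal, y = rnorm(30, 8, 2),
                  grp = sample(c("u", "v"), 30, TRUE))
  f1 <- reml_univariate(d, "y", ped, fixed = ~grp, se = FALSE)
  f2 <- reml_univariate(d[sample(30), ], "y", ped, fixed = ~grp, se = FALSE)
  expect_equal(f1$components, f2$components, tolerance = 1e-6)
  expect_equal(f1$logLR, f2$logLR, tolerance = 1e-6)
  # relabelling factor levels does not change the fit
  d3 <- d; d3$grp <- ifelse(d3$grp == "u", "zebra", "ant")
  f3 <- reml_univariate(d3, "y", ped, fixed = ~grp, se = FALSE)
  expect_equal(f3$components, f1$components, tolerance = 1e-6)
})

test_that("null additive variance yields near-zero heritability estimates", {
  n_rep <- 20
  hits <- 0
  h2s <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    hs <- sim_halfsib(n_sires = 100, k = 10, h2 = 0, seed = 300 + r)
    fit <- reml_univariate(hs$data, "y", hs$ped, se = FALSE)
    h2s[r] <- unname(fit$components["additive"] / sum(fit$components))
    if (h2s[r] < 0.05) hits <- hits + 1
  }
  expect_gte(hits, 18)
  expect_lt(mean(h2s), 0.03)
})

test_that("repeated records give a repeatability between h2 and 1", {
  set.seed(55)
  ped <- small_ped(60, seed = 44)
  bv <- simulate_breeding_values(ped, matrix(1, 1, 1))
  pe <- rnorm(nrow(ped), 0, sqrt(0.7))
  d <- do.call(rbind, lapply(1:2, function(r) {
    data.frame(animal = ped$animal, round = r,
               y = 10 + bv[, 1] + pe + rnorm(nrow(ped), 0, sqrt(1.3)))
  }))
  fit <- reml_univariate(d, "y", ped, se = TRUE)
  expect_true("permanent_env" %in% names(fit$components))
  rat <- fit$ratios
  expect_true(all(rat$estimate >= 0 & rat$estimate <= 1))
  expect_gte(rat["repeatability", "estimate"], rat["h2_direct", "estimate"])
  expect_true(all(is.finite(rat$se)))
})

test_that("maternal variance is picked up when dams have repeated progeny", {
  # sires x dams with 3 progeny per dam; strong maternal component
  set.seed(66)
  ns <- 30; nd <- 60; ppd <- 3
  sires <- sprintf("S%02d", 1:ns)
  dams <- sprintf("D%02d", 1:nd)
  prog <- sprintf("P%03d", 1:(nd * ppd))
  ped <- read_pedigree(data.frame(
    animal = c(sires, dams, prog),
    sire = c(rep(NA, ns + nd), rep(sires, each = nd * ppd / ns)),
    dam = c(rep(NA, ns + nd), rep(dams, each = ppd))))
  a <- simulate_breeding_values(ped, matrix(0.3, 1, 1))
  m <- simulate_breeding_values(ped, matrix(0.4, 1, 1))
  dam_of <- setNames(ped$dam, ped$animal)
  d <- data.frame(animal = prog,
                  y = 3 + a[prog, 1] + m[dam_of[prog], 1] +
                    rnorm(length(prog), 0, sqrt(0.5)))
  fit <- reml_univariate(d, "y", ped, maternal = "genetic", se = TRUE)
  expect_true(fit$components["maternal"] > 0.05)
  expect_true(all(fit$ratios$estimate >= 0 & fit$ratios$estimate <= 1))
})

test_that("significance rule is a strict 2-SE threshold", {
  expect_true(significance_flag(-0.41, 0.15))
  expect_false(significance_flag(0.06, 0.18))
  expect_false(significance_flag(0.30, 0.15))  # boundary: strict inequality
  expect_true(is.na(significance_flag(0.3, NA)))
})

test_that("bivariate REML returns r_g = r_p = 1 for duplicated traits", {
  ped <- small_ped(40, seed = 77)
  set.seed(78)
  bv <- simulate_breeding_values(ped, matrix(0.6, 1, 1))
  d <- data.frame(animal = ped$animal,
                  y1 = 4 + bv[, 1] + rnorm(nrow(ped), 0, 0.8))
  d$y2 <- d$y1
  fit <- reml_bivariate(d, c("y1", "y2"), ped, se = FALSE)
  expect_equal(fit$correlations["r_g", "estimate"], 1, tolerance = 1e-3)
  expect_equal(fit$correlations["r_p", "estimate"], 1, tolerance = 1e-3)
})

test_that("bivariate REML recovers a known genetic correlation direction", {
  hs <- sim_halfsib(n_sires = 80, k = 8, h2 = 0.4, seed = 91)
  ped <- hs$ped
  set.seed(92)
  G <- matrix(c(1, 0.6, 0.6, 1), 2) * 0.4
  bv <- simulate_breeding_values(ped, G)
  prog <- hs$data$animal
  d <- data.frame(animal = prog,
                  y1 = 10 + bv[prog, 1] + rnorm(length(prog), 0, sqrt(0.6)),
                  y2 = -2 + bv[prog, 2] + rnorm(length(prog), 0, sqrt(0.6)))
  fit <- reml_bivariate(d, c("y1", "y2"), ped, se = TRUE)
  expect_true(fit$converged)
  rg <- fit$correlations["r_g", ]
  expect_gt(rg$estimate, 0.2)
  expect_lt(rg$estimate, 1)
  expect_true(is.finite(rg$se))
  expect_lt(abs(fit$correlations["r_p", "estimate"] -
                cor(d$y1, d$y2)), 0.1)
})
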