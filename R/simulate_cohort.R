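# Full synthetic study bundle: pedigree, ground-truth trait components, and
# the raw data streams (feeder events, liveweights, chamber profiles, CT
# stacks, ultrasound) that the trait-construction pipeline consumes.

pens_for_cohort <- function(label) {
  if (label %in% c("1", "2a", "2b")) LETTERS[1:5]
  else if (label %in% c("3a", "3b")) LETTERS[1:2]
  else LETTERS[1:4]
}

# fixed-effect term sets per trait, mirroring the management structures a
# variance-component analysis of these traits would fit
default_fixed_terms <- function(core_traits, ct_traits) {
  ft <- list(lw21 = c("cg", "brr", "aod", "aod2", "bdev"),
             adg = c("cg", "pen", "brr"),
             rfi = character(0),
             ch4 = c("cg", "brr", "aod2"),
             co2 = c("cohort", "brr"))
  for (tr in ct_traits) ft[[tr]] <- "cg"
  for (tr in setdiff(core_traits, names(ft))) ft[[tr]] <- "cg"
  ft
}

#' Simulate a complete synthetic study dataset
#'
#' Generates, under one seed, a linked multi-flock pedigree, true breeding
#' values (direct and maternal), fixed-effect contributions, permanent
#' environment and residual deviations for every trait, and forward-models
#' the raw data streams the pipeline consumes: feeder-event logs whose daily
#' sums equal the latent intake, twice-weekly liveweights with weighing
#' noise, two chamber rounds of timed gas-concentration triplets with
#' lot-level nuisance, CT slice-area stacks, and ultrasound fat depths. The
#' stored truth makes every downstream stage testable by parameter recovery:
#' each phenotype equals the exact sum of its stored components.
#'
#' @param config A [sim_config()].
#' @return list of class `ovi_cohort` with elements `config`, `pedigree`,
#'   `animals` (per-animal covariates), `truth` (`components` long table and
#'   `latents` wide table), `feeder_events`, `liveweights`, `pac`,
#'   `ct` (per-slice area table, CT subset only), `ultrasound`,
#'   `feed_by_cohort`, `fixed_terms`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  ped <- simulate_pedigree(config)   # seeds the RNG stream
  prog <- ped[!is.na(ped$cohort), ]
  n <- nrow(prog)
  labs <- cohort_labels(config$n_cohorts)

  # --- per-animal covariates ---------------------------------------------
  animals <- data.frame(animal = prog$animal, sire = prog$sire,
                        dam = prog$dam, flock = prog$flock,
                        cohort = prog$cohort, birth_year = prog$birth_year,
                        stringsAsFactors = FALSE)
  animals$pen <- NA_character_
  for (co in labs) {
    i <- which(animals$cohort == co)
    animals$pen[i] <- sample(rep(pens_for_cohort(co), length.out = length(i)))
  }
  animals$brr <- sample(1:3, n, TRUE, prob = c(0.25, 0.6, 0.15))
  dam_aod <- stats::setNames(sample(2:7, length(unique(animals$dam)), TRUE),
                             unique(animals$dam))
  animals$aod <- unname(dam_aod[animals$dam])
  animals$bdev <- round(stats::rnorm(n, 0, 7))
  animals$cg <- paste(cohort_year(animals$cohort), animals$flock, sep = "-")
  animals$cohort_pen <- paste(animals$cohort, animals$pen, sep = ".")

  # --- latent trait components -------------------------------------------
  tp <- config$trait_params
  ctp <- config$ct_params
  sd_a <- tp$sd * sqrt(tp$h2)
  G_core <- diag(sd_a, length(sd_a)) %*% config$genetic_correlations %*%
    diag(sd_a, length(sd_a))
  dimnames(G_core) <- list(tp$trait, tp$trait)
  G_ct <- diag((ctp$sd * sqrt(ctp$h2))^2, nrow(ctp))
  dimnames(G_ct) <- list(ctp$trait, ctp$trait)
  a_core <- simulate_breeding_values(ped, G_core)
  a_ct <- simulate_breeding_values(ped, G_ct)
  Gm_core <- diag((tp$sd * sqrt(tp$m2))^2, nrow(tp))
  dimnames(Gm_core) <- list(tp$trait, tp$trait)
  Gm_ct <- diag((ctp$sd * sqrt(ctp$m2))^2, nrow(ctp))
  dimnames(Gm_ct) <- list(ctp$trait, ctp$trait)
  m_core <- simulate_breeding_values(ped, Gm_core)
  m_ct <- simulate_breeding_values(ped, Gm_ct)

  fx <- config$fixed_effect_sd
  level_effect <- function(levels, sd) {
    stats::setNames(stats::rnorm(length(levels), 0, sd), levels)
  }
  fixed_terms <- default_fixed_terms(tp$trait, ctp$trait)
  fixed_contrib <- function(trait, sd_t) {
    terms <- fixed_terms[[trait]]
    out <- numeric(n)
    if ("cg" %in% terms) {
      ef <- level_effect(unique(animals$cg), fx[["cg"]] * sd_t)
      out <- out + ef[animals$cg]
    }
    if ("cohort" %in% terms) {
      ef <- level_effect(labs, fx[["cg"]] * sd_t)
      out <- out + ef[animals$cohort]
    }
    if ("pen" %in% terms) {
      ef <- level_effect(unique(animals$cohort_pen), fx[["pen"]] * sd_t)
      out <- out + ef[animals$cohort_pen]
    }
    if ("brr" %in% terms) {
      ef <- c(0.5, 0, -1) * fx[["brr"]] * sd_t
      out <- out + ef[animals$brr]
    }
    if ("aod" %in% terms) out <- out + fx[["aod"]] * sd_t * (animals$aod - 4.5)
    if ("aod2" %in% terms) {
      out <- out - fx[["aod2"]] * sd_t * ((animals$aod - 4.5)^2 - 2)
    }
    if ("bdev" %in% terms) out <- out - fx[["bdev"]] * sd_t * animals$bdev
    unname(out)
  }

  pid <- match(animals$animal, ped$animal)
  did <- match(animals$dam, ped$animal)
  comp <- list()
  add_trait <- function(trait, mean_t, sd_t, h2, m2, pe2, repeated, a_mat, m_mat) {
    e2 <- 1 - h2 - m2 - pe2
    stopifnot(e2 >= 0)
    fxc <- fixed_contrib(trait, sd_t)
    a <- a_mat[pid, trait]
    m <- m_mat[did, trait]
    pe <- if (pe2 > 0) stats::rnorm(n, 0, sd_t * sqrt(pe2)) else numeric(n)
    rounds <- if (repeated) 1:2 else NA_integer_
    for (r in rounds) {
      e <- stats::rnorm(n, 0, sd_t * sqrt(e2))
      comp[[length(comp) + 1L]] <<-
        data.frame(animal = animals$animal, trait = trait, round = r,
                   mu = mean_t, fixed = fxc, a = unname(a), m = unname(m),
                   pe = pe,
                   e = e, phenotype = mean_t + fxc + unname(a) + unname(m) +
                     pe + e)
    }
  }
  for (k in seq_len(nrow(tp))) {
    add_trait(tp$trait[k], tp$mean[k], tp$sd[k], tp$h2[k], tp$m2[k],
              tp$pe2[k], tp$repeated[k], a_core, m_core)
  }
  for (k in seq_len(nrow(ctp))) {
    add_trait(ctp$trait[k], ctp$mean[k], ctp$sd[k], ctp$h2[k], ctp$m2[k],
              0, FALSE, a_ct, m_ct)
  }
  components <- do.call(rbind, comp)

  pheno <- function(trait, round = NA) {
    i <- components$trait == trait &
      (is.na(round) | components$round %in% round)
    stats::setNames(components$phenotype[i], components$animal[i])
  }

  # --- latent intake model ------------------------------------------------
  lw21 <- pheno("lw21"); adg <- pheno("adg"); rfi <- pheno("rfi")
  mmwt <- metabolic_midweight(pmax(lw21, 20))
  ic <- config$intake_coef
  gs <- config$intake_group_sd
  eff_flock <- level_effect(unique(animals$flock), gs[["flock"]])
  eff_cohort <- level_effect(labs, gs[["cohort"]])
  eff_pen <- level_effect(unique(animals$cohort_pen), gs[["pen"]])
  ei <- ic[["b0"]] + ic[["b_mmwt"]] * mmwt + ic[["b_adg"]] * adg +
    eff_flock[animals$flock] + eff_cohort[animals$cohort] +
    eff_pen[animals$cohort_pen] + rfi
  ei <- pmax(unname(ei), 5)
  feed_by_cohort <- stats::setNames(
    lapply(labs, function(co) {
      yr <- cohort_year(co)
      yrs <- vapply(config$feed, function(f) as.numeric(f$year), numeric(1))
      config$feed[[which.min(abs(yrs - yr))]]
    }), labs)
  dmme <- vapply(feed_by_cohort[animals$cohort], function(f) {
    f$dm_frac * f$me_mj_per_kg_dm
  }, numeric(1))
  daily_grams <- unname(ei / dmme * 1000)

  # animal-level feeding behavior
  lgn <- function(mean, sd) {
    cv <- sd / mean
    sdl <- sqrt(log(1 + cv^2))
    stats::rlnorm(n, log(mean) - sdl^2 / 2, sdl)
  }
  events_day <- pmax(lgn(config$events_per_day_mean, config$events_per_day_sd), 2)
  rate_gs <- pmax(lgn(config$feed_rate_mean, config$feed_rate_sd), 0.05)

  w0 <- unname(lw21 - 21 * adg)
  latents <- data.frame(animal = animals$animal, lw21 = unname(lw21),
                        adg = unname(adg), w0 = w0, mmwt = unname(mmwt),
                        rfi = unname(rfi), energy_mj = ei,
                        daily_grams = daily_grams,
                        events_per_day = events_day, rate_g_s = rate_gs)
  for (r in 1:2) {
    latents[[paste0("ch4_r", r)]] <- unname(pheno("ch4", r))
    latents[[paste0("co2_r", r)]] <- unname(pheno("co2", r))
    latents[[paste0("bw_r", r)]] <-
      w0 + adg * config$pac$round_days[r]
  }

  # --- streams ------------------------------------------------------------
  cohort_start <- stats::setNames(
    as.Date(paste0(cohort_year(labs), "-07-01")) +
      ifelse(grepl("b$", labs), 70, 0), labs)
  feeder_events <- sim_feeder_events(animals, latents, config, cohort_start)
  liveweights <- sim_liveweights(animals, latents, config)
  pac <- sim_pac(animals, latents, config)
  ct_sub <- animals$cohort %in% labs[seq_len(min(config$ct$subset_cohorts,
                                                 length(labs)))]
  ct <- sim_ct(animals[ct_sub, ], components, config)
  ultrasound <- data.frame(animal = animals$animal,
                           c_start_mm = pmax(stats::rnorm(n, 3.85, 1.156), 0.5))
  ultrasound$c_final_mm <- pmax(ultrasound$c_start_mm +
                                  stats::rnorm(n, 0.74, 1.097), 0.5)
  structure(list(config = config, pedigree = ped, animals = animals,
                 truth = list(components = components, latents = latents),
                 feeder_events = feeder_events, liveweights = liveweights,
                 pac = pac, ct = ct, ultrasound = ultrasound,
                 feed_by_cohort = feed_by_cohort, fixed_terms = fixed_terms),
            class = "ovi_cohort")
}

# Feeder-event stream: per animal-day visit counts around the animal's
# latent visit rate, day factors normalized so the 42-day mean intake equals
# the latent daily intake exactly, gamma shares within a day.
sim_feeder_events <- function(animals, latents, config, cohort_start) {
  n <- nrow(animals)
  nd <- 42
  cv <- config$intake_day_cv
  fac <- matrix(if (cv > 0) stats::rlnorm(n * nd, 0, cv) else 1, n, nd)
  fac <- fac / rowMeans(fac)
  counts <- matrix(pmax(stats::rpois(n * nd, rep(latents$events_per_day, nd)),
                        1L), n, nd)
  tot <- sum(counts)
  an_i <- rep(rep(seq_len(n), nd), as.vector(counts))
  day_i <- rep(rep(seq_len(nd) - 1L, each = n), as.vector(counts))
  grp <- rep(seq_len(n * nd), as.vector(counts))
  share <- stats::rgamma(tot, shape = 1.5)
  share <- share / rep(rowsum(share, grp)[, 1], as.vector(counts))
  grams <- share * (latents$daily_grams[an_i] * as.vector(fac)[grp])
  rate <- latents$rate_g_s[an_i] * stats::rlnorm(tot, 0, 0.25)
  dur <- grams / rate
  start_s <- sort_within(stats::runif(tot, 6 * 3600, 22 * 3600), grp)
  date0 <- cohort_start[animals$cohort[an_i]]
  entry <- as.POSIXct(date0, tz = "UTC") + day_i * 86400 + start_s
  feeder <- paste0(animals$cohort_pen[an_i], "-F",
                   sample.int(4, tot, replace = TRUE))
  data.frame(animal = animals$animal[an_i], feeder = feeder, entry = entry,
             exit = entry + dur, grams = grams)
}

# ascending within each contiguous group (grp is non-decreasing here)
sort_within <- function(x, grp) x[order(grp, x)]

sim_liveweights <- function(animals, latents, config) {
  wd <- c(0, 3, 7, 10, 14, 17, 21, 24, 28, 31, 35, 38, 42)
  out <- expand.grid(animal = latents$animal, day = wd,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  i <- match(out$animal, latents$animal)
  out$kg <- latents$w0[i] + latents$adg[i] * out$day +
    stats::rnorm(nrow(out), 0, config$weighing_noise_sd)
  out[order(out$animal, out$day), ]
}

# Chamber concentration profiles: linear rise at the rate implied by the
# animal's round-level emission times a lot-level log-normal nuisance.
sim_pac <- function(animals, latents, config) {
  pc <- config$pac
  rows <- list()
  for (r in 1:2) {
    for (co in unique(animals$cohort)) {
      i <- which(animals$cohort == co)
      i <- sample(i)   # re-allocation to lots each round
      lot_no <- ceiling(seq_along(i) / pc$lot_size)
      for (lt in unique(lot_no)) {
        members <- i[lot_no == lt]
        lot_id <- sprintf("%s-R%d-%02d", co, r, lt)
        lotf <- stats::rlnorm(1, 0, pc$lot_log_sd)
        tK <- stats::rnorm(1, pc$temp_K, pc$temp_sd)
        pK <- stats::rnorm(1, pc$pressure_kPa, pc$pressure_sd)
        mins <- pc$read_minutes +
          c(0, stats::rnorm(length(pc$read_minutes) - 1, 0,
                            pc$read_jitter_min))
        mins <- round(sort(mins), 1)
        for (k in seq_along(members)) {
          a <- members[k]
          bw <- latents[[paste0("bw_r", r)]][a]
          molair <- pK * (pc$chamber_volume_L - bw) / (R_GAS_KPA_L * tK)
          for (gas in c("ch4", "co2")) {
            gday <- latents[[paste0(gas, "_r", r)]][a] * lotf
            slope <- gday / (1e-6 * molair * GAS_MOLAR_MASS[[gas]] * 1440)
            base <- if (gas == "ch4") 2 else 450
            ppm <- base + slope * mins +
              stats::rnorm(length(mins), 0, pc$reading_noise_ppm[[gas]])
            rows[[length(rows) + 1L]] <-
              data.frame(animal = latents$animal[a], round = r, lot = lot_id,
                         chamber = sprintf("C%02d", k), gas = gas,
                         minutes = mins, concentration_ppm = ppm,
                         temp_K = tK, pressure_kPa = pK)
          }
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

ct_depot_shapes <- function() {
  list(visceral_fat = c(4, 3), subcutaneous_fat = c(3, 2.5),
       intermuscular_fat = c(2.8, 2.8), lean = c(2.2, 2.6),
       bone = c(2, 2), nonfat_viscera = c(3.5, 3))
}

depot_hu_band <- function(depot, config_seg = seg_config()) {
  switch(depot,
         visceral_fat = , subcutaneous_fat = ,
         intermuscular_fat = config_seg$hu_fat,
         lean = , nonfat_viscera = config_seg$hu_lean,
         bone = config_seg$hu_bone)
}

#' Forward-model one CT slice-area stack from latent depot masses
#'
#' Converts latent depot masses to smooth axial area profiles (scaled Beta
#' densities along the body axis) and samples them at slice midpoints, so
#' the continuous volume integral is known exactly and the rectangular-rule
#' reconstruction error is pure discretization error that shrinks with the
#' slice spacing.
#'
#' @param masses_kg Named vector of the six depot masses.
#' @param mean_hu Named vector of per-depot HU values (same scale as the
#'   segmentation bands).
#' @param spacing_mm Slice spacing.
#' @param body_length_mm Axial extent of the scanned region.
#' @param config_seg [seg_config()] supplying the HU-density map used to
#'   convert mass to volume.
#' @return data.frame `slice, compartment, tissue, area_mm2, mean_hu`.
#' @export
simulate_ct_stack <- function(masses_kg, mean_hu, spacing_mm = 30,
                              body_length_mm = 930,
                              config_seg = seg_config()) {
  shapes <- ct_depot_shapes()
  z <- seq(spacing_mm / 2, body_length_mm, by = spacing_mm)
  out <- list()
  for (dp in names(shapes)) {
    mass <- masses_kg[[dp]]
    if (is.null(mass) || mass <= 0) next
    vol_mm3 <- mass * 1000 / hu_density(mean_hu[[dp]], config_seg) * 1000
    sh <- shapes[[dp]]
    area <- vol_mm3 * stats::dbeta(z / body_length_mm, sh[1], sh[2]) /
      body_length_mm
    comp <- if (dp %in% c("visceral_fat", "nonfat_viscera")) "viscera"
            else "carcass"
    out[[dp]] <- data.frame(slice = seq_along(z), compartment = comp,
                            tissue = dp, area_mm2 = area,
                            mean_hu = mean_hu[[dp]])
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

sim_ct <- function(animals_sub, components, config) {
  if (nrow(animals_sub) == 0L) return(NULL)
  depots <- ct_depot_names()
  cfg_seg <- seg_config()
  mass_tab <- sapply(depots, function(dp) {
    i <- components$trait == dp
    ph <- stats::setNames(components$phenotype[i], components$animal[i])
    pmax(unname(ph[animals_sub$animal]), 0.2)
  })
  rows <- vector("list", nrow(animals_sub))
  for (k in seq_len(nrow(animals_sub))) {
    hu <- vapply(depots, function(dp) {
      b <- depot_hu_band(dp, cfg_seg)
      stats::runif(1, b[1] + 0.2 * diff(b), b[2] - 0.2 * diff(b))
    }, numeric(1))
    st <- simulate_ct_stack(stats::setNames(mass_tab[k, ], depots), hu,
                            config$ct$spacing_mm,
                            config$ct$body_length_mm, cfg_seg)
    rows[[k]] <- cbind(animal = animals_sub$animal[k], st)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

ct_depot_names <- function() {
  c("visceral_fat", "subcutaneous_fat", "intermuscular_fat", "lean", "bone",
    "nonfat_viscera")
}

#' Write a synthetic cohort bundle to CSV/YAML files
#'
#' Emits the same CSV dialects the pipeline readers consume, plus
#' `truth.csv` (the component table) and the generating `config.yaml`.
#'
#' @param cohort An `ovi_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "ovi_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    p
  }
  ev <- cohort$feeder_events
  ev$entry <- format(ev$entry, "%Y-%m-%dT%H:%M:%OS1", tz = "UTC")
  ev$exit <- format(ev$exit, "%Y-%m-%dT%H:%M:%OS1", tz = "UTC")
  files <- c(
    wr(as.data.frame(cohort$pedigree), "pedigree.csv"),
    wr(cohort$animals, "animals.csv"),
    wr(ev, "feeder_events.csv"),
    wr(cohort$liveweights, "liveweights.csv"),
    wr(cohort$pac, "pac.csv"),
    wr(cohort$truth$components, "truth.csv"),
    wr(cohort$ultrasound, "ultrasound.csv"))
  if (!is.null(cohort$ct)) files <- c(files, wr(cohort$ct, "ct_slices.csv"))
  cfg <- cohort$config
  cfg$trait_params <- NULL; cfg$genetic_correlations <- NULL
  cfg$ct_params <- NULL
  cfg$feed <- lapply(cfg$feed, unclass)
  yaml::write_yaml(lapply(unclass(cfg), function(x)
    if (is.matrix(x)) as.data.frame(x) else x),
    file.path(dir, "config.yaml"))
  invisible(c(files, file.path(dir, "config.yaml")))
}
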