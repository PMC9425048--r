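# End-to-end orchestration: simulate -> derive traits -> fit models ->
# report, from a single configuration and seed, with a reproducibility
# manifest.

#' Derive all phenotypes from raw data streams
#'
#' Turns the raw streams (feeder events, liveweights, chamber profiles, CT
#' slice tables) into the analysis trait table: mean daily and energy
#' intake, growth summaries by both methods, feeding-behavior traits, the
#' RFI residual, per-round gas traits with lot scaling, and CT composition
#' traits.
#'
#' @param inputs list with data.frames `feeder_events`, `liveweights`,
#'   `pac`, `animals` (covariates incl. flock/cohort/pen), optional `ct`,
#'   and `feed_by_cohort` (named list of [feed_spec()]s).
#' @param growth_method `"interpolation"` (default) or `"regression"` for
#'   the MMWT/ADG entering the RFI model.
#' @param pac_round_days Test days of the two chamber rounds (default
#'   c(21, 35)), used to interpolate the body weight at measurement.
#' @param ct_spacing_mm CT slice spacing (default 30).
#' @return list: `traits` (one row per animal), `gas` (one row per
#'   animal-round), `rfi_fit`, `growth` (both methods side by side).
#' @export
derive_traits <- function(inputs, growth_method = c("interpolation", "regression"),
                          pac_round_days = c(21, 35), ct_spacing_mm = 30) {
  growth_method <- match.arg(growth_method)
  an <- inputs$animals
  di <- suppressWarnings(daily_intake(inputs$feeder_events))
  mean_grams <- tapply(di$grams, di$animal, mean)
  lw_split <- split(inputs$liveweights[, c("day", "kg")],
                    inputs$liveweights$animal)
  gi <- lapply(lw_split, interpolate_growth)
  gr <- lapply(lw_split, regression_growth)
  growth <- data.frame(
    animal = names(gi),
    mmwt_interp = vapply(gi, `[[`, numeric(1), "mmwt"),
    adg_interp = vapply(gi, `[[`, numeric(1), "adg"),
    mmwt_regr = vapply(gr, `[[`, numeric(1), "mmwt"),
    adg_regr = vapply(gr, `[[`, numeric(1), "adg"))
  fb <- feeding_behavior(inputs$feeder_events)
  traits <- merge(an, growth, by = "animal")
  traits <- merge(traits, fb, by = "animal", all.x = TRUE)
  traits$mean_daily_grams <- as.numeric(mean_grams[traits$animal])
  traits$energy_mj <- vapply(seq_len(nrow(traits)), function(i) {
    energy_intake(traits$mean_daily_grams[i],
                  inputs$feed_by_cohort[[traits$cohort[i]]])
  }, numeric(1))
  sel <- if (growth_method == "interpolation") {
    c("mmwt_interp", "adg_interp")
  } else c("mmwt_regr", "adg_regr")
  traits$mmwt <- traits[[sel[1]]]
  traits$adg <- traits[[sel[2]]]
  rfi_fit <- fit_rfi(traits)
  traits$rfi <- unname(rfi_fit$rfi[traits$animal])
  # body weight at each chamber round from the interpolated growth curve
  bw <- do.call(rbind, lapply(seq_along(pac_round_days), function(r) {
    data.frame(animal = names(gi), round = r,
               kg = vapply(gi, function(g) {
                 g$daily$kg[g$daily$day == pac_round_days[r]]
               }, numeric(1)))
  }))
  gas <- derive_gas_traits(inputs$pac, bodyweight = bw)
  gm <- stats::aggregate(gas[, c("ch4_g_day_scaled", "co2_g_day_scaled",
                                 "sum_mol_day", "ch4_ratio")],
                         by = list(animal = gas$animal), FUN = mean)
  names(gm)[-1] <- paste0("mean_", names(gm)[-1])
  traits <- merge(traits, gm, by = "animal", all.x = TRUE)
  if (!is.null(inputs$ct)) {
    ct_rows <- lapply(split(inputs$ct, inputs$ct$animal), derive_ct_traits,
                      spacing_mm = ct_spacing_mm)
    ct_tab <- cbind(animal = names(ct_rows), do.call(rbind, ct_rows))
    rownames(ct_tab) <- NULL
    traits <- merge(traits, ct_tab, by = "animal", all.x = TRUE)
  }
  list(traits = traits, gas = gas, rfi_fit = rfi_fit, growth = growth)
}

#' Summarise REML fits as publication-style parameter tables
#'
#' @param fits Named list of `ovi_reml` objects (one per trait).
#' @param data Optional trait table used to add phenotypic means and SDs.
#' @param bivariate Optional named list of `ovi_reml_biv` objects.
#' @return list of data.frames: `parameters` (one row per trait: mean, sd,
#'   h2 and SE, maternal h2, repeatability, convergence) and `correlations`
#'   (one row per trait pair: r_g, r_p with SEs and significance flags).
#'   With no fits, data.frames with headers only.
#' @export
report_tables <- function(fits = list(), data = NULL, bivariate = list()) {
  row_of <- function(name, fit) {
    g <- function(lab, col) {
      if (!is.null(fit$ratios) && lab %in% rownames(fit$ratios)) {
        fit$ratios[lab, col]
      } else NA_real_
    }
    data.frame(trait = name,
               mean = if (!is.null(data) && name %in% names(data)) {
                 mean(data[[name]], na.rm = TRUE)
               } else NA_real_,
               sd = if (!is.null(data) && name %in% names(data)) {
                 stats::sd(data[[name]], na.rm = TRUE)
               } else NA_real_,
               h2 = g("h2_direct", "estimate"), h2_se = g("h2_direct", "se"),
               h2_maternal = g("h2_maternal", "estimate"),
               h2_maternal_se = g("h2_maternal", "se"),
               repeatability = g("repeatability", "estimate"),
               repeatability_se = g("repeatability", "se"),
               converged = isTRUE(fit$converged))
  }
  parameters <- if (length(fits)) {
    do.call(rbind, Map(row_of, names(fits), fits))
  } else {
    data.frame(trait = character(), mean = numeric(), sd = numeric(),
               h2 = numeric(), h2_se = numeric(), h2_maternal = numeric(),
               h2_maternal_se = numeric(), repeatability = numeric(),
               repeatability_se = numeric(), converged = logical())
  }
  rownames(parameters) <- NULL
  corr_row <- function(name, fit) {
    co <- fit$correlations
    data.frame(pair = name,
               r_g = co["r_g", "estimate"], r_g_se = co["r_g", "se"],
               r_g_significant = co["r_g", "significant"],
               r_p = co["r_p", "estimate"], r_p_se = co["r_p", "se"],
               r_p_significant = co["r_p", "significant"],
               converged = isTRUE(fit$converged))
  }
  correlations <- if (length(bivariate)) {
    do.call(rbind, Map(corr_row, names(bivariate), bivariate))
  } else {
    data.frame(pair = character(), r_g = numeric(), r_g_se = numeric(),
               r_g_significant = logical(), r_p = numeric(),
               r_p_se = numeric(), r_p_significant = logical(),
               converged = logical())
  }
  rownames(correlations) <- NULL
  # internal consistency: printed flags must follow the 2-SE rule
  stopifnot(identical(correlations$r_g_significant,
                      as.logical(significance_flag(correlations$r_g,
                                                   correlations$r_g_se))))
  list(parameters = parameters, correlations = correlations)
}

#' Run the full pipeline from one configuration
#'
#' Stages: `simulate` writes the synthetic raw-data CSVs; `traits` reads
#' them back through the file interfaces and constructs all phenotypes;
#' `fit` estimates variance components for the core traits (univariate
#' animal models with a maternal dam effect, a repeated-measures model for
#' the gas traits) and the RFI x methane-yield genetic correlation; `report`
#' writes parameter tables, a truth-versus-estimate recovery table and a
#' run manifest. `all` runs everything. Deterministic given the config seed.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory.
#' @param stage One of `"all"`, `"simulate"`, `"traits"`, `"fit"`,
#'   `"report"` (later stages rerun the earlier ones in memory).
#' @param verbose Print stage progress.
#' @return Invisibly, a list with the cohort, derived traits, fits and
#'   report tables.
#' @export
run_pipeline <- function(config = sim_config(), out_dir, stage = "all",
                         verbose = TRUE) {
  stage <- match.arg(stage, c("all", "simulate", "traits", "fit", "report"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message("[ovitraits] ", ...)
  fail_marker <- file.path(out_dir, "FAILED")
  if (file.exists(fail_marker)) unlink(fail_marker)
  run_stage <- function(label, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(paste0("stage ", label, ": ", conditionMessage(e)),
                 fail_marker)
      stop("pipeline stage '", label, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  say("simulate: seed ", config$seed)
  cohort <- run_stage("simulate", {
    ch <- simulate_cohort(config)
    write_cohort(ch, file.path(out_dir, "inputs"))
    ch
  })
  if (stage == "simulate") return(invisible(list(cohort = cohort)))

  say("traits: reading inputs back from ", file.path(out_dir, "inputs"))
  derived <- run_stage("traits", {
    idir <- file.path(out_dir, "inputs")
    for (f in c("feeder_events", "liveweights", "pac", "animals")) {
      if (!file.exists(file.path(idir, paste0(f, ".csv")))) {
        stop("missing input file: ", paste0(f, ".csv"))
      }
    }
    inputs <- list(
      feeder_events = utils::read.csv(file.path(idir, "feeder_events.csv")),
      liveweights = utils::read.csv(file.path(idir, "liveweights.csv")),
      pac = utils::read.csv(file.path(idir, "pac.csv")),
      animals = utils::read.csv(file.path(idir, "animals.csv"),
                                colClasses = c(animal = "character",
                                               cohort = "character")),
      ct = if (file.exists(file.path(idir, "ct_slices.csv"))) {
        utils::read.csv(file.path(idir, "ct_slices.csv"))
      },
      feed_by_cohort = cohort$feed_by_cohort)
    d <- derive_traits(inputs, pac_round_days = config$pac$round_days,
                       ct_spacing_mm = config$ct$spacing_mm)
    utils::write.csv(d$traits, file.path(out_dir, "traits.csv"),
                     row.names = FALSE)
    utils::write.csv(d$gas, file.path(out_dir, "gas_traits.csv"),
                     row.names = FALSE)
    d
  })
  if (stage == "traits") {
    return(invisible(list(cohort = cohort, derived = derived)))
  }

  say("fit: variance components")
  fits <- run_stage("fit", {
    ped <- cohort$pedigree
    Ainv <- build_A_inverse(ped)
    tr <- derived$traits
    fits <- list(
      rfi = reml_univariate(tr, "rfi", ped, fixed = ~1,
                            maternal = "genetic", Ainv = Ainv),
      adg = reml_univariate(tr, "adg", ped, fixed = ~ cg + brr,
                            maternal = "genetic", Ainv = Ainv),
      mmwt = reml_univariate(tr, "mmwt", ped, fixed = ~ cg + brr + aod +
                               I(aod^2) + bdev,
                             maternal = "genetic", Ainv = Ainv))
    gas <- merge(derived$gas,
                 tr[, c("animal", "cg", "cohort", "brr")], by = "animal")
    fits$ch4 <- reml_univariate(gas, "ch4_g_day_scaled", ped,
                                fixed = ~ cg + brr, maternal = "genetic",
                                Ainv = Ainv)
    fits$co2 <- reml_univariate(gas, "co2_g_day_scaled", ped,
                                fixed = ~ cohort + brr, maternal = "genetic",
                                Ainv = Ainv)
    biv <- list(
      `rfi x ch4_ratio` = reml_bivariate(
        merge(tr, stats::aggregate(ch4_ratio ~ animal, derived$gas, mean),
              by = "animal"),
        c("rfi", "ch4_ratio"), ped, Ainv = Ainv))
    list(univariate = fits, bivariate = biv)
  })
  if (stage == "fit") {
    return(invisible(list(cohort = cohort, derived = derived, fits = fits)))
  }

  say("report: tables and manifest")
  report <- run_stage("report", {
    rep_ <- report_tables(fits$univariate, data = derived$traits,
                          bivariate = fits$bivariate)
    utils::write.csv(rep_$parameters,
                     file.path(out_dir, "parameter_estimates.csv"),
                     row.names = FALSE)
    utils::write.csv(rep_$correlations,
                     file.path(out_dir, "correlation_estimates.csv"),
                     row.names = FALSE)
    tp <- config$trait_params
    rec <- merge(
      data.frame(trait = tp$trait, h2_true = tp$h2, m2_true = tp$m2),
      stats::setNames(rep_$parameters[, c("trait", "h2", "h2_maternal")],
                      c("trait", "h2_est", "m2_est")),
      by = "trait")
    utils::write.csv(rec, file.path(out_dir, "recovery.csv"),
                     row.names = FALSE)
    cfg_path <- file.path(out_dir, "inputs", "config.yaml")
    manifest <- list(seed = config$seed,
                     config_md5 = unname(tools::md5sum(cfg_path)),
                     n_animals = nrow(cohort$animals),
                     package_version =
                       as.character(utils::packageVersion("ovitraits")),
                     r_version = R.version.string,
                     created = format(Sys.time(), tz = "UTC"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    rep_
  })
  say("done")
  invisible(list(cohort = cohort, derived = derived, fits = fits,
                 report = report))
}
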