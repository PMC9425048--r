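GAS_MOLAR_MASS <- c(ch4 = 16.04, co2 = 44.01, o2 = 32.00)
R_GAS_KPA_L <- 8.31446  # kPa.L / (mol.K)

#' Daily gas emission rate from chamber concentration readings
#'
#' Converts the timed concentration readings taken in a sealed accumulation
#' chamber into a daily emission rate. The concentration (ppm, i.e. micromole
#' fraction) is regressed on time by OLS; the slope is multiplied by the
#' chamber free volume expressed as moles of air at the recorded temperature
#' and pressure (ideal gas), by the gas molar mass, and by 1440 min/day.
#' The animal's body volume is subtracted from the chamber volume using the
#' approximation 1 kg liveweight = 1 L.
#'
#' @param minutes Numeric vector of reading times (minutes since closure).
#' @param ppm Concentrations at those times, in ppm.
#' @param molar_mass Gas molar mass in g/mol (e.g. 16.04 for methane,
#'   44.01 for carbon dioxide).
#' @param temp_K Ambient temperature (K).
#' @param pressure_kPa Atmospheric pressure (kPa).
#' @param chamber_volume_L Chamber internal volume (default 827 L).
#' @param animal_volume_L Volume displaced by the animal, in litres;
#'   typically the liveweight in kg.
#' @return list: `g_per_day`, `slope_ppm_min`, and `flagged` (TRUE when the
#'   fitted slope is negative; the value is retained).
#' @export
emission_rate <- function(minutes, ppm, molar_mass,
                          temp_K = 288.15, pressure_kPa = 101.325,
                          chamber_volume_L = 827, animal_volume_L = 0) {
  stopifnot(length(minutes) >= 2, length(ppm) == length(minutes),
            temp_K > 0, pressure_kPa > 0, chamber_volume_L > animal_volume_L)
  if (is.unsorted(minutes, strictly = TRUE)) stop("reading times must increase")
  slope <- unname(stats::coef(stats::lm(ppm ~ minutes))[2])  # ppm/min
  free_L <- chamber_volume_L - animal_volume_L
  mol_air <- pressure_kPa * free_L / (R_GAS_KPA_L * temp_K)
  g_day <- slope * 1e-6 * mol_air * molar_mass * 1440
  list(g_per_day = g_day, slope_ppm_min = slope, flagged = slope < 0)
}

#' Scale trait values to their contemporary-lot mean
#'
#' Removes nuisance variation between measurement lots (groups of animals
#' measured together) by replacing each value with its ratio to the lot mean
#' multiplied by the grand mean of the trait: after scaling, every lot mean
#' equals the grand mean, which itself is preserved exactly (for balanced
#' lots, and up to weighting otherwise).
#'
#' @param values Numeric trait values.
#' @param lot Lot identifier per value.
#' @return Numeric vector of scaled values.
#' @export
scale_by_lot <- function(values, lot) {
  stopifnot(length(values) == length(lot), !anyNA(values))
  lot <- as.character(lot)
  lm_ <- tapply(values, lot, mean)
  if (any(lm_ <= 0)) stop("non-positive lot mean; cannot ratio-scale")
  grand <- mean(values)
  as.numeric(values / lm_[lot] * grand)
}

#' Molar gas traits
#'
#' Converts daily methane and carbon dioxide mass emissions to the molar sum
#' CH4+CO2 (mol/day, a proxy for feed intake) and the methane-yield proxy
#' CH4/(CH4+CO2) (mol/mol).
#'
#' @param ch4_g_day,co2_g_day Daily emissions in grams.
#' @return data.frame `sum_mol_day`, `ch4_ratio`. The ratio is `NA` when both
#'   gases are zero.
#' @examples
#' molar_traits(17.2, 1248)  # about 29.4 mol/day, ratio about 0.037
#' @export
molar_traits <- function(ch4_g_day, co2_g_day) {
  stopifnot(all(ch4_g_day >= 0), all(co2_g_day >= 0))
  ch4_mol <- ch4_g_day / GAS_MOLAR_MASS[["ch4"]]
  co2_mol <- co2_g_day / GAS_MOLAR_MASS[["co2"]]
  s <- ch4_mol + co2_mol
  ratio <- ifelse(s > 0, ch4_mol / s, NA_real_)
  data.frame(sum_mol_day = s, ch4_ratio = ratio)
}

#' Derive per-animal-round gas traits from chamber records
#'
#' Runs [emission_rate()] on every animal-round-gas concentration profile in
#' a long-format chamber table, applies the lot-mean scaling correction per
#' trait within round, and appends the molar traits. Oxygen profiles, if
#' present, are parsed and ignored (no oxygen trait is derived).
#'
#' @param pac data.frame in long format with columns
#'   `animal, round, lot, chamber, gas, minutes, concentration_ppm, temp_K,
#'   pressure_kPa` (gas values `ch4`, `co2`, optionally `o2`).
#' @param bodyweight Optional data.frame `animal, round, kg` giving the
#'   liveweight at measurement, used as the displaced volume (1 kg = 1 L)
#'   and reported alongside the traits.
#' @param chamber_volume_L Chamber internal volume (default 827 L).
#' @param scale Apply the lot-mean scaling (default TRUE).
#' @return data.frame with one row per animal-round: raw and (if requested)
#'   scaled `ch4_g_day`, `co2_g_day`, the molar sum and ratio built from the
#'   scaled gases, lot, and `bw_kg` when supplied.
#' @export
derive_gas_traits <- function(pac, bodyweight = NULL, chamber_volume_L = 827,
                              scale = TRUE) {
  need <- c("animal", "round", "lot", "gas", "minutes", "concentration_ppm",
            "temp_K", "pressure_kPa")
  stopifnot(all(need %in% names(pac)))
  pac$gas <- tolower(as.character(pac$gas))
  pac <- pac[pac$gas %in% c("ch4", "co2"), , drop = FALSE]
  key <- interaction(pac$animal, pac$round, drop = TRUE)
  rows <- lapply(split(seq_len(nrow(pac)), key), function(i) {
    d <- pac[i, ]
    bw <- 0
    if (!is.null(bodyweight)) {
      m <- bodyweight$animal == d$animal[1] & bodyweight$round == d$round[1]
      if (any(m)) bw <- bodyweight$kg[which(m)[1]]
    }
    one_gas <- function(g) {
      dg <- d[d$gas == g, ]
      dg <- dg[order(dg$minutes), ]
      emission_rate(dg$minutes, dg$concentration_ppm, GAS_MOLAR_MASS[[g]],
                    temp_K = dg$temp_K[1], pressure_kPa = dg$pressure_kPa[1],
                    chamber_volume_L = chamber_volume_L,
                    animal_volume_L = bw)
    }
    ch4 <- one_gas("ch4"); co2 <- one_gas("co2")
    data.frame(animal = as.character(d$animal[1]), round = d$round[1],
               lot = as.character(d$lot[1]), bw_kg = bw,
               ch4_g_day = ch4$g_per_day, co2_g_day = co2$g_per_day,
               flagged = ch4$flagged || co2$flagged)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (scale) {
    # lots are re-allocated between rounds, so the scaling cell is round:lot;
    # the grand mean is taken over all animal-rounds of the dataset
    cell <- paste(out$round, out$lot, sep = ":")
    for (tr in c("ch4_g_day", "co2_g_day")) {
      out[[paste0(tr, "_scaled")]] <- scale_by_lot(out[[tr]], cell)
    }
    mt <- molar_traits(out$ch4_g_day_scaled, out$co2_g_day_scaled)
  } else {
    mt <- molar_traits(out$ch4_g_day, out$co2_g_day)
  }
  out$sum_mol_day <- mt$sum_mol_day
  out$ch4_ratio <- mt$ch4_ratio
  out
}
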