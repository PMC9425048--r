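#' Daily feed intake from feeder-event logs
#'
#' Sums feeder events to one intake value per animal per test day. Events are
#' assigned to the calendar day of their entry time, so a visit spanning
#' midnight is counted on the day it began. Records with negative mass are
#' rejected with a warning; animal-days with no events are reported as zero
#' grams with a warning.
#'
#' @param events data.frame with columns `animal`, `entry` (POSIXct or
#'   ISO-8601 string), `exit`, `grams`. A `feeder` column, if present, is
#'   ignored here.
#' @param days Integer vector of test-day indices to report (default
#'   `0:41`, i.e. a 42-day test period).
#' @param day0 Date of test day 0: a single date applied to all animals, a
#'   named vector of dates (one per animal), or `NULL` (default), in which
#'   case each animal's clock starts at its own first event date.
#' @return data.frame `animal, day, grams` with one row per animal-day.
#' @export
daily_intake <- function(events, days = 0:41, day0 = NULL) {
  events <- normalize_events(events)
  bad <- events$grams < 0
  if (any(bad)) {
    warning(sum(bad), " feeder event(s) with negative grams rejected")
    events <- events[!bad, , drop = FALSE]
  }
  evdate <- as.Date(events$entry, tz = "UTC")
  if (is.null(day0)) {
    # each animal's first event date starts its test clock (cohorts are
    # measured back-to-back, so a single global origin would misalign them)
    if (nrow(events) == 0L) stop("no events and no 'day0' supplied")
    first <- tapply(evdate, events$animal, min)
    origin <- as.Date(as.vector(first[events$animal]),
                      origin = "1970-01-01")
  } else if (length(day0) > 1L || !is.null(names(day0))) {
    origin <- as.Date(as.vector(day0[events$animal]))
  } else {
    origin <- as.Date(rep(day0, nrow(events)))
  }
  evday <- as.integer(evdate - origin)
  keep <- evday %in% days
  events <- events[keep, , drop = FALSE]
  evday <- evday[keep]
  animals <- sort(unique(events$animal))
  grid <- expand.grid(animal = animals, day = days,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  if (nrow(events)) {
    agg <- stats::aggregate(events$grams,
                            by = list(animal = events$animal, day = evday),
                            FUN = sum)
    names(agg)[3] <- "grams"
    grid <- merge(grid, agg, by = c("animal", "day"), all.x = TRUE)
  } else {
    grid$grams <- NA_real_
  }
  nz <- is.na(grid$grams)
  if (any(nz)) {
    warning(sum(nz), " animal-day(s) with no feeder events set to 0 g")
    grid$grams[nz] <- 0
  }
  grid <- grid[order(grid$animal, grid$day), ]
  rownames(grid) <- NULL
  grid
}

normalize_events <- function(events) {
  stopifnot(is.data.frame(events))
  if (!all(c("animal", "entry", "exit", "grams") %in% names(events))) {
    stop("events need columns 'animal', 'entry', 'exit', 'grams'")
  }
  ev <- events
  ev$animal <- as.character(ev$animal)
  for (cc in c("entry", "exit")) {
    if (!inherits(ev[[cc]], "POSIXct")) {
      ev[[cc]] <- as.POSIXct(ev[[cc]], tz = "UTC",
                             tryFormats = c("%Y-%m-%dT%H:%M:%OS",
                                            "%Y-%m-%d %H:%M:%OS"))
    }
  }
  if (any(ev$exit < ev$entry, na.rm = TRUE)) stop("event exit before entry")
  ev$grams <- as.numeric(ev$grams)
  ev
}

#' Convert mean daily feed intake to metabolizable energy intake
#'
#' Energy intake (MJ ME/day) is the product of as-fed intake, the feed's
#' dry-matter fraction and its metabolizable energy density:
#' `MJ = kg_as_fed * dm_frac * me_mj_per_kg_dm`.
#'
#' @param mean_daily_grams Mean as-fed intake in grams/day.
#' @param feed A feed spec: list or one-row data.frame with `dm_frac`
#'   (0--1) and `me_mj_per_kg_dm` (MJ/kg DM). See [feed_spec()].
#' @return Energy intake in MJ ME/day.
#' @examples
#' energy_intake(2500, feed_spec(dm_frac = 0.93, me_mj_per_kg_dm = 10.9))
#' @export
energy_intake <- function(mean_daily_grams, feed) {
  stopifnot(feed$dm_frac > 0, feed$dm_frac <= 1, feed$me_mj_per_kg_dm > 0)
  (mean_daily_grams / 1000) * feed$dm_frac * feed$me_mj_per_kg_dm
}

#' Feed composition specification
#'
#' @param dm_frac Dry-matter fraction of the pellets (0--1).
#' @param me_mj_per_kg_dm Metabolizable energy, MJ per kg dry matter.
#' @param year Optional year/cohort label.
#' @return list of class `feed_spec`.
#' @export
feed_spec <- function(dm_frac, me_mj_per_kg_dm, year = NA) {
  stopifnot(dm_frac > 0, dm_frac <= 1, me_mj_per_kg_dm > 0)
  structure(list(dm_frac = dm_frac, me_mj_per_kg_dm = me_mj_per_kg_dm,
                 year = year), class = "feed_spec")
}

#' Growth summaries by piecewise-linear interpolation
#'
#' Interpolates liveweights linearly between consecutive weighings to a daily
#' grid over the test period (days 0--42 inclusive), then summarises growth:
#' ADG is the (fitted day-42 minus day-0) weight over 42, and the metabolic
#' mid-weight is the day-21 weight raised to the 0.75 power. Days outside the
#' observed range are extrapolated with the nearest segment's slope (with a
#' warning).
#'
#' @param weights data.frame with columns `day` (numeric, day 0 = first
#'   test-period weighing) and `kg`. One animal's records.
#' @param test_length Length of the test period in days (default 42).
#' @return list of class `growth_summary`: `daily` (data.frame day/kg over
#'   the full grid), `adg` (kg/day), `day21_kg`, `mmwt` (kg^0.75).
#' @export
interpolate_growth <- function(weights, test_length = 42) {
  w <- check_weights(weights)
  grid <- 0:test_length
  if (min(w$day) > 0 || max(w$day) < test_length) {
    warning("weighings do not span the full test period; extrapolating ",
            "with the nearest segment slope")
  }
  kg <- stats::approx(w$day, w$kg, xout = grid, rule = 2)$y
  # linear extrapolation by nearest segment slope beyond the observed range
  if (nrow(w) >= 2) {
    lo <- w$day[1]; hi <- w$day[nrow(w)]
    s_lo <- (w$kg[2] - w$kg[1]) / (w$day[2] - w$day[1])
    s_hi <- (w$kg[nrow(w)] - w$kg[nrow(w) - 1]) /
            (w$day[nrow(w)] - w$day[nrow(w) - 1])
    kg[grid < lo] <- w$kg[1] + s_lo * (grid[grid < lo] - lo)
    kg[grid > hi] <- w$kg[nrow(w)] + s_hi * (grid[grid > hi] - hi)
  }
  mid <- test_length / 2
  day21 <- stats::approx(grid, kg, xout = mid)$y
  growth_summary(daily = data.frame(day = grid, kg = kg),
                 adg = (kg[length(kg)] - kg[1]) / test_length,
                 day21_kg = day21)
}

#' Growth summaries by ordinary least-squares regression
#'
#' Fits `kg ~ day` by OLS over the weighing records; ADG is the slope and the
#' metabolic mid-weight comes from the fitted day-21 weight.
#'
#' @inheritParams interpolate_growth
#' @return As [interpolate_growth()].
#' @export
regression_growth <- function(weights, test_length = 42) {
  w <- check_weights(weights)
  fit <- stats::lm(kg ~ day, data = w)
  grid <- 0:test_length
  kg <- unname(stats::predict(fit, newdata = data.frame(day = grid)))
  day21 <- unname(stats::predict(fit, newdata = data.frame(day = test_length / 2)))
  growth_summary(daily = data.frame(day = grid, kg = kg),
                 adg = unname(stats::coef(fit)[2]),
                 day21_kg = day21)
}

check_weights <- function(weights) {
  stopifnot(is.data.frame(weights), all(c("day", "kg") %in% names(weights)))
  w <- weights[order(weights$day), c("day", "kg")]
  if (nrow(w) < 2) stop("need at least two weighings")
  if (anyDuplicated(w$day)) stop("duplicate weighing days")
  w
}

growth_summary <- function(daily, adg, day21_kg) {
  structure(list(daily = daily, adg = adg, day21_kg = day21_kg,
                 mmwt = metabolic_midweight(day21_kg)),
            class = "growth_summary")
}

#' Metabolic mid-weight
#'
#' The mid-test liveweight raised to the 0.75 power, the conventional proxy
#' for maintenance energy requirement.
#'
#' @param day21_kg Mid-test (day 21) liveweight in kg; must be positive.
#' @return Metabolic weight in kg^0.75.
#' @examples
#' metabolic_midweight(57.2)  # 20.8 to 1 d.p.
#' @export
metabolic_midweight <- function(day21_kg) {
  if (any(day21_kg <= 0)) stop("liveweight must be positive")
  day21_kg^0.75
}

#' Feeding-behavior traits from feeder events
#'
#' Per animal: average number of feeding events per day, average event
#' duration (s), average intake per event (g), and average feeding rate
#' (g/s). The rate is computed per event (intake/duration) and then
#' averaged across events, not pooled; zero-duration events are excluded
#' from the rate average but still counted as events.
#'
#' @inheritParams daily_intake
#' @param n_days Number of test days over which events/day is computed
#'   (default 42).
#' @return data.frame with one row per animal: `animal, events_per_day,
#'   mean_duration_s, mean_grams_per_event, mean_rate_g_s`.
#' @export
feeding_behavior <- function(events, n_days = 42) {
  events <- normalize_events(events)
  if (nrow(events) == 0L) {
    warning("no feeder events; feeding behavior undefined")
    return(data.frame(animal = character(), events_per_day = numeric(),
                      mean_duration_s = numeric(),
                      mean_grams_per_event = numeric(),
                      mean_rate_g_s = numeric()))
  }
  dur <- as.numeric(difftime(events$exit, events$entry, units = "secs"))
  sp <- split(seq_len(nrow(events)), events$animal)
  out <- lapply(names(sp), function(a) {
    i <- sp[[a]]
    d <- dur[i]; g <- events$grams[i]
    pos <- d > 0
    data.frame(animal = a,
               events_per_day = length(i) / n_days,
               mean_duration_s = mean(d),
               mean_grams_per_event = mean(g),
               mean_rate_g_s = if (any(pos)) mean(g[pos] / d[pos]) else NA_real_)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Fit the residual feed intake model
#'
#' Regresses energy intake on metabolic mid-weight and average daily gain
#' together with management factors (flock, cohort, and pen nested within
#' cohort); the residual is the RFI trait. Aliased columns arising from the
#' nesting are dropped by the OLS fit.
#'
#' @param data data.frame with columns `animal`, `energy_mj` (MJ ME/day),
#'   `mmwt`, `adg`, and factors `flock`, `cohort`, `pen`.
#' @return list of class `rfi_fit`: `coefficients`, `rfi` (named residual
#'   vector, MJ/day), `fitted`, `r2` (overall), `r2_by_cohort`, and the
#'   underlying `lm` object.
#' @export
fit_rfi <- function(data) {
  need <- c("animal", "energy_mj", "mmwt", "adg", "flock", "cohort", "pen")
  stopifnot(all(need %in% names(data)))
  d <- data
  for (cc in c("flock", "cohort")) d[[cc]] <- factor(d[[cc]])
  d$pen <- factor(paste(d$cohort, d$pen, sep = "."))  # pen nested in cohort
  fit <- stats::lm(energy_mj ~ mmwt + adg + flock + cohort + pen, data = d)
  res <- stats::residuals(fit)
  names(res) <- d$animal
  r2_cohort <- vapply(split(seq_len(nrow(d)), d$cohort), function(i) {
    1 - sum(res[i]^2) / sum((d$energy_mj[i] - mean(d$energy_mj[i]))^2)
  }, numeric(1))
  structure(list(coefficients = stats::coef(fit), rfi = res,
                 fitted = stats::fitted(fit),
                 r2 = 1 - sum(res^2) / sum((d$energy_mj - mean(d$energy_mj))^2),
                 r2_by_cohort = r2_cohort, lm = fit),
            class = "rfi_fit")
}
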