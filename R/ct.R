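#' Hounsfield-unit segmentation configuration
#'
#' Default bands follow the offset display scale used by livestock CT
#' protocols, with fat 40--115, lean 116--200 and bone 201--255; the bands
#' are configuration, not constants, because the offset is scanner-dependent.
#' The density map is a linear attenuation-to-density relationship
#' `g/cm^3 = intercept + slope * HU` on the same scale.
#'
#' @param hu_fat,hu_lean,hu_bone Inclusive `[low, high]` bands.
#' @param density_intercept,density_slope Linear HU-to-density coefficients.
#' @return list of class `seg_config`.
#' @export
seg_config <- function(hu_fat = c(40, 115), hu_lean = c(116, 200),
                       hu_bone = c(201, 255),
                       density_intercept = 0.7697, density_slope = 0.002326) {
  bands <- rbind(hu_fat, hu_lean, hu_bone)
  if (any(diff(as.vector(t(bands))) <= 0)) {
    stop("HU bands must be disjoint and ordered fat < lean < bone")
  }
  structure(list(hu_fat = hu_fat, hu_lean = hu_lean, hu_bone = hu_bone,
                 density_intercept = density_intercept,
                 density_slope = density_slope), class = "seg_config")
}

hu_density <- function(hu, config) {
  d <- config$density_intercept + config$density_slope * hu
  if (any(d <= 0)) stop("non-positive tissue density from HU map")
  d
}

#' Segment one CT slice raster by Hounsfield-unit bands
#'
#' Assigns every pixel to exactly one of fat, lean, bone or background.
#' Band edges are inclusive on both sides.
#'
#' @param raster Numeric matrix of pixel values on the same scale as the
#'   configured bands.
#' @param config A [seg_config()].
#' @param pixel_area_mm2 Area of one pixel in mm^2.
#' @return data.frame with one row per tissue (`fat`, `lean`, `bone`,
#'   `background`): pixel `count`, `area_mm2`, and `mean_hu` (NA for empty
#'   classes; background mean is not reported).
#' @export
segment_slice <- function(raster, config = seg_config(), pixel_area_mm2 = 1) {
  v <- as.vector(raster)
  cls <- rep("background", length(v))
  cls[v >= config$hu_fat[1] & v <= config$hu_fat[2]] <- "fat"
  cls[v >= config$hu_lean[1] & v <= config$hu_lean[2]] <- "lean"
  cls[v >= config$hu_bone[1] & v <= config$hu_bone[2]] <- "bone"
  tissues <- c("fat", "lean", "bone", "background")
  count <- vapply(tissues, function(t) sum(cls == t), integer(1))
  mean_hu <- vapply(tissues, function(t) {
    if (t == "background" || count[[t]] == 0L) NA_real_ else mean(v[cls == t])
  }, numeric(1))
  data.frame(tissue = tissues, count = unname(count),
             area_mm2 = unname(count) * pixel_area_mm2,
             mean_hu = unname(mean_hu))
}

#' Tissue volume from per-slice areas
#'
#' Numerically integrates per-slice tissue areas along the body axis by the
#' rectangular rule: the sum of areas multiplied by the slice spacing.
#' A trapezoidal alternative is available behind a flag.
#'
#' @param areas_mm2 Per-slice areas (mm^2), in axial order.
#' @param spacing_mm Distance between slices (mm); default 30.
#' @param method `"rectangular"` (default) or `"trapezoidal"`.
#' @return Volume in cm^3.
#' @export
tissue_volume <- function(areas_mm2, spacing_mm = 30, method = "rectangular") {
  stopifnot(length(areas_mm2) >= 1, spacing_mm > 0, all(areas_mm2 >= 0))
  method <- match.arg(method, c("rectangular", "trapezoidal"))
  v_mm3 <- switch(method,
    rectangular = sum(areas_mm2) * spacing_mm,
    trapezoidal = if (length(areas_mm2) == 1L) areas_mm2 * spacing_mm else
      sum((areas_mm2[-1] + areas_mm2[-length(areas_mm2)]) / 2) * spacing_mm)
  v_mm3 / 1000
}

#' Convert a tissue volume to mass via the HU-density relationship
#'
#' @param volume_cm3 Tissue volume (cm^3).
#' @param mean_hu Area-weighted mean HU of the tissue across slices.
#' @param config A [seg_config()] carrying the linear HU-to-density map.
#' @return Mass in kg.
#' @export
volume_to_mass <- function(volume_cm3, mean_hu, config = seg_config()) {
  stopifnot(volume_cm3 >= 0)
  volume_cm3 * hu_density(mean_hu, config) / 1000
}

#' Assemble derived carcass-composition traits from depot masses
#'
#' Applies the standard identities: carcass fat = subcutaneous +
#' intermuscular fat; total fat = carcass fat + visceral fat; carcass weight
#' = carcass fat + lean + bone; CT weight (fasted empty body weight) =
#' carcass weight + visceral fat + non-fat visceral components;
#' dressing-out percent = 100 * carcass weight / CT weight.
#'
#' @param masses Named list or one-row data.frame with kg masses
#'   `subcutaneous_fat`, `intermuscular_fat`, `visceral_fat`, `lean`,
#'   `bone`, `nonfat_viscera`.
#' @return One-row data.frame with the input depots plus `carcass_fat`,
#'   `total_fat`, `carcass_weight`, `ct_weight`, `dressing_out_pct`,
#'   `fat_lean_ratio`.
#' @examples
#' assemble_composition(list(subcutaneous_fat = 5.51, intermuscular_fat = 2.29,
#'                           visceral_fat = 5.13, lean = 19.10, bone = 4.36,
#'                           nonfat_viscera = 10.76))
#' @export
assemble_composition <- function(masses) {
  need <- c("subcutaneous_fat", "intermuscular_fat", "visceral_fat",
            "lean", "bone", "nonfat_viscera")
  stopifnot(all(need %in% names(masses)))
  m <- lapply(masses[need], as.numeric)
  if (any(unlist(m) < 0)) stop("negative depot mass")
  carcass_fat <- m$subcutaneous_fat + m$intermuscular_fat
  total_fat <- carcass_fat + m$visceral_fat
  carcass_weight <- carcass_fat + m$lean + m$bone
  ct_weight <- carcass_weight + m$visceral_fat + m$nonfat_viscera
  out <- data.frame(as.data.frame(m),
                    carcass_fat = carcass_fat, total_fat = total_fat,
                    carcass_weight = carcass_weight, ct_weight = ct_weight,
                    dressing_out_pct = 100 * carcass_weight / ct_weight,
                    fat_lean_ratio = if (m$lean > 0) carcass_fat / m$lean else NA_real_)
  stopifnot(abs(out$total_fat - (m$subcutaneous_fat + m$visceral_fat +
                                 m$intermuscular_fat)) < 1e-9,
            out$dressing_out_pct > 0, out$dressing_out_pct < 100)
  out
}

#' Segment a raster CT stack into a labelled tissue-area table
#'
#' Runs [segment_slice()] over each slice raster and maps the fat/lean/bone
#' classes to body-composition depots using the per-slice compartment label
#' (the manual carcass/viscera split) and, for carcass slices, a logical
#' subcutaneous mask separating subcutaneous from intermuscular fat pixels.
#' In visceral slices, fat maps to visceral fat and lean to non-fat visceral
#' components; bone maps to bone in either compartment.
#'
#' @param rasters List of numeric matrices (one per slice, axial order).
#' @param compartments Character vector per slice: `"carcass"` or
#'   `"viscera"`.
#' @param subcut_masks Optional list of logical matrices (same shapes as the
#'   rasters); `TRUE` marks the subcutaneous region of a carcass slice.
#' @param config A [seg_config()].
#' @param pixel_area_mm2 Pixel area in mm^2.
#' @return data.frame in the format accepted by [derive_ct_traits()].
#' @export
segment_stack <- function(rasters, compartments, subcut_masks = NULL,
                          config = seg_config(), pixel_area_mm2 = 1) {
  stopifnot(length(rasters) == length(compartments),
            all(compartments %in% c("carcass", "viscera")))
  out <- list()
  for (k in seq_along(rasters)) {
    r <- rasters[[k]]
    comp <- compartments[k]
    seg_one <- function(sub_raster, depot_map) {
      seg <- segment_slice(sub_raster, config, pixel_area_mm2)
      seg <- seg[seg$tissue %in% names(depot_map) & seg$count > 0, ,
                 drop = FALSE]
      if (nrow(seg) == 0L) return(NULL)
      data.frame(slice = k, compartment = comp,
                 tissue = unname(depot_map[seg$tissue]),
                 area_mm2 = seg$area_mm2, mean_hu = seg$mean_hu)
    }
    if (comp == "viscera") {
      out[[length(out) + 1L]] <- seg_one(r, c(fat = "visceral_fat",
                                              lean = "nonfat_viscera",
                                              bone = "bone"))
    } else {
      mask <- if (!is.null(subcut_masks)) subcut_masks[[k]] else
        matrix(FALSE, nrow(r), ncol(r))
      bg <- config$hu_fat[1] - 1000  # value outside every band
      rs <- r; rs[!mask] <- bg
      ri <- r; ri[mask] <- bg
      out[[length(out) + 1L]] <- seg_one(rs, c(fat = "subcutaneous_fat"))
      out[[length(out) + 1L]] <- seg_one(ri, c(fat = "intermuscular_fat",
                                               lean = "lean", bone = "bone"))
    }
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  rownames(res) <- NULL
  res
}

#' Derive body-composition traits from a labelled CT stack
#'
#' Consumes a per-slice tissue-area table for one animal (the fast fixture
#' format, or the output of [segment_slice()] on rasters plus compartment
#' labels), integrates areas to volumes per depot, converts to masses via
#' the HU-density map, and assembles the derived traits.
#'
#' Depot mapping: carcass-compartment fat is split by its `tissue` label into
#' `subcutaneous_fat` and `intermuscular_fat`; carcass lean maps to `lean`;
#' bone from both compartments maps to `bone`; viscera-compartment fat is
#' `visceral_fat`; viscera lean is counted as non-fat visceral components.
#' Rumen contents are assumed already excluded from the visceral areas.
#'
#' @param stack data.frame with columns `slice`, `compartment` (`carcass` or
#'   `viscera`), `tissue` (`subcutaneous_fat`, `intermuscular_fat`, `lean`,
#'   `bone`, `visceral_fat`, `nonfat_viscera`), `area_mm2`, `mean_hu`.
#' @param spacing_mm Slice spacing (default 30).
#' @param config A [seg_config()].
#' @param method Integration rule passed to [tissue_volume()].
#' @return One-row data.frame as [assemble_composition()].
#' @export
derive_ct_traits <- function(stack, spacing_mm = 30, config = seg_config(),
                             method = "rectangular") {
  need <- c("slice", "compartment", "tissue", "area_mm2", "mean_hu")
  stopifnot(all(need %in% names(stack)))
  depots <- c("subcutaneous_fat", "intermuscular_fat", "visceral_fat",
              "lean", "bone", "nonfat_viscera")
  masses <- stats::setNames(numeric(length(depots)), depots)
  for (dp in depots) {
    rows <- stack[stack$tissue == dp, , drop = FALSE]
    if (nrow(rows) == 0L) next
    rows <- rows[order(rows$slice), ]
    vol <- tissue_volume(rows$area_mm2, spacing_mm, method)
    whu <- sum(rows$mean_hu * rows$area_mm2) / sum(rows$area_mm2)
    masses[[dp]] <- volume_to_mass(vol, whu, config)
  }
  assemble_composition(as.list(masses))
}
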