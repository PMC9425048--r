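test_that("segment_slice partitions pixels with inclusive band edges", {
  cfg <- seg_config()
  uni <- matrix(80, 10, 10)
  seg <- segment_slice(uni, cfg, pixel_area_mm2 = 2)
  expect_equal(seg$count[seg$tissue == "fat"], 100)
  expect_equal(seg$area_mm2[seg$tissue == "fat"], 200)
  # band boundaries: 115 fat, 116 lean, 200 lean, 201 bone
  edges <- matrix(c(115, 116, 200, 201), 2, 2)
  sege <- segment_slice(edges, cfg)
  expect_equal(sege$count[sege$tissue == "fat"], 1)
  expect_equal(sege$count[sege$tissue == "lean"], 2)
  expect_equal(sege$count[sege$tissue == "bone"], 1)
  # constructed 4x4 raster with known counts, background included
  r <- matrix(c(rep(50, 5), rep(150, 6), rep(220, 3), rep(-1000, 2)), 4, 4)
  segr <- segment_slice(r, cfg)
  expect_equal(segr$count, c(5, 6, 3, 2))
  expect_equal(sum(segr$count), 16)  # partition is exact
  expect_equal(segr$mean_hu[segr$tissue == "fat"], 50)
})

test_that("tissue volume integrates areas by the rectangular rule", {
  expect_equal(tissue_volume(100 * 100, spacing_mm = 30), 300)  # 100 cm2 slice
  expect_equal(tissue_volume(c(0, 0, 0), 30), 0)
  expect_equal(tissue_volume(c(1000, 2000, 3000), 30), 180)  # cm3 of mm2 ramp
  expect_equal(tissue_volume(c(1000, 2000, 3000), 30, method = "trapezoidal"),
               120)
})

test_that("volume_to_mass is linear in volume and uses area-weighted HU", {
  cfg <- seg_config(density_intercept = 1, density_slope = 0)
  expect_equal(volume_to_mass(1000, mean_hu = 80, cfg), 1)
  expect_equal(volume_to_mass(2000, 80, cfg), 2 * volume_to_mass(1000, 80, cfg))
  # weighted mean HU across two slices: (100*60 + 300*100)/400 = 90
  whu <- sum(c(100, 300) * c(60, 100)) / 400
  expect_equal(whu, 90)
  cfg2 <- seg_config()
  expect_equal(volume_to_mass(500, whu, cfg2),
               500 * (cfg2$density_intercept + cfg2$density_slope * 90) / 1000)
  expect_error(volume_to_mass(1, -4000, seg_config()), "density")
})

test_that("assemble_composition reproduces the depot-sum identities", {
  comp <- assemble_composition(list(subcutaneous_fat = 5.51,
                                    intermuscular_fat = 2.29,
                                    visceral_fat = 5.13, lean = 19.10,
                                    bone = 4.36, nonfat_viscera = 10.76))
  expect_equal(comp$carcass_fat, 7.80)
  expect_equal(comp$total_fat, 12.93)
  expect_equal(comp$carcass_weight, 31.26)
  expect_equal(comp$ct_weight, 31.26 + 5.13 + 10.76)
  expect_equal(comp$dressing_out_pct,
               100 * comp$carcass_weight / comp$ct_weight)
  # degenerate: lean only
  lean_only <- assemble_composition(list(subcutaneous_fat = 0,
                                         intermuscular_fat = 0,
                                         visceral_fat = 0, lean = 10,
                                         bone = 0, nonfat_viscera = 1))
  expect_equal(lean_only$carcass_weight, 10)
  expect_equal(lean_only$fat_lean_ratio, 0)
})

test_that("segment_stack maps compartments and subcutaneous masks to depots", {
  cfg <- seg_config()
  # carcass slice: left half subcutaneous fat, right half lean with a bone pixel
  r1 <- matrix(150, 8, 8); r1[, 1:4] <- 80; r1[1, 8] <- 220
  mask1 <- matrix(FALSE, 8, 8); mask1[, 1:4] <- TRUE
  # viscera slice: fat + lean mix
  r2 <- matrix(-1000, 8, 8); r2[1:4, ] <- 70; r2[5:6, ] <- 130
  tab <- segment_stack(list(r1, r2), c("carcass", "viscera"),
                       subcut_masks = list(mask1, NULL),
                       config = cfg, pixel_area_mm2 = 4)
  expect_equal(tab$area_mm2[tab$tissue == "subcutaneous_fat"], 32 * 4)
  expect_equal(tab$area_mm2[tab$tissue == "lean"], 31 * 4)
  expect_equal(tab$area_mm2[tab$tissue == "bone"], 4)
  expect_equal(tab$area_mm2[tab$tissue == "visceral_fat"], 32 * 4)
  expect_equal(tab$area_mm2[tab$tissue == "nonfat_viscera"], 16 * 4)
  comp <- derive_ct_traits(tab, spacing_mm = 30, config = cfg)
  expect_gt(comp$carcass_weight, 0)
  expect_equal(comp$total_fat,
               comp$subcutaneous_fat + comp$intermuscular_fat +
               comp$visceral_fat)
})
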