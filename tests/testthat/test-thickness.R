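test_that("clean_mask fills a one-pixel interior hole", {
  px <- matrix(0L, 7, 7)
  px[3:5, 2:6] <- 1L
  px[4, 4] <- 0L
  out <- clean_mask(px, min_component_px = 1L)
  expect_equal(sum(out), sum(px) + 1)
  expect_equal(out[4, 4], 1L)
})

test_that("clean_mask removes small components and keeps the band", {
  px <- matrix(0L, 40, 40)
  px[10:22, 1:40] <- 1L               # band, area 520
  px[30:31, 5:6] <- 1L                # 4-px blob
  out <- clean_mask(px, min_component_px = 25L)
  expect_equal(sum(out), 13 * 40)
  expect_true(all(out[30:31, 5:6] == 0L))
  expect_true(all(out[10:22, ] == 1L))
})

test_that("clean_mask uses 8-connectivity for components", {
  # diagonal chain of 30 pixels: one component under 8-connectivity,
  # 30 singletons under 4-connectivity
  px <- matrix(0L, 40, 40)
  for (k in 1:30) px[k, k] <- 1L
  out <- clean_mask(px, min_component_px = 25L, fill_holes = FALSE)
  expect_equal(sum(out), 30)
})

test_that("clean_mask is a fixed point on already-clean masks", {
  sp <- small_spec()
  ph <- render_bscan(sp, tsnit_profile(sp, 4), seed = 4)
  m <- ph$truth$mask
  out <- clean_mask(m)
  expect_identical(out$pixels, m$pixels)
  expect_error(clean_mask(matrix(0.5, 3, 3)), "binary")
})

test_that("column thickness equals independent per-column counting", {
  m <- flat_band_mask(10)
  prof <- thickness_profile(m, method = "column")
  expect_equal(prof$values_um, rep(10 * 3.87, 24))
  set.seed(101)
  for (rep in 1:50) {
    px <- random_mask(20, 15)
    prof <- thickness_profile(px, method = "column", axial_spacing_um = 2.5)
    oracle <- vapply(seq_len(ncol(px)), function(j) sum(px[, j]) * 2.5,
                     numeric(1))
    expect_equal(prof$values_um, oracle)
  }
})

test_that("all-zero masks give all-zero profiles under both methods", {
  px <- matrix(0L, 16, 16)
  expect_equal(thickness_profile(px, "column", 3.87)$values_um, rep(0, 16))
  expect_equal(thickness_profile(px, "edt", 3.87)$values_um, rep(0, 16))
})

test_that("distance-transform thickness agrees with column counts within one pixel", {
  for (h in 4:40) {
    m <- flat_band_mask(h, H = 60L, W = 16L, r0 = 10L, spacing = 1)
    col <- thickness_profile(m, method = "column")$values_um
    edt <- thickness_profile(m, method = "edt")$values_um
    expect_true(all(abs(edt - col) <= 1),
                info = paste("band height", h))
  }
})

test_that("edt tracks the column method on slope-gentle phantom bands", {
  # the per-column edt reads local band thickness, so it is only comparable
  # to the column count where the band slope is gentle: full angular
  # resolution, no jitter spikes, flat internal limiting membrane
  sp <- phantom_spec(group_preset = "control", jitter_amp_um = 0,
                     ilm_undulation_px = 0)
  ph <- render_bscan(sp, tsnit_profile(sp, 6), seed = 6)
  edt <- thickness_profile(ph$truth$mask, method = "edt")$values_um
  col <- thickness_profile(ph$truth$mask, method = "column")$values_um
  expect_lt(max(abs(edt - col)), 2 * sp$axial_spacing_um + 1e-9)
  expect_lt(mean(abs(edt - col)), sp$axial_spacing_um)
})

test_that("uniform profiles give identical sector and average values", {
  st <- sector_thickness(rnfl_profile(rep(100, 64)), eye = "OD")
  for (f in c("average_um", "nasal_um", "temporal_um", "nasal_inferior_um",
              "temporal_inferior_um", "nasal_superior_um",
              "temporal_superior_um")) {
    expect_equal(st[[f]], 100)
  }
})

test_that("OD/OS mirroring swaps nasal and temporal on an asymmetric profile", {
  # 8 A-scans at 0,45,...,315 deg; temporal span [315,45) holds columns 1, 8
  vals <- rep(60, 8)
  vals[c(1, 8)] <- 120
  od <- sector_thickness(rnfl_profile(vals), eye = "OD")
  expect_equal(od$temporal_um, 120)
  expect_equal(od$nasal_um, 60)
  os <- sector_thickness(rnfl_profile(vals), eye = "OS")
  expect_equal(os$nasal_um, 120)
  expect_equal(os$temporal_um, 60)
  # superior stays superior under mirroring: 112.5 deg is nasal-superior for
  # OD and maps to 67.5 deg = temporal-superior for OS
  vals2 <- rep(60, 16)
  vals2[6] <- 150 # (6-1) * 22.5 = 112.5 deg
  od2 <- sector_thickness(rnfl_profile(vals2), eye = "OD")
  os2 <- sector_thickness(rnfl_profile(vals2), eye = "OS")
  expect_gt(od2$nasal_superior_um, 60)
  expect_equal(od2$nasal_superior_um, os2$temporal_superior_um)
  expect_equal(od2$nasal_inferior_um, 60)
})

test_that("average equals the width-weighted mean of the six sectors", {
  set.seed(77)
  for (n in c(8, 64, 256)) {
    vals <- runif(n, 40, 160)
    for (eye in c("OD", "OS")) {
      st <- sector_thickness(rnfl_profile(vals), eye = eye)
      weighted <- (90 * st$temporal_um + 90 * st$nasal_um +
                     45 * (st$temporal_superior_um + st$nasal_superior_um +
                             st$temporal_inferior_um + st$nasal_inferior_um)) / 360
      expect_equal(st$average_um, weighted, tolerance = 1e-9)
    }
  }
})

test_that("degenerate layouts are rejected", {
  bad <- data.frame(sector = c("a", "b"), start = c(0, 90), end = c(90, 350))
  expect_error(sector_layout(bad), "cover")
  expect_error(sector_thickness(rnfl_profile(rep(1, 4))), "at least 6")
})
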