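test_that("flat profile: no humps and no jitter give a constant profile", {
  sp <- phantom_spec(baseline_um = 100, hump_amplitude_um = 0,
                     jitter_amp_um = 0, group_preset = "custom")
  prof <- tsnit_profile(sp, seed = 3)
  expect_equal(prof$values_um, rep(100, 256))
  expect_equal(prof$n_ascans, 256L)
})

test_that("jitter-free profile equals the closed-form double hump, argmax at centres", {
  sp <- phantom_spec(baseline_um = 80, hump_amplitude_um = 40,
                     jitter_amp_um = 0, group_preset = "custom")
  prof <- tsnit_profile(sp, seed = 9)
  # independent closed-form evaluation on the column grid
  theta <- (0:255) * 360 / 256
  expected <- 80 + 40 * (
    rowSums(sapply(c(-360, 0, 360), function(m)
      exp(-((theta - 67.5 + m)^2) / (2 * 27^2)))) +
    rowSums(sapply(c(-360, 0, 360), function(m)
      exp(-((theta - 292.5 + m)^2) / (2 * 27^2))))
  )
  expect_equal(prof$values_um, expected, tolerance = 1e-12)
  peaks <- which(prof$values_um == max(prof$values_um))
  centre_cols <- c(67.5, 292.5) / (360 / 256) + 1
  expect_true(all(peaks %in% centre_cols))
  expect_true(all(prof$values_um >= 80))
})

test_that("profiles always stay at or above the baseline with jitter on", {
  sp <- small_spec()
  for (s in 1:25) {
    prof <- tsnit_profile(sp, seed = s)
    expect_true(all(prof$values_um >= sp$baseline_um))
  }
})

test_that("generator is deterministic given (spec, seed)", {
  sp <- small_spec()
  p1 <- tsnit_profile(sp, seed = 123)
  p2 <- tsnit_profile(sp, seed = 123)
  expect_identical(p1, p2)
  r1 <- render_bscan(sp, p1, seed = 55)
  r2 <- render_bscan(sp, p2, seed = 55)
  expect_identical(r1$image$pixels, r2$image$pixels)
  expect_identical(r1$truth$mask$pixels, r2$truth$mask$pixels)
  expect_false(identical(r1$image$pixels,
                         render_bscan(sp, p1, seed = 56)$image$pixels))
})

test_that("noise-free rendering has exactly three intensity levels", {
  sp <- small_spec(speckle_shape = Inf)
  ph <- render_bscan(sp, tsnit_profile(sp, 2), seed = 1)
  expect_identical(sort(unique(as.vector(ph$image$pixels))),
                   sort(c(sp$background_level, sp$deep_level, sp$band_level)))
})

test_that("mask column counts match the requested profile within one axial pixel", {
  for (s in 1:10) {
    sp <- small_spec()
    prof <- tsnit_profile(sp, seed = s)
    ph <- render_bscan(sp, prof, seed = s + 100)
    col_um <- colSums(ph$truth$mask$pixels) * sp$axial_spacing_um
    expect_true(all(abs(col_um - prof$values_um) <= sp$axial_spacing_um))
    # mask pixels form one contiguous run starting at the ILM row
    for (j in seq_len(sp$width_ascans)) {
      rows <- which(ph$truth$mask$pixels[, j] == 1)
      expect_equal(rows, seq(ph$truth$ilm_row_per_column[j],
                             length.out = length(rows)))
    }
  }
})

test_that("profile exceeding the axial frame is a configuration error", {
  sp <- small_spec()
  too_thick <- rnfl_profile(rep(64 * 3.87, 64))
  expect_error(render_bscan(sp, too_thick, 1), "exceeding frame")
  short <- rnfl_profile(rep(100, 10))
  expect_error(render_bscan(sp, short, 1), "width_ascans")
})

test_that("invalid specs name the violated invariant", {
  expect_error(phantom_spec(baseline_um = 900, hump_amplitude_um = 200,
                            group_preset = "custom"),
               "axial frame")
  expect_error(phantom_spec(baseline_um = 50, hump_amplitude_um = 10,
                            group_preset = "custom", band_level = 1.2),
               "intensity levels")
  expect_error(phantom_spec(group_preset = "custom"), "custom")
})

test_that("group presets hit the published circle-average means", {
  targets <- c(control = 100.3, NAION = 69.7, ON = 76.1)
  for (g in names(targets)) {
    sp <- phantom_spec(group_preset = g)
    avgs <- vapply(1:60, function(s) {
      circle_average(tsnit_profile(sp, derive_seed(77, s)))
    }, numeric(1))
    expect_lt(abs(mean(avgs) - targets[[g]]), 2.5)
  }
})

test_that("make_dataset writes n image/mask pairs and a faithful manifest", {
  dir <- withr::local_tempdir()
  sp <- small_spec()
  man <- make_dataset(10, sp, seed = 42, out_dir = dir)
  expect_equal(nrow(man), 10)
  expect_length(list.files(dir, pattern = "\\.png$"), 20)
  expect_true(all(c("scan_id", "eye", "group", "true_avg_um", "true_n_um",
                    "true_t_um", "true_ni_um", "true_ti_um", "true_ns_um",
                    "true_ts_um") %in% names(man)))
  # masks on disk round-trip to the same thickness as the manifest truth
  m1 <- read_mask(file.path(dir, man$mask[1]),
                  axial_spacing_um = sp$axial_spacing_um)
  avg <- circle_average(thickness_profile(m1))
  expect_lt(abs(avg - man$true_avg_um[1]), sp$axial_spacing_um)
})

test_that("make_dataset is reproducible and rejects n < 1", {
  sp <- small_spec()
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  m1 <- make_dataset(4, sp, seed = 9, out_dir = d1)
  m2 <- make_dataset(4, sp, seed = 9, out_dir = d2)
  attr(m1, "dir") <- attr(m2, "dir") <- NULL
  attr(m1, "spec") <- attr(m2, "spec") <- NULL
  expect_identical(m1, m2)
  expect_identical(unname(tools::md5sum(file.path(d1, m1$image))),
                   unname(tools::md5sum(file.path(d2, m2$image))))
  expect_error(make_dataset(0, sp, 1, withr::local_tempdir()), "n must be")
})

test_that("NAION dataset manifest mean tracks the published group mean", {
  dir <- withr::local_tempdir()
  sp <- phantom_spec(width_ascans = 64L, height_px = 64L, ilm_depth_px = 10L,
                     group_preset = "NAION")
  man <- make_dataset(50, sp, seed = 31, out_dir = dir)
  expect_lt(abs(mean(man$true_avg_um) - 69.7), 5)
})

test_that("derived child seeds are platform-stable and decorrelated", {
  s <- vapply(1:1000, function(i) derive_seed(1L, i), integer(1))
  expect_false(any(duplicated(s)))
  expect_true(all(s >= 1 & s < 2^31))
  expect_identical(derive_seed(1L, 5L), derive_seed(1L, 5L))
  expect_false(derive_seed(1L, 5L) == derive_seed(2L, 5L))
})
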