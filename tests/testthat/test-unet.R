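# tiny phantoms (64x64) and narrow filter ladders keep these tests fast; the
# scaled-down training analog on the full grid lives in test-acceptance.R

make_tiny_samples <- function(n, seed = 1L, spec = small_spec()) {
  lapply(seq_len(n), function(i) {
    prof <- tsnit_profile(spec, derive_seed(seed, 2L * i))
    ph <- render_bscan(spec, prof, derive_seed(seed, 2L * i + 1L))
    pr <- prepare_input(ph$image$pixels, target = 64L)
    list(x = pr$input, y = ph$truth$mask$pixels * 1.0, scale = pr$scale,
         truth = ph$truth$mask, profile = prof)
  })
}

test_that("config invariants are enforced", {
  expect_error(unet_config(c(16L, 8L)), "strictly increasing")
  expect_error(unet_config(c(16L, 32L, 64L), input_size = 250L), "divisible")
  expect_silent(unet_config(c(8L, 16L), input_size = 64L))
})

test_that("forward pass keeps spatial dims, probabilities, and halves per level", {
  cfg <- unet_config(input_size = 256L) # default (16,32,64,128,256)
  m <- build_unet(cfg, seed = 2)
  x <- matrix(runif(256 * 256), 256, 256)
  fw <- unet_forward(m, x)
  expect_equal(dim(fw$prob), c(256L, 256L))
  expect_true(all(fw$prob > 0 & fw$prob < 1))
  expect_equal(fw$bottleneck, c(16L, 16L)) # 256 / 2^4
  cfg3 <- unet_config(c(4L, 8L, 16L), input_size = 64L)
  fw3 <- unet_forward(build_unet(cfg3, 1), matrix(0.5, 64, 64))
  expect_equal(fw3$bottleneck, c(16L, 16L)) # 64 / 2^2
})

test_that("parameter count matches an independent per-layer hand count", {
  count_by_hand <- function(filters) {
    L <- length(filters)
    total <- 0
    conv <- function(k, cin, cout) (k * k * cin + 1) * cout
    cin <- 1
    for (l in seq_len(L - 1)) {
      total <- total + conv(3, cin, filters[l]) + conv(3, filters[l], filters[l])
      cin <- filters[l]
    }
    total <- total + conv(3, cin, filters[L]) + conv(3, filters[L], filters[L])
    for (l in seq(L - 1, 1)) {
      total <- total + conv(2, filters[l + 1], filters[l]) +
        conv(3, 2 * filters[l], filters[l]) + conv(3, filters[l], filters[l])
    }
    total + conv(1, filters[1], 1)
  }
  for (filters in list(c(16L, 32L, 64L, 128L, 256L), c(8L, 16L, 32L),
                       c(4L, 8L))) {
    lv <- length(filters)
    m <- build_unet(unet_config(filters, input_size = 2L^(lv + 2L)), seed = 1)
    expect_equal(unet_n_params(m), count_by_hand(filters))
  }
})

test_that("training splits scans 80/20 and records finite losses", {
  samples <- make_tiny_samples(10, seed = 3)
  m <- build_unet(unet_config(c(4L, 8L), input_size = 64L), seed = 4)
  tr <- train_model(m, samples, train_config(epochs = 2L, batch_size = 4L,
                                             seed = 7L))
  expect_length(tr$model$split$train, 8L)
  expect_length(tr$model$split$val, 2L)
  expect_equal(nrow(tr$history), 2L)
  expect_true(all(is.finite(tr$history$train_loss)))
  expect_true(all(is.finite(tr$history$val_loss)))
  expect_true(tr$model$trained)
})

test_that("the network overfits a repeated phantom", {
  s <- make_tiny_samples(1, seed = 5)
  samples <- list(s[[1]], s[[1]], s[[1]], s[[1]])
  m <- build_unet(unet_config(c(4L, 8L), input_size = 64L), seed = 6)
  tr <- train_model(m, samples, train_config(train_fraction = 0.75,
                                             epochs = 60L, batch_size = 4L,
                                             learning_rate = 3e-3, seed = 8L))
  expect_lt(tr$history$train_loss[60], tr$history$train_loss[1])
  expect_lt(tr$history$train_loss[60], 0.1)
})

test_that("training is deterministic given the seed", {
  samples <- make_tiny_samples(4, seed = 9)
  run <- function() {
    m <- build_unet(unet_config(c(4L, 8L), input_size = 64L), seed = 10)
    train_model(m, samples, train_config(train_fraction = 0.75, epochs = 3L,
                                         batch_size = 2L, seed = 11L))
  }
  t1 <- run(); t2 <- run()
  expect_identical(t1$history, t2$history)
  expect_identical(t1$model$params, t2$model$params)
})

test_that("predictions are strictly binary and follow the threshold", {
  samples <- make_tiny_samples(1, seed = 12)
  m <- build_unet(unet_config(c(4L, 8L), input_size = 64L), seed = 13)
  prob <- unet_forward(m, samples[[1]]$x)$prob
  lo <- predict_mask(m, samples[[1]]$x, samples[[1]]$scale,
                     threshold = 0.001)
  hi <- predict_mask(m, samples[[1]]$x, samples[[1]]$scale,
                     threshold = 0.999)
  expect_true(all(lo$pixels %in% c(0L, 1L)))
  thr <- stats::median(prob)
  mid <- predict_mask(m, samples[[1]]$x, samples[[1]]$scale, threshold = thr)
  expect_identical(mid$pixels, matrix((prob >= thr) * 1L, 64, 64))
  expect_gte(sum(lo$pixels), sum(mid$pixels))
  expect_gte(sum(mid$pixels), sum(hi$pixels))
})

test_that("masks predicted for large scans come back at original dims", {
  px <- matrix(runif(496 * 768), 496, 768)
  pr <- prepare_input(px)
  m <- build_unet(unet_config(c(4L, 8L), input_size = 256L), seed = 14)
  mask <- predict_mask(m, pr$input, pr$scale)
  expect_equal(dim(mask$pixels), c(496L, 768L))
  expect_true(all(mask$pixels %in% c(0L, 1L)))
  expect_error(predict_mask(m, matrix(0, 64, 64), pr$scale), "inconsistent")
})

test_that("misaligned masks raise a data error naming the scan", {
  dir <- withr::local_tempdir()
  sp <- small_spec()
  man <- make_dataset(2, sp, seed = 15, out_dir = dir)
  # overwrite one mask with wrong dims
  write_mask_png(matrix(0L, 10, 10), file.path(dir, man$mask[2]))
  m <- build_unet(unet_config(c(4L, 8L), input_size = 64L), seed = 16)
  expect_error(train_model(m, man, train_config(epochs = 1L)),
               "scan_0002")
  expect_error(train_model(m, man[1, ], train_config(epochs = 1L)),
               "at least 2")
})

test_that("checkpoints round-trip through disk with a JSON sidecar", {
  dir <- withr::local_tempdir()
  m <- build_unet(unet_config(c(4L, 8L), input_size = 64L), seed = 17)
  path <- file.path(dir, "model.rds")
  save_model(m, path)
  expect_true(file.exists(paste0(path, ".json")))
  m2 <- load_model(path)
  expect_identical(m2$params, m$params)
  side <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(unlist(side$encoder_filters), c(4, 8))
})
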