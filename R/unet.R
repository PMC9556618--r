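#' U-Net architecture configuration
#'
#' The segmentation network is the classic encoder/decoder with skip
#' connections: per encoder level two 3x3 convolutions with rectified-linear
#' activation followed by 2x2 max pooling, a symmetric decoder with 2x2
#' up-convolutions and skip concatenations, and a final 1x1 convolution to a
#' single-channel probability map (logistic squashing). The default filter
#' ladder is (16, 32, 64, 128, 256); the last entry is the bottleneck, so a
#' 256x256 input reaches a 16x16 deepest feature map.
#'
#' @param encoder_filters Strictly increasing integer ladder; the last entry
#'   is the bottleneck width.
#' @param input_size Square input side; must be divisible by
#'   `2^(length(encoder_filters) - 1)`.
#' @param activation Only `"relu"` is implemented.
#' @return An object of class `unet_config`.
#' @export
unet_config <- function(encoder_filters = c(16L, 32L, 64L, 128L, 256L),
                        input_size = 256L, activation = "relu") {
  encoder_filters <- as.integer(encoder_filters)
  if (length(encoder_filters) < 2L || any(diff(encoder_filters) <= 0L)) {
    stop("encoder_filters must be a strictly increasing ladder of length >= 2")
  }
  levels <- length(encoder_filters)
  if (input_size %% 2L^(levels - 1L) != 0L) {
    stop("input_size (", input_size, ") must be divisible by 2^(levels-1) = ",
         2L^(levels - 1L))
  }
  if (!identical(activation, "relu")) stop("only relu activation is available")
  structure(list(encoder_filters = encoder_filters,
                 input_size = as.integer(input_size),
                 activation = activation),
            class = "unet_config")
}

#' Training configuration
#'
#' Loss is binary cross-entropy; scans (never individual rows) are split
#' into training and validation sets by `train_fraction` using `seed`.
#' Optimizer is Adam. Training is deterministic given the data and seeds:
#' the native single-threaded implementation has no nondeterministic kernels.
#'
#' @param train_fraction Fraction of scans used for training (0, 1).
#' @param epochs Training epochs.
#' @param learning_rate Adam step size.
#' @param batch_size Scans per gradient step (gradients averaged).
#' @param seed Seed for the split and epoch shuffling.
#' @param mask_threshold Probability threshold used at prediction time.
#' @param denoise Apply morphological denoising before the network.
#' @return An object of class `train_config`.
#' @export
train_config <- function(train_fraction = 0.8, epochs = 50L,
                         learning_rate = 1e-3, batch_size = 8L, seed = 1L,
                         mask_threshold = 0.5, denoise = TRUE) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must lie strictly between 0 and 1")
  }
  if (mask_threshold <= 0 || mask_threshold >= 1) {
    stop("mask_threshold must lie strictly between 0 and 1")
  }
  structure(list(loss = "binary_cross_entropy",
                 train_fraction = train_fraction, epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 mask_threshold = mask_threshold, denoise = isTRUE(denoise)),
            class = "train_config")
}

# parameter shapes in architecture order; each row matrix is (patch*c_in) x c_out
unet_param_shapes <- function(filters) {
  L <- length(filters)
  shapes <- list()
  cin <- 1L
  for (l in seq_len(L - 1L)) {
    shapes <- c(shapes, list(list(kind = "conv3", rows = 9L * cin,
                                  cols = filters[l])))
    shapes <- c(shapes, list(list(kind = "conv3", rows = 9L * filters[l],
                                  cols = filters[l])))
    cin <- filters[l]
  }
  shapes <- c(shapes, list(list(kind = "conv3", rows = 9L * cin,
                                cols = filters[L])))
  shapes <- c(shapes, list(list(kind = "conv3", rows = 9L * filters[L],
                                cols = filters[L])))
  for (l in seq(L - 1L, 1L)) {
    shapes <- c(shapes, list(list(kind = "up2", rows = 4L * filters[l + 1L],
                                  cols = filters[l])))
    shapes <- c(shapes, list(list(kind = "conv3", rows = 9L * 2L * filters[l],
                                  cols = filters[l])))
    shapes <- c(shapes, list(list(kind = "conv3", rows = 9L * filters[l],
                                  cols = filters[l])))
  }
  shapes <- c(shapes, list(list(kind = "conv1", rows = filters[1L],
                                cols = 1L)))
  shapes
}

#' Build a U-Net segmentation model
#'
#' Allocates and seed-initializes all weights (He-scaled normal draws, zero
#' biases) for the architecture described by a [unet_config()].
#'
#' @param config A [unet_config()].
#' @param seed Seed for the weight initialization.
#' @return An object of class `unet_model`.
#' @export
build_unet <- function(config = unet_config(), seed = 1L) {
  stopifnot(inherits(config, "unet_config"))
  filters <- config$encoder_filters
  shapes <- unet_param_shapes(filters)
  params <- withr::with_seed(as.integer(seed), {
    lapply(shapes, function(s) {
      list(W = matrix(stats::rnorm(s$rows * s$cols, sd = sqrt(2 / s$rows)),
                      s$rows, s$cols),
           b = numeric(s$cols))
    })
  })
  structure(list(config = config, params = params, trained = FALSE,
                 init_seed = as.integer(seed)),
            class = "unet_model")
}

#' Number of trainable parameters of a model
#' @param model A [unet_model][build_unet()].
#' @return Integer parameter count (weights + biases).
#' @export
unet_n_params <- function(model) {
  sum(vapply(model$params, function(p) length(p$W) + length(p$b), numeric(1)))
}

#' @export
print.unet_model <- function(x, ...) {
  cat(sprintf("unet_model: filters (%s), input %d, %s, %d parameters\n",
              paste(x$config$encoder_filters, collapse = ", "),
              x$config$input_size,
              if (x$trained) "trained" else "untrained",
              unet_n_params(x)))
  invisible(x)
}

#' Forward pass of the network
#'
#' @param model A [unet_model][build_unet()].
#' @param input Square matrix of side `config$input_size` in \[0,1\].
#' @return A list with `prob` (probability map, same dims as input) and
#'   `bottleneck` (dims of the deepest encoder feature map).
#' @export
unet_forward <- function(model, input) {
  input <- as.matrix(input)
  if (nrow(input) != model$config$input_size ||
      ncol(input) != model$config$input_size) {
    stop("input must be ", model$config$input_size, "x",
         model$config$input_size)
  }
  unet_forward_cpp(input, model$config$encoder_filters, model$params)
}

# load one manifest row into a prepared training sample
load_sample <- function(row, dir, tc, target) {
  img <- read_bscan(file.path(dir, row$image), eye = row$eye,
                    scan_id = row$scan_id)
  msk <- read_mask(file.path(dir, row$mask), eye = row$eye)
  if (!all(dim(msk$pixels) == dim(img$pixels))) {
    stop("mask misaligned with image for scan ", row$scan_id, ": ",
         paste(dim(msk$pixels), collapse = "x"), " vs ",
         paste(dim(img$pixels), collapse = "x"))
  }
  if (tc$denoise) img <- denoise_morphological(img)
  pr <- prepare_input(img, target = target)
  prm <- prepare_input(msk$pixels, target = target)
  list(x = pr$input, y = (prm$input > 0.5) * 1, scale = pr$scale,
       scan_id = row$scan_id, eye = row$eye,
       axial_spacing_um = img$axial_spacing_um)
}

# dataset can be a manifest data frame or a list of prepared samples (x, y)
as_samples <- function(dataset, tc, target) {
  if (is.data.frame(dataset)) {
    dir <- attr(dataset, "dir") %||% "."
    lapply(seq_len(nrow(dataset)), function(i) {
      load_sample(dataset[i, ], dir, tc, target)
    })
  } else if (is.list(dataset)) {
    dataset
  } else {
    stop("dataset must be a manifest data frame or a list of samples")
  }
}

#' Train the U-Net
#'
#' Minimizes binary cross-entropy with Adam. The scan-level train/validation
#' split, the epoch shuffles, and every numerical kernel are deterministic
#' given `tc$seed`, so identical inputs reproduce identical losses and
#' weights.
#'
#' @param model A [unet_model][build_unet()].
#' @param dataset A manifest from [make_dataset()] / [load_manifest()], or a
#'   list of prepared samples (`x`, `y` square matrices).
#' @param tc A [train_config()].
#' @return A list with `model` (trained) and `history` (data frame of epoch,
#'   train_loss, val_loss).
#' @export
train_model <- function(model, dataset, tc = train_config()) {
  stopifnot(inherits(model, "unet_model"), inherits(tc, "train_config"))
  target <- model$config$input_size
  samples <- as_samples(dataset, tc, target)
  n <- length(samples)
  if (n < 2L) stop("dataset must contain at least 2 image/mask pairs")

  filters <- model$config$encoder_filters
  params <- model$params

  split <- withr::with_seed(tc$seed, {
    idx <- sample.int(n)
    n_train <- max(1L, round(tc$train_fraction * n))
    list(train = idx[seq_len(n_train)], val = idx[-seq_len(n_train)])
  })

  m_state <- lapply(params, function(p) list(W = p$W * 0, b = p$b * 0))
  v_state <- lapply(params, function(p) list(W = p$W * 0, b = p$b * 0))
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  t_step <- 0L

  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())
  epoch_orders <- withr::with_seed(tc$seed + 1L, {
    lapply(seq_len(tc$epochs), function(e) sample(split$train))
  })

  for (epoch in seq_len(tc$epochs)) {
    order <- epoch_orders[[epoch]]
    batches <- split(order, ceiling(seq_along(order) / tc$batch_size))
    epoch_losses <- numeric(0)
    for (batch in batches) {
      acc <- NULL
      bl <- 0
      for (i in batch) {
        g <- unet_grad_cpp(samples[[i]]$x, samples[[i]]$y, filters, params)
        bl <- bl + g$loss
        if (is.null(acc)) {
          acc <- g$grads
        } else {
          for (k in seq_along(acc)) {
            acc[[k]]$W <- acc[[k]]$W + g$grads[[k]]$W
            acc[[k]]$b <- acc[[k]]$b + g$grads[[k]]$b
          }
        }
      }
      nb <- length(batch)
      t_step <- t_step + 1L
      bc1 <- 1 - beta1^t_step
      bc2 <- 1 - beta2^t_step
      for (k in seq_along(params)) {
        gW <- acc[[k]]$W / nb
        gb <- acc[[k]]$b / nb
        m_state[[k]]$W <- beta1 * m_state[[k]]$W + (1 - beta1) * gW
        m_state[[k]]$b <- beta1 * m_state[[k]]$b + (1 - beta1) * gb
        v_state[[k]]$W <- beta2 * v_state[[k]]$W + (1 - beta2) * gW^2
        v_state[[k]]$b <- beta2 * v_state[[k]]$b + (1 - beta2) * gb^2
        params[[k]]$W <- params[[k]]$W - tc$learning_rate *
          (m_state[[k]]$W / bc1) / (sqrt(v_state[[k]]$W / bc2) + eps)
        params[[k]]$b <- params[[k]]$b - tc$learning_rate *
          (m_state[[k]]$b / bc1) / (sqrt(v_state[[k]]$b / bc2) + eps)
      }
      epoch_losses <- c(epoch_losses, bl / nb)
    }
    val_loss <- if (length(split$val) > 0) {
      mean(vapply(split$val, function(i) {
        unet_loss_cpp(samples[[i]]$x, samples[[i]]$y, filters, params)
      }, numeric(1)))
    } else NA_real_
    if (!all(is.finite(epoch_losses))) {
      stop("non-finite training loss at epoch ", epoch)
    }
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = mean(epoch_losses),
                                         val_loss = val_loss))
  }

  model$params <- params
  model$trained <- TRUE
  model$split <- split
  list(model = model, history = history)
}

#' Predict a binary RNFL mask
#'
#' Runs the forward pass on a prepared network input, thresholds the
#' probability map, and maps the binary result back to the original image
#' dimensions through the recorded [scale_info()].
#'
#' @param model A [unet_model][build_unet()].
#' @param input Prepared square network input (matrix from
#'   [prepare_input()]), or a [bscan_image()] already on the network grid.
#' @param scale The [scale_info()] from [prepare_input()].
#' @param threshold Probability cut for foreground.
#' @param axial_spacing_um,eye Calibration attached to the returned mask.
#' @return An [rnfl_mask()] of the original dimensions (strictly binary).
#' @export
predict_mask <- function(model, input, scale, threshold = 0.5,
                         axial_spacing_um = 3.87, eye = "OD") {
  if (inherits(input, "bscan_image")) {
    axial_spacing_um <- input$axial_spacing_um
    eye <- input$eye
    input <- input$pixels
  }
  input <- as.matrix(input)
  stopifnot(inherits(scale, "scale_info"))
  if (nrow(input) != scale$target || ncol(input) != scale$target) {
    stop("predict_mask: input dims inconsistent with scale_info target")
  }
  fw <- unet_forward(model, input)
  bin <- (fw$prob >= threshold) * 1L
  rnfl_mask(restore_mask(bin, scale), axial_spacing_um = axial_spacing_um,
            eye = eye)
}

#' Save / load a model checkpoint
#'
#' The checkpoint is an RDS file holding the weights; a JSON sidecar
#' (`<path>.json`) records the architecture and provenance for inspection.
#'
#' @param model A [unet_model][build_unet()].
#' @param path Checkpoint file path.
#' @return `save_model` returns the path invisibly; `load_model` the model.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  sidecar <- list(encoder_filters = model$config$encoder_filters,
                  input_size = model$config$input_size,
                  trained = model$trained,
                  n_params = unet_n_params(model))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "unet_model"))
  model
}
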