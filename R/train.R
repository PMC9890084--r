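#' Training configuration for the saturation-correction network
#'
#' The defaults are the full training recipe: 20 000 optimizer iterations
#' (one freshly augmented batch of 10 pairs each), Adam with learning rate
#' 0.001, mean-squared-error loss on the normalized curves, Gaussian
#' augmentation noise of SD 0.02 on the input and 0.03 on the target, and a
#' shared random start-time offset of 0-3 frames. `scaled = TRUE` selects
#' the compact recipe (2 000 iterations) used throughout this package's
#' tests and examples.
#'
#' @param iterations Number of optimizer steps.
#' @param batch_size Pairs per step (drawn with replacement).
#' @param learning_rate Adam learning rate.
#' @param noise_sd_in,noise_sd_out Augmentation noise SDs (normalized
#'   signal units) for the saturated input and unsaturated target.
#' @param time_offsets Integer set of start-time offsets (frames).
#' @param val_interval Iterations between validation evaluations.
#' @param seed Integer seed covering initialization, batching, and
#'   augmentation.
#' @param scaled If `TRUE`, use the compact 2 000-iteration recipe.
#' @return An object of class `train_config`.
#' @export
train_config <- function(iterations = 20000L, batch_size = 10L,
                         learning_rate = 0.001,
                         noise_sd_in = 0.02, noise_sd_out = 0.03,
                         time_offsets = 0:3, val_interval = 100L,
                         seed = 1L, scaled = FALSE) {
  if (scaled) iterations <- 2000L
  stopifnot(
    "counts must be positive" =
      iterations >= 1 && batch_size >= 1 && val_interval >= 1,
    "noise SDs must be >= 0" = noise_sd_in >= 0 && noise_sd_out >= 0,
    "`learning_rate` must be positive" = learning_rate > 0
  )
  structure(
    list(
      iterations = as.integer(iterations),
      batch_size = as.integer(batch_size),
      learning_rate = learning_rate,
      noise_sd_in = noise_sd_in, noise_sd_out = noise_sd_out,
      time_offsets = as.integer(time_offsets),
      val_interval = as.integer(val_interval),
      seed = as.integer(seed)
    ),
    class = "train_config"
  )
}

#' Augment a normalized AIF pair
#'
#' Applies the two augmentations used during training: a single random
#' start-time offset (the pair is cropped to start `offset` frames later
#' and re-fixed to its length, simulating a different contrast arrival
#' time, identically for input and target) and independent Gaussian noise
#' (`noise_sd_in` on the saturated input, `noise_sd_out` on the
#' unsaturated target, in normalized units).
#'
#' @param pair An `aif_pair`.
#' @param noise_sd_in,noise_sd_out Noise standard deviations.
#' @param time_offsets Integer offsets to sample from (uniformly).
#' @param offset Optional fixed offset, bypassing the random draw.
#' @return The augmented `aif_pair`.
#' @export
augment_pair <- function(pair, noise_sd_in = 0.02, noise_sd_out = 0.03,
                         time_offsets = 0:3, offset = NULL) {
  stopifnot(inherits(pair, "aif_pair"))
  n <- length(pair$sat)
  o <- if (is.null(offset)) {
    time_offsets[sample.int(length(time_offsets), 1L)]
  } else {
    as.integer(offset)
  }
  sat <- fix_length(pair$sat[seq(1L + o, n)], n)
  unsat <- fix_length(pair$unsat[seq(1L + o, n)], n)
  if (noise_sd_in > 0) sat <- sat + stats::rnorm(n, 0, noise_sd_in)
  if (noise_sd_out > 0) unsat <- unsat + stats::rnorm(n, 0, noise_sd_out)
  structure(
    list(
      sat = sat, unsat = unsat, scale = pair$scale, dt = pair$dt,
      arrival_index = pair$arrival_index
    ),
    class = "aif_pair"
  )
}

pairs_to_matrix <- function(pairs, field) {
  vapply(pairs, function(p) p[[field]], numeric(length(pairs[[1]]$sat)))
}

#' Train the AIF saturation-correction network
#'
#' Minimizes the mean squared error between predicted and reference
#' unsaturated AIFs over freshly augmented batches, evaluating validation
#' MSE every `val_interval` iterations and returning the checkpoint with
#' the lowest validation MSE. Fully deterministic for a fixed
#' `train_config$seed`.
#'
#' @param train_pairs,val_pairs Lists of `aif_pair` objects (normalized,
#'   length matching `unet_config$input_length`).
#' @param config A [unet_config()].
#' @param train_cfg A [train_config()].
#' @param augment Set `FALSE` to disable augmentation (noise and offsets).
#' @param verbose Print validation progress.
#' @return An object of class `aif_model`: the best-validation network,
#'   both configurations, `validation_loss`, and a `history` tibble with
#'   one row per validation evaluation (`iteration`, `train_mse`,
#'   `val_mse`).
#' @export
train_unet <- function(train_pairs, val_pairs, config = unet_config(),
                       train_cfg = train_config(scaled = TRUE),
                       augment = TRUE, verbose = FALSE) {
  if (length(train_pairs) < 1 || length(val_pairs) < 1) {
    stop("training and validation sets must be non-empty", call. = FALSE)
  }
  stopifnot(inherits(config, "unet_config"), inherits(train_cfg, "train_config"))
  L <- config$input_length
  if (length(train_pairs[[1]]$sat) != L) {
    stop("pair length does not match `config$input_length`", call. = FALSE)
  }
  local_seed(train_cfg$seed)
  net <- build_unet(config, seed = stats::runif(1, 1, 2^30))
  opt <- adam_init(net$params, train_cfg$learning_rate)
  val_X <- pairs_to_matrix(val_pairs, "sat")
  val_Y <- pairs_to_matrix(val_pairs, "unsat")
  n_train <- length(train_pairs)

  best <- list(loss = Inf, params = NULL, bn_state = NULL)
  hist_it <- integer(0)
  hist_train <- numeric(0)
  hist_val <- numeric(0)

  for (it in seq_len(train_cfg$iterations)) {
    ids <- sample.int(n_train, train_cfg$batch_size, replace = TRUE)
    batch <- lapply(train_pairs[ids], function(p) {
      if (augment) {
        augment_pair(p, train_cfg$noise_sd_in, train_cfg$noise_sd_out,
          time_offsets = train_cfg$time_offsets
        )
      } else {
        p
      }
    })
    X <- matrix(as.vector(pairs_to_matrix(batch, "sat")), ncol = 1)
    Yt <- as.vector(pairs_to_matrix(batch, "unsat"))
    fw <- unet_forward(net, X, B = train_cfg$batch_size, training = TRUE)
    net <- fw$model
    resid <- as.vector(fw$out) - Yt
    loss <- mean(resid^2)
    if (!is.finite(loss)) {
      stop("training diverged (non-finite loss)", call. = FALSE)
    }
    grads <- unet_backward(net, fw$tape, matrix(
      2 * resid / length(resid),
      ncol = 1
    ))
    upd <- adam_step(opt, net$params, grads)
    opt <- upd$opt
    net$params <- upd$params

    if (it %% train_cfg$val_interval == 0 || it == train_cfg$iterations) {
      pred <- unet_apply(net, val_X, training = FALSE)
      val_mse <- mean((pred - val_Y)^2)
      hist_it <- c(hist_it, it)
      hist_train <- c(hist_train, loss)
      hist_val <- c(hist_val, val_mse)
      if (val_mse < best$loss) {
        best <- list(loss = val_mse, params = net$params, bn_state = net$bn_state)
      }
      if (verbose) {
        message(sprintf(
          "iter %6d  train MSE %.5f  val MSE %.5f", it, loss, val_mse
        ))
      }
    }
  }
  if (!is.null(best$params)) {
    net$params <- best$params
    net$bn_state <- best$bn_state
  }
  structure(
    list(
      net = net, unet_config = config, train_config = train_cfg,
      validation_loss = best$loss,
      history = tibble::tibble(
        iteration = hist_it, train_mse = hist_train, val_mse = hist_val
      )
    ),
    class = "aif_model"
  )
}

#' @export
print.aif_model <- function(x, ...) {
  cat(sprintf(
    "<aif_model> 1D U-Net, depth %d, %d parameters; best val MSE %.3g\n",
    x$unet_config$depth, n_params(x$net), x$validation_loss
  ))
  invisible(x)
}

#' Predict the unsaturated AIF from a saturated signal curve
#'
#' Applies the preprocessing chain (arrival detection, four-beat
#' pre-contrast crop, length fixing, normalization by the saturated
#' maximum), runs the network in inference mode (dropout off,
#' normalization layers in evaluation state), and unnormalizes by the
#' stored scale so the prediction is returned in the input's signal units
#' on the input's time grid. Pre-contrast samples (before the detected
#' arrival) carry no saturation, so they are passed through from the
#' measured input unchanged -- only frames from contrast arrival onward
#' take the network's correction. This pins the predicted curve to the
#' measured baseline, to which the downstream relative-enhancement
#' conversion is highly sensitive. Samples beyond the 64-frame analysis
#' window take the last predicted value.
#'
#' @param model An `aif_model` from [train_unet()].
#' @param sat_curve A saturated `signal_curve` from a standard acquisition.
#' @param n_pre,k_sigma Preprocessing parameters (see [prep_aif_pair()]).
#' @return A `signal_curve` of the predicted unsaturated AIF.
#' @export
predict_aif <- function(model, sat_curve, n_pre = 4L, k_sigma = 5) {
  stopifnot(inherits(model, "aif_model"))
  if (all(sat_curve$value == 0)) {
    stop("input curve is identically zero", call. = FALSE)
  }
  L <- model$unet_config$input_length
  arr <- detect_arrival(sat_curve, n_base = n_pre, k_sigma = k_sigma)
  cropped <- crop_pre_contrast(sat_curve, arr, n_pre)
  vals <- fix_length(cropped$value, L)
  scale <- max(vals)
  pred_norm <- as.vector(unet_apply(model$net, vals / scale, training = FALSE))
  pred <- pred_norm * scale

  n_in <- nrow(sat_curve)
  start <- max(1L, arr - n_pre)
  out <- numeric(n_in)
  win <- seq(start, min(n_in, start + L - 1L))
  out[win] <- pred[seq_along(win)]
  if (start + L <= n_in) out[seq(start + L, n_in)] <- pred[[L]]
  # pre-contrast frames are unsaturated: keep the measured signal there
  out[seq_len(arr - 1L)] <- sat_curve$value[seq_len(arr - 1L)]
  signal_curve(sat_curve$time_s, pmax(out, 0),
    ts = attr(sat_curve, "ts"), baseline_n = attr(sat_curve, "baseline_n")
  )
}

#' Save or load a trained model checkpoint
#'
#' The checkpoint is self-describing: weights, batch-norm statistics, both
#' configurations and the validation loss. Loading restores predictions
#' bit-for-bit.
#'
#' @param model An `aif_model`. @param path Checkpoint file path.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "aif_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "aif_model"))
  model
}

# ---- Adam optimizer --------------------------------------------------------

adam_init <- function(params, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  list(
    lr = lr, beta1 = beta1, beta2 = beta2, eps = eps, t = 0L,
    m = lapply(params, function(p) p * 0),
    v = lapply(params, function(p) p * 0)
  )
}

adam_step <- function(opt, params, grads) {
  opt$t <- opt$t + 1L
  c1 <- 1 - opt$beta1^opt$t
  c2 <- 1 - opt$beta2^opt$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    opt$m[[nm]] <- opt$beta1 * opt$m[[nm]] + (1 - opt$beta1) * g
    opt$v[[nm]] <- opt$beta2 * opt$v[[nm]] + (1 - opt$beta2) * g * g
    params[[nm]] <- params[[nm]] -
      opt$lr * (opt$m[[nm]] / c1) / (sqrt(opt$v[[nm]] / c2) + opt$eps)
  }
  list(opt = opt, params = params)
}
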