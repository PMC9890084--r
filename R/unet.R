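# 1D U-Net for AIF saturation correction.
#
# The network is implemented directly on matrices: an activation tensor of
# shape (batch B, length L, channels C) is stored as an (L*B) x C matrix
# with rows ordered position-within-subject, so convolutions become an
# im2col gather followed by one BLAS matrix multiply. The forward pass
# records an op tape; the backward pass walks the tape in reverse. This
# keeps the whole model in plain R while the heavy lifting stays in BLAS.

#' U-Net architecture configuration
#'
#' A 1D U-Net with `depth` resolution steps. Each step applies two
#' convolutional blocks (convolution, batch normalization, ReLU, dropout);
#' the encoder halves the signal length per step with max-pooling and
#' doubles the channel count from `base_channels`, and the decoder restores
#' length with stride-2 transposed convolutions and skip connections.
#'
#' @param depth Number of resolution steps.
#' @param base_channels Channels of the first resolution step (doubled per
#'   step).
#' @param kernel_size Convolution kernel size (odd).
#' @param dropout_p Dropout probability in `[0, 1)`.
#' @param input_length Input curve length; must be divisible by
#'   `2^(depth - 1)`.
#' @param residual If `TRUE` (default) the network output is the input
#'   plus a learned correction (a global skip connection). Since the
#'   saturated and unsaturated AIFs agree at baseline and diverge mainly
#'   around the bolus peak, learning the correction rather than the full
#'   curve makes short training runs track individual peak heights
#'   instead of regressing towards the cohort-average curve.
#' @return An object of class `unet_config`.
#' @export
unet_config <- function(depth = 5L, base_channels = 32L, kernel_size = 3L,
                        dropout_p = 0.2, input_length = 64L,
                        residual = TRUE) {
  if (kernel_size %% 2 != 1) stop("`kernel_size` must be odd", call. = FALSE)
  if (dropout_p < 0 || dropout_p >= 1) {
    stop("`dropout_p` must be in [0, 1)", call. = FALSE)
  }
  if (input_length %% 2^(depth - 1) != 0) {
    stop("`input_length` must be divisible by 2^(depth - 1)", call. = FALSE)
  }
  structure(
    list(
      depth = as.integer(depth), base_channels = as.integer(base_channels),
      kernel_size = as.integer(kernel_size), dropout_p = dropout_p,
      input_length = as.integer(input_length),
      residual = isTRUE(residual)
    ),
    class = "unet_config"
  )
}

# ---- tensor helpers (rows = position l within subject b, row (b-1)*L + l) --

# column-wise scale/shift without sweep()'s aperm overhead
cs <- function(X, v) X * rep(v, rep.int(nrow(X), length(v)))
ca <- function(X, v) X + rep(v, rep.int(nrow(X), length(v)))

shift_rows <- function(X, L, B, o) {
  if (o == 0) {
    return(X)
  }
  out <- matrix(0, nrow(X), ncol(X))
  l <- seq_len(L)
  src <- l + o
  valid <- src >= 1 & src <= L
  base <- rep((seq_len(B) - 1L) * L, each = sum(valid))
  out[rep(l[valid], B) + base, ] <- X[rep(src[valid], B) + base, ]
  out
}

im2col <- function(X, L, B, k) {
  half <- (k - 1L) %/% 2L
  do.call(cbind, lapply(seq(-half, half), function(o) shift_rows(X, L, B, o)))
}

col2im_grad <- function(dXcol, L, B, k, cin) {
  half <- (k - 1L) %/% 2L
  dX <- matrix(0, nrow(dXcol), cin)
  for (j in seq_len(k)) {
    o <- j - half - 1L
    block <- dXcol[, (j - 1L) * cin + seq_len(cin), drop = FALSE]
    dX <- dX + shift_rows(block, L, B, -o)
  }
  dX
}

pool_indices <- function(L, B) {
  odd <- as.vector(outer(seq(1L, L, 2L), (seq_len(B) - 1L) * L, "+"))
  even <- odd + 1L
  list(odd = odd, even = even)
}

# ---- parameter construction ------------------------------------------------

unet_channels <- function(config) {
  config$base_channels * 2^(seq_len(config$depth) - 1L)
}

he_mat <- function(nr, nc, fan_in) {
  matrix(stats::rnorm(nr * nc, sd = sqrt(2 / fan_in)), nr, nc)
}

#' Build a 1D U-Net with He-normal initial weights
#'
#' @param config A [unet_config()].
#' @param seed Integer seed for the weight initialization (two builds with
#'   the same seed have identical parameters).
#' @return An object of class `unet1d` holding parameters and batch-norm
#'   running statistics.
#' @export
build_unet <- function(config = unet_config(), seed = 1L) {
  stopifnot(inherits(config, "unet_config"))
  local_seed(seed)
  k <- config$kernel_size
  ch <- unet_channels(config)
  depth <- config$depth
  params <- list()
  bn_state <- list()

  add_conv <- function(name, cin, cout) {
    params[[paste0(name, "_W")]] <<- he_mat(k * cin, cout, fan_in = k * cin)
  }
  add_bn <- function(name, c) {
    params[[paste0(name, "_gamma")]] <<- rep(1, c)
    params[[paste0(name, "_beta")]] <<- rep(0, c)
    bn_state[[name]] <<- list(mean = rep(0, c), var = rep(1, c))
  }
  for (d in seq_len(depth)) {
    cin <- if (d == 1) 1L else ch[d - 1]
    add_conv(sprintf("enc%d_conv1", d), cin, ch[d])
    add_bn(sprintf("enc%d_bn1", d), ch[d])
    add_conv(sprintf("enc%d_conv2", d), ch[d], ch[d])
    add_bn(sprintf("enc%d_bn2", d), ch[d])
  }
  for (d in rev(seq_len(depth - 1L))) {
    params[[sprintf("dec%d_up_W", d)]] <-
      he_mat(ch[d + 1], 2L * ch[d], fan_in = ch[d + 1])
    params[[sprintf("dec%d_up_b", d)]] <- rep(0, 2L * ch[d])
    add_conv(sprintf("dec%d_conv1", d), 2L * ch[d], ch[d])
    add_bn(sprintf("dec%d_bn1", d), ch[d])
    add_conv(sprintf("dec%d_conv2", d), ch[d], ch[d])
    add_bn(sprintf("dec%d_bn2", d), ch[d])
  }
  params[["final_W"]] <- he_mat(ch[1], 1L, fan_in = ch[1])
  params[["final_b"]] <- 0
  structure(
    list(config = config, params = params, bn_state = bn_state),
    class = "unet1d"
  )
}

#' Number of trainable parameters of a network
#' @param model A `unet1d`.
#' @return Integer count of trainable parameters.
#' @export
n_params <- function(model) sum(vapply(model$params, length, integer(1)))

# ---- forward / backward ----------------------------------------------------

bn_eps <- 1e-5
bn_momentum <- 0.1

unet_forward <- function(model, X, B, training = FALSE) {
  cfg <- model$config
  params <- model$params
  k <- cfg$kernel_size
  keep <- 1 - cfg$dropout_p
  L <- cfg$input_length
  X0 <- X
  tape <- list()
  push <- function(op) tape[[length(tape) + 1L]] <<- op

  conv_block <- function(X, name_conv, name_bn, L, B) {
    Xcol <- im2col(X, L, B, k)
    W <- params[[paste0(name_conv, "_W")]]
    Y <- Xcol %*% W
    push(list(
      type = "conv", name = name_conv, Xcol = Xcol, L = L, B = B,
      cin = ncol(Xcol) / k
    ))
    # batch norm
    g <- params[[paste0(name_bn, "_gamma")]]
    be <- params[[paste0(name_bn, "_beta")]]
    if (training) {
      mu <- colMeans(Y)
      Yc <- ca(Y, -mu)
      v <- colMeans(Yc * Yc)
      inv <- 1 / sqrt(v + bn_eps)
      xhat <- cs(Yc, inv)
      st <- model$bn_state[[name_bn]]
      st$mean <- (1 - bn_momentum) * st$mean + bn_momentum * mu
      nb <- nrow(Y)
      st$var <- (1 - bn_momentum) * st$var +
        bn_momentum * v * nb / max(nb - 1, 1)
      model$bn_state[[name_bn]] <<- st
    } else {
      st <- model$bn_state[[name_bn]]
      inv <- 1 / sqrt(st$var + bn_eps)
      xhat <- cs(ca(Y, -st$mean), inv)
    }
    Y <- ca(cs(xhat, g), be)
    push(list(type = "bn", name = name_bn, xhat = xhat, inv = inv, gamma = g))
    # relu
    mask <- Y > 0
    Y <- Y * mask
    push(list(type = "relu", mask = mask))
    # dropout
    if (training && cfg$dropout_p > 0) {
      dmask <- matrix(
        (stats::runif(length(Y)) < keep) / keep, nrow(Y), ncol(Y)
      )
      Y <- Y * dmask
      push(list(type = "dropout", mask = dmask))
    }
    Y
  }

  skips <- list()
  for (d in seq_len(cfg$depth)) {
    X <- conv_block(X, sprintf("enc%d_conv1", d), sprintf("enc%d_bn1", d), L, B)
    X <- conv_block(X, sprintf("enc%d_conv2", d), sprintf("enc%d_bn2", d), L, B)
    if (d < cfg$depth) {
      skips[[d]] <- X
      push(list(type = "skip_src", d = d))
      idx <- pool_indices(L, B)
      A <- X[idx$odd, , drop = FALSE]
      Bm <- X[idx$even, , drop = FALSE]
      takeA <- A >= Bm
      Y <- Bm
      Y[takeA] <- A[takeA]
      push(list(
        type = "pool", takeA = takeA, odd = idx$odd, even = idx$even,
        L_in = L, nrow_in = nrow(X)
      ))
      X <- Y
      L <- L %/% 2L
    }
  }
  for (d in rev(seq_len(cfg$depth - 1L))) {
    W <- params[[sprintf("dec%d_up_W", d)]]
    b <- params[[sprintf("dec%d_up_b", d)]]
    cout <- ncol(W) %/% 2L
    Y0 <- ca(X %*% W, b)
    L2 <- 2L * L
    idx <- pool_indices(L2, B)
    Y <- matrix(0, L2 * B, cout)
    Y[idx$odd, ] <- Y0[, seq_len(cout)]
    Y[idx$even, ] <- Y0[, cout + seq_len(cout)]
    push(list(type = "up", d = d, Xin = X, odd = idx$odd, even = idx$even))
    L <- L2
    X <- cbind(Y, skips[[d]])
    push(list(type = "concat", d = d, n_main = cout))
    X <- conv_block(X, sprintf("dec%d_conv1", d), sprintf("dec%d_bn1", d), L, B)
    X <- conv_block(X, sprintf("dec%d_conv2", d), sprintf("dec%d_bn2", d), L, B)
  }
  out <- X %*% params[["final_W"]] + params[["final_b"]]
  if (isTRUE(cfg$residual)) out <- out + X0
  push(list(type = "final", Xin = X))
  list(out = out, tape = tape, model = model)
}

unet_backward <- function(model, tape, dOut) {
  params <- model$params
  k <- model$config$kernel_size
  grads <- list()
  skip_grads <- list()
  dX <- dOut
  for (i in rev(seq_along(tape))) {
    op <- tape[[i]]
    switch(op$type,
      final = {
        grads[["final_W"]] <- crossprod(op$Xin, dX)
        grads[["final_b"]] <- sum(dX)
        dX <- tcrossprod(dX, params[["final_W"]])
      },
      conv = {
        W <- params[[paste0(op$name, "_W")]]
        grads[[paste0(op$name, "_W")]] <- crossprod(op$Xcol, dX)
        dXcol <- tcrossprod(dX, W)
        dX <- col2im_grad(dXcol, op$L, op$B, k, op$cin)
      },
      bn = {
        grads[[paste0(op$name, "_gamma")]] <- colSums(dX * op$xhat)
        grads[[paste0(op$name, "_beta")]] <- colSums(dX)
        dxhat <- cs(dX, op$gamma)
        m1 <- colMeans(dxhat)
        m2 <- colMeans(dxhat * op$xhat)
        dX <- cs(ca(dxhat - cs(op$xhat, m2), -m1), op$inv)
      },
      relu = {
        dX <- dX * op$mask
      },
      dropout = {
        dX <- dX * op$mask
      },
      pool = {
        dIn <- matrix(0, op$nrow_in, ncol(dX))
        dIn[op$odd, ] <- dX * op$takeA
        dIn[op$even, ] <- dX * (!op$takeA)
        dX <- dIn
      },
      skip_src = {
        dX <- dX + skip_grads[[op$d]]
      },
      concat = {
        nm <- op$n_main
        skip_grads[[op$d]] <- dX[, -(seq_len(nm)), drop = FALSE]
        dX <- dX[, seq_len(nm), drop = FALSE]
      },
      up = {
        nameW <- sprintf("dec%d_up_W", op$d)
        dY0 <- cbind(
          dX[op$odd, , drop = FALSE],
          dX[op$even, , drop = FALSE]
        )
        grads[[nameW]] <- crossprod(op$Xin, dY0)
        grads[[sprintf("dec%d_up_b", op$d)]] <- colSums(dY0)
        dX <- tcrossprod(dY0, params[[nameW]])
      }
    )
  }
  grads
}

#' Run a network on a batch of normalized curves
#'
#' @param model A `unet1d`.
#' @param inputs Numeric matrix, one column per curve of length
#'   `input_length` (or a single vector).
#' @param training Logical; `TRUE` uses batch statistics and dropout,
#'   `FALSE` (inference) uses running statistics and no dropout.
#' @return Matrix of predicted curves, same shape as `inputs`.
#' @export
unet_apply <- function(model, inputs, training = FALSE) {
  stopifnot(inherits(model, "unet1d"))
  if (is.vector(inputs)) inputs <- matrix(inputs, ncol = 1)
  L <- model$config$input_length
  if (nrow(inputs) != L) {
    stop(sprintf("inputs must have %d rows (curve length)", L), call. = FALSE)
  }
  B <- ncol(inputs)
  X <- matrix(as.vector(inputs), ncol = 1)
  fw <- unet_forward(model, X, B, training = training)
  matrix(fw$out, nrow = L, ncol = B)
}
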