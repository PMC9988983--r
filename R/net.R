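#' Model configuration
#'
#' Configures the fully convolutional encoder/decoder/segment-classifier
#' stager. The encoder halves the temporal resolution `depth` times, so the
#' cumulative downsampling factor is `pool^depth` (4096 at the default
#' depth 12); inputs are right-padded with zeros to a multiple of that
#' factor and outputs cropped. The filter schedule is
#' `ceiling(base_filters * filter_growth^block)`.
#'
#' @param depth number of encoder (and decoder) blocks.
#' @param base_filters,filter_growth filter schedule parameters.
#' @param kernel_size convolution taps (odd; stride-1, zero-padded "same").
#' @param pool max-pool stride per encoder block.
#' @param fs sampling rate the model expects, in Hz.
#' @param K number of classes (5 sleep stages).
#' @param in_channels input channels (one EEG + one EOG derivation).
#' @param norm_mode `"vanilla"`, `"ccbn"` (categorical conditional) or
#'   `"sabn"` (sandwich) batch normalization.
#' @param G number of condition groups for ccbn/sabn.
#' @export
model_config <- function(depth = 12, base_filters = 5,
                         filter_growth = sqrt(2), kernel_size = 9,
                         pool = 2L, fs = 128, K = 5, in_channels = 2L,
                         norm_mode = c("vanilla", "ccbn", "sabn"), G = 1L) {
  norm_mode <- match.arg(norm_mode)
  stopifnot(depth >= 1, base_filters >= 1, filter_growth > 0,
            kernel_size >= 1, kernel_size %% 2 == 1, pool == 2L,
            fs > 0, K >= 2, G >= 1)
  if (norm_mode == "vanilla") G <- 1L
  filters <- as.integer(ceiling(base_filters * filter_growth^(seq_len(depth + 1))))
  structure(list(depth = as.integer(depth), base_filters = base_filters,
                 filter_growth = filter_growth,
                 kernel_size = as.integer(kernel_size), pool = 2L,
                 fs = fs, K = as.integer(K),
                 in_channels = as.integer(in_channels),
                 epoch_samples = as.integer(30 * fs),
                 filters = filters, seg_filters = filters[1],
                 norm_mode = norm_mode, G = as.integer(G)),
            class = "model_config")
}

new_conv <- function(k, cin, cout, zero = FALSE) {
  sdv <- sqrt(2 / (k * cin))
  W <- if (zero) matrix(0, k * cin, cout)
       else matrix(rnorm(k * cin * cout, 0, sdv), k * cin, cout)
  list(W = W, b = numeric(cout))
}

new_norm <- function(C, G) {
  list(gamma = rep(1, C), beta = rep(0, C),
       gamma_g = matrix(1, G, C), beta_g = matrix(0, G, C),
       gamma_sa = rep(1, C), beta_sa = rep(0, C),
       run_mean = rep(0, C), run_var = rep(0, C), run_count = 0)
}

#' Build a stager model
#'
#' Encoder blocks are conv -> ELU -> BN -> max-pool (the BN output feeds the
#' skip connection); a bottleneck block follows; decoder blocks are
#' nearest-neighbor upsample -> conv -> ELU -> BN -> skip concatenation ->
#' conv -> ELU -> BN; the segment classifier is a dense segmentation conv
#' with tanh, an average-pool with kernel = stride = 30 s * fs, and two
#' 1-tap convolutions (ELU, then softmax). The output conv is zero-
#' initialized, so an untrained model predicts the uniform distribution.
#'
#' @param config a [model_config()].
#' @param seed integer seed for parameter initialization.
#' @return object of class `psg_model`.
#' @export
build_model <- function(config = model_config(), seed = 1L) {
  stopifnot(inherits(config, "model_config"))
  k <- config$kernel_size
  f <- config$filters
  d <- config$depth
  G <- config$G
  with_seed(seed, {
    enc <- lapply(seq_len(d), function(b) {
      cin <- if (b == 1) config$in_channels else f[b - 1]
      list(conv = new_conv(k, cin, f[b]), norm = new_norm(f[b], G))
    })
    bot <- list(conv = new_conv(k, f[d], f[d + 1]),
                norm = new_norm(f[d + 1], G))
    dec <- lapply(seq_len(d), function(b) {
      cin <- if (b == d) f[d + 1] else f[b + 1]
      list(conv1 = new_conv(k, cin, f[b]), norm1 = new_norm(f[b], G),
           conv2 = new_conv(k, 2 * f[b], f[b]), norm2 = new_norm(f[b], G))
    })
    fs_ <- config$seg_filters
    seg <- list(conv_t = new_conv(1, f[1], fs_),
                conv_h = new_conv(1, fs_, fs_),
                norm_h = new_norm(fs_, G),
                conv_o = new_conv(1, fs_, config$K, zero = TRUE))
    structure(list(config = config,
                   params = list(enc = enc, bot = bot, dec = dec, seg = seg),
                   iteration = 0L),
              class = "psg_model")
  })
}

#' @export
print.psg_model <- function(x, ...) {
  cfg <- x$config
  cat("<psg_model> depth ", cfg$depth, ", downsampling x", cfg$pool^cfg$depth,
      ", norm ", cfg$norm_mode,
      if (cfg$norm_mode != "vanilla") paste0(" (G=", cfg$G, ")"),
      ", ", count_params(x), " trainable parameters\n", sep = "")
  invisible(x)
}

#' Cumulative encoder downsampling factor
#' @param model a `psg_model` or [model_config()].
#' @export
downsampling_factor <- function(model) {
  cfg <- if (inherits(model, "psg_model")) model$config else model
  cfg$pool^cfg$depth
}

#' Count trainable parameters
#'
#' Convolution weights/biases plus the normalization affine parameters of
#' the active mode (vanilla: gamma/beta; ccbn: per-group gamma_g/beta_g;
#' sabn: the shared sandwich affine plus the per-group affines). Running
#' statistics are not trainable.
#' @param model a `psg_model`.
#' @export
count_params <- function(model) {
  mode <- model$config$norm_mode
  n <- 0L
  walk <- function(x, nm) {
    if (is.list(x) && !is.null(x$W)) n <<- n + length(x$W) + length(x$b)
    else if (is.list(x) && !is.null(x$run_mean)) {
      n <<- n + switch(mode,
        vanilla = length(x$gamma) + length(x$beta),
        ccbn = length(x$gamma_g) + length(x$beta_g),
        sabn = length(x$gamma_sa) + length(x$beta_sa) +
          length(x$gamma_g) + length(x$beta_g))
    } else if (is.list(x)) for (i in seq_along(x)) walk(x[[i]], nm)
  }
  walk(model$params, "")
  n
}

# ---- primitive layers ----------------------------------------------------

elu_fwd <- function(x) elu_fwd_cpp(x)
elu_bwd <- function(dy, y) elu_bwd_cpp(dy, y)

# per-feature-channel scale and shift on a (B, T, C) block
chan_affine <- function(X, a, b) {
  y <- scale_shift_cpp(X, a, b)
  dim(y) <- dim(X)
  y
}

maxpool_fwd <- function(X) {
  T <- dim(X)[2]
  X1 <- X[, seq(1, T, 2), , drop = FALSE]
  X2 <- X[, seq(2, T, 2), , drop = FALSE]
  M <- X1 >= X2
  list(Y = pmax(X1, X2), M = M)
}
maxpool_bwd <- function(dY, M) {
  d <- dim(dY)
  dX <- array(0, c(d[1], 2 * d[2], d[3]))
  dX[, seq(1, 2 * d[2], 2), ] <- dY * M
  dX[, seq(2, 2 * d[2], 2), ] <- dY * !M
  dX
}

upsample_fwd <- function(X) X[, rep(seq_len(dim(X)[2]), each = 2), , drop = FALSE]
upsample_bwd <- function(dY) {
  T2 <- dim(dY)[2]
  dY[, seq(1, T2, 2), , drop = FALSE] + dY[, seq(2, T2, 2), , drop = FALSE]
}

concat_c <- function(A, B) {
  da <- dim(A); db <- dim(B)
  Y <- array(0, c(da[1], da[2], da[3] + db[3]))
  Y[, , seq_len(da[3])] <- A
  Y[, , da[3] + seq_len(db[3])] <- B
  Y
}

avgpool_fwd <- function(X, i, L) {
  d <- dim(X)
  Xc <- X[, seq_len(L * i), , drop = FALSE]
  arr <- array(Xc, c(d[1], i, L, d[3]))
  colMeans(aperm(arr, c(2, 1, 3, 4)))           # (B, L, C)
}
avgpool_bwd <- function(dY, i, Tpad) {
  d <- dim(dY)                                   # (B, L, C)
  dX <- array(0, c(d[1], Tpad, d[3]))
  dX[, seq_len(d[2] * i), ] <- dY[, rep(seq_len(d[2]), each = i), , drop = FALSE] / i
  dX
}

softmax3 <- function(Z) {
  d <- dim(Z)
  M <- matrix(Z, d[1] * d[2], d[3])
  M <- exp(M - apply(M, 1, max))
  array(M / rowSums(M), d)
}

# ---- batch normalization family -----------------------------------------

BN_EPS <- 1e-5
BN_RATE <- 0.1

norm_fwd <- function(X, norm, mode, g, training) {
  d <- dim(X); B <- d[1]; T <- d[2]; C <- d[3]
  Xm <- matrix(X, B * T, C)
  if (training) {
    mu <- colMeans(Xm)
    va <- colMeans(Xm^2) - mu^2
    # bias-corrected exponential running estimates: exact after the first
    # batch, ~10-batch memory afterwards, so inference statistics stay
    # fresh during short desk-scale runs
    norm$run_mean <- (1 - BN_RATE) * norm$run_mean + BN_RATE * mu
    norm$run_var <- (1 - BN_RATE) * norm$run_var + BN_RATE * va
    norm$run_count <- (norm$run_count %||% 0) + 1
  } else {
    k <- norm$run_count %||% 0
    if (k > 0) {
      corr <- 1 - (1 - BN_RATE)^k
      mu <- norm$run_mean / corr
      va <- norm$run_var / corr
    } else {
      mu <- norm$run_mean
      va <- norm$run_var + 1           # untrained: standard normal prior
    }
  }
  sdv <- sqrt(va + BN_EPS)
  xhat <- chan_affine(X, 1 / sdv, -mu / sdv)
  if (mode == "vanilla") {
    Y <- chan_affine(xhat, norm$gamma, norm$beta)
    inner <- NULL
  } else {
    if (is.null(g)) stop("condition index g required for mode ", mode)
    if (any(g < 1 | g > nrow(norm$gamma_g)))
      stop("condition index g out of range [1, G]")
    inner <- xhat
    if (mode == "sabn")
      inner <- chan_affine(xhat, norm$gamma_sa, norm$beta_sa)
    Gm <- norm$gamma_g[g, , drop = FALSE]
    Bm <- norm$beta_g[g, , drop = FALSE]
    Y <- inner
    for (c in seq_len(C)) Y[, , c] <- inner[, , c] * Gm[, c] + Bm[, c]
  }
  list(Y = Y, norm = norm,
       cache = list(xhat = xhat, inner = inner, sdv = sdv, g = g))
}

norm_bwd <- function(dY, cache, norm, mode) {
  d <- dim(dY); B <- d[1]; T <- d[2]; C <- d[3]
  n <- B * T
  xhat <- cache$xhat
  grads <- list()
  if (mode == "vanilla") {
    dYm <- matrix(dY, n, C)
    grads$gamma <- colSums(dYm * matrix(xhat, n, C))
    grads$beta <- colSums(dYm)
    dxhat <- chan_affine(dY, norm$gamma, numeric(C))
  } else {
    g <- cache$g
    G <- nrow(norm$gamma_g)
    inner <- cache$inner
    # per-sample channel sums for the group affine gradients
    s_gy <- matrix(0, B, C); s_y <- matrix(0, B, C)
    for (c in seq_len(C)) {
      s_gy[, c] <- rowSums(dY[, , c, drop = FALSE] * inner[, , c, drop = FALSE])
      s_y[, c] <- rowSums(dY[, , c, drop = FALSE])
    }
    gf <- factor(g, levels = seq_len(G))
    grads$gamma_g <- apply(s_gy, 2, function(col) tapply(col, gf, sum, default = 0))
    grads$beta_g <- apply(s_y, 2, function(col) tapply(col, gf, sum, default = 0))
    if (G == 1) {
      grads$gamma_g <- matrix(grads$gamma_g, 1, C)
      grads$beta_g <- matrix(grads$beta_g, 1, C)
    }
    Gm <- norm$gamma_g[g, , drop = FALSE]
    dinner <- dY
    for (c in seq_len(C)) dinner[, , c] <- dY[, , c] * Gm[, c]
    if (mode == "sabn") {
      dIm <- matrix(dinner, n, C)
      grads$gamma_sa <- colSums(dIm * matrix(xhat, n, C))
      grads$beta_sa <- colSums(dIm)
      dxhat <- chan_affine(dinner, norm$gamma_sa, numeric(C))
    } else {
      dxhat <- dinner
    }
  }
  # batch-norm backward through the standardization (biased batch variance)
  dxm <- matrix(dxhat, n, C)
  xm <- matrix(xhat, n, C)
  m1 <- colMeans(dxm)
  m2 <- colMeans(dxm * xm)
  sdv <- cache$sdv
  grads$dX <- chan_affine(dxhat, 1 / sdv, -m1 / sdv) -
    chan_affine(xhat, m2 / sdv, numeric(C))
  grads
}

#' Conditional batch normalization family
#'
#' Applies vanilla batch normalization
#' `h = gamma * (f - mu) / sigma + beta`, its categorical conditional
#' variant (per-group affines `gamma_g`, `beta_g` selected by the
#' per-sample condition `g`) or sandwich normalization (a shared affine
#' cascaded by the per-group affines). In training mode the statistics are
#' the batch moments over the sample and time axes and the running
#' estimates are updated (returned in the `"params"` attribute); in
#' inference mode the running estimates are used.
#'
#' @param f feature block, array of shape batch x channels x time.
#' @param g integer condition index per sample (1-based), or `NULL` for
#'   vanilla mode.
#' @param params list with `gamma`, `beta`, `gamma_g` (G x C), `beta_g`,
#'   `gamma_sa`, `beta_sa`, `run_mean`, `run_var`; see the norm layers of
#'   [build_model()].
#' @param mode `"vanilla"`, `"ccbn"` or `"sabn"`.
#' @param training logical; use (and update) batch statistics.
#' @return the normalized block (same shape); in training mode the updated
#'   parameter list is attached as attribute `"params"`.
#' @export
conditional_normalize <- function(f, g = NULL, params,
                                  mode = c("vanilla", "ccbn", "sabn"),
                                  training = FALSE) {
  mode <- match.arg(mode)
  stopifnot(is.array(f), length(dim(f)) == 3)
  Xa <- aperm(f, c(1, 3, 2))                     # to (B, T, C)
  res <- norm_fwd(Xa, params, mode, g, training)
  out <- aperm(res$Y, c(1, 3, 2))
  if (training) attr(out, "params") <- res$norm
  out
}

# ---- full network forward / backward ------------------------------------

conv_fwd <- function(X, cv) conv1d_fwd_cpp(X, cv$W, cv$b)

net_forward <- function(model, X, g = NULL, training = FALSE) {
  cfg <- model$config
  if (is.matrix(X)) X <- array(X, c(1, nrow(X), ncol(X)))
  stopifnot(length(dim(X)) == 3)
  if (!all(is.finite(X))) stop("non-finite values in input")
  d <- dim(X); B <- d[1]; T <- d[2]
  if (d[3] != cfg$in_channels)
    stop(sprintf("expected %d input channels, got %d", cfg$in_channels, d[3]))
  i <- cfg$epoch_samples
  if (T %% i != 0) stop("input length must be a whole number of 30-s epochs")
  L <- T %/% i
  if (cfg$norm_mode != "vanilla") {
    if (is.null(g)) stop("condition index g required for norm mode ", cfg$norm_mode)
    g <- as.integer(g)
    if (length(g) == 1) g <- rep(g, B)
    if (any(g < 1 | g > cfg$G)) stop("condition index g out of [1, G]")
  } else g <- NULL
  fac <- downsampling_factor(model)
  Tp <- as.integer(ceiling(T / fac) * fac)
  if (Tp > T) {
    Xp <- array(0, c(B, Tp, d[3]))
    Xp[, seq_len(T), ] <- X
    X <- Xp
  }
  p <- model$params
  cache <- list(g = g, T = T, Tp = Tp, L = L, X = X)
  skips <- vector("list", cfg$depth)
  h <- X
  ec <- vector("list", cfg$depth)
  for (b in seq_len(cfg$depth)) {
    cin <- h
    z <- conv_fwd(cin, p$enc[[b]]$conv)
    a <- elu_fwd(z)
    nf <- norm_fwd(a, p$enc[[b]]$norm, cfg$norm_mode, g, training)
    p$enc[[b]]$norm <- nf$norm
    skips[[b]] <- nf$Y
    mp <- maxpool_fwd(nf$Y)
    ec[[b]] <- list(cin = cin, a = a, nc = nf$cache, M = mp$M)
    h <- mp$Y
  }
  z <- conv_fwd(h, p$bot$conv)
  a <- elu_fwd(z)
  nf <- norm_fwd(a, p$bot$norm, cfg$norm_mode, g, training)
  p$bot$norm <- nf$norm
  bc <- list(cin = h, a = a, nc = nf$cache)
  h <- nf$Y
  dc <- vector("list", cfg$depth)
  for (b in rev(seq_len(cfg$depth))) {
    u <- upsample_fwd(h)
    z1 <- conv_fwd(u, p$dec[[b]]$conv1)
    a1 <- elu_fwd(z1)
    n1 <- norm_fwd(a1, p$dec[[b]]$norm1, cfg$norm_mode, g, training)
    p$dec[[b]]$norm1 <- n1$norm
    cat2 <- concat_c(n1$Y, skips[[b]])
    z2 <- conv_fwd(cat2, p$dec[[b]]$conv2)
    a2 <- elu_fwd(z2)
    n2 <- norm_fwd(a2, p$dec[[b]]$norm2, cfg$norm_mode, g, training)
    p$dec[[b]]$norm2 <- n2$norm
    dc[[b]] <- list(u = u, a1 = a1, nc1 = n1$cache, cat = cat2,
                    a2 = a2, nc2 = n2$cache)
    h <- n2$Y
  }
  t1 <- conv_fwd(h, p$seg$conv_t)
  th <- tanh(t1)
  ap <- avgpool_fwd(th, i, L)
  z2 <- conv_fwd(ap, p$seg$conv_h)
  a2 <- elu_fwd(z2)
  nh <- norm_fwd(a2, p$seg$norm_h, cfg$norm_mode, g, training)
  p$seg$norm_h <- nh$norm
  logits <- conv_fwd(nh$Y, p$seg$conv_o)
  probs <- softmax3(logits)
  model$params <- p
  cache <- c(cache, list(enc = ec, bot = bc, dec = dc,
                         seg = list(dec_out = h, th = th, ap = ap,
                                    a2 = a2, nch = nh$cache, nhY = nh$Y),
                         probs = probs))
  list(probs = probs, model = model, cache = cache)
}

net_backward <- function(model, cache, dlogits) {
  cfg <- model$config
  p <- model$params
  i <- cfg$epoch_samples
  mode <- cfg$norm_mode
  grads <- list(enc = vector("list", cfg$depth), bot = NULL,
                dec = vector("list", cfg$depth), seg = NULL)
  sg <- cache$seg
  cb <- conv1d_bwd_cpp(sg$nhY, dlogits, p$seg$conv_o$W)
  g_conv_o <- list(W = cb$dW, b = cb$db)
  nb <- norm_bwd(cb$dX, sg$nch, p$seg$norm_h, mode)
  g_norm_h <- nb[setdiff(names(nb), "dX")]
  da2 <- elu_bwd(nb$dX, sg$a2)
  cb <- conv1d_bwd_cpp(sg$ap, da2, p$seg$conv_h$W)
  g_conv_h <- list(W = cb$dW, b = cb$db)
  dth <- avgpool_bwd(cb$dX, i, cache$Tp) * (1 - sg$th^2)
  cb <- conv1d_bwd_cpp(sg$dec_out, dth, p$seg$conv_t$W)
  g_conv_t <- list(W = cb$dW, b = cb$db)
  grads$seg <- list(conv_t = g_conv_t, conv_h = g_conv_h,
                    norm_h = g_norm_h, conv_o = g_conv_o)
  dh <- cb$dX
  dskips <- vector("list", cfg$depth)
  for (b in seq_len(cfg$depth)) {
    dcb <- cache$dec[[b]]
    nb2 <- norm_bwd(dh, dcb$nc2, p$dec[[b]]$norm2, mode)
    da2 <- elu_bwd(nb2$dX, dcb$a2)
    cb2 <- conv1d_bwd_cpp(dcb$cat, da2, p$dec[[b]]$conv2$W)
    Cf <- dim(dcb$cat)[3] / 2
    dn1 <- cb2$dX[, , seq_len(Cf), drop = FALSE]
    dskips[[b]] <- cb2$dX[, , Cf + seq_len(Cf), drop = FALSE]
    nb1 <- norm_bwd(dn1, dcb$nc1, p$dec[[b]]$norm1, mode)
    da1 <- elu_bwd(nb1$dX, dcb$a1)
    cb1 <- conv1d_bwd_cpp(dcb$u, da1, p$dec[[b]]$conv1$W)
    grads$dec[[b]] <- list(conv1 = list(W = cb1$dW, b = cb1$db),
                           norm1 = nb1[setdiff(names(nb1), "dX")],
                           conv2 = list(W = cb2$dW, b = cb2$db),
                           norm2 = nb2[setdiff(names(nb2), "dX")])
    dh <- upsample_bwd(cb1$dX)
  }
  nb <- norm_bwd(dh, cache$bot$nc, p$bot$norm, mode)
  da <- elu_bwd(nb$dX, cache$bot$a)
  cb <- conv1d_bwd_cpp(cache$bot$cin, da, p$bot$conv$W)
  grads$bot <- list(conv = list(W = cb$dW, b = cb$db),
                    norm = nb[setdiff(names(nb), "dX")])
  dh <- cb$dX
  for (b in rev(seq_len(cfg$depth))) {
    eb <- cache$enc[[b]]
    dn <- maxpool_bwd(dh, eb$M) + dskips[[b]]
    nb <- norm_bwd(dn, eb$nc, p$enc[[b]]$norm, mode)
    da <- elu_bwd(nb$dX, eb$a)
    cb <- conv1d_bwd_cpp(eb$cin, da, p$enc[[b]]$conv$W)
    grads$enc[[b]] <- list(conv = list(W = cb$dW, b = cb$db),
                           norm = nb[setdiff(names(nb), "dX")])
    dh <- cb$dX
  }
  grads
}

#' Predict stage probabilities for a signal block
#'
#' The length-agnostic forward pass: any whole number of 30-second epochs
#' is accepted and one probability row per epoch is returned (rows sum
#' to 1). Uses the stored running normalization statistics (inference
#' mode).
#'
#' @param model a `psg_model`.
#' @param X time-by-channel matrix (`L * 30 * fs` rows, one EEG and one EOG
#'   derivation), or a batch array (B x time x channels).
#' @param g condition index (scalar or per-sample), required for
#'   ccbn/sabn models.
#' @return an L x K probability matrix (or B x L x K array for batches).
#' @export
forward <- function(model, X, g = NULL) {
  res <- net_forward(model, X, g, training = FALSE)
  pr <- res$probs
  if (dim(pr)[1] == 1 && is.matrix(X)) {
    matrix(pr, dim(pr)[2], dim(pr)[3],
           dimnames = list(NULL, stage_levels()[seq_len(dim(pr)[3])]))
  } else pr
}

#' Convert a model's normalization mode
#'
#' Duplicates the vanilla affine parameters into every group's affine
#' (gamma_g = gamma, beta_g = beta) and initializes the sandwich affine to
#' the identity, so predictions are unchanged for every condition index
#' until further training.
#'
#' @param model a `psg_model`.
#' @param mode target mode, `"ccbn"` or `"sabn"`.
#' @param G number of condition groups.
#' @export
convert_norm_mode <- function(model, mode = c("ccbn", "sabn"), G) {
  mode <- match.arg(mode)
  stopifnot(G >= 1)
  src <- model$config$norm_mode
  conv_one <- function(norm) {
    C <- length(norm$run_mean)
    base_g <- if (src == "vanilla") norm$gamma else norm$gamma_g[1, ]
    base_b <- if (src == "vanilla") norm$beta else norm$beta_g[1, ]
    norm$gamma_g <- matrix(base_g, G, C, byrow = TRUE)
    norm$beta_g <- matrix(base_b, G, C, byrow = TRUE)
    norm$gamma_sa <- rep(1, C)
    norm$beta_sa <- rep(0, C)
    norm
  }
  walk <- function(x) {
    if (is.list(x) && !is.null(x$run_mean)) return(conv_one(x))
    if (is.list(x)) for (nm in seq_along(x)) x[[nm]] <- walk(x[[nm]])
    x
  }
  model$params <- walk(model$params)
  model$config$norm_mode <- mode
  model$config$G <- as.integer(G)
  model
}

# Sum of all parameter values; cheap fingerprint for determinism checks.
param_checksum <- function(model) {
  s <- 0
  walk <- function(x) {
    if (is.numeric(x)) s <<- s + sum(abs(x))
    else if (is.list(x)) for (e in x) walk(e)
  }
  walk(model$params)
  s
}
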