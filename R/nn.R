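# Minimal CNN engine behind the kernel classifier and the center regressor.
# Activations for a batch of N inputs live in a (H*W*C) x N matrix whose
# column layout matches as.vector() on an R [H, W, C] array; the compiled
# kernels in src/conv_ops.cpp do the heavy lifting (im2col GEMM convolutions,
# pooling, batch normalization). All randomness flows through R's RNG so
# seeded training is bit-reproducible.
#
# A network is a list of layer specs:
#   conv(k, out) | bn | relu | avgpool(k, s) | maxpool(k, s) | fc(out) |
#   sigmoid | linear
# with shapes inferred once at construction. Weights use Xavier (Glorot)
# uniform initialization; batch norm uses momentum 0.9 and epsilon 1e-5 and
# switches to running statistics at inference.

BN_MOMENTUM <- 0.9
BN_EPS <- 1e-5

conv_spec <- function(out, k = 3L) list(type = "conv", k = as.integer(k), out = as.integer(out))
bn_spec <- function() list(type = "bn")
relu_spec <- function() list(type = "relu")
avgpool_spec <- function(k, s) list(type = "avgpool", k = as.integer(k), s = as.integer(s))
maxpool_spec <- function(k, s) list(type = "maxpool", k = as.integer(k), s = as.integer(s))
fc_spec <- function(out) list(type = "fc", out = as.integer(out))

xavier_uniform <- function(nrow, ncol, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(runif(nrow * ncol, -lim, lim), nrow, ncol)
}

# Build a network: infer shapes, initialize parameters (under the current RNG
# state -- callers wrap in with_seed), allocate Adam state.
new_cnn <- function(specs, input_shape = c(32L, 32L, 3L), out_activation = "sigmoid") {
  shape <- as.integer(input_shape)          # (H, W, C); C = features for FC
  layers <- list()
  for (s in specs) {
    l <- s
    l$in_shape <- shape
    if (s$type == "conv") {
      H <- shape[1]; W <- shape[2]; C <- shape[3]; k <- s$k
      stopifnot(H >= k, W >= k)
      fan_in <- C * k * k; fan_out <- s$out * k * k
      l$W <- xavier_uniform(s$out, C * k * k, fan_in, fan_out)
      l$b <- numeric(s$out)
      shape <- c(H - k + 1L, W - k + 1L, s$out)
    } else if (s$type %in% c("avgpool", "maxpool")) {
      H <- shape[1]; W <- shape[2]
      shape <- c((H - s$k) %/% s$s + 1L, (W - s$k) %/% s$s + 1L, shape[3])
    } else if (s$type == "bn") {
      C <- shape[3]
      l$gamma <- rep(1, C); l$beta <- numeric(C)
      l$rmean <- numeric(C); l$rvar <- rep(1, C)
    } else if (s$type == "fc") {
      n_in <- prod(shape)
      l$W <- xavier_uniform(s$out, n_in, n_in, s$out)
      l$b <- numeric(s$out)
      shape <- c(1L, 1L, s$out)
    } else if (s$type != "relu") {
      stop("unknown layer type: ", s$type)
    }
    l$out_shape <- shape
    layers[[length(layers) + 1L]] <- l
  }
  structure(list(layers = layers, input_shape = as.integer(input_shape),
                 out_activation = out_activation, adam = NULL, adam_t = 0L),
            class = "maize_cnn")
}

# Per-layer output shapes (H, W, C), used by the architecture-conformance
# checks.
cnn_shapes <- function(net) {
  lapply(net$layers, `[[`, "out_shape")
}

# Forward pass. Returns list(out, caches, net) -- net comes back because
# training-mode batch norm updates its running moments.
cnn_forward <- function(net, X, training = FALSE, keep_cache = FALSE) {
  caches <- if (keep_cache) vector("list", length(net$layers))
  for (i in seq_along(net$layers)) {
    l <- net$layers[[i]]
    s <- l$in_shape
    if (l$type == "conv") {
      out <- conv_forward_cpp(X, s[1], s[2], s[3], l$W, l$b, l$k)
      if (keep_cache) caches[[i]] <- list(X = X)
    } else if (l$type == "avgpool") {
      out <- avgpool_forward_cpp(X, s[1], s[2], s[3], l$k, l$s)
    } else if (l$type == "maxpool") {
      mp <- maxpool_forward_cpp(X, s[1], s[2], s[3], l$k, l$s)
      out <- mp$out
      if (keep_cache) caches[[i]] <- list(idx = mp$idx, in_rows = nrow(X))
    } else if (l$type == "bn") {
      S <- s[1] * s[2]
      bn <- bn_forward_cpp(X, S, l$gamma, l$beta, l$rmean, l$rvar,
                           BN_MOMENTUM, BN_EPS, training)
      out <- bn$out
      if (training) {
        net$layers[[i]]$rmean <- as.numeric(bn$rmean)
        net$layers[[i]]$rvar <- as.numeric(bn$rvar)
      }
      if (keep_cache) caches[[i]] <- list(xhat = bn$xhat, sd = as.numeric(bn$sd), S = S)
    } else if (l$type == "relu") {
      out <- relu_cpp(X)
    } else if (l$type == "fc") {
      out <- l$W %*% X + l$b
      if (keep_cache) caches[[i]] <- list(X = X)
    }
    X <- out
  }
  list(out = X, caches = caches, net = net)
}

# Backward pass from the gradient at the network output (pre-activation of
# the head is handled by the caller). Returns per-layer gradients.
cnn_backward <- function(net, caches, d, acts = NULL) {
  grads <- vector("list", length(net$layers))
  for (i in rev(seq_along(net$layers))) {
    l <- net$layers[[i]]
    s <- l$in_shape
    need_dx <- i > 1L
    if (l$type == "conv") {
      g <- conv_backward_cpp(caches[[i]]$X, s[1], s[2], s[3], l$W, l$k, d)
      grads[[i]] <- list(W = g$dW, b = as.numeric(g$db))
      d <- if (need_dx) g$dX else NULL
    } else if (l$type == "avgpool") {
      d <- avgpool_backward_cpp(d, s[1], s[2], s[3], l$k, l$s)
    } else if (l$type == "maxpool") {
      d <- maxpool_backward_cpp(d, caches[[i]]$idx, caches[[i]]$in_rows)
    } else if (l$type == "bn") {
      cb <- caches[[i]]
      g <- bn_backward_cpp(d, cb$xhat, cb$S, l$gamma, cb$sd)
      grads[[i]] <- list(gamma = as.numeric(g$dgamma), beta = as.numeric(g$dbeta))
      d <- g$dX
    } else if (l$type == "relu") {
      d <- d * (acts[[i]] > 0)
    } else if (l$type == "fc") {
      X <- caches[[i]]$X
      grads[[i]] <- list(W = d %*% t(X), b = rowSums(d))
      d <- if (need_dx) crossprod(l$W, d) else NULL
    }
  }
  grads
}

# Forward keeping the per-layer outputs (needed for the relu backward mask).
cnn_forward_train <- function(net, X) {
  acts <- vector("list", length(net$layers))
  caches <- vector("list", length(net$layers))
  for (i in seq_along(net$layers)) {
    l <- net$layers[[i]]
    s <- l$in_shape
    if (l$type == "conv") {
      out <- conv_forward_cpp(X, s[1], s[2], s[3], l$W, l$b, l$k)
      caches[[i]] <- list(X = X)
    } else if (l$type == "avgpool") {
      out <- avgpool_forward_cpp(X, s[1], s[2], s[3], l$k, l$s)
    } else if (l$type == "maxpool") {
      mp <- maxpool_forward_cpp(X, s[1], s[2], s[3], l$k, l$s)
      out <- mp$out
      caches[[i]] <- list(idx = mp$idx, in_rows = nrow(X))
    } else if (l$type == "bn") {
      S <- s[1] * s[2]
      bn <- bn_forward_cpp(X, S, l$gamma, l$beta, l$rmean, l$rvar,
                           BN_MOMENTUM, BN_EPS, TRUE)
      out <- bn$out
      net$layers[[i]]$rmean <- as.numeric(bn$rmean)
      net$layers[[i]]$rvar <- as.numeric(bn$rvar)
      caches[[i]] <- list(xhat = bn$xhat, sd = as.numeric(bn$sd), S = S)
    } else if (l$type == "relu") {
      out <- relu_cpp(X)
    } else if (l$type == "fc") {
      out <- l$W %*% X + l$b
      caches[[i]] <- list(X = X)
    }
    acts[[i]] <- out
    X <- out
  }
  list(out = X, caches = caches, acts = acts, net = net)
}

# One Adam update (beta1 = 0.9, beta2 = 0.999, eps = 1e-8) over every
# parameter tensor with a gradient.
adam_step <- function(net, grads, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  if (is.null(net$adam)) {
    net$adam <- lapply(seq_along(net$layers), function(i) {
      g <- grads[[i]]
      if (is.null(g)) return(NULL)
      lapply(g, function(p) list(m = p * 0, v = p * 0))
    })
  }
  net$adam_t <- net$adam_t + 1L
  t <- net$adam_t
  bc1 <- 1 - beta1^t; bc2 <- 1 - beta2^t
  for (i in seq_along(grads)) {
    g <- grads[[i]]
    if (is.null(g)) next
    for (nm in names(g)) {
      st <- net$adam[[i]][[nm]]
      st$m <- beta1 * st$m + (1 - beta1) * g[[nm]]
      st$v <- beta2 * st$v + (1 - beta2) * g[[nm]]^2
      net$adam[[i]][[nm]] <- st
      upd <- lr * (st$m / bc1) / (sqrt(st$v / bc2) + eps)
      net$layers[[i]][[nm]] <- net$layers[[i]][[nm]] - upd
    }
  }
  net
}

# Fold inference-mode batch norm into the network: after a conv or fc layer,
# the per-channel affine x -> gamma * (x - mu) / sd + beta is absorbed into
# that layer's weights; after a pooling layer it becomes a lightweight
# per-channel "affine" layer. Valid only with running statistics (inference).
fold_bn_for_inference <- function(net) {
  layers <- list()
  for (l in net$layers) {
    if (l$type == "bn") {
      s <- l$gamma / sqrt(l$rvar + BN_EPS)
      off <- l$beta - l$rmean * s
      prev <- if (length(layers)) layers[[length(layers)]]
      if (!is.null(prev) && prev$type %in% c("conv", "fc")) {
        prev$W <- prev$W * s          # rows = output channels
        prev$b <- prev$b * s + off
        layers[[length(layers)]] <- prev
      } else {
        S <- l$in_shape[1] * l$in_shape[2]
        layers[[length(layers) + 1L]] <-
          list(type = "affine", a = rep(s, each = S), b = rep(off, each = S),
               in_shape = l$in_shape, out_shape = l$out_shape)
      }
    } else {
      layers[[length(layers) + 1L]] <- l
    }
  }
  net$layers <- layers
  net
}

# forward through a folded (inference-only) network
folded_forward <- function(layers, X) {
  for (l in layers) {
    s <- l$in_shape
    X <- switch(l$type,
                conv = conv_forward_cpp(X, s[1], s[2], s[3], l$W, l$b, l$k),
                avgpool = avgpool_forward_cpp(X, s[1], s[2], s[3], l$k, l$s),
                maxpool = maxpool_forward_cpp(X, s[1], s[2], s[3], l$k, l$s)$out,
                relu = relu_cpp(X),
                affine = X * l$a + l$b,
                fc = l$W %*% X + l$b)
  }
  X
}

# Inference in chunks to bound workspace memory; batch norm is folded once.
cnn_predict <- function(net, X, chunk = 128L) {
  folded <- fold_bn_for_inference(net)$layers
  n <- ncol(X)
  j0 <- min(chunk, n)
  first <- folded_forward(folded, X[, seq_len(j0), drop = FALSE])
  if (n <= chunk) return(first)
  out <- matrix(0, nrow(first), n)
  out[, seq_len(j0)] <- first
  i <- j0
  while (i < n) {
    j <- min(i + chunk, n)
    out[, (i + 1):j] <- folded_forward(folded, X[, (i + 1):j, drop = FALSE])
    i <- j
  }
  out
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# Binary cross-entropy on probabilities (clipped for numerical safety).
bce_loss <- function(p, y) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}
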