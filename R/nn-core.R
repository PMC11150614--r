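# Minimal neural-network core: layers as mutable environments holding
# parameters `p`, accumulated gradients `g`, and a per-forward `cache`.
# Feature maps travel as (H*W*B) x C matrices with pixels in R's
# column-major order (h fastest), image blocks stacked along rows.
# All heavy lifting is BLAS matrix products, so the core stays fast
# enough for desk-scale training on one CPU.

.vn_maps <- new.env(parent = emptyenv())

#' Run code with a private RNG state
#'
#' Seeds R's RNG, runs `expr`, and restores the caller's RNG state so
#' that seeded helpers never perturb the global random stream.
#' @noRd
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# truncated normal on [-2 sd, 2 sd], the usual transformer init
trunc_normal <- function(n, sd = 0.02) {
  u <- runif(n, stats::pnorm(-2), stats::pnorm(2))
  stats::qnorm(u) * sd
}

zero_like <- function(p) lapply(p, function(x) {
  if (is.list(x)) zero_like(x) else x * 0   # preserves shape attributes
})

bcast_row <- function(v, n) matrix(v, n, length(v), byrow = TRUE)

# ---- convolution index maps ------------------------------------------------

# For a k x k "same" convolution with stride s on an H x W grid (batch B),
# precompute, for each kernel offset, the input row index feeding each
# output position; out-of-bounds positions point at a shared zero row
# (index n_in + 1).  Maps are memoised on (H, W, B, k, stride).
conv_maps <- function(H, W, B, k, stride) {
  key <- paste(H, W, B, k, stride, sep = "_")
  hit <- .vn_maps[[key]]
  if (!is.null(hit)) return(hit)
  pad <- (k - 1L) %/% 2L
  ho <- seq.int(1L, H, by = stride)
  wo <- seq.int(1L, W, by = stride)
  Hout <- length(ho); Wout <- length(wo)
  hh <- rep(ho, times = Wout)
  ww <- rep(wo, each = Hout)
  npix <- H * W
  zero_row <- npix * B + 1L
  offs <- expand.grid(dh = seq.int(-pad, pad), dw = seq.int(-pad, pad))
  idx <- vector("list", nrow(offs))
  boff <- rep((seq_len(B) - 1L) * npix, each = Hout * Wout)
  for (i in seq_len(nrow(offs))) {
    hs <- hh + offs$dh[i]; ws <- ww + offs$dw[i]
    ok <- hs >= 1L & hs <= H & ws >= 1L & ws <= W
    base <- ifelse(ok, hs + H * (ws - 1L), NA_integer_)
    full <- rep(base, times = B) + boff
    full[is.na(full)] <- zero_row
    idx[[i]] <- as.integer(full)
  }
  res <- list(idx = idx, Hout = Hout, Wout = Wout, nk = nrow(offs))
  assign(key, res, envir = .vn_maps)
  res
}

# ---- layers ----------------------------------------------------------------

nn_conv2d <- function(cin, cout, k = 3L, stride = 1L, init = c("kaiming", "trunc")) {
  init <- match.arg(init)
  L <- new.env(parent = emptyenv())
  L$type <- "conv2d"; L$cin <- cin; L$cout <- cout
  L$k <- as.integer(k); L$stride <- as.integer(stride)
  nk <- L$k * L$k
  w <- if (init == "kaiming") stats::rnorm(nk * cin * cout, sd = sqrt(2 / (nk * cin)))
       else trunc_normal(nk * cin * cout)
  L$p <- list(W = array(w, dim = c(nk, cin, cout)), b = numeric(cout))
  L$g <- zero_like(L$p)
  class(L) <- c("nn_conv2d", "nn_layer")
  L
}

conv2d_fwd <- function(L, X, H, W, B) {
  m <- conv_maps(H, W, B, L$k, L$stride)
  Xa <- rbind(X, 0)
  out <- matrix(0, m$Hout * m$Wout * B, L$cout)
  for (i in seq_len(m$nk)) {
    Wi <- matrix(L$p$W[i, , ], L$cin, L$cout)
    out <- out + Xa[m$idx[[i]], , drop = FALSE] %*% Wi
  }
  out <- out + bcast_row(L$p$b, nrow(out))
  L$cache <- list(Xa = Xa, m = m, n_in = nrow(X))
  list(out = out, H = m$Hout, W = m$Wout)
}

conv2d_bwd <- function(L, dY) {
  cc <- L$cache; m <- cc$m
  L$g$b <- L$g$b + colSums(dY)
  dX <- matrix(0, cc$n_in, L$cin)
  for (i in seq_len(m$nk)) {
    idx <- m$idx[[i]]
    ok <- idx <= cc$n_in            # drop zero-row (padding) positions
    Xi <- cc$Xa[idx, , drop = FALSE]
    L$g$W[i, , ] <- matrix(L$g$W[i, , ], L$cin, L$cout) + crossprod(Xi, dY)
    Wi <- matrix(L$p$W[i, , ], L$cin, L$cout)
    Mi <- dY[ok, , drop = FALSE] %*% t(Wi)
    ii <- idx[ok]
    dX[ii, ] <- dX[ii, ] + Mi       # per-offset input rows are unique
  }
  dX
}

nn_batchnorm <- function(C, momentum = 0.1, eps = 1e-5) {
  L <- new.env(parent = emptyenv())
  L$type <- "batchnorm"; L$C <- C; L$momentum <- momentum; L$eps <- eps
  L$p <- list(gamma = rep(1, C), beta = numeric(C))
  L$g <- zero_like(L$p)
  L$rmean <- numeric(C); L$rvar <- rep(1, C)
  class(L) <- c("nn_batchnorm", "nn_layer")
  L
}

batchnorm_fwd <- function(L, X, training) {
  n <- nrow(X)
  if (training) {
    mu <- colMeans(X)
    xc <- X - bcast_row(mu, n)
    v <- colMeans(xc * xc)
    L$rmean <- (1 - L$momentum) * L$rmean + L$momentum * mu
    L$rvar <- (1 - L$momentum) * L$rvar + L$momentum * v * n / max(n - 1, 1)
  } else {
    mu <- L$rmean; v <- L$rvar
    xc <- X - bcast_row(mu, n)
  }
  ivar <- 1 / sqrt(v + L$eps)
  xhat <- xc * bcast_row(ivar, n)
  L$cache <- list(xhat = xhat, ivar = ivar, n = n, training = training)
  xhat * bcast_row(L$p$gamma, n) + bcast_row(L$p$beta, n)
}

batchnorm_bwd <- function(L, dY) {
  cc <- L$cache; n <- cc$n
  L$g$gamma <- L$g$gamma + colSums(dY * cc$xhat)
  L$g$beta <- L$g$beta + colSums(dY)
  dxhat <- dY * bcast_row(L$p$gamma, n)
  if (!cc$training)
    return(dxhat * bcast_row(cc$ivar, n))
  s1 <- colSums(dxhat)
  s2 <- colSums(dxhat * cc$xhat)
  bcast_row(cc$ivar / n, n) * (n * dxhat - bcast_row(s1, n) - cc$xhat * bcast_row(s2, n))
}

nn_layernorm <- function(J, eps = 1e-5) {
  L <- new.env(parent = emptyenv())
  L$type <- "layernorm"; L$J <- J; L$eps <- eps
  L$p <- list(gamma = rep(1, J), beta = numeric(J))
  L$g <- zero_like(L$p)
  class(L) <- c("nn_layernorm", "nn_layer")
  L
}

layernorm_fwd <- function(L, X) {
  n <- nrow(X)
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc * xc)
  ivar <- 1 / sqrt(v + L$eps)
  xhat <- xc * ivar
  L$cache <- list(xhat = xhat, ivar = ivar)
  xhat * bcast_row(L$p$gamma, n) + bcast_row(L$p$beta, n)
}

layernorm_bwd <- function(L, dY) {
  cc <- L$cache; n <- nrow(dY)
  L$g$gamma <- L$g$gamma + colSums(dY * cc$xhat)
  L$g$beta <- L$g$beta + colSums(dY)
  dxhat <- dY * bcast_row(L$p$gamma, n)
  cc$ivar * (dxhat - rowMeans(dxhat) - cc$xhat * rowMeans(dxhat * cc$xhat))
}

nn_linear <- function(cin, cout, init_sd = 0.02, zero_init = FALSE) {
  L <- new.env(parent = emptyenv())
  L$type <- "linear"; L$cin <- cin; L$cout <- cout
  w <- if (zero_init) numeric(cin * cout) else trunc_normal(cin * cout, sd = init_sd)
  L$p <- list(W = matrix(w, cin, cout), b = numeric(cout))
  L$g <- zero_like(L$p)
  class(L) <- c("nn_linear", "nn_layer")
  L
}

linear_fwd <- function(L, X) {
  L$cache <- list(X = X)
  X %*% L$p$W + bcast_row(L$p$b, nrow(X))
}

linear_bwd <- function(L, dY) {
  L$g$W <- L$g$W + crossprod(L$cache$X, dY)
  L$g$b <- L$g$b + colSums(dY)
  dY %*% t(L$p$W)
}

# activations (stateless; caller keeps the cache)
relu_fwd <- function(X) pmax(X, 0)
relu_bwd <- function(dY, X) dY * (X > 0)

gelu_fwd <- function(X) X * stats::pnorm(X)
gelu_bwd <- function(dY, X) dY * (stats::pnorm(X) + X * stats::dnorm(X))

sigmoid <- function(x) 1 / (1 + exp(-x))

softmax_rows <- function(S) {
  m <- apply(S, 1, max)
  E <- exp(S - m)
  E / rowSums(E)
}

# ---- multi-head self-attention --------------------------------------------

nn_mha <- function(J, n_heads) {
  stopifnot(J %% n_heads == 0)
  L <- new.env(parent = emptyenv())
  L$type <- "mha"; L$J <- J; L$h <- n_heads; L$dh <- J %/% n_heads
  L$p <- list(Wqkv = matrix(trunc_normal(J * 3 * J), J, 3 * J), bqkv = numeric(3 * J),
              Wo = matrix(trunc_normal(J * J), J, J), bo = numeric(J))
  L$g <- zero_like(L$p)
  class(L) <- c("nn_mha", "nn_layer")
  L
}

# X: (B * L1) x J token matrix, per-image blocks of L1 rows
mha_fwd <- function(L, X, L1, B) {
  J <- L$J; h <- L$h; dh <- L$dh
  out <- matrix(0, nrow(X), J)
  caches <- vector("list", B)
  for (b in seq_len(B)) {
    rows <- (b - 1L) * L1 + seq_len(L1)
    Tb <- X[rows, , drop = FALSE]
    QKV <- Tb %*% L$p$Wqkv + bcast_row(L$p$bqkv, L1)
    O <- matrix(0, L1, J)
    Ps <- vector("list", h)
    for (hd in seq_len(h)) {
      sl <- (hd - 1L) * dh + seq_len(dh)
      Q <- QKV[, sl, drop = FALSE]
      K <- QKV[, J + sl, drop = FALSE]
      V <- QKV[, 2L * J + sl, drop = FALSE]
      P <- softmax_rows(Q %*% t(K) / sqrt(dh))
      O[, sl] <- P %*% V
      Ps[[hd]] <- P
    }
    out[rows, ] <- O %*% L$p$Wo + bcast_row(L$p$bo, L1)
    caches[[b]] <- list(Tb = Tb, QKV = QKV, O = O, P = Ps)
  }
  L$cache <- list(per_image = caches, L1 = L1, B = B)
  out
}

mha_bwd <- function(L, dY) {
  J <- L$J; h <- L$h; dh <- L$dh
  cc <- L$cache; L1 <- cc$L1
  dX <- matrix(0, nrow(dY), J)
  for (b in seq_len(cc$B)) {
    rows <- (b - 1L) * L1 + seq_len(L1)
    dYb <- dY[rows, , drop = FALSE]
    cb <- cc$per_image[[b]]
    L$g$Wo <- L$g$Wo + crossprod(cb$O, dYb)
    L$g$bo <- L$g$bo + colSums(dYb)
    dO <- dYb %*% t(L$p$Wo)
    dQKV <- matrix(0, L1, 3 * J)
    for (hd in seq_len(h)) {
      sl <- (hd - 1L) * dh + seq_len(dh)
      Q <- cb$QKV[, sl, drop = FALSE]
      K <- cb$QKV[, J + sl, drop = FALSE]
      V <- cb$QKV[, 2L * J + sl, drop = FALSE]
      P <- cb$P[[hd]]
      dOh <- dO[, sl, drop = FALSE]
      dP <- dOh %*% t(V)
      dV <- crossprod(P, dOh)
      dS <- P * (dP - rowSums(dP * P))
      dQKV[, sl] <- dS %*% K / sqrt(dh)
      dQKV[, J + sl] <- crossprod(dS, Q) / sqrt(dh)
      dQKV[, 2L * J + sl] <- dV
    }
    L$g$Wqkv <- L$g$Wqkv + crossprod(cb$Tb, dQKV)
    L$g$bqkv <- L$g$bqkv + colSums(dQKV)
    dX[rows, ] <- dQKV %*% t(L$p$Wqkv)
  }
  dX
}

# ---- spatial resampling ----------------------------------------------------

# 1-D resampling operator as an n_out x n_in matrix.  "bilinear" uses
# half-pixel-centre linear interpolation (rows sum to 1, so constants are
# preserved); "avgpool" is exact block averaging and requires n_in to be
# a multiple of n_out.
resample_operator <- function(n_out, n_in, mode = c("bilinear", "avgpool")) {
  mode <- match.arg(mode)
  A <- matrix(0, n_out, n_in)
  if (mode == "avgpool") {
    if (n_in %% n_out != 0)
      stop("avgpool requires the input size to be a multiple of the output size")
    r <- n_in %/% n_out
    for (i in seq_len(n_out)) A[i, (i - 1L) * r + seq_len(r)] <- 1 / r
  } else {
    scale <- n_in / n_out
    for (i in seq_len(n_out)) {
      src <- (i - 0.5) * scale - 0.5       # 0-based source coordinate
      src <- min(max(src, 0), n_in - 1)
      f <- floor(src); w <- src - f
      i0 <- as.integer(f) + 1L
      i1 <- min(i0 + 1L, n_in)
      A[i, i0] <- A[i, i0] + (1 - w)
      A[i, i1] <- A[i, i1] + w
    }
  }
  A
}

# Separable resize of a pixel-matrix X ((H*W*B) x C) to H2 x W2.
resample_fwd <- function(X, H, W, B, H2, W2, mode = "bilinear") {
  Ar <- resample_operator(H2, H, mode)
  Ac <- resample_operator(W2, W, mode)
  C <- ncol(X)
  Y <- matrix(0, H2 * W2 * B, C)
  for (b in seq_len(B)) {
    rin <- (b - 1L) * H * W
    rout <- (b - 1L) * H2 * W2
    for (cch in seq_len(C)) {
      M <- matrix(X[rin + seq_len(H * W), cch], H, W)
      Y[rout + seq_len(H2 * W2), cch] <- Ar %*% M %*% t(Ac)
    }
  }
  attr(Y, "ops") <- list(Ar = Ar, Ac = Ac, H = H, W = W, B = B, H2 = H2, W2 = W2)
  Y
}

resample_bwd <- function(dY, ops) {
  C <- ncol(dY)
  with(ops, {
    dX <- matrix(0, H * W * B, C)
    for (b in seq_len(B)) {
      rin <- (b - 1L) * H * W
      rout <- (b - 1L) * H2 * W2
      for (cch in seq_len(C)) {
        M <- matrix(dY[rout + seq_len(H2 * W2), cch], H2, W2)
        dX[rin + seq_len(H * W), cch] <- t(Ar) %*% M %*% Ac
      }
    }
    dX
  })
}

# ---- parameter traversal / optimiser hooks --------------------------------

layer_nparams <- function(L) sum(vapply(L$p, length, 1L))

zero_grads <- function(layers) {
  for (L in layers) L$g <- zero_like(L$p)
  invisible(NULL)
}

collect_layers <- function(x) {
  # flatten a nested list of layers/NULLs into a flat list of nn_layer envs
  out <- list()
  rec <- function(v) {
    if (is.null(v)) return()
    if (inherits(v, "nn_layer")) { out[[length(out) + 1L]] <<- v; return() }
    if (is.list(v)) for (el in v) rec(el)
  }
  rec(x)
  out
}
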