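# Analytic gradients of every layer type against central finite
# differences, plus resampling-operator algebra.  All fixtures are
# seeded, so results are bitwise reproducible.

fd_check <- function(fwd, L, n_probe = 6, eps = 1e-6, tol = 1e-4, seed = 1) {
  # fwd() must run forward + backward and return the scalar loss;
  # gradients are read from L$g after one backward call.
  loss0 <- fwd(accumulate = TRUE)
  set.seed(seed)
  for (probe in seq_len(n_probe)) {
    nm <- sample(names(L$p), 1)
    k <- sample(length(L$p[[nm]]), 1)
    ga <- L$g[[nm]][k]
    orig <- L$p[[nm]][k]
    L$p[[nm]][k] <- orig + eps; lp <- fwd(accumulate = FALSE)
    L$p[[nm]][k] <- orig - eps; lm <- fwd(accumulate = FALSE)
    L$p[[nm]][k] <- orig
    gn <- (lp - lm) / (2 * eps)
    expect_equal(ga, gn, tolerance = tol,
                 label = sprintf("%s %s[%d] analytic", L$type, nm, k))
  }
  invisible(loss0)
}

test_that("conv2d gradients (stride 1 and 2, k 1 and 3) match finite differences", {
  for (cse in list(list(k = 3, s = 1), list(k = 1, s = 1), list(k = 3, s = 2))) {
    set.seed(31)
    L <- vesselnet:::nn_conv2d(3, 4, k = cse$k, stride = cse$s)
    X <- matrix(rnorm(8 * 6 * 3), 48, 3)
    R <- NULL
    fwd <- function(accumulate) {
      y <- vesselnet:::conv2d_fwd(L, X, 8, 6, 1)
      if (is.null(R)) R <<- matrix(rnorm(length(y$out)), nrow(y$out))
      if (accumulate) {
        L$g <- vesselnet:::zero_like(L$p)
        vesselnet:::conv2d_bwd(L, R)
      }
      sum(R * y$out)
    }
    fd_check(fwd, L)
  }
})

test_that("conv2d input gradient matches finite differences", {
  set.seed(32)
  L <- vesselnet:::nn_conv2d(2, 3, k = 3)
  X <- matrix(rnorm(5 * 4 * 2), 20, 2)
  y <- vesselnet:::conv2d_fwd(L, X, 5, 4, 1)
  R <- matrix(rnorm(length(y$out)), nrow(y$out))
  L$g <- vesselnet:::zero_like(L$p)
  dX <- vesselnet:::conv2d_bwd(L, R)
  eps <- 1e-6
  for (k in c(1, 9, 20, 33)) {
    Xp <- X; Xp[k] <- Xp[k] + eps
    Xm <- X; Xm[k] <- Xm[k] - eps
    gn <- (sum(R * vesselnet:::conv2d_fwd(L, Xp, 5, 4, 1)$out) -
           sum(R * vesselnet:::conv2d_fwd(L, Xm, 5, 4, 1)$out)) / (2 * eps)
    expect_equal(dX[k], gn, tolerance = 1e-4)
  }
})

test_that("batchnorm and layernorm gradients match finite differences", {
  set.seed(33)
  Lb <- vesselnet:::nn_batchnorm(4)
  X <- matrix(rnorm(30 * 4), 30, 4)
  R <- matrix(rnorm(120), 30, 4)
  fwd_b <- function(accumulate) {
    y <- vesselnet:::batchnorm_fwd(Lb, X, training = TRUE)
    if (accumulate) {
      Lb$g <- vesselnet:::zero_like(Lb$p)
      vesselnet:::batchnorm_bwd(Lb, R)
    }
    sum(R * y)
  }
  fd_check(fwd_b, Lb)
  # input gradient through the batch statistics
  invisible(fwd_b(TRUE))
  dX <- vesselnet:::batchnorm_bwd(Lb, R)
  eps <- 1e-6
  for (k in c(3, 50, 100)) {
    Xp <- X; Xp[k] <- Xp[k] + eps
    Xm <- X; Xm[k] <- Xm[k] - eps
    gn <- (sum(R * vesselnet:::batchnorm_fwd(Lb, Xp, TRUE)) -
           sum(R * vesselnet:::batchnorm_fwd(Lb, Xm, TRUE))) / (2 * eps)
    expect_equal(dX[k], gn, tolerance = 1e-4)
  }

  Ll <- vesselnet:::nn_layernorm(6)
  X2 <- matrix(rnorm(10 * 6), 10, 6)
  R2 <- matrix(rnorm(60), 10, 6)
  fwd_l <- function(accumulate) {
    y <- vesselnet:::layernorm_fwd(Ll, X2)
    if (accumulate) {
      Ll$g <- vesselnet:::zero_like(Ll$p)
      vesselnet:::layernorm_bwd(Ll, R2)
    }
    sum(R2 * y)
  }
  fd_check(fwd_l, Ll)
})

test_that("multi-head attention gradients match finite differences", {
  set.seed(34)
  L <- vesselnet:::nn_mha(8, 2)
  X <- matrix(rnorm(5 * 8), 5, 8)
  R <- matrix(rnorm(40), 5, 8)
  fwd <- function(accumulate) {
    y <- vesselnet:::mha_fwd(L, X, 5, 1)
    if (accumulate) {
      L$g <- vesselnet:::zero_like(L$p)
      vesselnet:::mha_bwd(L, R)
    }
    sum(R * y)
  }
  fd_check(fwd, L, n_probe = 8)
  # input gradient
  invisible(fwd(TRUE))
  dX <- vesselnet:::mha_bwd(L, R)
  eps <- 1e-6
  for (k in c(1, 17, 40)) {
    Xp <- X; Xp[k] <- Xp[k] + eps
    Xm <- X; Xm[k] <- Xm[k] - eps
    gn <- (sum(R * vesselnet:::mha_fwd(L, Xp, 5, 1)) -
           sum(R * vesselnet:::mha_fwd(L, Xm, 5, 1))) / (2 * eps)
    expect_equal(dX[k], gn, tolerance = 1e-4)
  }
})

test_that("resampling operators preserve constants and satisfy the adjoint identity", {
  for (mode in c("bilinear", "avgpool")) {
    A <- vesselnet:::resample_operator(4, 16, mode)
    expect_equal(rowSums(A), rep(1, 4))                 # constants preserved
  }
  Aup <- vesselnet:::resample_operator(16, 4, "bilinear")
  expect_equal(rowSums(Aup), rep(1, 16))
  expect_error(vesselnet:::resample_operator(5, 16, "avgpool"), "multiple")

  set.seed(35)
  X <- matrix(rnorm(8 * 8 * 2), 64, 2)
  Y <- vesselnet:::resample_fwd(X, 8, 8, 1, 16, 16, "bilinear")
  G <- matrix(rnorm(16 * 16 * 2), 256, 2)
  dX <- vesselnet:::resample_bwd(G, attr(Y, "ops"))
  # <A x, g> == <x, A' g>
  expect_equal(sum(Y * G), sum(X * dX), tolerance = 1e-10)

  # avgpool of a constant block structure is exact
  Xc <- matrix(2.5, 64, 1)
  Yc <- vesselnet:::resample_fwd(Xc, 8, 8, 1, 2, 2, "avgpool")
  expect_equal(as.numeric(Yc), rep(2.5, 4))
})

test_that("whole-model analytic gradients agree with finite differences", {
  set.seed(36)
  cfg <- model_config("tiny", n_trans_blocks = 2, embed_dim = 8, n_heads = 2,
                      stem_channels = c(4, 5, 6, 8), n_conv_blocks = 2,
                      decoder_channels = c(6, 5, 4), mlp_ratio = 2)
  m <- build_model(cfg, seed = 7)
  imgs <- lapply(1:2, function(i) array(runif(32 * 32 * 3), dim = c(32, 32, 3)))
  layers <- vesselnet:::model_layers(m)
  fw <- model_forward(m, imgs, training = TRUE)
  R <- matrix(rnorm(length(fw$logits)), ncol = 1)
  vesselnet:::zero_grads(layers)
  invisible(model_forward(m, imgs, training = TRUE))
  vesselnet:::model_backward(m, R)
  loss_of <- function() sum(R * model_forward(m, imgs, training = TRUE)$logits)
  eps <- 1e-6
  set.seed(37)
  rels <- replicate(25, {
    li <- sample(length(layers), 1); L <- layers[[li]]
    nm <- sample(names(L$p), 1); k <- sample(length(L$p[[nm]]), 1)
    ga <- L$g[[nm]][k]; orig <- L$p[[nm]][k]
    L$p[[nm]][k] <- orig + eps; lp <- loss_of()
    L$p[[nm]][k] <- orig - eps; lm <- loss_of()
    L$p[[nm]][k] <- orig
    gn <- (lp - lm) / (2 * eps)
    abs(ga - gn) / max(1e-4, abs(ga) + abs(gn))
  })
  # occasional ReLU-kink crossings inflate single probes; the bulk must
  # agree tightly
  expect_lt(stats::median(rels), 1e-5)
  expect_lt(max(rels), 0.05)
})
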