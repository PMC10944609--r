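test_that("shared encoder output is nonnegative with the configured width", {
  cfg <- model_config(m = 50, b = 3, C = 2)
  set.seed(1)
  params <- init_params(cfg)
  X <- matrix(rnorm(10 * 50), 10, 50)
  B <- one_hot(sample(c("a", "b", "c"), 10, replace = TRUE))
  L <- encode_shared(X, B, params)
  expect_equal(dim(L), c(10, 256))
  expect_true(all(L >= 0))
  # zero weights and biases give zero output
  p0 <- condiva:::walk_tree(params, function(x) x * 0)
  expect_equal(encode_shared(X, B, p0), matrix(0, 10, 256))
  expect_error(encode_shared(X[, 1:10], B, params), "dimension")
})

test_that("init_scale scales every weight matrix proportionally", {
  cfg1 <- model_config(m = 40, b = 2, C = 2, init_scale = 1)
  cfg2 <- model_config(m = 40, b = 2, C = 2, init_scale = 0.25)
  set.seed(77); p1 <- init_params(cfg1)
  set.seed(77); p2 <- init_params(cfg2)
  expect_equal(p2$enc[[1]]$W, 0.25 * p1$enc[[1]]$W, tolerance = 1e-12)
  expect_equal(p2$dec[[2]]$W, 0.25 * p1$dec[[2]]$W, tolerance = 1e-12)
  expect_equal(p2$mu_cond$W, 0.25 * p1$mu_cond$W, tolerance = 1e-12)
  expect_error(model_config(m = 40, b = 2, C = 2, init_scale = 0),
               "init_scale")
})

test_that("variational heads: unbounded mean, strictly positive variance", {
  cfg <- model_config(m = 40, b = 2, C = 2)
  set.seed(2)
  params <- init_params(cfg)
  L <- matrix(rnorm(20 * 256), 20, 256)
  bio <- encode_bio(L, params)
  cond <- encode_cond(L, params)
  expect_equal(ncol(bio$mu), cfg$d1)
  expect_equal(ncol(cond$mu), 8)
  expect_true(any(bio$mu < 0))
  expect_true(all(bio$var > 0))
  expect_true(all(cond$var > 0))
})

test_that("reparameterization: zero noise returns the mean; seeded draws replay", {
  mu <- matrix(rnorm(12), 4, 3)
  v <- matrix(rexp(12) + 0.1, 4, 3)
  expect_equal(reparameterize(mu, v, matrix(0, 4, 3)), mu)
  set.seed(5); z1 <- reparameterize(mu, v, matrix(rnorm(12), 4, 3))
  set.seed(5); z2 <- reparameterize(mu, v, matrix(rnorm(12), 4, 3))
  expect_identical(z1, z2)
  # variance scaling as defined: Z - mu = var * noise exactly
  noise <- matrix(rnorm(12), 4, 3)
  expect_equal(reparameterize(mu, v, noise) - mu, v * noise)
  expect_equal(reparameterize(mu, v, noise, scale = "stddev") - mu,
               sqrt(v) * noise)
  expect_error(reparameterize(mu, v * 0, noise), "positive")
})

test_that("DSBN hand case: domain values (1, 3) standardize to ±1/sqrt(1+eps)", {
  cfg <- model_config(m = 40, b = 2, C = 2, d2 = 1)
  st <- init_dsbn_state(cfg)
  Z <- matrix(c(1, 3), 2, 1)
  out <- dsbn_forward(Z, c(0L, 0L), st, "train", eps = cfg$eps_bn)
  expect_equal(out$out[, 1], c(-1, 1) / sqrt(1 + cfg$eps_bn), tolerance = 1e-12)
  # running stats moved toward the batch statistics by momentum 0.1
  expect_equal(out$state$mean[1, 1], 0.9 * 0 + 0.1 * 2)
  expect_equal(out$state$var[1, 1], 0.9 * 1 + 0.1 * 1)
})

test_that("DSBN train-mode moments: per-domain per-feature mean 0, var near 1", {
  cfg <- model_config(m = 40, b = 2, C = 3, d2 = 5)
  st <- init_dsbn_state(cfg)
  set.seed(8)
  Z <- matrix(rnorm(60 * 5, sd = 3), 60, 5)
  codes <- sample(0:2, 60, replace = TRUE)
  out <- dsbn_forward(Z, codes, st, "train", eps = cfg$eps_bn)
  for (c in 0:2) {
    rows <- out$out[codes == c, , drop = FALSE]
    expect_true(all(abs(colMeans(rows)) <= 1e-5))
    v <- colMeans(rows^2) - colMeans(rows)^2
    # variance is sigma^2 / (sigma^2 + eps), within 1e-5 of 1 here
    expect_true(all(abs(v - 1) <= 1e-4))
  }
  # single-cell domain: output is exactly 0
  out1 <- dsbn_forward(matrix(5, 1, 5), 1L, st, "train", eps = cfg$eps_bn)
  expect_equal(out1$out, matrix(0, 1, 5))
})

test_that("DSBN branch assignment is label-symmetric", {
  cfg <- model_config(m = 40, b = 2, C = 2, d2 = 3)
  st <- init_dsbn_state(cfg)
  set.seed(3)
  Z <- matrix(rnorm(30), 10, 3)
  codes <- rep(c(0L, 1L), 5)
  a <- dsbn_forward(Z, codes, st, "train")$out
  b <- dsbn_forward(Z, 1L - codes, st, "train")$out
  # swapping domain labels permutes branches but the outputs are unchanged
  expect_equal(a, b)
})

test_that("eval mode uses running statistics and is deterministic", {
  cfg <- model_config(m = 40, b = 2, C = 2, d2 = 2)
  st <- init_dsbn_state(cfg)
  st$mean[1, ] <- c(1, -1)
  st$var[1, ] <- c(4, 0.25)
  Z <- matrix(c(3, 0), 1, 2)
  out <- dsbn_forward(Z, 0L, st, "eval", eps = 0)
  expect_equal(out$out[1, ], c((3 - 1) / 2, (0 + 1) / 0.5))
  expect_identical(out$state$mean, st$mean)   # eval never updates
})

test_that("residual decomposition is exact", {
  set.seed(4)
  Z <- matrix(rnorm(24), 3, 8)
  Zs <- matrix(rnorm(24), 3, 8)
  sp <- condition_residual(Z, Zs)
  expect_identical(sp, Z - Zs)            # brute-force subtraction oracle
  # reconstruction: (Z - Zs) + Zs need not be bitwise Z in floating point,
  # but must agree to machine precision
  expect_equal(sp + Zs, Z, tolerance = 1e-14)
  expect_equal(condition_residual(Z, Z), matrix(0, 3, 8))
  expect_error(condition_residual(Z, Zs[, 1:4]), "shape")
})

test_that("classifier normalizes log-probabilities; zero weights are uniform", {
  cfg <- model_config(m = 40, b = 2, C = 4)
  set.seed(6)
  params <- init_params(cfg)
  expect_equal(vapply(params$cls, function(l) ncol(l$W), numeric(1)),
               c(100, 100, 100, 100, 4))
  Z <- matrix(rnorm(12 * 8), 12, 8)
  lp <- classify_condition(Z, params)
  expect_equal(rowSums(exp(lp)), rep(1, 12), tolerance = 1e-6)
  p0 <- params
  p0$cls[[5]]$W <- p0$cls[[5]]$W * 0
  p0$cls[[5]]$b <- p0$cls[[5]]$b * 0
  expect_equal(exp(classify_condition(Z, p0)), matrix(0.25, 12, 4))
})

test_that("decoder maps latents and batch back to gene space", {
  cfg <- model_config(m = 35, b = 2, C = 2)
  set.seed(7)
  params <- init_params(cfg)
  Zb <- matrix(rnorm(6 * cfg$d1), 6, cfg$d1)
  Zc <- matrix(rnorm(6 * cfg$d2), 6, cfg$d2)
  B <- one_hot(rep(c("a", "b"), 3))
  Xt <- decode(Zb, Zc, B, params)
  expect_equal(dim(Xt), c(6, 35))
  expect_true(any(Xt < 0))   # linear output, signed targets
  p0 <- condiva:::walk_tree(params, function(x) x * 0)
  expect_equal(decode(Zb, Zc, B, p0), matrix(0, 6, 35))
})

test_that("eval-mode forward is deterministic given parameters and stats", {
  cfg <- tiny_config()
  set.seed(9)
  params <- init_params(cfg)
  st <- init_dsbn_state(cfg)
  X <- matrix(rnorm(10 * cfg$m), 10, cfg$m)
  B <- one_hot(rep(c("a", "b"), 5))
  codes <- rep(0:1, 5)
  f1 <- condiva:::model_forward(params, st, X, B, codes, cfg, "eval")
  f2 <- condiva:::model_forward(params, st, X, B, codes, cfg, "eval")
  expect_identical(f1$X_tilde, f2$X_tilde)
  expect_identical(f1$Z_bio, f1$mu_bio)     # mean embeddings at eval
  expect_identical(f1$Z_cond_sp + f1$Z_cond_shared, f1$Z_cond)
})
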