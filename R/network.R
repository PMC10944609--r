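# Network graph: shared feature encoder -> (bio, condition) variational heads
# -> condition-specific DSBN branches -> residual condition-specific
# representation -> condition classifier; batch-conditioned decoder.
# Forward and backward passes are written explicitly in matrix algebra;
# gradients are verified against finite differences in the test suite.

relu <- function(x) pmax(x, 0)

init_layer <- function(fan_in, fan_out, gain = sqrt(2)) {
  list(W = matrix(stats::rnorm(fan_in * fan_out, sd = gain / sqrt(fan_in)),
                  fan_in, fan_out),
       b = numeric(fan_out))
}

init_layers <- function(sizes, gain = sqrt(2)) {
  lapply(seq_len(length(sizes) - 1),
         function(k) init_layer(sizes[k], sizes[k + 1], gain))
}

# forward through a stack of fully connected layers; ReLU between layers,
# final activation "relu" or "linear". Returns output plus pre-activations.
mlp_forward <- function(layers, X, final_act = "linear") {
  K <- length(layers)
  pre <- vector("list", K)
  A <- X
  for (k in seq_len(K)) {
    Z <- A %*% layers[[k]]$W
    Z <- sweep(Z, 2, layers[[k]]$b, "+")
    pre[[k]] <- Z
    A <- if (k < K || final_act == "relu") relu(Z) else Z
  }
  list(out = A, pre = pre, input = X)
}

# backward through the same stack; returns per-layer gradients and the
# gradient with respect to the stack input.
mlp_backward <- function(layers, cache, dOut, final_act = "linear") {
  K <- length(layers)
  grads <- vector("list", K)
  dA <- dOut
  for (k in rev(seq_len(K))) {
    dZ <- if (k < K || final_act == "relu") dA * (cache$pre[[k]] > 0) else dA
    A_prev <- if (k == 1) cache$input else relu(cache$pre[[k - 1]])
    grads[[k]] <- list(W = crossprod(A_prev, dZ), b = colSums(dZ))
    dA <- tcrossprod(dZ, layers[[k]]$W)
  }
  list(grads = grads, dX = dA)
}

#' Initialize model parameters
#'
#' Weights are He-normal initialized, scaled by `config$init_scale` (see
#' [model_config()] for why the default is below 1); variance heads are
#' initialized near zero log-variance so latent variances start close to 1.
#' Uses the current RNG state (seed control lives in [fit_model()]).
#'
#' @param config a [model_config()].
#' @return a nested parameter list (shared encoder, variational heads,
#'   classifier, decoder, optional DSBN affine parameters).
#' @export
init_params <- function(config) {
  sc <- if (is.null(config$init_scale)) 1 else config$init_scale
  p <- list(
    enc = init_layers(c(config$m + config$b, config$enc_hidden),
                      gain = sc * sqrt(2)),
    mu_bio = init_layer(last(config$enc_hidden), config$d1, gain = sc),
    lv_bio = init_layer(last(config$enc_hidden), config$d1, gain = sc * 0.1),
    mu_cond = init_layer(last(config$enc_hidden), config$d2, gain = sc),
    lv_cond = init_layer(last(config$enc_hidden), config$d2, gain = sc * 0.1),
    cls = init_layers(c(config$d2, config$cls_hidden, config$C),
                      gain = sc * sqrt(2)),
    dec = init_layers(c(config$d1 + config$d2 + config$b,
                        config$dec_hidden, config$m), gain = sc * sqrt(2))
  )
  if (config$dsbn_affine) {
    p$dsbn_gamma <- matrix(1, config$C, config$d2)
    p$dsbn_beta <- matrix(0, config$C, config$d2)
  }
  p
}

last <- function(x) x[length(x)]

#' Initialize DSBN running statistics
#' @param config a [model_config()].
#' @return list with `mean` (C x d2, zeros), `var` (C x d2, ones) and the
#'   running-statistic momentum.
#' @export
init_dsbn_state <- function(config) {
  list(mean = matrix(0, config$C, config$d2),
       var = matrix(1, config$C, config$d2),
       momentum = config$bn_momentum)
}

#' Shared feature encoder
#'
#' Two fully connected layers over the concatenated expression row block and
#' batch one-hot block, with ReLU between layers and on the output, so shared
#' features are nonnegative.
#'
#' @param X cell x gene block.
#' @param B cell x batch one-hot block.
#' @param params model parameters from [init_params()].
#' @return cell x d shared-feature matrix L.
#' @export
encode_shared <- function(X, B, params) {
  if (ncol(X) + ncol(B) != nrow(params$enc[[1]]$W))
    stop("encode_shared: input dimension ", ncol(X) + ncol(B),
         " does not match encoder fan-in ", nrow(params$enc[[1]]$W))
  mlp_forward(params$enc, cbind(X, B), final_act = "relu")$out
}

#' Variational heads over the shared features
#'
#' Each head is a single fully connected layer without activation; the
#' variance head is parameterized as log-variance and exponentiated, so the
#' returned variance is strictly positive for any weights.
#'
#' @param L cell x d shared-feature matrix.
#' @param params model parameters.
#' @return list with `mu` and `var` matrices (cell x d1 / cell x d2).
#' @export
encode_bio <- function(L, params) {
  list(mu = linear(L, params$mu_bio), var = exp(linear(L, params$lv_bio)))
}

#' @rdname encode_bio
#' @export
encode_cond <- function(L, params) {
  list(mu = linear(L, params$mu_cond), var = exp(linear(L, params$lv_cond)))
}

linear <- function(X, layer) sweep(X %*% layer$W, 2, layer$b, "+")

#' Reparameterized latent draw
#'
#' `Z = var * noise + mu` under the default `"variance"` scaling (the form
#' the model is defined with), or `Z = sqrt(var) * noise + mu` under
#' `"stddev"`.
#'
#' @param mu,var n x k mean and variance matrices (`var > 0`).
#' @param noise n x k standard-normal draw (zeros reproduce the mean).
#' @param scale `"variance"` or `"stddev"`.
#' @return n x k latent matrix.
#' @export
reparameterize <- function(mu, var, noise, scale = c("variance", "stddev")) {
  scale <- match.arg(scale)
  if (any(var <= 0)) stop("reparameterize: variance must be strictly positive")
  if (scale == "variance") var * noise + mu else sqrt(var) * noise + mu
}

#' Condition-specific domain batch normalization
#'
#' One batch-normalization branch per condition domain. In `train` mode each
#' domain present in the minibatch is normalized by its per-feature
#' minibatch mean and (population) variance, and running statistics are
#' updated by momentum; domains absent from the minibatch are skipped. In
#' `eval` mode running statistics are used for every cell.
#'
#' @param Z_cond n x d2 condition embedding block.
#' @param codes 0-based condition codes (length n, all `< C`).
#' @param state DSBN state from [init_dsbn_state()].
#' @param mode `"train"` or `"eval"`.
#' @param eps variance floor constant.
#' @param gamma,beta optional C x d2 affine parameters (learnable scale and
#'   shift per domain); `NULL` for pure normalization.
#' @return list with `out` (the condition-shared representation `Z'`),
#'   updated `state`, and a backward `cache`.
#' @export
dsbn_forward <- function(Z_cond, codes, state, mode = c("train", "eval"),
                         eps = 1e-5, gamma = NULL, beta = NULL) {
  mode <- match.arg(mode)
  C <- nrow(state$mean)
  if (any(codes < 0 | codes >= C)) stop("dsbn_forward: condition code out of range")
  out <- Z_cond
  cache <- list()
  for (c in sort(unique(codes))) {
    idx <- which(codes == c)
    Zc <- Z_cond[idx, , drop = FALSE]
    if (mode == "train") {
      mu_c <- colMeans(Zc)
      var_c <- colMeans(Zc^2) - mu_c^2
      var_c <- pmax(var_c, 0)
      mom <- state$momentum
      state$mean[c + 1, ] <- (1 - mom) * state$mean[c + 1, ] + mom * mu_c
      state$var[c + 1, ] <- (1 - mom) * state$var[c + 1, ] + mom * var_c
    } else {
      mu_c <- state$mean[c + 1, ]
      var_c <- state$var[c + 1, ]
    }
    s <- sqrt(var_c + eps)
    xhat <- sweep(sweep(Zc, 2, mu_c, "-"), 2, s, "/")
    y <- xhat
    if (!is.null(gamma))
      y <- sweep(sweep(xhat, 2, gamma[c + 1, ], "*"), 2, beta[c + 1, ], "+")
    out[idx, ] <- y
    cache[[as.character(c)]] <- list(idx = idx, xhat = xhat, s = s)
  }
  list(out = out, state = state, cache = cache)
}

# backward through DSBN (train-mode batch statistics); running statistics are
# constants. Returns dZ_cond and, with affine branches, dgamma/dbeta.
dsbn_backward <- function(dOut, cache, mode, gamma = NULL, C = NULL, d2 = NULL) {
  dZ <- dOut * 0
  dgamma <- if (!is.null(gamma)) matrix(0, C, d2) else NULL
  dbeta <- if (!is.null(gamma)) matrix(0, C, d2) else NULL
  for (key in names(cache)) {
    cc <- cache[[key]]
    c1 <- as.integer(key) + 1L
    dy <- dOut[cc$idx, , drop = FALSE]
    if (!is.null(gamma)) {
      dgamma[c1, ] <- colSums(dy * cc$xhat)
      dbeta[c1, ] <- colSums(dy)
      dy <- sweep(dy, 2, gamma[c1, ], "*")
    }
    if (mode == "train") {
      k <- length(cc$idx)
      mean_dy <- colMeans(dy)
      mean_dyx <- colMeans(dy * cc$xhat)
      dx <- sweep(sweep(dy, 2, mean_dy, "-") -
                    sweep(cc$xhat, 2, mean_dyx, "*"), 2, cc$s, "/")
    } else {
      dx <- sweep(dy, 2, cc$s, "/")
    }
    dZ[cc$idx, ] <- dx
  }
  list(dZ = dZ, dgamma = dgamma, dbeta = dbeta)
}

#' Condition-specific residual representation
#'
#' The exact elementwise difference `Z_cond - Z'`, retaining
#' condition-specific information while removing per-domain mean/variance.
#'
#' @param Z_cond,Z_cond_shared matrices of identical shape.
#' @return `Z_cond - Z_cond_shared`.
#' @export
condition_residual <- function(Z_cond, Z_cond_shared) {
  if (!identical(dim(Z_cond), dim(Z_cond_shared)))
    stop("condition_residual: shape mismatch")
  Z_cond - Z_cond_shared
}

#' Condition classifier
#'
#' Fully connected stack `d2 -> cls_hidden ... -> C` with ReLU between hidden
#' layers; outputs row-normalized log-probabilities.
#'
#' @param Z_cond_sp n x d2 condition-specific residual block.
#' @param params model parameters.
#' @return n x C log-probability matrix (rows of `exp(.)` sum to 1).
#' @export
classify_condition <- function(Z_cond_sp, params) {
  logits <- mlp_forward(params$cls, Z_cond_sp, final_act = "linear")$out
  log_softmax(logits)
}

log_softmax <- function(logits) {
  mx <- apply(logits, 1, max)
  shifted <- logits - mx
  shifted - log(rowSums(exp(shifted)))
}

#' Decoder
#'
#' Three fully connected layers mapping `[Z_bio, Z_cond, B]` back to the
#' preprocessed gene expression space, ReLU between hidden layers, linear
#' output (z-scored targets are signed).
#'
#' @param Z_bio,Z_cond latent blocks; `Z_cond` (not the residual) is decoded.
#' @param B batch one-hot block.
#' @param params model parameters.
#' @return n x m reconstruction.
#' @export
decode <- function(Z_bio, Z_cond, B, params) {
  D <- cbind(Z_bio, Z_cond, B)
  if (ncol(D) != nrow(params$dec[[1]]$W))
    stop("decode: input dimension ", ncol(D),
         " does not match decoder fan-in ", nrow(params$dec[[1]]$W))
  mlp_forward(params$dec, D, final_act = "linear")$out
}

# Full forward pass. In train mode noise matrices must be supplied (drawn by
# the caller so that seeding is centralized); in eval mode latents equal the
# mean heads and DSBN uses running statistics.
model_forward <- function(params, dsbn_state, X, B, cond_codes, config,
                          mode = c("train", "eval"),
                          noise_bio = NULL, noise_cond = NULL) {
  mode <- match.arg(mode)
  n <- nrow(X)
  enc_fw <- mlp_forward(params$enc, cbind(X, B), final_act = "relu")
  L <- enc_fw$out
  mu_bio <- linear(L, params$mu_bio)
  lv_bio <- linear(L, params$lv_bio)
  var_bio <- exp(lv_bio)
  mu_cond <- linear(L, params$mu_cond)
  lv_cond <- linear(L, params$lv_cond)
  var_cond <- exp(lv_cond)
  if (mode == "eval" || is.null(noise_bio)) noise_bio <- matrix(0, n, config$d1)
  if (mode == "eval" || is.null(noise_cond)) noise_cond <- matrix(0, n, config$d2)
  Z_bio <- reparameterize(mu_bio, var_bio, noise_bio, config$reparam_scale)
  Z_cond <- reparameterize(mu_cond, var_cond, noise_cond, config$reparam_scale)
  ds <- dsbn_forward(Z_cond, cond_codes, dsbn_state, mode, eps = config$eps_bn,
                     gamma = params$dsbn_gamma, beta = params$dsbn_beta)
  Z_sp <- condition_residual(Z_cond, ds$out)
  cls_fw <- mlp_forward(params$cls, Z_sp, final_act = "linear")
  cls_logprob <- log_softmax(cls_fw$out)
  dec_fw <- mlp_forward(params$dec, cbind(Z_bio, Z_cond, B), final_act = "linear")
  list(
    L = L, enc_fw = enc_fw,
    mu_bio = mu_bio, lv_bio = lv_bio, var_bio = var_bio, Z_bio = Z_bio,
    mu_cond = mu_cond, lv_cond = lv_cond, var_cond = var_cond, Z_cond = Z_cond,
    Z_cond_shared = ds$out, Z_cond_sp = Z_sp,
    dsbn_state = ds$state, dsbn_cache = ds$cache,
    cls_fw = cls_fw, cls_logprob = cls_logprob,
    dec_fw = dec_fw, X_tilde = dec_fw$out,
    noise_bio = noise_bio, noise_cond = noise_cond, mode = mode
  )
}

# Gradient of the total loss
#   scale_r * (recon + lambda * kl) + mu_cls * mean cross-entropy
# with respect to every parameter. `scale_r` rescales the minibatch sums to
# the full-data objective (n_total / n_minibatch).
model_backward <- function(params, fw, X, B, cond_codes, config, scale_r = 1) {
  n <- nrow(X)
  lam <- config$lambda_kl
  muw <- config$mu_cls

  grads <- list()

  # decoder: recon = scale_r * sum (x - xt)^2
  dXt <- scale_r * 2 * (fw$X_tilde - X)
  dec_bw <- mlp_backward(params$dec, fw$dec_fw, dXt, final_act = "linear")
  grads$dec <- dec_bw$grads
  dZ_bio <- dec_bw$dX[, seq_len(config$d1), drop = FALSE]
  dZ_cond <- dec_bw$dX[, config$d1 + seq_len(config$d2), drop = FALSE]

  # classifier: mu_cls * mean(-logp[true])
  Y <- matrix(0, n, config$C)
  Y[cbind(seq_len(n), cond_codes + 1L)] <- 1
  dlogits <- (exp(fw$cls_logprob) - Y) * (muw / n)
  cls_bw <- mlp_backward(params$cls, fw$cls_fw, dlogits, final_act = "linear")
  grads$cls <- cls_bw$grads
  dZ_sp <- cls_bw$dX

  # residual Z_sp = Z_cond - Z'  ->  dZ_cond += dZ_sp ; dZ' = -dZ_sp
  if (!config$alternating_cls) {
    bn_bw <- dsbn_backward(-dZ_sp, fw$dsbn_cache, fw$mode,
                           gamma = params$dsbn_gamma,
                           C = config$C, d2 = config$d2)
    dZ_cond <- dZ_cond + dZ_sp + bn_bw$dZ
    if (config$dsbn_affine) {
      grads$dsbn_gamma <- bn_bw$dgamma
      grads$dsbn_beta <- bn_bw$dbeta
    }
  } else if (config$dsbn_affine) {
    # affine DSBN parameters still learn from the classifier signal
    bn_bw <- dsbn_backward(-dZ_sp, fw$dsbn_cache, fw$mode,
                           gamma = params$dsbn_gamma,
                           C = config$C, d2 = config$d2)
    grads$dsbn_gamma <- bn_bw$dgamma
    grads$dsbn_beta <- bn_bw$dbeta
  }

  # reparameterization + KL for both latent blocks
  bk <- latent_backward(dZ_bio, fw$mu_bio, fw$lv_bio, fw$var_bio,
                        fw$noise_bio, lam * scale_r, config$reparam_scale)
  ck <- latent_backward(dZ_cond, fw$mu_cond, fw$lv_cond, fw$var_cond,
                        fw$noise_cond, lam * scale_r, config$reparam_scale)

  L <- fw$L
  grads$mu_bio <- list(W = crossprod(L, bk$dmu), b = colSums(bk$dmu))
  grads$lv_bio <- list(W = crossprod(L, bk$dlv), b = colSums(bk$dlv))
  grads$mu_cond <- list(W = crossprod(L, ck$dmu), b = colSums(ck$dmu))
  grads$lv_cond <- list(W = crossprod(L, ck$dlv), b = colSums(ck$dlv))

  dL <- tcrossprod(bk$dmu, params$mu_bio$W) + tcrossprod(bk$dlv, params$lv_bio$W) +
        tcrossprod(ck$dmu, params$mu_cond$W) + tcrossprod(ck$dlv, params$lv_cond$W)
  enc_bw <- mlp_backward(params$enc, fw$enc_fw, dL, final_act = "relu")
  grads$enc <- enc_bw$grads
  grads
}

# dZ flows into mu and log-variance through the reparameterization; the KL
# term 0.5 * sum(mu^2 + var - 1 - log var) adds kl_w * mu to dmu and
# kl_w * 0.5 * (var - 1) to dlv.
latent_backward <- function(dZ, mu, lv, var, noise, kl_w, scale) {
  dmu <- dZ + kl_w * mu
  dvar_rep <- if (scale == "variance") dZ * noise else dZ * noise * 0.5 / sqrt(var)
  dlv <- dvar_rep * var + kl_w * 0.5 * (var - 1)
  list(dmu = dmu, dlv = dlv)
}

# --- parameter tree utilities (Adam lives on the same nested structure) ----

walk_tree <- function(x, f) {
  if (is.list(x)) lapply(x, walk_tree, f = f) else f(x)
}

walk_tree2 <- function(x, y, f) {
  if (is.list(x)) {
    out <- vector("list", length(x))
    names(out) <- names(x)
    keys <- if (!is.null(names(x)) && all(nzchar(names(x)))) names(x) else seq_along(x)
    for (i in seq_along(x)) out[[i]] <- walk_tree2(x[[i]], y[[keys[i]]], f)
    out
  } else f(x, y)
}

flatten_tree <- function(x) {
  if (is.list(x)) unlist(lapply(x, flatten_tree), use.names = FALSE) else as.numeric(x)
}

#' Save / load a model checkpoint
#'
#' Serializes parameters, DSBN running statistics, label coding tables, gene
#' identifiers, configuration and training history to a single file (RDS).
#'
#' @param state a train state from [fit_model()].
#' @param path destination file.
#' @return `path` invisibly; `load_checkpoint` returns the train state.
#' @export
save_checkpoint <- function(state, path) {
  saveRDS(unclass(state), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  structure(readRDS(path), class = "condiva_state")
}
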