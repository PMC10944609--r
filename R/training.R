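# Adam optimizer over the nested parameter tree.

adam_init <- function(params) {
  list(m = walk_tree(params, function(x) x * 0),
       v = walk_tree(params, function(x) x * 0),
       t = 0L)
}

adam_step <- function(params, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1L
  opt$m <- walk_tree2(opt$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  opt$v <- walk_tree2(opt$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  mhat <- walk_tree(opt$m, function(m) m / bc1)
  vhat <- walk_tree(opt$v, function(v) v / bc2)
  step <- walk_tree2(mhat, vhat, function(m, v) lr * m / (sqrt(v) + eps))
  params <- walk_tree2(params, step, function(p, s) p - s)
  list(params = params, opt = opt)
}

#' Fit the integration model
#'
#' Trains the disentangling VAE on a preprocessed (z-scored) dataset with
#' Adam over shuffled minibatches. Minibatches are drawn across all
#' conditions jointly; DSBN normalizes the condition subsets present in each
#' minibatch. Per-minibatch reconstruction and KL sums are rescaled by
#' `n / minibatch` so the full-data objective is optimized regardless of the
#' minibatch size, while the classification term is a per-cell mean.
#' Classifier gradients flow back into the encoders (joint backpropagation)
#' unless `alternating_cls` is set in the configuration. The run seed
#' controls parameter initialization, shuffling and reparameterization noise,
#' so two single-threaded runs with the same seed are identical.
#'
#' @param ds an `expression_dataset` at stage `zscored` with batch and
#'   condition labels.
#' @param config a [model_config()]; `m`, `b`, `C` must match the dataset.
#' @return a `condiva_state` with parameters, DSBN running statistics,
#'   per-epoch loss history, label coding tables and gene identifiers.
#' @export
fit_model <- function(ds, config) {
  require_stage(ds, "zscored", "fit_model")
  n <- n_cells(ds)
  m <- n_genes(ds)
  if (m != config$m)
    stop("config m (", config$m, ") does not match dataset genes (", m, ")")
  if (nlevels(ds$batch) != config$b)
    stop("config b (", config$b, ") does not match dataset batches (",
         nlevels(ds$batch), ")")
  if (nlevels(ds$condition) != config$C)
    stop("config C (", config$C, ") does not match dataset conditions (",
         nlevels(ds$condition), ")")
  cond_counts <- table(ds$condition)
  if (any(cond_counts == 0))
    stop("condition level(s) with zero cells: ",
         paste(names(cond_counts)[cond_counts == 0], collapse = ", "))

  X <- as.matrix(ds$matrix)
  B <- one_hot(ds$batch)
  codes <- label_codes(ds$condition)

  set.seed(config$seed)
  params <- init_params(config)
  dsbn <- init_dsbn_state(config)
  opt <- adam_init(params)

  history <- data.frame(epoch = integer(0), recon = numeric(0),
                        kl = numeric(0), cls = numeric(0), total = numeric(0))
  mb <- min(config$minibatch, n)
  for (epoch in seq_len(config$epochs)) {
    perm <- sample.int(n)
    starts <- seq(1, n, by = mb)
    ep_recon <- 0; ep_kl <- 0; ep_cls <- 0; n_batches <- 0
    for (s in starts) {
      idx <- perm[s:min(s + mb - 1, n)]
      k <- length(idx)
      # "mean": per-entry mean of the VAE terms; "sum": full-data sums
      scale_r <- if (config$loss_reduction == "mean") 1 / (k * m) else n / k
      noise_bio <- matrix(stats::rnorm(k * config$d1), k, config$d1)
      noise_cond <- matrix(stats::rnorm(k * config$d2), k, config$d2)
      fw <- model_forward(params, dsbn, X[idx, , drop = FALSE],
                          B[idx, , drop = FALSE], codes[idx], config,
                          mode = "train", noise_bio = noise_bio,
                          noise_cond = noise_cond)
      dsbn <- fw$dsbn_state
      grads <- model_backward(params, fw, X[idx, , drop = FALSE],
                              B[idx, , drop = FALSE], codes[idx], config,
                              scale_r = scale_r)
      st <- adam_step(params, grads, opt, config$lr)
      params <- st$params
      opt <- st$opt
      # epoch bookkeeping: unscaled minibatch sums add up to full-data sums
      ep_recon <- ep_recon + reconstruction_loss(X[idx, , drop = FALSE], fw$X_tilde)
      ep_kl <- ep_kl + kl_loss(fw$mu_bio, fw$var_bio, fw$mu_cond, fw$var_cond)
      ep_cls <- ep_cls + classification_loss(fw$cls_logprob, codes[idx]) * k
      n_batches <- n_batches + 1
    }
    red <- if (config$loss_reduction == "mean") 1 / (n * m) else 1
    bd <- total_loss(ep_recon * red, ep_kl * red, ep_cls / n,
                     config$lambda_kl, config$mu_cls)
    history <- rbind(history, data.frame(epoch = epoch, recon = bd$recon,
                                         kl = bd$kl, cls = bd$cls,
                                         total = bd$total))
  }

  structure(list(
    params = params,
    dsbn = dsbn,
    config = config,
    history = history,
    gene_ids = ds$gene_ids,
    batch_levels = levels(ds$batch),
    condition_levels = levels(ds$condition)
  ), class = "condiva_state")
}

#' @export
print.condiva_state <- function(x, ...) {
  cat("condiva_state: trained ", nrow(x$history), " epochs on ",
      length(x$gene_ids), " genes; final total loss ",
      format(x$history$total[nrow(x$history)], digits = 6), "\n", sep = "")
  invisible(x)
}

#' Integrate cells: eval-mode latent bundle
#'
#' Runs a deterministic eval-mode forward pass (latents equal the mean heads;
#' DSBN uses running statistics) and returns every latent block for all
#' cells. Gene identifiers and label levels must match training; unseen batch
#' or condition levels raise an error rather than being silently re-coded.
#'
#' @param state a `condiva_state` from [fit_model()].
#' @param ds an `expression_dataset` at stage `zscored`.
#' @return a `latent_bundle` list: `L`, `mu_bio`/`var_bio`/`Z_bio`,
#'   `mu_cond`/`var_cond`/`Z_cond`, `Z_cond_shared`, `Z_cond_sp`,
#'   `cls_logprob`, plus the cell ids and labels.
#' @export
transform_cells <- function(state, ds) {
  require_stage(ds, "zscored", "transform_cells")
  if (!identical(ds$gene_ids, state$gene_ids))
    stop("gene set does not match the training gene set")
  unseen_b <- setdiff(levels(ds$batch), state$batch_levels)
  if (length(unseen_b) > 0)
    stop("unseen batch level(s): ", paste(unseen_b, collapse = ", "))
  unseen_c <- setdiff(levels(ds$condition), state$condition_levels)
  if (length(unseen_c) > 0)
    stop("unseen condition level(s): ", paste(unseen_c, collapse = ", "))
  X <- as.matrix(ds$matrix)
  B <- one_hot(ds$batch, levels = state$batch_levels)
  codes <- as.integer(factor(as.character(ds$condition),
                             levels = state$condition_levels)) - 1L
  fw <- model_forward(state$params, state$dsbn, X, B, codes, state$config,
                      mode = "eval")
  structure(list(
    L = fw$L,
    mu_bio = fw$mu_bio, var_bio = fw$var_bio, Z_bio = fw$Z_bio,
    mu_cond = fw$mu_cond, var_cond = fw$var_cond, Z_cond = fw$Z_cond,
    Z_cond_shared = fw$Z_cond_shared, Z_cond_sp = fw$Z_cond_sp,
    cls_logprob = fw$cls_logprob,
    cell_ids = ds$cell_ids, batch = ds$batch, condition = ds$condition,
    cell_type = ds$cell_type
  ), class = "latent_bundle")
}

#' Write the per-epoch loss history as CSV
#' @param state a `condiva_state`.
#' @param path destination CSV (columns epoch, recon, kl, cls, total).
#' @return `path` invisibly.
#' @export
write_loss_log <- function(state, path) {
  utils::write.csv(state$history, path, row.names = FALSE)
  invisible(path)
}
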