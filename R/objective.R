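#' Reconstruction loss
#'
#' Sum of squared differences over all entries (not reduced by the number of
#' cells), matching the squared-error form of the negative Gaussian
#' log-likelihood with the observation constant absorbed.
#'
#' @param X,X_tilde matrices of identical shape.
#' @return a nonnegative scalar.
#' @export
reconstruction_loss <- function(X, X_tilde) {
  if (!identical(dim(X), dim(X_tilde)))
    stop("reconstruction_loss: shape mismatch")
  sum((X - X_tilde)^2)
}

#' KL divergence to the standard-normal prior
#'
#' Closed form `0.5 * sum(mu^2 + var - 1 - log var)` summed over both latent
#' blocks (mean-field factorization over the bio and condition latents).
#'
#' @param mu_bio,var_bio bio-latent mean and variance matrices.
#' @param mu_cond,var_cond condition-latent mean and variance matrices.
#' @return a nonnegative scalar.
#' @export
kl_loss <- function(mu_bio, var_bio, mu_cond, var_cond) {
  if (any(var_bio <= 0) || any(var_cond <= 0))
    stop("kl_loss: variances must be strictly positive")
  kl_block(mu_bio, var_bio) + kl_block(mu_cond, var_cond)
}

kl_block <- function(mu, var) 0.5 * sum(mu^2 + var - 1 - log(var))

#' Condition classification loss
#'
#' Mean over cells of the negative log-probability of the true condition
#' (cross-entropy with one-hot targets).
#'
#' @param cls_logprob n x C log-probability matrix.
#' @param codes 0-based true condition codes.
#' @return a nonnegative scalar.
#' @export
classification_loss <- function(cls_logprob, codes) {
  n <- nrow(cls_logprob)
  if (length(codes) != n) stop("classification_loss: length mismatch")
  if (any(codes < 0 | codes >= ncol(cls_logprob)))
    stop("classification_loss: code out of range")
  -mean(cls_logprob[cbind(seq_len(n), codes + 1L)])
}

#' Compose the three-term training objective
#'
#' `total = recon + lambda_kl * kl + mu_cls * cls`.
#'
#' @param recon,kl,cls the three loss components.
#' @param lambda_kl KL weight (default 0.001).
#' @param mu_cls classification weight (default 0.001).
#' @return a `loss_breakdown` list with fields `recon`, `kl`, `cls`, `total`.
#' @export
total_loss <- function(recon, kl, cls, lambda_kl = 0.001, mu_cls = 0.001) {
  if (lambda_kl < 0 || mu_cls < 0) stop("loss weights must be nonnegative")
  structure(list(recon = recon, kl = kl, cls = cls,
                 total = recon + lambda_kl * kl + mu_cls * cls),
            class = "loss_breakdown")
}

# loss of a forward pass on one block of data (sums over the block)
forward_losses <- function(fw, X, codes, config, scale_r = 1) {
  recon <- scale_r * reconstruction_loss(X, fw$X_tilde)
  kl <- scale_r * kl_loss(fw$mu_bio, fw$var_bio, fw$mu_cond, fw$var_cond)
  cls <- classification_loss(fw$cls_logprob, codes)
  total_loss(recon, kl, cls, config$lambda_kl, config$mu_cls)
}
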