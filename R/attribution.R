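# Condition-specific gene selection: unit deviations of the condition-specific
# residual embedding are backpropagated (vector-Jacobian product) through the
# eval-mode input -> Z_sp map to the gene expression space, and genes are
# ranked by the averaged signed gradient.

#' Unit deviation between a query cell and reference cells
#'
#' `(query - mean(refs)) / ||query - mean(refs)||` in the condition-specific
#' embedding space; the direction of movement from the reference conditions
#' towards the query cell.
#'
#' @param query_embedding length-d2 embedding of the query cell.
#' @param ref_embeddings reference embeddings, one row per reference cell.
#' @param tol deviations with Euclidean norm below `tol` are degenerate and
#'   yield `NULL` (the caller skips the cell).
#' @return a unit vector of length d2, or `NULL`.
#' @export
deviation_vector <- function(query_embedding, ref_embeddings, tol = 1e-12) {
  d <- query_embedding - colMeans(ref_embeddings)
  nrm <- sqrt(sum(d^2))
  if (nrm < tol) return(NULL)
  d / nrm
}

#' Gene-space gradient of the condition-specific embedding
#'
#' Computes the vector-Jacobian product of the eval-mode map from the
#' preprocessed expression row to the condition-specific residual embedding
#' `Z_sp`, contracted with a direction `delta_z`. The batch one-hot is held
#' fixed and DSBN running statistics are treated as constants.
#'
#' @param state a `condiva_state`.
#' @param cell_input length-m preprocessed (z-scored) expression row.
#' @param batch_code 0-based batch code of the cell.
#' @param cond_code 0-based condition code of the cell (selects the DSBN
#'   branch).
#' @param delta_z length-d2 direction in the `Z_sp` space.
#' @return length-m gradient vector over genes.
#' @export
gene_gradient <- function(state, cell_input, batch_code, cond_code, delta_z) {
  X <- matrix(cell_input, nrow = 1)
  D <- matrix(delta_z, nrow = 1)
  gene_gradient_block(state, X, batch_code, cond_code, D)[1, ]
}

# vectorized VJP: one row of X / codes / delta per cell. Rows are independent
# in eval mode, so a single forward + backward covers all query cells.
gene_gradient_block <- function(state, X, batch_codes, cond_codes, delta) {
  config <- state$config
  B <- matrix(0, nrow(X), config$b)
  B[cbind(seq_len(nrow(X)), batch_codes + 1L)] <- 1
  fw <- model_forward(state$params, state$dsbn, X, B, cond_codes, config,
                      mode = "eval")
  # Z_sp = Z_cond - Z'(Z_cond); eval-mode DSBN is an affine map per domain
  bn_bw <- dsbn_backward(-delta, fw$dsbn_cache, "eval",
                         gamma = state$params$dsbn_gamma,
                         C = config$C, d2 = config$d2)
  dZ_cond <- delta + bn_bw$dZ
  # eval: Z_cond = mu_cond (noise = 0), so only the mean head carries gradient
  dL <- tcrossprod(dZ_cond, state$params$mu_cond$W)
  enc_bw <- mlp_backward(state$params$enc, fw$enc_fw, dL, final_act = "relu")
  enc_bw$dX[, seq_len(config$m), drop = FALSE]
}

#' Rank condition-specific genes
#'
#' For every cell of the query condition, samples 5 reference cells from the
#' union of all other conditions, forms the unit deviation of the
#' condition-specific embeddings, backpropagates it to the gene space, and
#' averages the per-gene gradients over all query cells. Genes are ranked by
#' descending signed mean gradient (higher gradient = expression pushing
#' cells towards the query condition); ties break by gene identifier.
#'
#' Reference sampling is without replacement when at least 5 references
#' exist, with replacement otherwise. Each query cell draws from an RNG
#' substream keyed by its stable cell identifier, and reference cells are
#' indexed in cell-id order, so the ranking is invariant to the row order of
#' the dataset.
#'
#' @param state a `condiva_state`.
#' @param ds the `expression_dataset` (stage `zscored`) the model was fit on.
#' @param query_condition condition level to score.
#' @param top_k number of top genes to report (default 15).
#' @param seed integer seed for the reference sampling.
#' @param n_ref reference cells per query cell (default 5).
#' @return a `gene_score_table` list: `condition`, `gradient_mean` (named
#'   length-m vector), `ranked_genes`, `top_genes`, `top_k`, `n_query_used`.
#' @export
rank_condition_genes <- function(state, ds, query_condition, top_k = 15,
                                 seed = 0, n_ref = 5) {
  lev <- as.character(query_condition)
  if (!lev %in% levels(ds$condition))
    stop("unknown condition level: ", lev)
  if (nlevels(droplevels(ds$condition)) < 2)
    stop("gene ranking needs at least two condition levels (no reference exists)")
  bundle <- transform_cells(state, ds)
  q_idx <- which(as.character(ds$condition) == lev)
  r_idx <- which(as.character(ds$condition) != lev)
  if (length(q_idx) == 0) stop("query condition has no cells: ", lev)
  # reference pool in stable cell-id order (row-order invariance)
  r_idx <- r_idx[order(ds$cell_ids[r_idx])]
  Zsp <- bundle$Z_cond_sp

  deltas <- matrix(0, length(q_idx), ncol(Zsp))
  used <- logical(length(q_idx))
  replace <- length(r_idx) < n_ref
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  for (i in seq_along(q_idx)) {
    q <- q_idx[i]
    set.seed(substream_seed(seed, ds$cell_ids[q]))
    sel <- r_idx[sample.int(length(r_idx), n_ref, replace = replace)]
    dz <- deviation_vector(Zsp[q, ], Zsp[sel, , drop = FALSE])
    if (is.null(dz)) {
      message("skipping cell ", ds$cell_ids[q], ": zero-norm deviation")
      next
    }
    deltas[i, ] <- dz
    used[i] <- TRUE
  }
  if (!any(used)) stop("no usable query cell (all deviations degenerate)")
  q_used <- q_idx[used]
  G <- gene_gradient_block(state, as.matrix(ds$matrix)[q_used, , drop = FALSE],
                           label_codes(ds$batch)[q_used],
                           label_codes(ds$condition)[q_used],
                           deltas[used, , drop = FALSE])
  gradient_mean <- colMeans(G)
  names(gradient_mean) <- ds$gene_ids
  ord <- order(-gradient_mean, ds$gene_ids)
  ranked <- ds$gene_ids[ord]
  structure(list(
    condition = lev,
    gradient_mean = gradient_mean,
    ranked_genes = ranked,
    top_genes = utils::head(ranked, top_k),
    top_k = as.integer(top_k),
    n_query_used = length(q_used)
  ), class = "gene_score_table")
}

# deterministic 31-bit substream seed from a base seed and a stable string key
substream_seed <- function(seed, key) {
  h <- as.double(seed %% 2147483647)
  for (code in utf8ToInt(key)) h <- (h * 31 + code) %% 2147483647
  as.integer(h)
}

#' @export
print.gene_score_table <- function(x, ...) {
  cat("gene_score_table for condition '", x$condition, "' (",
      x$n_query_used, " query cells)\n", sep = "")
  cat("top ", x$top_k, ": ", paste(x$top_genes, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Write a gene score table as TSV
#'
#' Emits `top_k` rows with columns condition, rank, gene_id, gradient_mean.
#'
#' @param table a `gene_score_table`.
#' @param path destination TSV.
#' @return `path` invisibly.
#' @export
write_gene_scores <- function(table, path) {
  df <- data.frame(
    condition = table$condition,
    rank = seq_len(table$top_k),
    gene_id = table$top_genes,
    gradient_mean = unname(table$gradient_mean[table$top_genes])
  )
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
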