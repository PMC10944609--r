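#' Filter low-coverage cells and unexpressed genes
#'
#' Removes cells expressing fewer than `min_genes` genes (value > 0) and
#' genes expressed in zero cells. Both masks are computed on the raw matrix
#' and applied in a single sweep (no iterative re-filtering), so the result
#' is reproducible and order-independent.
#'
#' @param ds an `expression_dataset` at stage `raw`.
#' @param min_genes minimum number of expressed genes per retained cell
#'   (default 200).
#' @return the filtered dataset, still at stage `raw`.
#' @export
filter_cells_genes <- function(ds, min_genes = 200) {
  require_stage(ds, "raw", "filter_cells_genes")
  if (any(ds$matrix < 0)) stop("raw counts must be nonnegative")
  nz <- ds$matrix > 0
  gene_keep <- Matrix::colSums(nz) >= 1
  cell_keep <- Matrix::rowSums(nz) >= min_genes
  if (!any(cell_keep))
    stop("all cells removed: no cell expresses >= ", min_genes, " genes")
  if (!any(gene_keep)) stop("all genes removed: matrix is empty")
  subset_dataset(ds, cells = which(cell_keep), genes = which(gene_keep))
}

#' Library-size normalization
#'
#' Divides each cell's counts by its library size factor, defined as the
#' cell's total count divided by the median total count over all cells.
#' After normalization every cell total equals the median raw total.
#'
#' @param ds an `expression_dataset` at stage `raw` (post-filtering).
#' @return the normalized dataset at stage `normalized`.
#' @export
normalize_library_size <- function(ds) {
  require_stage(ds, "raw", "normalize_library_size")
  totals <- Matrix::rowSums(ds$matrix)
  med <- stats::median(totals)
  if (med == 0) stop("degenerate input: median library size is zero")
  factors <- totals / med
  factors[factors == 0] <- 1    # empty cells (possible pre-filter) untouched
  ds$matrix <- ds$matrix / factors
  advance_stage(ds, "normalized")
}

#' Log transform and highly variable gene selection
#'
#' Values are replaced by `log(1 + x)` and the `n_hvg` most highly variable
#' genes are retained. Variability is ranked by the binned normalized
#' dispersion of the normalized (pre-log) values: per gene, dispersion =
#' variance / mean; genes are grouped into `n_bins` equal-frequency bins of
#' their mean and the dispersion is z-scored within each bin. Ties are broken
#' by gene identifier order.
#'
#' @param ds an `expression_dataset` at stage `normalized`.
#' @param n_hvg number of genes to keep (default 3000); clamped to the number
#'   of genes available.
#' @param n_bins number of mean-expression bins (default 20).
#' @return the log-transformed, gene-subset dataset at stage `hvg`.
#' @export
log_select_hvg <- function(ds, n_hvg = 3000, n_bins = 20) {
  require_stage(ds, "normalized", "log_select_hvg")
  X <- as.matrix(ds$matrix)
  m <- ncol(X)
  keep_n <- min(n_hvg, m)
  disp_norm <- normalized_dispersion(X, n_bins)
  ord <- order(-disp_norm, ds$gene_ids)
  keep <- sort(ord[seq_len(keep_n)])
  ds$matrix <- log1p(X)
  ds <- advance_stage(ds, "log")
  ds <- subset_dataset(ds, genes = keep)
  advance_stage(ds, "hvg")
}

# binned normalized dispersion of normalized expression values
normalized_dispersion <- function(X, n_bins = 20) {
  mu <- colMeans(X)
  v <- colMeans(X^2) - mu^2
  disp <- ifelse(mu > 0, v / mu, 0)
  breaks <- unique(stats::quantile(mu, probs = seq(0, 1, length.out = n_bins + 1)))
  if (length(breaks) < 2) {
    bin <- rep(1L, length(mu))
  } else {
    bin <- cut(mu, breaks = breaks, include.lowest = TRUE, labels = FALSE)
  }
  out <- numeric(length(disp))
  for (b in unique(bin)) {
    idx <- which(bin == b)
    s <- stats::sd(disp[idx])
    ctr <- disp[idx] - mean(disp[idx])
    out[idx] <- if (is.na(s) || s == 0) 0 else ctr / s
  }
  out
}

#' Per-gene z-scoring
#'
#' Centers and scales each gene to zero mean and unit variance across cells,
#' using the population (1/n) variance convention. Zero-variance genes are
#' set to all-zero columns with a message rather than an error.
#'
#' @param ds an `expression_dataset` at stage `hvg`.
#' @return the dense z-scored dataset at stage `zscored`.
#' @export
zscore_genes <- function(ds) {
  require_stage(ds, "hvg", "zscore_genes")
  X <- as.matrix(ds$matrix)
  mu <- colMeans(X)
  sdv <- sqrt(colMeans(X^2) - mu^2)
  zero <- sdv <= 0 | !is.finite(sdv)
  if (any(zero)) {
    message(sum(zero), " zero-variance gene(s) set to all-zero columns")
    sdv[zero] <- 1
  }
  X <- sweep(X, 2, mu, "-")
  X <- sweep(X, 2, sdv, "/")
  X[, zero] <- 0
  ds$matrix <- X
  advance_stage(ds, "zscored")
}

#' Run the full preprocessing pipeline
#'
#' filter -> library-size normalize -> log1p + HVG selection -> z-score.
#' Deterministic: identical input yields bit-identical output, and cells are
#' never reordered.
#'
#' @param ds an `expression_dataset` at stage `raw`.
#' @param n_hvg number of highly variable genes to keep (default 3000).
#' @param min_genes minimum expressed genes per cell (default 200).
#' @return an `expression_dataset` at stage `zscored`.
#' @export
preprocess_dataset <- function(ds, n_hvg = 3000, min_genes = 200) {
  ds <- filter_cells_genes(ds, min_genes = min_genes)
  ds <- normalize_library_size(ds)
  ds <- log_select_hvg(ds, n_hvg = n_hvg)
  zscore_genes(ds)
}
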