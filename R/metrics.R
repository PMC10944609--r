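# Integration benchmarking: k-means labeling, ARI/NMI partition agreement,
# silhouette-derived batch-mixing and cell-type-purity scores, and the
# stratified repeated-subsampling protocol.

#' k-means cluster labels on an embedding
#'
#' Deterministic given the seed. When evaluating integration quality the
#' number of clusters equals the number of true cell types.
#'
#' @param Z n x k embedding.
#' @param n_clusters number of clusters (`<= n`).
#' @param seed integer seed.
#' @return integer labels of length n.
#' @export
kmeans_labels <- function(Z, n_clusters, seed = 0) {
  if (n_clusters > nrow(Z)) stop("n_clusters exceeds the number of cells")
  if (n_clusters == 1) return(rep(1L, nrow(Z)))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  stats::kmeans(Z, centers = n_clusters, nstart = 10, iter.max = 100)$cluster
}

#' Adjusted Rand index
#'
#' Pair-counting agreement between two partitions, adjusted for chance;
#' ranges over \[-1, 1\] with 1 for identical partitions.
#'
#' @param labels_a,labels_b label vectors of equal length.
#' @return a scalar in \[-1, 1\].
#' @export
ari <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) stop("ari: length mismatch")
  tab <- table(labels_a, labels_b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  total <- choose2(length(labels_a))
  expected <- sum_a * sum_b / total
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(if (sum_ij == expected) 1 else 0)
  (sum_ij - expected) / (max_index - expected)
}

#' Normalized mutual information
#'
#' Mutual information between two partitions normalized by the arithmetic
#' mean of their entropies; 1 for identical partitions, 0 for independent
#' ones.
#'
#' @param labels_a,labels_b label vectors of equal length.
#' @return a scalar in \[0, 1\].
#' @export
nmi <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) stop("nmi: length mismatch")
  n <- length(labels_a)
  tab <- table(labels_a, labels_b) / n
  pa <- rowSums(tab)
  pb <- colSums(tab)
  nz <- tab > 0
  mi <- sum(tab[nz] * log(tab[nz] / outer(pa, pb)[nz]))
  ha <- -sum(pa[pa > 0] * log(pa[pa > 0]))
  hb <- -sum(pb[pb > 0] * log(pb[pb > 0]))
  denom <- (ha + hb) / 2
  if (denom == 0) return(if (mi == 0) 1 else 0)
  max(0, min(1, mi / denom))
}

# mean silhouette width with Euclidean distance; label classes with fewer
# than 2 members contribute 0 (with a notice); a single overall class gives 0
mean_silhouette <- function(Z, labels) {
  labels <- as.character(labels)
  if (length(unique(labels)) < 2) {
    message("silhouette undefined for a single label class; returning 0")
    return(0)
  }
  counts <- table(labels)
  if (any(counts < 2))
    message(sum(counts < 2), " singleton label class(es): those cells contribute 0")
  sil <- cluster::silhouette(as.integer(factor(labels)), stats::dist(Z))
  mean(sil[, "sil_width"])
}

#' Silhouette-derived integration scores
#'
#' `CASW = (1 + s_celltype) / 2` rewards cell-type purity;
#' `BASW = 1 - (1 + s_batch) / 2` rewards batch mixing (batches inseparable
#' in the embedding); `ASW` is their arithmetic mean and `F1` their harmonic
#' mean, where `s_x` is the mean silhouette width under labeling `x`. All
#' four lie in \[0, 1\]; `F1 <= ASW` always.
#'
#' @param Z n x k embedding.
#' @param celltype per-cell cell-type labels.
#' @param batch per-cell batch labels.
#' @return named list with `BASW`, `CASW`, `ASW`, `F1`.
#' @export
asw_components <- function(Z, celltype, batch) {
  casw <- (1 + mean_silhouette(Z, celltype)) / 2
  basw <- 1 - (1 + mean_silhouette(Z, batch)) / 2
  asw <- (basw + casw) / 2
  f1 <- if (basw + casw == 0) 0 else 2 * basw * casw / (basw + casw)
  list(BASW = basw, CASW = casw, ASW = asw, F1 = f1)
}

#' Evaluate an integration with repeated stratified subsampling
#'
#' Per replicate, draws a stratified subsample keeping
#' `ceiling(fraction * n_t)` cells of every cell type, clusters the
#' bio embedding `Z_bio` with k-means (k = number of cell types present),
#' and computes ARI, NMI, BASW, CASW, ASW and F1. With `fraction = 1` and
#' `n_replicates = 1` this reproduces the no-sampling path used for large
#' datasets.
#'
#' @param bundle a `latent_bundle` from [transform_cells()] (cell-type labels
#'   required).
#' @param n_replicates number of subsampling replicates (default 10).
#' @param fraction per-stratum subsample fraction (default 0.95).
#' @param seed integer seed.
#' @return a `metrics_report`: `replicates` data frame (one row each),
#'   `summary` (mean and sd per metric), plus the protocol settings.
#' @export
evaluate_integration <- function(bundle, n_replicates = 10, fraction = 0.95,
                                 seed = 0) {
  if (is.null(bundle$cell_type))
    stop("evaluate_integration requires cell-type labels")
  Z <- bundle$Z_bio
  ct <- as.character(bundle$cell_type)
  bt <- as.character(bundle$batch)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  rows <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    set.seed(seed + r - 1L)
    if (fraction >= 1) {
      idx <- seq_len(nrow(Z))
    } else {
      idx <- unlist(lapply(split(seq_len(nrow(Z)), ct), function(ii) {
        sample(ii, ceiling(fraction * length(ii)))
      }), use.names = FALSE)
      idx <- sort(idx)
    }
    k <- length(unique(ct[idx]))
    cl <- kmeans_labels(Z[idx, , drop = FALSE], k, seed = seed + r - 1L)
    asw <- asw_components(Z[idx, , drop = FALSE], ct[idx], bt[idx])
    rows[[r]] <- data.frame(
      replicate = r, n = length(idx), k = k,
      ARI = ari(cl, ct[idx]), NMI = nmi(cl, ct[idx]),
      BASW = asw$BASW, CASW = asw$CASW, ASW = asw$ASW, F1 = asw$F1
    )
  }
  reps <- do.call(rbind, rows)
  metric_cols <- c("ARI", "NMI", "BASW", "CASW", "ASW", "F1")
  summary <- data.frame(
    metric = metric_cols,
    mean = vapply(metric_cols, function(mc) mean(reps[[mc]]), numeric(1)),
    sd = vapply(metric_cols, function(mc) stats::sd(reps[[mc]]), numeric(1))
  )
  structure(list(replicates = reps, summary = summary,
                 n_replicates = n_replicates, fraction = fraction,
                 seed = seed),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("metrics_report: ", x$n_replicates, " replicate(s), ",
      round(100 * x$fraction), "% per-stratum subsampling\n", sep = "")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Write a metrics report
#'
#' @param report a `metrics_report`.
#' @param json_path optional JSON destination (replicates + summary).
#' @param csv_path optional CSV destination (one row per replicate plus a
#'   summary row of means).
#' @return the report, invisibly.
#' @export
write_metrics_report <- function(report, json_path = NULL, csv_path = NULL) {
  if (!is.null(json_path)) {
    jsonlite::write_json(list(replicates = report$replicates,
                              summary = report$summary,
                              n_replicates = report$n_replicates,
                              fraction = report$fraction),
                         json_path, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(csv_path)) {
    reps <- report$replicates
    summary_row <- reps[1, ]
    summary_row$replicate <- NA
    for (mc in c("ARI", "NMI", "BASW", "CASW", "ASW", "F1"))
      summary_row[[mc]] <- mean(reps[[mc]])
    utils::write.csv(rbind(reps, summary_row), csv_path, row.names = FALSE)
  }
  invisible(report)
}
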