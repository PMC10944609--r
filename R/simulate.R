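# Multi-batch, multi-condition negative-binomial count simulator with planted
# ground truth: per-cell-type marker programs, per-(gene, batch) log-scale
# batch shifts, and disjoint per-condition differentially expressed gene sets.

#' Simulation design
#'
#' The default design reproduces the benchmark composition: 3 conditions
#' (T1-T3) with 2 samples each (the sample id doubles as the batch label),
#' 6 cell types of which c1-c3 are shared and one type is absent per
#' condition (T1 lacks c4, T2 lacks c5, T3 lacks c6); every sample carries
#' 100 cells of each of its 5 present types, for 3000 cells total over 4977
#' genes, with 30 disjoint condition-specific DE genes per condition.
#'
#' Counts are drawn as NB(mean = exp(baseline + marker effect + batch shift +
#' condition DE shift), dispersion fixed); batch shifts are drawn once per
#' (gene, batch) from N(0, `batch_effect_sd`^2).
#'
#' @param n_conditions,samples_per_condition,n_cell_types,n_shared_types
#'   composition structure (defaults 3, 2, 6, 3). With the defaults each
#'   condition `i` excludes cell type `n_shared_types + i`.
#' @param cells_per_type cells of every present type in every sample
#'   (default 100).
#' @param n_genes gene count (default 4977).
#' @param n_condition_de_genes condition-specific DE genes per condition
#'   (default 30; sets are disjoint across conditions and from markers).
#' @param batch_effect_sd log-scale sd of the per-(gene, batch) shift
#'   (default 0.3).
#' @param condition_logfc log fold change planted on DE genes (default 1).
#' @param marker_genes_per_type,marker_logfc per-type expression program
#'   (defaults 50 genes at logFC 2).
#' @param baseline_meanlog,baseline_sdlog log-normal baseline mean expression
#'   (defaults 0, 1).
#' @param dispersion NB dispersion (variance = mu + dispersion * mu^2;
#'   default 0.5).
#' @param seed integer seed.
#' @return a `simulation_design` list including the condition x sample x
#'   cell-type `composition` count table.
#' @export
simulation_design <- function(n_conditions = 3, samples_per_condition = 2,
                              n_cell_types = 6, n_shared_types = 3,
                              cells_per_type = 100,
                              n_genes = 4977, n_condition_de_genes = 30,
                              batch_effect_sd = 0.3, condition_logfc = 1,
                              marker_genes_per_type = 50, marker_logfc = 2,
                              baseline_meanlog = 0, baseline_sdlog = 1,
                              dispersion = 0.5, seed = 0) {
  stopifnot(n_conditions >= 1, samples_per_condition >= 1,
            n_cell_types >= n_shared_types, cells_per_type >= 0,
            n_genes >= 1, dispersion > 0)
  n_excluded <- n_cell_types - n_shared_types
  if (n_excluded > n_conditions)
    stop("more condition-restricted cell types than conditions")
  conditions <- paste0("T", seq_len(n_conditions))
  types <- paste0("c", seq_len(n_cell_types))
  samples <- paste0("S", seq_len(n_conditions * samples_per_condition))
  comp <- expand.grid(sample = samples, cell_type = types,
                      stringsAsFactors = FALSE)
  comp$condition <- conditions[ceiling(match(comp$sample, samples) /
                                         samples_per_condition)]
  excluded_of <- stats::setNames(rep(NA_character_, n_conditions), conditions)
  for (i in seq_len(n_excluded))
    excluded_of[conditions[i]] <- types[n_shared_types + i]
  comp$n <- ifelse(!is.na(excluded_of[comp$condition]) &
                     comp$cell_type == excluded_of[comp$condition],
                   0L, as.integer(cells_per_type))
  if (n_genes < n_cell_types * marker_genes_per_type +
      n_conditions * n_condition_de_genes)
    stop("n_genes too small for disjoint marker and DE gene sets")
  structure(list(
    composition = comp[, c("condition", "sample", "cell_type", "n")],
    conditions = conditions, samples = samples, cell_types = types,
    excluded_type = excluded_of,
    n_genes = as.integer(n_genes),
    n_condition_de_genes = as.integer(n_condition_de_genes),
    batch_effect_sd = batch_effect_sd, condition_logfc = condition_logfc,
    marker_genes_per_type = as.integer(marker_genes_per_type),
    marker_logfc = marker_logfc,
    baseline_meanlog = baseline_meanlog, baseline_sdlog = baseline_sdlog,
    dispersion = dispersion, seed = as.integer(seed)
  ), class = "simulation_design")
}

#' Simulate a multi-batch, multi-condition count dataset
#'
#' @param design a [simulation_design()].
#' @return list with `dataset` (an `expression_dataset` at stage `raw`;
#'   batch = sample id) and `truth` (cell type, per-condition DE gene sets,
#'   per-type marker sets, and the design).
#' @export
simulate_dataset <- function(design) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(design$seed)
  m <- design$n_genes
  gene_ids <- sprintf("gene%04d", seq_len(m))
  baseline <- stats::rnorm(m, design$baseline_meanlog, design$baseline_sdlog)

  # disjoint gene programs: markers per type, then DE genes per condition
  pool <- seq_len(m)
  marker_sets <- list()
  for (ty in design$cell_types) {
    marker_sets[[ty]] <- pool[seq_len(design$marker_genes_per_type)]
    pool <- setdiff(pool, marker_sets[[ty]])
  }
  de_sets <- list()
  for (co in design$conditions) {
    de_sets[[co]] <- pool[seq_len(design$n_condition_de_genes)]
    pool <- setdiff(pool, de_sets[[co]])
  }

  batch_shift <- matrix(stats::rnorm(m * length(design$samples),
                                     sd = design$batch_effect_sd),
                        m, length(design$samples),
                        dimnames = list(NULL, design$samples))

  comp <- design$composition
  comp <- comp[comp$n > 0, , drop = FALSE]
  n_total <- sum(comp$n)
  counts <- matrix(0L, n_total, m)
  batch <- character(n_total)
  condition <- character(n_total)
  cell_type <- character(n_total)
  row <- 0L
  size <- 1 / design$dispersion
  for (g in seq_len(nrow(comp))) {
    logmu <- baseline
    logmu[marker_sets[[comp$cell_type[g]]]] <-
      logmu[marker_sets[[comp$cell_type[g]]]] + design$marker_logfc
    logmu[de_sets[[comp$condition[g]]]] <-
      logmu[de_sets[[comp$condition[g]]]] + design$condition_logfc
    logmu <- logmu + batch_shift[, comp$sample[g]]
    mu <- exp(logmu)
    for (i in seq_len(comp$n[g])) {
      row <- row + 1L
      counts[row, ] <- stats::rnbinom(m, size = size, mu = mu)
      batch[row] <- comp$sample[g]
      condition[row] <- comp$condition[g]
      cell_type[row] <- comp$cell_type[g]
    }
  }
  ds <- expression_dataset(
    matrix = counts, gene_ids = gene_ids,
    cell_ids = sprintf("cell%05d", seq_len(n_total)),
    batch = batch, condition = condition, cell_type = cell_type,
    stage = "raw"
  )
  truth <- list(
    cell_type = cell_type,
    de_genes = lapply(de_sets, function(ix) gene_ids[ix]),
    marker_genes = lapply(marker_sets, function(ix) gene_ids[ix]),
    design = design
  )
  list(dataset = ds, truth = truth)
}

#' Small, strongly structured benchmark preset
#'
#' 600 cells over 1000 genes with the same 3-condition x 2-batch x 6-type
#' composition as the default design (20 cells per present type per sample),
#' strong cell-type programs and moderate batch effects, sized so the full
#' training pipeline completes in minutes. "Easy" means k-means on the top
#' principal components of the log counts already recovers the planted types
#' well before any integration.
#'
#' @param seed integer seed.
#' @return list with `dataset` and `truth`, as [simulate_dataset()].
#' @export
easy_benchmark <- function(seed = 0) {
  design <- simulation_design(
    cells_per_type = 20, n_genes = 1000,
    n_condition_de_genes = 30,
    batch_effect_sd = 0.3, condition_logfc = 1.5,
    marker_genes_per_type = 50, marker_logfc = 2.5,
    dispersion = 0.5, seed = seed
  )
  simulate_dataset(design)
}

#' Write ground-truth DE gene sets as JSON
#' @param truth the `truth` component of [simulate_dataset()].
#' @param path destination JSON file.
#' @return `path` invisibly.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(list(de_genes = truth$de_genes,
                            marker_genes = truth$marker_genes),
                       path, auto_unbox = FALSE)
  invisible(path)
}
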