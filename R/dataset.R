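#' Expression dataset container
#'
#' Lightweight container for a cell-by-gene expression matrix with per-cell
#' batch and condition labels (and optional cell-type labels). Rows are cells,
#' columns are genes. Batch and condition labels are stored as factors whose
#' levels are lexicographically sorted, so that the induced integer coding
#' (0-based) and one-hot column order are stable across runs and platforms.
#'
#' The `stage` field records where the dataset sits in the preprocessing
#' pipeline and may only move forward through
#' `raw -> normalized -> log -> hvg -> zscored`.
#'
#' @param matrix numeric cell x gene matrix (dense or `Matrix` sparse).
#' @param gene_ids character vector of gene identifiers (length = ncol).
#' @param cell_ids character vector of cell identifiers (length = nrow).
#' @param batch per-cell batch labels (factor or character).
#' @param condition per-cell condition labels (factor or character).
#' @param cell_type optional per-cell cell-type labels.
#' @param stage pipeline stage, one of `dataset_stages()`.
#' @return an object of class `expression_dataset`.
#' @export
expression_dataset <- function(matrix, gene_ids, cell_ids, batch, condition,
                               cell_type = NULL, stage = "raw") {
  if (is.data.frame(matrix)) matrix <- as.matrix(matrix)
  n <- nrow(matrix)
  m <- ncol(matrix)
  if (length(gene_ids) != m)
    stop("gene_ids length (", length(gene_ids), ") != number of genes (", m, ")")
  if (length(cell_ids) != n)
    stop("cell_ids length (", length(cell_ids), ") != number of cells (", n, ")")
  if (length(batch) != n)
    stop("batch labels length (", length(batch), ") != number of cells (", n, ")")
  if (length(condition) != n)
    stop("condition labels length (", length(condition), ") != number of cells (", n, ")")
  if (!is.null(cell_type) && length(cell_type) != n)
    stop("cell_type labels length (", length(cell_type), ") != number of cells (", n, ")")
  if (anyDuplicated(cell_ids)) stop("cell_ids must be unique")
  stage <- match.arg(stage, dataset_stages())
  ds <- structure(list(
    matrix = matrix,
    gene_ids = as.character(gene_ids),
    cell_ids = as.character(cell_ids),
    batch = sorted_factor(batch),
    condition = sorted_factor(condition),
    cell_type = if (is.null(cell_type)) NULL else sorted_factor(cell_type),
    stage = stage
  ), class = "expression_dataset")
  ds
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat("expression_dataset: ", nrow(x$matrix), " cells x ", ncol(x$matrix),
      " genes [stage: ", x$stage, "]\n", sep = "")
  cat("  batches:    ", paste(levels(x$batch), collapse = ", "), "\n", sep = "")
  cat("  conditions: ", paste(levels(x$condition), collapse = ", "), "\n", sep = "")
  if (!is.null(x$cell_type))
    cat("  cell types: ", paste(levels(x$cell_type), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Pipeline stages in forward order
#' @return character vector of valid stages.
#' @export
dataset_stages <- function() c("raw", "normalized", "log", "hvg", "zscored")

# factor with lexicographically sorted levels (stable 0-based coding)
sorted_factor <- function(x) {
  x <- as.character(x)
  factor(x, levels = sort(unique(x)))
}

#' Number of cells / genes
#' @param ds an `expression_dataset`.
#' @return integer count.
#' @export
n_cells <- function(ds) nrow(ds$matrix)

#' @rdname n_cells
#' @export
n_genes <- function(ds) ncol(ds$matrix)

#' 0-based integer codes for a label factor
#'
#' Codes follow the sorted level order: level `k` (1-based in R) maps to
#' integer `k - 1`.
#'
#' @param labels a factor produced by `expression_dataset`.
#' @return integer vector in `0..nlevels-1`.
#' @export
label_codes <- function(labels) as.integer(labels) - 1L

#' One-hot encode a label factor
#'
#' @param labels a factor; column order follows the sorted level coding.
#' @param levels optional explicit level set (for encoding against a
#'   training-time coding).
#' @return n x k numeric indicator matrix; every row sums to exactly 1.
#' @export
one_hot <- function(labels, levels = NULL) {
  if (is.null(levels)) {
    f <- sorted_factor(labels)
  } else {
    f <- factor(as.character(labels), levels = levels)
    if (anyNA(f)) stop("labels contain levels outside the supplied coding: ",
                       paste(setdiff(unique(as.character(labels)), levels), collapse = ", "))
  }
  k <- nlevels(f)
  M <- matrix(0, length(f), k, dimnames = list(NULL, levels(f)))
  M[cbind(seq_along(f), as.integer(f))] <- 1
  M
}

# internal: move stage forward, error on backwards transitions
advance_stage <- function(ds, to) {
  stages <- dataset_stages()
  if (match(to, stages) < match(ds$stage, stages))
    stop("stage may only advance forward: ", ds$stage, " -> ", to)
  ds$stage <- to
  ds
}

# internal: require an exact stage before an operation
require_stage <- function(ds, stage, op) {
  if (ds$stage != stage)
    stop(op, " expects a dataset at stage '", stage, "', got '", ds$stage, "'")
  invisible(ds)
}

#' Subset a dataset by cells and/or genes
#'
#' Keeps labels aligned with rows and re-derives the sorted level coding on
#' the retained cells.
#'
#' @param ds an `expression_dataset`.
#' @param cells logical or integer row index (default: all).
#' @param genes logical or integer column index (default: all).
#' @return the subset `expression_dataset` (same stage).
#' @export
subset_dataset <- function(ds, cells = NULL, genes = NULL) {
  if (is.null(cells)) cells <- seq_len(n_cells(ds))
  if (is.null(genes)) genes <- seq_len(n_genes(ds))
  expression_dataset(
    matrix = ds$matrix[cells, genes, drop = FALSE],
    gene_ids = ds$gene_ids[genes],
    cell_ids = ds$cell_ids[cells],
    batch = as.character(ds$batch)[cells],
    condition = as.character(ds$condition)[cells],
    cell_type = if (is.null(ds$cell_type)) NULL else as.character(ds$cell_type)[cells],
    stage = ds$stage
  )
}

#' Read an expression dataset from disk
#'
#' Supported formats:
#' * `h5ad`: AnnData layout (matrix in `X`, labels as `obs` columns; dense or
#'   CSR/CSC sparse `X`; plain string or categorical obs columns).
#' * `csv`: a cells x genes matrix CSV (first column = cell id, header = gene
#'   ids) plus a metadata CSV keyed by cell id (`metadata_path`).
#' * `mtx`: MatrixMarket triple `matrix.mtx` (genes x cells, the common
#'   CellRanger orientation), `genes.tsv`, `barcodes.tsv` in one directory,
#'   plus a metadata CSV keyed by cell id.
#'
#' @param path file (h5ad, csv) or directory (mtx).
#' @param format one of "h5ad", "csv", "mtx".
#' @param batch_key metadata column holding batch labels.
#' @param condition_key metadata column holding condition labels.
#' @param celltype_key optional metadata column holding cell-type labels.
#' @param metadata_path metadata CSV path (csv/mtx formats).
#' @return an `expression_dataset` (stage as recorded in the file, default raw).
#' @export
read_dataset <- function(path, format = c("h5ad", "csv", "mtx"),
                         batch_key = "batch", condition_key = "condition",
                         celltype_key = NULL, metadata_path = NULL) {
  format <- match.arg(format)
  switch(format,
    h5ad = read_h5ad_dataset(path, batch_key, condition_key, celltype_key),
    csv = read_csv_dataset(path, metadata_path, batch_key, condition_key, celltype_key),
    mtx = read_mtx_dataset(path, metadata_path, batch_key, condition_key, celltype_key)
  )
}

fetch_meta_column <- function(meta, key, what) {
  if (is.null(key)) return(NULL)
  if (!key %in% names(meta))
    stop("metadata column '", key, "' (", what, ") not found; available: ",
         paste(setdiff(names(meta), "_index"), collapse = ", "))
  as.character(meta[[key]])
}

read_csv_dataset <- function(path, metadata_path, batch_key, condition_key, celltype_key) {
  if (!file.exists(path)) stop("matrix file not found: ", path)
  if (is.null(metadata_path) || !file.exists(metadata_path))
    stop("csv format requires an existing metadata_path")
  tab <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  X <- as.matrix(tab)
  if (!is.numeric(X)) stop("matrix CSV contains non-numeric values")
  meta <- utils::read.csv(metadata_path, row.names = 1, check.names = FALSE)
  missing <- setdiff(rownames(X), rownames(meta))
  if (length(missing) > 0)
    stop("metadata is missing cells: ", paste(utils::head(missing, 5), collapse = ", "))
  meta <- meta[rownames(X), , drop = FALSE]
  expression_dataset(
    matrix = X, gene_ids = colnames(X), cell_ids = rownames(X),
    batch = fetch_meta_column(meta, batch_key, "batch"),
    condition = fetch_meta_column(meta, condition_key, "condition"),
    cell_type = fetch_meta_column(meta, celltype_key, "cell type"),
    stage = "raw"
  )
}

read_mtx_dataset <- function(path, metadata_path, batch_key, condition_key, celltype_key) {
  mtx <- file.path(path, "matrix.mtx")
  genes <- file.path(path, "genes.tsv")
  barcodes <- file.path(path, "barcodes.tsv")
  for (f in c(mtx, genes, barcodes))
    if (!file.exists(f)) stop("mtx component not found: ", f)
  if (is.null(metadata_path) || !file.exists(metadata_path))
    stop("mtx format requires an existing metadata_path")
  M <- Matrix::readMM(mtx)           # genes x cells on disk
  gene_ids <- utils::read.table(genes, sep = "\t", header = FALSE,
                                stringsAsFactors = FALSE)[[1]]
  cell_ids <- utils::read.table(barcodes, sep = "\t", header = FALSE,
                                stringsAsFactors = FALSE)[[1]]
  if (nrow(M) != length(gene_ids) || ncol(M) != length(cell_ids))
    stop("matrix.mtx dimensions do not match genes.tsv/barcodes.tsv")
  meta <- utils::read.csv(metadata_path, row.names = 1, check.names = FALSE)
  missing <- setdiff(cell_ids, rownames(meta))
  if (length(missing) > 0)
    stop("metadata is missing cells: ", paste(utils::head(missing, 5), collapse = ", "))
  meta <- meta[cell_ids, , drop = FALSE]
  expression_dataset(
    matrix = Matrix::t(M), gene_ids = gene_ids, cell_ids = cell_ids,
    batch = fetch_meta_column(meta, batch_key, "batch"),
    condition = fetch_meta_column(meta, condition_key, "condition"),
    cell_type = fetch_meta_column(meta, celltype_key, "cell type"),
    stage = "raw"
  )
}

#' Write a dataset to an AnnData-layout h5ad file
#'
#' Writes `X` (dense, cells x genes), `obs` with batch / condition
#' (/ cell_type) string columns, `var` with the gene index, the pipeline
#' stage under `uns/stage`, and any embeddings under `obsm`.
#'
#' @param ds an `expression_dataset`.
#' @param path destination; overwritten if present.
#' @param obsm optional named list of per-cell embedding matrices.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path, obsm = NULL) {
  if (file.exists(path)) file.remove(path)
  rhdf5::h5createFile(path)
  h <- rhdf5::H5Fopen(path)
  on.exit(rhdf5::H5Fclose(h), add = TRUE)

  # X: anndata stores obs x var row-major; rhdf5 writes column-major, so the
  # transposed R matrix lands with the expected h5py shape.
  X <- as.matrix(ds$matrix)
  rhdf5::h5write(t(X), h, "X")

  obs_cols <- c("batch", "condition")
  obs <- list(batch = as.character(ds$batch), condition = as.character(ds$condition))
  if (!is.null(ds$cell_type)) {
    obs_cols <- c(obs_cols, "cell_type")
    obs$cell_type <- as.character(ds$cell_type)
  }
  write_h5ad_dataframe(h, "obs", ds$cell_ids, obs, obs_cols)
  write_h5ad_dataframe(h, "var", ds$gene_ids, list(), character(0))

  rhdf5::h5createGroup(h, "uns")
  rhdf5::h5write(ds$stage, h, "uns/stage")
  h5_set_encoding(h, "uns/stage", "string", "0.2.0")

  rhdf5::h5createGroup(h, "obsm")
  if (!is.null(obsm)) {
    for (nm in names(obsm)) {
      rhdf5::h5write(t(obsm[[nm]]), h, paste0("obsm/", nm))
      h5_set_encoding(h, paste0("obsm/", nm), "array", "0.2.0")
    }
  }
  h5_set_encoding(h, "X", "array", "0.2.0")
  invisible(path)
}

h5_set_encoding <- function(h, name, type, version) {
  obj <- rhdf5::H5Oopen(h, name)
  on.exit(rhdf5::H5Oclose(obj), add = TRUE)
  rhdf5::h5writeAttribute(type, obj, "encoding-type", asScalar = TRUE,
                          variableLengthString = TRUE, encoding = "UTF-8")
  rhdf5::h5writeAttribute(version, obj, "encoding-version", asScalar = TRUE,
                          variableLengthString = TRUE, encoding = "UTF-8")
}

write_h5ad_dataframe <- function(h, group, index, columns, column_order) {
  rhdf5::h5createGroup(h, group)
  rhdf5::h5write(index, h, paste0(group, "/_index"),
                 variableLengthString = TRUE, encoding = "UTF-8")
  h5_set_encoding(h, paste0(group, "/_index"), "string-array", "0.2.0")
  for (nm in names(columns)) {
    rhdf5::h5write(columns[[nm]], h, paste0(group, "/", nm),
                   variableLengthString = TRUE, encoding = "UTF-8")
    h5_set_encoding(h, paste0(group, "/", nm), "string-array", "0.2.0")
  }
  obj <- rhdf5::H5Oopen(h, group)
  on.exit(rhdf5::H5Oclose(obj), add = TRUE)
  rhdf5::h5writeAttribute("dataframe", obj, "encoding-type", asScalar = TRUE,
                          variableLengthString = TRUE, encoding = "UTF-8")
  rhdf5::h5writeAttribute("0.2.0", obj, "encoding-version", asScalar = TRUE,
                          variableLengthString = TRUE, encoding = "UTF-8")
  rhdf5::h5writeAttribute("_index", obj, "_index", asScalar = TRUE,
                          variableLengthString = TRUE, encoding = "UTF-8")
  if (length(column_order) > 0) {
    rhdf5::h5writeAttribute(column_order, obj, "column-order",
                            variableLengthString = TRUE, encoding = "UTF-8")
  } else {
    # rhdf5::h5writeAttribute cannot write zero-length attributes; create an
    # empty variable-length string attribute through the low-level API so
    # readers still find "column-order" on column-free dataframes.
    tid <- rhdf5::H5Tcopy("H5T_C_S1")
    rhdf5::H5Tset_size(tid, NULL)
    rhdf5::H5Tset_cset(tid, "UTF-8")
    sid <- rhdf5::H5Screate_simple(0)
    aid <- rhdf5::H5Acreate(obj, "column-order", tid, sid)
    rhdf5::H5Aclose(aid)
    rhdf5::H5Sclose(sid)
  }
}

read_h5ad_dataset <- function(path, batch_key, condition_key, celltype_key) {
  if (!file.exists(path)) stop("h5ad file not found: ", path)
  contents <- rhdf5::h5ls(path)
  X <- read_h5ad_matrix(path, "X", contents)
  obs <- read_h5ad_dataframe(path, "obs", contents)
  var <- read_h5ad_dataframe(path, "var", contents)
  if (nrow(X) != length(obs$`_index`) && ncol(X) == length(obs$`_index`)) X <- t(X)
  stage <- "raw"
  if (any(contents$group == "/uns" & contents$name == "stage"))
    stage <- as.character(rhdf5::h5read(path, "uns/stage"))
  if (!is.numeric(X)) stop("h5ad X matrix is not numeric")
  ds <- expression_dataset(
    matrix = X, gene_ids = var$`_index`, cell_ids = obs$`_index`,
    batch = fetch_meta_column(obs, batch_key, "batch"),
    condition = fetch_meta_column(obs, condition_key, "condition"),
    cell_type = fetch_meta_column(obs, celltype_key, "cell type"),
    stage = stage
  )
  # per-cell embeddings: h5py row-major arrays arrive transposed in R
  obsm_rows <- contents[contents$group == "/obsm" &
                          contents$otype == "H5I_DATASET", ]
  if (nrow(obsm_rows) > 0) {
    ds$obsm <- stats::setNames(lapply(obsm_rows$name, function(nm) {
      t(drop(rhdf5::h5read(path, paste0("obsm/", nm))))
    }), obsm_rows$name)
  }
  ds
}

read_h5ad_matrix <- function(path, name, contents) {
  here <- contents[contents$group == paste0("/", name) |
                   (contents$group == "/" & contents$name == name), ]
  if (any(contents$group == "/" & contents$name == name &
          contents$otype == "H5I_DATASET")) {
    # dense: h5py row-major (n_obs, n_var) arrives transposed in R
    return(t(drop(rhdf5::h5read(path, name))))
  }
  sub <- contents[contents$group == paste0("/", name), ]
  if (all(c("data", "indices", "indptr") %in% sub$name)) {
    data <- as.numeric(rhdf5::h5read(path, paste0(name, "/data")))
    indices <- as.integer(rhdf5::h5read(path, paste0(name, "/indices")))
    indptr <- as.integer(rhdf5::h5read(path, paste0(name, "/indptr")))
    attrs <- rhdf5::h5readAttributes(path, name)
    shape <- as.integer(attrs[["shape"]])        # (n_obs, n_var)
    enc <- as.character(attrs[["encoding-type"]])
    if (length(enc) == 0) enc <- "csr_matrix"
    if (grepl("csr", enc)) {
      # CSR over obs rows == CSC of the var x obs matrix
      M <- Matrix::sparseMatrix(i = indices + 1L, p = indptr, x = data,
                                dims = c(shape[2], shape[1]))
      return(as.matrix(Matrix::t(M)))
    } else {
      M <- Matrix::sparseMatrix(i = indices + 1L, p = indptr, x = data,
                                dims = c(shape[1], shape[2]))
      return(as.matrix(M))
    }
  }
  stop("unsupported h5ad X layout in ", path)
}

read_h5ad_dataframe <- function(path, group, contents) {
  sub <- contents[contents$group == paste0("/", group), ]
  out <- list()
  for (i in seq_len(nrow(sub))) {
    nm <- sub$name[i]
    full <- paste0(group, "/", nm)
    if (sub$otype[i] == "H5I_DATASET") {
      out[[nm]] <- as.vector(rhdf5::h5read(path, full))
    } else {
      inner <- contents[contents$group == paste0("/", full), ]
      if (all(c("codes", "categories") %in% inner$name)) {
        codes <- as.integer(rhdf5::h5read(path, paste0(full, "/codes")))
        cats <- as.character(rhdf5::h5read(path, paste0(full, "/categories")))
        vals <- rep(NA_character_, length(codes))
        vals[codes >= 0] <- cats[codes[codes >= 0] + 1L]
        out[[nm]] <- vals
      }
    }
  }
  out
}

#' Convert to a SingleCellExperiment
#'
#' Genes become rows (the Bioconductor convention); labels land in `colData`.
#' Requires the SingleCellExperiment package.
#'
#' @param ds an `expression_dataset`.
#' @return a `SingleCellExperiment`.
#' @export
as_single_cell_experiment <- function(ds) {
  if (!requireNamespace("SingleCellExperiment", quietly = TRUE))
    stop("as_single_cell_experiment requires the SingleCellExperiment package")
  cd <- data.frame(batch = ds$batch, condition = ds$condition,
                   row.names = ds$cell_ids)
  if (!is.null(ds$cell_type)) cd$cell_type <- ds$cell_type
  assay_name <- if (ds$stage == "raw") "counts" else "logcounts"
  assays <- stats::setNames(list(Matrix::t(ds$matrix)), assay_name)
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = assays, colData = cd)
  rownames(sce) <- ds$gene_ids
  S4Vectors::metadata(sce)$stage <- ds$stage
  sce
}
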