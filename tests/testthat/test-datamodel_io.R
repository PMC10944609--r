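test_that("label coding is stable and sorted; one-hot rows sum to 1", {
  ds <- expression_dataset(
    matrix = matrix(1, 4, 2), gene_ids = c("g1", "g2"),
    cell_ids = paste0("c", 1:4),
    batch = c("zeta", "alpha", "zeta", "mid"),
    condition = c("t2", "t1", "t1", "t2")
  )
  expect_identical(levels(ds$batch), c("alpha", "mid", "zeta"))
  expect_identical(label_codes(ds$batch), c(2L, 0L, 2L, 1L))
  oh <- one_hot(ds$batch)
  expect_identical(colnames(oh), c("alpha", "mid", "zeta"))
  expect_true(all(rowSums(oh) == 1))
  # property: one-hot rows sum to 1 for random label vectors
  set.seed(11)
  for (i in 1:20) {
    labs <- sample(letters[1:5], 30, replace = TRUE)
    expect_true(all(rowSums(one_hot(labs)) == 1))
  }
})

test_that("container validates label lengths and stage transitions", {
  expect_error(
    expression_dataset(matrix(1, 3, 2), c("g1", "g2"), paste0("c", 1:3),
                       batch = c("a", "b"), condition = rep("t", 3)),
    "batch"
  )
  ds <- make_toy_dataset()
  ds2 <- condiva:::advance_stage(ds, "hvg")
  expect_error(condiva:::advance_stage(ds2, "raw"), "forward")
})

test_that("csv round trip recovers matrix, shapes and labels", {
  dir <- withr::local_tempdir()
  X <- matrix(c(1, 0, 2, 5, 3, 1, 0, 0, 4, 2, 2, 7), nrow = 4)
  rownames(X) <- paste0("cell", 1:4)
  colnames(X) <- paste0("gene", 1:3)
  write.csv(X, file.path(dir, "mat.csv"))
  meta <- data.frame(row.names = rownames(X),
                     batch = c("b1", "b1", "b2", "b2"),
                     cond = c("x", "y", "x", "y"))
  write.csv(meta, file.path(dir, "meta.csv"))
  ds <- read_dataset(file.path(dir, "mat.csv"), format = "csv",
                     batch_key = "batch", condition_key = "cond",
                     metadata_path = file.path(dir, "meta.csv"))
  expect_equal(n_cells(ds), 4)
  expect_equal(n_genes(ds), 3)
  expect_equal(unname(as.matrix(ds$matrix)), unname(X))
  expect_identical(as.character(ds$condition), meta$cond)
  expect_error(
    read_dataset(file.path(dir, "mat.csv"), format = "csv",
                 batch_key = "nope", condition_key = "cond",
                 metadata_path = file.path(dir, "meta.csv")),
    "nope"
  )
})

test_that("mtx triple with metadata reads into the expected orientation", {
  dir <- withr::local_tempdir()
  set.seed(3)
  M <- Matrix::rsparsematrix(5, 8, density = 0.5,
                             rand.x = function(n) rpois(n, 4) + 1)  # genes x cells
  Matrix::writeMM(M, file.path(dir, "matrix.mtx"))
  writeLines(paste0("g", 1:5), file.path(dir, "genes.tsv"))
  writeLines(paste0("bc", 1:8), file.path(dir, "barcodes.tsv"))
  meta <- data.frame(row.names = paste0("bc", 1:8),
                     batch = rep(c("b1", "b2"), 4),
                     condition = rep(c("t1", "t2"), each = 4))
  write.csv(meta, file.path(dir, "meta.csv"))
  ds <- read_dataset(dir, format = "mtx",
                     metadata_path = file.path(dir, "meta.csv"))
  expect_equal(n_cells(ds), 8)
  expect_equal(n_genes(ds), 5)
  expect_equal(as.matrix(ds$matrix), unname(as.matrix(Matrix::t(M))))
})

test_that("h5ad write -> read round trip is exact, including obsm and stage", {
  dir <- withr::local_tempdir()
  ds <- make_toy_dataset(n = 6, m = 8)
  path <- file.path(dir, "toy.h5ad")
  emb <- matrix(rnorm(12), 6, 2)
  write_dataset(ds, path, obsm = list(X_bio = emb))
  back <- read_dataset(path, format = "h5ad", celltype_key = "cell_type")
  expect_equal(unname(back$obsm$X_bio), emb, tolerance = 1e-12)
  expect_equal(as.matrix(back$matrix), unname(as.matrix(ds$matrix)))
  expect_identical(back$gene_ids, ds$gene_ids)
  expect_identical(back$cell_ids, ds$cell_ids)
  expect_identical(as.character(back$batch), as.character(ds$batch))
  expect_identical(as.character(back$condition), as.character(ds$condition))
  expect_identical(as.character(back$cell_type), as.character(ds$cell_type))
  expect_identical(back$stage, "raw")
  # stage survives for preprocessed data
  pp <- zscore_genes(log_select_hvg(normalize_library_size(
    filter_cells_genes(ds, min_genes = 1)), n_hvg = 5))
  write_dataset(pp, path)
  expect_identical(read_dataset(path, format = "h5ad")$stage, "zscored")
})

test_that("written h5ad is readable by an independent AnnData implementation", {
  py <- Sys.which("python")
  skip_if(py == "", "python not on PATH")
  dir <- withr::local_tempdir()
  ds <- make_toy_dataset(n = 5, m = 7)
  path <- file.path(dir, "toy.h5ad")
  write_dataset(ds, path)
  script <- file.path(dir, "check.py")
  writeLines(c(
    "import anndata, sys",
    sprintf("a = anndata.read_h5ad('%s')", path),
    "print(a.shape[0], a.shape[1])",
    "print(float(a.X.sum()))",
    "print(','.join(a.obs['batch'].astype(str)))",
    "print(','.join(a.var_names))"
  ), script)
  out <- suppressWarnings(system2(py, script, stdout = TRUE, stderr = FALSE))
  skip_if(length(out) < 4, "anndata unavailable")
  expect_identical(out[1], paste(n_cells(ds), n_genes(ds)))
  expect_equal(as.numeric(out[2]), sum(ds$matrix))
  expect_identical(out[3], paste(as.character(ds$batch), collapse = ","))
  expect_identical(out[4], paste(ds$gene_ids, collapse = ","))
})

test_that("sparse CSR h5ad written by AnnData reads back correctly", {
  py <- Sys.which("python")
  skip_if(py == "", "python not on PATH")
  dir <- withr::local_tempdir()
  path <- file.path(dir, "sp.h5ad")
  script <- file.path(dir, "make.py")
  writeLines(c(
    "import anndata, numpy as np, pandas as pd, scipy.sparse as sp",
    "rng = np.random.default_rng(0)",
    "X = sp.random(6, 9, density=0.4, random_state=1, format='csr')",
    "obs = pd.DataFrame({'batch': ['b1','b2','b1','b2','b1','b2'],",
    "                    'condition': ['t1']*3 + ['t2']*3},",
    "                   index=[f'c{i}' for i in range(6)])",
    "var = pd.DataFrame(index=[f'g{i}' for i in range(9)])",
    "a = anndata.AnnData(X=X, obs=obs, var=var)",
    sprintf("a.write_h5ad('%s')", path),
    "print(float(X.sum()))"
  ), script)
  out <- suppressWarnings(system2(py, script, stdout = TRUE, stderr = FALSE))
  skip_if(length(out) < 1, "anndata unavailable")
  ds <- read_dataset(path, format = "h5ad")
  expect_equal(n_cells(ds), 6)
  expect_equal(n_genes(ds), 9)
  expect_equal(sum(ds$matrix), as.numeric(out[1]), tolerance = 1e-12)
  expect_identical(as.character(ds$condition), c(rep("t1", 3), rep("t2", 3)))
})

test_that("SingleCellExperiment conversion preserves data and labels", {
  skip_if_not_installed("SingleCellExperiment")
  ds <- make_toy_dataset()
  sce <- as_single_cell_experiment(ds)
  expect_equal(dim(sce), c(n_genes(ds), n_cells(ds)))
  expect_identical(as.character(sce$batch), as.character(ds$batch))
  expect_equal(unname(as.matrix(SummarizedExperiment::assay(sce, "counts"))),
               unname(t(as.matrix(ds$matrix))))
})
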