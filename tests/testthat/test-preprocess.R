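make_filter_dataset <- function(expressed_per_cell, m = 300) {
  # one row per requested count of expressed genes
  n <- length(expressed_per_cell)
  X <- matrix(0, n, m)
  for (i in seq_len(n)) X[i, seq_len(expressed_per_cell[i])] <- 1
  expression_dataset(X, sprintf("g%03d", 1:m), sprintf("c%02d", 1:n),
                     batch = rep("b1", n), condition = rep("t1", n))
}

test_that("cell filter boundary: 199 expressed genes removed, 200 retained", {
  ds <- make_filter_dataset(c(199, 200, 300))
  out <- filter_cells_genes(ds)
  expect_identical(out$cell_ids, c("c02", "c03"))
})

test_that("genes expressed in zero cells are removed; full matrix untouched", {
  set.seed(5)
  X <- matrix(rpois(5 * 300, 3) + 1, 5, 300)   # everything expressed
  X[, 17] <- 0                                  # one silent gene
  ds <- expression_dataset(X, sprintf("g%03d", 1:300), paste0("c", 1:5),
                           batch = rep("b", 5), condition = rep("t", 5))
  out <- filter_cells_genes(ds)
  # brute-force oracle: count nonzero columns
  expect_equal(n_genes(out), sum(colSums(X > 0) > 0))
  expect_false("g017" %in% out$gene_ids)
  expect_equal(n_cells(out), 5)
  # dataset where every cell expresses all genes is unchanged
  ds2 <- expression_dataset(X[, -17], sprintf("g%03d", (1:300)[-17]),
                            paste0("c", 1:5), rep("b", 5), rep("t", 5))
  expect_equal(as.matrix(filter_cells_genes(ds2)$matrix), as.matrix(ds2$matrix))
  expect_error(filter_cells_genes(make_filter_dataset(c(10, 20))), "all cells")
})

test_that("library-size normalization follows total/median factors", {
  X <- rbind(rep(25, 4), rep(50, 4), rep(75, 4))   # totals 100, 200, 300
  ds <- expression_dataset(X, paste0("g", 1:4), paste0("c", 1:3),
                           batch = rep("b", 3), condition = rep("t", 3))
  out <- normalize_library_size(ds)
  # factors 0.5, 1.0, 1.5; all post-normalization totals equal the median 200
  expect_equal(unname(rowSums(out$matrix)), rep(200, 3))
  expect_equal(unname(out$matrix[1, 1]), 50)
  expect_equal(unname(out$matrix[3, 1]), 50)
  expect_identical(out$stage, "normalized")

  # equal totals: factors all 1, matrix unchanged
  Y <- matrix(10, 3, 4)
  dsy <- expression_dataset(Y, paste0("g", 1:4), paste0("c", 1:3),
                            rep("b", 3), rep("t", 3))
  expect_equal(as.matrix(normalize_library_size(dsy)$matrix), Y)

  # single cell: factor 1 (median = own total)
  ds1 <- expression_dataset(matrix(c(1, 2, 3), 1), paste0("g", 1:3), "c1",
                            "b", "t")
  expect_equal(unname(as.matrix(normalize_library_size(ds1)$matrix)),
               matrix(c(1, 2, 3), 1))
})

test_that("HVG selection keeps the requested count and clamps", {
  set.seed(9)
  n <- 30
  ds <- expression_dataset(matrix(rpois(n * 120, 8), n, 120),
                           sprintf("g%03d", 1:120), paste0("c", 1:n),
                           rep(c("b1", "b2"), n / 2), rep("t", n))
  nrm <- normalize_library_size(ds)
  out <- log_select_hvg(nrm, n_hvg = 40)
  expect_equal(n_genes(out), 40)
  expect_identical(out$stage, "hvg")
  # log1p applied
  expect_true(max(out$matrix) <= log1p(max(nrm$matrix)) + 1e-12)
  # clamp: fewer genes than requested keeps all
  expect_equal(n_genes(log_select_hvg(nrm, n_hvg = 5000)), 120)
})

test_that("a constant gene never outranks a high-dispersion gene", {
  # 10-gene toy: gene 1 constant, gene 2 wildly dispersed, same mean bin
  set.seed(2)
  n <- 50
  X <- matrix(rpois(n * 10, 5), n, 10)
  X[, 1] <- 5
  X[, 2] <- rep(c(0, 10), n / 2)
  ds <- expression_dataset(X, sprintf("g%02d", 1:10), paste0("c", 1:n),
                           rep("b", n), rep("t", n))
  nrm <- normalize_library_size(ds)
  disp <- condiva:::normalized_dispersion(as.matrix(nrm$matrix), n_bins = 2)
  # brute-force oracle on the raw dispersion ordering
  mu <- colMeans(as.matrix(nrm$matrix))
  v <- colMeans(as.matrix(nrm$matrix)^2) - mu^2
  expect_true((v / mu)[2] > (v / mu)[1])
  expect_gt(disp[2], disp[1])
  kept <- log_select_hvg(nrm, n_hvg = 5)$gene_ids
  expect_true("g02" %in% kept)
  # note: g01 is constant in raw counts but not after library-size scaling,
  # so only the bimodal gene's membership is asserted
})

test_that("z-scoring yields per-gene mean 0 and unit population variance", {
  set.seed(4)
  n <- 25
  ds <- expression_dataset(matrix(rpois(n * 40, 6), n, 40),
                           sprintf("g%02d", 1:40), paste0("c", 1:n),
                           rep("b", n), rep("t", n))
  out <- zscore_genes(log_select_hvg(normalize_library_size(ds), n_hvg = 40))
  X <- as.matrix(out$matrix)
  expect_true(all(abs(colMeans(X)) < 1e-6))
  expect_true(all(abs(colMeans(X^2) - colMeans(X)^2 - 1) < 1e-6))
  expect_identical(out$stage, "zscored")
})

test_that("z-score hand case (1,2,3) uses the population variance convention", {
  ds <- expression_dataset(matrix(c(1, 2, 3), 3, 1), "g1", paste0("c", 1:3),
                           rep("b", 3), rep("t", 3), stage = "raw")
  ds <- condiva:::advance_stage(condiva:::advance_stage(ds, "normalized"), "hvg")
  out <- zscore_genes(ds)
  expect_equal(unname(as.matrix(out$matrix)[, 1]),
               c(-1.22474487, 0, 1.22474487), tolerance = 1e-8)
  # idempotence: an already-standardized column passes through unchanged
  ds2 <- expression_dataset(as.matrix(out$matrix), "g1", paste0("c", 1:3),
                            rep("b", 3), rep("t", 3), stage = "hvg")
  expect_equal(as.matrix(zscore_genes(ds2)$matrix), as.matrix(out$matrix),
               tolerance = 1e-12)
})

test_that("zero-variance genes become zero columns with a notice", {
  X <- cbind(c(1, 2, 3, 6), rep(4, 4))
  ds <- expression_dataset(X, c("g1", "g2"), paste0("c", 1:4),
                           rep("b", 4), rep("t", 4))
  ds <- condiva:::advance_stage(condiva:::advance_stage(ds, "normalized"), "hvg")
  expect_message(out <- zscore_genes(ds), "zero-variance")
  expect_equal(unname(as.matrix(out$matrix)[, 2]), rep(0, 4))
})

test_that("full pipeline is deterministic and never reorders cells", {
  sim <- easy_benchmark(seed = 3)
  a <- preprocess_dataset(sim$dataset, n_hvg = 200)
  b <- preprocess_dataset(sim$dataset, n_hvg = 200)
  expect_identical(a$matrix, b$matrix)
  expect_identical(a$gene_ids, b$gene_ids)
  # cells survive in their original relative order
  expect_true(!is.unsorted(match(a$cell_ids, sim$dataset$cell_ids)))
  expect_identical(as.character(a$condition),
                   as.character(sim$dataset$condition)[match(a$cell_ids, sim$dataset$cell_ids)])
})
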