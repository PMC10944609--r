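# Shared fixtures. The trained easy-benchmark model is expensive (a full
# 50-epoch run), so it is computed lazily once per test session and reused by
# the training, attribution and end-to-end tests.

.fixture_env <- new.env(parent = emptyenv())

# tiny labelled dataset for I/O and preprocessing tests
make_toy_dataset <- function(n = 6, m = 8, seed = 1, stage = "raw") {
  set.seed(seed)
  X <- matrix(rpois(n * m, lambda = 5), n, m)
  expression_dataset(
    matrix = X,
    gene_ids = sprintf("g%02d", seq_len(m)),
    cell_ids = sprintf("c%02d", seq_len(n)),
    batch = rep(c("b1", "b2"), length.out = n),
    condition = rep(c("t1", "t2"), each = ceiling(n / 2))[seq_len(n)],
    cell_type = rep(c("x", "y"), length.out = n),
    stage = stage
  )
}

# small model configuration for fast network/gradient tests
tiny_config <- function(m = 30, b = 2, C = 3, ...) {
  model_config(m = m, b = b, C = C, d1 = 4, d2 = 3,
               enc_hidden = c(16, 8), dec_hidden = c(8, 16),
               cls_hidden = c(8, 8), minibatch = 20, ...)
}

# a z-scored dataset small enough to fit in seconds
make_tiny_zscored <- function(n = 40, m = 30, seed = 7) {
  set.seed(seed)
  X <- matrix(rnorm(n * m), n, m)
  X <- scale(X, scale = apply(X, 2, function(v) sqrt(mean((v - mean(v))^2))))
  expression_dataset(
    matrix = unclass(X),
    gene_ids = sprintf("g%02d", seq_len(m)),
    cell_ids = sprintf("c%02d", seq_len(n)),
    batch = rep(c("b1", "b2"), length.out = n),
    condition = rep(c("t1", "t2", "t3"), length.out = n),
    cell_type = rep(c("x", "y"), each = n / 2),
    stage = "zscored"
  )
}

# the full end-to-end fixture: simulate, preprocess, train with defaults
trained_easy <- function() {
  if (is.null(.fixture_env$easy)) {
    sim <- easy_benchmark(seed = 1)
    pp <- preprocess_dataset(sim$dataset)
    # minibatch 32 instead of the default 128: the 600-cell benchmark needs
    # the optimizer steps (50 * 600/32 vs 50 * 600/128) to train adequately
    cfg <- model_config(m = n_genes(pp), b = nlevels(pp$batch),
                        C = nlevels(pp$condition), minibatch = 32, seed = 1)
    state <- fit_model(pp, cfg)
    .fixture_env$easy <- list(sim = sim, pp = pp, config = cfg,
                              state = state,
                              bundle = transform_cells(state, pp))
  }
  .fixture_env$easy
}

# rebuild a parameter tree from a flat vector (finite-difference tests)
unflatten_into <- function(tree, flat) {
  rebuild <- function(x, pos) {
    if (is.list(x)) {
      for (i in seq_along(x)) {
        r <- rebuild(x[[i]], pos)
        x[[i]] <- r$x
        pos <- r$pos
      }
      list(x = x, pos = pos)
    } else {
      len <- length(x)
      x[] <- flat[pos:(pos + len - 1)]
      list(x = x, pos = pos + len)
    }
  }
  rebuild(tree, 1)$x
}
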