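# Shared small fixtures, built once per test run.

tiny_cfg <- function(...) {
  defaults <- list(n_genes = 300, cells_per_stage = 120,
                   markers_per_stage = 20, marker_fold = 5,
                   nb_dispersion = 2, n_bulk = 60)
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}

rand_expr <- function(n, g, seed = 1, prefix = "s", layer = "counts") {
  set.seed(seed)
  m <- matrix(rpois(n * g, 5), n, g,
              dimnames = list(sprintf("%s%03d", prefix, seq_len(n)),
                              sprintf("g%03d", seq_len(g))))
  expr_mat(m + 0, layer)
}

# A small trained front half (cells -> pseudobulk -> teacher), cached.
.fixture_env <- new.env()

small_trained <- function() {
  if (!is.null(.fixture_env$small)) return(.fixture_env$small)
  cfg <- tiny_cfg()
  sim <- simulate_cells(cfg, seed = 11)
  norm <- normalize_cells(sim$cells)
  hvg <- select_hvg(norm, 150)
  norm2 <- expr_mat(norm$values[, hvg, drop = FALSE], "lognorm")
  pb <- sample_blocks(norm2, sim$labels, block_size = 40, n_blocks = 150,
                      seed = 11)
  bs <- simulate_bulk(sim$truth, cfg, seed = 11)
  bulk_hvg <- expr_mat(bs$bulk$values[, hvg, drop = FALSE], "counts")
  be <- expand_bulk(bulk_hvg, 200, seed = 11)
  teacher <- train_teacher(pb, be, loss_config(),
                           train_config(epochs = 60, d_latent = 48,
                                        batch_size = 50, seed = 11))
  .fixture_env$small <- list(cfg = cfg, sim = sim, norm = norm2, hvg = hvg,
                             pb = pb, bs = bs, bulk_hvg = bulk_hvg,
                             be = be, teacher = teacher)
  .fixture_env$small
}
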