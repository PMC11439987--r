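#' Held-out benchmark of terminal-stage identification
#'
#' For each replicate seed the full front half of the pipeline is run on
#' synthetic data: cells are simulated and log-normalized, highly variable
#' genes selected, pseudo-bulk blocks sampled, a random 20% of blocks held
#' out, bulk mixtures simulated from the same stage profiles and expanded,
#' and the domain-adaptation teacher trained on the remaining blocks. The
#' held-out blocks are then scored and the terminal-stage AUROC and AUPRC
#' (terminal-stage pseudo-label vs. terminal-stage score) are recorded.
#'
#' @param sim_cfg A [sim_config()].
#' @param seeds Integer vector of replicate seeds.
#' @param n_hvg Number of highly variable genes to keep.
#' @param block_size,n_blocks,target_weight Pseudo-bulk sampling
#'   parameters (see [sample_blocks()]).
#' @param holdout_frac Fraction of blocks held out for evaluation.
#' @param loss_cfg A [loss_config()].
#' @param train_cfg A [train_config()]; its seed is overridden per
#'   replicate.
#' @return Data frame with one row per replicate (`seed`, `auroc`,
#'   `auprc`, `n_holdout`, `n_pos`) plus attributes `median_auroc` and
#'   `median_auprc`.
#' @export
benchmark_stage_identification <- function(sim_cfg = sim_config(),
                                           seeds = 1:5,
                                           n_hvg = 2000,
                                           block_size = 100,
                                           n_blocks = 1000,
                                           target_weight = 10,
                                           holdout_frac = 0.2,
                                           loss_cfg = loss_config(),
                                           train_cfg = train_config()) {
  res <- lapply(seeds, function(sd) {
    sim <- simulate_cells(sim_cfg, seed = sd)
    norm <- normalize_cells(sim$cells)
    hvg <- select_hvg(norm, n_hvg)
    norm <- expr_mat(norm$values[, hvg, drop = FALSE], "lognorm")
    pb <- sample_blocks(norm, sim$labels, block_size = block_size,
                        n_blocks = n_blocks,
                        target_weight = target_weight, seed = sd)
    bs <- simulate_bulk(sim$truth, sim_cfg, seed = sd)
    bulk <- expr_mat(bs$bulk$values[, hvg, drop = FALSE], "counts")
    bulk_exp <- expand_bulk(bulk, n = train_cfg$bulk_expansion_n, seed = sd)

    n_pb <- nrow(pb$X2)
    hold <- with_seed(sd, sample.int(n_pb, round(holdout_frac * n_pb)))
    train_pb <- subset_blocks(pb, setdiff(seq_len(n_pb), hold))
    tc <- train_cfg
    tc$seed <- sd
    teacher <- train_teacher(train_pb, bulk_exp, loss_cfg, tc)

    xs <- apply_minmax(pb$X2[hold, , drop = FALSE], teacher$scaler_pseudo)
    z <- classify(encode(xs, teacher$params), teacher$params)
    score <- z[, match(pb$terminal_stage, pb$stage_order)]
    is_term <- pb$pseudo_labels[hold] == pb$terminal_stage
    data.frame(seed = sd,
               auroc = auroc(score, is_term),
               auprc = auprc(score, is_term),
               n_holdout = length(hold),
               n_pos = sum(is_term))
  })
  out <- do.call(rbind, res)
  attr(out, "median_auroc") <- stats::median(out$auroc)
  attr(out, "median_auprc") <- stats::median(out$auprc)
  out
}

# Restrict a pseudobulk_set to a subset of blocks.
subset_blocks <- function(pb, idx) {
  structure(list(X2 = pb$X2[idx, , drop = FALSE],
                 Y2 = pb$Y2[idx, , drop = FALSE],
                 pseudo_labels = pb$pseudo_labels[idx],
                 block_members = pb$block_members[idx],
                 target_stage = pb$target_stage[idx],
                 stage_order = pb$stage_order,
                 terminal_stage = pb$terminal_stage,
                 block_size = pb$block_size,
                 target_weight = pb$target_weight),
            class = "pseudobulk_set")
}
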