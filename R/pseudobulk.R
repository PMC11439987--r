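#' Library-size normalize and log-transform single-cell counts
#'
#' Each cell is scaled to `scale_total` total counts and transformed with
#' `log(1 + x)` — the standard CP10K/log1p normalization. Cells with zero
#' total counts cannot be normalized and raise an error naming them.
#'
#' @param cells [expr_mat()] with layer `"counts"`.
#' @param scale_total Target total per cell (default 1e4).
#' @return [expr_mat()] with layer `"lognorm"`.
#' @export
normalize_cells <- function(cells, scale_total = 1e4) {
  stopifnot(inherits(cells, "expr_mat"))
  if (cells$layer != "counts")
    stop("normalize_cells expects a counts layer, got '", cells$layer, "'",
         call. = FALSE)
  totals <- rowSums(cells$values)
  if (any(totals == 0)) {
    bad <- rownames(cells$values)[totals == 0]
    stop("cannot normalize all-zero cell(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  x <- log1p(cells$values * (scale_total / totals))
  expr_mat(x, "lognorm")
}

#' Select highly variable genes
#'
#' With the default `"standardized"` method, genes are ranked by their
#' log-variance residual around a lowess fit of log-variance against
#' log-mean — the mean-variance-trend correction used by the standard
#' single-cell variable-feature selectors, without which highly expressed
#' genes crowd out genuinely variable ones. The `"variance"` method ranks
#' by raw variance of the (log-normalized) values. Ties break
#' deterministically by gene symbol; panels too small to fit a trend
#' (fewer than 20 genes with positive variance) fall back to raw
#' variance. When fewer than `n_top` genes are present, all genes are
#' returned in rank order.
#'
#' @param cells [expr_mat()] (log-normalized).
#' @param n_top Number of genes to keep (default 2000).
#' @param method `"standardized"` (default) or `"variance"`.
#' @return Character vector of gene symbols, most variable first.
#' @export
select_hvg <- function(cells, n_top = 2000,
                       method = c("standardized", "variance")) {
  method <- match.arg(method)
  stopifnot(inherits(cells, "expr_mat"))
  v <- col_vars(cells$values)
  g <- gene_ids(cells)
  score <- v
  if (method == "standardized" && sum(v > 0) >= 20) {
    m <- colMeans(cells$values)
    ok <- v > 0
    lw <- stats::lowess(log(m[ok] + 1e-10), log(v[ok]), f = 0.3)
    fitted <- stats::approx(lw$x, lw$y, xout = log(m + 1e-10),
                            rule = 2, ties = mean)$y
    score <- ifelse(v > 0, log(v) - fitted, -Inf)
  }
  ord <- order(-score, g)
  g[ord][seq_len(min(n_top, length(g)))]
}

#' Majority label of a block
#'
#' Returns the stage with the maximal count. Ties are broken toward the
#' block's drawn target stage (when it attains the maximum), then by
#' position in `stage_order`.
#'
#' @param counts Named integer vector (or table) of per-stage cell counts.
#' @param target The block's drawn target stage, or `NULL`.
#' @param stage_order Ordered stage vocabulary used for the final
#'   tie-break.
#' @return A single stage name.
#' @export
majority_label <- function(counts, target = NULL, stage_order = NULL) {
  counts <- counts[counts > 0]
  if (length(counts) == 0) stop("empty block counts", call. = FALSE)
  top <- names(counts)[counts == max(counts)]
  if (length(top) == 1) return(top)
  if (!is.null(target) && target %in% top) return(target)
  if (!is.null(stage_order)) {
    top <- top[order(match(top, stage_order))]
  } else top <- sort(top)
  top[1]
}

#' Build a pseudo-bulk training set by weighted block sampling
#'
#' For each block a target stage is drawn round-robin over `stage_order`
#' (so per-stage block counts differ by at most one). `block_size` cells
#' are then sampled — without replacement by default — with selection
#' weight `target_weight` for cells of the target stage and 1 for all
#' others. The block's profile is the arithmetic mean of its cells'
#' (log-normalized) expression rows, and its pseudo-label is the majority
#' stage of the block (ties toward the target stage).
#'
#' @param cells [expr_mat()], typically log-normalized.
#' @param labels [stage_labels()] covering every cell.
#' @param block_size Cells per block (default 100).
#' @param n_blocks Number of blocks (default 1000).
#' @param target_weight Relative selection weight of target-stage cells
#'   (default 10).
#' @param replace Sample cells within a block with replacement? Default
#'   `FALSE` (a block is a set of cells).
#' @param seed Integer seed.
#' @return A `pseudobulk_set`: list with `X2` (blocks-by-genes mean
#'   matrix), `Y2` (one-hot blocks-by-stages pseudo-label matrix),
#'   `pseudo_labels` (character vector), `block_members` (list of cell
#'   ids), `target_stage` (drawn target per block), `stage_order`,
#'   `terminal_stage`, `block_size`, and `target_weight`.
#' @export
sample_blocks <- function(cells, labels, block_size = 100, n_blocks = 1000,
                          target_weight = 10, replace = FALSE, seed = 1) {
  stopifnot(inherits(cells, "expr_mat"), inherits(labels, "stage_labels"))
  ids <- sample_ids(cells)
  lab <- labels$labels[ids]
  if (anyNA(lab))
    stop("cells without a stage label: ",
         paste(utils::head(ids[is.na(lab)], 5), collapse = ", "),
         call. = FALSE)
  stages <- labels$stage_order
  present <- stages %in% lab
  if (!all(present))
    stop("stage(s) with no cells: ",
         paste(stages[!present], collapse = ", "), call. = FALSE)
  n_cells <- length(ids)
  if (!replace && block_size > n_cells)
    stop("block_size (", block_size, ") exceeds number of cells (",
         n_cells, ")", call. = FALSE)

  with_seed(seed, {
    targets <- rep_len(stages, n_blocks)
    X2 <- matrix(0, n_blocks, ncol(cells$values),
                 dimnames = list(sprintf("pb%04d", seq_len(n_blocks)),
                                 gene_ids(cells)))
    members <- vector("list", n_blocks)
    plab <- character(n_blocks)
    lab_f <- factor(lab, levels = stages)
    for (b in seq_len(n_blocks)) {
      w <- ifelse(lab == targets[b], target_weight, 1)
      ix <- sample.int(n_cells, block_size, replace = replace, prob = w)
      members[[b]] <- ids[ix]
      X2[b, ] <- colMeans(cells$values[ix, , drop = FALSE])
      plab[b] <- majority_label(table(lab_f[ix]), targets[b], stages)
    }
    structure(list(X2 = X2,
                   Y2 = one_hot(plab, stages),
                   pseudo_labels = plab,
                   block_members = members,
                   target_stage = targets,
                   stage_order = stages,
                   terminal_stage = labels$terminal_stage,
                   block_size = block_size,
                   target_weight = target_weight),
              class = "pseudobulk_set")
  })
}

#' @export
print.pseudobulk_set <- function(x, ...) {
  cat(sprintf(paste0("<pseudobulk_set> %d blocks x %d genes, block size %d,",
                     " target weight %g\n"),
              nrow(x$X2), ncol(x$X2), x$block_size, x$target_weight))
  print(table(factor(x$pseudo_labels, levels = x$stage_order)))
  invisible(x)
}
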