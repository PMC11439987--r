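#' Teacher soft labels: per-sample terminal-stage score
#'
#' Scores real bulk samples with the trained teacher: the bulk matrix is
#' log2-transformed if needed, restricted to the teacher's gene set,
#' min-max scaled with the scaler stored at training time, encoded, and
#' classified; the returned soft label is the terminal-stage column of the
#' classifier output.
#'
#' @param bulk [expr_mat()] of bulk expression (linear scale or already
#'   `log2`).
#' @param teacher A `tex_teacher` from [train_teacher()].
#' @return Named numeric vector of scores in (0, 1), one per sample.
#' @export
teacher_soft_labels <- function(bulk, teacher) {
  stopifnot(inherits(bulk, "expr_mat"), inherits(teacher, "tex_teacher"))
  missing <- setdiff(teacher$genes, gene_ids(bulk))
  if (length(missing))
    stop("bulk matrix lacks ", length(missing), " teacher gene(s), e.g. ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  x <- bulk$values[, teacher$genes, drop = FALSE]
  if (bulk$layer != "log2") x <- log2(1 + x)
  xs <- apply_minmax(x, teacher$scaler_bulk)
  z <- classify(encode(xs, teacher$params), teacher$params)
  stats::setNames(z[, match(teacher$terminal_stage, teacher$stage_order)],
                  rownames(x))
}

#' Single-sample gene-set activity matrix
#'
#' A light-weight single-sample scorer: genes are z-scored across samples
#' and a set's activity in a sample is the mean z-score of the set's genes
#' present in the matrix. Genes with zero variance across samples are
#' unusable; sets with fewer than two usable genes are dropped with a
#' message. This is deliberately simple plumbing for feeding the student
#' with a pathway-level modality — it is not a GSVA reimplementation, and a
#' precomputed activity matrix can be supplied instead wherever this one is
#' accepted.
#'
#' @param bulk [expr_mat()] (samples x genes).
#' @param sets A `gene_sets` collection from [read_gmt()].
#' @return [expr_mat()] with layer `"activity"` (samples x sets).
#' @export
activity_matrix <- function(bulk, sets) {
  stopifnot(inherits(bulk, "expr_mat"), inherits(sets, "gene_sets"))
  x <- bulk$values
  sds <- sqrt(col_vars(x))
  usable <- colnames(x)[is.finite(sds) & sds > 0]
  z <- scale(x[, usable, drop = FALSE])
  act <- list()
  dropped <- character()
  for (nm in names(sets$sets)) {
    g <- intersect(sets$sets[[nm]], usable)
    if (length(g) < 2) {
      dropped <- c(dropped, nm)
      next
    }
    act[[nm]] <- rowMeans(z[, g, drop = FALSE])
  }
  if (length(dropped))
    message("dropped ", length(dropped),
            " gene set(s) with < 2 usable genes: ",
            paste(utils::head(dropped, 5), collapse = ", "))
  if (length(act) == 0)
    stop("no usable gene sets (need >= 2 present, non-constant genes)",
         call. = FALSE)
  m <- do.call(cbind, act)
  rownames(m) <- rownames(x)
  expr_mat(m, "activity")
}

#' Student network forward pass
#'
#' The student is a one-hidden-layer network
#' `sigmoid(relu(X3 W1 + b1) W2 + b2)` mapping a feature matrix (pathway
#' activities or genes) to a per-sample exhaustion score.
#'
#' @param X3 Numeric matrix (samples x features) or [expr_mat()]; columns
#'   must match the parameters' feature axis.
#' @param sp A `student_params` list with `W1`, `b1`, `W2`, `b2`.
#' @return Named numeric vector of scores in (0, 1).
#' @export
student_forward <- function(X3, sp) {
  if (inherits(X3, "expr_mat")) X3 <- X3$values
  if (ncol(X3) != nrow(sp$W1))
    stop("dimension error: input has ", ncol(X3), " features but student ",
         "expects ", nrow(sp$W1), call. = FALSE)
  H <- relu(sweep(X3 %*% sp$W1, 2, sp$b1, "+"))
  stats::setNames(as.vector(sigmoid(H %*% sp$W2 + sp$b2)), rownames(X3))
}

train_student_member <- function(X3, y, l1_coeff, d_hidden, lr, epochs,
                                 batch_size, loss, seed) {
  with_seed(seed, {
    n <- nrow(X3); F_in <- ncol(X3)
    boot <- sample.int(n, n, replace = TRUE)
    Xb_all <- X3[boot, , drop = FALSE]
    yb_all <- y[boot]
    sp <- list(
      W1 = matrix(stats::rnorm(F_in * d_hidden, 0, sqrt(2 / F_in)),
                  F_in, d_hidden),
      b1 = rep(0, d_hidden),
      W2 = matrix(stats::rnorm(d_hidden, 0, sqrt(2 / (d_hidden + 1)))),
      # start at the constant predictor: soft labels often sit far from
      # 0.5, where a zero-initialized sigmoid output learns very slowly
      b2 = stats::qlogis(min(max(mean(y), 1e-4), 1 - 1e-4)))
    state <- adam_init(sp)
    bs <- min(batch_size, n)
    steps <- ceiling(n / bs)
    final_loss <- NA_real_
    for (ep in seq_len(epochs)) {
      perm <- sample.int(n)
      lsum <- 0
      for (st in seq_len(steps)) {
        ix <- perm[seq((st - 1) * bs + 1, min(st * bs, n))]
        Xb <- Xb_all[ix, , drop = FALSE]
        yb <- yb_all[ix]
        m <- length(ix)
        A1 <- sweep(Xb %*% sp$W1, 2, sp$b1, "+")
        H <- relu(A1)
        A2 <- as.vector(H %*% sp$W2 + sp$b2)
        yhat <- sigmoid(A2)
        if (loss == "mse") {
          l <- mean((yhat - yb)^2)
          dA2 <- (2 / m) * (yhat - yb) * yhat * (1 - yhat)
        } else {  # cross-entropy on soft targets
          p <- pmin(pmax(yhat, 1e-7), 1 - 1e-7)
          l <- mean(-(yb * log(p) + (1 - yb) * log(1 - p)))
          dA2 <- (yhat - yb) / m
        }
        l <- l + l1_coeff * sum(abs(sp$W1))
        dA2 <- matrix(dA2, ncol = 1)
        g <- list(W2 = crossprod(H, dA2), b2 = sum(dA2))
        dH <- tcrossprod(dA2, sp$W2)
        dA1 <- dH * (A1 > 0)
        g$W1 <- crossprod(Xb, dA1) + l1_coeff * sign(sp$W1)
        g$b1 <- colSums(dA1)
        upd <- adam_step(sp, g, state, lr)
        sp <- upd$params
        state <- upd$state
        lsum <- lsum + l
      }
      final_loss <- lsum / steps
      if (!is.finite(final_loss))
        stop("student training diverged (non-finite loss) at epoch ", ep,
             call. = FALSE)
    }
    sp$final_loss <- final_loss
    sp
  })
}

#' Distil the teacher into a bagged ensemble of L1-sparse students
#'
#' Trains `B` student networks, each on a bootstrap resample (with
#' replacement, same n) of the feature matrix and the teacher's soft
#' labels, minimizing mean squared error to the soft label plus an L1
#' penalty `l1_coeff * sum(|W1|)` on the first-layer weights. Features are
#' standardized (mean 0, sd 1) on the training data and the scaler is
#' stored in the ensemble, so first-layer weight mass is comparable across
#' features. The ensemble prediction is the mean of the member outputs.
#'
#' @param X3 Samples x features matrix or [expr_mat()]: a pathway-activity
#'   matrix, a user-supplied precomputed activity matrix, or the full bulk
#'   gene matrix.
#' @param soft_labels Numeric vector in (0, 1), one per row of `X3`
#'   (see [teacher_soft_labels()]).
#' @param l1_coeff L1 coefficient on the first layer (default 1e-4).
#' @param d_hidden Hidden width (default 128).
#' @param lr Learning rate (default 1e-3).
#' @param epochs Training epochs per member (default 4000).
#' @param batch_size Minibatch size (default 100).
#' @param B Ensemble size (default 10).
#' @param loss `"mse"` (default) or `"ce"` (cross-entropy on soft
#'   targets).
#' @param standardize Standardize features before training (default
#'   `TRUE`).
#' @param seed Integer seed; member seeds are derived as `seed + 1:B` and
#'   recorded.
#' @return A `student_ensemble`: list with `members` (each a
#'   `student_params` list), `member_seeds`, `feature_ids`, `scaler`
#'   (feature means/sds or `NULL`), `l1_coeff`, and `config`.
#' @export
train_student <- function(X3, soft_labels, l1_coeff = 1e-4, d_hidden = 128,
                          lr = 1e-3, epochs = 4000, batch_size = 100,
                          B = 10, loss = c("mse", "ce"), standardize = TRUE,
                          seed = 1) {
  loss <- match.arg(loss)
  if (inherits(X3, "expr_mat")) X3 <- X3$values
  stopifnot(is.matrix(X3), nrow(X3) == length(soft_labels), l1_coeff >= 0)
  if (is.null(colnames(X3)))
    colnames(X3) <- sprintf("f%04d", seq_len(ncol(X3)))
  scaler <- NULL
  if (standardize) {
    mu <- colMeans(X3)
    sd <- sqrt(col_vars(X3))
    sd[!is.finite(sd) | sd == 0] <- 1
    scaler <- list(mean = mu, sd = sd)
    X3 <- sweep(sweep(X3, 2, mu, "-"), 2, sd, "/")
  }
  member_seeds <- seed + seq_len(B)
  members <- lapply(member_seeds, function(s)
    train_student_member(X3, soft_labels, l1_coeff, d_hidden, lr, epochs,
                         batch_size, loss, s))
  structure(list(members = members,
                 member_seeds = member_seeds,
                 feature_ids = colnames(X3),
                 scaler = scaler,
                 l1_coeff = l1_coeff,
                 config = list(d_hidden = d_hidden, lr = lr,
                               epochs = epochs, batch_size = batch_size,
                               B = B, loss = loss)),
            class = "student_ensemble")
}

#' @export
print.student_ensemble <- function(x, ...) {
  cat(sprintf(paste0("<student_ensemble> %d members, %d features, hidden ",
                     "%d, L1 %g\n"),
              length(x$members), length(x$feature_ids),
              x$config$d_hidden, x$l1_coeff))
  invisible(x)
}

#' Ensemble exhaustion score
#'
#' Applies the ensemble's stored feature scaler (if any) and returns the
#' arithmetic mean of the member networks' outputs.
#'
#' @param X3 Samples x features matrix or [expr_mat()] with the ensemble's
#'   features.
#' @param ens A `student_ensemble`.
#' @return Named numeric vector of per-sample exhaustion scores in (0, 1).
#' @export
ensemble_score <- function(X3, ens) {
  stopifnot(inherits(ens, "student_ensemble"))
  if (inherits(X3, "expr_mat")) X3 <- X3$values
  missing <- setdiff(ens$feature_ids, colnames(X3))
  if (length(missing))
    stop("input lacks ", length(missing), " ensemble feature(s)",
         call. = FALSE)
  X3 <- X3[, ens$feature_ids, drop = FALSE]
  if (!is.null(ens$scaler))
    X3 <- sweep(sweep(X3, 2, ens$scaler$mean, "-"), 2, ens$scaler$sd, "/")
  preds <- vapply(ens$members, function(sp) student_forward(X3, sp),
                  numeric(nrow(X3)))
  if (is.null(dim(preds))) preds <- matrix(preds, nrow = 1)
  stats::setNames(rowMeans(preds), rownames(X3))
}

#' Rank input features by first-layer weight mass
#'
#' The importance of feature `f` is the ensemble mean of
#' `sum_h |W1[f, h]|` — the natural readout of the L1-penalized first
#' layer. A gradient-times-input attribution is available as a secondary
#' method (requires the data matrix).
#'
#' @param ens A `student_ensemble`.
#' @param method `"l1_weight"` (default) or `"grad_input"`.
#' @param X3 Feature matrix, required for `"grad_input"`.
#' @return Data frame with columns `feature_id`, `importance`, `rank`,
#'   sorted by rank (descending importance, ties broken by feature id).
#' @export
feature_importance <- function(ens, method = c("l1_weight", "grad_input"),
                               X3 = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(ens, "student_ensemble"))
  if (method == "l1_weight") {
    imp <- rowMeans(vapply(ens$members,
                           function(sp) rowSums(abs(sp$W1)),
                           numeric(length(ens$feature_ids))))
  } else {
    if (is.null(X3)) stop("grad_input importance needs X3", call. = FALSE)
    if (inherits(X3, "expr_mat")) X3 <- X3$values
    X3 <- X3[, ens$feature_ids, drop = FALSE]
    if (!is.null(ens$scaler))
      X3 <- sweep(sweep(X3, 2, ens$scaler$mean, "-"), 2, ens$scaler$sd, "/")
    imp <- rowMeans(vapply(ens$members, function(sp) {
      A1 <- sweep(X3 %*% sp$W1, 2, sp$b1, "+")
      H <- relu(A1)
      yhat <- as.vector(sigmoid(H %*% sp$W2 + sp$b2))
      # d yhat / d x_f = yhat(1-yhat) * sum_h W1[f,h] 1[A1_h>0] W2[h]
      gate <- (A1 > 0) * matrix(rep(as.vector(sp$W2), each = nrow(X3)),
                                nrow(X3), length(sp$W2))
      grad <- tcrossprod(gate, sp$W1) * (yhat * (1 - yhat))
      colMeans(abs(grad * X3))
    }, numeric(length(ens$feature_ids))))
  }
  names(imp) <- ens$feature_ids
  ord <- order(-imp, names(imp))
  data.frame(feature_id = names(imp)[ord],
             importance = unname(imp[ord]),
             rank = seq_along(imp),
             row.names = NULL)
}
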