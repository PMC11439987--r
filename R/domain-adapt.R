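#' Loss configuration for the domain-adaptation teacher
#'
#' @param lambda1 Weight of the category (cross-entropy) loss on
#'   pseudo-bulk. Default 0.1.
#' @param lambda2 Weight of the reconstruction loss on real bulk. Default
#'   0.1.
#' @param lambda3 Weight of the maximum-mean-discrepancy penalty between
#'   the two latent representations. Default 0.8.
#' @param sigma Gaussian kernel bandwidth, or `"median-heuristic"` to use
#'   the median pairwise distance of the pooled latent batch.
#' @return A `loss_config` list.
#' @export
loss_config <- function(lambda1 = 0.1, lambda2 = 0.1, lambda3 = 0.8,
                        sigma = "median-heuristic") {
  if (lambda1 < 0 || lambda2 < 0 || lambda3 < 0)
    stop("loss weights must be >= 0", call. = FALSE)
  if (is.numeric(sigma) && sigma <= 0)
    stop("sigma must be > 0", call. = FALSE)
  structure(list(lambda1 = lambda1, lambda2 = lambda2, lambda3 = lambda3,
                 sigma = sigma), class = "loss_config")
}

#' Training configuration for the domain-adaptation teacher
#'
#' Defaults follow the method's published training regime: learning rate
#' 1e-3, 100 epochs, batch size 100, latent dimension 256, and 1000 rounds
#' of bulk resampling.
#'
#' @param lr Learning rate of the Adam optimizer.
#' @param epochs Training epochs.
#' @param batch_size Minibatch size (applied to both domains).
#' @param d_latent Latent dimension shared by the autoencoder and the
#'   classifier.
#' @param bulk_expansion_n Number of bulk resampling rounds used by
#'   [expand_bulk()].
#' @param seed Integer seed for initialization and batching.
#' @return A `train_config` list.
#' @export
train_config <- function(lr = 1e-3, epochs = 100, batch_size = 100,
                         d_latent = 256, bulk_expansion_n = 1000,
                         seed = 1) {
  stopifnot(lr > 0, epochs >= 1, batch_size >= 1, d_latent >= 1,
            bulk_expansion_n >= 1)
  structure(list(lr = lr, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 d_latent = as.integer(d_latent),
                 bulk_expansion_n = as.integer(bulk_expansion_n),
                 seed = seed),
            class = "train_config")
}

#' Expand a bulk cohort by resampling and apply log2 normalization
#'
#' Rows are sampled with replacement from the input until `n` rows are
#' obtained, then `log2(1 + x)` is applied. Row ids carry a replicate
#' suffix.
#'
#' @param bulk [expr_mat()] on a linear expression scale.
#' @param n Number of output rows (default 1000).
#' @param seed Integer seed.
#' @return [expr_mat()] with layer `"log2"`.
#' @export
expand_bulk <- function(bulk, n = 1000, seed = 1) {
  stopifnot(inherits(bulk, "expr_mat"))
  if (nrow(bulk$values) < 1) stop("empty bulk matrix", call. = FALSE)
  with_seed(seed, {
    ix <- sample.int(nrow(bulk$values), n, replace = TRUE)
    x <- log2(1 + bulk$values[ix, , drop = FALSE])
    rownames(x) <- sprintf("%s_r%04d", rownames(bulk$values)[ix],
                           seq_len(n))
    expr_mat(x, "log2")
  })
}

# --- min-max gene scaler (sigmoid decoder needs targets in [0,1]) --------

fit_minmax <- function(x) {
  lo <- apply(x, 2, min)
  hi <- apply(x, 2, max)
  list(min = lo, range = pmax(hi - lo, 1e-12))
}

apply_minmax <- function(x, scaler) {
  sweep(sweep(x, 2, scaler$min, "-"), 2, scaler$range, "/")
}

# --- network primitives --------------------------------------------------

#' Network primitives of the teacher
#'
#' `encode()` is the shared encoder `relu(X W1 + b1)`; `decode()` is the
#' autoencoder's reconstruction head `sigmoid(Y W2_dec + b2_dec)`; `tss()`
#' is the temperature-scaled sigmoid `1 / (1 + exp(-x / t))`; `classify()`
#' maps latents to per-stage scores through `tss` of an affine map (or a
#' temperature-scaled softmax when the parameters were trained in softmax
#' mode).
#'
#' @param X Numeric matrix (rows = samples) whose columns match the
#'   encoder input.
#' @param Y Latent matrix (rows = samples).
#' @param p A `da_params` object (see [train_teacher()]).
#' @param x Numeric vector or matrix.
#' @param t Temperature, must be positive.
#' @param convention `"scaled"` computes `sigmoid(x / t)` (the
#'   conventional temperature scaling); `"literal"` computes
#'   `sigmoid(x * t)`. Both coincide at `t = 1`.
#' @return A numeric matrix (or vector for `tss`).
#' @name teacher-primitives
NULL

#' @rdname teacher-primitives
#' @export
encode <- function(X, p) {
  if (inherits(X, "expr_mat")) X <- X$values
  if (ncol(X) != nrow(p$W1))
    stop("dimension error: input has ", ncol(X), " features but encoder ",
         "expects ", nrow(p$W1), call. = FALSE)
  relu(sweep(X %*% p$W1, 2, p$b1, "+"))
}

#' @rdname teacher-primitives
#' @export
decode <- function(Y, p) {
  if (ncol(Y) != nrow(p$W2_dec))
    stop("dimension error: latent has ", ncol(Y), " dims but decoder ",
         "expects ", nrow(p$W2_dec), call. = FALSE)
  sigmoid(sweep(Y %*% p$W2_dec, 2, p$b2_dec, "+"))
}

#' @rdname teacher-primitives
#' @export
tss <- function(x, t = 2, convention = c("scaled", "literal")) {
  convention <- match.arg(convention)
  if (t <= 0) stop("temperature must be > 0", call. = FALSE)
  if (convention == "scaled") sigmoid(x / t) else sigmoid(x * t)
}

#' @rdname teacher-primitives
#' @export
classify <- function(Y, p) {
  if (ncol(Y) != nrow(p$W2_cls))
    stop("dimension error: latent has ", ncol(Y), " dims but classifier ",
         "expects ", nrow(p$W2_cls), call. = FALSE)
  A <- sweep(Y %*% p$W2_cls, 2, p$b2_cls, "+")
  if (identical(p$activation, "softmax")) {
    E <- exp((A - apply(A, 1, max)) / p$t)
    E / rowSums(E)
  } else {
    tss(A, p$t, p$temp_convention %||% "scaled")
  }
}

# --- loss components -----------------------------------------------------

pairwise_sqdist <- function(A, B) {
  d <- outer(rowSums(A * A), rowSums(B * B), "+") - 2 * tcrossprod(A, B)
  d[d < 0] <- 0
  d
}

resolve_sigma <- function(Y1, Y2, sigma) {
  if (is.numeric(sigma)) return(sigma)
  P <- rbind(Y1, Y2)
  d <- sqrt(pairwise_sqdist(P, P))
  med <- stats::median(d[upper.tri(d)])
  if (!is.finite(med) || med <= 0) 1 else med
}

#' Maximum mean discrepancy between two latent sets
#'
#' The biased (V-statistic) squared MMD with Gaussian kernel
#' `k(x, y) = exp(-||x - y||^2 / (2 sigma^2))`:
#' `mean(K11) + mean(K22) - 2 mean(K12)`, multiplied by `lambda3`. With
#' `sigma = "median-heuristic"` the bandwidth is the median pairwise
#' distance of the pooled rows.
#'
#' @param Y1,Y2 Numeric matrices with the same number of columns; rows are
#'   samples.
#' @param sigma Kernel bandwidth or `"median-heuristic"`.
#' @param lambda3 Multiplier (default 1 returns the plain statistic).
#' @return A single non-negative number.
#' @export
mmd_loss <- function(Y1, Y2, sigma = "median-heuristic", lambda3 = 1) {
  if (is.null(dim(Y1))) Y1 <- matrix(Y1, ncol = 1)
  if (is.null(dim(Y2))) Y2 <- matrix(Y2, ncol = 1)
  if (nrow(Y1) == 0 || nrow(Y2) == 0)
    stop("mmd_loss requires non-empty sets", call. = FALSE)
  s <- resolve_sigma(Y1, Y2, sigma)
  k11 <- exp(-pairwise_sqdist(Y1, Y1) / (2 * s^2))
  k22 <- exp(-pairwise_sqdist(Y2, Y2) / (2 * s^2))
  k12 <- exp(-pairwise_sqdist(Y1, Y2) / (2 * s^2))
  lambda3 * (mean(k11) + mean(k22) - 2 * mean(k12))
}

#' Reconstruction loss of the autoencoder branch
#'
#' `lambda2` times the mean over samples of the squared Euclidean distance
#' between each (min-max-scaled) input row and its reconstruction.
#'
#' @param Z1_hat Reconstruction matrix.
#' @param X_target Target matrix (same shape).
#' @param lambda2 Loss weight.
#' @return A single non-negative number.
#' @export
reconstruction_loss <- function(Z1_hat, X_target, lambda2 = 0.1) {
  if (is.null(dim(Z1_hat))) Z1_hat <- matrix(Z1_hat, nrow = 1)
  if (is.null(dim(X_target))) X_target <- matrix(X_target, nrow = 1)
  stopifnot(all(dim(Z1_hat) == dim(X_target)))
  lambda2 * sum((X_target - Z1_hat)^2) / nrow(Z1_hat)
}

#' Category loss of the classifier branch
#'
#' `lambda1` times the cross-entropy `-sum_j z_ij log(zhat_ij)` averaged
#' over samples, with predictions clipped to `[1e-7, 1 - 1e-7]`.
#'
#' @param Z2_hat Predicted score matrix (rows = samples).
#' @param labels One-hot label matrix of the same shape.
#' @param lambda1 Loss weight.
#' @return A single non-negative number.
#' @export
category_loss <- function(Z2_hat, labels, lambda1 = 0.1) {
  if (is.null(dim(Z2_hat))) Z2_hat <- matrix(Z2_hat, nrow = 1)
  if (is.null(dim(labels))) labels <- matrix(labels, nrow = 1)
  stopifnot(all(dim(Z2_hat) == dim(labels)))
  p <- pmin(pmax(Z2_hat, 1e-7), 1 - 1e-7)
  lambda1 * sum(-labels * log(p)) / nrow(Z2_hat)
}

# --- Adam optimizer ------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

init_da_params <- function(n_genes, d_latent, n_classes, t, activation,
                           temp_convention, tied = TRUE) {
  p <- list(
    W1 = matrix(stats::rnorm(n_genes * d_latent, 0, sqrt(2 / n_genes)),
                n_genes, d_latent),
    b1 = rep(0, d_latent),
    W2_dec = matrix(stats::rnorm(d_latent * n_genes, 0,
                                 sqrt(2 / (d_latent + n_genes))),
                    d_latent, n_genes),
    b2_dec = rep(0, n_genes),
    W2_cls = matrix(stats::rnorm(d_latent * n_classes, 0,
                                 sqrt(2 / (d_latent + n_classes))),
                    d_latent, n_classes),
    b2_cls = rep(0, n_classes))
  if (!tied) {
    p$W1_src <- matrix(stats::rnorm(n_genes * d_latent, 0,
                                    sqrt(2 / n_genes)), n_genes, d_latent)
    p$b1_src <- rep(0, d_latent)
  }
  p$t <- t
  p$activation <- activation
  p$temp_convention <- temp_convention
  p$tied <- tied
  structure(p, class = "da_params")
}

# Gradient of the V-statistic MMD with respect to both latent sets.
# d/dx_i sum_j k(x_i, x_j) pairs = -(2/s^2) (rowSums(K) * x - K x);
# cross terms analogous with a single factor 1/s^2.
mmd_grads <- function(Y1, Y2, s, lambda3) {
  n <- nrow(Y1); m <- nrow(Y2)
  k11 <- exp(-pairwise_sqdist(Y1, Y1) / (2 * s^2))
  k22 <- exp(-pairwise_sqdist(Y2, Y2) / (2 * s^2))
  k12 <- exp(-pairwise_sqdist(Y1, Y2) / (2 * s^2))
  val <- lambda3 * (mean(k11) + mean(k22) - 2 * mean(k12))
  g1 <- lambda3 * (-2 / s^2) *
    ((rowSums(k11) * Y1 - k11 %*% Y1) / n^2 -
       (rowSums(k12) * Y1 - k12 %*% Y2) / (n * m))
  g2 <- lambda3 * (-2 / s^2) *
    ((rowSums(k22) * Y2 - k22 %*% Y2) / m^2 -
       (colSums(k12) * Y2 - crossprod(k12, Y1)) / (n * m))
  list(value = val, g1 = g1, g2 = g2)
}

#' Train the domain-adaptation teacher
#'
#' Jointly trains, by minibatch Adam on the composite loss, (i) an
#' autoencoder on the (expanded, log2, min-max-scaled) real bulk matrix,
#' (ii) a stage classifier on the (min-max-scaled) pseudo-bulk matrix
#' through a shared encoder, and (iii) a Gaussian-kernel MMD penalty
#' pulling the two latent representations together. Per-gene min-max
#' scalers are fitted on each domain and stored in the returned model so
#' new samples can be scored on the training scale.
#'
#' @param pseudo A `pseudobulk_set` from [sample_blocks()] (source
#'   domain).
#' @param bulk [expr_mat()] of expanded, log2-normalized real bulk (target
#'   domain), gene axis identical to `pseudo`'s (see [align_genes()]).
#' @param loss_cfg A [loss_config()].
#' @param train_cfg A [train_config()].
#' @param t Temperature of the temperature-scaled sigmoid (the published
#'   equations leave it free; default 2).
#' @param activation `"softmax"` (temperature-scaled softmax, the
#'   default) or `"tss"` (per-class temperature-scaled sigmoid). The
#'   per-class sigmoid, combined with the positive-only cross-entropy of
#'   [category_loss()], has no term pushing wrong-class scores down, so
#'   all scores saturate toward 1 during long training runs; it is kept as
#'   an option but softmax is the default.
#' @param temp_convention `"scaled"` for `sigmoid(x / t)` or `"literal"`
#'   for `sigmoid(x * t)`.
#' @param tied Use one shared encoder for both domains (default `TRUE`);
#'   `FALSE` trains a separate source encoder.
#' @return A `tex_teacher`: list with `params` (`da_params`),
#'   `scaler_bulk`, `scaler_pseudo`, `genes`, `stage_order`,
#'   `terminal_stage`, `trace` (per-epoch data frame of the three loss
#'   components and their sum), `loss_cfg`, `train_cfg`.
#' @export
train_teacher <- function(pseudo, bulk, loss_cfg = loss_config(),
                          train_cfg = train_config(), t = 2,
                          activation = c("softmax", "tss"),
                          temp_convention = c("scaled", "literal"),
                          tied = TRUE) {
  activation <- match.arg(activation)
  temp_convention <- match.arg(temp_convention)
  stopifnot(inherits(pseudo, "pseudobulk_set"), inherits(bulk, "expr_mat"))
  if (!identical(colnames(pseudo$X2), gene_ids(bulk)))
    stop("gene axes differ between pseudo-bulk and bulk; run align_genes()",
         call. = FALSE)

  scaler_src <- fit_minmax(pseudo$X2)
  scaler_tgt <- fit_minmax(bulk$values)
  Xs <- apply_minmax(pseudo$X2, scaler_src)
  Xt <- apply_minmax(bulk$values, scaler_tgt)
  Ys <- pseudo$Y2
  C <- ncol(Ys)
  G <- ncol(Xs)
  ns <- nrow(Xs); nt <- nrow(Xt)
  bs <- min(train_cfg$batch_size, ns, nt)

  with_seed(train_cfg$seed, {
    params <- init_da_params(G, train_cfg$d_latent, C, t, activation,
                             temp_convention, tied)
    opt_names <- c("W1", "b1", "W2_dec", "b2_dec", "W2_cls", "b2_cls",
                   if (!tied) c("W1_src", "b1_src"))
    state <- adam_init(params[opt_names])
    steps <- ceiling(ns / bs)
    trace <- data.frame(epoch = seq_len(train_cfg$epochs),
                        reconstruction = NA_real_, category = NA_real_,
                        mmd = NA_real_, total = NA_real_)

    for (ep in seq_len(train_cfg$epochs)) {
      ps <- sample.int(ns)
      pt <- sample.int(nt)
      acc <- c(rec = 0, cat = 0, mmd = 0)
      tpos <- 0L
      for (st in seq_len(steps)) {
        si <- ps[seq((st - 1) * bs + 1, min(st * bs, ns))]
        ti <- pt[(tpos + seq_len(bs) - 1L) %% nt + 1L]
        tpos <- (tpos + bs) %% nt
        Xb <- Xt[ti, , drop = FALSE]
        Xp <- Xs[si, , drop = FALSE]
        Yp <- Ys[si, , drop = FALSE]
        nb <- nrow(Xb); np <- nrow(Xp)

        W1s <- if (tied) params$W1 else params$W1_src
        b1s <- if (tied) params$b1 else params$b1_src

        # forward: autoencoder branch (target domain)
        A1 <- sweep(Xb %*% params$W1, 2, params$b1, "+")
        Y1 <- relu(A1)
        A2 <- sweep(Y1 %*% params$W2_dec, 2, params$b2_dec, "+")
        Z1 <- sigmoid(A2)
        l_rec <- loss_cfg$lambda2 * sum((Xb - Z1)^2) / nb

        # forward: classifier branch (source domain)
        A3 <- sweep(Xp %*% W1s, 2, b1s, "+")
        Y2 <- relu(A3)
        A4 <- sweep(Y2 %*% params$W2_cls, 2, params$b2_cls, "+")
        if (activation == "softmax") {
          E <- exp((A4 - apply(A4, 1, max)) / t)
          Z2 <- E / rowSums(E)
        } else {
          Z2 <- if (temp_convention == "scaled") sigmoid(A4 / t) else
            sigmoid(A4 * t)
        }
        pclip <- pmin(pmax(Z2, 1e-7), 1 - 1e-7)
        l_cat <- loss_cfg$lambda1 * sum(-Yp * log(pclip)) / np

        # backward: decoder
        dZ1 <- (2 * loss_cfg$lambda2 / nb) * (Z1 - Xb)
        dA2 <- dZ1 * Z1 * (1 - Z1)
        g <- list()
        g$W2_dec <- crossprod(Y1, dA2)
        g$b2_dec <- colSums(dA2)
        dY1 <- tcrossprod(dA2, params$W2_dec)

        # backward: classifier head
        if (activation == "softmax") {
          dA4 <- (loss_cfg$lambda1 / (np * t)) * (Z2 - Yp)
        } else {
          tmul <- if (temp_convention == "scaled") 1 / t else t
          dA4 <- (loss_cfg$lambda1 / np) * (-Yp * (1 - Z2)) * tmul
        }
        g$W2_cls <- crossprod(Y2, dA4)
        g$b2_cls <- colSums(dA4)
        dY2 <- tcrossprod(dA4, params$W2_cls)

        # MMD penalty between the two latent batches
        if (loss_cfg$lambda3 > 0) {
          s <- resolve_sigma(Y1, Y2, loss_cfg$sigma)
          mg <- mmd_grads(Y1, Y2, s, loss_cfg$lambda3)
          l_mmd <- mg$value
          dY1 <- dY1 + mg$g1
          dY2 <- dY2 + mg$g2
        } else l_mmd <- 0

        # through the relu encoder(s)
        dA1 <- dY1 * (A1 > 0)
        dA3 <- dY2 * (A3 > 0)
        if (tied) {
          g$W1 <- crossprod(Xb, dA1) + crossprod(Xp, dA3)
          g$b1 <- colSums(dA1) + colSums(dA3)
        } else {
          g$W1 <- crossprod(Xb, dA1)
          g$b1 <- colSums(dA1)
          g$W1_src <- crossprod(Xp, dA3)
          g$b1_src <- colSums(dA3)
        }

        upd <- adam_step(params[opt_names], g[opt_names], state,
                         train_cfg$lr)
        params[opt_names] <- upd$params
        state <- upd$state
        acc <- acc + c(l_rec, l_cat, l_mmd)
      }
      acc <- acc / steps
      tot <- sum(acc)
      if (!is.finite(tot))
        stop("training diverged (non-finite loss) at epoch ", ep,
             call. = FALSE)
      trace[ep, -1] <- c(acc, tot)
    }

    structure(list(params = params,
                   scaler_bulk = scaler_tgt,
                   scaler_pseudo = scaler_src,
                   genes = colnames(pseudo$X2),
                   stage_order = pseudo$stage_order,
                   terminal_stage = pseudo$terminal_stage,
                   trace = trace,
                   loss_cfg = loss_cfg,
                   train_cfg = train_cfg),
              class = "tex_teacher")
  })
}

#' @export
print.tex_teacher <- function(x, ...) {
  last <- x$trace[nrow(x$trace), ]
  cat(sprintf(paste0("<tex_teacher> %d genes -> latent %d -> %d stages ",
                     "(terminal: %s)\n  final losses: reconstruction ",
                     "%.4g, category %.4g, mmd %.4g\n"),
              length(x$genes), x$train_cfg$d_latent,
              length(x$stage_order), x$terminal_stage,
              last$reconstruction, last$category, last$mmd))
  invisible(x)
}
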