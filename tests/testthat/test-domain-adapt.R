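test_that("encoder, decoder and tss match brute-force oracles", {
  set.seed(41)
  G <- 7; d <- 5; C <- 3
  p <- structure(list(
    W1 = matrix(rnorm(G * d), G, d), b1 = rnorm(d),
    W2_dec = matrix(rnorm(d * G), d, G), b2_dec = rnorm(G),
    W2_cls = matrix(rnorm(d * C), d, C), b2_cls = rnorm(C),
    t = 2, activation = "tss", temp_convention = "scaled", tied = TRUE),
    class = "da_params")
  X <- matrix(rnorm(5 * G), 5, G)

  # explicit elementwise matrix-product + clamp oracle
  oracle_enc <- matrix(0, 5, d)
  for (i in 1:5) for (j in 1:d)
    oracle_enc[i, j] <- max(0, sum(X[i, ] * p$W1[, j]) + p$b1[j])
  expect_equal(encode(X, p), oracle_enc, tolerance = 1e-12)

  Y <- encode(X, p)
  oracle_dec <- matrix(0, 5, G)
  for (i in 1:5) for (j in 1:G)
    oracle_dec[i, j] <- 1 / (1 + exp(-(sum(Y[i, ] * p$W2_dec[, j]) +
                                         p$b2_dec[j])))
  expect_equal(decode(Y, p), oracle_dec, tolerance = 1e-12)
  expect_true(all(decode(Y, p) > 0 & decode(Y, p) < 1))

  # zero parameters: zero latent; zero affine input decodes to 0.5
  p0 <- p
  p0$W1 <- p$W1 * 0; p0$b1 <- p$b1 * 0
  expect_true(all(encode(X, p0) == 0))
  pz <- p
  pz$W2_dec <- p$W2_dec * 0; pz$b2_dec <- p$b2_dec * 0
  expect_true(all(decode(Y * 0, pz) == 0.5))

  # logistic symmetry of the decoder
  pneg <- p
  pneg$W2_dec <- -p$W2_dec; pneg$b2_dec <- -p$b2_dec
  expect_equal(decode(Y, p) + decode(Y, pneg),
               matrix(1, 5, G), tolerance = 1e-12)

  # temperature-scaled sigmoid
  expect_equal(tss(0, 7), 0.5)
  expect_equal(tss(1.3, 1), 1 / (1 + exp(-1.3)))
  expect_lt(abs(tss(1, 10) - 0.5), abs(tss(1, 1) - 0.5))
  xg <- seq(-3, 3, by = 0.25)
  expect_true(all(diff(tss(xg, 2)) > 0))
  expect_error(tss(1, 0), "temperature")

  # classifier: tss of the affine map; oracle agreement
  Z <- classify(Y, p)
  oracle_cls <- matrix(0, 5, C)
  for (i in 1:5) for (j in 1:C)
    oracle_cls[i, j] <- 1 / (1 + exp(-(sum(Y[i, ] * p$W2_cls[, j]) +
                                         p$b2_cls[j]) / p$t))
  expect_equal(Z, oracle_cls, tolerance = 1e-12)
  psm <- p
  psm$activation <- "softmax"
  expect_equal(rowSums(classify(Y, psm)), rep(1, 5), tolerance = 1e-9)

  expect_error(encode(X[, 1:3], p), "dimension")
  expect_error(decode(Y[, 1:2], p), "dimension")
})

test_that("mmd_loss matches closed forms and an explicit double sum", {
  set.seed(42)
  A <- matrix(rnorm(12), 4, 3)
  expect_identical(mmd_loss(A, A, sigma = 1), 0)
  expect_equal(mmd_loss(A, A[sample(4), ], sigma = 1), 0, tolerance = 1e-12)

  # two point masses at distance d: MMD^2 = 2(1 - exp(-d^2 / 2 sigma^2))
  x <- matrix(c(0, 0), 1)
  y <- matrix(c(3, 4), 1)  # distance 5
  s <- 1.7
  expect_equal(mmd_loss(x, y, sigma = s),
               2 * (1 - exp(-25 / (2 * s^2))), tolerance = 1e-12)

  # brute-force double-sum oracle on random 10-point sets
  Y1 <- matrix(rnorm(10 * 4), 10, 4)
  Y2 <- matrix(rnorm(10 * 4), 10, 4)
  s <- 1.3
  k <- function(a, b) exp(-sum((a - b)^2) / (2 * s^2))
  acc <- c(0, 0, 0)
  for (i in 1:10) for (j in 1:10) {
    acc[1] <- acc[1] + k(Y1[i, ], Y1[j, ])
    acc[2] <- acc[2] + k(Y2[i, ], Y2[j, ])
    acc[3] <- acc[3] + k(Y1[i, ], Y2[j, ])
  }
  oracle <- acc[1] / 100 + acc[2] / 100 - 2 * acc[3] / 100
  expect_equal(mmd_loss(Y1, Y2, sigma = s), oracle, tolerance = 1e-10)
  # lambda3 scales linearly; symmetry in the arguments
  expect_equal(mmd_loss(Y1, Y2, sigma = s, lambda3 = 0.8), 0.8 * oracle,
               tolerance = 1e-10)
  expect_equal(mmd_loss(Y2, Y1, sigma = s), mmd_loss(Y1, Y2, sigma = s),
               tolerance = 1e-12)
  expect_gte(mmd_loss(Y1, Y2), 0)
  expect_error(mmd_loss(Y1[0, , drop = FALSE], Y2), "non-empty")
})

test_that("reconstruction and category losses match closed forms", {
  expect_identical(reconstruction_loss(matrix(1), matrix(1), 0.1), 0)
  expect_equal(reconstruction_loss(0, 1, lambda2 = 0.1), 0.1)
  set.seed(43)
  Z <- matrix(runif(20), 4, 5)
  X <- matrix(runif(20), 4, 5)
  oracle <- 0.1 * mean(sapply(1:4, function(i) sum((X[i, ] - Z[i, ])^2)))
  expect_equal(reconstruction_loss(Z, X, 0.1), oracle, tolerance = 1e-12)

  Yp <- diag(4)
  expect_lte(category_loss(Yp, Yp, lambda1 = 0.1), 0.1 * 1e-6)
  U <- matrix(0.25, 4, 4)
  expect_equal(category_loss(U, Yp, lambda1 = 0.1), 0.1 * log(4),
               tolerance = 1e-12)
  # hand-computed oracle on a random batch
  set.seed(44)
  P <- matrix(runif(12, 0.05, 0.95), 3, 4)
  L <- t(sapply(1:3, function(i) as.numeric(1:4 == sample(4, 1))))
  oracle <- 0.1 * mean(sapply(1:3, function(i) -sum(L[i, ] * log(P[i, ]))))
  expect_equal(category_loss(P, L, 0.1), oracle, tolerance = 1e-10)
})

test_that("bulk expansion resamples rows and log2-normalizes", {
  em <- rand_expr(1, 6, seed = 45)
  ex <- expand_bulk(em, n = 5, seed = 1)
  expect_equal(nrow(ex$values), 5)
  for (i in 1:5)
    expect_equal(unname(ex$values[i, ]), unname(log2(1 + em$values[1, ])))
  expect_identical(ex$layer, "log2")

  # membership: every expanded row is the log2 of some original row
  em2 <- rand_expr(4, 6, seed = 46)
  ex2 <- expand_bulk(em2, n = 4, seed = 2)
  orig <- apply(log2(1 + em2$values), 1, paste, collapse = ",")
  got <- apply(ex2$values, 1, paste, collapse = ",")
  expect_true(all(got %in% orig))

  # multinomial oracle: row frequencies uniform within 1% over 1e5 draws
  em3 <- rand_expr(10, 3, seed = 47)
  ex3 <- expand_bulk(em3, n = 1e5, seed = 3)
  src <- sub("_r[0-9]+$", "", rownames(ex3$values))
  freq <- table(src) / 1e5
  expect_lt(max(abs(freq - 0.1)), 0.01)
})

test_that("degenerate loss weights recover the pure submodels", {
  st <- small_trained()
  # plain autoencoder: reconstruction decreases over the first 10 epochs
  te_ae <- train_teacher(st$pb, st$be,
                         loss_config(lambda1 = 0, lambda3 = 0),
                         train_config(epochs = 10, d_latent = 48,
                                      batch_size = 50, seed = 1))
  expect_true(all(diff(te_ae$trace$reconstruction) < 0))
  expect_true(all(te_ae$trace$category == 0) ||
                all(abs(te_ae$trace$category) < 1e-12))

  # plain classifier: high training accuracy on well-separated pseudo-bulk
  te_cls <- train_teacher(st$pb, st$be,
                          loss_config(lambda2 = 0, lambda3 = 0),
                          train_config(epochs = 100, d_latent = 48,
                                       batch_size = 50, seed = 1))
  xs <- texdistill:::apply_minmax(st$pb$X2, te_cls$scaler_pseudo)
  pred <- st$pb$stage_order[max.col(classify(encode(xs, te_cls$params),
                                             te_cls$params))]
  expect_gt(mean(pred == st$pb$pseudo_labels), 0.95)
})

test_that("the composite loss is the sum of its traced components", {
  st <- small_trained()
  tr <- st$teacher$trace
  expect_equal(tr$total, tr$reconstruction + tr$category + tr$mmd,
               tolerance = 1e-12)
  expect_true(all(tr$reconstruction >= 0))
  expect_true(all(tr$category >= 0))
})

test_that("teacher training is reproducible under a fixed seed", {
  st <- small_trained()
  again <- train_teacher(st$pb, st$be, loss_config(),
                         train_config(epochs = 60, d_latent = 48,
                                      batch_size = 50, seed = 11))
  expect_equal(again$params$W1, st$teacher$params$W1, tolerance = 1e-6)
  expect_equal(again$trace, st$teacher$trace, tolerance = 1e-6)
  expect_error(train_teacher(st$pb,
                             expr_mat(st$be$values[, 1:10], "log2"),
                             loss_config(), train_config(epochs = 1)),
               "align_genes")
})

test_that("the mmd penalty brings the two latent domains closer", {
  # paired seeds: latent-space MMD with lambda3 = 0.8 vs 0
  cfg <- tiny_cfg(n_genes = 200, cells_per_stage = 100,
                  markers_per_stage = 15)
  wins <- 0
  for (sd in 1:10) {
    sim <- simulate_cells(cfg, seed = sd)
    norm <- normalize_cells(sim$cells)
    pb <- sample_blocks(norm, sim$labels, block_size = 30, n_blocks = 100,
                        seed = sd)
    bs <- simulate_bulk(sim$truth, cfg, seed = sd)
    be <- expand_bulk(bs$bulk, 100, seed = sd)
    lat_mmd <- function(l3) {
      te <- train_teacher(pb, be, loss_config(lambda3 = l3),
                          train_config(epochs = 25, d_latent = 32,
                                       batch_size = 50, seed = sd))
      Y1 <- encode(texdistill:::apply_minmax(be$values, te$scaler_bulk),
                   te$params)
      Y2 <- encode(texdistill:::apply_minmax(pb$X2, te$scaler_pseudo),
                   te$params)
      mmd_loss(Y1, Y2, sigma = 1)
    }
    if (lat_mmd(0.8) < lat_mmd(0)) wins <- wins + 1
  }
  expect_gte(wins, 8)
})
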