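test_that("teacher soft labels are the terminal column of the composition", {
  st <- small_trained()
  sl <- teacher_soft_labels(st$bs$bulk, st$teacher)
  expect_true(all(sl > 0 & sl < 1))
  expect_identical(names(sl), sample_ids(st$bs$bulk))

  # manual composition oracle: log2 -> scale -> encode -> classify -> column
  x <- log2(1 + st$bs$bulk$values[, st$teacher$genes])
  xs <- texdistill:::apply_minmax(x, st$teacher$scaler_bulk)
  z <- classify(encode(xs, st$teacher$params), st$teacher$params)
  expect_equal(unname(sl),
               unname(z[, match("TEXterm", st$teacher$stage_order)]),
               tolerance = 1e-12)

  expect_error(teacher_soft_labels(
    expr_mat(st$bs$bulk$values[, 1:5], "counts"), st$teacher),
    "teacher gene")
})

test_that("activity scores are mean z-scores over present set genes", {
  set.seed(51)
  m <- matrix(rnorm(8 * 10, 10, 2), 8, 10,
              dimnames = list(paste0("s", 1:8), paste0("g", 1:10)))
  m[, "g9"] <- 7  # constant gene: unusable
  em <- expr_mat(m, "log2")
  gs <- structure(list(
    sets = list(A = c("g1", "g2", "g3"), B = c("g4", "g5"),
                C = c("g9", "g1"),            # 1 usable gene -> dropped
                D = c("nope1", "nope2")),     # absent -> dropped
    descriptions = c(A = "", B = "", C = "", D = "")),
    class = "gene_sets")
  expect_message(act <- activity_matrix(em, gs), "dropped 2")
  expect_identical(colnames(act$values), c("A", "B"))

  z <- scale(m[, paste0("g", c(1:8, 10))])
  expect_equal(unname(act$values[, "A"]),
               unname(rowMeans(z[, c("g1", "g2", "g3")])), tolerance = 1e-12)

  # permutation symmetry within a set
  gs2 <- gs
  gs2$sets$A <- rev(gs$sets$A)
  act2 <- suppressMessages(activity_matrix(em, gs2))
  expect_equal(act2$values[, "A"], act$values[, "A"])

  # shifting one sample's set genes by +1 sd moves its activity by ~ +1
  # (exact only in the large-sample limit where the shift barely moves the
  # pooled mean and sd, hence many samples here)
  set.seed(59)
  mb <- matrix(rnorm(100 * 6, 10, 2), 100, 6,
               dimnames = list(sprintf("s%03d", 1:100), paste0("g", 1:6)))
  gsb <- structure(list(sets = list(B = c("g1", "g2", "g3")),
                        descriptions = c(B = "")), class = "gene_sets")
  act_b <- activity_matrix(expr_mat(mb, "log2"), gsb)
  sds <- apply(mb, 2, sd)
  mb2 <- mb
  mb2["s007", 1:3] <- mb["s007", 1:3] + sds[1:3]
  act_b2 <- activity_matrix(expr_mat(mb2, "log2"), gsb)
  expect_equal(unname(act_b2$values["s007", "B"] - act_b$values["s007", "B"]),
               1, tolerance = 0.1)

  gs_bad <- structure(list(sets = list(C = c("g9", "g1")),
                           descriptions = c(C = "")), class = "gene_sets")
  expect_error(suppressMessages(activity_matrix(em, gs_bad)), "usable")
})

test_that("student forward pass equals the explicit two-layer formula", {
  set.seed(52)
  F_in <- 9; H <- 4
  sp <- list(W1 = matrix(rnorm(F_in * H), F_in, H), b1 = rnorm(H),
             W2 = matrix(rnorm(H)), b2 = 0.3)
  X <- matrix(rnorm(6 * F_in), 6, F_in,
              dimnames = list(paste0("s", 1:6), NULL))
  out <- student_forward(X, sp)
  oracle <- sapply(1:6, function(i) {
    h <- pmax(0, as.vector(X[i, ] %*% sp$W1) + sp$b1)
    1 / (1 + exp(-(sum(h * sp$W2) + sp$b2)))
  })
  expect_equal(unname(out), oracle, tolerance = 1e-12)
  expect_true(all(out > 0 & out < 1))

  sp0 <- list(W1 = sp$W1 * 0, b1 = sp$b1 * 0, W2 = sp$W2 * 0, b2 = 0)
  expect_true(all(student_forward(X, sp0) == 0.5))

  # monotone response through an all-positive path
  spm <- list(W1 = matrix(abs(rnorm(F_in * H)), F_in, H), b1 = rep(0.1, H),
              W2 = matrix(abs(rnorm(H))), b2 = 0)
  x1 <- X
  x1[, 3] <- x1[, 3] + 1
  expect_true(all(student_forward(x1, spm) >= student_forward(X, spm)))
  expect_error(student_forward(X[, 1:3], sp), "dimension")
})

test_that("the student can recover a 1-feature generating function", {
  set.seed(53)
  x <- matrix(rnorm(260), ncol = 1, dimnames = list(paste0("s", 1:260), "f"))
  y <- 1 / (1 + exp(-(2 * x[, 1] - 0.5)))
  tr <- 1:200
  ens <- train_student(x[tr, , drop = FALSE], y[tr], l1_coeff = 0,
                       d_hidden = 16, epochs = 400, B = 1, seed = 1)
  pred <- ensemble_score(x[-tr, , drop = FALSE], ens)
  expect_lt(mean((pred - y[-tr])^2), 1e-3)
})

test_that("a dominant L1 penalty collapses the first layer", {
  set.seed(54)
  X <- matrix(rnorm(100 * 20), 100, 20,
              dimnames = list(paste0("s", 1:100), paste0("f", 1:20)))
  y <- runif(100, 0.3, 0.7)
  # Adam's per-step movement is bounded by lr, so the run must be long
  # enough for |W1| (~0.3 at init) to reach the origin and small-stepped
  # enough to sit inside the 1e-3 band once there
  ens <- train_student(X, y, l1_coeff = 10, d_hidden = 8, lr = 3e-4,
                       epochs = 5000, B = 1, seed = 2)
  expect_lt(mean(abs(ens$members[[1]]$W1)), 1e-3)
  pred <- ensemble_score(X, ens)
  expect_lt(diff(range(pred)), 0.02)  # essentially constant
})

test_that("ensemble scoring is the arithmetic mean of member outputs", {
  set.seed(55)
  F_in <- 5
  X <- matrix(rnorm(8 * F_in), 8, F_in,
              dimnames = list(paste0("s", 1:8), paste0("f", 1:F_in)))
  y <- runif(8)
  ens <- train_student(X, y, epochs = 20, d_hidden = 6, B = 3, seed = 3)
  manual <- rowMeans(sapply(ens$members, function(sp) {
    Xs <- sweep(sweep(X, 2, ens$scaler$mean, "-"), 2, ens$scaler$sd, "/")
    student_forward(Xs, sp)
  }))
  expect_equal(unname(ensemble_score(X, ens)), unname(manual),
               tolerance = 1e-12)

  # B = 1: the ensemble IS its single member
  e1 <- train_student(X, y, epochs = 20, d_hidden = 6, B = 1, seed = 3)
  Xs <- sweep(sweep(X, 2, e1$scaler$mean, "-"), 2, e1$scaler$sd, "/")
  expect_equal(ensemble_score(X, e1),
               student_forward(Xs, e1$members[[1]]), tolerance = 1e-12)

  # hand-made constant members average exactly
  mk_const <- function(v) list(W1 = matrix(0, F_in, 2), b1 = c(0, 0),
                               W2 = matrix(c(0, 0)), b2 = qlogis(v))
  ce <- structure(list(members = list(mk_const(0.2), mk_const(0.6)),
                       member_seeds = 1:2,
                       feature_ids = colnames(X), scaler = NULL,
                       l1_coeff = 0, config = list()),
                  class = "student_ensemble")
  expect_equal(unname(ensemble_score(X, ce)), rep(0.4, 8),
               tolerance = 1e-12)
})

test_that("bagging reduces error relative to the average member", {
  st <- small_trained()
  sl <- teacher_soft_labels(st$bs$bulk, st$teacher)
  X3 <- expr_mat(log2(1 + st$bs$bulk$values[, st$hvg]), "log2")
  ens <- train_student(X3, sl, epochs = 120, d_hidden = 16, B = 4,
                       seed = 5)
  Xs <- sweep(sweep(X3$values, 2, ens$scaler$mean, "-"), 2,
              ens$scaler$sd, "/")
  member_mse <- sapply(ens$members,
                       function(sp) mean((student_forward(Xs, sp) - sl)^2))
  ens_mse <- mean((ensemble_score(X3, ens) - sl)^2)
  expect_lte(ens_mse, mean(member_mse))

  # distillation fidelity: better than the best constant predictor
  expect_lt(ens_mse, mean((mean(sl) - sl)^2))
})

test_that("ensembles are reproducible under a fixed seed list", {
  set.seed(56)
  X <- matrix(rnorm(40 * 6), 40, 6,
              dimnames = list(paste0("s", 1:40), paste0("f", 1:6)))
  y <- runif(40)
  e1 <- train_student(X, y, epochs = 30, d_hidden = 8, B = 2, seed = 9)
  e2 <- train_student(X, y, epochs = 30, d_hidden = 8, B = 2, seed = 9)
  expect_identical(e1$member_seeds, e2$member_seeds)
  expect_equal(ensemble_score(X, e1), ensemble_score(X, e2),
               tolerance = 1e-6)
})

test_that("importance ranks planted predictive features on top", {
  set.seed(57)
  n <- 300; F_in <- 200
  hits <- 0
  for (sd in 1:3) {
    X <- matrix(rnorm(n * F_in), n, F_in,
                dimnames = list(paste0("s", 1:n), sprintf("f%03d", 1:F_in)))
    beta <- rep(0, F_in)
    planted <- sprintf("f%03d", 1:5)
    beta[1:5] <- c(2, -2, 1.5, 1.5, -1.5)
    y <- 1 / (1 + exp(-(X %*% beta) / 2))
    ens <- train_student(X, as.vector(y), d_hidden = 32, epochs = 250,
                         B = 3, seed = sd * 100)
    imp <- feature_importance(ens)
    if (all(planted %in% imp$feature_id[1:10])) hits <- hits + 1
  }
  expect_gte(hits, 2)
})

test_that("importance table is well-formed and permutation invariant", {
  set.seed(58)
  X <- matrix(rnorm(50 * 8), 50, 8,
              dimnames = list(paste0("s", 1:50), paste0("f", 1:8)))
  y <- runif(50)
  ens <- train_student(X, y, epochs = 30, d_hidden = 4, B = 3, seed = 4)
  imp <- feature_importance(ens)
  expect_setequal(imp$rank, 1:8)
  expect_true(all(diff(imp$importance) <= 0))

  # member order must not matter
  ens_rev <- ens
  ens_rev$members <- rev(ens$members)
  expect_equal(feature_importance(ens_rev), imp)

  # a feature with all-zero first-layer weights ranks last with importance 0
  ens0 <- ens
  for (i in seq_along(ens0$members)) ens0$members[[i]]$W1[3, ] <- 0
  imp0 <- feature_importance(ens0)
  expect_equal(imp0$importance[imp0$feature_id == "f3"], 0)
  expect_equal(imp0$rank[imp0$feature_id == "f3"], 8)

  # gradient-times-input alternative runs and is non-negative
  gi <- feature_importance(ens, method = "grad_input", X3 = X)
  expect_true(all(gi$importance >= 0))
})
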