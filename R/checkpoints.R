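#' Save and load model checkpoints
#'
#' Checkpoints are directories of full-precision TSV arrays plus a
#' `meta.json` sidecar carrying shapes, hyperparameters and seeds, so they
#' are portable text; reloaded models agree with the originals to well
#' below 1e-6.
#'
#' @param teacher A `tex_teacher`.
#' @param ens A `student_ensemble`.
#' @param dir Checkpoint directory (created if needed).
#' @return The directory (writers, invisibly) or the reloaded object
#'   (readers).
#' @name checkpoints
NULL

write_array <- function(x, path) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1)
  data.table::fwrite(as.data.frame(x), path, sep = "\t", col.names = FALSE)
}

read_array <- function(path, nrow, ncol) {
  m <- as.matrix(data.table::fread(path, sep = "\t", header = FALSE))
  dimnames(m) <- NULL
  stopifnot(nrow(m) == nrow, ncol(m) == ncol)
  if (ncol == 1 && nrow > 1) as.vector(m) else m
}

#' @rdname checkpoints
#' @export
save_teacher <- function(teacher, dir) {
  stopifnot(inherits(teacher, "tex_teacher"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- teacher$params
  arrays <- c("W1", "b1", "W2_dec", "b2_dec", "W2_cls", "b2_cls",
              if (!p$tied) c("W1_src", "b1_src"))
  for (nm in arrays) write_array(p[[nm]], file.path(dir, paste0(nm, ".tsv")))
  write_array(cbind(teacher$scaler_bulk$min, teacher$scaler_bulk$range),
              file.path(dir, "scaler_bulk.tsv"))
  write_array(cbind(teacher$scaler_pseudo$min, teacher$scaler_pseudo$range),
              file.path(dir, "scaler_pseudo.tsv"))
  data.table::fwrite(teacher$trace, file.path(dir, "trace.tsv"), sep = "\t")
  meta <- list(kind = "tex_teacher",
               genes = teacher$genes,
               stage_order = teacher$stage_order,
               terminal_stage = teacher$terminal_stage,
               t = p$t, activation = p$activation,
               temp_convention = p$temp_convention, tied = p$tied,
               d_latent = teacher$train_cfg$d_latent,
               loss_cfg = unclass(teacher$loss_cfg),
               train_cfg = unclass(teacher$train_cfg))
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname checkpoints
#' @export
load_teacher <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  stopifnot(identical(meta$kind, "tex_teacher"))
  G <- length(meta$genes)
  d <- meta$d_latent
  C <- length(meta$stage_order)
  p <- list(
    W1 = read_array(file.path(dir, "W1.tsv"), G, d),
    b1 = read_array(file.path(dir, "b1.tsv"), d, 1),
    W2_dec = read_array(file.path(dir, "W2_dec.tsv"), d, G),
    b2_dec = read_array(file.path(dir, "b2_dec.tsv"), G, 1),
    W2_cls = read_array(file.path(dir, "W2_cls.tsv"), d, C),
    b2_cls = read_array(file.path(dir, "b2_cls.tsv"), C, 1))
  if (!meta$tied) {
    p$W1_src <- read_array(file.path(dir, "W1_src.tsv"), G, d)
    p$b1_src <- read_array(file.path(dir, "b1_src.tsv"), d, 1)
  }
  p$t <- meta$t
  p$activation <- meta$activation
  p$temp_convention <- meta$temp_convention
  p$tied <- meta$tied
  class(p) <- "da_params"
  sb <- read_array(file.path(dir, "scaler_bulk.tsv"), G, 2)
  sp <- read_array(file.path(dir, "scaler_pseudo.tsv"), G, 2)
  structure(list(params = p,
                 scaler_bulk = list(min = stats::setNames(sb[, 1], meta$genes),
                                    range = stats::setNames(sb[, 2], meta$genes)),
                 scaler_pseudo = list(min = stats::setNames(sp[, 1], meta$genes),
                                      range = stats::setNames(sp[, 2], meta$genes)),
                 genes = meta$genes,
                 stage_order = meta$stage_order,
                 terminal_stage = meta$terminal_stage,
                 trace = as.data.frame(
                   data.table::fread(file.path(dir, "trace.tsv"))),
                 loss_cfg = structure(as.list(meta$loss_cfg),
                                      class = "loss_config"),
                 train_cfg = structure(as.list(meta$train_cfg),
                                       class = "train_config")),
            class = "tex_teacher")
}

#' @rdname checkpoints
#' @export
save_students <- function(ens, dir) {
  stopifnot(inherits(ens, "student_ensemble"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(ens$members)) {
    sp <- ens$members[[i]]
    for (nm in c("W1", "b1", "W2"))
      write_array(sp[[nm]], file.path(dir, sprintf("m%02d_%s.tsv", i, nm)))
  }
  if (!is.null(ens$scaler))
    write_array(cbind(ens$scaler$mean, ens$scaler$sd),
                file.path(dir, "scaler.tsv"))
  meta <- list(kind = "student_ensemble",
               feature_ids = ens$feature_ids,
               member_seeds = ens$member_seeds,
               b2 = vapply(ens$members, `[[`, numeric(1), "b2"),
               final_loss = vapply(ens$members, function(m)
                 m$final_loss %||% NA_real_, numeric(1)),
               l1_coeff = ens$l1_coeff,
               standardized = !is.null(ens$scaler),
               config = ens$config)
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname checkpoints
#' @export
load_students <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  stopifnot(identical(meta$kind, "student_ensemble"))
  F_in <- length(meta$feature_ids)
  H <- meta$config$d_hidden
  B <- meta$config$B
  members <- lapply(seq_len(B), function(i) {
    sp <- list(
      W1 = read_array(file.path(dir, sprintf("m%02d_W1.tsv", i)), F_in, H),
      b1 = read_array(file.path(dir, sprintf("m%02d_b1.tsv", i)), H, 1),
      W2 = matrix(read_array(file.path(dir, sprintf("m%02d_W2.tsv", i)),
                             H, 1)),
      b2 = meta$b2[i],
      final_loss = meta$final_loss[i])
    sp
  })
  scaler <- NULL
  if (isTRUE(meta$standardized)) {
    s <- read_array(file.path(dir, "scaler.tsv"), F_in, 2)
    scaler <- list(mean = stats::setNames(s[, 1], meta$feature_ids),
                   sd = stats::setNames(s[, 2], meta$feature_ids))
  }
  structure(list(members = members,
                 member_seeds = meta$member_seeds,
                 feature_ids = meta$feature_ids,
                 scaler = scaler,
                 l1_coeff = meta$l1_coeff,
                 config = as.list(meta$config)),
            class = "student_ensemble")
}
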