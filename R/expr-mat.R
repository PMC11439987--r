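#' Expression matrix container
#'
#' A lightweight container for an expression matrix together with a layer
#' tag describing the scale its values live on. Rows are always samples (or
#' cells), columns are always genes; every function in the package assumes
#' this orientation.
#'
#' @param values Numeric matrix, rows = samples/cells, columns = genes.
#'   Must carry unique rownames (sample/cell ids) and unique colnames
#'   (gene symbols).
#' @param layer One of `"counts"`, `"lognorm"`, `"log2"`, `"scaled"`,
#'   `"activity"`. `"counts"` asserts non-negative entries and is also used
#'   for simulated bulk mixtures, which are non-negative values on the
#'   linear expression scale.
#'
#' @return An object of class `expr_mat`: a list with elements `values`
#'   (the matrix) and `layer` (the tag).
#' @export
expr_mat <- function(values, layer = c("counts", "lognorm", "log2",
                                       "scaled", "activity")) {
  layer <- match.arg(layer)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  rid <- rownames(values)
  gid <- colnames(values)
  if (is.null(rid) || is.null(gid))
    stop("`values` must have rownames (sample ids) and colnames (gene ids)",
         call. = FALSE)
  if (anyDuplicated(rid))
    stop("duplicate sample/cell ids: ",
         paste(unique(rid[duplicated(rid)])[1:min(3, sum(duplicated(rid)))],
               collapse = ", "), call. = FALSE)
  if (anyDuplicated(gid))
    stop("duplicate gene ids: ",
         paste(unique(gid[duplicated(gid)])[1:min(3, sum(duplicated(gid)))],
               collapse = ", "), call. = FALSE)
  if (layer == "counts" && any(values < 0))
    stop("layer 'counts' requires non-negative entries", call. = FALSE)
  structure(list(values = values, layer = layer), class = "expr_mat")
}

#' @export
print.expr_mat <- function(x, ...) {
  cat(sprintf("<expr_mat> %d samples x %d genes, layer '%s'\n",
              nrow(x$values), ncol(x$values), x$layer))
  invisible(x)
}

#' @export
dim.expr_mat <- function(x) dim(x$values)

#' Sample/cell and gene identifiers of an expression matrix
#' @param x An `expr_mat`.
#' @return Character vector of ids.
#' @export
sample_ids <- function(x) rownames(x$values)

#' @rdname sample_ids
#' @export
gene_ids <- function(x) colnames(x$values)

as_expr_mat <- function(x, layer) {
  if (inherits(x, "expr_mat")) x else expr_mat(x, layer)
}

#' Restrict two expression matrices to their shared genes
#'
#' Both matrices are subset to the intersection of their gene symbols, in
#' the same (first matrix's) order, so that downstream models see an
#' identical gene axis. Applying the function twice is equivalent to
#' applying it once.
#'
#' @param a,b `expr_mat` objects.
#' @return A list with elements `a` and `b`, both restricted to the shared
#'   genes in identical order.
#' @export
align_genes <- function(a, b) {
  shared <- intersect(gene_ids(a), gene_ids(b))
  if (length(shared) == 0)
    stop("no shared gene symbols between the two matrices", call. = FALSE)
  list(a = expr_mat(a$values[, shared, drop = FALSE], a$layer),
       b = expr_mat(b$values[, shared, drop = FALSE], b$layer))
}

#' Per-cell stage labels
#'
#' Holds the exhaustion-stage label of each cell together with the ordered
#' stage vocabulary. The terminal stage (whose classifier score becomes the
#' teacher's soft label) is recorded by name so that auxiliary categories
#' such as `"other"` can follow it in `stage_order`.
#'
#' @param labels Named character vector: names are cell ids, values are
#'   stages drawn from `stage_order`.
#' @param stage_order Ordered character vector of stage names.
#' @param terminal_stage Name of the terminal exhaustion stage. Defaults to
#'   `"TEXterm"` when present, else the last element of `stage_order`.
#' @return An object of class `stage_labels`.
#' @export
stage_labels <- function(labels, stage_order,
                         terminal_stage = NULL) {
  if (is.null(names(labels)))
    stop("`labels` must be named by cell id", call. = FALSE)
  bad <- setdiff(unique(labels), stage_order)
  if (length(bad))
    stop("labels outside stage_order: ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (is.null(terminal_stage))
    terminal_stage <- if ("TEXterm" %in% stage_order) "TEXterm" else
      stage_order[length(stage_order)]
  if (!terminal_stage %in% stage_order)
    stop("terminal_stage not in stage_order", call. = FALSE)
  structure(list(labels = labels, stage_order = stage_order,
                 terminal_stage = terminal_stage),
            class = "stage_labels")
}

#' @export
print.stage_labels <- function(x, ...) {
  tab <- table(factor(x$labels, levels = x$stage_order))
  cat(sprintf("<stage_labels> %d cells, %d stages (terminal: %s)\n",
              length(x$labels), length(x$stage_order), x$terminal_stage))
  print(tab)
  invisible(x)
}
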