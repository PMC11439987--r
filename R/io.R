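#' Read an expression matrix from disk
#'
#' Supports dense CSV/TSV (header row of gene symbols, first column the
#' sample/cell id) and Matrix Market triplet files with plain-text name
#' sidecars (`<path>.rows`, `<path>.cols`, one identifier per line).
#' Whatever the on-disk orientation, the returned matrix has rows =
#' samples/cells and columns = genes. Duplicate gene symbols are collapsed
#' by keeping the occurrence with the highest total expression (a message
#' reports how many were dropped).
#'
#' @param path Path to the matrix file.
#' @param format `"csv"`, `"tsv"`, or `"mtx"`.
#' @param orientation `"rows_are_samples"` (default) or `"rows_are_genes"`,
#'   describing the file as stored.
#' @param layer Layer tag to attach (see [expr_mat()]).
#' @return An [expr_mat()].
#' @export
read_matrix <- function(path,
                        format = c("csv", "tsv", "mtx"),
                        orientation = c("rows_are_samples",
                                        "rows_are_genes"),
                        layer = "counts") {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "mtx") {
    m <- read_mtx_with_sidecars(path)
  } else {
    sep <- if (format == "csv") "," else "\t"
    # take the header straight off the file: fread would mangle duplicate
    # gene symbols, which collapse_duplicate_genes() needs to see
    header <- strsplit(readLines(path, n = 1), sep, fixed = TRUE)[[1]]
    header <- gsub('^"|"$', "", header)
    if (length(header) < 2)
      stop("malformed header in ", path,
           ": line 1 must contain an id column plus at least one data column",
           call. = FALSE)
    dt <- data.table::fread(path, sep = sep, header = TRUE,
                            data.table = FALSE)
    if (ncol(dt) != length(header))
      stop("malformed header in ", path, ": line 1 names ",
           length(header), " columns but rows have ", ncol(dt),
           call. = FALSE)
    ids <- as.character(dt[[1]])
    m <- as.matrix(dt[, -1, drop = FALSE])
    if (!is.numeric(m))
      stop("non-numeric data cells in ", path, call. = FALSE)
    dimnames(m) <- list(ids, header[-1])
  }
  if (orientation == "rows_are_genes") m <- t(m)
  m <- collapse_duplicate_genes(m)
  expr_mat(m, layer)
}

read_mtx_with_sidecars <- function(path) {
  rows_file <- paste0(path, ".rows")
  cols_file <- paste0(path, ".cols")
  if (!file.exists(rows_file) || !file.exists(cols_file))
    stop("sidecar files missing: expected ", rows_file, " and ", cols_file,
         call. = FALSE)
  sm <- tryCatch(Matrix::readMM(path),
                 error = function(e)
                   stop("malformed Matrix Market file ", path, ": ",
                        conditionMessage(e), call. = FALSE))
  rn <- readLines(rows_file)
  cn <- readLines(cols_file)
  if (length(rn) != nrow(sm) || length(cn) != ncol(sm))
    stop(sprintf(paste0("dimension mismatch: matrix is %dx%d but sidecars ",
                        "name %d rows and %d columns"),
                 nrow(sm), ncol(sm), length(rn), length(cn)),
         call. = FALSE)
  m <- as.matrix(sm)
  dimnames(m) <- list(rn, cn)
  m
}

collapse_duplicate_genes <- function(m) {
  gid <- colnames(m)
  if (is.null(gid)) stop("matrix has no gene names", call. = FALSE)
  if (!anyDuplicated(gid)) return(m)
  totals <- colSums(m)
  # keep, per symbol, the column with the highest total expression,
  # preserving first-occurrence order of the symbols
  keep <- vapply(split(seq_along(gid), gid),
                 function(ix) ix[which.max(totals[ix])], integer(1))
  keep <- unname(keep[match(unique(gid), names(keep))])
  message(sprintf("collapsed %d duplicate gene symbols (kept highest-total)",
                  length(gid) - length(keep)))
  m[, keep, drop = FALSE]
}

#' Write an expression matrix to disk
#'
#' Inverse of [read_matrix()]. CSV/TSV files carry a header row of gene
#' symbols and the sample id in the first column (`sample_id`); values are
#' written at full precision so a read/write round trip preserves them.
#' Matrix Market output stores the matrix sparsely with `.rows`/`.cols`
#' name sidecars.
#'
#' @param x An [expr_mat()].
#' @param path Output path.
#' @param format `"csv"`, `"tsv"`, or `"mtx"`.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path, format = c("csv", "tsv", "mtx")) {
  format <- match.arg(format)
  stopifnot(inherits(x, "expr_mat"))
  if (format == "mtx") {
    Matrix::writeMM(Matrix::Matrix(x$values, sparse = TRUE), path)
    writeLines(rownames(x$values), paste0(path, ".rows"))
    writeLines(colnames(x$values), paste0(path, ".cols"))
  } else {
    sep <- if (format == "csv") "," else "\t"
    df <- data.frame(sample_id = rownames(x$values), x$values,
                     check.names = FALSE)
    data.table::fwrite(df, path, sep = sep)
  }
  invisible(path)
}

#' Read a gene-set collection in GMT format
#'
#' One set per tab-separated line: set name, description, then gene
#' symbols. Empty gene fields are dropped and duplicate genes within a line
#' are de-duplicated.
#'
#' @param path Path to a GMT file.
#' @return A `gene_sets` object: list with `sets` (named list of character
#'   vectors) and `descriptions` (named character vector).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- vector("list", length(lines))
  descs <- character(length(lines))
  nms <- character(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop(sprintf("GMT parse error at line %d: expected >= 3 tab-separated fields",
                   i), call. = FALSE)
    nms[i] <- f[1]
    descs[i] <- f[2]
    genes <- unique(f[-(1:2)][nzchar(f[-(1:2)])])
    if (length(genes) == 0)
      stop(sprintf("GMT parse error at line %d: set '%s' has no genes",
                   i, f[1]), call. = FALSE)
    sets[[i]] <- genes
  }
  if (anyDuplicated(nms))
    stop("duplicate set names in GMT: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "), call. = FALSE)
  names(sets) <- nms
  names(descs) <- nms
  structure(list(sets = sets, descriptions = descs), class = "gene_sets")
}

#' @rdname read_gmt
#' @param x A `gene_sets` object.
#' @export
write_gmt <- function(x, path) {
  stopifnot(inherits(x, "gene_sets"))
  lines <- vapply(names(x$sets), function(nm) {
    paste(c(nm, x$descriptions[[nm]], x$sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.gene_sets <- function(x, ...) {
  cat(sprintf("<gene_sets> %d sets, median size %g\n", length(x$sets),
              stats::median(lengths(x$sets))))
  invisible(x)
}

#' Read/write per-sample score tables
#'
#' Scores are stored as TSV with columns `sample_id` and `score`.
#'
#' @param scores Named numeric vector (names = sample ids).
#' @param path File path.
#' @return `read_scores` returns a named numeric vector.
#' @export
write_scores <- function(scores, path) {
  df <- data.frame(sample_id = names(scores), score = unname(scores))
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' @rdname write_scores
#' @export
read_scores <- function(path) {
  df <- data.table::fread(path, sep = "\t", data.table = FALSE)
  stats::setNames(df$score, df$sample_id)
}

#' Read/write survival tables
#'
#' TSV with columns `sample_id`, `time` (days, > 0) and `event`
#' (1 = death observed, 0 = censored).
#'
#' @param surv Data frame with columns `sample_id`, `time`, `event`.
#' @param path File path.
#' @export
write_survival <- function(surv, path) {
  validate_survival(surv)
  data.table::fwrite(surv[, c("sample_id", "time", "event")], path,
                     sep = "\t")
  invisible(path)
}

#' @rdname write_survival
#' @export
read_survival <- function(path) {
  df <- data.table::fread(path, sep = "\t", data.table = FALSE)
  validate_survival(df)
  df
}

validate_survival <- function(surv) {
  need <- c("sample_id", "time", "event")
  if (!all(need %in% names(surv)))
    stop("survival table needs columns sample_id, time, event",
         call. = FALSE)
  if (any(surv$time <= 0)) stop("survival times must be > 0", call. = FALSE)
  if (!all(surv$event %in% c(0, 1)))
    stop("event must be 0/1", call. = FALSE)
  if (anyDuplicated(surv$sample_id))
    stop("duplicate sample_ids in survival table", call. = FALSE)
  invisible(surv)
}
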