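#' Area under the ROC curve
#'
#' Computed by the rank (Mann-Whitney) formulation: the probability that a
#' uniformly random positive outranks a uniformly random negative, with
#' tied scores counted one half. Exact under ties and invariant to any
#' strictly monotone transform of the scores.
#'
#' @param scores Numeric vector.
#' @param labels Binary vector (0/1 or logical) of the same length.
#' @return A number in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  stopifnot(length(scores) == length(labels))
  np <- sum(labels == 1)
  nn <- sum(labels == 0)
  if (np == 0 || nn == 0)
    stop("auroc needs both classes present", call. = FALSE)
  r <- rank(scores)
  (sum(r[labels == 1]) - np * (np + 1) / 2) / (np * nn)
}

#' Area under the precision-recall curve
#'
#' Area under the precision-recall step curve obtained by sweeping a
#' descending-score threshold (tied scores enter together); no
#' interpolation between points.
#'
#' @inheritParams auroc
#' @return A number in `(0, 1]`.
#' @export
auprc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  stopifnot(length(scores) == length(labels))
  np <- sum(labels == 1)
  if (np == 0 || np == length(labels))
    stop("auprc needs both classes present", call. = FALSE)
  ord <- order(-scores)
  s <- scores[ord]
  y <- labels[ord]
  # group ties: cumulative counts at each distinct threshold
  last_of_group <- c(diff(s) != 0, TRUE)
  tp <- cumsum(y)[last_of_group]
  n_at <- seq_along(y)[last_of_group]
  precision <- tp / n_at
  recall <- tp / np
  sum(diff(c(0, recall)) * precision)
}

#' Split samples into high/low groups at the median score
#'
#' Scores strictly above the median go to `"high"`, all others (including
#' scores equal to the median) to `"low"` — a deterministic, conservative
#' convention for the high-risk group. All-identical scores produce an
#' all-`"low"` grouping with a warning.
#'
#' @param scores Named numeric vector of per-sample scores.
#' @return A `risk_grouping`: list with `groups` (named character vector
#'   in `{"high","low"}`) and `threshold` (the median).
#' @export
median_split <- function(scores) {
  stopifnot(is.numeric(scores), length(scores) >= 2)
  if (is.null(names(scores)))
    names(scores) <- sprintf("s%04d", seq_along(scores))
  med <- stats::median(scores)
  grp <- ifelse(scores > med, "high", "low")
  if (all(grp == "low") && length(unique(scores)) == 1)
    warning("all scores identical; every sample assigned to 'low'")
  structure(list(groups = stats::setNames(grp, names(scores)),
                 threshold = med),
            class = "risk_grouping")
}

#' @export
print.risk_grouping <- function(x, ...) {
  cat(sprintf("<risk_grouping> threshold %.4g: %d high, %d low\n",
              x$threshold, sum(x$groups == "high"),
              sum(x$groups == "low")))
  invisible(x)
}

#' Two-sample log-rank test
#'
#' The Mantel-Haenszel log-rank statistic: at each distinct event time the
#' observed events in group one are compared with their hypergeometric
#' expectation given the risk sets, and the squared standardized sum is
#' referred to a chi-square distribution with one degree of freedom.
#'
#' @param groups A `risk_grouping` from [median_split()], or a named
#'   character vector of group assignments with exactly two levels.
#' @param surv Survival table (data frame with `sample_id`, `time`,
#'   `event`).
#' @return List with `chi_square`, `p_value`, and the per-group
#'   observed/expected event counts.
#' @export
log_rank <- function(groups, surv) {
  if (inherits(groups, "risk_grouping")) groups <- groups$groups
  validate_survival(surv)
  missing <- setdiff(names(groups), surv$sample_id)
  if (length(missing))
    stop("samples without survival data: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  surv <- surv[match(names(groups), surv$sample_id), ]
  lev <- sort(unique(groups))
  if (length(lev) != 2)
    stop("log_rank needs exactly two non-empty groups", call. = FALSE)
  g1 <- groups == lev[1]
  times <- sort(unique(surv$time[surv$event == 1]))
  O <- E <- V <- 0
  for (tt in times) {
    at_risk <- surv$time >= tt
    n <- sum(at_risk)
    n1 <- sum(at_risk & g1)
    d <- sum(surv$time == tt & surv$event == 1)
    d1 <- sum(surv$time == tt & surv$event == 1 & g1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1)
      V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chi <- if (V > 0) (O - E)^2 / V else 0
  list(chi_square = chi,
       p_value = stats::pchisq(chi, df = 1, lower.tail = FALSE),
       observed = stats::setNames(c(O, sum(surv$event) - O), lev),
       expected = stats::setNames(c(E, sum(surv$event) - E), lev))
}
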