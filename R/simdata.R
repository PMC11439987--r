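#' Configuration for the synthetic exhaustion-stage generator
#'
#' The generator emulates the structure the pipeline assumes: single cells
#' carrying a discrete exhaustion-stage label, with stage identity encoded
#' by blocks of marker genes whose negative-binomial means are multiplied
#' by `marker_fold`, and bulk samples that are convex mixtures of the stage
#' mean profiles with known mixing weights.
#'
#' @param n_genes Number of genes.
#' @param stages Ordered stage names; the four canonical exhaustion stages
#'   plus an `"other"` catch-all so the terminal-stage score is not simply
#'   one minus the rest.
#' @param cells_per_stage Cells simulated per stage.
#' @param markers_per_stage Number of marker genes planted per stage
#'   (disjoint blocks).
#' @param marker_fold Mean multiplier applied to a stage's markers in that
#'   stage (`1` = no signal).
#' @param nb_dispersion Negative-binomial dispersion: variance is
#'   `mu + mu^2 / nb_dispersion`.
#' @param n_bulk Number of bulk mixture samples.
#' @param mixing_concentration Dirichlet concentration per stage for the
#'   bulk mixing weights (scalar recycled, or one value per stage).
#' @param bulk_noise_sd Standard deviation of additive Gaussian noise on
#'   bulk mixtures (linear expression scale; values clipped at 0).
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters for the
#'   per-gene baseline mean expression.
#' @param terminal_stage Name of the terminal stage.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 5000,
                       stages = c("TEXprog", "TEXint1", "TEXint2",
                                  "TEXterm", "other"),
                       cells_per_stage = 2000,
                       markers_per_stage = 50,
                       marker_fold = 5,
                       nb_dispersion = 2,
                       n_bulk = 300,
                       mixing_concentration = 1,
                       bulk_noise_sd = 0.1,
                       baseline_meanlog = log(0.5),
                       baseline_sdlog = 1,
                       terminal_stage = "TEXterm") {
  cfg <- list(n_genes = n_genes, stages = stages,
              cells_per_stage = cells_per_stage,
              markers_per_stage = markers_per_stage,
              marker_fold = marker_fold, nb_dispersion = nb_dispersion,
              n_bulk = n_bulk,
              mixing_concentration = rep_len(mixing_concentration,
                                             length(stages)),
              bulk_noise_sd = bulk_noise_sd,
              baseline_meanlog = baseline_meanlog,
              baseline_sdlog = baseline_sdlog,
              terminal_stage = terminal_stage)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$markers_per_stage * length(cfg$stages) > cfg$n_genes)
    stop("marker budget exceeds n_genes: ",
         cfg$markers_per_stage, " x ", length(cfg$stages), " > ",
         cfg$n_genes, call. = FALSE)
  if (cfg$cells_per_stage < 1 || cfg$n_genes < 1)
    stop("counts in sim_config must be positive", call. = FALSE)
  if (cfg$marker_fold < 1) stop("marker_fold must be >= 1", call. = FALSE)
  if (cfg$nb_dispersion <= 0) stop("nb_dispersion must be > 0", call. = FALSE)
  if (cfg$bulk_noise_sd < 0) stop("bulk_noise_sd must be >= 0", call. = FALSE)
  if (any(cfg$mixing_concentration <= 0))
    stop("mixing_concentration must be > 0", call. = FALSE)
  if (!cfg$terminal_stage %in% cfg$stages)
    stop("terminal_stage must be one of `stages`", call. = FALSE)
  invisible(cfg)
}

#' Simulate stage-labelled single-cell counts
#'
#' Counts are negative-binomial with per-gene baseline means drawn once
#' from a log-normal; each stage's marker block has its mean multiplied by
#' `marker_fold` in cells of that stage. Identical `(cfg, seed)` gives
#' identical output.
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed.
#' @return List with `cells` ([expr_mat()] of counts), `labels`
#'   ([stage_labels()]), and `truth` (list with `stage_profiles`, the
#'   stage-by-gene mean matrix, `baseline_mean`, and `marker_genes`, the
#'   per-stage marker gene names).
#' @export
simulate_cells <- function(cfg, seed = 1) {
  validate_sim_config(cfg)
  with_seed(seed, {
    S <- length(cfg$stages)
    genes <- sprintf("g%04d", seq_len(cfg$n_genes))
    base_mu <- stats::rlnorm(cfg$n_genes, cfg$baseline_meanlog,
                             cfg$baseline_sdlog)
    names(base_mu) <- genes

    marker_idx <- split(seq_len(cfg$markers_per_stage * S),
                        rep(seq_len(S), each = cfg$markers_per_stage))
    names(marker_idx) <- cfg$stages
    profiles <- matrix(rep(base_mu, each = S), S, cfg$n_genes,
                       dimnames = list(cfg$stages, genes))
    for (s in seq_len(S))
      profiles[s, marker_idx[[s]]] <-
        profiles[s, marker_idx[[s]]] * cfg$marker_fold

    n_cells <- cfg$cells_per_stage * S
    counts <- matrix(0, n_cells, cfg$n_genes)
    lab <- character(n_cells)
    for (s in seq_len(S)) {
      ix <- (s - 1) * cfg$cells_per_stage + seq_len(cfg$cells_per_stage)
      counts[ix, ] <- matrix(
        stats::rnbinom(cfg$cells_per_stage * cfg$n_genes,
                       size = cfg$nb_dispersion,
                       mu = rep(profiles[s, ], each = cfg$cells_per_stage)),
        cfg$cells_per_stage, cfg$n_genes)
      lab[ix] <- cfg$stages[s]
    }
    cell_ids <- sprintf("c%05d", seq_len(n_cells))
    dimnames(counts) <- list(cell_ids, genes)
    list(cells = expr_mat(counts, "counts"),
         labels = stage_labels(stats::setNames(lab, cell_ids), cfg$stages,
                               cfg$terminal_stage),
         truth = list(stage_profiles = profiles,
                      baseline_mean = base_mu,
                      marker_genes = lapply(marker_idx,
                                            function(ix) genes[ix])))
  })
}

#' Simulate bulk mixtures of the stage profiles
#'
#' Each bulk sample is a convex combination of the stage mean profiles with
#' Dirichlet-distributed weights, plus additive Gaussian noise clipped at
#' zero. The terminal-stage weight of every sample is recorded as the
#' ground-truth exhaustion fraction.
#'
#' @param truth The `truth` element returned by [simulate_cells()] (or any
#'   list with a `stage_profiles` matrix).
#' @param cfg A [sim_config()].
#' @param seed Integer seed.
#' @param weights Optional samples-by-stages matrix of mixing weights
#'   (rows summing to 1) overriding the Dirichlet prior; its row count
#'   overrides `cfg$n_bulk`.
#' @return List with `bulk` ([expr_mat()], linear scale), `fractions`
#'   (sample-by-stage weight matrix, rows summing to 1) and
#'   `texterm_fraction` (named vector, the terminal-stage column).
#' @export
simulate_bulk <- function(truth, cfg, seed = 1, weights = NULL) {
  validate_sim_config(cfg)
  profiles <- truth$stage_profiles
  stopifnot(is.matrix(profiles))
  if (!is.null(weights)) {
    stopifnot(ncol(weights) == nrow(profiles),
              all(abs(rowSums(weights) - 1) < 1e-9))
    cfg$n_bulk <- nrow(weights)
  }
  with_seed(seed, {
    S <- nrow(profiles)
    w <- weights
    if (is.null(w)) {
      g <- matrix(stats::rgamma(cfg$n_bulk * S,
                                shape = rep(cfg$mixing_concentration,
                                            each = cfg$n_bulk)),
                  cfg$n_bulk, S)
      w <- g / rowSums(g)
    }
    x <- w %*% profiles
    if (cfg$bulk_noise_sd > 0)
      x <- x + matrix(stats::rnorm(length(x), 0, cfg$bulk_noise_sd),
                      nrow(x), ncol(x))
    x[x < 0] <- 0
    ids <- sprintf("b%04d", seq_len(cfg$n_bulk))
    dimnames(x) <- list(ids, colnames(profiles))
    dimnames(w) <- list(ids, rownames(profiles))
    list(bulk = expr_mat(x, "counts"),
         fractions = w,
         texterm_fraction = stats::setNames(w[, cfg$terminal_stage], ids))
  })
}

#' Simulate survival times driven by the terminal-exhaustion fraction
#'
#' Event times are exponential with log-hazard linear in the fraction:
#' `h_i = exp(log(hazard_ratio) * f_i) / baseline_scale`, so
#' `hazard_ratio` is the hazard ratio between a fully terminal-exhausted
#' sample (`f = 1`) and one with none (`f = 0`). Censoring times are
#' independent exponentials with rate `censor_rate` (0 = no censoring).
#'
#' @param texterm_fraction Named numeric vector in `[0, 1]`.
#' @param hazard_ratio Hazard ratio across the full fraction range; must be
#'   positive.
#' @param baseline_scale Mean survival time (days) at fraction 0.
#' @param censor_rate Rate (per day) of the exponential censoring process.
#' @param seed Integer seed.
#' @return A survival table: data frame with `sample_id`, `time`, `event`.
#' @export
simulate_survival <- function(texterm_fraction, hazard_ratio = 4,
                              baseline_scale = 1000, censor_rate = 0,
                              seed = 1) {
  if (hazard_ratio <= 0) stop("hazard_ratio must be > 0", call. = FALSE)
  if (any(texterm_fraction < 0 | texterm_fraction > 1))
    stop("fractions must lie in [0, 1]", call. = FALSE)
  with_seed(seed, {
    n <- length(texterm_fraction)
    rate <- exp(log(hazard_ratio) * texterm_fraction) / baseline_scale
    t_event <- stats::rexp(n, rate)
    t_cens <- if (censor_rate > 0) stats::rexp(n, censor_rate) else
      rep(Inf, n)
    time <- pmin(t_event, t_cens)
    data.frame(sample_id = names(texterm_fraction) %||%
                 sprintf("s%04d", seq_len(n)),
               time = time,
               event = as.integer(t_event <= t_cens))
  })
}
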