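#' Evenly spaced sampling design
#'
#' Describes a fixed-rate sampling scheme: samples every `interval_minutes`
#' over `duration_hours`. The default — one sample every 3 minutes for 24
#' hours — gives 480 time points, dense enough for histogram-based transfer
#' entropy and long enough to cover one full circadian cycle.
#'
#' @param interval_minutes Minutes between consecutive samples.
#' @param duration_hours Total sampling duration in hours; must be an exact
#'   multiple of the interval.
#' @return A `sampling_design` list: `interval_minutes`, `duration_hours`,
#'   `n_timepoints`, and `time_hours` (sample times, starting at 0).
#' @examples
#' sampling_design(3, 24)$n_timepoints # 480
#' @export
sampling_design <- function(interval_minutes = 3, duration_hours = 24) {
  if (interval_minutes <= 0 || duration_hours <= 0) {
    stop("Interval and duration must be positive.", call. = FALSE)
  }
  total_min <- duration_hours * 60
  n <- total_min / interval_minutes
  if (abs(n - round(n)) > 1e-9) {
    stop("Sampling interval must divide the duration exactly.",
         call. = FALSE)
  }
  n <- as.integer(round(n))
  structure(
    list(
      interval_minutes = interval_minutes,
      duration_hours = duration_hours,
      n_timepoints = n,
      time_hours = (seq_len(n) - 1L) * interval_minutes / 60
    ),
    class = "sampling_design"
  )
}

#' Define a planted regulatory network for simulation
#'
#' Describes the ground truth handed to [simulate_expression()]: gene names,
#' directed regulator-to-target edges with coupling strengths in `[0, 1]`
#' (0 behaves as no edge), the dynamics mode, and the noise level.
#'
#' @param genes Character vector of gene names.
#' @param edges Data frame with columns `regulator`, `target`, `coupling`
#'   (zero-row for an empty network). Self-loops are rejected.
#' @param mode Dynamics: `"linear-lag"` (linear lag-1 coupling),
#'   `"nonlinear-lag"` (tanh-squashed coupling), or `"circadian"` (lag-1
#'   coupling on top of a 24-hour cosine baseline with per-gene phase).
#' @param noise_sd Gaussian innovation standard deviation; the default 0.1
#'   is one tenth of the unit signal amplitude.
#' @param ar AR(1) self-dependence coefficient of each gene (default 0.5).
#' @param lag Coupling delay in time steps (default 1, matching the lag-1
#'   estimation regime; `lag = 2` creates a deliberate model mismatch for
#'   stress-testing the estimator).
#' @return A `planted_network` list.
#' @export
planted_network <- function(genes, edges, mode = c("linear-lag",
                                                   "nonlinear-lag",
                                                   "circadian"),
                            noise_sd = 0.1, ar = 0.5, lag = 1) {
  mode <- match.arg(mode)
  stopifnot(is.character(genes), !anyDuplicated(genes))
  edges <- as_tibble(edges)
  needed <- c("regulator", "target", "coupling")
  if (!all(needed %in% names(edges))) {
    stop("`edges` needs columns regulator, target, coupling.", call. = FALSE)
  }
  if (any(edges$regulator == edges$target)) {
    stop("Planted network contains self-loops.", call. = FALSE)
  }
  if (!all(edges$regulator %in% genes) || !all(edges$target %in% genes)) {
    stop("Edge endpoints must be listed in `genes`.", call. = FALSE)
  }
  if (any(edges$coupling < 0 | edges$coupling > 1)) {
    stop("Couplings must lie in [0, 1].", call. = FALSE)
  }
  lag <- as.integer(lag)
  if (is.na(lag) || lag < 1L) stop("`lag` must be >= 1.", call. = FALSE)
  structure(
    list(genes = genes, edges = edges, mode = mode,
         noise_sd = noise_sd, ar = ar, lag = lag),
    class = "planted_network"
  )
}

#' Random planted network
#'
#' Draws `n_edges` distinct directed non-self edges uniformly at random among
#' `n_genes` genes, with couplings drawn uniformly from `coupling_range`.
#' By default the network is acyclic (a regulatory cascade): edges are drawn
#' consistent with a random topological order. Acyclic coupling keeps the
#' lag-1 dynamics of [simulate_expression()] stationary for any couplings in
#' `[0, 1]`; cyclic networks with strong coupling can be explosive in
#' `"linear-lag"` mode.
#'
#' @param n_genes Number of genes (named `G01`, `G02`, ...).
#' @param n_edges Number of planted directed edges.
#' @param coupling_range Length-2 numeric range for the coupling strengths.
#' @param seed Integer seed.
#' @param acyclic If `TRUE` (default) the planted network is a DAG.
#' @inheritParams planted_network
#' @return A `planted_network`.
#' @export
random_planted_network <- function(n_genes, n_edges,
                                   coupling_range = c(0.7, 1),
                                   seed = 1,
                                   mode = "circadian",
                                   noise_sd = 0.1, ar = 0.5,
                                   acyclic = TRUE) {
  genes <- sprintf("G%02d", seq_len(n_genes))
  max_edges <- if (acyclic) {
    n_genes * (n_genes - 1L) %/% 2L
  } else {
    n_genes * (n_genes - 1L)
  }
  if (n_edges > max_edges) stop("Too many edges requested.", call. = FALSE)
  edges <- with_local_seed(seed, function() {
    cp <- stats::runif(n_edges, coupling_range[1], coupling_range[2])
    if (acyclic) {
      topo <- sample(genes) # random topological order
      pairs <- utils::combn(n_genes, 2L)
      idx <- sample.int(ncol(pairs), n_edges)
      tibble(regulator = topo[pairs[1L, idx]],
             target = topo[pairs[2L, idx]], coupling = cp)
    } else {
      idx <- sample.int(n_genes * (n_genes - 1L), n_edges)
      reg <- (idx - 1L) %/% (n_genes - 1L) + 1L
      off <- (idx - 1L) %% (n_genes - 1L) + 1L
      tgt <- ifelse(off >= reg, off + 1L, off)
      tibble(regulator = genes[reg], target = genes[tgt], coupling = cp)
    }
  })
  planted_network(genes, edges, mode = mode, noise_sd = noise_sd, ar = ar)
}

#' Simulate coupled expression time series with a known network
#'
#' Generates a genes x time expression table from lag-1 coupled stochastic
#' dynamics: each gene's next deviation is an AR(1) term plus the summed
#' coupling-weighted (optionally tanh-squashed) lag-1 deviations of its
#' regulators plus Gaussian noise. In `"circadian"` mode a 24-hour cosine
#' baseline with a per-gene phase (jittered around a common peak) is added,
#' reproducing the rhythmic cluster structure that pattern-based target
#' selection expects. Each gene is shifted so expression is non-negative
#' (an affine change that leaves transfer entropy untouched). The matching
#' gold standard over all ordered pairs is emitted alongside.
#'
#' @param network A [planted_network()].
#' @param design A [sampling_design()].
#' @param seed Integer seed; identical seeds give identical output.
#' @param amplitude Circadian baseline amplitude (circadian mode only).
#' @param common_peak_hours Center of the per-gene peak-phase distribution,
#'   hours after the start of sampling.
#' @param phase_jitter_hours Standard deviation of the per-gene phase jitter.
#' @return List with `expression` (tibble, gene column + one column per time
#'   point), `gold` (tibble `regulator`, `target`, `label` over all ordered
#'   pairs), and `network`.
#' @export
simulate_expression <- function(network, design, seed = 1, amplitude = 1,
                                common_peak_hours = 17,
                                phase_jitter_hours = 1.5) {
  stopifnot(inherits(network, "planted_network"),
            inherits(design, "sampling_design"))
  genes <- network$genes
  ng <- length(genes)
  nt <- design$n_timepoints
  coupling <- matrix(0, ng, ng, dimnames = list(genes, genes))
  if (nrow(network$edges)) {
    coupling[cbind(network$edges$regulator, network$edges$target)] <-
      network$edges$coupling
  }
  squash <- if (network$mode == "nonlinear-lag") tanh else identity

  sim <- with_local_seed(seed, function() {
    dev <- matrix(0, ng, nt)
    innov <- matrix(stats::rnorm(ng * nt, sd = network$noise_sd), ng, nt)
    dev[, 1L] <- innov[, 1L]
    lag <- network$lag
    for (t in seq_len(nt - 1L)) {
      parent_in <- if (t >= lag) {
        as.vector(t(coupling) %*% squash(dev[, t - lag + 1L]))
      } else {
        0
      }
      dev[, t + 1L] <- network$ar * dev[, t] + parent_in + innov[, t + 1L]
    }
    if (network$mode == "circadian") {
      phases <- stats::rnorm(ng, common_peak_hours, phase_jitter_hours)
      base <- amplitude *
        cos(2 * pi * outer(phases, design$time_hours, function(p, h) h - p) / 24)
      dev <- dev + base
    }
    dev
  })
  # per-gene shift to non-negative support; affine, so TE-invariant
  sim <- sim - pmin(apply(sim, 1L, min), 0)
  rownames(sim) <- genes
  colnames(sim) <- sprintf("t%03d", seq_len(nt))

  gold <- tidyr::expand_grid(regulator = genes, target = genes) |>
    dplyr::filter(.data$regulator != .data$target) |>
    dplyr::left_join(
      dplyr::transmute(network$edges, .data$regulator, .data$target,
                       label = as.integer(.data$coupling > 0)),
      by = c("regulator", "target")
    ) |>
    dplyr::mutate(label = dplyr::coalesce(.data$label, 0L))
  attr(gold, "universe") <- genes

  list(expression = matrix_to_expr(sim), gold = gold, network = network)
}

#' Reference rhythmic expression waveform
#'
#' Generates a non-negative, single-peaked 24-hour waveform — a von
#' Mises-style bump \eqn{\exp(\kappa(\cos(2\pi (t - t_{peak})/24) - 1))} plus
#' optional Gaussian noise — emulating the sharply night-peaked expression of
#' a rhythmic reference gene such as the melatonin rate-limiting enzyme
#' AANAT. Used as the reference profile for pattern-based target selection.
#'
#' @param design A [sampling_design()].
#' @param peak_phase_hours Peak time in hours after the sampling start
#'   (default 17: about midnight for sampling that begins at 7 a.m.).
#' @param concentration Peak sharpness \eqn{\kappa} (larger = narrower peak).
#' @param noise_sd Gaussian noise standard deviation.
#' @param seed Integer seed for the noise.
#' @return Numeric vector of length `design$n_timepoints`, non-negative.
#' @export
make_rhythm_reference <- function(design, peak_phase_hours = 17,
                                  concentration = 3, noise_sd = 0.05,
                                  seed = 1) {
  stopifnot(inherits(design, "sampling_design"))
  wave <- exp(concentration *
                (cos(2 * pi * (design$time_hours - peak_phase_hours) / 24) - 1))
  if (noise_sd > 0) {
    wave <- with_local_seed(seed, function() {
      wave + stats::rnorm(length(wave), sd = noise_sd)
    })
  }
  pmax(wave, 0)
}
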