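#' Synthetic cohort specification
#'
#' Describes a cohort of subjects that emulates a structural-connectome
#' study: per subject a binarized structural network at fixed link density
#' with modular-but-overlapping structure, a matched functional time-series
#' panel whose community-switching rate is coupled to the structural overlap
#' score, and behavioral scores linearly coupled to overlap.
#'
#' The structural generator samples a between-module mixing fraction
#' `mu ~ U(mixing_range)` (the fraction of the edge budget placed between
#' modules) and solves the planted-partition probabilities from the exact
#' density constraint `p_in * W + p_out * B = k` (W/B = within-/between-
#' module pair counts, k = edge budget), so every subject hits the target
#' density while spanning low-to-high segregation.
#'
#' @param n_subjects cohort size (100 subjects is the emulated study size).
#' @param N_structural structural nodes (164-region parcellation scale).
#' @param M_structural planted structural module count (divides
#'   `N_structural`).
#' @param density structural link density (0.10).
#' @param mixing_range range of the between-module mixing fraction.
#' @param N_ts functional nodes per panel.
#' @param T panel length in samples (4,800 emulates a full resting-state
#'   scan).
#' @param sampling_interval seconds per sample (0.72).
#' @param M_ts latent functional module count.
#' @param switch_rate_base expected module-structure switches per scan at
#'   the bottom of the overlap distribution.
#' @param coupling_flex additional expected switches at the top of the
#'   overlap distribution (the planted structure-dynamics slope).
#' @param coupling_behavior target population Pearson r between overlap and
#'   each behavioral score, in (-1, 1); 0.26 sits in the r range typically
#'   reported for overlap-behavior associations.
#' @param noise_sd node noise SD relative to the unit-variance shared module
#'   signal; 0.8 gives within-module correlations near 0.6.
#' @param seed optional integer governing the whole cohort.
#' @return a list of class `cn_cohortspec`.
#' @export
cohort_spec <- function(n_subjects = 100, N_structural = 164,
                        M_structural = 4, density = 0.10,
                        mixing_range = c(0.10, 0.60), N_ts = 50, T = 4800,
                        sampling_interval = 0.72, M_ts = 4,
                        switch_rate_base = 2, coupling_flex = 8,
                        coupling_behavior = 0.26, noise_sd = 0.8,
                        seed = NULL) {
  stopifnot(n_subjects >= 1, N_structural %% M_structural == 0,
            density > 0, density <= 1,
            abs(coupling_behavior) < 1, coupling_flex >= 0,
            switch_rate_base >= 0, noise_sd >= 0, T >= 2, N_ts >= 2)
  structure(list(n_subjects = n_subjects, N_structural = N_structural,
                 M_structural = M_structural, density = density,
                 mixing_range = mixing_range, N_ts = N_ts, T = T,
                 sampling_interval = sampling_interval, M_ts = M_ts,
                 switch_rate_base = switch_rate_base,
                 coupling_flex = coupling_flex,
                 coupling_behavior = coupling_behavior,
                 noise_sd = noise_sd, seed = seed),
            class = "cn_cohortspec")
}

# planted-partition draw adjusted to an exact edge budget
structural_network <- function(N, M, mu, k) {
  Wp <- M * choose(N / M, 2)
  Bp <- choose(N, 2) - Wp
  p_in <- (1 - mu) * k / Wp
  p_out <- mu * k / Bp
  if (p_in > 1) stop("infeasible density: p_in > 1 for mu = ", mu)
  g <- generate_modular(N, M, p_in, p_out)
  planted <- attr(g, "planted")
  m <- n_edges(g)
  A <- adjacency(g)
  if (m > k) {
    drop <- sample.int(m, m - k)
    em <- g$edges[-drop, , drop = FALSE]
    g <- new_network(g$nodes, em[order(em[, 1], em[, 2]), , drop = FALSE])
  } else if (m < k) {
    non <- which(upper.tri(A) & !A, arr.ind = TRUE)
    add <- non[sample.int(nrow(non), k - m), , drop = FALSE]
    em <- rbind(g$edges, add)
    g <- new_network(g$nodes, em[order(em[, 1], em[, 2]), , drop = FALSE])
  }
  attr(g, "planted") <- planted
  g
}

#' Piecewise-stationary switching block-correlation panel
#'
#' Latent module membership of the nodes is redrawn at each switch time;
#' within a stationary segment every node's signal is its module's shared
#' standard-normal signal (fresh draw per sample) plus independent Gaussian
#' noise, giving within-module correlation `1 / (1 + noise_sd^2)`.
#'
#' @param N nodes.
#' @param T samples.
#' @param sampling_interval seconds per sample.
#' @param switch_times strictly increasing integer sample indices in
#'   `(0, T)`; membership changes after each listed sample.
#' @param M latent module count.
#' @param noise_sd node noise SD.
#' @param seed optional integer.
#' @return a `cn_panel` with attribute `"segments"` (per-segment membership
#'   and boundaries).
#' @export
generate_switch_panel <- function(N, T, sampling_interval, switch_times,
                                  M, noise_sd = 0.8, seed = NULL) {
  switch_times <- as.integer(switch_times)
  if (length(switch_times) > 0) {
    stopifnot(all(diff(switch_times) > 0), all(switch_times > 0),
              all(switch_times < T))
  }
  run <- function() {
    bounds <- c(0L, switch_times, T)
    x <- matrix(NA_real_, N, T)
    segs <- vector("list", length(bounds) - 1)
    for (s in seq_len(length(bounds) - 1)) {
      cols <- (bounds[s] + 1):bounds[s + 1]
      mem <- sample(rep_len(seq_len(M), N))
      sig <- matrix(stats::rnorm(M * length(cols)), M, length(cols))
      x[, cols] <- sig[mem, , drop = FALSE] +
        noise_sd * matrix(stats::rnorm(N * length(cols)), N, length(cols))
      segs[[s]] <- list(from = bounds[s] + 1L, to = bounds[s + 1],
                        membership = mem)
    }
    p <- time_series_panel(x, sampling_interval)
    attr(p, "segments") <- segs
    p
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Generate a synthetic cohort
#'
#' Per subject: (1) draw a structural network spanning low-to-high
#' segregation at the exact target density; (2) score its community overlap
#' (mean link-community memberships per node); (3) simulate a functional
#' panel whose expected number of latent module switches is
#' `switch_rate_base + coupling_flex * overlap_percentile` (Poisson count,
#' uniform switch times); (4) draw three behavioral scores
#' (pattern-completion-, card-sorting- and flanker-like) as
#' \eqn{\rho \cdot z(overlap) + \sqrt{1 - \rho^2} \cdot noise} with
#' \eqn{\rho} = `coupling_behavior`, so the population overlap-behavior
#' correlation equals the planted coupling.
#'
#' @param spec a [cohort_spec()].
#' @param panels generate the time-series panels (set FALSE to skip them
#'   when only structure/behavior is needed; much faster).
#' @return an object of class `cn_cohort`: list with `subjects` (each a
#'   `cn_subject` with `structural`, `panel`, `behavior`, `planted`) and
#'   `spec`.
#' @export
generate_cohort <- function(spec, panels = TRUE) {
  stopifnot(inherits(spec, "cn_cohortspec"))
  n <- spec$n_subjects
  k <- round_half_up(spec$density * spec$N_structural *
                       (spec$N_structural - 1) / 2)
  seeds <- draw_subseeds(2 * n + 1, spec$seed)
  nets <- vector("list", n)
  ov <- numeric(n)
  for (i in seq_len(n)) {
    nets[[i]] <- withr::with_seed(seeds[i], {
      mu <- stats::runif(1, spec$mixing_range[1], spec$mixing_range[2])
      structural_network(spec$N_structural, spec$M_structural, mu, k)
    })
    ov[i] <- overlap_score(nets[[i]])
  }
  pct <- (rank(ov, ties.method = "average") - 0.5) / n
  r <- spec$coupling_behavior
  z <- as.vector(scale(ov))
  behav <- withr::with_seed(seeds[2 * n + 1], {
    sapply(c("pattern_completion", "card_sorting", "flanker"),
           function(task) r * z + sqrt(1 - r^2) * stats::rnorm(n))
  })
  subjects <- vector("list", n)
  for (i in seq_len(n)) {
    sub_seed <- seeds[n + i]
    rate <- spec$switch_rate_base + spec$coupling_flex * pct[i]
    panel <- NULL
    n_switch <- NA_integer_
    st <- integer(0)
    if (panels) {
      panel <- withr::with_seed(sub_seed, {
        n_switch <- min(stats::rpois(1, rate), spec$T - 1L)
        st <- sort(sample.int(spec$T - 1L, n_switch))
        generate_switch_panel(spec$N_ts, spec$T, spec$sampling_interval,
                              st, spec$M_ts, spec$noise_sd)
      })
    }
    subjects[[i]] <- structure(
      list(id = sprintf("S%03d", i),
           structural = nets[[i]],
           panel = panel,
           behavior = stats::setNames(as.numeric(behav[i, ]),
                                      colnames(behav)),
           planted = list(overlap_score = ov[i], overlap_percentile = pct[i],
                          switch_rate = rate, n_switches = n_switch,
                          switch_times = st)),
      class = "cn_subject")
  }
  structure(list(subjects = subjects, spec = spec), class = "cn_cohort")
}

#' @export
print.cn_cohort <- function(x, ...) {
  cat("<cn_cohort> ", length(x$subjects), " subjects (N = ",
      x$spec$N_structural, ", density ", x$spec$density, ")\n", sep = "")
  invisible(x)
}

#' Cohort manifest table
#'
#' @param cohort a `cn_cohort`.
#' @return data.frame with one row per subject: id, structural overlap
#'   score and percentile, planted switch rate and count, behavior scores.
#' @export
cohort_manifest <- function(cohort) {
  stopifnot(inherits(cohort, "cn_cohort"))
  do.call(rbind, lapply(cohort$subjects, function(s) {
    data.frame(id = s$id,
               overlap_score = s$planted$overlap_score,
               overlap_percentile = s$planted$overlap_percentile,
               switch_rate = s$planted$switch_rate,
               n_switches = s$planted$n_switches,
               pattern_completion = s$behavior[["pattern_completion"]],
               card_sorting = s$behavior[["card_sorting"]],
               flanker = s$behavior[["flanker"]])
  }))
}
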