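#' Specification for Crooks-consistent synthetic work data
#'
#' Defines a Gaussian work model with a known ground-truth free energy: the
#' forward (reduction) work is drawn from
#' \eqn{N(\Delta G + \beta\sigma^2/2,\ \sigma^2)} and the backward
#' (oxidation) work from \eqn{N(-\Delta G + \beta\sigma^2/2,\ \sigma^2)}.
#' This pair satisfies the Crooks relation exactly with free-energy
#' difference `delta_g_true`, so every estimator can be validated against an
#' analytic truth. At \eqn{\sigma = 0} the construction collapses to the
#' quasistatic limit where every run yields \eqn{W = \Delta G}.
#'
#' @param delta_g_true Ground-truth reduction free energy, kJ/mol.
#' @param sigma Work standard deviation, kJ/mol (>= 0).
#' @param n_per_direction Samples per direction (>= 1).
#' @param temperature Temperature in kelvin.
#' @param seed Integer seed; all randomness flows from it through an
#'   isolated RNG stream (the global RNG state is untouched).
#' @return An object of class `synthetic_work_spec`.
#' @export
synthetic_work_spec <- function(delta_g_true, sigma, n_per_direction,
                                temperature = 298, seed = 1L) {
  if (!is.finite(delta_g_true)) stop_param("delta_g_true must be finite")
  if (!is.finite(sigma) || sigma < 0) stop_param("sigma must be >= 0")
  if (n_per_direction < 1L) stop_param("n_per_direction must be >= 1")
  structure(
    list(delta_g_true = as.numeric(delta_g_true), sigma = as.numeric(sigma),
         n_per_direction = as.integer(n_per_direction),
         temperature = as.numeric(temperature), seed = as.integer(seed)),
    class = "synthetic_work_spec"
  )
}

#' Generate a Crooks-consistent Gaussian WorkSet
#'
#' @param spec A [synthetic_work_spec()].
#' @param label System label for the resulting WorkSet.
#' @return A `workset` whose true free-energy difference is
#'   `spec$delta_g_true`.
#' @examples
#' ws <- generate_crooks_gaussian(synthetic_work_spec(5, 2, 1000, seed = 42))
#' cb_estimate(ws)
#' @export
generate_crooks_gaussian <- function(spec, label = "synthetic") {
  stopifnot(inherits(spec, "synthetic_work_spec"))
  thermo <- make_thermo(spec$temperature)
  shift <- thermo$beta * spec$sigma^2 / 2
  samples <- withr::with_seed(spec$seed, {
    list(fwd = rnorm(spec$n_per_direction, spec$delta_g_true + shift, spec$sigma),
         bwd = rnorm(spec$n_per_direction, -spec$delta_g_true + shift, spec$sigma))
  })
  workset(samples$fwd, samples$bwd, thermo, label = label)
}

#' Generate a synthetic snapshot-energy table
#'
#' Wraps the Gaussian work generator in per-frame paired energies so the
#' table readers and [build_workset()] can be exercised end to end:
#' oxidized-ensemble frames get a baseline `eps_ox` ~ N(0, baseline_sd^2)
#' and `eps_red = eps_ox + W_fwd`; reduced-ensemble frames get a baseline
#' `eps_red` and `eps_ox = eps_red + W_bwd`. Frames are split evenly over
#' replicates, mirroring how a production study pools a few hundred frames
#' from each of several independent trajectories.
#'
#' @param spec A [synthetic_work_spec()].
#' @param n_replicates Number of replicates per direction.
#' @param baseline_sd SD of the baseline ensemble energy, kJ/mol.
#' @param system System label.
#' @return A data frame of snapshot-energy pairs (see [read_energy_table()]).
#' @export
generate_energy_table <- function(spec, n_replicates = 10L, baseline_sd = 50,
                                  system = "synthetic") {
  stopifnot(inherits(spec, "synthetic_work_spec"))
  if (n_replicates < 1L) stop_param("n_replicates must be >= 1")
  if (baseline_sd < 0) stop_param("baseline_sd must be >= 0")
  ws <- generate_crooks_gaussian(spec, label = system)
  n <- spec$n_per_direction
  base <- withr::with_seed(spec$seed + 1L, {
    list(ox = rnorm(n, 0, baseline_sd), red = rnorm(n, 0, baseline_sd))
  })
  rep_of <- function(i) ((i - 1L) %/% ceiling(n / n_replicates)) + 1L
  frames <- seq_len(n)
  rbind(
    data.frame(system = system, replicate = rep_of(frames), frame = frames,
               source_ensemble = "oxidized",
               eps_ox = base$ox, eps_red = base$ox + ws$forward,
               stringsAsFactors = FALSE),
    data.frame(system = system, replicate = rep_of(frames), frame = frames,
               source_ensemble = "reduced",
               eps_red = base$red, eps_ox = base$red + ws$backward,
               stringsAsFactors = FALSE)[, c("system", "replicate", "frame",
                                             "source_ensemble", "eps_ox", "eps_red")]
  )
}

#' Generate an exactly Crooks-consistent Gaussian-mixture WorkSet
#'
#' Stress generator with non-Gaussian work distributions. Given forward
#' mixture components \eqn{\sum_k w_k N(m_k, s_k^2)}, the Crooks relation
#' fixes both the ground truth,
#' \eqn{e^{-\beta\Delta G} = \sum_k w_k e^{-\beta m_k + \beta^2 s_k^2/2}},
#' and the backward density, which is again a Gaussian mixture with
#' components \eqn{N(-(m_k - \beta s_k^2), s_k^2)} and reweighted weights
#' \eqn{w_k e^{\beta(\Delta G - m_k) + \beta^2 s_k^2/2}}. The construction
#' is exact, not approximate.
#'
#' @param means,sds,weights Forward mixture components (kJ/mol; weights sum
#'   to 1).
#' @param n_per_direction Samples per direction.
#' @param temperature Temperature in kelvin.
#' @param seed Integer seed.
#' @param label System label.
#' @return A list with `ws` (the `workset`) and `delta_g_true` (kJ/mol).
#' @export
generate_crooks_mixture <- function(means, sds, weights, n_per_direction,
                                    temperature = 298, seed = 1L,
                                    label = "synthetic-mixture") {
  if (length(means) != length(sds) || length(means) != length(weights)) {
    stop_param("means, sds and weights must have equal length")
  }
  if (any(sds < 0) || any(weights <= 0)) {
    stop_param("sds must be >= 0 and weights > 0")
  }
  weights <- weights / sum(weights)
  thermo <- make_thermo(temperature)
  beta <- thermo$beta
  # e^{-beta dG} = sum_k w_k e^{-beta m_k + beta^2 s_k^2 / 2}, via log-sum-exp
  le <- log(weights) - beta * means + beta^2 * sds^2 / 2
  m <- max(le)
  delta_g <- -(m + log(sum(exp(le - m)))) / beta
  w_back <- exp(log(weights) + beta * (delta_g - means) + beta^2 * sds^2 / 2)
  w_back <- w_back / sum(w_back) # exact up to rounding
  m_back <- -(means - beta * sds^2)
  n <- as.integer(n_per_direction)
  samples <- withr::with_seed(seed, {
    kf <- sample.int(length(weights), n, replace = TRUE, prob = weights)
    kb <- sample.int(length(weights), n, replace = TRUE, prob = w_back)
    list(fwd = rnorm(n, means[kf], sds[kf]),
         bwd = rnorm(n, m_back[kb], sds[kb]))
  })
  list(ws = workset(samples$fwd, samples$bwd, thermo, label = label),
       delta_g_true = delta_g)
}

#' Generate a synthetic one-electron titration curve
#'
#' Applied potentials span `midpoint` +/- 150 mV uniformly; the response is
#' the one-electron Nernst reduced fraction (reduction favoured at low
#' potential, so the curve decreases with increasing applied potential) plus
#' Gaussian noise, clipped to [-0.1, 1.1] as a crude model of normalized
#' absorbance changes.
#'
#' @param midpoint True midpoint potential, mV.
#' @param n_points Number of potential steps (>= 4).
#' @param noise_sd SD of the additive response noise (dimensionless).
#' @param temperature Temperature in kelvin.
#' @param seed Integer seed (unused when `noise_sd = 0`).
#' @return A `titration_curve` data frame with columns `applied_potential`
#'   (mV) and `response`.
#' @export
generate_titration <- function(midpoint, n_points = 25L, noise_sd = 0,
                               temperature = 298, seed = 1L) {
  if (n_points < 4L) stop_param("n_points must be >= 4")
  if (noise_sd < 0) stop_param("noise_sd must be >= 0")
  e_app <- seq(midpoint - 150, midpoint + 150, length.out = n_points)
  resp <- nernst_fraction(e_app, midpoint, temperature = temperature)
  if (noise_sd > 0) {
    resp <- resp + withr::with_seed(seed, rnorm(n_points, 0, noise_sd))
  }
  titration_curve(e_app, pmin(pmax(resp, -0.1), 1.1))
}
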