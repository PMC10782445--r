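#' Free-energy estimate
#'
#' A reduction free energy \eqn{\Delta G} (kJ/mol) with standard error and
#' the estimator that produced it.
#'
#' @param delta_g Estimate, kJ/mol.
#' @param std_error Standard error, kJ/mol (`NA` when the estimator defines
#'   none, e.g. histogram crossing).
#' @param method One of `"cb"`, `"crossing"`, `"bar"`, `"jarzynski"`,
#'   `"fep"`, `"lr"`.
#' @param n_forward,n_backward Sample counts used.
#' @param diagnostics Optional free-form notes.
#' @return An object of class `fe_estimate`.
#' @export
fe_estimate <- function(delta_g, std_error = NA_real_, method, n_forward = 0L,
                        n_backward = 0L, diagnostics = NULL) {
  if (!is.na(std_error) && std_error < 0) stop_param("std_error must be >= 0")
  structure(
    list(delta_g = as.numeric(delta_g), std_error = as.numeric(std_error),
         method = as.character(method), n_forward = as.integer(n_forward),
         n_backward = as.integer(n_backward), diagnostics = diagnostics),
    class = "fe_estimate"
  )
}

#' @export
print.fe_estimate <- function(x, ...) {
  se <- if (is.na(x$std_error)) "NA" else sprintf("%.4f", x$std_error)
  cat(sprintf("Delta G [%s]: %.4f +/- %s kJ/mol (n_fwd = %d, n_bwd = %d)\n",
              x$method, x$delta_g, se, x$n_forward, x$n_backward))
  invisible(x)
}

require_two_sided <- function(ws, what) {
  if (n_forward(ws) < 1L || n_backward(ws) < 1L) {
    stop_unsupported(sprintf(
      "%s needs work values in both directions; use jarzynski_estimate()/fep for one-sided data",
      what))
  }
}

# ---- Crooks-Bayes -----------------------------------------------------------

#' Crooks-Bayes posterior over the free-energy difference
#'
#' Builds the posterior density over free-energy hypotheses \eqn{\Delta g}
#' implied by the Crooks fluctuation relation with a flat prior: each forward
#' (reduction) work value contributes a factor
#' \eqn{f(\beta(W_i - \Delta g) + M)} and each backward (oxidation) value a
#' factor \eqn{f(\beta(W_j + \Delta g) - M)}, where
#' \eqn{f(x) = 1/(1+e^{-x})} is the logistic function and
#' \eqn{M = \ln(n_F/n_R)} accounts for unequal sample counts (zero in the
#' equal-count case). The likelihood is accumulated in the log domain with
#' max-subtraction, then normalized by the trapezoid rule.
#'
#' The default grid is centred on the BAR estimate and spans
#' \eqn{\pm\max(10\,k_BT,\ 5\,\mathrm{sd})} of the pooled work values
#' (backward values negated) with 4001 uniform points; if more than 1e-4 of
#' the posterior mass falls in the outermost grid cells the span is doubled
#' and the density recomputed, up to six times.
#'
#' @param ws A two-sided `workset`.
#' @param grid Optional explicit grid of \eqn{\Delta g} hypotheses (kJ/mol),
#'   strictly increasing and uniformly spaced, length >= 101.
#' @param grid_points Number of grid points for the default grid.
#' @return An object of class `cb_posterior` with fields `grid`, `density`,
#'   `thermo`, `n_forward`, `n_backward`.
#' @seealso [crooks_bayes_estimate()] for the posterior-mean estimator.
#' @export
crooks_bayes_posterior <- function(ws, grid = NULL, grid_points = 4001L) {
  require_two_sided(ws, "crooks_bayes_posterior")
  beta <- ws$thermo$beta
  M <- log(n_forward(ws) / n_backward(ws))

  eval_density <- function(g) {
    ll <- cb_loglik_grid(ws$forward, ws$backward, g, beta, M)
    d <- exp(ll - max(ll))
    z <- pracma::trapz(g, d)
    if (!is.finite(z) || z <= 0) {
      stop_convergence("Crooks-Bayes likelihood vanished on the whole grid")
    }
    d / z
  }

  if (!is.null(grid)) {
    grid <- as.numeric(grid)
    if (length(grid) < 101L || is.unsorted(grid, strictly = TRUE)) {
      stop_param("grid must be strictly increasing with >= 101 points")
    }
    steps <- diff(grid)
    if (max(steps) - min(steps) > 1e-9 * mean(steps)) {
      stop_param("grid must be uniformly spaced")
    }
    density <- eval_density(grid)
  } else {
    center <- bar_root(ws)
    pooled <- c(ws$forward, -ws$backward)
    spread <- if (length(pooled) > 1L) sd(pooled) else 0
    half <- max(10 / beta, 5 * spread)
    grid_points <- max(101L, as.integer(grid_points))
    for (attempt in 1:7) {
      grid <- seq(center - half, center + half, length.out = grid_points)
      density <- eval_density(grid)
      h <- grid[2] - grid[1]
      edge_mass <- h * (density[1] + density[2] +
                        density[grid_points - 1L] + density[grid_points]) / 2
      if (edge_mass <= 1e-4) break
      if (attempt == 7) {
        stop_convergence("posterior mass keeps clipping the grid edges after widening")
      }
      half <- half * 2
    }
  }

  structure(
    list(grid = grid, density = density, thermo = ws$thermo,
         n_forward = n_forward(ws), n_backward = n_backward(ws),
         label = ws$label),
    class = "cb_posterior"
  )
}

#' @export
print.cb_posterior <- function(x, ...) {
  cat(sprintf("Crooks-Bayes posterior over [%.3f, %.3f] kJ/mol (%d points), n_fwd = %d, n_bwd = %d\n",
              min(x$grid), max(x$grid), length(x$grid), x$n_forward, x$n_backward))
  invisible(x)
}

#' Posterior-mean Crooks-Bayes estimate
#'
#' The posterior mean is the square-error-optimal point estimate of
#' \eqn{\Delta G}; the reported error is the posterior standard deviation.
#' Both moments are evaluated by trapezoid quadrature on the posterior grid.
#'
#' @param post A [crooks_bayes_posterior()] density.
#' @return An [fe_estimate] with `method = "cb"`.
#' @export
crooks_bayes_estimate <- function(post) {
  if (!inherits(post, "cb_posterior")) stop_param("expected a cb_posterior")
  z <- pracma::trapz(post$grid, post$density)
  if (abs(z - 1) > 1e-6) {
    stop("internal error: posterior density is not normalized")
  }
  m <- pracma::trapz(post$grid, post$grid * post$density)
  v <- pracma::trapz(post$grid, (post$grid - m)^2 * post$density)
  fe_estimate(m, sqrt(max(v, 0)), method = "cb",
              n_forward = post$n_forward, n_backward = post$n_backward)
}

#' One-call Crooks-Bayes estimate from a WorkSet
#'
#' @inheritParams crooks_bayes_posterior
#' @return An [fe_estimate] with `method = "cb"`.
#' @export
cb_estimate <- function(ws, grid = NULL, grid_points = 4001L) {
  crooks_bayes_estimate(crooks_bayes_posterior(ws, grid, grid_points))
}

# ---- BAR --------------------------------------------------------------------

bar_root <- function(ws) {
  beta <- ws$thermo$beta
  M <- log(n_forward(ws) / n_backward(ws))
  resid <- function(g) bar_residual_cpp(ws$forward, ws$backward, g, beta, M)
  # bracket from the two one-sided Jarzynski estimates, expanded on demand
  j_f <- jarzynski_estimate(ws$forward, ws$thermo)$delta_g
  j_b <- -jarzynski_estimate(ws$backward, ws$thermo)$delta_g
  lo <- min(j_f, j_b) - 1e-9
  hi <- max(j_f, j_b) + 1e-9
  limit_lo <- min(c(ws$forward, -ws$backward)) - 50 / beta
  limit_hi <- max(c(ws$forward, -ws$backward)) + 50 / beta
  step <- 1 / beta
  while (resid(lo) >= 0) { # residual is strictly increasing in g
    lo <- lo - step; step <- step * 2
    if (lo < limit_lo) stop_convergence("BAR bracket expansion failed (low side)")
  }
  step <- 1 / beta
  while (resid(hi) <= 0) {
    hi <- hi + step; step <- step * 2
    if (hi > limit_hi) stop_convergence("BAR bracket expansion failed (high side)")
  }
  stats::uniroot(resid, c(lo, hi), tol = 1e-12)$root
}

#' Bennett acceptance ratio estimate
#'
#' Solves the BAR self-consistency equation
#' \deqn{\sum_i f(\beta(W_i - \Delta g) + M) = \sum_j f(\beta(W_j + \Delta g) - M)}
#' (\eqn{M = \ln n_F/n_R}) for \eqn{\Delta g} with a bracketing root solver
#' to better than 1e-10 kJ/mol; the bracket starts at the two one-sided
#' Jarzynski estimates and is expanded until the residual changes sign, up
#' to \eqn{50\,k_BT} beyond the data range. The standard error is the BAR
#' asymptotic (maximum-likelihood) variance
#' \eqn{\beta^{-2}[(\sum f(1-f))^{-1} - (1/n_F + 1/n_R)]}, falling back to
#' the observed-information form when the small-sample subtraction is
#' non-positive.
#'
#' @param ws A two-sided `workset`.
#' @return An [fe_estimate] with `method = "bar"`.
#' @export
bar_estimate <- function(ws) {
  require_two_sided(ws, "bar_estimate")
  beta <- ws$thermo$beta
  M <- log(n_forward(ws) / n_backward(ws))
  root <- bar_root(ws)
  x <- c(beta * (ws$forward - root) + M, beta * (ws$backward + root) - M)
  fx <- plogis(x)
  info <- sum(fx * (1 - fx))
  v_beta <- if (info > 0) 1 / info - (1 / n_forward(ws) + 1 / n_backward(ws)) else Inf
  if (!is.finite(v_beta) || v_beta <= 0) v_beta <- if (info > 0) 1 / info else Inf
  se <- if (is.finite(v_beta)) sqrt(v_beta) / beta else NA_real_
  fe_estimate(root, se, method = "bar",
              n_forward = n_forward(ws), n_backward = n_backward(ws))
}

# ---- one-sided estimators ---------------------------------------------------

#' Jarzynski / free-energy-perturbation estimate
#'
#' One-sided exponential-average estimator
#' \eqn{\Delta G = -\beta^{-1}\ln\langle e^{-\beta W}\rangle}, evaluated with
#' log-sum-exp to tolerate work values of hundreds of kJ/mol. For
#' instantaneous switches this coincides with Zwanzig's free energy
#' perturbation formula (`method = "fep"` records the alias). When applied
#' to backward (oxidation) work values the result is \eqn{-\Delta G} of the
#' forward (reduction) process; the caller interprets the sign.
#'
#' @param values One direction's work values, kJ/mol (>= 1 value).
#' @param thermo A [make_thermo()] state (or temperature in kelvin).
#' @param method `"jarzynski"` (default) or the alias `"fep"`.
#' @return An [fe_estimate]; no standard error is defined by default.
#' @export
jarzynski_estimate <- function(values, thermo = make_thermo(),
                               method = c("jarzynski", "fep")) {
  method <- match.arg(method)
  thermo <- as_thermo(thermo)
  values <- as.numeric(values)
  if (!length(values)) stop_data("jarzynski_estimate needs at least one work value")
  if (any(!is.finite(values))) stop_data("work values must be finite")
  beta <- thermo$beta
  x <- -beta * values
  m <- max(x)
  lme <- m + log(mean(exp(x - m))) # log-mean-exp
  fe_estimate(-lme / beta, NA_real_, method = method,
              n_forward = length(values), n_backward = 0L)
}

#' Linear-response (Gaussian work) estimate
#'
#' Assumes the work distribution is Gaussian, in which case
#' \eqn{\Delta G = \langle W\rangle - \beta\sigma^2/2} with the unbiased
#' sample variance \eqn{\sigma^2}.
#'
#' @param values One direction's work values, kJ/mol (>= 2 values).
#' @param thermo A [make_thermo()] state (or temperature in kelvin).
#' @return An [fe_estimate] with `method = "lr"`; no standard error is
#'   defined.
#' @export
lr_estimate <- function(values, thermo = make_thermo()) {
  thermo <- as_thermo(thermo)
  values <- as.numeric(values)
  if (length(values) < 2L) stop_data("lr_estimate needs at least two work values")
  if (any(!is.finite(values))) stop_data("work values must be finite")
  fe_estimate(mean(values) - thermo$beta * var(values) / 2, NA_real_,
              method = "lr", n_forward = length(values), n_backward = 0L)
}

# ---- histogram crossing -----------------------------------------------------

shared_breaks <- function(pooled, bins = NULL) {
  if (!is.null(bins)) {
    h <- diff(range(pooled)) / bins
  } else {
    h <- 2 * stats::IQR(pooled) / length(pooled)^(1 / 3) # Freedman-Diaconis
  }
  if (!is.finite(h) || h <= 0) return(NULL)
  center <- mean(pooled)
  lo <- floor((min(pooled) - center) / h) - 1L
  hi <- ceiling((max(pooled) - center) / h) + 1L
  center + (lo:hi) * h
}

#' Histogram-crossing estimate
#'
#' The Crooks relation implies the forward work density \eqn{p(W|\Lambda)}
#' and the negated backward density \eqn{\tilde p(-W|\tilde\Lambda)} cross
#' exactly at \eqn{W^* = \Delta G}. Both samples are binned on shared
#' uniform bins (Freedman-Diaconis width by default) over the union support;
#' the crossing is located by linear interpolation between adjacent bin
#' centres where the density difference changes sign. Among multiple
#' crossings, the one inside the sample-overlap region closest to the BAR
#' estimate is returned. No standard error is defined for this estimator.
#'
#' @param ws A two-sided `workset` with at least 10 values per direction.
#' @param bins Optional bin count overriding the Freedman-Diaconis rule.
#' @return An [fe_estimate] with `method = "crossing"` and `std_error = NA`.
#' @export
histogram_crossing <- function(ws, bins = NULL) {
  require_two_sided(ws, "histogram_crossing")
  if (n_forward(ws) < 10L || n_backward(ws) < 10L) {
    stop_param("histogram_crossing needs >= 10 work values per direction")
  }
  x <- ws$forward
  y <- -ws$backward
  if (length(x) == length(y) && all(sort(x) == sort(y))) {
    stop_data("degenerate crossing: forward and negated-backward samples are identical; use cb_estimate()/bar_estimate()")
  }
  overlap <- c(max(min(x), min(y)), min(max(x), max(y)))
  if (overlap[1] > overlap[2]) {
    stop_data("no crossing: forward and negated-backward work histograms do not overlap")
  }
  breaks <- shared_breaks(c(x, y), bins)
  if (is.null(breaks)) {
    stop_data("degenerate crossing: too few distinct work values to histogram")
  }
  h <- breaks[2] - breaks[1]
  cx <- graphics::hist(x, breaks = breaks, plot = FALSE)$counts / (length(x) * h)
  cy <- graphics::hist(y, breaks = breaks, plot = FALSE)$counts / (length(y) * h)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  d <- cx - cy
  i <- seq_len(length(d) - 1L)
  sign_change <- d[i] * d[i + 1L] < 0
  supported <- (cx[i] > 0 & cy[i] > 0) | (cx[i + 1L] > 0 & cy[i + 1L] > 0)
  idx <- which(sign_change & supported)
  # a bin where both densities are positive and exactly equal is itself a
  # crossing; without this, a difference sequence like (-, 0, +) has no
  # strict sign change between adjacent bins
  tie_idx <- which(d == 0 & cx > 0 & cy > 0)
  if (!length(idx) && !length(tie_idx)) {
    stop_data("no crossing found between the work histograms")
  }
  crossings <- c(
    mids[idx] + (mids[idx + 1L] - mids[idx]) * d[idx] / (d[idx] - d[idx + 1L]),
    mids[tie_idx])
  inside <- crossings >= overlap[1] & crossings <= overlap[2]
  if (any(inside)) crossings <- crossings[inside]
  ref <- bar_root(ws)
  fe_estimate(crossings[which.min(abs(crossings - ref))], NA_real_,
              method = "crossing",
              n_forward = n_forward(ws), n_backward = n_backward(ws),
              diagnostics = list(n_crossings = length(crossings), bin_width = h))
}

# ---- convergence ------------------------------------------------------------

#' Crooks-Bayes convergence curve
#'
#' Re-estimates \eqn{\Delta G} on growing prefixes of the work samples
#' (first \eqn{\mu} forward and first \eqn{\mu} backward values, preserving
#' trajectory order), tracking how the posterior mean and SD settle as more
#' nonequilibrium iterations are included.
#'
#' @param ws A two-sided `workset`.
#' @param mu_schedule Strictly increasing sample counts; entries exceeding
#'   the available data are dropped with a warning.
#' @param grid_points Grid size passed to [crooks_bayes_posterior()].
#' @return A data frame of class `convergence_series` with columns `mu`,
#'   `delta_g`, `std_error`.
#' @export
convergence_curve <- function(ws, mu_schedule, grid_points = 4001L) {
  require_two_sided(ws, "convergence_curve")
  mu_schedule <- as.integer(mu_schedule)
  if (is.unsorted(mu_schedule, strictly = TRUE) || any(mu_schedule < 1L)) {
    stop_param("mu_schedule must be strictly increasing positive counts")
  }
  n_avail <- min(n_forward(ws), n_backward(ws))
  if (any(mu_schedule > n_avail)) {
    warning(sprintf("mu_schedule truncated to the %d available samples per direction", n_avail))
    mu_schedule <- mu_schedule[mu_schedule <= n_avail]
  }
  est <- lapply(mu_schedule, function(mu) {
    sub <- workset(ws$forward[seq_len(mu)], ws$backward[seq_len(mu)],
                   ws$thermo, ws$label)
    cb_estimate(sub, grid_points = grid_points)
  })
  structure(
    data.frame(mu = mu_schedule,
               delta_g = vapply(est, `[[`, 0, "delta_g"),
               std_error = vapply(est, `[[`, 0, "std_error")),
    class = c("convergence_series", "data.frame")
  )
}

# ---- Crooks self-consistency diagnostic ------------------------------------

#' Empirical Crooks-relation check
#'
#' The Crooks relation states
#' \eqn{\ln[p(W|\Lambda)/\tilde p(-W|\tilde\Lambda)] = \beta(W - \Delta G)}.
#' This diagnostic histograms both directions on shared bins, keeps bins
#' where both histograms have at least `min_count` observations, and
#' regresses the empirical log-density ratio on the bin centre. For
#' Crooks-consistent data the slope recovers \eqn{\beta} and the intercept
#' \eqn{-\beta\Delta G}.
#'
#' @param ws A two-sided `workset`.
#' @param min_count Minimum per-direction bin count for a bin to enter the
#'   regression.
#' @param bins Optional bin count overriding the Freedman-Diaconis rule.
#' @return A list with `slope`, `intercept`, `delta_g` (= -intercept/slope),
#'   `beta` (the expected slope) and `n_bins` used.
#' @export
crooks_consistency <- function(ws, min_count = 10L, bins = NULL) {
  require_two_sided(ws, "crooks_consistency")
  x <- ws$forward
  y <- -ws$backward
  breaks <- shared_breaks(c(x, y), bins)
  if (is.null(breaks)) stop_data("too few distinct work values to histogram")
  h <- breaks[2] - breaks[1]
  cx <- graphics::hist(x, breaks = breaks, plot = FALSE)$counts
  cy <- graphics::hist(y, breaks = breaks, plot = FALSE)$counts
  keep <- cx >= min_count & cy >= min_count
  if (sum(keep) < 3L) {
    stop_data("insufficient histogram overlap for the Crooks regression")
  }
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  logratio <- log(cx[keep] / length(x)) - log(cy[keep] / length(y))
  fit <- lm(logratio ~ mids[keep])
  slope <- unname(coef(fit)[2])
  intercept <- unname(coef(fit)[1])
  list(slope = slope, intercept = intercept,
       delta_g = -intercept / slope,
       beta = ws$thermo$beta, n_bins = sum(keep))
}

# ---- exports ----------------------------------------------------------------

#' Export a posterior density as two-column TSV
#'
#' Columns `delta_g_kjmol` and `density`, suitable for plotting.
#'
#' @param post A `cb_posterior`.
#' @param path Output path.
#' @export
export_posterior <- function(post, path) {
  df <- data.frame(delta_g_kjmol = post$grid, density = post$density)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export an estimate as a JSON record
#'
#' Writes `{label, method, delta_g_kjmol, stderr_kjmol, n_forward,
#' n_backward}`.
#'
#' @param est An [fe_estimate].
#' @param label System label.
#' @param path Output path.
#' @export
export_estimate <- function(est, label, path) {
  rec <- list(label = label, method = est$method,
              delta_g_kjmol = est$delta_g,
              stderr_kjmol = if (is.na(est$std_error)) NULL else est$std_error,
              n_forward = est$n_forward, n_backward = est$n_backward)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
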