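#' Titration curve
#'
#' Applied potential (mV) versus normalized absorbance-change response, the
#' layout produced by thin-layer spectroelectrochemical titrations after
#' mediator equilibration, reference calibration and replicate averaging
#' (all treated as upstream data preparation).
#'
#' @param applied_potential Applied potentials, mV (>= 4 finite values).
#' @param response Normalized responses, same length.
#' @param replicate Optional replicate id.
#' @return A data frame of class `titration_curve`.
#' @export
titration_curve <- function(applied_potential, response, replicate = NULL) {
  applied_potential <- as.numeric(applied_potential)
  response <- as.numeric(response)
  if (length(applied_potential) != length(response)) {
    stop_data("applied_potential and response must have equal length")
  }
  if (length(applied_potential) < 4L) {
    stop_data("a titration curve needs at least 4 points")
  }
  if (any(!is.finite(applied_potential)) || any(!is.finite(response))) {
    stop_data("titration data must be finite")
  }
  df <- data.frame(applied_potential = applied_potential, response = response)
  if (!is.null(replicate)) df$replicate <- replicate
  structure(df, class = c("titration_curve", "data.frame"))
}

#' Read a titration CSV
#'
#' Header `potential_mV,response[,replicate]`.
#'
#' @param path Path to the CSV.
#' @return A `titration_curve`.
#' @export
read_titration <- function(path) {
  if (!file.exists(path)) stop_data(sprintf("file not found: %s", path))
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("potential_mV", "response") %in% names(df))) {
    stop_data("titration CSV needs columns potential_mV,response")
  }
  titration_curve(df$potential_mV, df$response, replicate = df$replicate)
}

#' Write a titration curve as CSV
#'
#' @param curve A `titration_curve`.
#' @param path Output path.
#' @export
write_titration <- function(curve, path) {
  out <- data.frame(potential_mV = curve$applied_potential,
                    response = curve$response)
  if (!is.null(curve$replicate)) out$replicate <- curve$replicate
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' One-electron Nernst reduced fraction
#'
#' From the Nernst equation
#' \eqn{E_{app} = E + (RT/nF)\ln([ox]/[red])}, the reduced fraction is
#' \deqn{[red]/([red]+[ox]) = 1/\left(1 + e^{nF(E_{app} - E)/RT}\right),}
#' a sigmoid that equals 0.5 at the midpoint \eqn{E} and decreases with
#' increasing applied potential (reduction is favoured at low potential).
#' At 298 K and n = 1, \eqn{RT\ln 10/F \approx 59.13} mV per decade of
#' [ox]/[red].
#'
#' @param e_app Applied potential(s), mV.
#' @param midpoint Midpoint potential, mV.
#' @param temperature Temperature in kelvin (> 0).
#' @param n_electrons Electrons transferred (default 1).
#' @return Reduced fraction(s) in (0, 1).
#' @export
nernst_fraction <- function(e_app, midpoint, temperature = 298, n_electrons = 1) {
  if (!is.finite(temperature) || temperature <= 0) {
    stop_param("temperature must be > 0 K")
  }
  rt_nf_mv <- 1000 * .kB * temperature / (.FARADAY_KJ_PER_V * n_electrons)
  plogis((midpoint - e_app) / rt_nf_mv)
}

#' Fit the one-electron Nernst equation to a titration curve
#'
#' Least-squares fit of
#' `response = baseline + amplitude * nernst_fraction(e_app, midpoint)`
#' with n fixed at 1 electron (set `fix_n = FALSE` to also float n, off by
#' default). Baseline and amplitude are free because experimental
#' normalization is imperfect; the midpoint is initialized at the potential
#' whose response is closest to mid-range. Standard errors come from the
#' fit's covariance matrix. The fit is solved with [minpack.lm::nls.lm()]
#' directly rather than the `nls`-style wrapper: on noiseless data the
#' baseline converges to ~1e-11, where `stats::numericDeriv`'s relative step
#' produces an exactly-zero gradient column and a spurious "singular
#' gradient" error in the wrapper's model construction.
#'
#' @param curve A `titration_curve` (>= 4 points with response range >= 0.3,
#'   so both plateaus are represented).
#' @param temperature Temperature in kelvin.
#' @param fix_n Keep the electron count fixed at 1 (default).
#' @return An object of class `nernst_fit` with fields `midpoint`,
#'   `midpoint_se` (mV), `n_electrons`, `amplitude`, `baseline`, `rss`.
#' @export
fit_nernst <- function(curve, temperature = 298, fix_n = TRUE) {
  if (!inherits(curve, "titration_curve")) {
    curve <- titration_curve(curve$applied_potential, curve$response)
  }
  e <- curve$applied_potential
  r <- curve$response
  if (length(e) < 4L) stop_data("fit_nernst needs at least 4 points")
  if (diff(range(r)) < 0.3) {
    stop_data("ill-conditioned fit: responses do not span the sigmoid (range < 0.3)")
  }
  mid0 <- e[which.min(abs(r - (min(r) + max(r)) / 2))]
  amp0 <- diff(range(r))
  base0 <- min(r)
  ctrl <- minpack.lm::nls.lm.control(ftol = 1e-10, ptol = 1e-10, maxiter = 500)
  resid_fn <- if (fix_n) {
    function(p) r - (p[3] + p[2] * nernst_fraction(e, p[1], temperature))
  } else {
    function(p) r - (p[3] + p[2] * nernst_fraction(e, p[1], temperature, p[4]))
  }
  start <- if (fix_n) c(mid0, amp0, base0) else c(mid0, amp0, base0, 1)
  lower <- if (fix_n) rep(-Inf, 3L) else c(-Inf, -Inf, -Inf, 0.1)
  fit <- minpack.lm::nls.lm(par = start, fn = resid_fn, lower = lower,
                            control = ctrl)
  if (fit$info < 1L || fit$info > 4L) {
    stop_convergence(sprintf("Nernst fit did not converge: %s", fit$message))
  }
  cf <- fit$par
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, length(cf)))
  structure(
    list(midpoint = cf[1],
         midpoint_se = unname(se[1]),
         n_electrons = if (fix_n) 1 else cf[4],
         amplitude = cf[2],
         baseline = cf[3],
         rss = fit$deviance,
         temperature = temperature),
    class = "nernst_fit"
  )
}

#' @export
print.nernst_fit <- function(x, ...) {
  cat(sprintf("Nernst fit (n = %g e-): midpoint = %.2f +/- %.2f mV, amplitude = %.3f, baseline = %.3f, RSS = %.3g\n",
              x$n_electrons, x$midpoint, x$midpoint_se, x$amplitude, x$baseline,
              x$rss))
  invisible(x)
}

#' Export a Nernst fit as a JSON report
#'
#' @param fit A `nernst_fit`.
#' @param path Output path.
#' @export
export_nernst_fit <- function(fit, path) {
  jsonlite::write_json(unclass(fit), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
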