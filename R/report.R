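#' Redox shift between a variant and a reference protein
#'
#' \eqn{\delta E = E_{var} - E_{ref}}, with the standard errors combined in
#' quadrature. Because force-field energies omit electronic (quantum)
#' contributions, absolute potentials from work-based estimators are
#' uncalibrated; shifts relative to a reference protein are the meaningful
#' quantity.
#'
#' @param est_var,est_ref [redox_estimate]s (same method and units; a method
#'   mismatch triggers a warning, not an error).
#' @param system,reference Labels for the result.
#' @return A list of class `shift_result` with `system`, `reference`,
#'   `delta_e` (mV) and `std_error` (mV).
#' @export
compute_shift <- function(est_var, est_ref, system = "variant",
                          reference = "reference") {
  if (!inherits(est_var, "redox_estimate") || !inherits(est_ref, "redox_estimate")) {
    stop_param("compute_shift expects two redox_estimate objects")
  }
  if (!identical(est_var$method, est_ref$method)) {
    warning(sprintf("method mismatch: %s vs %s", est_var$method, est_ref$method))
  }
  se <- sqrt(sum(c(est_var$std_error, est_ref$std_error)^2, na.rm = FALSE))
  structure(
    list(system = system, reference = reference,
         delta_e = est_var$potential - est_ref$potential,
         std_error = se, method = est_var$method),
    class = "shift_result"
  )
}

#' @export
print.shift_result <- function(x, ...) {
  se <- if (is.na(x$std_error)) "NA" else sprintf("%.2f", x$std_error)
  cat(sprintf("delta E (%s - %s) [%s]: %.2f +/- %s mV\n",
              x$system, x$reference, x$method, x$delta_e, se))
  invisible(x)
}

#' Pearson product-moment correlation
#'
#' Thin validated wrapper around [stats::cor()] used by the benchmarking
#' report: requires equal lengths >= 3 and non-zero variance in both
#' arguments.
#'
#' @param x,y Numeric vectors.
#' @return The correlation coefficient in [-1, 1].
#' @export
pearson_correlation <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y) || length(x) < 3L) {
    stop_data("pearson_correlation needs equal-length vectors with >= 3 values")
  }
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop_data("pearson_correlation needs finite values")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    stop_data("undefined correlation: zero variance in an argument")
  }
  cor(x, y)
}

#' Read a redox shift table
#'
#' CSV with one header row and columns `system`, `exp_dE_mV`, `exp_err_mV`,
#' plus one `<method>_dE_mV` column per prediction method (optionally with a
#' matching `<method>_err_mV`). Exactly one reference row (experimental
#' shift 0 relative to itself) must be present.
#'
#' @param path Path to the CSV.
#' @return A data frame of class `shift_table`.
#' @export
read_shift_table <- function(path) {
  if (!file.exists(path)) stop_data(sprintf("file not found: %s", path))
  df <- read.csv(path, stringsAsFactors = FALSE)
  as_shift_table(df)
}

#' @rdname read_shift_table
#' @param df A data frame in the shift-table layout.
#' @export
as_shift_table <- function(df) {
  if (!all(c("system", "exp_dE_mV") %in% names(df))) {
    stop_data("shift table needs columns system and exp_dE_mV")
  }
  if (anyDuplicated(df$system)) stop_data("one row per system required")
  structure(as.data.frame(df), class = c("shift_table", "data.frame"))
}

shift_methods <- function(table) {
  cols <- grep("_dE_mV$", names(table), value = TRUE)
  setdiff(sub("_dE_mV$", "", cols), "exp")
}

#' Bundled benchmark shift table for the m4D2 maquette variants
#'
#' The published measurements and predictions for the de novo four-helix
#' bundle heme protein m4D2 and its variants: experimental midpoint shifts
#' relative to m4D2 (mV, from thin-layer spectroelectrochemistry), the
#' work-based MD + CB predictions, and continuum-electrostatics (PB + MC)
#' predictions. DM is the T19D-T77D double mutant; the other four rows are
#' single mutants.
#'
#' @return A `shift_table` with rows m4D2 (reference), T19D, M23N, R34Q,
#'   R92Q, DM.
#' @export
m4d2_shift_table <- function() {
  path <- system.file("extdata", "m4d2_shift_table.csv", package = "redoxcb",
                      mustWork = TRUE)
  read_shift_table(path)
}

#' Benchmark predicted redox shifts against experiment
#'
#' For every prediction method in the table, computes the Pearson
#' correlation with the experimental shifts over (a) all non-reference
#' variants and (b) the single mutants only. The reference row (shift 0 by
#' definition) is excluded from both correlations. Single mutants are
#' identified by a one-substitution label such as `T19D` (override with
#' `single_systems`). The mean signed offset between prediction and
#' experiment is reported under both sign conventions.
#'
#' @param table A `shift_table`.
#' @param reference Reference system label; defaults to the row whose
#'   experimental shift is 0.
#' @param single_systems Optional character vector naming the single-mutant
#'   rows.
#' @return A list of class `benchmark_report`: per-method `cor_all`,
#'   `cor_single`, `offset_exp_minus_pred_mV`, `offset_pred_minus_exp_mV`,
#'   and the row sets used.
#' @export
benchmark_report <- function(table, reference = NULL, single_systems = NULL) {
  table <- as_shift_table(table)
  methods <- shift_methods(table)
  if (!length(methods)) stop_data("shift table has no prediction columns (*_dE_mV)")
  if (is.null(reference)) {
    ref_idx <- which(table$exp_dE_mV == 0)
    if (length(ref_idx) != 1L) {
      stop_data("no unique reference row (exp_dE_mV == 0); pass `reference`")
    }
  } else {
    ref_idx <- which(table$system == reference)
    if (length(ref_idx) != 1L) stop_data(sprintf("reference '%s' not found", reference))
  }
  variants <- table[-ref_idx, , drop = FALSE]
  if (nrow(variants) < 3L) stop_data("need >= 3 non-reference rows to benchmark")
  if (is.null(single_systems)) {
    single <- grepl("^[A-Za-z][0-9]+[A-Za-z]$", variants$system)
  } else {
    single <- variants$system %in% single_systems
  }
  per_method <- lapply(methods, function(m) {
    pred <- variants[[paste0(m, "_dE_mV")]]
    out <- list(
      cor_all = pearson_correlation(variants$exp_dE_mV, pred),
      cor_single = if (sum(single) >= 3L) {
        pearson_correlation(variants$exp_dE_mV[single], pred[single])
      } else NA_real_,
      offset_exp_minus_pred_mV = mean(variants$exp_dE_mV[single] - pred[single]),
      offset_pred_minus_exp_mV = mean(pred[single] - variants$exp_dE_mV[single])
    )
    out
  })
  structure(
    list(methods = setNames(per_method, methods),
         reference = table$system[ref_idx],
         systems = variants$system,
         single_systems = variants$system[single]),
    class = "benchmark_report"
  )
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat(sprintf("Benchmark vs experiment (reference: %s)\n", x$reference))
  cat(sprintf("Single mutants: %s\n", paste(x$single_systems, collapse = ", ")))
  for (m in names(x$methods)) {
    r <- x$methods[[m]]
    cat(sprintf("  %-8s rho(single) = %.2f  rho(all) = %.2f  mean offset (pred - exp, single) = %.1f mV\n",
                m, r$cor_single, r$cor_all, r$offset_pred_minus_exp_mV))
  }
  invisible(x)
}

#' Export a benchmark report
#'
#' Writes the per-method correlations as TSV (2 d.p., human-readable) and,
#' optionally, a full-precision JSON record.
#'
#' @param report A `benchmark_report`.
#' @param path_tsv,path_json Output paths (either may be `NULL`).
#' @export
export_benchmark <- function(report, path_tsv = NULL, path_json = NULL) {
  if (!is.null(path_tsv)) {
    df <- data.frame(
      method = names(report$methods),
      cor_single = sprintf("%.2f", vapply(report$methods, `[[`, 0, "cor_single")),
      cor_all = sprintf("%.2f", vapply(report$methods, `[[`, 0, "cor_all"))
    )
    utils::write.table(df, path_tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  if (!is.null(path_json)) {
    jsonlite::write_json(unclass(report), path_json, auto_unbox = TRUE, digits = NA)
  }
  invisible(report)
}
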