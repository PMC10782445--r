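#' Work values from paired snapshot energies
#'
#' Each equilibrium snapshot carries the potential energy of the protein in
#' both redox states (`eps_ox`, `eps_red`, kJ/mol). The instantaneous
#' (Kubo-Onsager) work of switching state on that snapshot is the signed
#' final-minus-initial energy difference: a frame sampled from the
#' *oxidized* ensemble defines a forward (reduction) work
#' \eqn{W = \epsilon_{red} - \epsilon_{ox}}, a frame from the *reduced*
#' ensemble a backward (oxidation) work
#' \eqn{W = \epsilon_{ox} - \epsilon_{red}}. No heat term enters because the
#' switch is instantaneous. Energies are protein-only contributions as
#' delivered by the upstream simulations; no solvent decomposition is
#' attempted here.
#'
#' @param pair A single snapshot-energy pair: a list or one-row data frame
#'   with fields `eps_ox`, `eps_red` (kJ/mol) and `source_ensemble`
#'   (`"oxidized"` or `"reduced"`; common aliases such as `"oxidised"`,
#'   `"ox"`, `"red"` are accepted), optionally `replicate` and `frame`.
#' @return A list of class `work_sample` with fields `value` (kJ/mol),
#'   `direction` (`"forward"` for reduction, `"backward"` for oxidation) and
#'   `origin` (replicate/frame if present).
#' @examples
#' compute_work(list(eps_ox = 100, eps_red = 90, source_ensemble = "oxidized"))
#' @export
compute_work <- function(pair) {
  eo <- as.numeric(pair$eps_ox)
  er <- as.numeric(pair$eps_red)
  if (length(eo) != 1L || length(er) != 1L || !is.finite(eo) || !is.finite(er)) {
    stop_data(sprintf("non-finite snapshot energies (replicate %s, frame %s)",
                      pair$replicate %||% "?", pair$frame %||% "?"))
  }
  src <- normalize_ensemble(pair$source_ensemble)
  structure(
    list(
      value = if (src == "oxidized") er - eo else eo - er,
      direction = if (src == "oxidized") "forward" else "backward",
      origin = list(replicate = pair$replicate %||% NA,
                    frame = pair$frame %||% NA)
    ),
    class = "work_sample"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

normalize_ensemble <- function(x) {
  tok <- tolower(trimws(as.character(x)))
  out <- character(length(tok))
  out[tok %in% c("oxidized", "oxidised", "ox", "o")] <- "oxidized"
  out[tok %in% c("reduced", "red", "r")] <- "reduced"
  bad <- which(out == "")
  if (length(bad)) {
    stop_data(sprintf("unknown source_ensemble token '%s' (record %d)",
                      tok[bad[1]], bad[1]))
  }
  out
}

#' Pool snapshot-energy pairs into a WorkSet
#'
#' Computes the per-snapshot work values and pools them across replicates
#' into one forward (reduction) and one backward (oxidation) sample, with
#' input order preserved within each direction. Replicates are pooled by
#' default, matching how the upstream simulations contribute thousands of
#' frames per system; set `per_replicate = TRUE` to keep per-replicate
#' subsets for diagnostics.
#'
#' @param pairs Data frame of snapshot-energy pairs with columns `system`,
#'   `replicate`, `frame`, `source_ensemble`, `eps_ox`, `eps_red`
#'   (see [read_energy_table()]).
#' @param thermo A [make_thermo()] state (or temperature in kelvin).
#' @param system Optional system label; inferred from the table when `NULL`.
#'   Mixing several systems in one call is an error.
#' @param per_replicate If `TRUE`, return a named list with one WorkSet per
#'   replicate instead of the pooled set.
#' @return A `workset` (or list of them): forward/backward numeric work
#'   vectors (kJ/mol), the thermal state and the system label. An empty
#'   input yields an empty WorkSet flagged with a warning.
#' @export
build_workset <- function(pairs, thermo = make_thermo(), system = NULL,
                          per_replicate = FALSE) {
  thermo <- as_thermo(thermo)
  if (is.null(pairs) || nrow(as.data.frame(pairs)) == 0L) {
    warning("empty input: returning a WorkSet with zero samples")
    return(workset(numeric(0), numeric(0), thermo,
                   label = system %||% "unknown"))
  }
  pairs <- as.data.frame(pairs)
  systems <- unique(as.character(pairs$system %||% system %||% "unknown"))
  if (length(systems) > 1L) {
    stop_data(sprintf("pairs span multiple systems: %s",
                      paste(systems, collapse = ", ")))
  }
  label <- system %||% systems
  if (!is.null(system) && !is.null(pairs$system) &&
      any(as.character(pairs$system) != system)) {
    stop_data(sprintf("pairs labelled '%s' do not match system '%s'",
                      systems, system))
  }
  eo <- as.numeric(pairs$eps_ox)
  er <- as.numeric(pairs$eps_red)
  if (any(!is.finite(eo)) || any(!is.finite(er))) {
    bad <- which(!is.finite(eo) | !is.finite(er))[1]
    stop_data(sprintf("non-finite snapshot energies at record %d (frame %s)",
                      bad, pairs$frame[bad] %||% "?"))
  }
  src <- normalize_ensemble(pairs$source_ensemble)
  w <- ifelse(src == "oxidized", er - eo, eo - er)
  if (per_replicate) {
    reps <- as.character(pairs$replicate %||% rep("1", length(w)))
    out <- lapply(split(seq_along(w), reps), function(idx) {
      workset(w[idx][src[idx] == "oxidized"], w[idx][src[idx] == "reduced"],
              thermo, label = label)
    })
    return(out)
  }
  workset(w[src == "oxidized"], w[src == "reduced"], thermo, label = label)
}

#' Construct a WorkSet directly from work values
#'
#' @param forward Forward (reduction) work values, kJ/mol.
#' @param backward Backward (oxidation) work values, kJ/mol.
#' @param thermo A [make_thermo()] state (or temperature in kelvin).
#' @param label System label.
#' @return An object of class `workset`.
#' @export
workset <- function(forward, backward, thermo = make_thermo(), label = "unknown") {
  forward <- as.numeric(forward)
  backward <- as.numeric(backward)
  if (any(!is.finite(forward)) || any(!is.finite(backward))) {
    stop_data("work values must all be finite")
  }
  structure(
    list(forward = forward, backward = backward,
         thermo = as_thermo(thermo), label = as.character(label)),
    class = "workset"
  )
}

#' @export
print.workset <- function(x, ...) {
  cat(sprintf("WorkSet '%s': %d forward (reduction), %d backward (oxidation) values at T = %g K\n",
              x$label, length(x$forward), length(x$backward),
              x$thermo$temperature))
  invisible(x)
}

#' @rdname workset
#' @param ws A `workset`.
#' @export
n_forward <- function(ws) length(ws$forward)

#' @rdname workset
#' @export
n_backward <- function(ws) length(ws$backward)

#' Read a snapshot-energy table
#'
#' Expects a header row with columns `system`, `replicate`, `frame`,
#' `source_ensemble` and the paired energies, either as
#' `eps_ox_kjmol`/`eps_red_kjmol` (the canonical headers) or plain
#' `eps_ox`/`eps_red`. British spelling `oxidised` is normalized to
#' `oxidized`.
#'
#' @param path Path to the table.
#' @param dialect `"csv"` (default) or `"tsv"`.
#' @return A data frame of snapshot-energy pairs with normalized column
#'   names `system`, `replicate`, `frame`, `source_ensemble`, `eps_ox`,
#'   `eps_red`.
#' @export
read_energy_table <- function(path, dialect = c("csv", "tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_data(sprintf("file not found: %s", path))
  df <- if (dialect == "csv") {
    read.csv(path, stringsAsFactors = FALSE)
  } else {
    read.delim(path, stringsAsFactors = FALSE)
  }
  names(df) <- sub("_kjmol$", "", names(df))
  required <- c("system", "replicate", "frame", "source_ensemble",
                "eps_ox", "eps_red")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop_data(sprintf("missing required column(s): %s",
                      paste(missing, collapse = ", ")))
  }
  for (col in c("eps_ox", "eps_red")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(!is.finite(v))
    if (length(bad)) {
      stop_data(sprintf("unparseable or non-finite %s at data line %d of %s",
                        col, bad[1], path))
    }
    df[[col]] <- v
  }
  df$source_ensemble <- normalize_ensemble(df$source_ensemble)
  key <- paste(df$system, df$replicate, df$frame, df$source_ensemble)
  if (anyDuplicated(key)) {
    stop_data(sprintf("duplicate (system, replicate, frame, ensemble) record at data line %d",
                      which(duplicated(key))[1]))
  }
  df[required]
}

#' Write a snapshot-energy table
#'
#' Writes the canonical CSV layout with `eps_ox_kjmol`/`eps_red_kjmol`
#' headers, the format [read_energy_table()] reads back.
#'
#' @param pairs Data frame of snapshot-energy pairs.
#' @param path Output path.
#' @export
write_energy_table <- function(pairs, path) {
  out <- as.data.frame(pairs)
  names(out)[names(out) == "eps_ox"] <- "eps_ox_kjmol"
  names(out)[names(out) == "eps_red"] <- "eps_red_kjmol"
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a two-column xvg-style series
#'
#' Lenient reader for the plain-text energy series GROMACS tooling writes:
#' lines starting with `#` or `@` are metadata and skipped; every remaining
#' line must hold two numerics (time, energy).
#'
#' @param path Path to the file.
#' @return A data frame with columns `time` and `energy`.
#' @export
read_xvg <- function(path) {
  if (!file.exists(path)) stop_data(sprintf("file not found: %s", path))
  lines <- readLines(path)
  keep <- !grepl("^[ \t]*[#@]", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (!length(idx)) return(data.frame(time = numeric(0), energy = numeric(0)))
  parts <- strsplit(trimws(lines[idx]), "[ \t,]+")
  bad <- which(vapply(parts, length, 1L) < 2L)
  if (length(bad)) {
    stop_data(sprintf("expected two numeric columns at line %d of %s",
                      idx[bad[1]], path))
  }
  t <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 1L)))
  e <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  nf <- which(!is.finite(t) | !is.finite(e))
  if (length(nf)) {
    stop_data(sprintf("unparseable numeric at line %d of %s", idx[nf[1]], path))
  }
  data.frame(time = t, energy = e)
}

#' Pair two xvg energy series into snapshot-energy pairs
#'
#' The xvg-pairs dialect: one file holds the oxidized-state energy and one
#' the reduced-state energy evaluated on the same frames of one ensemble.
#' Rows are matched by position.
#'
#' @param path_ox,path_red Paths to the oxidized/reduced energy series.
#' @param source_ensemble Which ensemble the frames were sampled from.
#' @param system,replicate Labels for the resulting records.
#' @return A data frame of snapshot-energy pairs (see [read_energy_table()]).
#' @export
read_energy_xvg <- function(path_ox, path_red,
                            source_ensemble = c("oxidized", "reduced"),
                            system = "unknown", replicate = 1L) {
  source_ensemble <- match.arg(source_ensemble)
  ox <- read_xvg(path_ox)
  red <- read_xvg(path_red)
  if (nrow(ox) != nrow(red)) {
    stop_data(sprintf("xvg pair length mismatch: %d vs %d rows",
                      nrow(ox), nrow(red)))
  }
  data.frame(system = system, replicate = replicate, frame = seq_len(nrow(ox)),
             source_ensemble = source_ensemble,
             eps_ox = ox$energy, eps_red = red$energy,
             stringsAsFactors = FALSE)
}

read_work_values <- function(path) {
  if (!file.exists(path)) stop_data(sprintf("file not found: %s", path))
  lines <- readLines(path)
  keep <- !grepl("^[ \t]*#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (!length(idx)) return(numeric(0))
  # U+2212 minus signs occur in copy-pasted tables; accept them
  v <- suppressWarnings(as.numeric(gsub("−", "-", trimws(lines[idx]))))
  bad <- which(!is.finite(v))
  if (length(bad)) {
    stop_data(sprintf("non-numeric work value at line %d of %s",
                      idx[bad[1]], path))
  }
  v
}

#' Read forward/backward work files into a WorkSet
#'
#' Plain-text work files: one value (kJ/mol) per line, `#` comment lines
#' ignored, separate files for the forward (reduction) and backward
#' (oxidation) direction.
#'
#' @param path_forward,path_backward Paths to the two work files.
#' @param thermo A [make_thermo()] state (or temperature in kelvin).
#' @param label System label.
#' @return A `workset`.
#' @export
read_work_file <- function(path_forward, path_backward,
                           thermo = make_thermo(), label = "unknown") {
  fwd <- read_work_values(path_forward)
  bwd <- read_work_values(path_backward)
  if (!length(fwd) && !length(bwd)) {
    stop_data("both work files are empty")
  }
  workset(fwd, bwd, thermo, label = label)
}

#' Write a WorkSet to forward/backward work files
#'
#' Full-precision text so that [read_work_file()] reproduces the values
#' bit-exactly.
#'
#' @param ws A `workset`.
#' @param path_forward,path_backward Output paths.
#' @export
write_work_file <- function(ws, path_forward, path_backward) {
  writeLines(c(sprintf("# forward (reduction) work, kJ/mol, system %s", ws$label),
               sprintf("%.17g", ws$forward)), path_forward)
  writeLines(c(sprintf("# backward (oxidation) work, kJ/mol, system %s", ws$label),
               sprintf("%.17g", ws$backward)), path_backward)
  invisible(ws)
}
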