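#' Construct a centroided peak list
#'
#' @param mz Numeric vector of mass-to-charge values (> 0).
#' @param intensity Numeric vector of non-negative intensities.
#' @return Object of class `peak_list`: a data frame with columns `mz` and
#'   `intensity`, sorted ascending by `mz`.
#' @export
peak_list <- function(mz = numeric(0), intensity = numeric(0)) {
  if (length(mz) != length(intensity)) {
    stop("mz and intensity must have the same length", call. = FALSE)
  }
  if (length(mz) > 0 && (any(!is.finite(mz)) || any(mz <= 0))) {
    stop("mz values must be finite and > 0", call. = FALSE)
  }
  if (length(intensity) > 0 &&
      (any(!is.finite(intensity)) || any(intensity < 0))) {
    stop("intensities must be finite and >= 0", call. = FALSE)
  }
  ord <- order(mz)
  structure(data.frame(mz = mz[ord], intensity = intensity[ord]),
            class = c("peak_list", "data.frame"))
}

#' Construct a mass-spectrometry time series
#'
#' @param times Strictly increasing acquisition times in hours, length >= 2.
#' @param spectra List of `peak_list` objects, one per time point.
#' @return Object of class `ms_timeseries`.
#' @export
ms_timeseries <- function(times, spectra) {
  if (length(times) != length(spectra)) {
    stop("one spectrum per time point required", call. = FALSE)
  }
  if (length(times) < 2L) {
    stop("a time series needs at least 2 time points", call. = FALSE)
  }
  if (any(diff(times) <= 0)) {
    stop("acquisition times must be strictly increasing", call. = FALSE)
  }
  spectra <- lapply(spectra, function(s) {
    if (!inherits(s, "peak_list")) s <- peak_list(s$mz, s$intensity)
    s
  })
  structure(list(times = as.numeric(times), spectra = spectra),
            class = "ms_timeseries")
}

#' @export
print.ms_timeseries <- function(x, ...) {
  cat(sprintf("MS time series: %d spectra, t = %.3g..%.3g h\n",
              length(x$times), min(x$times), max(x$times)))
  invisible(x)
}

#' Read a peak-list time series from a manifest file
#'
#' The manifest is a CSV with columns `time_hours` and `file`; each peak
#' list file is a headerless 2-column CSV or TSV (`mz`, `intensity`).
#' Relative file paths are resolved against the manifest's directory. Rows
#' are sorted by time on input.
#'
#' @param manifest Path to the manifest CSV.
#' @return An `ms_timeseries`.
#' @export
read_timeseries <- function(manifest) {
  if (!file.exists(manifest)) {
    stop(sprintf("manifest file '%s' not found", manifest), call. = FALSE)
  }
  mf <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  if (!all(c("time_hours", "file") %in% names(mf))) {
    stop("manifest must have columns 'time_hours' and 'file'",
         call. = FALSE)
  }
  if (anyDuplicated(mf$time_hours)) {
    stop("manifest contains duplicate time points", call. = FALSE)
  }
  mf <- mf[order(mf$time_hours), , drop = FALSE]
  base <- dirname(manifest)
  spectra <- lapply(seq_len(nrow(mf)), function(i) {
    f <- mf$file[i]
    if (!file.exists(f)) f <- file.path(base, mf$file[i])
    if (!file.exists(f)) {
      stop(sprintf("peak list file '%s' (t = %s h) not found", mf$file[i],
                   mf$time_hours[i]), call. = FALSE)
    }
    sep <- if (grepl("\\.tsv$", f, ignore.case = TRUE)) "\t" else ","
    pk <- utils::read.table(f, sep = sep, header = FALSE,
                            col.names = c("mz", "intensity"))
    if (nrow(pk) == 0L) {
      stop(sprintf("peak list '%s' is empty", f), call. = FALSE)
    }
    peak_list(pk$mz, pk$intensity)
  })
  ms_timeseries(mf$time_hours, spectra)
}

#' Write a time series as peak-list CSVs plus a manifest
#'
#' @param timeseries An `ms_timeseries`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix for the per-time-point CSVs.
#' @return Path to the written manifest, invisibly.
#' @export
write_timeseries <- function(timeseries, dir, prefix = "spectrum") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- sprintf("%s_%02d.csv", prefix, seq_along(timeseries$times))
  for (i in seq_along(files)) {
    utils::write.table(
      as.data.frame(timeseries$spectra[[i]]),
      file.path(dir, files[i]), sep = ",", row.names = FALSE,
      col.names = FALSE)
  }
  manifest <- file.path(dir, "manifest.csv")
  ## %.17g round-trips doubles exactly through the text format
  utils::write.csv(
    data.frame(time_hours = sprintf("%.17g", timeseries$times),
               file = files),
    manifest, row.names = FALSE, quote = FALSE)
  invisible(manifest)
}

#' Convert a neutral mass to m/z
#' @param mass Neutral monoisotopic mass (Da).
#' @param charge Charge state (default 1, i.e. singly protonated).
#' @param table Mass table.
#' @return m/z value.
#' @export
mass_to_mz <- function(mass, charge = 1L, table = mass_table()) {
  (mass + charge * table$proton) / charge
}

#' Match a theoretical mass against a peak list (PMF lookup)
#'
#' Among the peaks within `tolerance` of the target m/z the most intense one
#' is returned; ties are broken by smaller m/z distance, then lower m/z, so
#' the result does not depend on peak order.
#'
#' @param peaklist A `peak_list`.
#' @param target_mass Neutral monoisotopic mass to look for (Da).
#' @param tolerance Match tolerance (> 0).
#' @param unit `"da"` or `"ppm"` (applied on the m/z axis).
#' @param charge Assumed charge state (default 1).
#' @return A list `(mz, intensity)` for the matched peak, or `NULL` when no
#'   peak lies in the window (absence is a value, not an error).
#' @export
match_peak <- function(peaklist, target_mass, tolerance = 0.3,
                       unit = c("da", "ppm"), charge = 1L) {
  unit <- match.arg(unit)
  if (tolerance <= 0) stop("tolerance must be > 0", call. = FALSE)
  target_mz <- mass_to_mz(target_mass, charge)
  tol_da <- if (unit == "ppm") tolerance * 1e-6 * target_mz else tolerance
  mz <- peaklist$mz
  lo <- findInterval(target_mz - tol_da, mz) + 1L
  hi <- findInterval(target_mz + tol_da, mz)
  if (hi < lo) return(NULL)
  idx <- lo:hi
  ints <- peaklist$intensity[idx]
  best <- idx[ints == max(ints)]
  if (length(best) > 1L) {
    d <- abs(mz[best] - target_mz)
    best <- best[d == min(d)]
    best <- best[which.min(mz[best])]
  }
  list(mz = mz[best], intensity = peaklist$intensity[best])
}

#' Normalize a time series of peak lists
#'
#' `none` returns the input unchanged. `tic` rescales every spectrum so its
#' total ion current equals the series-median TIC (within-spectrum intensity
#' ratios are preserved exactly). `reference_mass` rescales so that the peak
#' matching `reference_mass` has the same (series-median) intensity in every
#' spectrum.
#'
#' @param timeseries An `ms_timeseries`.
#' @param method One of `"none"`, `"tic"`, `"reference_mass"`.
#' @param reference_mass Neutral mass of the reference peptide (required for
#'   `reference_mass`).
#' @param tolerance,unit,charge Matching parameters for the reference peak.
#' @return A normalized `ms_timeseries`.
#' @export
normalize_timeseries <- function(timeseries,
                                 method = c("none", "tic", "reference_mass"),
                                 reference_mass = NULL, tolerance = 0.3,
                                 unit = "da", charge = 1L) {
  method <- match.arg(method)
  if (method == "none") return(timeseries)
  if (method == "tic") {
    tics <- vapply(timeseries$spectra,
                   function(s) sum(s$intensity), numeric(1))
    target <- stats::median(tics)
    scale <- ifelse(tics > 0, target / tics, 1)
  } else {
    if (is.null(reference_mass)) {
      stop("reference_mass required for method 'reference_mass'",
           call. = FALSE)
    }
    ref <- lapply(timeseries$spectra, match_peak,
                  target_mass = reference_mass, tolerance = tolerance,
                  unit = unit, charge = charge)
    missing_at <- which(vapply(ref, is.null, logical(1)))
    if (length(missing_at) > 0L) {
      stop(sprintf(
        "reference mass %.4f not matched at time point(s): %s",
        reference_mass,
        paste(signif(timeseries$times[missing_at], 4), collapse = ", ")),
        call. = FALSE)
    }
    ints <- vapply(ref, function(r) r$intensity, numeric(1))
    scale <- stats::median(ints) / ints
  }
  spectra <- Map(function(s, f) peak_list(s$mz, s$intensity * f),
                 timeseries$spectra, scale)
  ms_timeseries(timeseries$times, spectra)
}

#' Extract the intensity trace of one mass across a time series
#'
#' @param timeseries An `ms_timeseries`.
#' @param target_mass Neutral mass (Da).
#' @param tolerance,unit,charge Matching parameters (see [match_peak()]).
#' @return Numeric vector over time points; `NA` marks time points where no
#'   peak matched (a missing observation, never imputed as 0).
#' @export
extract_trace <- function(timeseries, target_mass, tolerance = 0.3,
                          unit = "da", charge = 1L) {
  vapply(timeseries$spectra, function(s) {
    hit <- match_peak(s, target_mass, tolerance, unit, charge)
    if (is.null(hit)) NA_real_ else hit$intensity
  }, numeric(1))
}

#' Observed intensity matrix over the isobaric groups of a graph
#'
#' For every isobaric mass group of the graph the representative mass is
#' matched in every spectrum; unmatched points are `NA`. The per-group
#' standard deviation `sigma` over the observed points feeds the
#' variability score of the structure search.
#'
#' @param graph A `degradation_graph`.
#' @param timeseries An `ms_timeseries`.
#' @param tolerance,unit,charge Matching parameters.
#' @param group_tolerance Isobaric grouping tolerance (defaults to
#'   `tolerance`).
#' @return Object of class `intensity_matrix`: list with `values` (groups x
#'   times matrix, `NA` = missing), `mass` (representative masses), `times`,
#'   `sequences` (list of member sequences per group) and `sigma`.
#' @export
intensity_matrix <- function(graph, timeseries, tolerance = 0.3,
                             unit = "da", charge = 1L,
                             group_tolerance = tolerance) {
  groups <- isobaric_groups(graph, group_tolerance, unit)
  values <- t(vapply(groups$mass, function(m) {
    extract_trace(timeseries, m, tolerance, unit, charge)
  }, numeric(length(timeseries$times))))
  rownames(values) <- sprintf("m%.4f", groups$mass)
  sigma <- apply(values, 1L, function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2L) 0 else stats::sd(v)
  })
  structure(list(values = values, mass = groups$mass,
                 times = timeseries$times, sequences = groups$sequences,
                 sigma = unname(sigma), tolerance = tolerance),
            class = "intensity_matrix")
}

#' @export
print.intensity_matrix <- function(x, ...) {
  cat(sprintf("intensity matrix: %d mass group(s) x %d time point(s), %d missing\n",
              nrow(x$values), ncol(x$values), sum(is.na(x$values))))
  invisible(x)
}
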