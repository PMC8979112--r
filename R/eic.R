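#' Mass of a proton (u), for negative-mode adduct arithmetic
#'
#' `[M-H]-` m/z = monoisotopic mass - `PROTON_MASS`. Provided as a helper;
#' never applied automatically.
#' @export
PROTON_MASS <- 1.007276

#' Negative-mode deprotonated m/z
#'
#' @param monoisotopic_mass Neutral monoisotopic mass (u).
#' @return `[M-H]-` m/z.
#' @examples
#' mz_mh_neg(284.032088)  # rhein
#' @export
mz_mh_neg <- function(monoisotopic_mass) monoisotopic_mass - PROTON_MASS

#' Centroided mass spectrum
#'
#' @param retention_time Retention time in minutes (>= 0).
#' @param mz Centroid m/z values (> 0).
#' @param intensity Centroid intensities (>= 0), same length as `mz`.
#' @return An object of class `"centroid_spectrum"`.
#' @export
centroid_spectrum <- function(retention_time, mz, intensity) {
  if (retention_time < 0) stop("'retention_time' must be >= 0", call. = FALSE)
  if (length(mz) != length(intensity))
    stop("'mz' and 'intensity' lengths differ", call. = FALSE)
  if (any(mz <= 0)) stop("m/z must be > 0", call. = FALSE)
  if (any(intensity < 0)) stop("intensities must be >= 0", call. = FALSE)
  structure(list(retention_time = retention_time, mz = as.numeric(mz),
                 intensity = as.numeric(intensity)),
            class = "centroid_spectrum")
}

#' Extract a high-resolution ion chromatogram (EIC) at ppm tolerance
#'
#' For each spectrum, sums the intensities of all centroids whose m/z lies
#' in the closed interval `target_mz * (1 +/- ppm * 1e-6)`; spectra with no
#' centroid in the window contribute a zero, so the trace always has one
#' point per spectrum. Boundary ties are included (closed interval).
#'
#' @param spectra A non-empty list of [centroid_spectrum()] objects with
#'   strictly increasing retention times.
#' @param target_mz Target m/z (> 0).
#' @param ppm_tolerance Window half-width in parts per million (> 0);
#'   5 ppm is the conventional high-resolution setting.
#' @return An object of class `"eic_trace"`: `target_mz`, `ppm_tolerance`,
#'   `times` (minutes), `intensities`.
#' @export
extract_eic <- function(spectra, target_mz, ppm_tolerance = 5) {
  if (length(spectra) == 0L) stop("'spectra' is empty", call. = FALSE)
  stopifnot(all(vapply(spectra, inherits, TRUE, "centroid_spectrum")))
  if (target_mz <= 0) stop("'target_mz' must be > 0", call. = FALSE)
  if (ppm_tolerance <= 0) stop("'ppm_tolerance' must be > 0", call. = FALSE)
  lo <- target_mz * (1 - ppm_tolerance * 1e-6)
  hi <- target_mz * (1 + ppm_tolerance * 1e-6)
  times <- vapply(spectra, `[[`, 0, "retention_time")
  if (any(diff(times) <= 0))
    stop("spectra retention times must be strictly increasing", call. = FALSE)
  intensities <- vapply(spectra, function(s) {
    sel <- s$mz >= lo & s$mz <= hi
    if (any(sel)) sum(s$intensity[sel]) else 0
  }, 0)
  structure(list(target_mz = target_mz, ppm_tolerance = ppm_tolerance,
                 times = times, intensities = intensities),
            class = "eic_trace")
}

#' @export
print.eic_trace <- function(x, ...) {
  cat(sprintf("EIC m/z %.4f +/- %g ppm: %d spectra, max intensity %g\n",
              x$target_mz, x$ppm_tolerance, length(x$times),
              max(x$intensities)))
  invisible(x)
}

#' @export
plot.eic_trace <- function(x, ...) {
  graphics::plot(x$times, x$intensities, type = "l", xlab = "RT (min)",
                 ylab = "intensity",
                 main = sprintf("m/z %.4f (%g ppm)", x$target_mz,
                                x$ppm_tolerance), ...)
  invisible(x)
}

#' Integrate an EIC trace over a retention-time window
#'
#' Trapezoidal integration of the trace restricted to `rt_window`; no
#' smoothing, baseline model or peak detection — the window is an input, as
#' in targeted semi-quantification. An empty window yields area 0 with a
#' warning.
#'
#' @param trace An [extract_eic()] trace.
#' @param rt_window Length-2 numeric `c(start, end)` in minutes, within the
#'   trace span.
#' @param compound_id Identifier attached to the result.
#' @return An object of class `"peak_area"`: `compound_id`, `area`
#'   (counts x minutes), `rt_window`, `is_normalized = FALSE`.
#' @export
integrate_eic <- function(trace, rt_window, compound_id = "compound") {
  stopifnot(inherits(trace, "eic_trace"), length(rt_window) == 2L)
  if (rt_window[1] >= rt_window[2])
    stop("'rt_window' must be c(start, end) with start < end", call. = FALSE)
  span_t <- range(trace$times)
  if (rt_window[1] < span_t[1] || rt_window[2] > span_t[2])
    stop("'rt_window' extends beyond the trace span", call. = FALSE)
  sel <- trace$times >= rt_window[1] & trace$times <= rt_window[2]
  if (sum(sel) < 2L) {
    warning("fewer than 2 trace points in the RT window; area set to 0",
            call. = FALSE)
    area <- 0
  } else {
    t <- trace$times[sel]; y <- trace$intensities[sel]
    n <- length(t)
    area <- sum((y[-n] + y[-1]) / 2 * diff(t))
  }
  structure(list(compound_id = compound_id, area = area,
                 rt_window = rt_window, is_normalized = FALSE),
            class = "peak_area")
}

#' @export
print.peak_area <- function(x, ...) {
  cat(sprintf("Peak area '%s': %g%s (RT %.2f-%.2f min)\n", x$compound_id,
              x$area, if (x$is_normalized) " (IS-normalized)" else "",
              x$rt_window[1], x$rt_window[2]))
  invisible(x)
}

#' Normalize a peak area to the internal standard
#'
#' Dimensionless ratio `area / is_area`; normalization is optional and off
#' by default throughout the package, since semi-quantitative screens often
#' report raw areas.
#'
#' @param area A [integrate_eic()] peak area.
#' @param is_area The internal-standard peak area (a `peak_area` or a
#'   positive number).
#' @return A `peak_area` with `is_normalized = TRUE`.
#' @export
normalize_to_is <- function(area, is_area) {
  stopifnot(inherits(area, "peak_area"))
  isv <- if (inherits(is_area, "peak_area")) is_area$area else
    as.numeric(is_area)
  if (!is.finite(isv) || isv <= 0)
    stop("internal-standard area must be > 0", call. = FALSE)
  out <- area
  out$area <- area$area / isv
  out$is_normalized <- TRUE
  out
}

#' Read / write centroided spectra as delimited text
#'
#' Long-format CSV with header `spectrum, rt_min, mz, intensity`; one row
#' per centroid, `spectrum` indexing spectra in retention-time order.
#' Spectra with no centroids are represented by a single row with missing
#' `mz`/`intensity`.
#'
#' @param spectra A list of [centroid_spectrum()] objects.
#' @param path File path.
#' @return `write_spectra` returns `path` invisibly; `read_spectra` returns
#'   a list of `centroid_spectrum` objects.
#' @export
write_spectra <- function(spectra, path) {
  rows <- lapply(seq_along(spectra), function(i) {
    s <- spectra[[i]]
    if (length(s$mz) == 0L)
      data.frame(spectrum = i, rt_min = s$retention_time, mz = NA_real_,
                 intensity = NA_real_)
    else
      data.frame(spectrum = i, rt_min = s$retention_time, mz = s$mz,
                 intensity = s$intensity)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectra
#' @export
read_spectra <- function(path) {
  df <- utils::read.csv(path)
  needed <- c("spectrum", "rt_min", "mz", "intensity")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols))
    stop("spectra file is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  unname(lapply(split(df, df$spectrum), function(d) {
    keep <- !is.na(d$mz)
    centroid_spectrum(d$rt_min[1], d$mz[keep], d$intensity[keep])
  }))
}

#' Read centroided spectra from an mzML file
#'
#' Thin wrapper over `mzR` (must be installed); returns the same
#' `centroid_spectrum` list as [read_spectra()]. Retention times are
#' converted from seconds to minutes.
#'
#' @param path Path to a centroided mzML file.
#' @return A list of [centroid_spectrum()] objects.
#' @export
read_spectra_mzml <- function(path) {
  if (!requireNamespace("mzR", quietly = TRUE))
    stop("reading mzML requires the 'mzR' package", call. = FALSE)
  handle <- mzR::openMSfile(path)
  on.exit(mzR::close(handle))
  hdr <- mzR::header(handle)
  pk <- mzR::peaks(handle)
  if (is.matrix(pk)) pk <- list(pk)
  lapply(seq_along(pk), function(i)
    centroid_spectrum(hdr$retentionTime[i] / 60, pk[[i]][, 1], pk[[i]][, 2]))
}
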