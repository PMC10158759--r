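#' Negative first derivative of a melt trace
#'
#' Smooths the trace by local quadratic fitting ([smooth_quadratic()])
#' and differentiates it: central differences in the interior, one-sided
#' differences at the endpoints, negated so that melting transitions
#' appear as positive peaks in -dF/dT.
#'
#' @param trace fluorescence readings
#' @param temperatures strictly increasing temperatures in degrees
#'   Celsius, at least 5 points
#' @return numeric vector of -dF/dT, same length as `trace`
#' @export
derivative_curve <- function(trace, temperatures) {
  n <- length(trace)
  if (n < 5L)
    rdes_stop("INSUFFICIENT_DATA", "need at least 5 temperature points (got %d)", n)
  if (length(temperatures) != n)
    rdes_stop("FORMAT", "trace and temperature axis differ in length")
  if (any(diff(temperatures) <= 0))
    rdes_stop("FORMAT", "temperature axis must be strictly increasing")
  if (anyNA(trace)) rdes_stop("INSUFFICIENT_DATA", "trace contains missing readings")
  sm <- smooth_quadratic(trace)
  d <- numeric(n)
  d[1] <- (sm[2] - sm[1]) / (temperatures[2] - temperatures[1])
  d[n] <- (sm[n] - sm[n - 1]) / (temperatures[n] - temperatures[n - 1])
  idx <- 2:(n - 1)
  d[idx] <- (sm[idx + 1] - sm[idx - 1]) / (temperatures[idx + 1] - temperatures[idx - 1])
  -d
}

#' Call melting temperatures from a derivative curve
#'
#' Local maxima of -dF/dT with prominence at least `min_prominence`
#' (default: 5% of the curve's global maximum) are reported as melting
#' transitions, their positions refined by parabolic interpolation
#' through the three points around each peak. More than one peak flags
#' `MULTIPLE_PEAKS` (a primer-dimer indicator); no qualifying peak flags
#' `NO_PEAK`.
#'
#' @param deriv -dF/dT series from [derivative_curve()]
#' @param temperatures matching temperature axis
#' @param min_prominence absolute prominence cutoff; `NULL` for the 5%
#'   default
#' @param well_id optional label carried into the result
#' @return a `melt_call`: list with `well_id`, `tm_peaks` (data.frame
#'   `tm`, `height`, sorted by temperature), `n_peaks`, `flags`
#' @export
call_tm <- function(deriv, temperatures, min_prominence = NULL, well_id = NA_character_) {
  n <- length(deriv)
  if (length(temperatures) != n)
    rdes_stop("FORMAT", "derivative and temperature axis differ in length")
  gmax <- max(deriv)
  # numerically flat derivative (constant trace): no transition
  if (diff(range(deriv)) < 1e-10) {
    return(structure(list(well_id = well_id,
                          tm_peaks = data.frame(tm = numeric(0), height = numeric(0)),
                          n_peaks = 0L, flags = "NO_PEAK"),
                     class = "melt_call"))
  }
  if (is.null(min_prominence)) {
    min_prominence <- if (gmax > 0) 0.05 * gmax else Inf
  }
  peaks <- find_peaks(deriv)
  keep <- peaks[vapply(peaks, function(i)
    peak_prominence(deriv, i) >= min_prominence && deriv[i] > 0, logical(1))]
  tm <- numeric(0); ht <- numeric(0)
  for (i in keep) {
    pos <- temperatures[i]; h <- deriv[i]
    if (i > 1L && i < n) {
      den <- deriv[i - 1L] - 2 * deriv[i] + deriv[i + 1L]
      if (den < 0) {
        delta <- 0.5 * (deriv[i - 1L] - deriv[i + 1L]) / den
        # local temperature step (uniform grids in practice)
        step <- if (i < n) temperatures[i + 1L] - temperatures[i] else
          temperatures[i] - temperatures[i - 1L]
        pos <- temperatures[i] + delta * step
        h <- deriv[i] - 0.25 * (deriv[i - 1L] - deriv[i + 1L]) * delta
      }
    }
    tm <- c(tm, pos); ht <- c(ht, h)
  }
  ord <- order(tm)
  tm_peaks <- data.frame(tm = tm[ord], height = ht[ord])
  flags <- character(0)
  if (nrow(tm_peaks) == 0L) flags <- "NO_PEAK"
  if (nrow(tm_peaks) > 1L) flags <- "MULTIPLE_PEAKS"
  structure(list(well_id = well_id, tm_peaks = tm_peaks,
                 n_peaks = nrow(tm_peaks), flags = flags),
            class = "melt_call")
}

#' @export
print.melt_call <- function(x, ...) {
  cat(sprintf("<melt_call%s: %d peak(s)%s>\n",
              if (is.na(x$well_id)) "" else paste0(" ", x$well_id),
              x$n_peaks,
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]") else ""))
  if (x$n_peaks > 0)
    for (i in seq_len(x$n_peaks))
      cat(sprintf("  Tm %.2f C, height %.4g\n", x$tm_peaks$tm[i], x$tm_peaks$height[i]))
  invisible(x)
}

# strict local maxima (plateau-tolerant on the right)
find_peaks <- function(y) {
  n <- length(y)
  if (n < 3L) return(integer(0))
  which(vapply(2:(n - 1L), function(i) y[i] > y[i - 1L] && y[i] >= y[i + 1L],
               logical(1))) + 1L
}

# topographic prominence: height above the higher of the two valley
# floors separating the peak from higher terrain (or the series edge)
peak_prominence <- function(y, i) {
  n <- length(y)
  left <- if (i > 1L) {
    higher <- which(y[1:(i - 1L)] > y[i])
    lo <- if (length(higher)) max(higher) + 1L else 1L
    min(y[lo:(i - 1L)])
  } else y[i]
  right <- if (i < n) {
    higher <- which(y[(i + 1L):n] > y[i])
    hi <- if (length(higher)) i + min(higher) - 1L else n
    min(y[(i + 1L):hi])
  } else y[i]
  y[i] - max(left, right)
}

#' Call Tm peaks for every well of a melt plate
#'
#' @param plate a melt-variant [plate_table()] with complete traces
#' @param min_prominence_frac prominence cutoff as a fraction of each
#'   well's global derivative maximum
#' @return data.frame with one row per well: `well_id`, `sample`,
#'   `target`, `dye`, `n_peaks`, `tm` (position of the highest peak, NA
#'   when none), `height`, `flags`; the full `melt_call` objects are
#'   attached as attribute `calls`
#' @export
analyze_melt <- function(plate, min_prominence_frac = 0.05) {
  if (plate$variant != "melt")
    rdes_stop("INVALID_PLATE", "analyze_melt needs a melt-variant plate")
  calls <- vector("list", n_wells(plate))
  rows <- vector("list", n_wells(plate))
  for (i in seq_len(n_wells(plate))) {
    d <- derivative_curve(plate$traces[i, ], plate$axis)
    mp <- if (max(d) > 1e-10) min_prominence_frac * max(d) else Inf
    cl <- call_tm(d, plate$axis, mp, well_id = plate$wells$well_id[i])
    calls[[i]] <- cl
    top <- if (cl$n_peaks > 0) which.max(cl$tm_peaks$height) else NA_integer_
    rows[[i]] <- data.frame(
      well_id = plate$wells$well_id[i], sample = plate$wells$sample[i],
      target = plate$wells$target[i], dye = plate$wells$dye[i],
      n_peaks = cl$n_peaks,
      tm = if (is.na(top)) NA_real_ else cl$tm_peaks$tm[top],
      height = if (is.na(top)) NA_real_ else cl$tm_peaks$height[top],
      flags = paste(cl$flags, collapse = ";"),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "calls") <- calls
  out
}
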