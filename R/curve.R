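#' Estimate the pre-amplification baseline of a trace
#'
#' The baseline segment is the longest initial run of cycles showing no
#' systematic upward trend: the segment end is extended cycle by cycle
#' while the t-statistic of the slope of a straight-line fit stays below
#' 3. The baseline is the median of that segment, its noise the median
#' absolute deviation (scaled to be consistent with the standard
#' deviation under Gaussian noise), both robust to occasional early-cycle
#' spikes.
#'
#' @param trace numeric fluorescence readings, no `NA`
#' @param axis cycle numbers (defaults to `1..n`)
#' @return list with `baseline_f`, `noise_sd` and `segment_end` (last
#'   cycle index included in the baseline segment)
#' @export
fit_baseline <- function(trace, axis = seq_along(trace)) {
  if (length(trace) < 10L)
    rdes_stop("INSUFFICIENT_DATA", "need at least 10 cycles to estimate a baseline (got %d)",
              length(trace))
  if (anyNA(trace))
    rdes_stop("INSUFFICIENT_DATA", "trace contains missing readings")
  n <- length(trace)
  last_ok <- 4L
  e <- 5L
  while (e <= n) {
    x <- axis[1:e]; y <- trace[1:e]
    sxx <- sum((x - mean(x))^2)
    slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
    res <- y - mean(y) - slope * (x - mean(x))
    se <- sqrt(sum(res^2) / (e - 2) / sxx)
    tstat <- if (se > 0) slope / se else if (slope > 0) Inf else 0
    if (is.finite(tstat) && tstat > 3) break
    if (!is.finite(tstat) && slope > 0) break
    last_ok <- e
    e <- e + 1L
  }
  seg <- trace[1:last_ok]
  list(baseline_f = median(seg), noise_sd = mad(seg), segment_end = last_ok)
}

#' Fit the PCR efficiency from the exponential phase
#'
#' Window-of-linearity estimator with explicit saturation handling.
#' Amplification saturates like `F - b = P q / (q + 1)` (with `q` the
#' accumulated product and `P` the plateau height); the deskew transform
#' `y / (1 - y / P)` inverts that saturation and is exactly exponential
#' in the cycle number, reducing to the identity wherever `y << P`.
#'
#' The procedure: (1) a four-parameter sigmoid fit of the whole trace
#' supplies baseline, plateau and efficiency whenever the trace actually
#' plateaus and the fit converges to admissible values — for such traces
#' the sigmoid model is the deskewed log-linear fit using every
#' exponential-phase cycle, and its efficiency is reported; (2) among
#' all runs of 4, 5 or 6 consecutive cycles lying above the noise band
#' (`baseline + k * noise_sd`) and below half the observed amplitude,
#' the window maximizing the r-squared of the deskewed log-linear
#' regression is selected (ties, within 1e-9: longer window, then lower
#' starting cycle) and reported together with its r-squared; (3) for
#' traces with no plateau (pure exponentials — where the sigmoid is
#' unidentifiable) the efficiency is `10^slope` of that window
#' regression, after a closed-form baseline refinement: consecutive
#' differences of `b + A E^c` are geometric and free of `b`, so they
#' identify `A` and `E` and hence the offset; the refined offset is kept
#' only within 2 noise SDs of the robust initial estimate. On a
#' noiseless exponential the estimator recovers the amplification factor
#' to near machine precision.
#'
#' @param trace,axis as in [fit_baseline()]
#' @param baseline_f,noise_sd initial baseline estimate and noise spread
#' @param k noise-band multiplier (default 10; conservative standard
#'   practice)
#' @param refine logical; allow the closed-form baseline refinement on
#'   the exponential-only path
#' @return list with `window` (first and last cycle of the selected
#'   window), `efficiency_E`, `r2`, `baseline_f` (refined), and `flags`
#'   (subset of `NO_AMPLIFICATION`, `LOW_R2`, `EFFICIENCY_OUT_OF_RANGE`)
#' @export
fit_efficiency <- function(trace, axis = seq_along(trace), baseline_f, noise_sd,
                           k = 10, refine = TRUE) {
  y <- trace - baseline_f
  floor_ <- max(k * noise_sd, 1e-12 * max(abs(trace), 1))
  above <- which(y > floor_)
  no_amp <- list(window = c(NA_real_, NA_real_), efficiency_E = NA_real_,
                 r2 = NA_real_, baseline_f = baseline_f,
                 flags = "NO_AMPLIFICATION")
  if (length(above) < 4L) return(no_amp)
  ymax <- max(y)
  eligible <- y > floor_ & y < 0.5 * ymax

  wins <- list()
  for (L in c(4L, 5L, 6L)) {
    for (s in seq_len(length(y) - L + 1L)) {
      idx <- s:(s + L - 1L)
      if (all(eligible[idx])) wins[[length(wins) + 1L]] <- idx
    }
  }
  if (length(wins) == 0L) return(no_amp)

  sig <- fit_sigmoid(trace, axis)
  b_cand <- if (!is.null(sig)) sig$b else baseline_f
  p_cand <- if (!is.null(sig)) sig$P else Inf

  # deskewed log-linear fit of a window given baseline and plateau
  win_fit <- function(idx, b, p) {
    yy <- trace[idx] - b
    if (any(yy <= 0) || any(yy >= p)) return(list(slope = NA_real_, r2 = NA_real_))
    loglin_fit(axis[idx], yy / (1 - yy / p))
  }
  win_r2 <- function(idx, b, p) {
    f <- win_fit(idx, b, p)
    if (is.na(f$r2)) -Inf else f$r2
  }

  score <- vapply(wins, function(idx) win_r2(idx, b_cand, p_cand), numeric(1))
  best <- max(score, na.rm = TRUE)
  if (!is.finite(best)) return(no_amp)
  tied <- which(!is.na(score) & score >= best - 1e-9)
  lens <- vapply(wins[tied], length, integer(1))
  starts <- vapply(wins[tied], function(i) i[1], integer(1))
  pick <- tied[order(-lens, starts)][1]
  idx <- wins[[pick]]

  b <- b_cand
  if (is.null(sig) && refine) {
    d <- diff(trace[idx])
    if (all(d > 0)) {
      df <- loglin_fit(axis[idx][-length(idx)], d)
      if (!is.na(df$slope) && df$slope > 0) {
        e_d <- 10^df$slope
        a_d <- 10^df$intercept / (e_d - 1)
        b_new <- mean(trace[idx] - a_d * e_d^axis[idx])
        tol_b <- max(2 * noise_sd, 1e-9 * max(abs(trace), 1))
        if (is.finite(b_new) && abs(b_new - baseline_f) <= tol_b &&
            b_new < min(trace[idx])) b <- b_new
      }
    }
  }
  fitv <- win_fit(idx, b, p_cand)
  E <- if (!is.null(sig)) sig$E else 10^fitv$slope
  flags <- character(0)
  if (is.na(fitv$r2) || fitv$r2 < 0.99) flags <- c(flags, "LOW_R2")
  if (is.na(E) || !(E > 1.6 && E <= 2.2)) flags <- c(flags, "EFFICIENCY_OUT_OF_RANGE")
  list(window = c(axis[idx[1]], axis[idx[length(idx)]]),
       efficiency_E = E, r2 = fitv$r2, baseline_f = b, flags = flags)
}

# Four-parameter sigmoid fit F = A + (B - A)/(1 + exp((xmid - c)/scal));
# in amplification terms baseline A, plateau height B - A, efficiency
# exp(1/scal). Returns NULL when the fit fails or the trace carries no
# usable plateau (xmid too close to the last cycle, inadmissible E).
fit_sigmoid <- function(trace, axis) {
  fit <- tryCatch(
    suppressWarnings(stats::nls(trace ~ SSfpl(axis, A, B, xmid, scal),
                                control = stats::nls.control(warnOnly = FALSE))),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  co <- coef(fit)
  if (!all(is.finite(co))) return(NULL)
  if (co[["scal"]] <= 0) return(NULL)
  e_s <- exp(1 / co[["scal"]])
  if (e_s <= 1.05 || e_s > 2.5) return(NULL)
  if (co[["B"]] <= co[["A"]]) return(NULL)
  if (co[["xmid"]] > max(axis) - 2 || co[["xmid"]] < min(axis)) return(NULL)
  list(b = co[["A"]], P = co[["B"]] - co[["A"]], E = e_s, xmid = co[["xmid"]])
}

loglin_fit <- function(x, y) {
  if (any(y <= 0)) return(list(slope = NA_real_, intercept = NA_real_, r2 = NA_real_))
  ly <- log10(y)
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (ly - mean(ly))) / sxx
  sst <- sum((ly - mean(ly))^2)
  res <- ly - mean(ly) - slope * (x - mean(x))
  r2 <- if (sst > 0) 1 - sum(res^2) / sst else NA_real_
  list(slope = slope, intercept = mean(ly) - slope * mean(x), r2 = r2)
}

loglin_r2 <- function(x, y) {
  f <- loglin_fit(x, y)
  if (is.na(f$r2)) -Inf else f$r2
}

#' Define a quantification-threshold policy
#'
#' @param mode `"fraction_of_plateau"` (threshold = `value` times the
#'   plateau height; at plate level the median plateau across amplifying
#'   wells, giving one plate-wide standard), `"fixed"` (threshold =
#'   `value`, in fluorescence units above baseline), or
#'   `"sd_above_baseline"` (threshold = `value` times the baseline noise
#'   SD).
#' @param value threshold fluorescence or multiplier; default 0.1 with
#'   `fraction_of_plateau`
#' @return a `threshold_policy` object
#' @export
threshold_policy <- function(mode = c("fraction_of_plateau", "fixed", "sd_above_baseline"),
                             value = NULL) {
  mode <- match.arg(mode)
  if (is.null(value)) value <- switch(mode, fraction_of_plateau = 0.1,
                                      sd_above_baseline = 10, fixed = NULL)
  if (is.null(value) || !is.finite(value) || value <= 0)
    rdes_stop("CONFIG", "threshold policy needs a positive value")
  structure(list(mode = mode, value = value), class = "threshold_policy")
}

resolve_nq <- function(policy, y_max, noise_sd) {
  switch(policy$mode,
         fixed = policy$value,
         fraction_of_plateau = policy$value * y_max,
         sd_above_baseline = policy$value * noise_sd)
}

#' Determine the quantification cycle of a trace
#'
#' `cq_threshold` is the fractional cycle at which the
#' baseline-subtracted fluorescence first crosses the threshold Nq,
#' located by log-linear interpolation between the bracketing cycles
#' (exact for exponential growth). `cq_sdm` is the second-derivative
#' maximum of the smoothed trace, refined by parabolic interpolation — a
#' threshold-free alternative.
#'
#' @param trace,axis as in [fit_baseline()]
#' @param baseline_f baseline to subtract (use the refined value from
#'   [fit_efficiency()] for best accuracy)
#' @param policy a [threshold_policy()]; with `fraction_of_plateau` the
#'   plateau is this trace's own maximum unless a plate-level threshold
#'   is supplied via a `fixed` policy
#' @param noise_sd needed for the `sd_above_baseline` mode
#' @return list with `cq_threshold`, `cq_sdm` and `nq` (the resolved
#'   threshold, in baseline-subtracted fluorescence units)
#' @export
call_cq <- function(trace, axis = seq_along(trace), baseline_f,
                    policy = threshold_policy(), noise_sd = NULL) {
  y <- trace - baseline_f
  nq <- resolve_nq(policy, max(y), noise_sd %||% 0)
  if (!is.finite(nq) || nq <= 0)
    rdes_stop("CONFIG", "resolved threshold is not positive")
  if (nq >= max(y))
    rdes_stop("NO_CROSSING", "threshold %.4g at or above the trace maximum %.4g",
              nq, max(y))
  i <- which(y >= nq)[1]
  cq <- if (i == 1L) axis[1L]
  else if (y[i - 1L] > 0) {
    axis[i - 1L] + (log(nq) - log(y[i - 1L])) / (log(y[i]) - log(y[i - 1L])) *
      (axis[i] - axis[i - 1L])
  } else {
    axis[i - 1L] + (nq - y[i - 1L]) / (y[i] - y[i - 1L]) * (axis[i] - axis[i - 1L])
  }
  list(cq_threshold = cq, cq_sdm = sdm_cycle(trace, axis), nq = nq)
}

# second-derivative-maximum cycle of the smoothed trace, parabolic refinement
sdm_cycle <- function(trace, axis = seq_along(trace)) {
  n <- length(trace)
  if (n < 7L) return(NA_real_)
  sm <- smooth_quadratic(trace)
  d2 <- sm[3:n] - 2 * sm[2:(n - 1)] + sm[1:(n - 2)]  # centered at 2..(n-1)
  if (all(abs(d2) < 1e-12)) return(NA_real_)
  j <- which.max(d2)
  pos <- axis[j + 1L]
  if (j > 1L && j < length(d2)) {
    den <- d2[j - 1L] - 2 * d2[j] + d2[j + 1L]
    if (den < 0) pos <- pos + 0.5 * (d2[j - 1L] - d2[j + 1L]) / den
  }
  pos
}

#' Smooth a series by local quadratic fitting
#'
#' Savitzky-Golay filter, polynomial order 2, window 5: preserves the
#' position of peaks and inflections of smooth curves (to well under 0.1
#' cycle or degree on noiseless sigmoids) while attenuating
#' point-to-point noise. Series shorter than the window are returned
#' unchanged.
#'
#' @param y numeric vector
#' @return smoothed numeric vector of the same length
#' @export
smooth_quadratic <- function(y) {
  if (length(y) < 5L) return(y)
  as.numeric(signal::sgolayfilt(y, p = 2, n = 5))
}

#' Efficiency-corrected initial target quantity
#'
#' `N0 = Nq / E^Cq`: the fluorescence threshold projected back `Cq`
#' cycles at per-cycle amplification factor `E`.
#'
#' @param efficiency_E amplification factor per cycle, must exceed 1
#' @param cq quantification cycle
#' @param nq threshold fluorescence (baseline-subtracted, a.u.)
#' @return initial quantity in the same arbitrary units as `nq`
#' @export
estimate_n0 <- function(efficiency_E, cq, nq) {
  if (any(!is.finite(efficiency_E)) || any(efficiency_E <= 1))
    rdes_stop("DOMAIN", "efficiency must exceed 1 to project back to an initial quantity")
  nq / efficiency_E^cq
}

#' Fit one amplification trace end to end
#'
#' Chains [fit_baseline()], [fit_efficiency()] (which refines the
#' baseline) and [call_cq()] (using the refined baseline), then derives
#' `n0` via [estimate_n0()].
#'
#' @inheritParams fit_efficiency
#' @param policy a [threshold_policy()]
#' @return list: `baseline_f`, `noise_sd`, `window`, `efficiency_E`,
#'   `r2`, `cq_threshold`, `cq_sdm`, `nq`, `n0`, `flags`
#' @export
fit_curve <- function(trace, axis = seq_along(trace),
                      policy = threshold_policy(), k = 10) {
  bl <- fit_baseline(trace, axis)
  ef <- fit_efficiency(trace, axis, bl$baseline_f, bl$noise_sd, k = k)
  out <- list(baseline_f = ef$baseline_f, noise_sd = bl$noise_sd,
              window = ef$window, efficiency_E = ef$efficiency_E, r2 = ef$r2,
              cq_threshold = NA_real_, cq_sdm = NA_real_, nq = NA_real_,
              n0 = NA_real_, flags = ef$flags)
  if ("NO_AMPLIFICATION" %in% ef$flags) return(out)
  cq <- tryCatch(call_cq(trace, axis, ef$baseline_f, policy, bl$noise_sd),
                 rdes_no_crossing = function(e) NULL)
  if (is.null(cq)) {
    out$flags <- c(out$flags, "NO_CROSSING")
    return(out)
  }
  out$cq_threshold <- cq$cq_threshold
  out$cq_sdm <- cq$cq_sdm
  out$nq <- cq$nq
  if (!is.na(out$efficiency_E) && out$efficiency_E > 1)
    out$n0 <- estimate_n0(out$efficiency_E, cq$cq_threshold, cq$nq)
  out
}

#' Recompute curve fits for every well of a plate
#'
#' Runs the full curve engine on each well. With the default
#' `fraction_of_plateau` policy the threshold is set once per plate, at
#' `value` times the median plateau height across wells with detected
#' amplification, so every well is quantified against the same standard.
#'
#' @param plate an amplification-variant [plate_table()] with complete
#'   traces
#' @param policy a [threshold_policy()]
#' @param k noise-band multiplier passed to [fit_efficiency()]
#' @return data.frame (class `curve_fits`) with one row per well record:
#'   annotations, `reported_cq`, `baseline_f`, `noise_sd`, `win_start`,
#'   `win_end`, `efficiency_E`, `r2`, `cq_threshold`, `cq_sdm`, `n0` and
#'   `flags` (semicolon-joined). The plate-level threshold is attached as
#'   attribute `nq`.
#' @export
analyze_plate <- function(plate, policy = threshold_policy(), k = 10) {
  if (plate$variant != "amplification")
    rdes_stop("INVALID_PLATE", "analyze_plate needs an amplification-variant plate")
  n <- n_wells(plate)
  bls <- vector("list", n); efs <- vector("list", n)
  for (i in seq_len(n)) {
    bls[[i]] <- fit_baseline(plate$traces[i, ], plate$axis)
    efs[[i]] <- fit_efficiency(plate$traces[i, ], plate$axis,
                               bls[[i]]$baseline_f, bls[[i]]$noise_sd, k = k)
  }
  amp_ok <- !vapply(efs, function(e) "NO_AMPLIFICATION" %in% e$flags, logical(1))
  plateaus <- vapply(seq_len(n), function(i)
    max(plate$traces[i, ] - efs[[i]]$baseline_f), numeric(1))
  nq <- switch(policy$mode,
               fixed = policy$value,
               fraction_of_plateau = {
                 if (!any(amp_ok))
                   rdes_stop("NO_AMPLIFICATION", "no well shows amplification; cannot set a plate threshold")
                 policy$value * median(plateaus[amp_ok])
               },
               sd_above_baseline =
                 policy$value * median(vapply(bls, `[[`, numeric(1), "noise_sd")))
  fixed <- threshold_policy("fixed", nq)

  rows <- lapply(seq_len(n), function(i) {
    ef <- efs[[i]]; bl <- bls[[i]]
    cqv <- NA_real_; sdm <- NA_real_; n0 <- NA_real_
    flags <- ef$flags
    if (amp_ok[i]) {
      cq <- tryCatch(call_cq(plate$traces[i, ], plate$axis, ef$baseline_f, fixed),
                     rdes_no_crossing = function(e) NULL)
      if (is.null(cq)) flags <- c(flags, "NO_CROSSING")
      else {
        cqv <- cq$cq_threshold; sdm <- cq$cq_sdm
        if (!is.na(ef$efficiency_E) && ef$efficiency_E > 1)
          n0 <- estimate_n0(ef$efficiency_E, cqv, nq)
      }
    }
    data.frame(plate$wells[i, , drop = FALSE],
               baseline_f = ef$baseline_f, noise_sd = bl$noise_sd,
               win_start = ef$window[1], win_end = ef$window[2],
               efficiency_E = ef$efficiency_E, r2 = ef$r2,
               cq_threshold = cqv, cq_sdm = sdm, n0 = n0,
               flags = paste(flags, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "nq") <- nq
  attr(out, "policy") <- policy
  class(out) <- c("curve_fits", class(out))
  out
}

#' Audit the reported Cq column against the raw traces
#'
#' The integrity check that raw-data disclosure enables: every well's
#' reported Cq is compared with the Cq recomputed from its trace, and
#' no-template controls are checked for amplification.
#'
#' @param plate amplification plate with complete traces
#' @param policy a [threshold_policy()]
#' @param tolerance cycles; reported-vs-recomputed discrepancies beyond
#'   it raise a `CQ_MISMATCH` warning (default 1.0 — generous, since the
#'   instrument's thresholding is unknown)
#' @return a `validation_report` whose warnings carry `CQ_MISMATCH` and
#'   `NTC_AMPLIFICATION` findings; the underlying `curve_fits` are
#'   attached as attribute `fits`
#' @export
audit_reported_cq <- function(plate, policy = threshold_policy(), tolerance = 1.0) {
  fits <- analyze_plate(plate, policy)
  finding <- function(code, well_id, message)
    data.frame(code = code, well_id = well_id, message = message,
               stringsAsFactors = FALSE)
  warnings <- finding(character(0), character(0), character(0))
  for (i in seq_len(nrow(fits))) {
    rep_cq <- fits$reported_cq[i]
    rec_cq <- fits$cq_threshold[i]
    amp <- !grepl("NO_AMPLIFICATION", fits$flags[i])
    if (!is.na(rep_cq)) {
      if (!amp || is.na(rec_cq)) {
        warnings <- rbind(warnings, finding(
          "CQ_MISMATCH", fits$well_id[i],
          sprintf("reported Cq %.4g but no Cq could be recomputed from the trace", rep_cq)))
      } else if (abs(rep_cq - rec_cq) > tolerance) {
        warnings <- rbind(warnings, finding(
          "CQ_MISMATCH", fits$well_id[i],
          sprintf("reported Cq %.4g vs recomputed %.4g (|diff| > %.3g)",
                  rep_cq, rec_cq, tolerance)))
      }
    }
    if (fits$sample_type[i] == "ntc" && amp)
      warnings <- rbind(warnings, finding(
        "NTC_AMPLIFICATION", fits$well_id[i],
        "no-template control shows amplification: possible contamination"))
  }
  base <- validate_plate(plate)
  out <- structure(list(errors = base$errors,
                        warnings = rbind(base$warnings, warnings),
                        suggestions = base$suggestions,
                        counts = base$counts),
                   class = "validation_report")
  attr(out, "fits") <- fits
  out
}
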