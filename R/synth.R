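#' Simulate an amplification plate with recorded ground truth
#'
#' The noiseless signal follows a saturating (logistic) amplification
#' model: with per-well initial quantity `n0` (arbitrary quantity units),
#' per-cycle amplification factor `E` and half-saturation constant fixed
#' at 1 quantity unit, the accumulated product at cycle `c` is
#' `q_c = n0 * E^c` and the fluorescence is
#' `F_c = baseline + plateau * q_c / (q_c + 1)`.
#' Early on (`q_c << 1`) this is exactly exponential, so closed-form
#' relations between `E`, `Cq` and `N0` hold in the fitting window;
#' late cycles saturate at `baseline + plateau` like real traces.
#' Noise is multiplicative Gaussian on the noiseless signal (coefficient
#' of variation `cv`) plus additive Gaussian baseline noise; readings are
#' rounded to 4 decimals, as instrument exports are, which also makes the
#' canonical CSV byte-deterministic.
#'
#' The emitted Cq column is the generator's own threshold crossing at
#' `threshold_frac * plateau` (above baseline), solved in closed form on
#' the noiseless curve; wells whose crossing falls beyond the last cycle
#' get an empty Cq.
#'
#' @param n_samples,n_targets grid dimensions; sample i runs target j in
#'   one well, laid out row-major on an 8x12 (or 16x24) plate
#' @param n_cycles at least 20 (default 45)
#' @param e_true per-target efficiency: vector of length `n_targets`, or
#'   `NULL` to draw uniformly from `e_range`
#' @param e_range range efficiencies are drawn from
#' @param n0_true per-well initial quantity: vector of length
#'   `n_samples * n_targets` (well order), or `NULL` to draw
#'   log-uniformly from `n0_range`
#' @param n0_range range (quantity units) initial quantities are drawn
#'   from
#' @param baseline_range per-well baseline fluorescence range (a.u.)
#' @param plateau plateau height above baseline (a.u.)
#' @param cv coefficient of variation of the multiplicative noise
#'   (default 0.01 = 1%)
#' @param baseline_noise_sd additive baseline noise SD (a.u.)
#' @param threshold_frac generator threshold as a fraction of `plateau`
#' @param n_ref_targets how many targets (the last ones) are annotated as
#'   reference genes
#' @param seed RNG seed; the same seed always yields byte-identical
#'   plates
#' @return list with `plate` (a valid [plate_table()]) and `truth`
#'   (`SimTruth`: per-well data.frame `wells` with `n0_true`, `e_true`,
#'   `baseline_true`, `plateau_true`, `cq_true`, plus the global
#'   parameters including the generator threshold `nq` in
#'   baseline-subtracted fluorescence units)
#' @export
simulate_amplification <- function(n_samples = 8, n_targets = 12, n_cycles = 45,
                                   e_true = NULL, e_range = c(1.8, 2.0),
                                   n0_true = NULL, n0_range = c(1e-10, 1e-6),
                                   baseline_range = c(1.2, 1.6), plateau = 10,
                                   cv = 0.01, baseline_noise_sd = 0.01,
                                   threshold_frac = 0.1, n_ref_targets = 1,
                                   seed = 1) {
  if (n_cycles < 20) rdes_stop("CONFIG", "n_cycles must be at least 20 (got %d)", n_cycles)
  if (cv < 0 || baseline_noise_sd < 0) rdes_stop("CONFIG", "noise parameters must be >= 0")
  if (threshold_frac <= 0 || threshold_frac >= 1)
    rdes_stop("CONFIG", "threshold_frac must lie in (0, 1)")
  n <- n_samples * n_targets
  geom <- if (n <= 96) c(8L, 12L) else c(16L, 24L)
  if (n > geom[1] * geom[2])
    rdes_stop("CONFIG", "%d wells exceed a %dx%d plate", n, geom[1], geom[2])
  set.seed(seed)

  if (is.null(e_true)) e_true <- stats::runif(n_targets, e_range[1], e_range[2])
  if (length(e_true) != n_targets)
    rdes_stop("CONFIG", "e_true must have one value per target")
  if (any(e_true <= 1 | e_true > 2.2))
    rdes_stop("CONFIG", "e_true values must lie in (1, 2.2]")
  if (is.null(n0_true))
    n0_true <- 10^stats::runif(n, log10(n0_range[1]), log10(n0_range[2]))
  n0_true <- rep_len(n0_true, n)
  if (any(n0_true <= 0)) rdes_stop("CONFIG", "n0_true must be positive")
  baseline_true <- stats::runif(n, baseline_range[1], baseline_range[2])

  si <- rep(seq_len(n_samples), each = n_targets)
  ti <- rep(seq_len(n_targets), times = n_samples)
  pos <- seq_len(n)
  well_id <- paste0(LETTERS[(pos - 1L) %/% geom[2] + 1L], (pos - 1L) %% geom[2] + 1L)
  ttype <- ifelse(ti > n_targets - n_ref_targets, "ref", "toi")

  nq <- threshold_frac * plateau
  qstar <- nq / (plateau - nq)           # accumulated product at threshold
  e_w <- e_true[ti]
  cq_true <- log(qstar / n0_true) / log(e_w)
  cq_emit <- ifelse(cq_true >= 1 & cq_true <= n_cycles, cq_true, NA_real_)

  cyc <- seq_len(n_cycles)
  traces <- matrix(0, nrow = n, ncol = n_cycles)
  for (i in seq_len(n)) {
    q <- n0_true[i] * e_w[i]^cyc
    f <- baseline_true[i] + plateau * q / (q + 1)
    f <- f * (1 + stats::rnorm(n_cycles, 0, cv)) + stats::rnorm(n_cycles, 0, baseline_noise_sd)
    traces[i, ] <- round(f, 4)
  }

  wells <- data.frame(
    well_id = well_id,
    sample = sprintf("Sample_%02d", si),
    sample_type = "unkn",
    target = sprintf("Gene_%02d", ti),
    target_type = ttype,
    dye = "SYBR",
    reported_cq = cq_emit,
    stringsAsFactors = FALSE)
  plate <- plate_table(wells, traces, cyc, "amplification",
                       meta = list(source = "simulate_amplification", seed = seed))
  truth <- list(
    wells = data.frame(well_id = well_id, sample = wells$sample,
                       target = wells$target, n0_true = n0_true, e_true = e_w,
                       baseline_true = baseline_true, plateau_true = plateau,
                       cq_true = cq_true,
                       # initial signal in fluorescence units under the
                       # exponential back-projection nq / E^cq
                       n0_signal = nq / e_w^cq_true,
                       stringsAsFactors = FALSE),
    seed = seed, n_cycles = n_cycles, nq = nq, threshold_frac = threshold_frac,
    cv = cv, baseline_noise_sd = baseline_noise_sd)
  list(plate = plate, truth = truth)
}

#' Simulate a melt plate with recorded ground truth
#'
#' Each well's fluorescence is a sum of logistic melting transitions,
#' `F(T) = baseline + sum_i A_i / (1 + exp((T - Tm_i) / w_i))`, plus
#' additive Gaussian noise; -dF/dT then peaks at each `Tm_i`. Readings
#' are rounded to 4 decimals.
#'
#' @param n_wells number of wells (laid out A1, A2, ...)
#' @param tm_true list of numeric vectors (one per well) or a single
#'   vector recycled to all wells: transition temperatures in degrees
#'   Celsius
#' @param amplitude,width transition amplitude (a.u.) and width (degrees;
#'   recycled across transitions)
#' @param temp_range,temp_step temperature grid; must cover every
#'   transition by at least 5 degrees on each side
#' @param baseline residual fluorescence after full melting
#' @param noise_sd additive noise SD
#' @param seed RNG seed
#' @return list with `plate` (melt-variant [plate_table()]; the reported
#'   Tm column carries the true Tm of the largest transition) and `truth`
#' @export
simulate_melt <- function(n_wells = 8, tm_true = 82, amplitude = 5, width = 0.8,
                          temp_range = c(60, 95), temp_step = 0.5,
                          baseline = 1, noise_sd = 0.01, seed = 1) {
  if (noise_sd < 0) rdes_stop("CONFIG", "noise_sd must be >= 0")
  if (!is.list(tm_true)) tm_true <- rep(list(as.numeric(tm_true)), n_wells)
  if (length(tm_true) != n_wells)
    rdes_stop("CONFIG", "tm_true must give one transition set per well")
  all_tm <- unlist(tm_true)
  if (length(all_tm) &&
      (min(all_tm) - 5 < temp_range[1] || max(all_tm) + 5 > temp_range[2]))
    rdes_stop("CONFIG", "temperature range must cover every Tm by at least 5 degrees")
  set.seed(seed)
  temps <- seq(temp_range[1], temp_range[2], by = temp_step)
  geom_cols <- 12L
  well_id <- paste0(LETTERS[(seq_len(n_wells) - 1L) %/% geom_cols + 1L],
                    (seq_len(n_wells) - 1L) %% geom_cols + 1L)
  traces <- matrix(0, nrow = n_wells, ncol = length(temps))
  rep_tm <- rep(NA_real_, n_wells)
  for (i in seq_len(n_wells)) {
    tms <- tm_true[[i]]
    amps <- rep_len(amplitude, length(tms))
    ws <- rep_len(width, length(tms))
    f <- rep(baseline, length(temps))
    for (j in seq_along(tms))
      f <- f + amps[j] / (1 + exp((temps - tms[j]) / ws[j]))
    f <- f + stats::rnorm(length(temps), 0, noise_sd)
    traces[i, ] <- round(f, 4)
    if (length(tms) && any(amps > 0)) rep_tm[i] <- tms[which.max(amps)]
  }
  wells <- data.frame(
    well_id = well_id, sample = sprintf("Sample_%02d", seq_len(n_wells)),
    sample_type = "unkn", target = "Gene_01", target_type = "toi", dye = "SYBR",
    reported_cq = rep_tm, stringsAsFactors = FALSE)
  plate <- plate_table(wells, traces, temps, "melt",
                       meta = list(source = "simulate_melt", seed = seed))
  truth <- list(wells = data.frame(well_id = well_id, stringsAsFactors = FALSE),
                tm_true = tm_true, amplitude = amplitude, width = width,
                baseline = baseline, noise_sd = noise_sd, seed = seed)
  list(plate = plate, truth = truth)
}

#' Fill elided trace readings with a deterministic model curve
#'
#' Published RDES excerpts elide interior cycles (printed tables keep the
#' first and last few). For end-to-end demonstrations those gaps can be
#' filled synthetically: per well, a saturating amplification curve is
#' anchored to the printed early cycles (baseline = their mean), the
#' reported Cq (placed at `threshold_frac` of the plateau, assuming
#' efficiency `e_assumed`) and the last printed reading (fixing the
#' plateau). Only `NA` readings are replaced; printed cells are kept
#' verbatim. The result is synthetic in-fill for plumbing tests, not
#' reconstructed data.
#'
#' @param plate amplification plate with `NA` gaps in its traces
#' @param e_assumed efficiency used for the in-fill model
#' @param threshold_frac fraction of plateau the reported Cq is assumed
#'   to correspond to
#' @return a plate with complete traces; `meta$infilled = TRUE`
#' @export
infill_elided <- function(plate, e_assumed = 1.9, threshold_frac = 0.1) {
  if (plate$variant != "amplification")
    rdes_stop("INVALID_PLATE", "infill_elided needs an amplification plate")
  tr <- plate$traces
  for (i in seq_len(nrow(tr))) {
    miss <- is.na(tr[i, ])
    if (!any(miss)) next
    obs <- which(!miss)
    lead <- obs[obs < min(which(miss))]
    if (length(lead) == 0L)
      rdes_stop("INSUFFICIENT_DATA", "well %s has no printed early cycles to anchor a baseline",
                plate$wells$well_id[i])
    b <- mean(tr[i, lead])
    cqv <- plate$wells$reported_cq[i]
    last <- max(obs)
    f_last <- tr[i, last]
    if (is.na(cqv) || f_last <= b) {
      tr[i, miss] <- b                     # no amplification: flat baseline
      next
    }
    # q at the reported Cq equals thr/(1-thr) of the plateau fraction
    qstar <- threshold_frac / (1 - threshold_frac)
    n0 <- qstar * e_assumed^(-cqv)
    q_last <- n0 * e_assumed^plate$axis[last]
    p <- (f_last - b) * (q_last + 1) / q_last
    q <- n0 * e_assumed^plate$axis[miss]
    tr[i, miss] <- round(b + p * q / (q + 1), 4)
  }
  plate$traces <- tr
  plate$meta$infilled <- TRUE
  plate$meta$infill_e_assumed <- e_assumed
  plate
}
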