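#' Aggregate per-well efficiencies into assay-specific values
#'
#' The efficiency of an assay (target) is estimated once per plate as the
#' mean of the per-well window-of-linearity efficiencies, excluding wells
#' flagged `NO_AMPLIFICATION`, `LOW_R2` or `EFFICIENCY_OUT_OF_RANGE`.
#' At least two usable wells per target are required: a single well gives
#' no handle on assay-level spread.
#'
#' @param fits a `curve_fits` data.frame from [analyze_plate()]
#' @return named numeric vector, target -> efficiency
#' @export
per_target_efficiency <- function(fits) {
  usable <- !grepl("NO_AMPLIFICATION|LOW_R2|EFFICIENCY_OUT_OF_RANGE", fits$flags) &
    !is.na(fits$efficiency_E)
  out <- numeric(0)
  for (tg in unique(fits$target)) {
    sel <- usable & fits$target == tg
    if (sum(sel) < 2L)
      rdes_stop("MISSING_EFFICIENCY",
                "target '%s' has %d usable well(s); need at least 2 to estimate its efficiency",
                tg, sum(sel))
    out[tg] <- mean(fits$efficiency_E[sel])
  }
  out
}

#' Efficiency-corrected normalized expression
#'
#' For each sample, the target quantity of every target of interest
#' (`N0 = Nq / E_target^Cq`, with the assay-specific efficiency) is
#' divided by the geometric mean of the reference targets' quantities —
#' geometric because quantities are ratio-scale, and so that the
#' aggregation is invariant to the order of the references. Replicate
#' wells of the same (sample, target) are combined by geometric mean of
#' their quantities. Fold-differences are expressed against a calibrator
#' sample (default: the first sample in plate order).
#'
#' @param fits a `curve_fits` data.frame from [analyze_plate()]
#' @param efficiencies named target -> E vector; defaults to
#'   [per_target_efficiency()]
#' @param reference_targets character vector of reference assays;
#'   defaults to the targets annotated `target_type = "ref"`
#' @param nq threshold fluorescence used for the fits; defaults to the
#'   `nq` attribute of `fits`
#' @param calibrator sample name the fold column is expressed against
#' @return data.frame with `sample`, `target`, `n0`, `normalized`,
#'   `fold_vs_calibrator`, `efficiency_used`; samples that could not be
#'   normalized are listed in the `errors` attribute (data.frame
#'   `sample`, `message`) and omitted from the result
#' @export
normalized_expression <- function(fits, efficiencies = NULL,
                                  reference_targets = NULL,
                                  nq = attr(fits, "nq"), calibrator = NULL) {
  if (is.null(nq))
    rdes_stop("CONFIG", "no threshold: pass nq or use fits from analyze_plate()")
  if (is.null(efficiencies)) efficiencies <- per_target_efficiency(fits)
  if (is.null(reference_targets))
    reference_targets <- unique(fits$target[fits$target_type == "ref"])
  if (length(reference_targets) == 0L)
    rdes_stop("CONFIG", "no reference targets (target_type = 'ref') found or given")
  miss_e <- setdiff(unique(fits$target), names(efficiencies))
  if (length(miss_e))
    rdes_stop("MISSING_EFFICIENCY", "no efficiency for target(s): %s",
              paste(miss_e, collapse = ", "))

  usable <- !grepl("NO_AMPLIFICATION|NO_CROSSING", fits$flags) & !is.na(fits$cq_threshold)
  # per (sample, target) quantity: geometric mean over replicate wells
  q_of <- function(sample, target) {
    sel <- usable & fits$sample == sample & fits$target == target
    if (!any(sel)) return(NA_real_)
    n0s <- nq / efficiencies[[target]]^fits$cq_threshold[sel]
    exp(mean(log(n0s)))
  }

  samples <- unique(fits$sample)
  if (is.null(calibrator)) calibrator <- samples[1]
  if (!calibrator %in% samples)
    rdes_stop("CONFIG", "calibrator sample '%s' not present", calibrator)
  tois <- setdiff(unique(fits$target), reference_targets)

  err <- data.frame(sample = character(0), message = character(0),
                    stringsAsFactors = FALSE)
  rows <- list()
  ref_agg <- setNames(rep(NA_real_, length(samples)), samples)
  for (s in samples) {
    refq <- vapply(reference_targets, function(r) q_of(s, r), numeric(1))
    if (anyNA(refq)) {
      err <- rbind(err, data.frame(
        sample = s,
        message = sprintf("missing or unusable reference well(s): %s",
                          paste(reference_targets[is.na(refq)], collapse = ", ")),
        stringsAsFactors = FALSE))
      next
    }
    ref_agg[s] <- exp(mean(log(refq)))
  }
  for (s in samples[!is.na(ref_agg)]) {
    for (tg in tois) {
      q <- q_of(s, tg)
      if (is.na(q)) next
      rows[[length(rows) + 1L]] <- data.frame(
        sample = s, target = tg, n0 = q, normalized = q / ref_agg[[s]],
        efficiency_used = efficiencies[[tg]], stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sample = character(0), target = character(0), n0 = numeric(0),
               normalized = numeric(0), efficiency_used = numeric(0))
  out$fold_vs_calibrator <- NA_real_
  for (i in seq_len(nrow(out))) {
    cal <- out$normalized[out$sample == calibrator & out$target == out$target[i]]
    if (length(cal) == 1L) out$fold_vs_calibrator[i] <- out$normalized[i] / cal
  }
  out <- out[, c("sample", "target", "n0", "normalized", "fold_vs_calibrator",
                 "efficiency_used")]
  rownames(out) <- NULL
  attr(out, "errors") <- err
  attr(out, "calibrator") <- calibrator
  out
}

#' Cq-dependent bias of assuming the wrong efficiency
#'
#' If amplification really proceeds at `e_true` per cycle but quantities
#' are computed assuming `e_assumed` (classically: perfect doubling,
#' E = 2), the estimated quantity is wrong by the factor
#' `(e_assumed / e_true)^cq` — an error that grows geometrically with Cq,
#' which is why ignoring assay-specific efficiency biases late-Cq
#' (low-abundance) results the most.
#'
#' @param e_true,e_assumed per-cycle amplification factors, in (1, 2.2]
#' @param cq_range length-2 numeric: Cq interval to tabulate
#' @param by Cq step
#' @return data.frame with `cq` and `fold_error`
#' @export
cq_bias_assessment <- function(e_true, e_assumed, cq_range = c(15, 40), by = 1) {
  for (e in c(e_true, e_assumed))
    if (!is.finite(e) || e <= 1 || e > 2.2)
      rdes_stop("CONFIG", "efficiencies must lie in (1, 2.2]; got %.4g", e)
  cq <- seq(cq_range[1], cq_range[2], by = by)
  data.frame(cq = cq, fold_error = (e_assumed / e_true)^cq)
}
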