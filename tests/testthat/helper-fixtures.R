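# shared fixture builders; everything is generated in code

table1_path <- function() {
  system.file("extdata", "table1_rdes.csv", package = "rdes")
}

table1_infilled_path <- function() {
  system.file("extdata", "table1_infilled_synthetic.csv", package = "rdes")
}

# minimal hand-built valid plate: 2 wells, explicit numbers
tiny_plate <- function(cq = c(2.5, NA)) {
  plate_table(
    wells = data.frame(
      well_id = c("A1", "A2"), sample = c("s1", "s2"),
      sample_type = c("unkn", "ntc"), target = "g1", target_type = "toi",
      dye = "SYBR", reported_cq = cq, stringsAsFactors = FALSE),
    traces = rbind(c(1.0, 1.1, 1.5, 2.4), c(1.0, 1.0, 1.0, 1.0)),
    axis = 1:4, variant = "amplification")
}

# a plate with n_samples x n_targets distinct labels, one cycle-trivial
# trace per well (for validator rules that only look at annotations)
label_grid_plate <- function(n_samples, n_targets) {
  n <- n_samples * n_targets
  geom_cols <- if (n <= 96) 12L else 24L
  pos <- seq_len(n)
  wells <- data.frame(
    well_id = paste0(LETTERS[(pos - 1L) %/% geom_cols + 1L],
                     (pos - 1L) %% geom_cols + 1L),
    sample = sprintf("S%02d", rep(seq_len(n_samples), each = n_targets)),
    sample_type = "unkn",
    target = sprintf("G%02d", rep(seq_len(n_targets), times = n_samples)),
    target_type = "toi", dye = "SYBR", reported_cq = NA_real_,
    stringsAsFactors = FALSE)
  plate_table(wells, matrix(1, nrow = n, ncol = 3), 1:3, "amplification")
}

# noiseless exponential trace: baseline + a0 * e^cycle
exp_trace <- function(n_cycles, e, a0, baseline = 1) {
  baseline + a0 * e^seq_len(n_cycles)
}
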