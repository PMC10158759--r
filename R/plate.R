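#' Construct a PlateTable
#'
#' A `plate_table` holds one RDES plate: per-well annotations, the shared
#' cycle (or temperature) axis, and the raw fluorescence traces as a
#' rectangular matrix (one row per well record, one column per axis value).
#'
#' @param wells data.frame with character columns `well_id`, `sample`,
#'   `sample_type`, `target`, `target_type`, `dye` and numeric
#'   `reported_cq` (the reported Cq for amplification plates, the reported
#'   Tm for melt plates; `NA` when absent).
#' @param traces numeric matrix, `nrow(wells)` rows by `length(axis)`
#'   columns; `NA` marks readings absent from the source (e.g. elided
#'   cycle columns).
#' @param axis numeric vector: cycle numbers (amplification) or
#'   temperatures in degrees Celsius (melt), strictly increasing.
#' @param variant `"amplification"` or `"melt"`.
#' @param meta free-form named list of provenance (source file, delimiter,
#'   original column order, ...).
#' @return An object of class `plate_table`.
#' @seealso [read_rdes()], [write_rdes()], [validate_plate()]
#' @export
plate_table <- function(wells, traces, axis,
                        variant = c("amplification", "melt"),
                        meta = list()) {
  variant <- match.arg(variant)
  wells <- as.data.frame(wells, stringsAsFactors = FALSE)
  need <- c("well_id", "sample", "sample_type", "target", "target_type", "dye")
  miss <- setdiff(need, names(wells))
  if (length(miss))
    rdes_stop("BAD_PLATE", "wells is missing column(s): %s", paste(miss, collapse = ", "))
  if (!"reported_cq" %in% names(wells)) wells$reported_cq <- NA_real_
  wells$reported_cq <- as.numeric(wells$reported_cq)
  for (cc in need) wells[[cc]] <- as.character(wells[[cc]])
  traces <- as.matrix(traces)
  storage.mode(traces) <- "double"
  axis <- as.numeric(axis)
  if (nrow(traces) != nrow(wells))
    rdes_stop("BAD_PLATE", "traces has %d rows but wells has %d", nrow(traces), nrow(wells))
  if (ncol(traces) != length(axis))
    rdes_stop("BAD_PLATE", "traces has %d columns but axis has length %d",
              ncol(traces), length(axis))
  dimnames(traces) <- NULL
  rownames(wells) <- NULL
  structure(list(wells = wells, traces = traces, axis = axis,
                 variant = variant, meta = meta),
            class = "plate_table")
}

#' @export
print.plate_table <- function(x, ...) {
  cat(sprintf("<plate_table: %s, %d well record(s), %d %s>\n",
              x$variant, nrow(x$wells), length(x$axis),
              if (x$variant == "amplification") "cycles" else "temperatures"))
  cat(sprintf("  wells: %s\n", paste(utils::head(x$wells$well_id, 8), collapse = " ")))
  invisible(x)
}

#' Number of well records in a plate
#' @param plate a `plate_table`
#' @return integer count
#' @export
n_wells <- function(plate) nrow(plate$wells)

#' Extract one well's record
#'
#' @param plate a `plate_table`
#' @param well_id plate coordinate label, e.g. `"A1"`
#' @param dye dye name; only needed when the well is multiplexed
#' @return list with the annotation fields, `reported_cq`, and the numeric
#'   `trace` named by the axis values
#' @export
well_record <- function(plate, well_id, dye = NULL) {
  sel <- plate$wells$well_id == well_id
  if (!is.null(dye)) sel <- sel & plate$wells$dye == dye
  i <- which(sel)
  if (length(i) == 0L) rdes_stop("NOT_FOUND", "no well '%s' in plate", well_id)
  if (length(i) > 1L)
    rdes_stop("NOT_FOUND", "well '%s' is multiplexed; give dye explicitly", well_id)
  rec <- as.list(plate$wells[i, , drop = FALSE])
  rec$trace <- setNames(plate$traces[i, ], fmt_num(plate$axis))
  rec
}

# TRUE when a label is a valid plate coordinate (rows A-P, columns 1-24,
# zero padding allowed)
is_well_id <- function(x) grepl("^[A-P]0*([1-9]|1[0-9]|2[0-4])$", x)

# "a01" -> "A1"
normalize_well_id <- function(x) {
  x <- toupper(trimws(x))
  sub("^([A-P])0+([1-9])", "\\1\\2", x)
}

# row-major canonical order key: row letter, then column number, then dye
well_order <- function(well_id, dye = "") {
  row <- match(substr(well_id, 1, 1), LETTERS)
  col <- suppressWarnings(as.integer(substring(well_id, 2)))
  order(row, col, dye)
}

#' Compare two plates field-for-field
#'
#' Annotations are compared exactly, traces and axis numerically with a
#' relative tolerance; `meta` is provenance and is ignored.
#'
#' @param a,b `plate_table` objects
#' @param tolerance relative numeric tolerance
#' @return logical scalar
#' @export
plates_equal <- function(a, b, tolerance = 1e-9) {
  if (!inherits(a, "plate_table") || !inherits(b, "plate_table")) return(FALSE)
  if (a$variant != b$variant) return(FALSE)
  if (nrow(a$wells) != nrow(b$wells)) return(FALSE)
  if (length(a$axis) != length(b$axis)) return(FALSE)
  ann <- c("well_id", "sample", "sample_type", "target", "target_type", "dye")
  oa <- well_order(a$wells$well_id, a$wells$dye)
  ob <- well_order(b$wells$well_id, b$wells$dye)
  wa <- a$wells[oa, , drop = FALSE]; wb <- b$wells[ob, , drop = FALSE]
  for (cc in ann) if (!identical(wa[[cc]], wb[[cc]])) return(FALSE)
  num_eq <- function(x, y) {
    if (length(x) != length(y)) return(FALSE)
    if (!identical(is.na(x), is.na(y))) return(FALSE)
    ok <- is.na(x) | abs(x - y) <= tolerance * pmax(abs(x), abs(y), 1)
    all(ok)
  }
  if (!num_eq(wa$reported_cq, wb$reported_cq)) return(FALSE)
  if (!num_eq(a$axis, b$axis)) return(FALSE)
  num_eq(as.vector(a$traces[oa, , drop = FALSE]), as.vector(b$traces[ob, , drop = FALSE]))
}
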