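#' Declare how an instrument export maps onto RDES
#'
#' A `shape_spec` is a declarative description of an arbitrary wide or
#' long instrument-export table, sufficient to reshape it into canonical
#' RDES without per-instrument code.
#'
#' @param layout `"wide"` (one row per well, one column per cycle) or
#'   `"long"` (one row per well x cycle reading).
#' @param column_map named list mapping RDES field keys (`well`, `sample`,
#'   `sample_type`, `target`, `target_type`, `dye`, `cq`) to source column
#'   names.
#' @param cycle_columns identifies the trace readings. Wide layout:
#'   `NULL` (all numeric-only headers), a character vector of explicit
#'   column names, or `list(pattern = <regex>)`; the cycle/temperature
#'   value is the first number embedded in each matched header. Long
#'   layout: `list(cycle = <col>, fluorescence = <col>)`.
#' @param constants named list of fixed values for RDES fields absent
#'   from the source (e.g. `dye = "SYBR"`).
#' @param variant forwarded to the resulting plate: `"auto"`,
#'   `"amplification"` or `"melt"`.
#' @return A `shape_spec` object.
#' @seealso [reshape_table()], [read_shape_spec()]
#' @export
shape_spec <- function(layout = c("wide", "long"), column_map = list(),
                       cycle_columns = NULL, constants = list(),
                       variant = "auto") {
  layout <- match.arg(layout)
  bad <- setdiff(names(column_map), names(RDES_FIELD_KEYS))
  if (length(bad))
    rdes_stop("SPEC", "unknown RDES field key(s) in column_map: %s",
              paste(bad, collapse = ", "))
  bad <- setdiff(names(constants), names(RDES_FIELD_KEYS))
  if (length(bad))
    rdes_stop("SPEC", "unknown RDES field key(s) in constants: %s",
              paste(bad, collapse = ", "))
  structure(list(layout = layout, column_map = column_map,
                 cycle_columns = cycle_columns, constants = constants,
                 variant = variant),
            class = "shape_spec")
}

#' Load a shape spec from a JSON or YAML config file
#' @param path file path; `.json` parsed with jsonlite, anything else
#'   with yaml
#' @return A [shape_spec()]
#' @export
read_shape_spec <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  cc <- cfg$cycle_columns
  if (!is.null(cc) && is.list(cc) && is.null(names(cc))) cc <- unlist(cc)
  shape_spec(layout = cfg$layout %||% "wide",
             column_map = as.list(cfg$column_map %||% list()),
             cycle_columns = cc,
             constants = as.list(cfg$constants %||% list()),
             variant = cfg$variant %||% "auto")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reshape an instrument export into an RDES plate
#'
#' Applies a [shape_spec()] to a delimited table (path, lines, or
#' data.frame) and returns a plate that passes [validate_plate()] with no
#' errors. Every mandatory RDES field must be covered by `column_map` or
#' `constants`, with one pragmatic default: an unmapped `sample` falls
#' back to the well label (recorded in `meta`), since many exports carry
#' no separate sample column.
#'
#' @param source path, character lines, or data.frame
#' @param spec a [shape_spec()]
#' @return A [plate_table()]
#' @export
reshape_table <- function(source, spec) {
  if (!inherits(spec, "shape_spec")) rdes_stop("SPEC", "spec must be a shape_spec")
  df <- if (is.data.frame(source)) source else read_delim_auto(source)
  for (src in unlist(spec$column_map))
    if (!src %in% names(df))
      rdes_stop("SPEC", "mapped source column '%s' not present in the input", src)

  get_field <- function(key, n) {
    src <- spec$column_map[[key]]
    if (!is.null(src)) return(as.character(df[[src]]))
    cst <- spec$constants[[key]]
    if (!is.null(cst)) return(rep(as.character(cst), n))
    NULL
  }
  mandatory <- c("well", "sample_type", "target", "target_type", "dye")
  for (key in mandatory) {
    if (is.null(spec$column_map[[key]]) && is.null(spec$constants[[key]]))
      rdes_stop("SPEC", "mandatory RDES field '%s' is not covered by the spec",
                RDES_FIELD_KEYS[[key]])
  }

  if (spec$layout == "wide") reshape_wide(df, spec, get_field)
  else reshape_long(df, spec, get_field)
}

read_delim_auto <- function(source) {
  lines <- read_source_lines(source)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) rdes_stop("FORMAT", "input has no data rows")
  delim <- detect_delimiter_loose(lines[1])
  read.table(text = lines, sep = delim, quote = "\"", header = TRUE,
             colClasses = "character", stringsAsFactors = FALSE,
             comment.char = "", check.names = FALSE,
             na.strings = character(0), encoding = "UTF-8")
}

detect_delimiter_loose <- function(header_line) {
  cand <- c(",", ";", "\t")
  counts <- vapply(cand, function(d)
    length(strsplit(header_line, d, fixed = TRUE)[[1]]), integer(1))
  if (max(counts) < 2L) rdes_stop("FORMAT", "could not detect a field delimiter")
  cand[which.max(counts)]
}

resolve_trace_columns <- function(df, spec) {
  nm <- names(df)
  mapped <- unlist(spec$column_map)
  cc <- spec$cycle_columns
  if (is.character(cc)) {
    cols <- cc
    miss <- setdiff(cols, nm)
    if (length(miss))
      rdes_stop("SPEC", "trace column(s) not in input: %s", paste(miss, collapse = ", "))
  } else if (is.list(cc) && !is.null(cc$pattern)) {
    cols <- nm[grepl(cc$pattern, nm)]
  } else {
    cols <- nm[grepl("^[0-9]+(\\.[0-9]+)?$", trimws(nm))]
  }
  cols <- setdiff(cols, mapped)
  if (length(cols) < 2L)
    rdes_stop("SPEC", "cycle_columns resolves to %d trace column(s); need at least 2",
              length(cols))
  num <- suppressWarnings(as.numeric(regmatches(
    cols, regexpr("[0-9]+(\\.[0-9]+)?", cols))))
  if (anyNA(num)) num <- seq_along(cols)  # no embedded numbers: document order
  ord <- order(num, seq_along(cols))
  list(cols = cols[ord], axis = num[ord])
}

reshape_wide <- function(df, spec, get_field) {
  n <- nrow(df)
  if (n == 0L) rdes_stop("EMPTY_PLATE", "empty plate: no data rows")
  tc <- resolve_trace_columns(df, spec)
  if (any(diff(tc$axis) <= 0))
    rdes_stop("FORMAT", "trace columns do not yield a strictly increasing axis")
  well <- normalize_well_id(get_field("well", n))
  wells <- data.frame(
    well_id = well,
    sample = get_field("sample", n) %||% well,
    sample_type = get_field("sample_type", n),
    target = get_field("target", n),
    target_type = get_field("target_type", n),
    dye = get_field("dye", n),
    reported_cq = suppressWarnings(as.numeric(get_field("cq", n) %||% rep(NA, n))),
    stringsAsFactors = FALSE
  )
  traces <- sapply(tc$cols, function(cc) suppressWarnings(as.numeric(df[[cc]])))
  traces <- matrix(as.numeric(traces), nrow = n)
  finish_reshape(wells, traces, tc$axis, spec)
}

reshape_long <- function(df, spec, get_field) {
  cc <- spec$cycle_columns
  if (!is.list(cc) || is.null(cc$cycle) || is.null(cc$fluorescence))
    rdes_stop("SPEC", "long layout needs cycle_columns = list(cycle=, fluorescence=)")
  for (src in c(cc$cycle, cc$fluorescence))
    if (!src %in% names(df))
      rdes_stop("SPEC", "column '%s' not present in the input", src)
  n <- nrow(df)
  if (n == 0L) rdes_stop("EMPTY_PLATE", "empty plate: no data rows")
  well <- normalize_well_id(get_field("well", n))
  ann <- data.frame(
    well_id = well,
    sample = get_field("sample", n) %||% well,
    sample_type = get_field("sample_type", n),
    target = get_field("target", n),
    target_type = get_field("target_type", n),
    dye = get_field("dye", n),
    reported_cq = suppressWarnings(as.numeric(get_field("cq", n) %||% rep(NA, n))),
    stringsAsFactors = FALSE
  )
  cyc <- suppressWarnings(as.numeric(df[[cc$cycle]]))
  fl <- suppressWarnings(as.numeric(df[[cc$fluorescence]]))
  if (anyNA(cyc)) rdes_stop("FORMAT", "non-numeric cycle value in long input")
  key <- paste(ann$well_id, ann$dye, sep = "\r")
  dup <- duplicated(paste(key, cyc, sep = "\r"))
  if (any(dup)) {
    i <- which(dup)[1]
    rdes_stop("DATA", "duplicate reading for well '%s', cycle %s", ann$well_id[i], cyc[i])
  }
  axis <- sort(unique(cyc))
  groups <- split(seq_len(n), key)
  # preserve first-appearance order of the records
  groups <- groups[order(vapply(groups, min, integer(1)))]
  wells_l <- list(); traces <- matrix(NA_real_, nrow = length(groups), ncol = length(axis))
  for (g in seq_along(groups)) {
    idx <- groups[[g]]
    a <- unique(ann[idx, , drop = FALSE])
    if (nrow(a) > 1L)
      rdes_stop("DATA", "inconsistent annotations for well '%s'", ann$well_id[idx[1]])
    if (length(idx) != length(axis))
      rdes_stop("FORMAT", "well '%s' has %d reading(s); axis has %d",
                a$well_id, length(idx), length(axis))
    traces[g, match(cyc[idx], axis)] <- fl[idx]
    wells_l[[g]] <- a
  }
  wells <- do.call(rbind, wells_l)
  finish_reshape(wells, traces, axis, spec)
}

finish_reshape <- function(wells, traces, axis, spec) {
  variant <- if (spec$variant %in% c("amplification", "melt")) spec$variant
  else infer_variant(axis, NA_character_, "auto")
  plate <- plate_table(wells, traces, axis, variant,
                       meta = list(reshaped = TRUE,
                                   sample_defaulted_to_well =
                                     is.null(spec$column_map$sample) &&
                                     is.null(spec$constants$sample)))
  rep <- validate_plate(plate)
  if (nrow(rep$errors) > 0L)
    rdes_stop("INVALID_PLATE", "reshaped plate fails validation [%s]",
              paste(unique(rep$errors$code), collapse = ", "))
  plate
}
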