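#' Read an RDES spreadsheet
#'
#' Parses a Real-time PCR Data Essential Spreadsheet: one row per well
#' record with annotation columns `Well, Sample, Sample type, Target,
#' Target type, Dye`, a summary column (`Cq` for amplification plates,
#' `Tm` for melt plates, optional for melt), and one column per cycle or
#' temperature.
#'
#' The field delimiter is auto-detected among comma, semicolon and tab
#' (the detected delimiter is recorded in `meta$delimiter`); decimal
#' commas are accepted only when the field delimiter is semicolon or tab.
#' An ellipsis column (`...` or the Unicode ellipsis) between two integer
#' cycle headers marks elided cycles, as in published table excerpts: the
#' full axis is reconstructed and the elided readings become `NA`.
#' Zero-padded well labels (`A01`) are normalized to `A1`. Empty summary
#' cells mean "no Cq"; the literal strings `NA`, `NaN` and `Undetermined`
#' are accepted with a warning.
#'
#' @param source path to a file, a character vector of lines, or a single
#'   string containing the whole table.
#' @param variant_hint `"auto"` (default), `"amplification"` or `"melt"`.
#'   Under `"auto"`, consecutive integer axis headers starting at 1 mean
#'   amplification; anything else (or a `Tm` summary column) means melt.
#' @return A [plate_table()].
#' @examples
#' p <- read_rdes(c("Well,Sample,Sample type,Target,Target type,Dye,Cq,1,2,3",
#'                  "A1,s1,unkn,g1,toi,SYBR,2.5,1.0,1.1,1.2"))
#' well_record(p, "A1")$reported_cq
#' @export
read_rdes <- function(source, variant_hint = c("auto", "amplification", "melt")) {
  variant_hint <- match.arg(variant_hint)
  lines <- read_source_lines(source)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) rdes_stop("FORMAT", "empty input")

  delim <- detect_delimiter(lines[1])
  nf <- count.fields(textConnection(lines), sep = delim, quote = "\"",
                     comment.char = "")
  if (any(nf != nf[1])) {
    bad <- which(nf != nf[1])[1]
    rdes_stop("FORMAT", "ragged row %d: %d field(s), header has %d",
              bad, nf[bad], nf[1])
  }
  tab <- read.table(text = lines, sep = delim, quote = "\"", header = FALSE,
                    colClasses = "character", stringsAsFactors = FALSE,
                    comment.char = "", check.names = FALSE,
                    na.strings = character(0), encoding = "UTF-8")
  header <- trimws(as.character(tab[1, ]))
  body <- tab[-1, , drop = FALSE]

  for (i in seq_along(RDES_ANNOT_HEADER)) {
    if (i > length(header) || header[i] != RDES_ANNOT_HEADER[i])
      rdes_stop("FORMAT", "missing mandatory header column '%s' at position %d",
                RDES_ANNOT_HEADER[i], i)
  }
  if (length(header) < 8L)
    rdes_stop("FORMAT", "no trace columns found after the annotation columns")

  comma_dec <- delim %in% c(";", "\t")
  parse_num <- function(x) {
    x <- trimws(x)
    if (comma_dec) x <- sub(",", ".", x, fixed = TRUE)
    suppressWarnings(as.numeric(x))
  }

  # summary column (Cq or Tm) is the 7th column when labelled as such;
  # a numeric 7th header means a melt table without a Tm summary column
  col7 <- header[7]
  if (col7 %in% c("Cq", "Tm")) {
    summary_label <- col7
    axis_cols <- seq.int(8L, length(header))
  } else if (!is.na(parse_num(col7))) {
    summary_label <- NA_character_
    axis_cols <- seq.int(7L, length(header))
  } else {
    rdes_stop("FORMAT", "missing mandatory header column 'Cq' at position 7")
  }

  ax <- parse_axis_header(header[axis_cols], parse_num)
  # ax: list(values, src_col (index into axis_cols, NA for elided))

  variant <- infer_variant(ax$values, summary_label, variant_hint)
  if (!is.na(summary_label) && summary_label == "Tm" && variant == "amplification")
    rdes_stop("FORMAT", "Tm summary column on an amplification-like axis")

  if (nrow(body) == 0L) rdes_stop("EMPTY_PLATE", "empty plate: header only, no data rows")

  n <- nrow(body)
  wells <- data.frame(
    well_id = normalize_well_id(body[[1]]),
    sample = trimws(body[[2]]),
    sample_type = trimws(body[[3]]),
    target = trimws(body[[4]]),
    target_type = trimws(body[[5]]),
    dye = trimws(body[[6]]),
    reported_cq = NA_real_,
    stringsAsFactors = FALSE
  )
  if (!is.na(summary_label)) {
    raw_cq <- trimws(body[[7]])
    placeholder <- raw_cq %in% c("NA", "NaN", "Undetermined")
    if (any(placeholder))
      warning(sprintf("%d %s cell(s) use placeholder text (e.g. '%s'); treated as absent",
                      sum(placeholder), summary_label, raw_cq[placeholder][1]))
    raw_cq[placeholder | raw_cq == ""] <- NA
    cq <- parse_num(raw_cq)
    bad <- which(!is.na(raw_cq) & is.na(cq))
    if (length(bad))
      rdes_stop("FORMAT", "non-numeric %s cell in data row %d: '%s'",
                summary_label, bad[1], raw_cq[bad[1]])
    wells$reported_cq <- cq
  }

  traces <- matrix(NA_real_, nrow = n, ncol = length(ax$values))
  for (j in seq_along(ax$values)) {
    src <- ax$src_col[j]
    if (is.na(src)) next  # elided column, stays NA
    raw <- trimws(body[[axis_cols[src]]])
    elided_cell <- raw %in% c("", "...", "…")
    val <- parse_num(raw)
    bad <- which(!elided_cell & is.na(val))
    if (length(bad))
      rdes_stop("FORMAT", "non-numeric trace cell at data row %d, column '%s': '%s'",
                bad[1], header[axis_cols[src]], raw[bad[1]])
    val[elided_cell] <- NA_real_
    traces[, j] <- val
  }

  meta <- list(
    source = if (is.character(source) && length(source) == 1L &&
                 !grepl("\n", source) && file.exists(source)) source else "<text>",
    delimiter = delim,
    n_source_rows = length(lines),
    n_source_cols = length(header),
    column_order = header,
    summary_label = summary_label,
    elided_axis_values = ax$values[is.na(ax$src_col)]
  )
  plate_table(wells, traces, ax$values, variant, meta)
}

read_source_lines <- function(source) {
  if (inherits(source, "connection")) return(readLines(source, warn = FALSE))
  if (!is.character(source)) rdes_stop("FORMAT", "source must be a path, lines, or text")
  if (length(source) == 1L && !grepl("\n", source) && file.exists(source))
    return(readLines(source, warn = FALSE, encoding = "UTF-8"))
  unlist(strsplit(source, "\n", fixed = TRUE), use.names = FALSE)
}

detect_delimiter <- function(header_line) {
  cand <- c(",", ";", "\t")
  counts <- vapply(cand, function(d)
    length(strsplit(header_line, d, fixed = TRUE)[[1]]), integer(1))
  if (max(counts) < 7L)
    rdes_stop("FORMAT", "could not detect a field delimiter in the header row")
  cand[which.max(counts)]
}

# Expand an axis header that may contain ellipsis markers for elided
# integer cycle ranges. Returns values plus, per value, the source column
# it came from (NA = elided).
parse_axis_header <- function(hdr, parse_num) {
  hdr <- trimws(hdr)
  is_ell <- hdr %in% c("...", "…")
  vals <- parse_num(hdr)
  bad <- which(!is_ell & is.na(vals))
  if (length(bad))
    rdes_stop("FORMAT", "non-numeric trace column header '%s'", hdr[bad[1]])
  out_val <- numeric(0); out_src <- integer(0)
  for (i in seq_along(hdr)) {
    if (is_ell[i]) {
      if (i == 1L || i == length(hdr) || is_ell[i - 1] || is_ell[i + 1])
        rdes_stop("FORMAT", "ellipsis column must sit between two cycle headers")
      lo <- vals[i - 1]; hi <- vals[i + 1]
      if (lo != round(lo) || hi != round(hi) || hi <= lo + 1)
        rdes_stop("FORMAT", "ellipsis column must bridge an integer cycle gap (%s to %s)",
                  hdr[i - 1], hdr[i + 1])
      fill <- seq.int(lo + 1, hi - 1)
      out_val <- c(out_val, fill)
      out_src <- c(out_src, rep(NA_integer_, length(fill)))
    } else {
      out_val <- c(out_val, vals[i])
      out_src <- c(out_src, i)
    }
  }
  if (any(diff(out_val) <= 0))
    rdes_stop("FORMAT", "trace column headers must be strictly increasing")
  list(values = out_val, src_col = out_src)
}

infer_variant <- function(axis, summary_label, hint) {
  amp_like <- length(axis) >= 2 && all(axis == round(axis)) &&
    axis[1] == 1 && all(diff(axis) == 1)
  if (hint != "auto") return(hint)
  if (!is.na(summary_label) && summary_label == "Tm") return("melt")
  if (amp_like) "amplification" else "melt"
}

#' Write a plate as canonical RDES
#'
#' Refuses plates that fail [validate_plate()]. The canonical form is
#' comma-delimited, dot-decimal, header
#' `Well,Sample,Sample type,Target,Target type,Dye,Cq,...` (Tm for melt
#' plates), rows in row-major well order (`A1..A12, B1, ...`) then by dye,
#' unpadded well labels, and empty cells for absent values. The same plate
#' always serializes to identical bytes.
#'
#' @param plate a valid [plate_table()]
#' @param path optional file path; when given the lines are written there
#' @return character vector of lines, invisibly when `path` is given
#' @export
write_rdes <- function(plate, path = NULL) {
  rep <- validate_plate(plate)
  if (nrow(rep$errors) > 0L)
    rdes_stop("INVALID_PLATE", "refusing to write: validation errors [%s]",
              paste(unique(rep$errors$code), collapse = ", "))
  summary_label <- if (plate$variant == "amplification") "Cq" else "Tm"
  ax_lab <- format_axis_labels(plate$axis, plate$variant)
  header <- paste(c(RDES_ANNOT_HEADER, summary_label, ax_lab), collapse = ",")
  ord <- well_order(plate$wells$well_id, plate$wells$dye)
  w <- plate$wells[ord, , drop = FALSE]
  tr <- plate$traces[ord, , drop = FALSE]
  rows <- vapply(seq_len(nrow(w)), function(i) {
    paste(c(w$well_id[i], csv_field(w$sample[i]), csv_field(w$sample_type[i]),
            csv_field(w$target[i]), csv_field(w$target_type[i]),
            csv_field(w$dye[i]), fmt_num(w$reported_cq[i]),
            fmt_num(tr[i, ])), collapse = ",")
  }, character(1))
  out <- c(header, rows)
  if (!is.null(path)) {
    writeLines(out, path, useBytes = TRUE)
    return(invisible(out))
  }
  out
}

format_axis_labels <- function(axis, variant) {
  if (variant == "amplification") return(fmt_num(axis))
  # melt axis: one decimal when representable that way, per convention
  if (all(abs(axis * 10 - round(axis * 10)) < 1e-9)) sprintf("%.1f", axis)
  else fmt_num(axis)
}

csv_field <- function(x) {
  needs <- grepl('[",\n]', x)
  x[needs] <- paste0('"', gsub('"', '""', x[needs]), '"')
  x
}

#' Validate a plate against the RDES rules
#'
#' Applies every structural and vocabulary rule as a coded finding:
#' errors (`EMPTY_PLATE`, `BAD_WELL_ID`, `DUPLICATE_WELL`,
#' `BAD_SAMPLE_TYPE`, `BAD_TARGET_TYPE`, `AXIS_NOT_INCREASING`,
#' `AXIS_NOT_CYCLES`, `CQ_OUT_OF_RANGE`), warnings
#' (`MISSING_TRACE_VALUES`), and suggestions. Enumeration tokens are
#' matched case-sensitively. When the plate spans at least 20 distinct
#' samples and 20 distinct targets the report suggests public deposition
#' (`GEO_DEPOSIT`), the scale at which repositories accept qPCR raw-data
#' submissions.
#'
#' @param plate a `plate_table`
#' @return A `validation_report`: list with data.frames `errors`,
#'   `warnings`, `suggestions` (columns `code`, `well_id`, `message`) and
#'   a `counts` list (`n_wells`, `n_samples`, `n_targets`, `n_cycles`).
#' @export
validate_plate <- function(plate) {
  finding <- function(code, well_id, message)
    data.frame(code = code, well_id = well_id, message = message,
               stringsAsFactors = FALSE)
  empty <- finding(character(0), character(0), character(0))
  errors <- empty; warnings <- empty; suggestions <- empty
  add <- function(df, code, well, msg) rbind(df, finding(code, well, msg))

  w <- plate$wells
  if (nrow(w) == 0L)
    errors <- add(errors, "EMPTY_PLATE", NA_character_, "plate has no well records")

  bad_id <- !is_well_id(w$well_id)
  for (i in which(bad_id))
    errors <- add(errors, "BAD_WELL_ID", w$well_id[i],
                  sprintf("'%s' is not a plate coordinate", w$well_id[i]))
  key <- paste(w$well_id, w$dye, sep = "\r")
  for (k in unique(key[duplicated(key)])) {
    parts <- strsplit(k, "\r", fixed = TRUE)[[1]]
    errors <- add(errors, "DUPLICATE_WELL", parts[1],
                  sprintf("duplicate record for well '%s', dye '%s'", parts[1], parts[2]))
  }
  for (i in which(!w$sample_type %in% SAMPLE_TYPES))
    errors <- add(errors, "BAD_SAMPLE_TYPE", w$well_id[i],
                  sprintf("unknown sample type '%s' (allowed: %s)",
                          w$sample_type[i], paste(SAMPLE_TYPES, collapse = "/")))
  for (i in which(!w$target_type %in% TARGET_TYPES))
    errors <- add(errors, "BAD_TARGET_TYPE", w$well_id[i],
                  sprintf("unknown target type '%s' (allowed: %s)",
                          w$target_type[i], paste(TARGET_TYPES, collapse = "/")))

  if (any(diff(plate$axis) <= 0))
    errors <- add(errors, "AXIS_NOT_INCREASING", NA_character_,
                  "axis values must be strictly increasing")
  if (plate$variant == "amplification") {
    ok <- length(plate$axis) > 0 && all(plate$axis == round(plate$axis)) &&
      plate$axis[1] == 1 && all(diff(plate$axis) == 1)
    if (!ok)
      errors <- add(errors, "AXIS_NOT_CYCLES", NA_character_,
                    "amplification axis must be consecutive cycles starting at 1")
    cq_max <- max(plate$axis)
    bad_cq <- !is.na(w$reported_cq) & (w$reported_cq < 1 | w$reported_cq > cq_max)
    for (i in which(bad_cq))
      errors <- add(errors, "CQ_OUT_OF_RANGE", w$well_id[i],
                    sprintf("reported Cq %.4g outside [1, %d]", w$reported_cq[i], cq_max))
  }
  n_missing <- sum(is.na(plate$traces))
  if (n_missing > 0L)
    warnings <- add(warnings, "MISSING_TRACE_VALUES", NA_character_,
                    sprintf("%d trace reading(s) absent (elided or empty cells)", n_missing))

  n_samples <- length(unique(w$sample))
  n_targets <- length(unique(w$target))
  if (n_samples >= 20L && n_targets >= 20L)
    suggestions <- add(suggestions, "GEO_DEPOSIT", NA_character_,
                       sprintf(paste0("%d samples x %d targets: consider depositing the ",
                                      "raw data in a public repository such as GEO"),
                               n_samples, n_targets))

  structure(list(errors = errors, warnings = warnings, suggestions = suggestions,
                 counts = list(n_wells = nrow(w), n_samples = n_samples,
                               n_targets = n_targets, n_cycles = length(plate$axis))),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report: %d error(s), %d warning(s), %d suggestion(s)>\n",
              nrow(x$errors), nrow(x$warnings), nrow(x$suggestions)))
  show <- function(df, tag) for (i in seq_len(nrow(df)))
    cat(sprintf("  %s %s%s: %s\n", tag, df$code[i],
                ifelse(is.na(df$well_id[i]), "", paste0(" [", df$well_id[i], "]")),
                df$message[i]))
  show(x$errors, "E"); show(x$warnings, "W"); show(x$suggestions, "S")
  cat(sprintf("  counts: %s\n",
              paste(names(x$counts), unlist(x$counts), sep = "=", collapse = " ")))
  invisible(x)
}

#' Serialize a validation report to JSON
#' @param report a `validation_report`
#' @return single JSON string with stable keys `errors`, `warnings`,
#'   `suggestions`, `counts`
#' @export
report_to_json <- function(report) {
  as.character(jsonlite::toJSON(
    list(errors = report$errors, warnings = report$warnings,
         suggestions = report$suggestions, counts = report$counts),
    dataframe = "rows", auto_unbox = TRUE, na = "null", digits = NA))
}
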