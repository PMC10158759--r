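#' Convert RDES plates to RDML XML
#'
#' Emits a minimal, schema-faithful subset of the Real-Time PCR Data
#' Markup Language (element vocabulary of RDML 1.2): deduplicated
#' `sample` and `target` dictionaries, one `react` per well, one `data`
#' block per (well, target) carrying the reported `cq`, the amplification
#' data points (`adp` with `cyc`/`fluor`) and, when a melt plate is
#' given, the melt data points (`mdp` with `tmp`/`fluor`). Well labels
#' are encoded as RDML react ids via the `pcrFormat` plate geometry.
#'
#' @param amp amplification-variant [plate_table()]
#' @param melt optional melt-variant plate; its (well, dye) set must
#'   match `amp`'s
#' @param experiment_id,run_id identifiers written into the document
#' @return an `xml2::xml_document`
#' @seealso [from_rdml()], [write_rdml()]
#' @export
to_rdml <- function(amp, melt = NULL, experiment_id = "exp1", run_id = "run1") {
  check_valid <- function(p, what) {
    rep <- validate_plate(p)
    if (nrow(rep$errors) > 0L)
      rdes_stop("INVALID_PLATE", "%s plate fails validation [%s]", what,
                paste(unique(rep$errors$code), collapse = ", "))
  }
  check_valid(amp, "amplification")
  if (amp$variant != "amplification")
    rdes_stop("INVALID_PLATE", "amp must be an amplification-variant plate")
  if (!is.null(melt)) {
    check_valid(melt, "melt")
    if (melt$variant != "melt")
      rdes_stop("INVALID_PLATE", "melt must be a melt-variant plate")
    ka <- paste(amp$wells$well_id, amp$wells$dye, sep = "/")
    km <- paste(melt$wells$well_id, melt$wells$dye, sep = "/")
    off <- c(setdiff(ka, km), setdiff(km, ka))
    if (length(off))
      rdes_stop("CONFLICT", "amp/melt well sets differ: %s", paste(off, collapse = ", "))
  }

  w <- amp$wells
  # dictionaries
  samp_idx <- !duplicated(w$sample)
  samples <- data.frame(id = w$sample[samp_idx], type = w$sample_type[samp_idx],
                        stringsAsFactors = FALSE)
  conf <- tapply(w$sample_type, w$sample, function(x) length(unique(x)))
  if (any(conf > 1))
    warning(sprintf("sample(s) with conflicting types (first kept): %s",
                    paste(names(conf)[conf > 1], collapse = ", ")))
  tkey <- !duplicated(w$target)
  targets <- data.frame(id = w$target[tkey], type = w$target_type[tkey],
                        dye = w$dye[tkey], stringsAsFactors = FALSE)
  tdye <- tapply(w$dye, w$target, function(x) length(unique(x)))
  if (any(tdye > 1))
    rdes_stop("CONFLICT", "target(s) recorded with more than one dye: %s",
              paste(names(tdye)[tdye > 1], collapse = ", "))

  cols <- suppressWarnings(as.integer(substring(w$well_id, 2)))
  geom <- if (max(cols) <= 12L) c(8L, 12L) else c(16L, 24L)
  react_id <- (match(substr(w$well_id, 1, 1), LETTERS) - 1L) * geom[2] + cols

  esc <- xml_escape
  out <- c('<?xml version="1.0" encoding="UTF-8"?>',
           '<rdml version="1.2" xmlns="http://www.rdml.org">')
  out <- c(out, sprintf('<sample id="%s"><type>%s</type></sample>',
                        esc(samples$id), esc(samples$type)))
  out <- c(out, sprintf('<target id="%s"><type>%s</type><dyeId id="%s"/></target>',
                        esc(targets$id), esc(targets$type), esc(targets$dye)))
  out <- c(out, sprintf('<experiment id="%s"><run id="%s">',
                        esc(experiment_id), esc(run_id)))
  out <- c(out, sprintf(paste0('<pcrFormat><rows>%d</rows><columns>%d</columns>',
                               '<rowLabel>ABC</rowLabel><columnLabel>123</columnLabel>',
                               '</pcrFormat>'), geom[1], geom[2]))

  ord <- well_order(w$well_id, w$dye)
  melt_key <- if (!is.null(melt)) paste(melt$wells$well_id, melt$wells$dye, sep = "/")
  for (g in split(ord, react_id[ord])) {
    i0 <- g[1]
    out <- c(out, sprintf('<react id="%d"><sample id="%s"/>',
                          react_id[i0], esc(w$sample[i0])))
    for (i in g) {
      cq_el <- if (is.na(w$reported_cq[i])) "" else
        sprintf("<cq>%s</cq>", fmt_num(w$reported_cq[i]))
      adp <- sprintf("<adp><cyc>%s</cyc><fluor>%s</fluor></adp>",
                     fmt_num(amp$axis), fmt_num(amp$traces[i, ]))
      mdp <- character(0); mt_el <- ""
      if (!is.null(melt)) {
        j <- match(paste(w$well_id[i], w$dye[i], sep = "/"), melt_key)
        if (!is.na(melt$wells$reported_cq[j]))
          mt_el <- sprintf("<meltTemp>%s</meltTemp>", fmt_num(melt$wells$reported_cq[j]))
        mdp <- sprintf("<mdp><tmp>%s</tmp><fluor>%s</fluor></mdp>",
                       fmt_num(melt$axis), fmt_num(melt$traces[j, ]))
      }
      out <- c(out, sprintf('<data><tar id="%s"/>%s%s%s%s</data>',
                            esc(w$target[i]), cq_el, mt_el,
                            paste(adp, collapse = ""), paste(mdp, collapse = "")))
    }
    out <- c(out, "</react>")
  }
  out <- c(out, "</run></experiment></rdml>")
  xml2::read_xml(paste(out, collapse = "\n"))
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub('"', "&quot;", x, fixed = TRUE)
  x
}

#' Write an RDML document to disk
#' @param doc result of [to_rdml()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_rdml <- function(doc, path) {
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read RDES plates back out of an RDML document
#'
#' Accepts a file path (bare XML, or a ZIP container — RDML's on-disk
#' convention — detected by its magic bytes), an XML string, or an
#' `xml2::xml_document`. Only the subset emitted by [to_rdml()] is
#' interpreted; other RDML content is skipped. Sample and target types
#' map one-to-one onto the RDES vocabularies. All reactions must share an
#' identical cycle (and temperature) list, since RDES is a rectangular
#' table by construction.
#'
#' @param doc path, XML string, or `xml_document`
#' @return list with elements `amp` (a [plate_table()], or `NULL` when
#'   the document has no amplification data points) and `melt` (likewise)
#' @export
from_rdml <- function(doc) {
  x <- load_rdml_doc(doc)
  version <- xml2::xml_attr(x, "version")
  xml2::xml_ns_strip(x)

  samples <- xml2::xml_find_all(x, "/*/sample")
  sdict <- setNames(
    vapply(samples, function(s) {
      t <- xml2::xml_find_first(s, "./type")
      if (is.na(t)) "unkn" else xml2::xml_text(t)
    }, character(1)),
    xml2::xml_attr(samples, "id"))
  targets <- xml2::xml_find_all(x, "/*/target")
  tdict_type <- setNames(
    vapply(targets, function(s) {
      t <- xml2::xml_find_first(s, "./type")
      if (is.na(t)) "toi" else xml2::xml_text(t)
    }, character(1)),
    xml2::xml_attr(targets, "id"))
  tdict_dye <- setNames(
    vapply(targets, function(s) {
      d <- xml2::xml_find_first(s, "./dyeId")
      if (is.na(d)) "" else xml2::xml_attr(d, "id")
    }, character(1)),
    xml2::xml_attr(targets, "id"))

  ncols <- 12L
  pc <- xml2::xml_find_first(x, ".//pcrFormat/columns")
  if (!is.na(pc)) ncols <- as.integer(xml2::xml_text(pc))

  reacts <- xml2::xml_find_all(x, ".//react")
  if (length(reacts) == 0L) rdes_stop("FORMAT", "document contains no react elements")

  rows <- list(); amp_tr <- list(); melt_tr <- list()
  amp_axis <- NULL; melt_axis <- NULL
  k <- 0L
  for (re in reacts) {
    rid <- suppressWarnings(as.integer(xml2::xml_attr(re, "id")))
    if (is.na(rid)) rdes_stop("FORMAT", "react without a numeric id")
    well <- paste0(LETTERS[(rid - 1L) %/% ncols + 1L], (rid - 1L) %% ncols + 1L)
    sref <- xml2::xml_attr(xml2::xml_find_first(re, "./sample"), "id")
    if (is.na(sref) || !sref %in% names(sdict))
      rdes_stop("FORMAT", "react %d references unknown sample '%s'", rid, sref)
    for (da in xml2::xml_find_all(re, "./data")) {
      tref <- xml2::xml_attr(xml2::xml_find_first(da, "./tar"), "id")
      if (is.na(tref) || !tref %in% names(tdict_type))
        rdes_stop("FORMAT", "react %d references unknown target '%s'", rid, tref)
      cqn <- xml2::xml_find_first(da, "./cq")
      cq <- if (is.na(cqn)) NA_real_ else
        suppressWarnings(as.numeric(xml2::xml_text(cqn)))
      mtn <- xml2::xml_find_first(da, "./meltTemp")
      mt <- if (is.na(mtn)) NA_real_ else
        suppressWarnings(as.numeric(xml2::xml_text(mtn)))
      cyc <- num_texts(xml2::xml_find_all(da, "./adp/cyc"))
      afl <- num_texts(xml2::xml_find_all(da, "./adp/fluor"))
      tmp <- num_texts(xml2::xml_find_all(da, "./mdp/tmp"))
      mfl <- num_texts(xml2::xml_find_all(da, "./mdp/fluor"))
      if (length(cyc) && any(diff(cyc) <= 0))
        rdes_stop("FORMAT", "react %d: cycle data points not strictly increasing", rid)
      if (length(tmp) && any(diff(tmp) <= 0))
        rdes_stop("FORMAT", "react %d: melt data points not strictly increasing", rid)
      if (length(cyc)) {
        if (is.null(amp_axis)) amp_axis <- cyc
        else if (!isTRUE(all.equal(amp_axis, cyc)))
          rdes_stop("AXIS", "reactions carry differing cycle lists; cannot unify axis")
      }
      if (length(tmp)) {
        if (is.null(melt_axis)) melt_axis <- tmp
        else if (!isTRUE(all.equal(melt_axis, tmp)))
          rdes_stop("AXIS", "reactions carry differing temperature lists; cannot unify axis")
      }
      k <- k + 1L
      rows[[k]] <- data.frame(
        well_id = well, sample = sref, sample_type = unname(sdict[sref]),
        target = tref, target_type = unname(tdict_type[tref]),
        dye = unname(tdict_dye[tref]), reported_cq = cq, melt_temp = mt,
        stringsAsFactors = FALSE)
      amp_tr[[k]] <- if (length(cyc)) afl else NULL
      melt_tr[[k]] <- if (length(tmp)) mfl else NULL
    }
  }
  wells <- do.call(rbind, rows)
  meta <- list(rdml_version = version %||% "1.2", source = "rdml")

  build <- function(axis, tr_list, variant) {
    has <- !vapply(tr_list, is.null, logical(1))
    if (is.null(axis) || !any(has)) return(NULL)
    if (!all(has))
      rdes_stop("AXIS", "some reactions lack the %s data points others carry",
                if (variant == "amplification") "amplification" else "melt")
    tr <- do.call(rbind, tr_list)
    w <- wells
    if (variant == "melt") w$reported_cq <- w$melt_temp
    w$melt_temp <- NULL
    plate_table(w, tr, axis, variant, meta)
  }
  list(amp = build(amp_axis, amp_tr, "amplification"),
       melt = build(melt_axis, melt_tr, "melt"))
}

num_texts <- function(nodes) {
  if (length(nodes) == 0L) return(numeric(0))
  suppressWarnings(as.numeric(xml2::xml_text(nodes)))
}

load_rdml_doc <- function(doc) {
  if (inherits(doc, "xml_document")) return(doc)
  if (!is.character(doc) || length(doc) != 1L)
    rdes_stop("FORMAT", "doc must be a path, an XML string, or an xml_document")
  if (!grepl("<", doc, fixed = TRUE) && file.exists(doc)) {
    con <- file(doc, "rb"); magic <- readBin(con, "raw", 4L); close(con)
    if (length(magic) == 4L && identical(magic, as.raw(c(0x50, 0x4b, 0x03, 0x04)))) {
      tmp <- tempfile("rdml_unzip")
      entries <- utils::unzip(doc, exdir = tmp)
      pick <- entries[grepl("\\.(rdml|xml)$", entries, ignore.case = TRUE)]
      if (length(pick) == 0L) pick <- entries
      if (length(pick) == 0L) rdes_stop("FORMAT", "ZIP container holds no XML entry")
      return(xml2::read_xml(pick[1]))
    }
  }
  xml2::read_xml(doc)
}
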