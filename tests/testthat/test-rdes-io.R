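test_that("published table excerpt parses with annotations, Cq and traces intact", {
  p <- read_rdes(table1_path())
  expect_s3_class(p, "plate_table")
  expect_equal(p$variant, "amplification")
  expect_equal(length(p$axis), 45)
  expect_equal(n_wells(p), 12)

  a1 <- well_record(p, "A1")
  expect_equal(a1$reported_cq, 33.2)
  expect_equal(a1$sample, "Embryo_1")
  expect_equal(a1$sample_type, "unkn")
  expect_equal(a1$target_type, "toi")
  expect_equal(unname(a1$trace[1:4]), c(1.30, 1.28, 1.28, 1.27))
  expect_equal(unname(a1$trace[42:45]), c(15.10, 15.29, 15.34, 15.43))
  expect_true(all(is.na(a1$trace[5:41])))  # elided cycles
  expect_equal(well_record(p, "H12")$reported_cq, 19.0)
  expect_equal(unname(well_record(p, "A5")$trace[45]), 15.95)

  rep <- validate_plate(p)
  expect_equal(nrow(rep$errors), 0)
  expect_equal(rep$counts$n_cycles, 45)
  expect_equal(rep$counts$n_wells, 12)
})

test_that("reader handles delimiters, decimal commas, padded wells and Cq placeholders", {
  # semicolon-delimited with decimal commas, zero-padded well label
  lines <- c("Well;Sample;Sample type;Target;Target type;Dye;Cq;1;2;3",
             "A01;s1;unkn;g1;toi;SYBR;2,5;1,0;1,5;2,25")
  p <- read_rdes(lines)
  expect_equal(p$wells$well_id, "A1")
  expect_equal(p$wells$reported_cq, 2.5)
  expect_equal(p$traces[1, ], c(1.0, 1.5, 2.25))
  expect_equal(p$meta$delimiter, ";")

  # tab-delimited
  pt <- read_rdes(c("Well\tSample\tSample type\tTarget\tTarget type\tDye\tCq\t1\t2\t3",
                    "B2\ts\tstd\tg\tref\tFAM\t\t3\t4\t5"))
  expect_true(is.na(pt$wells$reported_cq))
  expect_equal(pt$wells$sample_type, "std")

  # Cq placeholder text is accepted with a warning
  expect_warning(
    pu <- read_rdes(c("Well,Sample,Sample type,Target,Target type,Dye,Cq,1,2,3",
                      "A1,s,unkn,g,toi,SYBR,Undetermined,1,2,3")),
    "placeholder")
  expect_true(is.na(pu$wells$reported_cq))
})

test_that("structural violations are refused with precise errors", {
  hdr <- "Well,Sample,Sample type,Target,Target type,Dye,Cq,1,2,3"
  expect_error(read_rdes(hdr), class = "rdes_empty_plate")
  expect_error(read_rdes(c("Well,Sample,Target,Dye,Cq,1,2", "A1,s,g,d,1,2,3")),
               "Sample type")
  expect_error(read_rdes(c(hdr, "A1,s,unkn,g,toi,SYBR,1,1,2")),
               class = "rdes_format", regexp = "ragged row")
  expect_error(read_rdes(c(hdr, "A1,s,unkn,g,toi,SYBR,1,1,oops,3")),
               class = "rdes_format", regexp = "row 1.*column '2'")
  # a gappy cycle axis parses but is flagged by the validator
  gap <- read_rdes(c("Well,Sample,Sample type,Target,Target type,Dye,Cq,1,2,4",
                     "A1,s,unkn,g,toi,SYBR,1,1,2,3"), "amplification")
  expect_true("AXIS_NOT_CYCLES" %in% validate_plate(gap)$errors$code)
})

test_that("validator applies vocabulary and identity rules with stable codes", {
  p <- tiny_plate()
  expect_equal(nrow(validate_plate(p)$errors), 0)

  dup <- p; dup$wells$well_id <- c("A1", "A1")
  expect_true("DUPLICATE_WELL" %in% validate_plate(dup)$errors$code)

  # same well, two dyes: allowed (multiplex)
  mux <- p; mux$wells$well_id <- c("A1", "A1"); mux$wells$dye <- c("FAM", "HEX")
  expect_equal(nrow(validate_plate(mux)$errors), 0)

  badtok <- p; badtok$wells$sample_type[1] <- "Unknown"
  expect_true("BAD_SAMPLE_TYPE" %in% validate_plate(badtok)$errors$code)
  badtt <- p; badtt$wells$target_type[1] <- "TOI"   # case-sensitive
  expect_true("BAD_TARGET_TYPE" %in% validate_plate(badtt)$errors$code)
  badid <- p; badid$wells$well_id[1] <- "Z99"
  expect_true("BAD_WELL_ID" %in% validate_plate(badid)$errors$code)
  badcq <- p; badcq$wells$reported_cq[1] <- 99
  expect_true("CQ_OUT_OF_RANGE" %in% validate_plate(badcq)$errors$code)

  js <- report_to_json(validate_plate(dup))
  parsed <- jsonlite::fromJSON(js)
  expect_equal(parsed$counts$n_wells, 2)
  expect_true("DUPLICATE_WELL" %in% parsed$errors$code)
})

test_that("public-deposition suggestion triggers at 20 samples and 20 targets only", {
  expect_true("GEO_DEPOSIT" %in%
                validate_plate(label_grid_plate(20, 20))$suggestions$code)
  expect_false("GEO_DEPOSIT" %in%
                 validate_plate(label_grid_plate(19, 20))$suggestions$code)
  expect_false("GEO_DEPOSIT" %in%
                 validate_plate(label_grid_plate(20, 19))$suggestions$code)
})

test_that("canonical writing is deterministic, sorted, and refuses invalid plates", {
  p <- tiny_plate()
  lines <- write_rdes(p)
  expect_match(lines[1], "^Well,Sample,Sample type,Target,Target type,Dye,Cq,1,2,3,4$")
  # absent Cq is an empty cell, not NA/NaN text
  expect_match(lines[3], "^A2,s2,ntc,g1,toi,SYBR,,", fixed = FALSE)
  expect_false(any(grepl("NaN|NA", lines[3])))

  # row-major well order regardless of record order
  sh <- p; ord <- c(2, 1)
  sh$wells <- sh$wells[ord, ]; sh$traces <- sh$traces[ord, ]
  expect_identical(write_rdes(sh), lines)

  dup <- p; dup$wells$well_id <- c("A1", "A1")
  expect_error(write_rdes(dup), class = "rdes_invalid_plate",
               regexp = "DUPLICATE_WELL")
})

test_that("read-write round trips are lossless and serialization is idempotent", {
  for (seed in 1:5) {
    sim <- simulate_amplification(n_samples = 2, n_targets = 3, n_cycles = 30,
                                  seed = seed)
    lines <- write_rdes(sim$plate)
    back <- read_rdes(lines)
    expect_true(plates_equal(sim$plate, back))
    expect_identical(write_rdes(back), lines)                    # canonical bytes
    expect_identical(write_rdes(read_rdes(write_rdes(back))), lines)
  }
  # the excerpt with elided cycles also round-trips (NA cells stay empty)
  p <- read_rdes(table1_path())
  expect_true(plates_equal(p, read_rdes(write_rdes(p))))
})

test_that("melt-variant tables are detected and round-trip with one-decimal headers", {
  sim <- simulate_melt(n_wells = 3, seed = 2)
  lines <- write_rdes(sim$plate)
  expect_match(lines[1], ",Tm,60.0,60.5,")
  back <- read_rdes(lines)
  expect_equal(back$variant, "melt")
  expect_true(plates_equal(sim$plate, back))
})
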