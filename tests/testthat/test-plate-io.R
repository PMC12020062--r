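test_that("filenames parse into file metadata by token content", {
  m <- parse_raw_filename("CTG_24h_R2_BEAS2B.csv")
  expect_equal(m$endpoint, "CTG")
  expect_equal(m$time_h, 24)
  expect_equal(m$replicate, 2L)
  expect_equal(m$cell_line, "BEAS-2B")

  # imaging files carry several endpoints, so no endpoint token
  m2 <- parse_raw_filename("imaging_72h_R4.txt")
  expect_true(is.na(m2$endpoint))
  expect_equal(m2$time_h, 72)
  expect_equal(m2$replicate, 4L)

  # nothing recognizable: all fields stay empty
  m3 <- parse_raw_filename("notes.bak")
  expect_true(all(is.na(unlist(m3[, -1]))))

  expect_error(parse_raw_filename("x.csv", pattern = list(sep = "_")),
               "pattern")
})

test_that("files-sheet auto-fill appends, harmonizes and is idempotent", {
  tpl <- annotation_template(simple_front_sheet())
  fns <- c("CTG_24h_R1_HEPG2.csv", "CTG_24h_R2_HEP-G2.csv",
           "imaging_24h_R1.txt")
  tpl <- autofill_files_sheet(fns, tpl)
  expect_equal(nrow(tpl$files_sheet), 3L)
  expect_equal(tpl$files_sheet$cell_line[1:2], c("HepG2", "HepG2"))

  # manual corrections survive a re-run
  tpl$files_sheet$endpoint[3] <- "DAPI"
  again <- autofill_files_sheet(fns, tpl)
  expect_identical(again$files_sheet, tpl$files_sheet)

  expect_error(autofill_files_sheet(c("a.csv", "a.csv"), tpl), "duplicate")
})

test_that("plate-reader CSVs parse into a 16 x 24 grid", {
  p <- tempfile(fileext = ".csv")
  write_plate_csv(p, value = 1, plate_id = "plateX")
  out <- read_plate_reader_table(p)
  expect_equal(out$plate_id, "plateX")
  expect_equal(dim(out$grid), c(16L, 24L))
  expect_true(all(out$grid == 1))

  # one empty cell becomes a missing value, the rest stay numeric
  g <- matrix(2, 16, 24)
  g[3, 7] <- NA
  write_plate_csv(p, grid = g)
  out2 <- read_plate_reader_table(p)
  expect_true(is.na(out2$grid[3, 7]))
  expect_equal(sum(!is.na(out2$grid)), 383L)

  # wrong dimensions are a format error naming the problem
  write_plate_csv(p, value = 1, n_rows = 15)
  expect_error(read_plate_reader_table(p), "16 rows")
})

test_that("imaging tables parse and keep DAPI technical duplicates", {
  p <- tempfile(fileext = ".txt")
  writeLines(c("A01\tDAPI\t523.0", "A01\tDAPI\t519.5", "A01\tH2AX\t301.2"),
             p)
  tab <- read_imaging_table(p)
  expect_equal(nrow(tab), 3L)
  expect_equal(tab$well, rep("A1", 3))
  expect_equal(sum(tab$endpoint == "DAPI"), 2L)
  expect_equal(tab$value[1], 523)

  writeLines(character(), p)
  expect_equal(nrow(read_imaging_table(p)), 0L)

  writeLines("B02\tWEIRD\t1.0", p)
  expect_warning(tab3 <- read_imaging_table(p), "unknown endpoint")
  expect_equal(tab3$endpoint, "WEIRD")
})

test_that("annotation joins every well to its material and role", {
  dir <- tempfile()
  dir.create(dir)
  write_plate_csv(file.path(dir, "CTG_24h_R1_BEAS2B.csv"), value = 100)
  tpl <- annotation_template(simple_front_sheet())
  tpl <- autofill_files_sheet("CTG_24h_R1_BEAS2B.csv", tpl)
  ds <- annotate_dataset(file.path(dir, "CTG_24h_R1_BEAS2B.csv"),
                         character(), tpl)
  expect_named(ds, "CTG")
  expect_equal(nrow(ds$CTG$data), 384L)
  ctrl <- ds$CTG$data[ds$CTG$data$role == "control", ]
  expect_true(all(ctrl$dose_value == 0))
  expect_equal(nrow(ctrl), 32L)

  # a file the sheet does not know is an error naming the file
  write_plate_csv(file.path(dir, "CTG_6h_R1_BEAS2B.csv"), value = 1)
  expect_error(
    annotate_dataset(file.path(dir, "CTG_6h_R1_BEAS2B.csv"), character(),
                     tpl),
    "CTG_6h_R1_BEAS2B.csv"
  )

  # a well missing from the front sheet is an error naming plate and well
  tpl2 <- tpl
  tpl2$front_sheet <- tpl2$front_sheet[tpl2$front_sheet$well != "A1", ]
  expect_error(
    annotate_dataset(file.path(dir, "CTG_24h_R1_BEAS2B.csv"), character(),
                     tpl2),
    "A1"
  )
})

test_that("annotation recovers the generator's truth for every well", {
  camp <- make_campaign(n_materials = 4, seed = 21, noise_cv = 0)
  ds <- ingest_campaign(camp$dir, camp$files$template_dir)
  front <- camp$truth |> (\(t) tox5r:::.front_layout(t))()
  for (ep in names(ds)) {
    d <- ds[[ep]]$data
    i <- match(d$well, front$well)
    expect_equal(d$material_id, front$material_id[i])
    expect_equal(d$dose_value, front$dose_value[i])
    expect_equal(d$role, front$role[i])
  }
  # no silent drops: records = wells x plates (x technical duplicates)
  n_plates <- nrow(camp$truth$plates)
  design <- camp$truth$design
  n_imaging <- sum(camp$truth$plates$kind == "imaging")
  n_ctg <- n_plates - n_imaging
  expect_equal(nrow(ds$CTG$data), 384L * n_ctg)
  expect_equal(nrow(ds$DAPI$data), 384L * n_imaging * 2L)
  expect_equal(nrow(ds$H2AX$data), 384L * n_imaging)
})

test_that("annotation templates survive a CSV round trip", {
  camp <- make_campaign(n_materials = 3, seed = 31, noise_cv = 0)
  tpl <- read_annotation_template(camp$files$template_dir)
  expect_s3_class(tpl, "annotation_template")
  d2 <- file.path(tempfile(), "tpl")
  write_annotation_template(tpl, d2)
  tpl2 <- read_annotation_template(d2)
  expect_equal(tpl2$front_sheet, tpl$front_sheet)
  expect_equal(tpl2$files_sheet$filename, tpl$files_sheet$filename)
  expect_equal(tpl2$materials_sheet$sbet_m2g, tpl$materials_sheet$sbet_m2g)
})
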