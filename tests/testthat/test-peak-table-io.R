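# CSV round-trips, validation errors with coordinates, TNM parsing and
# breath/ambient/metadata alignment.

test_that("peak tables round-trip through write and read", {
  m <- matrix(c(1.5, 0, 2.25, 1e7), 2, 2,
              dimnames = list(c("s1", "s2"), c("Acetone", "Isoprene")))
  pt <- peak_table(m, "breath")
  f <- tempfile(fileext = ".csv")
  write_peak_table(pt, f)
  back <- read_peak_table(f, "breath")
  expect_identical(unclass(back), unclass(pt))
  # write(read(x)) reproduces the file byte for byte
  f2 <- tempfile(fileext = ".csv")
  write_peak_table(back, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("gzip-compressed tables are read transparently", {
  m <- matrix(1:4 * 1.0, 2, 2, dimnames = list(c("a", "b"), c("X", "Y")))
  f <- tempfile(fileext = ".csv.gz")
  con <- gzfile(f, "w")
  writeLines(c("sample_id,X,Y", "a,1,3", "b,2,4"), con)
  close(con)
  got <- unclass(read_peak_table(f, "breath"))
  attr(got, "kind") <- NULL
  expect_equal(got, m)
})

test_that("parse errors name the offending cell", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("sample_id,Acetone,Isoprene", "s1,5,-2", "s2,1,1"), f)
  expect_error(read_peak_table(f, "breath"), "s1.*Isoprene")
  writeLines(c("sample_id,Acetone", "s1,abc"), f)
  expect_error(read_peak_table(f, "breath"), "non-numeric")
  writeLines(c("sample_id,Acetone", "s1,1", "s1,2"), f)
  expect_error(read_peak_table(f, "breath"), "duplicate sample ids")
})

test_that("empty cells are read as non-detections (area 0)", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("sample_id,Acetone,Isoprene", "s1,,3", "s2,2,"), f)
  pt <- read_peak_table(f, "breath")
  expect_equal(unclass(pt)["s1", "Acetone"], 0)
  expect_equal(unclass(pt)["s2", "Isoprene"], 0)
})

test_that("a study-sized metadata table round-trips with correct group counts", {
  meta <- generate_cohort(cohort_config(112, 120, seed = 5,
                                        voc_specs = clean_voc_panel("X")))$meta
  f <- tempfile(fileext = ".csv")
  write_metadata(meta, f)
  back <- read_metadata(f)
  expect_equal(sum(back$group == "cancer"), 112)
  expect_equal(sum(back$group == "healthy"), 120)
  expect_equal(as.data.frame(back), as.data.frame(meta))
})

test_that("metadata validation enforces the case-control structure", {
  meta <- tiny_meta(3, 3)
  bad <- meta; bad$localization[bad$group == "healthy"][1] <- "central"
  expect_error(validate_metadata(bad), "localization")
  bad <- meta; bad$histology[bad$group == "healthy"][1] <- "adeno"
  expect_error(validate_metadata(bad), "histology")
  bad <- meta; bad$chf[bad$group == "healthy"][1] <- TRUE
  expect_error(validate_metadata(bad), "comorbidity")
  bad <- meta; bad$group[1] <- "unwell"
  expect_error(validate_metadata(bad), "unknown group label 'unwell'")
})

test_that("TNM codes parse to their components", {
  expect_equal(parse_tnm("T3N2M0")[1, ], c(t = 3, n = 2, m = 0))
  expect_equal(parse_tnm(c("T1N0M1", "T4N3M1"))[, "t"], c(1, 4))
  expect_error(parse_tnm("T3NXM0"), "malformed")
})

test_that("alignment with identical id sets is the identity", {
  co <- generate_cohort(cohort_config(5, 5, seed = 2))
  al <- align_cohort(co$breath, co$ambient, co$meta)
  expect_identical(unclass(al$breath), unclass(co$breath))
  expect_identical(unclass(al$ambient), unclass(co$ambient))
  expect_identical(al$meta$sample_id, rownames(co$breath))
})

test_that("alignment reorders shuffled inputs into breath order", {
  co <- generate_cohort(cohort_config(6, 6, seed = 4))
  shuffle <- sample(nrow(co$ambient))
  amb <- peak_table(unclass(co$ambient)[shuffle, , drop = FALSE], "ambient")
  al <- align_cohort(co$breath, amb, co$meta[rev(seq_len(nrow(co$meta))), ])
  expect_identical(unname(unclass(al$ambient)), unname(unclass(co$ambient)))
  expect_identical(al$meta$sample_id, rownames(co$breath))
})

test_that("a breath VOC missing from ambient is kept with zero background", {
  co <- generate_cohort(cohort_config(4, 4, seed = 6,
                                      voc_specs = clean_voc_panel(c("P", "Q"))))
  amb <- peak_table(unclass(co$ambient)[, "P", drop = FALSE], "ambient")
  expect_warning(al <- align_cohort(co$breath, amb, co$meta),
                 "absent from ambient.*Q")
  expect_true(all(unclass(al$ambient)[, "Q"] == 0))
  expect_identical(colnames(al$ambient), colnames(co$breath))
})

test_that("a breath sample without an ambient row is an error naming it", {
  co <- generate_cohort(cohort_config(3, 3, seed = 8))
  amb <- peak_table(unclass(co$ambient)[-1, , drop = FALSE], "ambient")
  expect_error(align_cohort(co$breath, amb, co$meta),
               rownames(co$breath)[1])
})

test_that("a mapping table lets one ambient row serve several breath samples", {
  co <- generate_cohort(cohort_config(2, 2, seed = 9,
                                      voc_specs = clean_voc_panel("X")))
  day <- matrix(c(5, 7), 2, 1, dimnames = list(c("day1", "day2"), "X"))
  amb <- peak_table(day, "ambient")
  mapping <- data.frame(sample_id = rownames(co$breath),
                        ambient_id = c("day1", "day1", "day2", "day2"))
  al <- align_cohort(co$breath, amb, co$meta, mapping)
  expect_equal(unname(unclass(al$ambient)[, "X"]), c(5, 5, 7, 7))
})
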