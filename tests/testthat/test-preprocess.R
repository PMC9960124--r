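# Ambient correction, detection rule, occurrence filter, denominator
# selection and ratio-feature construction.

test_that("ambient subtraction clamps negatives to zero", {
  b <- peak_table(matrix(c(100, 100, 150), 3, 1,
                         dimnames = list(paste0("s", 1:3), "V")), "breath")
  a <- peak_table(matrix(c(120, 0, 50), 3, 1,
                         dimnames = list(paste0("s", 1:3), "V")), "ambient")
  out <- subtract_ambient(b, a)
  expect_equal(unname(unclass(out)[, "V"]), c(0, 100, 100))
})

test_that("subtraction output is bounded by the breath input and non-negative", {
  co <- generate_cohort(cohort_config(30, 30, seed = 15))
  al <- align_cohort(co$breath, co$ambient, co$meta)
  out <- subtract_ambient(al$breath, al$ambient)
  expect_true(all(unclass(out) >= 0))
  expect_true(all(unclass(out) <= unclass(al$breath)))
})

test_that("the detection rule needs a 20% excess over ambient and a positive area", {
  b <- peak_table(matrix(c(130, 119, 1, 120), 4, 1,
                         dimnames = list(paste0("s", 1:4), "V")), "breath")
  a <- peak_table(matrix(c(100, 100, 0, 100), 4, 1,
                         dimnames = list(paste0("s", 1:4), "V")), "ambient")
  flags <- detect_flags(b, a, min_excess = 0.20)
  expect_equal(unname(flags[, "V"]), c(TRUE, FALSE, TRUE, TRUE))
})

test_that("the occurrence filter is strict: exactly 50% is dropped", {
  toy <- toy_filter_tables()
  flags <- detect_flags(toy$breath, toy$ambient)
  filt <- filter_vocs(flags)
  expect_setequal(filt$retained, toy$retained_expected)
  occ <- filt$occurrence
  expect_equal(occ$overall[occ$voc == "C"], 0.5)   # dropped despite 50%
  expect_equal(occ$overall[occ$voc == "E"], 0)
  expect_error(filter_vocs(flags[0, , drop = FALSE]), "empty")
})

test_that("raising the occurrence threshold never enlarges the retained set", {
  co <- generate_cohort(cohort_config(60, 60, seed = 17))
  al <- align_cohort(co$breath, co$ambient, co$meta)
  flags <- detect_flags(al$breath, al$ambient)
  prev <- filter_vocs(flags, min_occurrence = 0)$retained
  for (thr in c(0.2, 0.4, 0.5, 0.6, 0.8, 0.95)) {
    cur <- filter_vocs(flags, min_occurrence = thr)$retained
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("the blocklist removes bag contaminants regardless of frequency", {
  toy <- toy_filter_tables()
  flags <- detect_flags(toy$breath, toy$ambient)
  filt <- filter_vocs(flags, blocklist = "A")
  expect_setequal(filt$retained, c("B", "F"))
})

test_that("denominator selection on the reference frequencies yields the ten main VOCs", {
  occ <- default_occurrence_report()
  dens <- select_denominators(occ, 0.86)
  expect_length(dens, 10)
  expect_setequal(dens, c("Isoprene", "Acetone", "Dimethylsulfide",
                          "1-Methylthiopropene", "Allyl methyl sulfide",
                          "1-Methylthiopropane", "2-Pentanone",
                          "Dimethyl disulfide", "2.3-Butandione",
                          "Acetonitrile"))
  expect_true("Acetonitrile" %in% dens)      # 87/88 just clears the bar
  expect_false("2-Butanone" %in% dens)       # 76/86 fails in the patient group
  # only the always-detected compounds survive a 100% requirement
  expect_setequal(select_denominators(occ, 1.0),
                  c("Acetone", "Isoprene", "Dimethylsulfide"))
  # threshold 0 admits everything
  expect_setequal(select_denominators(occ, 0), occ$voc)
  expect_error(select_denominators(occ, 2), "threshold")
})

test_that("ratio features follow the zero-numerator and zero-denominator rules", {
  m <- matrix(c(0, 8, 5,
                5, 4, 0), 3, 2,
              dimnames = list(paste0("s", 1:3), c("Num", "Den")))
  pt <- peak_table(m, "breath")
  feats <- build_ratio_features(pt, c("Num", "Den"), "Den")
  expect_equal(unname(feats[, "Num/Den"]), c(0, 2, NA))
  # masked denominator reduces the pairwise-complete n downstream
  r <- spearman_rho(feats[, "Num/Den"], c(1, 2, 3))
  expect_equal(r$n, 2)
  expect_error(build_ratio_features(pt, "Num", "Den"), "subset")
})

test_that("feature count matches the brute-force enumeration on a toy panel", {
  set.seed(19)
  m <- matrix(rlnorm(40, 13), 8, 5,
              dimnames = list(paste0("s", 1:8), paste0("V", 1:5)))
  pt <- peak_table(m, "breath")
  retained <- paste0("V", 1:5)
  dens <- c("V1", "V2")
  feats <- build_ratio_features(pt, retained, dens)
  brute <- c(retained,
             unlist(lapply(dens, function(d)
               paste0(setdiff(retained, d), "/", d))))
  expect_setequal(colnames(feats), brute)
  expect_equal(ncol(feats), length(retained) + length(dens) * (length(retained) - 1))
})

test_that("reciprocal ratios multiply to one where both are defined", {
  set.seed(23)
  m <- matrix(rlnorm(30, 13), 10, 3,
              dimnames = list(paste0("s", 1:10), c("A", "B", "C")))
  m[1, "A"] <- 0
  pt <- peak_table(m, "breath")
  feats <- build_ratio_features(pt, c("A", "B", "C"), c("A", "B"))
  prod_ab <- feats[, "A/B"] * feats[, "B/A"]
  defined <- !is.na(prod_ab) & feats[, "A/B"] > 0
  expect_true(all(abs(prod_ab[defined] - 1) < 1e-12))
})

test_that("the full preprocessing chain wires the pieces together", {
  co <- generate_cohort(cohort_config(80, 80, seed = 25))
  al <- align_cohort(co$breath, co$ambient, co$meta)
  pr <- preprocess_cohort(al)
  expect_true(all(pr$denominators %in% pr$retained))
  expect_equal(ncol(pr$features),
               length(pr$retained) +
                 length(pr$denominators) * (length(pr$retained) - 1))
  raw <- pr$features[, pr$retained]
  expect_true(all(raw >= 0))
  expect_error(
    preprocess_cohort(al, preprocess_config(min_occurrence = 0.999)),
    "no VOCs survive")
})
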