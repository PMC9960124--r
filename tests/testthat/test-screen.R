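# Spearman statistic, factor encodings, screening, confounder exclusion,
# age-independence check, top-feature selection and power analysis.

test_that("hand-computed Spearman values are reproduced", {
  expect_equal(spearman_rho(1:4, 1:4)$rho, 1)
  expect_equal(spearman_rho(1:4, 1:4)$p_value, 0)
  expect_equal(spearman_rho(1:4, c(1, 3, 2, 4))$rho, 0.8)
  # tie handled by average ranks: rho = 4.5 / sqrt(22.5)
  expect_equal(spearman_rho(c(1, 2, 2, 3), 1:4)$rho, 4.5 / sqrt(22.5))
})

test_that("rho and p agree with the reference implementation on random vectors", {
  set.seed(31)
  for (i in 1:200) {
    n <- sample(5:60, 1)
    x <- rnorm(n)
    y <- rnorm(n)
    if (i %% 2 == 0) {  # introduce ties
      x <- round(x, 1); y <- round(y, 1)
    }
    ref <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
    got <- spearman_rho(x, y)
    expect_equal(got$rho, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-9)
  }
})

test_that("the exact permutation p-value matches the exact reference for small n", {
  set.seed(33)
  for (i in 1:10) {
    x <- rnorm(7); y <- rnorm(7)
    ref <- cor.test(x, y, method = "spearman", exact = TRUE)
    expect_equal(spearman_rho(x, y, exact = TRUE)$p_value, ref$p.value,
                 tolerance = 1e-10)
  }
  expect_error(spearman_rho(rnorm(9), rnorm(9), exact = TRUE), "n <= 8")
})

test_that("spearman_rho has the invariances of a rank statistic", {
  set.seed(35)
  for (i in 1:25) {
    x <- rnorm(20); y <- rnorm(20)
    r <- spearman_rho(x, y)$rho
    expect_equal(spearman_rho(y, x)$rho, r)                 # symmetry
    expect_equal(spearman_rho(exp(x), y)$rho, r)            # monotone map
    expect_equal(spearman_rho(x, -y)$rho, -r)               # order reversal
  }
})

test_that("degenerate inputs give an undefined result, not an error", {
  expect_true(is.na(spearman_rho(c(1, 2), c(3, 4))$rho))
  r <- spearman_rho(c(1, 1, 1, 1), 1:4)
  expect_true(is.na(r$rho) && is.na(r$p_value))
  r2 <- spearman_rho(c(1, NA, NA, 4), c(1, 2, 3, 4))
  expect_equal(r2$n, 2)
  expect_true(is.na(r2$rho))
})

test_that("factor encodings follow the clinical conventions", {
  meta <- tiny_meta(40, 20)
  d <- encode_factor(meta, "disease")
  expect_equal(d, as.numeric(meta$group == "cancer"))
  tr <- encode_factor(meta, "treatment")
  expect_true(all(is.na(tr[meta$group == "healthy"])))
  expect_setequal(unique(tr[meta$group == "cancer"]), c(0, 1))
  # histology malignant-course ranking; non-differentiated masked out
  h <- encode_factor(meta, "histology")
  expect_equal(unname(h[meta$histology == "small_cell"][1]), 3)
  expect_equal(unname(h[meta$histology == "adeno"][1]), 2)
  expect_equal(unname(h[meta$histology == "squamous"][1]), 1)
  expect_true(all(is.na(h[meta$histology == "non_differentiated"])))
  expect_equal(sum(!is.na(h)),
               sum(meta$histology %in% c("squamous", "adeno", "small_cell")))
  # TNM lexicographic: T dominates N dominates M
  tn <- encode_factor(meta, "tnm")
  i1 <- which(meta$tnm_t == 1)[1]
  i2 <- which(meta$tnm_t == 2 & meta$tnm_n == 0 & meta$tnm_m == 0)[1]
  if (!is.na(i1) && !is.na(i2)) expect_lt(tn[i1], tn[i2])
  expect_true(all(is.na(tn[meta$group == "healthy"])))
  # localization orientation is configurable
  loc <- encode_factor(meta, "localization")
  loc_flip <- encode_factor(meta, "localization", central_high = FALSE)
  known <- !is.na(loc)
  expect_equal(loc[known], 1 - loc_flip[known])
  expect_error(encode_factor(meta, "weather"), "unknown factor")
})

test_that("TNM encoding sorts the tabulated codes lexicographically", {
  codes <- names(default_covariate_model()$tnm_counts)
  tnm <- parse_tnm(codes)
  score <- tnm[, "t"] * 100 + tnm[, "n"] * 10 + tnm[, "m"]
  # the oracle: ordering by score equals ordering rows lexicographically
  lex <- order(tnm[, "t"], tnm[, "n"], tnm[, "m"])
  expect_equal(order(score), lex)
})

test_that("a feature equal to the factor encoding screens at rho 1", {
  meta <- tiny_meta(10, 10)
  f <- matrix(encode_factor(meta, "disease"), ncol = 1,
              dimnames = list(meta$sample_id, "self"))
  s <- screen_features(f, meta, "disease")
  expect_equal(s$rho, 1)
  expect_true(s$significant)
})

test_that("a constant factor yields undefined-flagged results", {
  meta <- tiny_meta(8, 8)
  meta$treatment_status[meta$group == "cancer"] <- "under"
  f <- matrix(rnorm(16), ncol = 1, dimnames = list(meta$sample_id, "x"))
  s <- screen_features(f, meta, "treatment")
  expect_true(is.na(s$rho))
  expect_false(s$significant)
})

test_that("confounded features are excluded with the triggering factor recorded", {
  dis <- data.frame(feature_id = c("a", "b", "c"), factor = "disease",
                    rho = c(0.4, 0.3, 0.2), p_value = c(0.001, 0.002, 0.003),
                    n = 100, significant = TRUE)
  hyp <- data.frame(feature_id = c("b"), factor = "hypertension",
                    rho = -0.237, p_value = 0.01, n = 100, significant = TRUE)
  trt <- data.frame(feature_id = c("b", "c"), factor = "treatment",
                    rho = c(-0.2, 0.1), p_value = c(0.03, 0.5), n = 100,
                    significant = c(TRUE, FALSE))
  out <- exclude_confounded(dis, list(hyp, trt), alpha = 0.05)
  expect_setequal(out$surviving$feature_id, c("a", "c"))
  expect_equal(out$ledger$feature_id, "b")
  expect_match(out$ledger$excluded_by, "hypertension")
  expect_match(out$ledger$excluded_by, "treatment")
  # empty nuisance screens retain everything
  out2 <- exclude_confounded(dis, list(), alpha = 0.05)
  expect_equal(out2$surviving$feature_id, dis$feature_id)
  expect_equal(nrow(out2$ledger), 0)
})

test_that("the age check flags age itself and reports constants as undefined", {
  meta <- tiny_meta(60, 60)
  feats <- cbind(age_copy = meta$age, flat = rep(1, 120))
  rownames(feats) <- meta$sample_id
  rep <- check_age_independence(c("age_copy", "flat"), feats, meta)
  ac <- rep[rep$feature_id == "age_copy", ]
  expect_true(all(ac$flagged))
  expect_equal(ac$rho, rep(1, nrow(ac)))
  fl <- rep[rep$feature_id == "flat", ]
  expect_true(all(is.na(fl$rho)))
  expect_true(all(!fl$flagged))
})

test_that("top features are ordered by |rho| with a lexicographic tie-break", {
  sv <- data.frame(feature_id = c("zed", "abc", "mid", "low"),
                   factor = "disease",
                   rho = c(-0.5, 0.5, 0.3, 0.1),
                   p_value = 0.01, n = 100, significant = TRUE)
  sel <- select_top_features(sv, 3)
  expect_equal(sel, c("abc", "zed", "mid"))
  expect_warning(all_sel <- select_top_features(sv, 10), "only 4")
  expect_length(all_sel, 4)
})

test_that("the correlation power analysis reproduces the reference sample size", {
  expect_equal(required_sample_size(0.2, 0.05, 0.85), 221)
  # closed form at 50% power
  expect_equal(required_sample_size(0.2, 0.05, 0.5),
               round((qnorm(0.975) / atanh(0.2))^2 + 3))
  # near-unit correlations floor at the minimum feasible sample
  expect_equal(required_sample_size(0.9999), 4)
  expect_error(required_sample_size(0), "unbounded")
  # monotone: harder targets need more samples
  expect_gt(required_sample_size(0.1), required_sample_size(0.2))
  expect_gt(required_sample_size(0.2, alpha = 0.01), required_sample_size(0.2))
  expect_gt(required_sample_size(0.2, power = 0.95),
            required_sample_size(0.2, power = 0.85))
})
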