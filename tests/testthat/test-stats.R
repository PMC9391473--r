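test_that("per-scan and pooled summaries use the sample SD", {
  m <- array(7, c(3, 3, 1)); mask <- array(TRUE, c(3, 3, 1))
  expect_equal(per_scan_summary(m, mask), c(mean = 7, sd = 0))
  m[1:3] <- c(1, 2, 3); mask[] <- FALSE; mask[1:3] <- TRUE
  expect_equal(per_scan_summary(m, mask), c(mean = 2, sd = 1))
  expect_error(per_scan_summary(m, array(FALSE, c(3, 3, 1))), "empty")
  one <- array(FALSE, c(3, 3, 1)); one[1] <- TRUE
  expect_error(per_scan_summary(m, one), "single")
  expect_equal(overall_summary(c(1, 3)), c(mean_all = 2, sd_all = sqrt(2)))
  expect_error(overall_summary(5), "2 values")
})

test_that("variance components match hand-computed cases", {
  # subjects {1,3} and {2,4}: within-variances 2 and 2
  expect_equal(intra_var(c(1, 3, 2, 4), c(1, 1, 2, 2)), 2)
  # subject means 2 and 3 -> sample variance 0.5
  expect_equal(inter_var(c(1, 3, 2, 4), c(1, 1, 2, 2)), 0.5)
  expect_equal(intra_var(c(5, 5, 9, 9), c(1, 1, 2, 2)), 0)
  expect_equal(inter_var(c(5, 6, 5, 6), c(1, 1, 2, 2)), 0)
  expect_error(intra_var(c(1, 2, 3), c(1, 1, 2)), "2 scans")
  expect_error(inter_var(c(1, 2), c(1, 1)), "2 subjects")
})

test_that("statistics equal the brute-force oracles on random data", {
  set.seed(2024)
  for (rep in 1:100) {
    d <- random_grouped_data(sample(2:8, 1), sample(2:5, 1))
    expect_equal(intra_var(d$values, d$subject),
                 oracle_intra(d$values, d$subject), tolerance = 1e-12)
    expect_equal(inter_var(d$values, d$subject),
                 oracle_inter(d$values, d$subject), tolerance = 1e-12)
    expect_equal(cv_percent(d$values, d$subject),
                 oracle_cv(d$values, d$subject), tolerance = 1e-12)
    expect_equal(icc(inter_var(d$values, d$subject), intra_var(d$values, d$subject)),
                 oracle_inter(d$values, d$subject) /
                   (oracle_inter(d$values, d$subject) + oracle_intra(d$values, d$subject)),
                 tolerance = 1e-12)
  }
})

test_that("ICC is affine-invariant while CV is only scale-invariant", {
  set.seed(31)
  d <- random_grouped_data(6, 3)
  base_icc <- icc(inter_var(d$values, d$subject), intra_var(d$values, d$subject))
  base_cv <- cv_percent(d$values, d$subject)
  for (tf in list(c(2.5, 0), c(0.3, 40), c(-1.2, 200))) {
    v <- tf[1] * d$values + tf[2]
    expect_equal(icc(inter_var(v, d$subject), intra_var(v, d$subject)),
                 base_icc, tolerance = 1e-12)
  }
  expect_equal(cv_percent(3 * d$values, d$subject), base_cv, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(cv_percent(d$values + 100, d$subject), base_cv)))
})

test_that("CV and ICC handle edge cases per their definitions", {
  expect_equal(cv_percent(rep(c(10, 20), each = 3), rep(1:2, each = 3)), 0)
  # every subject mean 10, per-subject SD 1 -> 10%
  v <- c(9, 10, 11, 9, 10, 11)
  expect_equal(cv_percent(v, rep(1:2, each = 3)), 10)
  expect_error(cv_percent(c(-1, 1, 2, 2), c(1, 1, 2, 2)), "non-positive")
  expect_equal(icc(1344, 79), 0.94, tolerance = 0.005)
  expect_equal(icc(5, 0), 1)
  expect_equal(icc(0, 5), 0)
  expect_error(icc(0, 0), "undefined")
  expect_error(icc(-1, 2))
})

test_that("qualitative bands respect the stated boundaries", {
  expect_equal(classify_cv(c(6.9, 10, 10.1, 20, 25, 30, 35)),
               c("very good", "very good", "good", "good", "moderate",
                 "moderate", "poor"))
  expect_error(classify_cv(-1), "negative")
  expect_equal(classify_icc(c(0.39, 0.4, 0.59, 0.6, 0.61, 0.79, 0.8, 1)),
               c("poor", "fair/moderate", "fair/moderate", "good", "good",
                 "good", "very good", "very good"))
  expect_error(classify_icc(1.2), "0, 1")
  expect_equal(detectable_change(c(3.3, 0, 0.5)), c(6.6, 0, 1.0))
})

test_that("the repeatability table handles constants, gaps and round-trips", {
  set.seed(9)
  keys <- expand.grid(parameter = c("PD", "T1", "T2", "Na"),
                      tissue = c("GM", "WM", "CSF"), statistic = c("mean", "sd"),
                      stringsAsFactors = FALSE)
  rows <- do.call(rbind, lapply(seq_len(nrow(keys)), function(i)
    data.frame(subject = rep(1:4, each = 2), scan = rep(1:2, 4),
               keys[i, ], value = 50 + rnorm(8), row.names = NULL)))
  tab <- build_table(rows)
  expect_equal(nrow(tab), 24)
  const <- tab[tab$parameter == "PD" & tab$tissue == "CSF" & tab$statistic == "mean", ]
  expect_equal(const$mean_all, 1)
  expect_true(all(is.na(const[c("sd_all", "inter_var", "intra_var",
                                "cv_percent", "icc")])))
  expect_equal(tab$detectable_change_percent, 2 * tab$cv_percent)
  # zero-variance study: CV 0, ICC flagged not-applicable
  rows0 <- rows; rows0$value <- 42
  tab0 <- build_table(rows0)
  expect_true(all(tab0$cv_percent[!is.na(tab0$cv_percent)] == 0))
  expect_true(all(is.na(tab0$icc)))
  # missing key reported explicitly
  expect_error(build_table(rows[rows$tissue != "WM" | rows$parameter != "T2", ]),
               "missing measurement keys")
  # lossless CSV round-trip
  path <- tempfile(fileext = ".csv")
  write_repeatability_table(tab, path)
  back <- read_repeatability_table(path)
  expect_equal(as.data.frame(back), as.data.frame(tab), tolerance = 1e-15)
})

test_that("scan summaries flow from maps to the long format", {
  dist <- zero_noise_dist()
  geom <- make_geometry(phantom_spec(grid_shape = c(16, 16, 16)))
  study <- generate_study(study_design(2, 2, seed = 8),
                          phantom_spec(grid_shape = c(16, 16, 16)), dist,
                          geometry = geom)
  sm <- summarize_study(study)
  expect_setequal(names(sm), c("subject", "scan", "parameter", "tissue",
                               "statistic", "value"))
  expect_equal(nrow(sm), 2 * 2 * 24)
  # normalized PD CSF mean is 1 in every scan by construction
  pdcsf <- sm[sm$parameter == "PD" & sm$tissue == "CSF" & sm$statistic == "mean", ]
  expect_equal(pdcsf$value, rep(1, 4), tolerance = 1e-12)
  tab <- build_table(sm)
  expect_s3_class(tab, "repeatability_table")
  # statistics computed from the ingested long CSV equal the direct path
  path <- tempfile(fileext = ".csv")
  utils::write.csv(sm, path, row.names = FALSE)
  sm2 <- utils::read.csv(path, stringsAsFactors = FALSE)
  expect_equal(as.data.frame(build_table(sm2)), as.data.frame(tab), tolerance = 1e-12)
})
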