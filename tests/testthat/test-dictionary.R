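test_that("default grid enumerates the acquisition's matching axes", {
  g <- dictionary_grid()
  expect_length(g$t1_values, 70)
  expect_length(g$t2_values, 70)
  expect_length(g$b1_values, 121)
  expect_equal(g$t1_values[1], 150)
  expect_equal(g$t2_values[1], 15)
  expect_true(all(diff(g$t1_values) > 0) && max(g$t1_values) <= 4347)
  expect_true(all(diff(g$t2_values) > 0) && max(g$t2_values) <= 435)
  expect_equal(g$t1_values[-1] / g$t1_values[-70], rep(1.05, 69))
})

test_that("geometric axis handles degenerate and invalid ranges", {
  expect_equal(geometric_grid(100, 100), 100)
  expect_error(geometric_grid(-1, 10), "start")
  expect_error(geometric_grid(10, 100, ratio = 1), "ratio")
})

test_that("sliding window averages grouped samples", {
  expect_equal(sliding_window(c(1, 2, 3, 4), 2, 2), c(1.5, 3.5))
  x <- rnorm(20)
  expect_equal(sliding_window(x, 1, 1), x)               # identity
  expect_equal(sliding_window(rep(7, 15), 4, 3), rep(7, 4))  # constant in, constant out
  expect_length(sliding_window(rnorm(420), 8, 8), 52)
  expect_error(sliding_window(rnorm(5), 10, 1), "longer")
})

test_that("dictionary atoms are unit-norm windowed fingerprints", {
  train <- short_train()
  d <- build_dictionary(tiny_grid(), train, window_length = 4, window_stride = 4)
  expect_equal(sqrt(colSums(Mod(d$atoms)^2)), rep(1, ncol(d$atoms)), tolerance = 1e-12)
  expect_false(any(duplicated(d$params[, c("t1", "t2", "b1_deg")])))
  # an atom equals its directly simulated, windowed, normalized fingerprint
  i <- 5L
  fp <- simulate_fingerprint(tissue_params(d$params$t1[i], d$params$t2[i],
                                           b1 = d$params$b1_scale[i]),
                             train, max_order = d$max_order)
  w <- sliding_window(fp, 4, 4)
  expect_equal(d$atoms[, i], w / sqrt(sum(Mod(w)^2)), tolerance = 1e-12)
  expect_equal(d$norms[i], sqrt(sum(Mod(w)^2)), tolerance = 1e-12)
})

test_that("unphysical grid entries are excluded by default, kept on request", {
  g <- dictionary_grid(t1_min = 50, t1_max = 120, t2_min = 40, t2_max = 200,
                       b1_deg = 70)
  d <- build_dictionary(g, short_train())
  expect_true(all(d$params$t2 < d$params$t1))
  expect_gt(d$n_excluded, 0)
  g2 <- g; g2$include_unphysical <- TRUE
  d2 <- build_dictionary(g2, short_train())
  expect_equal(ncol(d2$atoms), ncol(d$atoms) + d$n_excluded)
})

test_that("atom norms scale linearly with m0", {
  train <- short_train()
  s1 <- sliding_window(simulate_fingerprint(tissue_params(900, 70, m0 = 1), train), 8, 8)
  s2 <- sliding_window(simulate_fingerprint(tissue_params(900, 70, m0 = 2), train), 8, 8)
  expect_equal(sqrt(sum(Mod(s2)^2)), 2 * sqrt(sum(Mod(s1)^2)), tolerance = 1e-12)
})

test_that("matching is exact for every atom of a small dictionary", {
  train <- short_train()
  d <- build_dictionary(tiny_grid(), train)
  for (i in seq_len(ncol(d$atoms))) {
    fp <- simulate_fingerprint(tissue_params(d$params$t1[i], d$params$t2[i],
                                             m0 = 1.7, b1 = d$params$b1_scale[i]),
                               train, max_order = d$max_order)
    m <- match_voxel(fp, d)
    expect_identical(c(m$t1, m$t2, m$b1_deg),
                     c(d$params$t1[i], d$params$t2[i], d$params$b1_deg[i]))
    expect_equal(m$score, 1, tolerance = 1e-9)
    expect_equal(m$pd, 1.7, tolerance = 1e-9)
  }
})

test_that("matching is invariant to global phase and scales pd linearly", {
  train <- short_train()
  d <- build_dictionary(tiny_grid(), train)
  fp <- simulate_fingerprint(tissue_params(d$params$t1[3], d$params$t2[3],
                                           b1 = d$params$b1_scale[3]), train,
                             max_order = d$max_order)
  m1 <- match_voxel(fp, d)
  m2 <- match_voxel(fp * 3 * exp(1.1i), d)
  expect_equal(c(m2$t1, m2$t2, m2$b1_deg), c(m1$t1, m1$t2, m1$b1_deg))
  expect_equal(m2$pd, 3 * m1$pd, tolerance = 1e-9)
  expect_equal(m2$score, m1$score, tolerance = 1e-12)
  expect_lte(m1$score, 1)
})

test_that("off-grid relaxation times match a bracketing grid point", {
  train <- short_train()
  d <- build_dictionary(tiny_grid(), train)
  t1s <- sort(unique(d$params$t1))
  t1mid <- sqrt(t1s[2] * t1s[3])   # geometric midpoint, off-grid
  fp <- simulate_fingerprint(tissue_params(t1mid, d$params$t2[1], b1 = 1), train,
                             max_order = d$max_order)
  m <- match_voxel(fp, d)
  expect_true(m$t1 %in% t1s[2:3])
})

test_that("degenerate signals are rejected with clear errors", {
  d <- build_dictionary(tiny_grid(), short_train())
  expect_error(match_voxel(complex(nrow(d$atoms)), d), "zero")
  bad <- rep(1 + 0i, nrow(d$atoms)); bad[2] <- NA
  expect_error(match_voxel(bad, d), "NaN|NA")
})

test_that("volume matching fills masked voxels and leaves the rest missing", {
  train <- short_train()
  d <- build_dictionary(tiny_grid(), train)
  fp <- simulate_fingerprint(tissue_params(d$params$t1[4], d$params$t2[4],
                                           b1 = d$params$b1_scale[4]), train,
                             max_order = d$max_order)
  w <- sliding_window(fp, d$window_length, d$window_stride)
  stack <- array(0i, c(2, 2, 1, length(w)))
  mask <- array(FALSE, c(2, 2, 1))
  mask[1, 1, 1] <- TRUE; mask[2, 2, 1] <- TRUE
  for (ii in which(mask)) stack[ii + c(0:(length(w) - 1)) * 4] <- w
  maps <- match_volume(stack, d, mask)
  expect_equal(maps$t1[mask], rep(d$params$t1[4], 2))
  expect_true(all(is.na(maps$t1[!mask])))
  # empty mask: all-missing maps
  maps0 <- match_volume(stack, d, array(FALSE, c(2, 2, 1)))
  expect_true(all(is.na(maps0$t1)))
  expect_error(match_volume(stack, d, array(FALSE, c(3, 2, 1))), "geometry")
})

test_that("dictionaries persist through the RDS + JSON container", {
  d <- build_dictionary(tiny_grid(), short_train())
  base <- tempfile()
  write_dictionary(d, base)
  expect_true(file.exists(paste0(base, ".json")))
  d2 <- read_dictionary(base)
  expect_equal(d2$atoms, d$atoms)
  expect_equal(d2$params, d$params)
  meta <- jsonlite::read_json(paste0(base, ".json"))
  expect_equal(meta$n_atoms, ncol(d$atoms))
})
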