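test_that("RF operator acts correctly on canonical states", {
  st <- epg_init(8, 1)
  expect_equal(epg_rf(st, 0, 0), st)                      # zero rotation
  inv <- epg_rf(st, 180, 33)                              # inversion
  expect_equal(Re(inv$Z[1]), -1, tolerance = 1e-12)
  expect_lt(max(Mod(inv$Fp), Mod(inv$Fm)), 1e-12)
  exc <- epg_rf(st, 90, 0)                                # full excitation
  expect_equal(Mod(exc$Fp[1]), 1, tolerance = 1e-12)
  expect_lt(Mod(exc$Z[1]), 1e-12)
  expect_equal(exc$Fm[1], Conj(exc$Fp[1]))
})

test_that("RF rotation conserves the EPG quadratic form on random states", {
  set.seed(101)
  for (rep in 1:20) {
    st <- epg_init(12, 1)
    st$Fp <- complex(real = rnorm(13), imaginary = rnorm(13))
    st$Fm <- complex(real = rnorm(13), imaginary = rnorm(13))
    st$Z <- complex(real = rnorm(13), imaginary = rnorm(13))
    a <- runif(1, 0, 360); p <- runif(1, 0, 360)
    expect_equal(epg_energy(epg_rf(st, a, p)), epg_energy(st), tolerance = 1e-10)
  }
})

test_that("relaxation follows the T1/T2 closed forms", {
  st <- epg_init(4, 1)
  expect_equal(epg_relax(st, 0, 800, 80, 1), st)
  # saturated Z0 recovers to m0/2 after t1*ln(2)
  st0 <- epg_rf(st, 90, 0)
  rec <- epg_relax(st0, 800 * log(2), 800, 80, 1)
  expect_equal(Re(rec$Z[1]), 0.5, tolerance = 1e-12)
  # transverse decay to 1/e after t2
  expect_equal(Mod(epg_relax(st0, 80, 800, 80, 1)$Fp[1]), exp(-1), tolerance = 1e-12)
})

test_that("gradient shift moves orders and conserves transverse power", {
  st <- epg_init(6, 1)
  expect_equal(epg_shift(st), st)          # all-zero F stays zero
  # single 90 then shift: F0+ fully dephased into order 1
  st1 <- epg_shift(epg_rf(st, 90, 0))
  expect_equal(Mod(st1$Fp[2]), 1, tolerance = 1e-12)
  expect_lt(Mod(st1$Fp[1]), 1e-12)
  # two shifts with no relaxation: total transverse power conserved
  set.seed(7)
  st2 <- epg_init(20, 1)
  st2$Fp[1:6] <- complex(real = rnorm(6), imaginary = rnorm(6))
  st2$Fm[1:6] <- complex(real = rnorm(6), imaginary = rnorm(6))
  st2$Fm[1] <- Conj(st2$Fp[1])
  # count each distinct dephasing order once (Fp[0] and Fm[0] are conjugates)
  pw <- function(s) sum(Mod(s$Fp)^2) + sum(Mod(s$Fm[-1])^2)
  before <- pw(st2)
  after <- pw(epg_shift(epg_shift(st2)))
  expect_equal(after, before, tolerance = 1e-12)
})

test_that("fingerprint simulation respects amplitude bounds and b1 scaling", {
  train <- short_train()
  expect_true(all(Mod(simulate_fingerprint(tissue_params(1000, 80, m0 = 2.5), train)) <= 2.5))
  # zero flip angles give zero signal
  tr0 <- pulse_train(rep(0, 20), rep(0, 20), 7.5, 2)
  expect_equal(max(Mod(simulate_fingerprint(tissue_params(1000, 80), tr0))), 0)
  # b1 acts multiplicatively on the nominal flips
  trA <- pulse_train(rep(15, 30), rep(0, 30), 7.5, 2)
  trB <- pulse_train(rep(30, 30), rep(0, 30), 7.5, 2)
  expect_equal(simulate_fingerprint(tissue_params(1000, 80, b1 = 2), trA),
               simulate_fingerprint(tissue_params(1000, 80, b1 = 1), trB))
})

test_that("compiled and reference engines agree to machine precision", {
  train <- make_pulse_train(n_pulses = 60, n_segments = 6, segment_gap_ms = 12)
  for (ts in list(tissue_params(1450, 40), tissue_params(940, 32, m0 = 0.66),
                  tissue_params(2570, 102, b1 = 1.2))) {
    a <- simulate_fingerprint(ts, train, engine = "reference")
    b <- simulate_fingerprint(ts, train, engine = "compiled")
    expect_lt(max(Mod(a - b)), 1e-13)
  }
  # inversion preparation path too
  a <- simulate_fingerprint(tissue_params(800, 60), short_train(),
                            inversion_prep = TRUE, engine = "reference")
  b <- simulate_fingerprint(tissue_params(800, 60), short_train(),
                            inversion_prep = TRUE, engine = "compiled")
  expect_lt(max(Mod(a - b)), 1e-13)
})

test_that("doubling the truncation order beyond n_pulses changes nothing", {
  train <- pulse_train(rep(25, 30), rep(0, 30), 7.5, 2)
  ts <- tissue_params(1000, 200)
  expect_equal(simulate_fingerprint(ts, train, max_order = 30),
               simulate_fingerprint(ts, train, max_order = 60))
})

test_that("constant-flip tail reaches the spoiled-GRE closed form when t2 << tr", {
  train <- pulse_train(rep(20, 1200), rep(0, 1200), tr = 7.5, te = 2)
  s <- simulate_fingerprint(tissue_params(800, 1), train)
  expect_equal(Mod(s[1200]), ernst_signal(20, 800, 1, 7.5, 2),
               tolerance = 0.01)
})

test_that("non-physical and invalid tissue parameters are rejected", {
  expect_error(tissue_params(-5, 40), "t1")
  expect_error(tissue_params(1000, 0), "t2")
  expect_error(tissue_params(100, 200), "unphysical")
  expect_s3_class(tissue_params(100, 200, allow_unphysical = TRUE), "tissue_params")
})

test_that("pulse trains round-trip through CSV", {
  train <- make_pulse_train(n_pulses = 36, n_segments = 6, segment_gap_ms = 5)
  path <- tempfile(fileext = ".csv")
  write_pulse_train(train, path)
  back <- read_pulse_train(path)
  expect_equal(back$flip_deg, train$flip_deg)
  expect_equal(back$pre_delay_ms, train$pre_delay_ms)
  expect_equal(back$tr, train$tr)
  expect_equal(back$te, train$te)
})
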