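test_that("truncation cuts or zero-pads to the analysis window", {
  ir <- binaural_ir(rnorm(4096), rnorm(4096))
  tr <- truncate_ir(ir, 128)
  expect_length(tr$left, 128)
  expect_equal(tr$left, ir$left[1:128])
  # 128 samples at 48 kHz print as 2.7 ms
  expect_equal(round(128 / 48000 * 1000, 1), 2.7)

  short <- binaural_ir(rnorm(64), rnorm(64))
  expect_warning(pad <- truncate_ir(short, 128), "zero-padding")
  expect_length(pad$left, 128)
  expect_equal(pad$left[65:128], numeric(64))
})

test_that("minimum phase preserves magnitude and front-loads energy", {
  # already minimum phase: unit impulse unchanged
  expect_equal(minimum_phase(c(1, numeric(31))), c(1, numeric(31)))
  # a pure delay is all-pass: collapses to an impulse at zero
  expect_equal(minimum_phase(c(numeric(17), 1, numeric(14))),
               c(1, numeric(31)))
  expect_error(minimum_phase(numeric(16)), "all-zero")

  set.seed(41)
  for (i in 1:20) {
    x <- rnorm(128)
    m <- minimum_phase(x)
    X <- Mod(stats::fft(c(x, numeric(384))))
    M <- Mod(stats::fft(c(m, numeric(384))))
    expect_lt(max(abs(20 * log10(X / M))), 1e-6)
    # cumulative energy dominance: minimum phase is maximally front-loaded
    expect_true(all(cumsum(m^2) - cumsum(x^2) > -1e-9))
  }
})

test_that("ear_delay matches a brute-force cross-correlation argmax", {
  expect_equal(ear_delay(c(1, 0.5, numeric(30))), 0)
  expect_equal(ear_delay(c(numeric(17), 1, numeric(14))), 17)

  # known construction: minimum-phase reference delayed by k
  set.seed(42)
  ref <- minimum_phase(rnorm(64))
  for (k in c(0, 3, 11)) {
    expect_equal(ear_delay(c(numeric(k), ref, numeric(16))), k)
  }

  brute_delay <- function(x) {
    m <- minimum_phase(x)
    n <- length(x)
    lags <- -(n - 1):(n - 1)
    r <- vapply(lags, function(l) {
      idx <- seq_len(n)
      valid <- idx - l >= 1 & idx - l <= n
      sum(x[idx[valid]] * m[idx[valid] - l])
    }, numeric(1))
    lags[which.max(r)]
  }
  for (i in 1:200) {
    x <- rnorm(128)
    expect_equal(ear_delay(x), brute_delay(x))
  }
})

test_that("ITD is sample-exact and antisymmetric under channel swap", {
  ir <- binaural_ir(c(1, numeric(63)), c(1, numeric(63)))
  expect_equal(itd_us(ir), 0)

  base <- minimum_phase(c(1, 0.4, 0.1, numeric(61)))
  d3 <- binaural_ir(c(numeric(3), base[1:61]), base, fs = 48000)
  expect_equal(itd_us(d3), 3 / 48000 * 1e6)  # +62.5 us, left lags

  set.seed(43)
  for (i in 1:20) {
    l <- rnorm(128); r <- rnorm(128)
    a <- binaural_ir(l, r)
    b <- binaural_ir(r, l)
    expect_equal(itd_us(a), -itd_us(b))
  }
})

test_that("imposed integer interchannel delays are recovered exactly", {
  set.seed(44)
  ref <- minimum_phase(rnorm(96))
  for (d in -10:10) {
    l <- if (d >= 0) c(numeric(d), ref, numeric(10 - d)) else c(ref, numeric(10))
    r <- if (d >= 0) c(ref, numeric(10)) else c(numeric(-d), ref, numeric(10 + d))
    ir <- binaural_ir(l, r, fs = 48000)
    expect_equal(itd_us(ir), d / 48000 * 1e6)
  }
})

test_that("spectral difference responds to broadband gain and is gain-invariant", {
  p <- null_pair(30)
  sd0 <- spectral_difference(p$with_hmd, p$without_hmd, "left")
  expect_equal(unname(sd0), c(0, 0, 0))

  g <- p
  g$with_hmd$left <- g$with_hmd$left * 10^(3 / 20)
  sd3 <- spectral_difference(g$with_hmd, g$without_hmd, "left")
  expect_equal(unname(sd3), c(3, 3, 3), tolerance = 1e-9)

  # common gain on both conditions cancels
  g2 <- g
  g2$with_hmd$left <- g2$with_hmd$left * 0.25
  g2$without_hmd$left <- g2$without_hmd$left * 0.25
  expect_equal(spectral_difference(g2$with_hmd, g2$without_hmd, "left"), sd3,
               tolerance = 1e-9)

  bad <- p$without_hmd; bad$fs <- 44100
  expect_error(spectral_difference(p$with_hmd, bad, "left"), "sampling rates")
})

test_that("regional ILD follows interaural gain arithmetic", {
  ir <- binaural_ir(c(1, numeric(63)), c(1, numeric(63)))
  expect_equal(unname(ild_regions(ir)), c(0, 0, 0), tolerance = 1e-9)
  half <- binaural_ir(c(1, numeric(63)), 0.5 * c(1, numeric(63)))
  expect_equal(unname(ild_regions(half)), rep(20 * log10(2), 3), tolerance = 1e-9)
})

test_that("cue errors vanish for identical condition pairs", {
  p <- null_pair(45)
  ce <- cue_errors(p$with_hmd, p$without_hmd)
  expect_equal(unname(ce$sd_left), c(0, 0, 0))
  expect_equal(unname(ce$sd_right), c(0, 0, 0))
  expect_equal(unname(ce$ild_error), c(0, 0, 0))
  expect_equal(ce$itd_error_us, 0)

  other <- spherical_head_brir(60)
  other$condition <- "without_hmd"
  expect_error(cue_errors(p$with_hmd, other), "same source")
})

test_that("cue_table emits one row per source and region", {
  pairs <- list(make_pair(0), make_pair(45), make_pair(75))
  tab <- cue_table(pairs)
  expect_equal(nrow(tab), 9)
  expect_setequal(unique(tab$region), c("low", "mid", "high"))
  expect_true(all(tab$sd_left_db >= 0))
  # ITD error identical across regions of one source
  expect_length(unique(tab$itd_error_us[tab$azimuth_deg == 75]), 1)
})
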