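test_that("the condition table mirrors the experimental design", {
  ct <- condition_table()
  expect_equal(nrow(ct), 8)
  expect_equal(sum(ct$visual_localization), 2)
  expect_equal(sum(ct$laser), 1)
  expect_equal(sum(ct$hmd), 5)
  expect_setequal(unique(ct$block), c("I", "II", "III", "IV"))
  expect_false(any(duplicated(ct$condition)))
})

test_that("handedness mirroring negates azimuths and is an involution", {
  r <- make_records(handedness = "left", offset_az = 5)
  m <- mirror_handedness(r)
  expect_equal(m$target_azimuth_deg, -r$target_azimuth_deg)
  expect_equal(m$response_azimuth_deg, -r$response_azimuth_deg)
  expect_equal(m$response_elevation_deg, r$response_elevation_deg)
  expect_equal(mirror_handedness(m)[names(r)], m[names(r)])  # no double mirror

  rr <- make_records(handedness = "right")
  expect_equal(mirror_handedness(rr)$response_azimuth_deg, rr$response_azimuth_deg)
})

test_that("pointing bias is the mean error over the visual conditions", {
  rec <- bias_fixture(offsets_az = c(2, -4), offsets_el = c(10, 6))
  b <- estimate_pointing_bias(rec)
  expect_equal(b$azimuth_bias, -1)    # mean of 2 and -4
  expect_equal(b$elevation_bias, 8)   # mean of 10 and 6
  expect_equal(sort(b$per_subject$azimuth_bias), c(-4, 2))
  expect_equal(b$per_subject$n, c(12, 12))

  expect_error(estimate_pointing_bias(rec[0, ]), "no response records")
  # a subject with only acoustic trials is excluded with a warning
  extra <- rbind(rec, make_records(subject = "S03"))
  expect_warning(b2 <- estimate_pointing_bias(extra), "S03")
  expect_equal(nrow(b2$per_subject), 2)
})

test_that("bias correction restores targets everywhere but the laser condition", {
  rec <- bias_fixture(offsets_az = c(2, 2), offsets_el = c(10, 10))
  laser_cond <- condition_table()$condition[condition_table()$laser]
  acou <- make_records(subject = "S01", offset_az = 2, offset_el = 10)
  laser <- make_records(subject = "S01", condition = laser_cond,
                        offset_az = 2, offset_el = 10)
  all_rec <- rbind(rec, acou, laser)
  b <- estimate_pointing_bias(all_rec)
  corr <- apply_bias_correction(all_rec, b)

  fixed <- corr$condition != laser_cond
  expect_equal(corr$response_azimuth_deg[fixed], corr$target_azimuth_deg[fixed])
  expect_equal(corr$response_elevation_deg[fixed], corr$target_elevation_deg[fixed])
  # laser rows pass through unchanged
  expect_equal(corr[corr$condition == laser_cond, "response_azimuth_deg"],
               all_rec[all_rec$condition == laser_cond, "response_azimuth_deg"])

  # zero bias is the identity
  zb <- b; zb$per_subject$azimuth_bias <- 0; zb$per_subject$elevation_bias <- 0
  corr0 <- apply_bias_correction(all_rec, zb)
  expect_equal(corr0$response_azimuth_deg, all_rec$response_azimuth_deg)

  expect_error(apply_bias_correction(rbind(rec, make_records(subject = "S09")), b),
               "S09")
})

test_that("re-estimating bias after correction gives zero", {
  set.seed(61)
  rec <- simulate_responses(seed = 61)
  rec <- mirror_handedness(rec)
  b <- estimate_pointing_bias(rec)
  corr <- apply_bias_correction(rec, b)
  b2 <- estimate_pointing_bias(corr)
  expect_lt(abs(b2$azimuth_bias), 1e-9)
  expect_lt(abs(b2$elevation_bias), 1e-9)
})

test_that("the outlier rule is strict and monotone in the threshold", {
  r <- make_records(az = 0, el = 0)
  r$response_azimuth_deg <- c(46)   # az error 46, el error 0
  expect_equal(nrow(filter_outliers(r)$removed), 1)

  r$response_azimuth_deg <- 45      # exactly at the boundary: kept
  f <- filter_outliers(r)
  expect_equal(nrow(f$removed), 0)
  expect_equal(f$removed_fraction, 0)

  r2 <- make_records(az = c(-30, 0, 30), el = 0, offset_az = 0)
  r2$response_elevation_deg <- c(0, 50, -80)
  expect_equal(nrow(filter_outliers(r2)$kept), 1)

  set.seed(62)
  rec <- simulate_responses(seed = 62)
  n_removed <- sapply(c(20, 45, 60, 200), function(th) {
    nrow(filter_outliers(rec, th)$removed)
  })
  expect_true(all(diff(n_removed) <= 0))
  expect_equal(n_removed[4], 0)  # nothing beyond 200 degrees
})

test_that("error summaries match direct and streaming computation", {
  one <- make_records(az = 10, el = 0)
  one$response_azimuth_deg <- 15
  s1 <- summarize_errors(one, keys = "condition")
  az1 <- s1[s1$dimension == "azimuth", ]
  expect_equal(az1$mean_absolute, 5)
  expect_equal(az1$median_signed, 5)
  expect_equal(az1$q1, 5)
  expect_equal(az1$q3, 5)

  three <- make_records(az = c(-30, 0, 30), el = 0)
  three$response_azimuth_deg <- three$target_azimuth_deg + c(-2, 0, 2)
  s3 <- summarize_errors(three, keys = "condition")
  az3 <- s3[s3$dimension == "azimuth", ]
  expect_equal(az3$mean_absolute, 4 / 3)
  expect_equal(az3$median_signed, 0)

  # streaming (single-pass running sums) oracle for group means
  set.seed(63)
  rec <- simulate_responses(n_subjects = 3, seed = 63)
  tab <- summarize_errors(rec, keys = "condition")
  err <- signed_errors(rec$target_azimuth_deg, rec$target_elevation_deg,
                       rec$response_azimuth_deg, rec$response_elevation_deg)
  for (cond in unique(rec$condition)) {
    sel <- rec$condition == cond
    acc <- 0; k <- 0
    for (v in abs(err$azimuth_error[sel])) { k <- k + 1; acc <- acc + (v - acc) / k }
    got <- tab$mean_absolute[tab$condition == cond & tab$dimension == "azimuth"]
    expect_equal(got, acc, tolerance = 1e-12)
  }
  # cell counts cover every record once per dimension
  expect_equal(sum(tab$n), 2 * nrow(rec))
  expect_true(all(tab$q1 <= tab$median_signed & tab$median_signed <= tab$q3))
})

test_that("hemifield contrasts recover a constructed left overshoot", {
  mk <- function(az, extra_left) {
    r <- make_records(az = az, el = 0, condition = "I-blindfolded-acoustic-nohmd")
    overshoot <- ifelse(az < 0, -(2 + extra_left), 2) * (abs(az) > 0)
    r$response_azimuth_deg <- r$target_azimuth_deg + overshoot
    r
  }
  rec <- do.call(rbind, lapply(c(-60, -30, 0, 30, 60), mk, extra_left = 2))
  tab <- summarize_errors(rec, keys = c("condition", "target_azimuth_deg"))
  hc <- hemifield_contrast(tab[tab$dimension == "azimuth", ])
  expect_setequal(hc$abs_azimuth_deg, c(30, 60))
  expect_true(all(hc$d_mean_absolute > 0))  # left error exceeds right
  expect_false(0 %in% hc$abs_azimuth_deg)

  # symmetric errors give zero contrast
  rec_sym <- do.call(rbind, lapply(c(-60, -30, 0, 30, 60), mk, extra_left = 0))
  tab_sym <- summarize_errors(rec_sym, keys = c("condition", "target_azimuth_deg"))
  hc_sym <- hemifield_contrast(tab_sym[tab_sym$dimension == "azimuth", ])
  expect_equal(hc_sym$d_mean_absolute, c(0, 0))

  # a missing mirror cell is skipped with a warning
  expect_warning(
    hemifield_contrast(tab[tab$dimension == "azimuth" &
                             tab$target_azimuth_deg != -30, ]),
    "missing mirror")
})
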