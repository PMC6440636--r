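test_that("plane_normal is translation-invariant with a deterministic sign", {
  t1 <- tracker_set(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  expect_equal(plane_normal(t1), c(0, 0, 1))
  t2 <- tracker_set(c(5, 5, 5), c(6, 5, 5), c(5, 6, 5))
  expect_equal(plane_normal(t2), c(0, 0, 1))
  # plane z = x: normal proportional to (-1, 0, 1)
  t3 <- tracker_set(c(0, 0, 0), c(1, 0, 1), c(0, 1, 0))
  expect_equal(plane_normal(t3), c(-1, 0, 1) / sqrt(2))
  expect_error(tracker_set(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2)), "collinear")
})

test_that("rotation_between handles parallel, generic and antiparallel pairs", {
  expect_equal(rotation_between(c(0, 0, 1), c(0, 0, 1)), diag(3))
  R90 <- rotation_between(c(1, 0, 0), c(0, 1, 0))
  expect_equal(as.numeric(R90 %*% c(1, 0, 0)), c(0, 1, 0), tolerance = 1e-12)
  expect_equal(det(R90), 1, tolerance = 1e-12)
  Rap <- rotation_between(c(1, 0, 0), c(-1, 0, 0))
  expect_equal(as.numeric(Rap %*% c(1, 0, 0)), c(-1, 0, 0), tolerance = 1e-12)
  expect_equal(det(Rap), 1, tolerance = 1e-12)
  expect_equal(max(abs(crossprod(Rap) - diag(3))), 0, tolerance = 1e-12)
})

test_that("calibrate recovers rigid displacements of the tracker frame", {
  real <- default_tracker_points()
  expect_equal(alignment_residual(calibrate(real, real), real, real)$max_offset,
               0, tolerance = 1e-12)

  # pure translation
  v <- unclass(real) + matrix(rep(c(0.1, 0, 0), each = 3), 3)
  tr <- calibrate(real, tracker_set(v[1, ], v[2, ], v[3, ]))
  expect_equal(tr$rotation, diag(3), tolerance = 1e-9)
  expect_equal(tr$translation, c(-0.1, 0, 0), tolerance = 1e-9)

  # apply-and-recover across random displacements, every reference point
  set.seed(21)
  for (i in 1:200) {
    disp <- random_rigid_transform()
    vm <- apply_transform(disp, unclass(real))
    virtual <- tracker_set(vm[1, ], vm[2, ], vm[3, ])
    tr <- calibrate(real, virtual, reference_index = sample(3, 1))
    expect_lt(alignment_residual(tr, real, virtual)$max_offset, 1e-9)
  }
})

test_that("three-step calibration agrees with least-squares registration", {
  real <- default_tracker_points()
  set.seed(22)
  for (i in 1:50) {
    disp <- random_rigid_transform()
    vm <- apply_transform(disp, unclass(real))
    virtual <- tracker_set(vm[1, ], vm[2, ], vm[3, ])
    t3 <- calibrate(real, virtual)
    tls <- kabsch(unclass(real), unclass(virtual))
    expect_lt(max(abs(apply_transform(t3, vm) - apply_transform(tls, vm))), 1e-6)
  }
})

test_that("calibration is invariant to relabeling the non-reference points", {
  real <- default_tracker_points()
  set.seed(23)
  disp <- random_rigid_transform()
  vm <- apply_transform(disp, unclass(real))
  t1 <- calibrate(real, tracker_set(vm[1, ], vm[2, ], vm[3, ]))
  # swap points 2 and 3 in both frames
  r2 <- unclass(real)[c(1, 3, 2), ]
  t2 <- calibrate(tracker_set(r2[1, ], r2[2, ], r2[3, ]),
                  tracker_set(vm[1, ], vm[3, ], vm[2, ]))
  probe <- c(0.3, -0.2, 1.1)
  expect_equal(apply_transform(t1, probe), apply_transform(t2, probe),
               tolerance = 1e-9)
})

test_that("the 2 cm trigger fires iff the residual exceeds the threshold", {
  real <- default_tracker_points()
  res0 <- alignment_residual(calibrate(real, real), real, real)
  expect_false(res0$recalibrate)
  expect_equal(res0$max_offset, 0, tolerance = 1e-12)

  perturb <- function(d) {
    v <- unclass(real); v[2, ] <- v[2, ] + c(0, 0, d)
    alignment_residual(rigid_transform(), real, tracker_set(v[1, ], v[2, ], v[3, ]))
  }
  expect_true(perturb(0.03)$recalibrate)
  expect_gte(perturb(0.03)$max_offset, 0.02)
  expect_false(perturb(0.01)$recalibrate)
})

test_that("worst-case rotation matches the small-angle geometry", {
  # 2 cm over the 0-to-45-degree tracker chord
  chord <- sqrt(sum((unclass(default_tracker_points())[1, ] -
                       unclass(default_tracker_points())[2, ])^2))
  ang <- worst_case_rotation_deg(0.02, chord)
  expect_equal(ang, asin(0.02 / chord) * 180 / pi)
  expect_error(worst_case_rotation_deg(0.02, 0.01))
})

test_that("transforms and tracker sets round-trip through disk", {
  tmp <- withr::local_tempdir()
  set.seed(24)
  tr <- random_rigid_transform()
  f <- file.path(tmp, "t.json")
  write_transform(tr, f)
  tr2 <- read_transform(f)
  expect_equal(tr2$rotation, tr$rotation, tolerance = 1e-12)
  expect_equal(tr2$translation, tr$translation, tolerance = 1e-12)

  real <- default_tracker_points()
  vm <- apply_transform(tr, unclass(real))
  csv <- file.path(tmp, "trackers.csv")
  utils::write.csv(data.frame(
    frame = rep(c("real", "virtual"), each = 3), point_id = rep(1:3, 2),
    x = c(real[, 1], vm[, 1]), y = c(real[, 2], vm[, 2]),
    z = c(real[, 3], vm[, 3])), csv, row.names = FALSE)
  ts <- read_tracker_sets(csv)
  expect_equal(unclass(ts$real), unclass(real), ignore_attr = TRUE)
  expect_lt(alignment_residual(calibrate(ts$real, ts$virtual),
                               ts$real, ts$virtual)$max_offset, 1e-9)
})
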