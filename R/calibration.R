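# Rigid alignment of the virtual environment (VE) onto the real environment
# (RE) from three tracked reference points placed on the ear-level
# loudspeakers at 0 and +/-45 degrees azimuth.

#' Tracker point set
#'
#' @param p1,p2,p3 Numeric length-3 Cartesian points in meters, one frame.
#' @return A 3x3 matrix (rows = points) of class \code{tracker_set}.
#' @export
tracker_set <- function(p1, p2, p3) {
  m <- rbind(p1 = as.numeric(p1), p2 = as.numeric(p2), p3 = as.numeric(p3))
  stopifnot(ncol(m) == 3, all(is.finite(m)))
  a <- 0.5 * sqrt(sum(cross3(m[2, ] - m[1, ], m[3, ] - m[1, ])^2))
  if (a <= 1e-9) stop("tracker points are collinear (triangle area <= 1e-9 m^2)")
  class(m) <- c("tracker_set", "matrix")
  m
}

#' Default tracker geometry on the loudspeaker array
#'
#' Trackers sit on top of the ear-level loudspeakers at 0 and +/-45 degrees
#' azimuth at the array radius.
#'
#' @param radius Array radius in meters.
#' @param height Tracker height above ear level in meters.
#' @return A \code{tracker_set}.
#' @export
default_tracker_points <- function(radius = 2.4, height = 0.15) {
  p <- function(az) radius * azel_to_direction(az, 0) + c(0, 0, height)
  tracker_set(p(0), p(-45), p(45))
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Unit normal of the plane spanned by three tracker points
#'
#' Orientation is sign-ambiguous for a plane; the normal is chosen with
#' positive z component, falling back to positive x, then positive y, so that
#' two measurements of the same physical plane always yield the same normal.
#'
#' @param t A \code{tracker_set} (or 3x3 matrix of points in rows).
#' @return Unit length-3 vector.
#' @export
plane_normal <- function(t) {
  t <- unclass(t)
  n <- cross3(t[2, ] - t[1, ], t[3, ] - t[1, ])
  len <- sqrt(sum(n^2))
  if (len <= 2e-9) stop("degenerate (collinear) tracker points")
  n <- n / len
  s <- if (abs(n[3]) > 1e-12) sign(n[3]) else if (abs(n[1]) > 1e-12) sign(n[1]) else sign(n[2])
  n * s
}

#' Minimal rotation taking direction u onto direction v
#'
#' Rodrigues rotation about axis u x v. For antiparallel inputs the rotation
#' is 180 degrees about a deterministic perpendicular axis (the normalized
#' rejection of the least-aligned coordinate axis from u).
#'
#' @param u,v Nonzero length-3 vectors.
#' @return 3x3 rotation matrix.
#' @export
rotation_between <- function(u, v) {
  u <- u / sqrt(sum(u^2))
  v <- v / sqrt(sum(v^2))
  a <- cross3(u, v)
  s <- sqrt(sum(a^2))
  cth <- sum(u * v)
  if (s < 1e-14) {
    if (cth > 0) return(diag(3))
    # antiparallel: 180 deg about a perpendicular axis
    e <- diag(3)[, which.min(abs(u))]
    ax <- e - sum(e * u) * u
    ax <- ax / sqrt(sum(ax^2))
    return(rotation_axis_angle(ax, pi))
  }
  rotation_axis_angle(a / s, atan2(s, cth))
}

#' Rotation matrix about an axis by an angle
#' @param axis Unit length-3 vector.
#' @param angle Radians.
#' @return 3x3 rotation matrix.
#' @keywords internal
rotation_axis_angle <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, axis[3], -axis[2],
                -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Rigid transform
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1.
#' @param translation Length-3 vector, meters.
#' @return Object of class \code{rigid_transform}. Applied as
#'   \code{rotation \%*\% x + translation}.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- unname(as.matrix(rotation))
  stopifnot(all(dim(rotation) == c(3, 3)), length(translation) == 3)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-10 ||
      abs(det(rotation) - 1) > 1e-10) {
    stop("rotation must be orthonormal with det = +1")
  }
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' Apply a rigid transform to points
#'
#' @param transform A \code{rigid_transform}.
#' @param points Length-3 vector or matrix with points in rows.
#' @return Transformed points, same shape as input.
#' @export
apply_transform <- function(transform, points) {
  if (is.null(dim(points))) {
    return(as.numeric(transform$rotation %*% points + transform$translation))
  }
  p <- unclass(points) %*% t(transform$rotation)
  sweep(p, 2, -transform$translation)
}

#' Compose two rigid transforms (first \code{b}, then \code{a})
#' @param a,b \code{rigid_transform} objects.
#' @return \code{rigid_transform} equal to a(b(x)).
#' @export
compose_transform <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' Invert a rigid transform
#' @param a A \code{rigid_transform}.
#' @return Inverse \code{rigid_transform}.
#' @export
invert_transform <- function(a) {
  rigid_transform(t(a$rotation), as.numeric(-t(a$rotation) %*% a$translation))
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- rad2deg(acos(max(-1, min(1, (sum(diag(x$rotation)) - 1) / 2))))
  cat("Rigid transform: rotation", sprintf("%.3f", ang), "deg, translation [",
      paste(sprintf("%.4f", x$translation), collapse = ", "), "] m\n")
  invisible(x)
}

#' Three-step VE-to-RE calibration
#'
#' Computes the rigid transform mapping virtual tracker coordinates onto
#' their real counterparts by the three-step procedure used at run time in
#' the localization setup: (1) rotate the virtual set so its plane normal
#' matches the real plane normal; (2) translate so the chosen reference
#' point coincides with its real counterpart; (3) rotate about the real
#' normal through the reference point by the angle between the in-plane
#' vectors from the reference point to a second point in each frame. The
#' second point is the lowest-index non-reference point.
#'
#' @param real,virtual \code{tracker_set} objects (corresponding rows).
#' @param reference_index Which point (1..3) is the positional anchor.
#' @return A \code{rigid_transform} t with \code{t(virtual) ~= real}.
#' @examples
#' ts <- default_tracker_points()
#' calibrate(ts, ts)  # identity
#' @export
calibrate <- function(real, virtual, reference_index = 1) {
  real <- unclass(tracker_set(real[1, ], real[2, ], real[3, ]))
  virtual <- unclass(tracker_set(virtual[1, ], virtual[2, ], virtual[3, ]))
  stopifnot(reference_index %in% 1:3)

  # step 1: match plane orientation. The ordered cross-product normal is
  # used in both frames (not the sign-canonicalized plane_normal): point
  # correspondence makes it rotate consistently with the frame, whereas a
  # sign tie-break can flip the virtual plane upside down.
  ordered_normal <- function(m) {
    n <- cross3(m[2, ] - m[1, ], m[3, ] - m[1, ])
    n / sqrt(sum(n^2))
  }
  R1 <- rotation_between(ordered_normal(virtual), ordered_normal(real))
  v1 <- virtual %*% t(R1)

  # step 2: anchor the reference point
  ref <- reference_index
  tr <- real[ref, ] - v1[ref, ]
  v2 <- sweep(v1, 2, -tr)

  # step 3: in-plane rotation about the real normal through the anchor
  n <- ordered_normal(real)
  other <- setdiff(1:3, ref)[1]
  a <- v2[other, ] - real[ref, ]
  b <- real[other, ] - real[ref, ]
  a <- a - sum(a * n) * n
  b <- b - sum(b * n) * n
  ang <- atan2(sum(cross3(a, b) * n), sum(a * b))
  R3 <- rotation_axis_angle(n, ang)

  # compose: T(x) = R3 ((R1 x + tr) - p) + p  with p = real[ref,]
  rot <- R3 %*% R1
  trans <- as.numeric(R3 %*% (tr - real[ref, ])) + real[ref, ]
  rigid_transform(rot, trans)
}

#' Alignment residual and the 2 cm recalibration trigger
#'
#' @param transform Candidate \code{rigid_transform} (virtual -> real).
#' @param real,virtual \code{tracker_set} objects.
#' @param threshold Recalibration threshold in meters (the setup recalibrates
#'   when a tracker is more than 2 cm from its true position).
#' @return List with \code{max_offset} (meters), \code{offsets} (per point)
#'   and logical \code{recalibrate}.
#' @export
alignment_residual <- function(transform, real, virtual, threshold = 0.02) {
  mapped <- apply_transform(transform, unclass(virtual))
  offs <- sqrt(rowSums((mapped - unclass(real))^2))
  list(max_offset = max(offs), offsets = unname(offs),
       recalibrate = max(offs) > threshold)
}

#' Least-squares rigid registration (Kabsch) of corresponding points
#'
#' Independent of the three-step procedure; useful as a cross-check.
#'
#' @param real,virtual Matrices of corresponding points in rows.
#' @return A \code{rigid_transform} minimizing the summed squared residual.
#' @export
kabsch <- function(real, virtual) {
  X <- unclass(virtual); Y <- unclass(real)
  cx <- colMeans(X); cy <- colMeans(Y)
  H <- t(sweep(X, 2, cx)) %*% sweep(Y, 2, cy)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  rigid_transform(R, cy - as.numeric(R %*% cx))
}

#' Worst-case rotation angle implied by a positional offset
#'
#' A tracker offset of \code{offset} meters acting across a lever arm of
#' \code{lever} meters can rotate the aligned frame by up to
#' \code{asin(offset/lever)}. Which lever applies depends on the assumed
#' offset direction and point pair, so the lever is a free argument rather
#' than derived from the tracker geometry.
#'
#' @param offset Positional tolerance in meters (default the 2 cm trigger).
#' @param lever Effective lever arm in meters.
#' @return Angle in degrees.
#' @export
worst_case_rotation_deg <- function(offset = 0.02, lever) {
  stopifnot(offset >= 0, lever > offset)
  rad2deg(asin(offset / lever))
}

#' Read tracker sets from CSV or JSON
#'
#' CSV columns: \code{frame} (real/virtual), \code{point_id}, \code{x},
#' \code{y}, \code{z} in meters. JSON: object with \code{real} and
#' \code{virtual} arrays of [x, y, z] triples.
#'
#' @param path Input file (.csv or .json).
#' @return List with \code{real} and \code{virtual} \code{tracker_set}s.
#' @export
read_tracker_sets <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    j <- jsonlite::read_json(path, simplifyVector = TRUE)
    mk <- function(m) tracker_set(m[1, ], m[2, ], m[3, ])
    return(list(real = mk(as.matrix(j$real)), virtual = mk(as.matrix(j$virtual))))
  }
  d <- utils::read.csv(path)
  need <- c("frame", "point_id", "x", "y", "z")
  if (!all(need %in% names(d))) {
    stop("tracker CSV must have columns: ", paste(need, collapse = ", "))
  }
  get <- function(fr) {
    s <- d[d$frame == fr, ]
    s <- s[order(s$point_id), ]
    if (nrow(s) != 3) stop("expected 3 '", fr, "' points, got ", nrow(s))
    tracker_set(unlist(s[1, c("x", "y", "z")]),
                unlist(s[2, c("x", "y", "z")]),
                unlist(s[3, c("x", "y", "z")]))
  }
  list(real = get("real"), virtual = get("virtual"))
}

#' Write a rigid transform as JSON
#'
#' @param transform A \code{rigid_transform}.
#' @param path Output .json path.
#' @return \code{path}, invisibly.
#' @export
write_transform <- function(transform, path) {
  jsonlite::write_json(
    list(rotation_row_major = as.numeric(t(transform$rotation)),
         translation_m = transform$translation),
    path, digits = NA, auto_unbox = FALSE
  )
  invisible(path)
}

#' Read a rigid transform from JSON
#' @param path Input .json path written by [write_transform()].
#' @return A \code{rigid_transform}.
#' @export
read_transform <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  rigid_transform(matrix(j$rotation_row_major, 3, 3, byrow = TRUE),
                  j$translation_m)
}
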