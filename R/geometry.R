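#' Rigid-body transform
#'
#' A proper rotation plus a translation, the object every superposition of
#' one structure onto another reduces to. Applying the transform maps a
#' coordinate `x` to `rotation %*% x + translation`.
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1 (checked to
#'   within `1e-8`).
#' @param translation numeric 3-vector in Angstroms.
#' @return An object of class `rigid_transform` with elements `rotation`
#'   and `translation`.
#' @examples
#' t1 <- rigid_transform(diag(3), c(1, 0, 0))
#' apply_transform(t1, matrix(0, 1, 3))
#' @export
rigid_transform <- function(rotation, translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  stopifnot(identical(dim(rotation), c(3L, 3L)), length(translation) == 3L)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8 ||
      abs(det(rotation) - 1) > 1e-8)
    stop("'rotation' must be orthonormal with determinant +1")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @rdname rigid_transform
#' @export
transform_identity <- function() rigid_transform(diag(3), c(0, 0, 0))

#' @param t1,t2 transforms; the composition applies `t2` first, then `t1`.
#' @rdname rigid_transform
#' @export
transform_compose <- function(t1, t2) {
  rigid_transform(t1$rotation %*% t2$rotation,
                  as.numeric(t1$rotation %*% t2$translation) + t1$translation)
}

#' @param tr a `rigid_transform`.
#' @rdname rigid_transform
#' @export
transform_inverse <- function(tr) {
  Rt <- t(tr$rotation)
  rigid_transform(Rt, as.numeric(-Rt %*% tr$translation))
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("rigid_transform: rotation angle",
      sprintf("%.2f deg,", rotation_angle(x$rotation)),
      "translation", sprintf("[%.2f %.2f %.2f] A\n", x$translation[1],
                             x$translation[2], x$translation[3]))
  invisible(x)
}

#' Rotation angle and rotation distance
#'
#' `rotation_angle()` returns the angle (degrees) of a single rotation
#' matrix; `rotation_distance()` the geodesic angle between two rotations
#' (or two transforms), used to compare a recovered superposition with a
#' planted one and to deduplicate seed transforms.
#'
#' @param rotation 3x3 rotation matrix.
#' @return Angle in degrees in `[0, 180]`.
#' @export
rotation_angle <- function(rotation) {
  acos(max(-1, min(1, (sum(diag(rotation)) - 1) / 2))) * 180 / pi
}

#' @param r1,r2 rotation matrices or `rigid_transform`s.
#' @rdname rotation_angle
#' @export
rotation_distance <- function(r1, r2) {
  if (inherits(r1, "rigid_transform")) r1 <- r1$rotation
  if (inherits(r2, "rigid_transform")) r2 <- r2$rotation
  rotation_angle(crossprod(r1, r2))
}

# Unit quaternion (w, x, y, z) of a rotation matrix; used for vectorized
# seed deduplication. Shepperd's method, numerically safe for all traces.
rotation_to_quaternion <- function(R) {
  tr <- sum(diag(R))
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else {
    k <- which.max(diag(R))
    i <- k; j <- k %% 3 + 1; l <- j %% 3 + 1
    s <- sqrt(max(1e-12, R[i, i] - R[j, j] - R[l, l] + 1)) * 2
    q <- numeric(4)
    q[1] <- (R[l, j] - R[j, l]) / s
    q[i + 1] <- 0.25 * s
    q[j + 1] <- (R[j, i] + R[i, j]) / s
    q[l + 1] <- (R[l, i] + R[i, l]) / s
  }
  q / sqrt(sum(q^2))
}

quaternion_to_rotation <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Apply a rigid transform
#'
#' Maps every coordinate `x` to `rotation %*% x + translation`. Works on a
#' plain `n x 3` coordinate matrix or on a [structure3d] (metadata
#' preserved).
#'
#' @param tr a `rigid_transform`.
#' @param x coordinate matrix or `structure3d`.
#' @return Object of the same type as `x`.
#' @export
apply_transform <- function(tr, x) {
  stopifnot(inherits(tr, "rigid_transform"))
  if (inherits(x, "structure3d")) {
    x$xyz <- apply_transform(tr, x$xyz)
    return(x)
  }
  sweep(x %*% t(tr$rotation), 2, -tr$translation)
}

#' Coordinate root-mean-square deviation of paired points
#'
#' `sqrt(mean(||a_r - b_r||^2))` over `k >= 1` paired coordinates; the
#' quantity every least-squares superposition minimizes.
#'
#' @param left,right `k x 3` coordinate matrices (or `structure3d`s of
#'   equal length).
#' @return Nonnegative scalar in Angstroms.
#' @examples
#' crms(matrix(0, 2, 3), cbind(c(0, 4), 0, 0))  # sqrt(8)
#' @export
crms <- function(left, right) {
  left <- as_xyz(left); right <- as_xyz(right)
  if (nrow(left) == 0L) stop("crms is undefined for an empty pairing")
  stopifnot(nrow(left) == nrow(right))
  sqrt(mean(rowSums((left - right)^2)))
}

#' Least-squares rigid superposition
#'
#' Finds the rigid transform of the `right` point set minimizing the cRMS
#' to the `left` set, by the Kabsch SVD construction with determinant sign
#' correction (default) or by Horn's closed-form quaternion method; the
#' two are equivalent minimizers and are cross-checked in the test suite.
#'
#' Pairings with fewer than 3 points, or (near-)collinear/coincident
#' points, do not pin down a unique rotation: a best-effort transform is
#' still returned, flagged `degenerate = TRUE`, so iterative aligners can
#' survive transient tiny pairings.
#'
#' @param left,right `k x 3` paired coordinate matrices (`right` is moved
#'   onto `left`).
#' @param method `"svd"` (Kabsch) or `"quaternion"` (Horn).
#' @return A list with `transform` ([rigid_transform]), `crms` (achieved
#'   minimum, Angstroms) and `degenerate` (logical).
#' @export
superpose_lsq <- function(left, right, method = c("svd", "quaternion")) {
  method <- match.arg(method)
  left <- as_xyz(left); right <- as_xyz(right)
  stopifnot(nrow(left) == nrow(right), nrow(left) >= 1L)
  k <- nrow(left)
  cl <- colMeans(left); cr <- colMeans(right)
  X <- sweep(right, 2, cr); Y <- sweep(left, 2, cl)
  B <- crossprod(X, Y)  # sum of X_i Y_i^T
  sv <- svd(B)
  degenerate <- k < 3L || sv$d[2] < 1e-8 * max(sv$d[1], 1e-12)
  if (sv$d[1] < 1e-12) {  # all points coincident with their centroids
    R <- diag(3)
  } else if (method == "svd") {
    s <- sign(det(sv$v %*% t(sv$u)))
    R <- sv$v %*% diag(c(1, 1, s)) %*% t(sv$u)
  } else {
    N <- horn_matrix(B)
    q <- eigen(N, symmetric = TRUE)$vectors[, 1]
    R <- quaternion_to_rotation(q)
  }
  tr <- rigid_transform(R, cl - as.numeric(R %*% cr))
  list(transform = tr, crms = crms(left, apply_transform(tr, right)),
       degenerate = degenerate)
}

# Horn's 4x4 symmetric matrix whose top eigenvector is the optimal
# rotation quaternion, built from B = sum X_i Y_i^T of centred sets.
horn_matrix <- function(B) {
  matrix(c(
    B[1, 1] + B[2, 2] + B[3, 3], B[2, 3] - B[3, 2],
    B[3, 1] - B[1, 3], B[1, 2] - B[2, 1],
    B[2, 3] - B[3, 2], B[1, 1] - B[2, 2] - B[3, 3],
    B[1, 2] + B[2, 1], B[3, 1] + B[1, 3],
    B[3, 1] - B[1, 3], B[1, 2] + B[2, 1],
    -B[1, 1] + B[2, 2] - B[3, 3], B[2, 3] + B[3, 2],
    B[1, 2] - B[2, 1], B[3, 1] + B[1, 3],
    B[2, 3] + B[3, 2], -B[1, 1] - B[2, 2] + B[3, 3]), 4, 4, byrow = TRUE)
}

#' Rotation-grid oracle for the least-squares superposition
#'
#' Brute-force check of [superpose_lsq()]: for centred point sets the
#' optimal translation is the centroid match for every rotation, so only
#' rotation space needs scanning. A global zyz-Euler grid at `coarse_deg`
#' is followed by `levels` nested local refinements (each shrinking the
#' step four-fold) started from each of the best coarse cells — the
#' multi-start guards against the gimbal degeneracy of the Euler
#' parametrization — giving a minimum independent of the Kabsch algebra.
#' Intended for small point sets (the cost is linear in points but cubic
#' in the grid).
#'
#' @param left,right paired `k x 3` coordinate matrices.
#' @param coarse_deg global grid step in degrees.
#' @param levels nested refinement levels.
#' @return The minimum cRMS (Angstroms) found by the scan.
#' @export
crms_rotation_grid <- function(left, right, coarse_deg = 6, levels = 12L) {
  .crms_grid_cpp(as_xyz(left), as_xyz(right), coarse_deg, as.integer(levels))
}

# Accept structure3d or bare matrix coordinates.
as_xyz <- function(x) {
  if (inherits(x, "structure3d")) return(x$xyz)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  stopifnot(ncol(x) == 3L)
  x
}

# zyz Euler grid over SO(3); rows are row-major flattened rotations.
# Used by the deep-search grid oracle.
euler_rotation_grid <- function(step_deg) {
  s <- step_deg * pi / 180
  al <- seq(0, 2 * pi - s / 2, by = s)
  be <- seq(0, pi + 1e-12, by = s)
  ga <- seq(0, 2 * pi - s / 2, by = s)
  g <- expand.grid(ga = ga, be = be, al = al)  # deterministic order
  rots <- matrix(0, nrow(g), 9)
  for (r in seq_len(nrow(g))) {
    R <- rot_z(g$al[r]) %*% rot_y(g$be[r]) %*% rot_z(g$ga[r])
    rots[r, ] <- as.numeric(t(R))
  }
  rots
}

rot_z <- function(a) matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1),
                            3, 3, byrow = TRUE)
rot_y <- function(a) matrix(c(cos(a), 0, sin(a), 0, 1, 0, -sin(a), 0, cos(a)),
                            3, 3, byrow = TRUE)
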