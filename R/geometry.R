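#' @title Local frames and quaternions
#' @description Per-residue right-handed orthonormal coordinate frames and
#'   the quaternion algebra used to express relative orientations as
#'   rotation-invariant edge features.
#' @name geometry
NULL

vnorm <- function(v) sqrt(sum(v^2))

unitize <- function(v, fallback = c(1, 0, 0)) {
  n <- vnorm(v)
  if (n < 1e-8) return(fallback)
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

## Gram-Schmidt: component of v orthogonal to unit vector u, normalized
gs_orth <- function(v, u) {
  w <- v - sum(v * u) * u
  if (vnorm(w) < 1e-8) return(NULL)
  w / vnorm(w)
}

make_frame <- function(origin, basis) {
  list(origin = as.numeric(origin), basis = basis)
}

frame_is_orthonormal <- function(frame, tol = 1e-6) {
  B <- frame$basis
  max(abs(B %*% t(B) - diag(3))) < tol && abs(det(B) - 1) < tol
}

## frame from two direction vectors: z-ish primary axis = a, xz-plane
## spanned with b; returns rows (x, y, z)... here primary is x
frame_from_xy <- function(origin, x_dir, y_hint) {
  xh <- unitize(x_dir)
  yh <- gs_orth(y_hint, xh)
  if (is.null(yh)) {
    yh <- gs_orth(c(0, 0, 1), xh)
    if (is.null(yh)) yh <- gs_orth(c(1, 0, 0), xh)
  }
  zh <- cross3(xh, yh)
  make_frame(origin, rbind(xh, yh, zh))
}

#' Build per-residue local frames
#'
#' For each residue the frame origin is the alpha-carbon; the x axis points
#' along the Calpha-to-C bond, the y axis is the Calpha-to-N direction
#' orthogonalized against x, and z completes the right-handed triad.
#' Residues missing backbone atoms (or with degenerate geometry) fall back
#' to a chain-direction frame: x toward the next residue's alpha-carbon
#' (previous for the chain terminus), y by Gram-Schmidt against the global
#' +z axis (+x if parallel).
#'
#' @param structure a \code{tribind_structure}.
#' @return list of frames, each \code{list(origin, basis)} with basis rows
#'   = (x, y, z) unit vectors; always right-handed and orthonormal.
#' @export
build_residue_frames <- function(structure) {
  n <- n_residues(structure)
  at <- structure$atom
  frames <- vector("list", n)
  fallbacks <- 0L
  for (i in seq_len(n)) {
    rows <- at[at$res_index == i, , drop = FALSE]
    ca <- structure$ca[i, ]
    cc <- rows[rows$elety == "C", c("x", "y", "z")]
    nn <- rows[rows$elety == "N", c("x", "y", "z")]
    frame <- NULL
    if (nrow(cc) == 1L && nrow(nn) == 1L) {
      xv <- as.numeric(cc) - ca
      yv <- as.numeric(nn) - ca
      if (vnorm(xv) > 1e-6 && vnorm(yv) > 1e-6) {
        xh <- unitize(xv)
        yh <- gs_orth(yv, xh)
        if (!is.null(yh)) {
          frame <- make_frame(ca, rbind(xh, yh, cross3(xh, yh)))
        }
      }
    }
    if (is.null(frame)) {
      fallbacks <- fallbacks + 1L
      tgt <- if (i < n) structure$ca[i + 1L, ] else structure$ca[max(1L, i - 1L), ]
      xv <- tgt - ca
      if (vnorm(xv) < 1e-8) xv <- c(1, 0, 0)
      frame <- frame_from_xy(ca, xv, c(0, 0, 1))
    }
    frames[[i]] <- frame
  }
  if (fallbacks > 0L) {
    warning(fallbacks, " residue frame(s) built from the chain-direction fallback")
  }
  frames
}

#' Quaternion of a rotation matrix
#'
#' Returns the unit quaternion (w, x, y, z) of a proper rotation, with the
#' canonical sign w >= 0 (if w = 0, the first nonzero of x, y, z positive).
#'
#' @param R 3 x 3 rotation matrix.
#' @export
quat_from_rotation <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s,
           (R[3, 2] - R[2, 3]) / s,
           (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] >= R[2, 2] && R[1, 1] >= R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s,
           (R[1, 2] + R[2, 1]) / s, (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] >= R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s,
           0.25 * s, (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s, 0.25 * s)
  }
  q <- q / sqrt(sum(q^2))
  canonical_quat(q)
}

canonical_quat <- function(q, tol = 1e-12) {
  if (q[1] < -tol) return(-q)
  if (abs(q[1]) <= tol) {
    for (k in 2:4) {
      if (abs(q[k]) > tol) {
        if (q[k] < 0) q <- -q
        break
      }
    }
    q[1] <- abs(q[1])
  }
  q
}

#' Relative rotation between two local frames, as a unit quaternion
#'
#' The rotation matrix whose columns are frame j's axes expressed in frame
#' i's coordinates; invariant under any global rigid motion applied to both
#' frames. Identical frames give the identity quaternion (1, 0, 0, 0).
#'
#' @param frame_i,frame_j frames from [build_residue_frames()].
#' @export
relative_quaternion <- function(frame_i, frame_j) {
  if (!frame_is_orthonormal(frame_i) || !frame_is_orthonormal(frame_j)) {
    stop("relative_quaternion requires orthonormal right-handed frames")
  }
  quat_from_rotation(frame_i$basis %*% t(frame_j$basis))
}

#' Quaternion conjugate
#' @param q quaternion (w, x, y, z).
#' @keywords internal
quat_conjugate <- function(q) c(q[1], -q[2:4])

#' Gaussian radial basis encoding of a distance
#'
#' \code{exp(-d^2 / (2 sigma^2))}: 1 at zero separation, strictly
#' decreasing, in (0, 1].
#' @param d distance (Å), vectorized.
#' @param sigma width (Å).
#' @export
rbf_distance <- function(d, sigma = 1.0) exp(-d^2 / (2 * sigma^2))

#' Apply a rigid motion to a structure (testing / augmentation helper)
#'
#' @param structure a \code{tribind_structure}.
#' @param rotation 3 x 3 rotation matrix.
#' @param translation length-3 vector (Å).
#' @export
transform_structure <- function(structure, rotation = diag(3),
                                translation = c(0, 0, 0)) {
  xyz <- as.matrix(structure$atom[, c("x", "y", "z")])
  xyz <- sweep(xyz %*% t(rotation), 2L, translation, "+")
  structure$atom$x <- xyz[, 1]
  structure$atom$y <- xyz[, 2]
  structure$atom$z <- xyz[, 3]
  structure$ca <- sweep(structure$ca %*% t(rotation), 2L, translation, "+")
  structure
}

#' Random rotation matrix (uniform over SO(3))
#' @param n ignored; one matrix per call.
#' @keywords internal
random_rotation <- function(n = 1) {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  rbind(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y)),
        c(2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x)),
        c(2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)))
}
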