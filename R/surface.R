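#' @title Molecular-surface descriptors
#' @description Per-residue surface features: mean curvature, Gaussian
#'   curvature, shape index and curvedness of the solvent-accessible
#'   surface, plus the residue's atom-type composition. The surface is
#'   sampled as a dot surface (Fibonacci points on each atom's
#'   probe-expanded sphere, pruned inside the union of spheres) and
#'   curvatures are estimated by local quadric fits around each surface
#'   point.
#' @name surface
NULL

VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20,
               P = 1.80, F = 1.47, Cl = 1.75, Br = 1.85, I = 1.98)

vdw_radius <- function(element) {
  r <- VDW_RADII[element]
  r[is.na(r)] <- 1.70
  unname(r)
}

## deterministic quasi-uniform points on the unit sphere
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Sample the solvent-accessible dot surface of a structure
#'
#' @param centers M x 3 atom coordinates (Å).
#' @param radii per-atom van der Waals radii (Å).
#' @param probe probe radius (Å), default 1.4 (water).
#' @param n_points sphere sample points per atom.
#' @return list with \code{points} (P x 3), \code{normals} (P x 3, outward)
#'   and \code{atom} (generating atom index per point).
#' @keywords internal
## canonical body frame of a point cloud: principal axes with sign fixed by
## the largest-magnitude component, right-handed. Sampling sphere directions
## in this frame makes the dot surface co-rotate exactly with the structure,
## so surface descriptors are rigid-motion invariant up to float roundoff.
body_frame <- function(centers) {
  if (nrow(centers) < 3L) return(diag(3))
  cc <- sweep(centers, 2L, colMeans(centers), "-")
  ev <- eigen(crossprod(cc) / nrow(cc), symmetric = TRUE)$vectors
  for (k in 1:2) {
    ## intrinsic sign: third moment of the cloud along the axis (invariant
    ## under rotation); component-magnitude rule only as a fallback
    s3 <- sum((cc %*% ev[, k])^3)
    if (abs(s3) > 1e-6) {
      if (s3 < 0) ev[, k] <- -ev[, k]
    } else if (ev[which.max(abs(ev[, k])), k] < 0) {
      ev[, k] <- -ev[, k]
    }
  }
  ev[, 3] <- cross3(ev[, 1], ev[, 2])
  ev
}

sample_dot_surface <- function(centers, radii, probe = 1.4, n_points = 40L) {
  m <- nrow(centers)
  base <- fibonacci_sphere(n_points) %*% t(body_frame(centers))
  exp_r <- radii + probe
  pts <- vector("list", m)
  owner <- vector("list", m)
  for (a in seq_len(m)) {
    p <- sweep(base * exp_r[a], 2L, centers[a, ], "+")
    pts[[a]] <- p
    owner[[a]] <- rep(a, n_points)
  }
  pts <- do.call(rbind, pts)
  owner <- unlist(owner)
  ## prune points buried inside any other expanded sphere (chunked)
  keep <- rep(TRUE, nrow(pts))
  chunk <- 2000L
  for (s in seq(1L, nrow(pts), by = chunk)) {
    e <- min(s + chunk - 1L, nrow(pts))
    blk <- pts[s:e, , drop = FALSE]
    d2 <- outer(rowSums(blk^2), rep(1, m)) -
      2 * blk %*% t(centers) +
      outer(rep(1, nrow(blk)), rowSums(centers^2))
    thr <- matrix((exp_r - 1e-6)^2, nrow(blk), m, byrow = TRUE)
    inside <- d2 < thr
    inside[cbind(seq_len(nrow(blk)), owner[s:e])] <- FALSE
    keep[s:e] <- rowSums(inside) == 0L
  }
  pts <- pts[keep, , drop = FALSE]
  owner <- owner[keep]
  normals <- (pts - centers[owner, , drop = FALSE]) / exp_r[owner]
  list(points = pts, normals = normals, atom = owner)
}

## principal curvatures at each surface point by local quadric fit:
## in the tangent frame, z ~ a x^2 + b xy + c y^2 + d x + e y; the shape
## operator is approximated by -[[2a, b], [b, 2c]] (outward normal as +z,
## so a convex sphere of radius R yields kappa = +1/R).
surface_curvatures <- function(pts, normals, fit_radius = 3.0) {
  p <- nrow(pts)
  out <- matrix(NA_real_, p, 2L)
  chunk <- 1500L
  for (s in seq(1L, p, by = chunk)) {
    e <- min(s + chunk - 1L, p)
    blk <- pts[s:e, , drop = FALSE]
    d2 <- outer(rowSums(blk^2), rep(1, p)) -
      2 * blk %*% t(pts) +
      outer(rep(1, nrow(blk)), rowSums(pts^2))
    nb <- d2 <= fit_radius^2
    for (r in seq_len(nrow(blk))) {
      idx <- which(nb[r, ])
      if (length(idx) < 7L) next
      i0 <- s + r - 1L
      nrm <- normals[i0, ]
      ## local tangent basis
      t1 <- gs_orth(c(1, 0, 0), nrm)
      if (is.null(t1)) t1 <- gs_orth(c(0, 1, 0), nrm)
      t2 <- cross3(nrm, t1)
      rel <- sweep(pts[idx, , drop = FALSE], 2L, pts[i0, ], "-")
      u <- rel %*% t1
      v <- rel %*% t2
      w <- rel %*% nrm
      X <- cbind(u^2, u * v, v^2, u, v)
      fit <- tryCatch(qr.solve(crossprod(X) + diag(1e-10, 5),
                               crossprod(X, w)),
                      error = function(e) NULL)
      if (is.null(fit)) next
      S <- -rbind(c(2 * fit[1], fit[2]), c(fit[2], 2 * fit[3]))
      k <- sort(eigen(S, symmetric = TRUE, only.values = TRUE)$values,
                decreasing = TRUE)
      out[i0, ] <- k
    }
  }
  out
}

#' Per-residue 10-d surface feature tensor
#'
#' Columns 1-4: mean curvature, Gaussian curvature, shape index and
#' curvedness (1/Å, 1/Å², unitless, 1/Å), averaged over the surface points
#' assigned to the residue (nearest heavy atom's parent residue); residues
#' with no surface points get a zero geometric block. Columns 5-10: mean
#' one-hot atom-type composition (C, H, O, N, S, other) over the residue's
#' atoms. Shape index is \code{(2/pi) atan((k1 + k2) / (k1 - k2))} with
#' k1 >= k2 (+-1 at umbilic points by the sign of the curvature); curvedness
#' is \code{sqrt((k1^2 + k2^2) / 2)}.
#'
#' @param structure a \code{tribind_structure} with >= 4 heavy atoms.
#' @param probe probe radius (Å).
#' @param n_points surface samples per atom.
#' @param fit_radius neighbourhood radius for the quadric fits (Å).
#' @return N x 10 matrix.
#' @export
compute_surface_features <- function(structure, probe = 1.4,
                                     n_points = 40L, fit_radius = 3.0) {
  n <- n_residues(structure)
  out <- matrix(0, n, 10L)
  colnames(out) <- c("mean_curv", "gauss_curv", "shape_index", "curvedness",
                     "C", "H", "O", "N", "S", "other")
  ## chemistry block: composition over all of the residue's atoms
  elem <- structure$atom$elesy
  slot <- match(elem, c("C", "H", "O", "N", "S"))
  slot[is.na(slot)] <- 6L
  for (i in seq_len(n)) {
    s <- slot[structure$atom$res_index == i]
    out[i, 4L + seq_len(6L)] <- tabulate(s, 6L) / length(s)
  }
  heavy <- which(elem != "H")
  if (length(heavy) < 4L) {
    warning("fewer than 4 heavy atoms; surface geometric block left at zero")
    return(out)
  }
  centers <- as.matrix(structure$atom[heavy, c("x", "y", "z")])
  radii <- vdw_radius(elem[heavy])
  surf <- tryCatch(
    sample_dot_surface(centers, radii, probe = probe, n_points = n_points),
    error = function(e) NULL)
  if (is.null(surf) || nrow(surf$points) == 0L) {
    warning("surface sampling failed; geometric block left at zero")
    return(out)
  }
  ks <- surface_curvatures(surf$points, surf$normals, fit_radius = fit_radius)
  ok <- !is.na(ks[, 1])
  if (!any(ok)) {
    warning("curvature estimation failed; geometric block left at zero")
    return(out)
  }
  k1 <- ks[ok, 1]; k2 <- ks[ok, 2]
  H <- (k1 + k2) / 2
  K <- k1 * k2
  denom <- k1 - k2
  si <- ifelse(denom > 1e-9, (2 / pi) * atan((k1 + k2) / denom),
               sign(k1 + k2))
  cv <- sqrt((k1^2 + k2^2) / 2)
  res_of_point <- structure$atom$res_index[heavy][surf$atom[ok]]
  geo <- cbind(H, K, si, cv)
  agg <- rowsum(geo, group = res_of_point)
  cnt <- as.numeric(table(res_of_point))
  out[as.integer(rownames(agg)), 1:4] <- agg / cnt
  out
}
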