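# Structural kernels: optimal superposition, RMSD, radius of gyration,
# Shrake-Rupley solvent-accessible surface area.

as_coord_matrix <- function(x, frame = 1L) {
  if (inherits(x, "trajectory")) return(x$coords[, , frame])
  if (is.matrix(x) && ncol(x) == 3L) return(x)
  stop("expected an n x 3 coordinate matrix or a trajectory")
}

check_mask <- function(mask, n) {
  if (is.null(mask)) mask <- seq_len(n)
  mask <- as.integer(mask)
  if (length(mask) == 0L) stop("empty atom mask")
  if (any(mask < 1L | mask > n)) stop("atom mask out of range")
  mask
}

#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares optimal proper rotation and translation of `mobile` onto
#' `reference` over the masked atoms, via the SVD of the cross-covariance
#' matrix with the usual reflection correction so that `det(rotation) = +1`.
#'
#' @param mobile,reference `n x 3` coordinate matrices (angstrom).
#' @param atom_mask integer indices of atoms used for the fit (default all).
#' @return list with `rotation` (3x3, proper), `translation` (length-3
#'   vector) and `rmsd_after` (angstrom over the mask).  The transformed
#'   coordinates are `coords %*% t(rotation) + translation` (row-wise).
#' @export
kabsch_superpose <- function(mobile, reference, atom_mask = NULL) {
  P <- as_coord_matrix(mobile)
  Q <- as_coord_matrix(reference)
  if (nrow(P) != nrow(Q)) stop("mismatched atom counts")
  mask <- check_mask(atom_mask, nrow(P))
  if (length(mask) < 3L) stop("degenerate geometry: need >= 3 atoms in mask")
  Pm <- P[mask, , drop = FALSE]
  Qm <- Q[mask, , drop = FALSE]
  cp <- colMeans(Pm)
  cq <- colMeans(Qm)
  Pc <- sweep(Pm, 2, cp)
  Qc <- sweep(Qm, 2, cq)
  sv_p <- svd(Pc)$d
  if (sv_p[2] < 1e-8 * max(sv_p[1], 1))
    stop("degenerate geometry: masked atoms are collinear")
  H <- crossprod(Pc, Qc)            # 3x3 cross-covariance
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  translation <- as.numeric(cq - R %*% cp)
  fitted <- Pm %*% t(R) + matrix(translation, nrow(Pm), 3, byrow = TRUE)
  rmsd_after <- sqrt(mean(rowSums((fitted - Qm)^2)))
  list(rotation = R, translation = translation, rmsd_after = rmsd_after)
}

#' Apply a superposition to coordinates
#' @param coords `n x 3` matrix.
#' @param sp result of [kabsch_superpose()].
#' @return transformed `n x 3` matrix.
#' @export
apply_superposition <- function(coords, sp) {
  coords %*% t(sp$rotation) + matrix(sp$translation, nrow(coords), 3, byrow = TRUE)
}

#' Root-mean-square deviation between two frames
#'
#' @param a,b `n x 3` coordinate matrices.
#' @param atom_mask atoms to compare (default all).
#' @param align if `TRUE`, superpose `a` onto `b` over the mask first and
#'   return the post-fit RMSD; if `FALSE`, the direct coordinate deviation.
#' @return RMSD in angstrom.
#' @export
rmsd <- function(a, b, atom_mask = NULL, align = FALSE) {
  A <- as_coord_matrix(a)
  B <- as_coord_matrix(b)
  if (nrow(A) != nrow(B)) stop("mismatched atom counts")
  mask <- check_mask(atom_mask, nrow(A))
  if (align) return(kabsch_superpose(A, B, mask)$rmsd_after)
  sqrt(mean(rowSums((A[mask, , drop = FALSE] - B[mask, , drop = FALSE])^2)))
}

#' Radius of gyration
#'
#' `sqrt(sum(w_i |r_i - r_bar|^2) / sum(w_i))` with unit weights or atomic
#' masses.
#'
#' @param frame `n x 3` coordinate matrix or a trajectory (first frame).
#' @param atom_mask atoms included (default all).
#' @param mass_weighted weight atoms by mass instead of uniformly.
#' @param masses per-atom masses; required if `mass_weighted` and `frame`
#'   is a bare matrix, otherwise taken from the trajectory topology.
#' @return radius of gyration in angstrom.
#' @export
radius_of_gyration <- function(frame, atom_mask = NULL, mass_weighted = FALSE,
                               masses = NULL) {
  X <- as_coord_matrix(frame)
  mask <- check_mask(atom_mask, nrow(X))
  X <- X[mask, , drop = FALSE]
  w <- if (mass_weighted) {
    if (is.null(masses) && inherits(frame, "trajectory"))
      masses <- atomic_mass(frame$topology$element)
    if (is.null(masses)) stop("mass_weighted = TRUE requires masses")
    masses[mask]
  } else rep(1, nrow(X))
  ctr <- colSums(X * w) / sum(w)
  Xc <- sweep(X, 2, ctr)
  sqrt(sum(w * rowSums(Xc^2)) / sum(w))
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Rolls a probe sphere over the van der Waals surface by testing a
#' deterministic golden-spiral lattice of points on each atom's expanded
#' sphere against all neighbours within `r_i + r_j + 2*probe`.  Per-atom
#' area is `(accessible points / n_points) * 4*pi*(r + probe)^2`; per-residue
#' area sums the member atoms (all atoms present in the topology, not a
#' heavy-atom subset).
#'
#' @param frame `n x 3` coordinate matrix, or a trajectory (then `frame_index`
#'   selects the frame and the topology supplies radii and residues).
#' @param topology topology data frame (required for a bare matrix).
#' @param probe_radius probe radius in angstrom (1.4 = water).
#' @param n_points number of lattice points per atom (>= 92).
#' @param frame_index frame to evaluate when `frame` is a trajectory.
#' @return list of class `"sasa_result"` with `per_atom_area` (A^2),
#'   `per_residue_area` (named by residue index), `probe_radius`,
#'   `n_sphere_points`.
#' @export
shrake_rupley_sasa <- function(frame, topology = NULL, probe_radius = 1.4,
                               n_points = 960L, frame_index = 1L) {
  if (inherits(frame, "trajectory")) {
    topology <- frame$topology
    frame <- frame$coords[, , frame_index]
  }
  if (is.null(topology)) stop("topology required")
  if (n_points < 92L) stop("n_points must be >= 92")
  if (!all(is.finite(frame))) stop("non-finite coordinates")
  pts <- golden_spiral_points(n_points)
  per_atom <- sasa_per_atom_cpp(frame, topology$vdw_radius, probe_radius, pts)
  per_res <- tapply(per_atom, topology$residue_index, sum)
  structure(list(per_atom_area = per_atom,
                 per_residue_area = setNames(as.numeric(per_res),
                                             names(per_res)),
                 probe_radius = probe_radius,
                 n_sphere_points = as.integer(n_points)),
            class = "sasa_result")
}

# Per-residue SASA for every frame of an ensemble/trajectory coordinate
# array; returns a frames x residues matrix.  Workhorse behind the exposure
# and surrogate-antigenicity tables.
sasa_per_residue_frames <- function(coords, topology, probe_radius = 1.4,
                                    n_points = 960L, frames = NULL) {
  if (is.null(frames)) frames <- seq_len(dim(coords)[3])
  pts <- golden_spiral_points(n_points)
  res_idx <- topology$residue_index
  res_lev <- sort(unique(res_idx))
  out <- matrix(NA_real_, length(frames), length(res_lev),
                dimnames = list(NULL, res_lev))
  for (k in seq_along(frames)) {
    pa <- sasa_per_atom_cpp(coords[, , frames[k]], topology$vdw_radius,
                            probe_radius, pts)
    out[k, ] <- as.numeric(tapply(pa, factor(res_idx, levels = res_lev), sum))
  }
  out
}
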