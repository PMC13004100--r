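# Combined-ensemble analysis: concatenation, two-pass alignment, coordinate
# PCA, conformational clustering and cluster characterisation.

#' Combine labelled trajectories into one ensemble
#'
#' Frames are concatenated in input order; per-frame provenance
#' (model_label, start_shape, repeat_id, time) is preserved so downstream
#' tables can be stratified by model and condition.  All trajectories must
#' share one topology.
#'
#' @param trajs list of [trajectory()] objects (>= 2, or 1 for convenience).
#' @return object of class `"conf_ensemble"`: `topology`, `coords`
#'   (`n_atoms x 3 x n_frames`), `provenance` data frame, `aligned` flag.
#' @export
combine_trajectories <- function(trajs) {
  stopifnot(length(trajs) >= 1L)
  ref <- trajs[[1]]$topology
  cols <- c("atom_name", "element", "residue_index", "residue_name", "vdw_radius")
  for (i in seq_along(trajs)) {
    top <- trajs[[i]]$topology
    if (nrow(top) != nrow(ref))
      stop("topology mismatch: trajectory ", i, " has ", nrow(top),
           " atoms, expected ", nrow(ref))
    for (cl in cols) {
      diff <- which(top[[cl]] != ref[[cl]])
      if (length(diff))
        stop("topology mismatch in trajectory ", i, ": atom ", diff[1],
             " differs in ", cl, " ('", top[[cl]][diff[1]], "' vs '",
             ref[[cl]][diff[1]], "')")
    }
  }
  nf <- vapply(trajs, n_frames, 1L)
  coords <- array(0, c(nrow(ref), 3, sum(nf)))
  at <- 0L
  prov <- vector("list", length(trajs))
  for (i in seq_along(trajs)) {
    coords[, , at + seq_len(nf[i])] <- trajs[[i]]$coords
    prov[[i]] <- data.frame(model_label = trajs[[i]]$model_label,
                            start_shape = trajs[[i]]$start_shape,
                            repeat_id = trajs[[i]]$repeat_id,
                            time = trajs[[i]]$time,
                            stringsAsFactors = FALSE)
    at <- at + nf[i]
  }
  prov <- do.call(rbind, prov)
  prov$frame <- seq_len(nrow(prov))
  structure(list(topology = ref, coords = coords,
                 provenance = prov[, c("frame", "model_label", "start_shape",
                                       "repeat_id", "time")],
                 aligned = FALSE),
            class = "conf_ensemble")
}

#' @export
print.conf_ensemble <- function(x, ...) {
  cat(sprintf("conformational ensemble: %d atoms, %d frames (%s)\n",
              nrow(x$topology), n_frames(x),
              if (x$aligned) "aligned" else "unaligned"))
  print(table(x$provenance$model_label, x$provenance$start_shape))
  invisible(x)
}

#' Indices of backbone "CA" atoms/beads
#' @param topology topology data frame.
#' @return integer atom indices with atom name `"CA"`.
#' @export
ca_mask <- function(topology) which(topology$atom_name == "CA")

#' Two-pass least-squares alignment of an ensemble
#'
#' Pass 1 superposes every frame onto frame 1; the mean structure of the
#' pass-1 coordinates is then used as the reference for a second
#' superposition pass.  Deterministic, and idempotent to numerical
#' precision.
#'
#' @param ens a `conf_ensemble`.
#' @param atom_mask atoms used for the fit (default: all atoms, matching
#'   full-protein alignment practice).
#' @return the aligned ensemble (`aligned = TRUE`).
#' @export
align_ensemble <- function(ens, atom_mask = NULL) {
  stopifnot(inherits(ens, "conf_ensemble"))
  mask <- check_mask(atom_mask, nrow(ens$topology))
  nf <- n_frames(ens)
  ref <- ens$coords[, , 1]
  pass1 <- ens$coords
  for (f in seq_len(nf)) {
    sp <- kabsch_superpose(ens$coords[, , f], ref, mask)
    pass1[, , f] <- apply_superposition(ens$coords[, , f], sp)
  }
  mean_struct <- apply(pass1, c(1, 2), mean)
  out <- pass1
  for (f in seq_len(nf)) {
    sp <- kabsch_superpose(pass1[, , f], mean_struct, mask)
    out[, , f] <- apply_superposition(pass1[, , f], sp)
  }
  ens$coords <- out
  ens$aligned <- TRUE
  ens
}

#' Coordinate principal component analysis of an aligned ensemble
#'
#' Eigendecomposition (via [stats::prcomp()]) of the covariance of the
#' flattened masked coordinates.  The ensemble must have been aligned first,
#' so that rigid-body motion does not masquerade as internal motion.
#'
#' @param ens an aligned `conf_ensemble`.
#' @param atom_mask atoms entering the PCA (default: CA beads/atoms, the
#'   usual ensemble-PCA choice keeping dimensionality modest).
#' @return list of class `"coord_pca"`: `mean_coordinates`, `components`
#'   (columns, orthonormal), `eigenvalues` (variance in A^2, non-increasing),
#'   `projections` (frames x components), `atom_mask`.
#' @export
coordinate_pca <- function(ens, atom_mask = ca_mask(ens$topology)) {
  stopifnot(inherits(ens, "conf_ensemble"))
  if (!isTRUE(ens$aligned))
    stop("ensemble is not aligned; run align_ensemble() first")
  if (n_frames(ens) < 2L) stop("need >= 2 frames for PCA")
  mask <- check_mask(atom_mask, nrow(ens$topology))
  X <- t(apply(ens$coords[mask, , , drop = FALSE], 3, as.numeric))
  p <- prcomp(X, center = TRUE, scale. = FALSE)
  structure(list(mean_coordinates = matrix(p$center, ncol = 3),
                 components = p$rotation,
                 eigenvalues = p$sdev^2,
                 projections = p$x,
                 atom_mask = mask),
            class = "coord_pca")
}

#' Choose the number of clusters by the k-means elbow rule
#'
#' Runs k-means (fixed seed, multiple restarts) for each candidate k and
#' returns the k maximising the second difference of the within-cluster sum
#' of squares, taken relative to the WSS at that k.  The relative form
#' matters: for a structureless cloud the raw WSS decays smoothly (roughly
#' like 1/k, whose relative curvature `2/(k^2-1)` is maximal at k = 2 and
#' below 1 everywhere), while genuine cluster structure makes the WSS
#' collapse at the true k and the relative curvature explode.  When the
#' winning relative curvature stays below 1 the data look like a single
#' diffuse cloud: the returned value then carries a `low_confidence`
#' attribute and a message is emitted.
#'
#' @param projections frames x components score matrix (or `coord_pca`).
#' @param n_pcs number of leading components used.
#' @param k_range integer candidate range (must allow an interior point).
#' @param seed RNG seed for the k-means restarts.
#' @param nstart restarts per k.
#' @return the selected k (integer, possibly with attribute
#'   `low_confidence`).
#' @export
select_k_elbow <- function(projections, n_pcs = 4L, k_range = 1:8,
                           seed = 1L, nstart = 10L) {
  proj <- if (inherits(projections, "coord_pca")) projections$projections
          else as.matrix(projections)
  n_pcs <- min(n_pcs, ncol(proj))
  X <- proj[, seq_len(n_pcs), drop = FALSE]
  k_range <- sort(unique(as.integer(k_range)))
  if (length(k_range) == 0L) stop("empty k_range")
  if (any(k_range < 1L) || any(k_range > nrow(X)))
    stop("k_range must lie within [1, n_frames]")
  set.seed(seed)
  wss <- vapply(k_range, function(k) {
    if (k == 1L) sum(scale(X, scale = FALSE)^2)
    else kmeans(X, centers = k, nstart = nstart, iter.max = 100L)$tot.withinss
  }, numeric(1))
  if (length(k_range) < 3L) {
    message("k_range too short for an elbow; returning k with lowest WSS")
    return(k_range[which.min(wss)])
  }
  d2 <- wss[seq_len(length(wss) - 2L)] - 2 * wss[seq(2L, length(wss) - 1L)] +
    wss[seq(3L, length(wss))]
  rel <- d2 / pmax(wss[seq(2L, length(wss) - 1L)], .Machine$double.eps)
  # smallest k whose curvature is close to the maximum: real structure
  # dominates by orders of magnitude, while smooth decay has a flat ridge
  # where the most parsimonious k wins
  best <- which(rel >= 0.5 * max(rel))[1] + 1L
  k <- k_range[best]
  if (rel[best - 1L] < 1) {
    message("elbow selection is low-confidence (no pronounced knee); k = ", k)
    attr(k, "low_confidence") <- TRUE
  }
  k
}

#' Average-linkage hierarchical clustering in PC space
#'
#' Agglomerates frames by average linkage on Euclidean distance over the
#' first `n_pcs` principal component scores and cuts the tree into exactly
#' `n_clusters` clusters.  Cluster ids are relabelled in order of first
#' occurrence along the frame sequence.
#'
#' @param projections frames x components score matrix or a `coord_pca`.
#' @param n_pcs number of leading components used (default 4).
#' @param n_clusters number of clusters (default 6).
#' @return list of class `"ensemble_clustering"`: `assignment` (per-frame id
#'   in 1..n_clusters), `n_clusters`, `midpoint_frame` (filled by
#'   [cluster_midpoints()]), `linkage_method`, `n_pcs_used`.
#' @export
hierarchical_clusters <- function(projections, n_pcs = 4L, n_clusters = 6L) {
  proj <- if (inherits(projections, "coord_pca")) projections$projections
          else as.matrix(projections)
  if (n_pcs > ncol(proj)) stop("n_pcs exceeds available components")
  if (n_clusters > nrow(proj)) stop("n_clusters exceeds frame count")
  X <- proj[, seq_len(n_pcs), drop = FALSE]
  hc <- hclust(dist(X), method = "average")
  raw <- cutree(hc, k = n_clusters)
  relab <- match(raw, unique(raw))   # first-occurrence order
  structure(list(assignment = relab,
                 n_clusters = as.integer(n_clusters),
                 midpoint_frame = NULL,
                 linkage_method = "average",
                 n_pcs_used = as.integer(n_pcs),
                 scores = X),
            class = "ensemble_clustering")
}

#' Representative (midpoint) frame of each cluster
#'
#' The midpoint is the member frame closest (Euclidean, in the clustering's
#' PC score space) to the cluster centroid; ties break to the lowest frame
#' index.
#'
#' @param clustering an `ensemble_clustering`.
#' @param projections score matrix used for the clustering (defaults to the
#'   scores stored in the clustering).
#' @return integer vector of frame indices, one per cluster id.
#' @export
cluster_midpoints <- function(clustering, projections = NULL) {
  X <- if (is.null(projections)) clustering$scores
       else {
         p <- if (inherits(projections, "coord_pca")) projections$projections
              else as.matrix(projections)
         p[, seq_len(clustering$n_pcs_used), drop = FALSE]
       }
  vapply(seq_len(clustering$n_clusters), function(cl) {
    members <- which(clustering$assignment == cl)
    ctr <- colMeans(X[members, , drop = FALSE])
    d2 <- rowSums(sweep(X[members, , drop = FALSE], 2, ctr)^2)
    members[which.min(d2)]   # which.min takes the first (lowest index) on ties
  }, integer(1))
}

#' Per-cluster structural profile
#'
#' For each cluster: mean/sd RMSD of member frames to the cluster midpoint
#' (with full-protein alignment), mean/sd radius of gyration, and occupancy
#' counts per model label.
#'
#' @param ens the (aligned) `conf_ensemble` that was clustered.
#' @param clustering an `ensemble_clustering`.
#' @param atom_mask atoms for the RMSD/Rg computations (default all).
#' @return data frame with one row per cluster: `cluster`, `n_frames`,
#'   `midpoint_frame`, `mean_rmsd`, `sd_rmsd`, `mean_rg`, `sd_rg`, and one
#'   `n_<model>` occupancy column per model label.
#' @export
cluster_profile <- function(ens, clustering, atom_mask = NULL) {
  stopifnot(inherits(ens, "conf_ensemble"))
  mids <- clustering$midpoint_frame
  if (is.null(mids)) mids <- cluster_midpoints(clustering)
  mask <- check_mask(atom_mask, nrow(ens$topology))
  models <- sort(unique(ens$provenance$model_label))
  rows <- lapply(seq_len(clustering$n_clusters), function(cl) {
    members <- which(clustering$assignment == cl)
    mid <- ens$coords[, , mids[cl]]
    r <- vapply(members, function(f)
      rmsd(ens$coords[, , f], mid, mask, align = TRUE), numeric(1))
    rg <- vapply(members, function(f)
      radius_of_gyration(ens$coords[, , f], mask), numeric(1))
    occ <- table(factor(ens$provenance$model_label[members], levels = models))
    out <- data.frame(cluster = cl, n_frames = length(members),
                      midpoint_frame = mids[cl],
                      mean_rmsd = mean(r), sd_rmsd = if (length(r) > 1) sd(r) else 0,
                      mean_rg = mean(rg), sd_rg = if (length(rg) > 1) sd(rg) else 0)
    for (m in models) out[[paste0("n_", m)]] <- as.integer(occ[[m]])
    out
  })
  do.call(rbind, rows)
}

#' Cluster occupancy over time and half-departure times
#'
#' Bins frames by time label and reports, per model, the fraction of frames
#' in each cluster per bin, together with the fraction *outside* a reference
#' cluster and the half-departure time: the first bin midpoint at which the
#' outside fraction reaches 0.5 (`NA` when it never does).
#'
#' @param ens a `conf_ensemble` with time labels.
#' @param clustering an `ensemble_clustering`.
#' @param reference_cluster cluster id regarded as the starting state.
#' @param n_bins number of equal-width time bins.
#' @param start_shape optional filter: use only frames with this starting
#'   shape (e.g. `"circular"` to follow the ring-opening transition).
#' @return list with `occupancy` (model, bin midpoint, cluster, fraction),
#'   `outside` (model, bin midpoint, fraction outside the reference) and
#'   `half_departure` (named numeric per model, ns; `NA` = never departs).
#' @export
occupancy_timecourse <- function(ens, clustering, reference_cluster = 1L,
                                 n_bins = 20L, start_shape = NULL) {
  prov <- ens$provenance
  keep <- rep(TRUE, nrow(prov))
  if (!is.null(start_shape)) keep <- prov$start_shape %in% start_shape
  prov <- prov[keep, , drop = FALSE]
  assign <- clustering$assignment[keep]
  if (nrow(prov) == 0L) stop("no frames left after start_shape filter")
  brk <- seq(min(prov$time), max(prov$time), length.out = n_bins + 1L)
  mid <- (brk[-1] + brk[-length(brk)]) / 2
  bin <- findInterval(prov$time, brk, rightmost.closed = TRUE,
                      all.inside = TRUE)
  models <- sort(unique(prov$model_label))
  clusters <- seq_len(clustering$n_clusters)
  occ <- expand.grid(model_label = models, bin_mid = mid, cluster = clusters,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  occ$fraction <- NA_real_
  outside <- expand.grid(model_label = models, bin_mid = mid,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  outside$fraction <- NA_real_
  half <- setNames(rep(NA_real_, length(models)), models)
  for (m in models) {
    sel_m <- prov$model_label == m
    if (!any(assign[sel_m] == reference_cluster))
      warning("reference cluster ", reference_cluster,
              " holds no frames for model ", m)
    for (b in seq_len(n_bins)) {
      sel <- sel_m & bin == b
      n <- sum(sel)
      if (n == 0L) next
      tab <- tabulate(assign[sel], nbins = clustering$n_clusters) / n
      occ$fraction[occ$model_label == m & occ$bin_mid == mid[b]] <- tab
      outside$fraction[outside$model_label == m & outside$bin_mid == mid[b]] <-
        1 - tab[reference_cluster]
    }
    fr <- outside$fraction[outside$model_label == m]
    hit <- which(!is.na(fr) & fr >= 0.5)
    if (length(hit)) half[m] <- mid[hit[1]]
  }
  list(occupancy = occ, outside = outside, half_departure = half)
}
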