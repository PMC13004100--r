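test_that("combining trajectories concatenates frames and preserves provenance", {
  sc <- small_scenario()
  t1 <- simulate_conformer_trajectory(sc, "WT", "circular", 1, seed = 1)$trajectory
  t2 <- simulate_conformer_trajectory(sc, "VARIANT", "circular", 1, seed = 2)$trajectory
  ens <- combine_trajectories(list(t1, t2))
  expect_equal(n_frames(ens), 80L)
  expect_equal(as.vector(table(ens$provenance$model_label)), c(40L, 40L))
  expect_equal(ens$coords[, , 41], t2$coords[, , 1])

  t3 <- t2
  t3$topology$atom_name[7] <- "CG"
  expect_error(combine_trajectories(list(t1, t3)), "atom 7")
})

test_that("two-pass alignment collapses rigid-body motion and is idempotent", {
  traj <- rigid_body_trajectory(n_atoms = 9, n_frames = 6, seed = 2)
  ens <- align_ensemble(combine_trajectories(list(traj)))
  for (f in 2:6)
    expect_lt(rmsd(ens$coords[, , 1], ens$coords[, , f]), 1e-6)
  again <- align_ensemble(ens)
  expect_lt(max(abs(again$coords - ens$coords)), 1e-6)
})

test_that("the second alignment pass never increases the mean RMSD to the mean structure", {
  sc <- small_scenario()
  sim <- simulate_conformer_ensemble(sc, seed = 7, start_shapes = "circular")
  ens0 <- sim$ensemble
  mask <- seq_len(nrow(ens0$topology))
  pass1 <- ens0$coords
  for (f in seq_len(n_frames(ens0))) {
    sp <- kabsch_superpose(ens0$coords[, , f], ens0$coords[, , 1], mask)
    pass1[, , f] <- apply_superposition(ens0$coords[, , f], sp)
  }
  mean1 <- apply(pass1, c(1, 2), mean)
  r1 <- mean(vapply(seq_len(dim(pass1)[3]), function(f)
    rmsd(pass1[, , f], mean1), numeric(1)))
  aligned <- align_ensemble(ens0)
  mean2 <- apply(aligned$coords, c(1, 2), mean)
  r2 <- mean(vapply(seq_len(n_frames(aligned)), function(f)
    rmsd(aligned$coords[, , f], mean2), numeric(1)))
  expect_lte(r2, r1 + 1e-9)
})

test_that("coordinate PCA conserves variance and reconstructs exactly", {
  sc <- small_scenario()
  sim <- simulate_conformer_ensemble(sc, seed = 3)
  ens <- align_ensemble(sim$ensemble)
  pca <- coordinate_pca(ens)
  mask <- pca$atom_mask
  X <- t(apply(ens$coords[mask, , , drop = FALSE], 3, as.numeric))
  total_var <- sum(apply(X, 2, var))
  expect_equal(sum(pca$eigenvalues), total_var, tolerance = 1e-6)
  # orthonormal components
  G <- crossprod(pca$components)
  expect_equal(G, diag(ncol(G)), tolerance = 1e-8, ignore_attr = TRUE)
  # full-rank reconstruction of the centred coordinates
  Xc <- sweep(X, 2, colMeans(X))
  recon <- pca$projections %*% t(pca$components)
  expect_lt(max(abs(recon - Xc)), 1e-8)

  expect_error(coordinate_pca(sim$ensemble), "align")
})

test_that("identical frames give all-zero eigenvalues", {
  one <- conformgen:::state_geometry("J", small_scenario(), "WT")
  coords <- array(rep(one, 4), c(nrow(one), 3, 4))
  traj <- trajectory(make_toy_topology(16), coords)
  ens <- align_ensemble(combine_trajectories(list(traj)))
  pca <- coordinate_pca(ens)
  expect_lt(max(pca$eigenvalues), 1e-12)
})

test_that("PC1 separates two planted conformational states with zero errors", {
  sc <- small_scenario()
  sim <- simulate_conformer_ensemble(sc, seed = 5, start_shapes = "circular")
  ens <- align_ensemble(sim$ensemble)
  pca <- coordinate_pca(ens)
  lab <- sim$truth_state
  keep <- lab %in% c("O", "J")
  pc1 <- pca$projections[keep, 1]
  grp <- lab[keep]
  # bimodal and linearly separable: the two states' PC1 ranges do not touch
  lo <- range(pc1[grp == "O"])
  hi <- range(pc1[grp == "J"])
  expect_true(lo[2] < hi[1] || hi[2] < lo[1])
  # planted separability: O-J gap exceeds 5x the coordinate noise
  gap <- abs(mean(pc1[grp == "J"]) - mean(pc1[grp == "O"]))
  expect_gt(gap, 5 * sc$noise_sd)
})

test_that("elbow rule finds three equidistant planted states and flags diffuse data", {
  set.seed(31)
  blobs <- rbind(matrix(rnorm(300, 0), ncol = 2),
                 matrix(rnorm(300, 12), ncol = 2),
                 cbind(rnorm(150, 0), rnorm(150, 12)))
  k <- select_k_elbow(blobs, n_pcs = 2, k_range = 1:8, seed = 1)
  expect_equal(as.integer(k), 3L)
  k2 <- select_k_elbow(blobs, n_pcs = 2, k_range = 1:8, seed = 1)
  expect_identical(as.integer(k), as.integer(k2))  # deterministic under the seed

  blob <- matrix(rnorm(600), ncol = 2)
  expect_message(kb <- select_k_elbow(blob, n_pcs = 2, k_range = 1:8, seed = 1),
                 "low-confidence")
  expect_true(as.integer(kb) %in% c(1L, 2L))
  expect_error(select_k_elbow(blobs, 2, integer(0)), "empty")
})

test_that("average-linkage clustering recovers planted states and ignores frame order", {
  sc <- small_scenario()
  sim <- simulate_conformer_ensemble(sc, seed = 11, start_shapes = "circular")
  ens <- align_ensemble(sim$ensemble)
  pca <- coordinate_pca(ens)
  cl <- hierarchical_clusters(pca, n_pcs = 4, n_clusters = 3)
  expect_equal(mclust::adjustedRandIndex(cl$assignment, sim$truth_state), 1.0)
  expect_equal(sort(unique(cl$assignment)), 1:3)
  expect_equal(cl$assignment[1], 1L)  # first-occurrence relabelling

  # permuting frames permutes labels but not the partition
  set.seed(2)
  perm <- sample(n_frames(ens))
  cl_p <- hierarchical_clusters(pca$projections[perm, ], 4, 3)
  expect_equal(mclust::adjustedRandIndex(cl_p$assignment,
                                         cl$assignment[perm]), 1.0)

  n <- nrow(pca$projections)
  singles <- hierarchical_clusters(pca, 4, n_clusters = n)
  expect_equal(sort(unique(singles$assignment)), seq_len(n))
  expect_error(hierarchical_clusters(pca, 4, n + 1), "exceeds")
})

test_that("cluster midpoints match an exhaustive distance scan", {
  set.seed(17)
  proj <- matrix(rnorm(60 * 4), ncol = 4)
  cl <- hierarchical_clusters(proj, n_pcs = 4, n_clusters = 5)
  mids <- cluster_midpoints(cl)
  for (c in 1:5) {
    members <- which(cl$assignment == c)
    ctr <- colMeans(proj[members, , drop = FALSE])
    d <- sqrt(rowSums(sweep(proj[members, , drop = FALSE], 2, ctr)^2))
    expect_equal(mids[c], members[which.min(d)])
  }
  # singleton cluster is its own midpoint
  one <- structure(list(assignment = c(1L, 2L, 2L), n_clusters = 2L,
                        n_pcs_used = 2L,
                        scores = matrix(c(0, 5, 6, 0, 5, 6), ncol = 2)),
                   class = "ensemble_clustering")
  expect_equal(cluster_midpoints(one)[1], 1L)
  # exact centroid member wins
  sym <- structure(list(assignment = rep(1L, 3), n_clusters = 1L,
                        n_pcs_used = 2L,
                        scores = rbind(c(-1, 0), c(0, 0), c(1, 0))),
                   class = "ensemble_clustering")
  expect_equal(cluster_midpoints(sym)[1], 2L)
})

test_that("cluster profiles report within-cluster similarity and occupancy conservation", {
  sc <- small_scenario()
  sim <- simulate_conformer_ensemble(sc, seed = 13)
  ens <- align_ensemble(sim$ensemble)
  pca <- coordinate_pca(ens)
  cl <- hierarchical_clusters(pca, 4, 3)
  cl$midpoint_frame <- cluster_midpoints(cl)
  prof <- cluster_profile(ens, cl)
  expect_equal(sum(prof$n_frames), n_frames(ens))
  expect_equal(sum(prof$n_WT + prof$n_VARIANT), n_frames(ens))
  expect_true(all(prof$mean_rmsd >= 0))
  # the extended states have strictly larger radius of gyration than the ring
  o_cl <- cl$assignment[1]
  expect_true(all(prof$mean_rg[prof$cluster != o_cl] >
                    prof$mean_rg[prof$cluster == o_cl]))

  # identical frames: zero spread
  one <- conformgen:::state_geometry("J", sc, "WT")
  dup <- trajectory(make_toy_topology(sc$n_residues),
                    array(rep(one, 5), c(nrow(one), 3, 5)))
  ens2 <- align_ensemble(combine_trajectories(list(dup)))
  cl2 <- structure(list(assignment = rep(1L, 5), n_clusters = 1L,
                        n_pcs_used = 1L, midpoint_frame = 1L,
                        scores = matrix(0, 5, 1)),
                   class = "ensemble_clustering")
  prof2 <- cluster_profile(ens2, cl2)
  expect_equal(prof2$mean_rmsd, 0, tolerance = 1e-9)
  expect_equal(prof2$sd_rmsd, 0, tolerance = 1e-9)
})

test_that("occupancy fractions are normalised and half-departure reflects the planted lag", {
  sc <- small_scenario()
  sim <- simulate_conformer_ensemble(sc, seed = 19)
  ens <- align_ensemble(sim$ensemble)
  pca <- coordinate_pca(ens)
  cl <- hierarchical_clusters(pca, 4, 3)
  ref <- cl$assignment[1]
  occ <- occupancy_timecourse(ens, cl, ref, n_bins = 10,
                              start_shape = "circular")
  sums <- aggregate(fraction ~ model_label + bin_mid, occ$occupancy, sum)
  expect_equal(sums$fraction, rep(1, nrow(sums)), tolerance = 1e-9)
  expect_true(occ$half_departure["VARIANT"] > occ$half_departure["WT"])

  # every frame in the reference cluster: outside fraction 0, no departure
  cl_all <- structure(list(assignment = rep(1L, n_frames(ens)),
                           n_clusters = 1L, n_pcs_used = 1L,
                           scores = matrix(0, n_frames(ens), 1)),
                      class = "ensemble_clustering")
  occ0 <- occupancy_timecourse(ens, cl_all, 1L, n_bins = 5)
  expect_true(all(occ0$outside$fraction == 0, na.rm = TRUE))
  expect_true(all(is.na(occ0$half_departure)))
})
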