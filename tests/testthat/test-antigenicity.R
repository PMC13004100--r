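small_clustered_ensemble <- function(seed = 29) {
  sc <- small_scenario()
  sim <- simulate_conformer_ensemble(sc, seed = seed)
  ens <- align_ensemble(sim$ensemble)
  pca <- coordinate_pca(ens)
  cl <- hierarchical_clusters(pca, 4, 3)
  list(sc = sc, ens = ens, cl = cl, truth = sim$truth_state)
}

test_that("cluster-frame sampling is uniform without replacement, within the stratum", {
  x <- small_clustered_ensemble()
  strata <- unique(data.frame(model = x$ens$provenance$model_label,
                              cluster = x$cl$assignment))
  set.seed(1)
  for (i in sample(nrow(strata), min(nrow(strata), 20), replace = TRUE)) {
    s <- sample_cluster_frames(x$ens, x$cl, strata$cluster[i],
                               strata$model[i], n = 10, seed = i)
    expect_true(all(x$cl$assignment[s] == strata$cluster[i]))
    expect_true(all(x$ens$provenance$model_label[s] == strata$model[i]))
    expect_false(any(duplicated(s)))
    expect_lte(length(s), 10)
    s2 <- sample_cluster_frames(x$ens, x$cl, strata$cluster[i],
                                strata$model[i], n = 10, seed = i)
    expect_identical(s, s2)
  }
  # stratum smaller than n: everything returned, with a note
  small <- which(x$cl$assignment == x$cl$assignment[1] &
                   x$ens$provenance$model_label == "WT")
  expect_message(
    all_of <- sample_cluster_frames(x$ens, x$cl, x$cl$assignment[1], "WT",
                                    n = length(small) + 50, seed = 1),
    "returning all")
  expect_identical(all_of, small)
  expect_error(sample_cluster_frames(x$ens, x$cl, 999, "WT", 10, 1), "empty")
})

test_that("surrogate scores are relative exposures in [0, 1], monotone in SASA", {
  x <- small_clustered_ensemble()
  frames <- seq(1, n_frames(x$ens), by = 10)
  sco <- surrogate_antigenicity(x$ens, frames, n_points = x$sc$n_points)
  # noise in the intra-residue geometry can nudge scores a little above 1
  expect_true(all(sco >= 0 & sco <= 1.1))
  expect_gt(mean(sco <= 1), 0.9)
  expect_equal(attr(sco, "scorer_tag"), "surrogate_rel_sasa")

  # a lone residue scores 1 by construction
  top1 <- make_toy_topology(10)[1:2, ]
  lone <- trajectory(top1, array(c(0, 0, 0, 0, 2.5, 0), c(2, 3, 1)))
  ens1 <- combine_trajectories(list(lone))
  s1 <- surrogate_antigenicity(ens1, 1L, n_points = 480)
  expect_equal(unname(s1[1, 1]), 1, tolerance = 1e-9)

  # monotone: per residue, score ranks across frames equal SASA ranks
  # exactly, because the normaliser is a per-residue constant
  sasa <- conformgen:::sasa_per_residue_frames(x$ens$coords, x$ens$topology,
                                               1.4, x$sc$n_points,
                                               frames = frames)
  sp <- vapply(seq_len(ncol(sco)), function(r)
    cor(sco[, r], sasa[, r], method = "spearman"), numeric(1))
  expect_equal(sp, rep(1, length(sp)))
})

test_that("external score import validates topology and round-trips exactly", {
  top <- make_toy_topology(10)
  d1 <- data.frame(residue_index = c(1, 2, 3), score = c(0.1, 0.5, 0.9))
  d2 <- data.frame(residue_index = c(2, 3, 4), score = c(0.2, 0.6, 1.0))
  p1 <- tempfile(fileext = ".csv"); write.csv(d1, p1, row.names = FALSE)
  p2 <- tempfile(fileext = ".csv"); write.csv(d2, p2, row.names = FALSE)
  sco <- import_external_scores(c(p1, p2), top, frame_indices = c(4L, 9L),
                                scorer_tag = "server_vX")
  expect_equal(sum(!is.na(sco)), 6L)
  expect_equal(sco["4", "2"], 0.5)
  expect_true(is.na(sco["9", "1"]))  # absent, not zero
  expect_equal(attr(sco, "scorer_tag"), "server_vX")

  # re-export and re-import preserves scores exactly
  p3 <- tempfile(fileext = ".csv")
  write.csv(data.frame(residue_index = as.integer(colnames(sco)),
                       score = sco["4", ]), p3, row.names = FALSE, na = "")
  back <- suppressWarnings(import_external_scores(p3, top))
  expect_equal(back[1, "2"], sco["4", "2"])

  bad <- data.frame(residue_index = 999, score = 0.5)
  pb <- tempfile(fileext = ".csv"); write.csv(bad, pb, row.names = FALSE)
  expect_error(import_external_scores(pb, top), "999")
  dup <- data.frame(residue_index = c(1, 1), score = c(0.1, 0.2))
  pd <- tempfile(fileext = ".csv"); write.csv(dup, pd, row.names = FALSE)
  expect_error(import_external_scores(pd, top), "duplicate")
})

test_that("stratum averaging is linear and degenerate cases behave", {
  x <- small_clustered_ensemble()
  frames <- seq(1, n_frames(x$ens), by = 7)
  sco <- surrogate_antigenicity(x$ens, frames, n_points = x$sc$n_points)
  tab <- average_antigenicity(sco, x$ens, x$cl)
  sco3 <- sco * 3
  attr(sco3, "scorer_tag") <- attr(sco, "scorer_tag")
  tab3 <- average_antigenicity(sco3, x$ens, x$cl)
  expect_equal(tab3$mean, 3 * tab$mean, tolerance = 1e-12)
  d <- exposure_delta(tab, x$sc$exposed_motif, "vs_reference_model",
                      "VARIANT", x$cl$assignment[1], reference_model = "WT")
  d3 <- exposure_delta(tab3, x$sc$exposed_motif, "vs_reference_model",
                       "VARIANT", x$cl$assignment[1], reference_model = "WT")
  expect_equal(d3$absolute_change, 3 * d$absolute_change, tolerance = 1e-12)
  expect_equal(d3$percent_change, d$percent_change, tolerance = 1e-9)

  # constant scores: means constant, all deltas 0
  const <- sco; const[] <- 0.5
  attr(const, "scorer_tag") <- "const"
  tabc <- average_antigenicity(const, x$ens, x$cl)
  expect_true(all(tabc$mean == 0.5))
  dc <- exposure_delta(tabc, x$sc$exposed_motif, "vs_reference_model",
                       "VARIANT", x$cl$assignment[1], reference_model = "WT")
  expect_equal(dc$percent_change, 0)

  # single scored frame: mean equals that frame
  one <- sco[1, , drop = FALSE]
  attr(one, "scorer_tag") <- "one"
  tab1 <- average_antigenicity(one, x$ens, x$cl)
  expect_equal(tab1$mean, unname(sco[1, ]))
  expect_true(all(tab1$sd == 0))
})

test_that("surrogate deltas agree in sign with SASA deltas on the same strata", {
  sc <- small_scenario()
  sim <- simulate_conformer_ensemble(sc, seed = 37, start_shapes = "linear")
  ens <- align_ensemble(sim$ensemble)
  cl <- structure(list(assignment = rep(1L, n_frames(ens)), n_clusters = 1L,
                       n_pcs_used = 1L, scores = matrix(0, n_frames(ens), 1)),
                  class = "ensemble_clustering")
  expo <- build_exposure_table(ens, cl, n_points = sc$n_points)
  sco <- surrogate_antigenicity(ens, seq_len(n_frames(ens)),
                                n_points = sc$n_points)
  anti <- average_antigenicity(sco, ens, cl)
  for (motif in list(sc$buried_loop, sc$exposed_motif)) {
    de <- exposure_delta(expo, motif, "vs_reference_model", "VARIANT", 1,
                         reference_model = "WT")
    da <- exposure_delta(anti, motif, "vs_reference_model", "VARIANT", 1,
                         reference_model = "WT")
    expect_equal(sign(de$percent_change), sign(da$percent_change))
  }
})
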