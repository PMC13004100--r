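# End-to-end orchestration: combine -> align -> PCA -> cluster -> profile
# -> exposure -> antigenicity -> TSV outputs + run manifest.

#' Pipeline configuration
#'
#' @param output_dir directory the output tables are written to (created
#'   if absent).
#' @param n_pcs principal components used for clustering (default 4).
#' @param n_clusters clusters the tree is cut into (default 6).
#' @param reference_cluster cluster id treated as the starting conformation
#'   for delta and occupancy computations.
#' @param reference_model model label the variant is compared against.
#' @param regions motif definitions: a path to a region config TSV or the
#'   list returned by [load_region_config()].
#' @param cluster_labels optional named character vector mapping cluster
#'   ids to display names (e.g. `c("1" = "O-Shape")`); conformational
#'   cluster naming is a caller decision, not inferred.
#' @param probe_radius,n_points SASA parameters.
#' @param sample_n frames sampled per stratum for antigenicity scoring.
#' @param n_bins time bins for the occupancy time course.
#' @param occupancy_start_shape starting-shape filter for the occupancy
#'   time course (default `"circular"`: follow the ring-opening runs).
#' @param seed seed recorded in every output header and used for frame
#'   sampling.
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(output_dir,
                            n_pcs = 4L, n_clusters = 6L,
                            reference_cluster = 1L, reference_model = "WT",
                            regions = default_region_config(),
                            cluster_labels = NULL,
                            probe_radius = 1.4, n_points = 960L,
                            sample_n = 100L, n_bins = 20L,
                            occupancy_start_shape = "circular",
                            seed = 1L) {
  if (is.character(regions)) {
    if (!file.exists(regions)) stop("region config not found: ", regions)
    regions <- load_region_config(regions)
  }
  structure(list(output_dir = output_dir, n_pcs = as.integer(n_pcs),
                 n_clusters = as.integer(n_clusters),
                 reference_cluster = as.integer(reference_cluster),
                 reference_model = reference_model, regions = regions,
                 cluster_labels = cluster_labels,
                 probe_radius = probe_radius, n_points = as.integer(n_points),
                 sample_n = as.integer(sample_n), n_bins = as.integer(n_bins),
                 occupancy_start_shape = occupancy_start_shape,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full ensemble analysis pipeline
#'
#' read/combine -> two-pass align -> coordinate PCA -> average-linkage
#' clustering -> cluster profiles and occupancy -> exposure table and motif
#' deltas -> surrogate-antigenicity table and deltas -> TSV outputs plus a
#' run manifest.  Deterministic given the trajectories, config and seed; a
#' stage failure removes any partial outputs and propagates with the stage
#' name.
#'
#' @param trajs list of [trajectory()] objects (from
#'   [read_multi_model_pdb()] or the synthetic generator).
#' @param config a [pipeline_config()].
#' @return invisible list with the in-memory results (`ensemble`, `pca`,
#'   `clustering`, `profile`, `occupancy`, `exposure`, `exposure_deltas`,
#'   `antigenicity`, `antigenicity_deltas`, `manifest`) and the output
#'   paths.
#' @export
run_ensemble_pipeline <- function(trajs, config) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$output_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  written <- character(0)
  stage <- "setup"
  on_fail <- function(e) {
    unlink(written)
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  }
  tryCatch({
    stage <- "combine"
    ens <- combine_trajectories(trajs)
    stage <- "align"
    ens <- align_ensemble(ens)
    stage <- "pca"
    pca <- coordinate_pca(ens)
    stage <- "cluster"
    clustering <- hierarchical_clusters(pca, config$n_pcs, config$n_clusters)
    clustering$midpoint_frame <- cluster_midpoints(clustering)
    label_of <- function(cl) {
      if (is.null(config$cluster_labels)) as.character(cl)
      else ifelse(is.na(config$cluster_labels[as.character(cl)]),
                  as.character(cl), config$cluster_labels[as.character(cl)])
    }
    hdr <- list(package = paste0("conformgen ", packageVersion("conformgen")),
                seed = config$seed, n_pcs = config$n_pcs,
                n_clusters = config$n_clusters,
                reference_cluster = config$reference_cluster,
                reference_model = config$reference_model,
                probe_radius = config$probe_radius, n_points = config$n_points,
                sample_n = config$sample_n, n_bins = config$n_bins)
    stage <- "projections"
    nshow <- min(config$n_pcs, ncol(pca$projections))
    proj <- data.frame(ens$provenance,
                       pca$projections[, seq_len(nshow), drop = FALSE],
                       cluster = clustering$assignment,
                       cluster_label = label_of(clustering$assignment))
    p_proj <- file.path(out_dir, "projections.tsv")
    write_tsv_with_header(proj, p_proj, hdr)
    written <- c(written, p_proj)
    stage <- "profile"
    prof <- cluster_profile(ens, clustering)
    prof$cluster_label <- label_of(prof$cluster)
    p_prof <- file.path(out_dir, "cluster_profile.tsv")
    write_tsv_with_header(prof, p_prof, hdr)
    written <- c(written, p_prof)
    stage <- "occupancy"
    occ <- occupancy_timecourse(ens, clustering, config$reference_cluster,
                                config$n_bins,
                                start_shape = config$occupancy_start_shape)
    p_occ <- file.path(out_dir, "occupancy.tsv")
    write_tsv_with_header(occ$occupancy, p_occ,
                          c(hdr, list(half_departure = paste(
                            names(occ$half_departure),
                            signif(occ$half_departure, 6), sep = "=",
                            collapse = "; "))))
    written <- c(written, p_occ)
    stage <- "exposure"
    expo <- build_exposure_table(ens, clustering, config$probe_radius,
                                 config$n_points)
    p_expo <- file.path(out_dir, "exposure.tsv")
    write_tsv_with_header(expo, p_expo, hdr)
    written <- c(written, p_expo)
    stage <- "exposure_deltas"
    deltas <- compute_all_deltas(expo, ens, config)
    p_ed <- file.path(out_dir, "exposure_deltas.tsv")
    write_tsv_with_header(deltas, p_ed, hdr)
    written <- c(written, p_ed)
    stage <- "antigenicity"
    anti <- score_strata_surrogate(ens, clustering, config)
    p_anti <- file.path(out_dir, "antigenicity.tsv")
    write_tsv_with_header(anti, p_anti,
                          c(hdr, list(scorer_tag = attr(anti, "scorer_tag"))))
    written <- c(written, p_anti)
    stage <- "antigenicity_deltas"
    adeltas <- compute_all_deltas(anti, ens, config)
    p_ad <- file.path(out_dir, "antigenicity_deltas.tsv")
    write_tsv_with_header(adeltas, p_ad, hdr)
    written <- c(written, p_ad)
    stage <- "manifest"
    manifest <- c(hdr,
                  list(n_trajectories = length(trajs),
                       n_frames = n_frames(ens),
                       n_atoms = nrow(ens$topology),
                       motifs = paste(names(config$regions), collapse = ","),
                       outputs = paste(basename(written), collapse = ",")))
    p_man <- file.path(out_dir, "manifest.tsv")
    write_tsv_with_header(
      data.frame(key = names(manifest),
                 value = vapply(manifest, paste, "", collapse = ";")),
      p_man)
    written <- c(written, p_man)
    invisible(list(ensemble = ens, pca = pca, clustering = clustering,
                   profile = prof, occupancy = occ, exposure = expo,
                   exposure_deltas = deltas, antigenicity = anti,
                   antigenicity_deltas = adeltas, manifest = manifest,
                   paths = written))
  }, error = on_fail)
}

# Motif deltas for every motif whose residues exist in the topology, every
# model and every non-reference cluster, in both comparison modes.
compute_all_deltas <- function(table, ens, config) {
  residues <- unique(ens$topology$residue_index)
  usable <- Filter(function(m) all(m$residue_indices %in% residues),
                   config$regions)
  skipped <- setdiff(names(config$regions), names(usable))
  if (length(skipped))
    message("motif(s) outside the topology skipped: ",
            paste(skipped, collapse = ", "))
  models <- unique(table$model_label)
  clusters <- unique(table$cluster)
  rows <- list()
  for (m in usable) for (mod in models) for (cl in clusters) {
    if (cl != config$reference_cluster &&
        any(table$model_label == mod & table$cluster == cl) &&
        any(table$model_label == mod &
              table$cluster == config$reference_cluster))
      rows[[length(rows) + 1L]] <-
        exposure_delta(table, m, "vs_reference_cluster", mod, cl,
                       reference_cluster = config$reference_cluster)
    if (mod != config$reference_model &&
        any(table$model_label == mod & table$cluster == cl) &&
        any(table$model_label == config$reference_model &
              table$cluster == cl))
      rows[[length(rows) + 1L]] <-
        exposure_delta(table, m, "vs_reference_model", mod, cl,
                       reference_model = config$reference_model)
  }
  if (length(rows) == 0L)
    return(data.frame(motif_name = character(0), comparison = character(0),
                      model_label = character(0), cluster = integer(0),
                      target_mean = numeric(0), reference_mean = numeric(0),
                      absolute_change = numeric(0),
                      percent_change = numeric(0),
                      percent_undefined = logical(0)))
  do.call(rbind, rows)
}

# Surrogate-antigenicity table over sampled frames of every stratum.
score_strata_surrogate <- function(ens, clustering, config) {
  strata <- unique(data.frame(model = ens$provenance$model_label,
                              cluster = clustering$assignment,
                              stringsAsFactors = FALSE))
  frames <- integer(0)
  for (i in seq_len(nrow(strata)))
    frames <- c(frames,
                sample_cluster_frames(ens, clustering, strata$cluster[i],
                                      strata$model[i], n = config$sample_n,
                                      seed = derive_seed(config$seed, i)))
  frames <- sort(unique(frames))
  scores <- surrogate_antigenicity(ens, frames, config$probe_radius,
                                   config$n_points)
  average_antigenicity(scores, ens, clustering)
}
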