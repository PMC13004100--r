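# Frame sampling per cluster, per-residue antigenicity scores (imported
# from an external epitope-prediction export, or a SASA-based surrogate),
# stratum averaging and motif-level deltas.

#' Sample frames from a (model, cluster) stratum
#'
#' Uniform sampling without replacement.  If the stratum holds at most `n`
#' frames, all of them are returned (with a note).
#'
#' @param ens a `conf_ensemble`.
#' @param clustering an `ensemble_clustering`.
#' @param cluster,model the stratum.
#' @param n frames to draw (default 100).
#' @param seed RNG seed.
#' @return sorted integer vector of frame indices.
#' @export
sample_cluster_frames <- function(ens, clustering, cluster, model,
                                  n = 100L, seed = 1L) {
  stratum <- which(clustering$assignment == cluster &
                     ens$provenance$model_label == model)
  if (length(stratum) == 0L)
    stop("empty stratum: model ", model, ", cluster ", cluster)
  if (length(stratum) <= n) {
    message("stratum has ", length(stratum), " <= ", n,
            " frames; returning all of them")
    return(stratum)
  }
  set.seed(seed)
  sort(sample(stratum, n))
}

#' Surrogate per-residue antigenicity score (relative solvent exposure)
#'
#' Residue SASA divided by that residue's isolated maximum accessibility:
#' the SASA its atoms would have detached from the rest of the structure.
#' As in standard relative-accessibility normalisation, the maximum is a
#' per-residue *constant* (the median over the scored frames of the
#' isolated-residue area), so scores are monotone in SASA within a run and
#' lie in `[0, 1]` up to coordinate noise in the intra-residue geometry.
#' This is a transparent, fully offline stand-in scorer: it is NOT the
#' external structure-based epitope predictor, and outputs carry the
#' scorer tag `"surrogate_rel_sasa"` to make that explicit.
#'
#' @param ens a `conf_ensemble` (or `trajectory`).
#' @param frames frame indices to score.
#' @param probe_radius,n_points SASA parameters.
#' @return a frames x residues matrix of scores in `[0, 1]` (rows named by
#'   frame index).
#' @export
surrogate_antigenicity <- function(ens, frames, probe_radius = 1.4,
                                   n_points = 960L) {
  top <- ens$topology
  sasa <- sasa_per_residue_frames(ens$coords, top, probe_radius, n_points,
                                  frames = frames)
  # Isolated maximum accessibility per residue and frame: evaluate SASA on
  # an "exploded" copy of the frame in which each residue is translated far
  # from every other, removing all inter-residue occlusion while keeping
  # the intra-residue geometry.
  offset <- (max(abs(ens$coords[, , frames])) + 1000) *
    match(top$residue_index, unique(top$residue_index))
  iso <- matrix(NA_real_, length(frames), ncol(sasa),
                dimnames = dimnames(sasa))
  pts <- golden_spiral_points(n_points)
  res_f <- factor(top$residue_index, levels = colnames(sasa))
  for (k in seq_along(frames)) {
    ex <- ens$coords[, , frames[k]]
    ex[, 1] <- ex[, 1] + offset
    pa <- sasa_per_atom_cpp(ex, top$vdw_radius, probe_radius, pts)
    iso[k, ] <- as.numeric(tapply(pa, res_f, sum))
  }
  iso_ref <- apply(iso, 2, stats::median)
  out <- sweep(sasa, 2, iso_ref, "/")
  rownames(out) <- frames
  attr(out, "scorer_tag") <- "surrogate_rel_sasa"
  out
}

#' Import per-frame per-residue antigenicity scores from CSV exports
#'
#' One CSV per frame (e.g. exported from an external epitope-prediction
#' server); column names are configurable to absorb export dialects.
#' Scores are validated against the topology residue range; residues absent
#' from a file are recorded as missing (`NA`), not zero.
#'
#' @param paths character vector of CSV paths, one per frame.
#' @param frame_indices frame index each file belongs to (defaults to
#'   1..length(paths)).
#' @param topology topology the scores must conform to.
#' @param residue_col,score_col column names in the CSVs.
#' @param scorer_tag label recorded on the result (e.g. the external tool's
#'   name and version).
#' @return a frames x residues matrix (rows named by frame index) with
#'   attribute `scorer_tag`.
#' @export
import_external_scores <- function(paths, topology,
                                   frame_indices = seq_along(paths),
                                   residue_col = "residue_index",
                                   score_col = "score",
                                   scorer_tag = "external") {
  res_lev <- sort(unique(topology$residue_index))
  out <- matrix(NA_real_, length(paths), length(res_lev),
                dimnames = list(frame_indices, res_lev))
  for (i in seq_along(paths)) {
    df <- read.csv(paths[i], stringsAsFactors = FALSE)
    if (!all(c(residue_col, score_col) %in% names(df)))
      stop("file ", paths[i], " lacks columns ", residue_col, "/", score_col)
    res <- df[[residue_col]]
    if (anyDuplicated(res))
      stop("duplicate residue ", res[duplicated(res)][1], " in ", paths[i])
    bad <- setdiff(res, res_lev)
    if (length(bad))
      stop("residue ", bad[1], " in ", paths[i], " is outside the topology")
    out[i, match(res, res_lev)] <- df[[score_col]]
  }
  attr(out, "scorer_tag") <- scorer_tag
  out
}

#' Average antigenicity scores per stratum
#'
#' Per-residue mean/sd of the supplied scores within each (model, cluster)
#' stratum, in the same table shape as [build_exposure_table()], so motif
#' means and deltas are computed identically to exposure deltas (via
#' [motif_exposure()] / [exposure_delta()]).
#'
#' @param scores frames x residues score matrix with rows named by frame
#'   index ([surrogate_antigenicity()] or [import_external_scores()]).
#' @param ens the `conf_ensemble` the frames belong to.
#' @param clustering the `ensemble_clustering`.
#' @return an `exposure_table`-shaped data frame with `value_type =
#'   "antigenicity"` and the scorer tag carried over.
#' @export
average_antigenicity <- function(scores, ens, clustering) {
  frames <- as.integer(rownames(scores))
  if (any(is.na(frames))) stop("score matrix rows must be named by frame index")
  keep <- !apply(is.na(scores), 1, all)
  if (!any(keep)) stop("no scored frames")
  scores <- scores[keep, , drop = FALSE]
  frames <- frames[keep]
  tab <- stratum_table(scores, ens$provenance$model_label[frames],
                       clustering$assignment[frames],
                       value_type = "antigenicity",
                       scorer_tag = attr(scores, "scorer_tag") %||% "unknown")
  tab
}

`%||%` <- function(a, b) if (is.null(a)) b else a
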