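# Per-residue SASA aggregated by (model, cluster) and motif-level exposure
# deltas between conformations and between models.

#' Build a per-stratum residue exposure table
#'
#' Computes per-residue Shrake-Rupley SASA for every frame and averages
#' within each (model, cluster) stratum.
#'
#' @param ens a `conf_ensemble`.
#' @param clustering an `ensemble_clustering` covering the ensemble.
#' @param probe_radius,n_points SASA parameters (see
#'   [shrake_rupley_sasa()]).
#' @return data frame of class `"exposure_table"` with columns
#'   `model_label`, `cluster`, `residue_index`, `mean`, `sd`, `n_frames`.
#'   Attribute `value_type` is `"sasa"` (A^2).
#' @export
build_exposure_table <- function(ens, clustering, probe_radius = 1.4,
                                 n_points = 960L) {
  stopifnot(inherits(ens, "conf_ensemble"))
  if (length(clustering$assignment) != n_frames(ens))
    stop("clustering does not cover the ensemble")
  sasa <- sasa_per_residue_frames(ens$coords, ens$topology,
                                  probe_radius, n_points)
  stratum_table(sasa, ens$provenance$model_label, clustering$assignment,
                value_type = "sasa")
}

# Shared aggregator: frames x residues value matrix -> per (model, cluster,
# residue) mean/sd/n.  Also used for antigenicity scores.
stratum_table <- function(values, model_label, cluster, value_type,
                          scorer_tag = NULL) {
  res_idx <- as.integer(colnames(values))
  strata <- split(seq_len(nrow(values)),
                  list(model = model_label, cluster = cluster), drop = TRUE)
  rows <- lapply(names(strata), function(key) {
    fs <- strata[[key]]
    part <- strsplit(key, ".", fixed = TRUE)[[1]]
    v <- values[fs, , drop = FALSE]
    data.frame(model_label = part[1], cluster = as.integer(part[2]),
               residue_index = res_idx,
               mean = colMeans(v),
               sd = if (nrow(v) > 1) apply(v, 2, sd) else 0,
               n_frames = nrow(v), row.names = NULL,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$model_label, out$cluster, out$residue_index), ]
  rownames(out) <- NULL
  attr(out, "value_type") <- value_type
  if (!is.null(scorer_tag)) attr(out, "scorer_tag") <- scorer_tag
  class(out) <- c("exposure_table", class(out))
  out
}

#' Motif-level exposure in one stratum
#'
#' Sum of the member residues' mean values (the motif is treated as a unit,
#' the way loop-level mean SASA is reported).
#'
#' @param table an `exposure_table` (SASA or antigenicity scores).
#' @param motif a motif definition from [load_region_config()], or an
#'   integer vector of residue indices.
#' @param model,cluster the stratum.
#' @return the motif mean value (A^2 for SASA tables).
#' @export
motif_exposure <- function(table, motif, model, cluster) {
  idx <- if (is.list(motif)) motif$residue_indices else as.integer(motif)
  sel <- table$model_label == model & table$cluster == cluster
  if (!any(sel)) stop("no stratum (", model, ", cluster ", cluster, ") in table")
  sub <- table[sel, , drop = FALSE]
  missing <- setdiff(idx, sub$residue_index)
  if (length(missing))
    stop("motif residue(s) missing from table: ",
         paste(missing, collapse = ", "))
  sum(sub$mean[match(idx, sub$residue_index)])
}

#' Motif exposure change between strata
#'
#' `vs_reference_cluster` compares (model, cluster) against (model,
#' reference_cluster): how the motif changes as the conformation changes
#' within a model.  `vs_reference_model` compares (model, cluster) against
#' (reference_model, cluster): how a variant changes the motif within the
#' same conformation.  Negative percent change = more buried.
#'
#' @param table an `exposure_table`.
#' @param motif motif definition or residue index vector.
#' @param mode `"vs_reference_cluster"` or `"vs_reference_model"`.
#' @param model,cluster the target stratum.
#' @param reference_cluster,reference_model the reference context for the
#'   respective mode.
#' @return data frame of class `"exposure_delta"`: `motif_name`,
#'   `comparison`, `model_label`, `cluster`, `target_mean`,
#'   `reference_mean`, `absolute_change`, `percent_change` (`NA` with a
#'   `percent_undefined` flag when the reference mean is 0).
#' @export
exposure_delta <- function(table, motif,
                           mode = c("vs_reference_cluster", "vs_reference_model"),
                           model, cluster,
                           reference_cluster = NULL, reference_model = NULL) {
  mode <- match.arg(mode)
  target <- motif_exposure(table, motif, model, cluster)
  ref <- switch(mode,
    vs_reference_cluster = {
      if (is.null(reference_cluster)) stop("reference_cluster required")
      motif_exposure(table, motif, model, reference_cluster)
    },
    vs_reference_model = {
      if (is.null(reference_model)) stop("reference_model required")
      motif_exposure(table, motif, reference_model, cluster)
    })
  abs_change <- target - ref
  pct <- if (ref > 0) 100 * abs_change / ref else NA_real_
  out <- data.frame(
    motif_name = if (is.list(motif)) motif$name else paste(motif, collapse = ","),
    comparison = mode, model_label = model, cluster = cluster,
    target_mean = target, reference_mean = ref,
    absolute_change = abs_change, percent_change = pct,
    percent_undefined = ref <= 0,
    stringsAsFactors = FALSE)
  class(out) <- c("exposure_delta", class(out))
  out
}
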