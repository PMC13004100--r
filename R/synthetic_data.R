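# Synthetic generators: (a) two-bead-per-residue conformer trajectories
# with planted circular -> extended transitions and residue burial/exposure
# changes; (b) two-trait GWAS summary statistics with known causal
# structure under AR(1)-style LD.

#' Toy two-bead-per-residue topology
#'
#' Each residue contributes a backbone bead (`"CA"`, vdW radius 1.9 A) and
#' a side bead (`"CB"`, radius 2.0 A) that sits 2.5 A from its backbone
#' bead in every generated frame.  Atom order is (res1 CA, res1 CB,
#' res2 CA, ...).
#'
#' @param n_residues chain length (>= 10).
#' @return a topology data frame (see [trajectory()]).
#' @export
make_toy_topology <- function(n_residues = 60L) {
  stopifnot(n_residues >= 10L)
  n <- as.integer(n_residues)
  data.frame(atom_index = seq_len(2L * n),
             atom_name = rep(c("CA", "CB"), n),
             element = "C",
             residue_index = rep(seq_len(n), each = 2L),
             residue_name = "GLY",
             chain_id = "A",
             vdw_radius = rep(c(1.9, 2.0), n),
             stringsAsFactors = FALSE)
}

#' Conformer-trajectory scenario
#'
#' Bundles every knob of the synthetic conformer generator.  The defaults
#' are the package's standard study conditions: a 60-residue chain visiting
#' three states (O = circular, J = singly-bent extended, S = doubly-bent
#' extended) under a logistic transition schedule, with the VARIANT model
#' transitioning later than the WT (the planted analogue of a slower
#' ring-opening), a Domain-V-like loop planted 30% more buried and an
#' epitope-like motif planted 15% more exposed in the VARIANT's extended
#' states, isotropic coordinate noise of 0.5 A, and 4 repeats of 200 frames
#' per (model, start shape).
#'
#' @param n_residues chain length.
#' @param transition_midpoint named frame index per model at which the
#'   first (O to J) transition is half-complete; the VARIANT midpoint must
#'   be >= the WT's.
#' @param transition_gap frames between the O-to-J and J-to-S midpoints.
#' @param transition_rate logistic slope per frame (larger = sharper).
#'   The default makes the switch complete within one coordinate-save
#'   interval: transitions between metastable conformations are fast
#'   relative to the dwell times, so every saved frame sits at a state
#'   rather than along the path.  Smaller values recover a gradual
#'   interpolating schedule.
#' @param midpoint_jitter standard deviation (frames) of the per-repeat
#'   Gaussian jitter on the transition midpoints, so repeats of the same
#'   model transition at slightly different times and the ensemble-level
#'   shift away from the circular state looks gradual.
#' @param noise_sd isotropic Gaussian coordinate noise, angstrom.
#' @param buried_loop residue indices of the loop planted to bury in the
#'   VARIANT's extended states.
#' @param burial_fraction target fractional SASA loss of `buried_loop`
#'   (0.30 = 30% more buried than WT in the same state).
#' @param exposed_motif residue indices planted to gain exposure.
#' @param exposure_fraction target fractional SASA gain of `exposed_motif`.
#' @param n_frames frames per repeat.
#' @param n_repeats repeats per (model, start_shape).
#' @param probe_radius,n_points SASA parameters used when calibrating the
#'   planted burial/exposure geometry.
#' @return list of class `"conformer_scenario"`.
#' @export
conformer_scenario <- function(n_residues = 60L,
                               transition_midpoint = c(WT = 60, VARIANT = 90),
                               transition_gap = 70,
                               transition_rate = 15,
                               midpoint_jitter = 5,
                               noise_sd = 0.5,
                               buried_loop = 28:30,
                               burial_fraction = 0.30,
                               exposed_motif = 45:48,
                               exposure_fraction = 0.15,
                               n_frames = 200L,
                               n_repeats = 4L,
                               probe_radius = 1.4,
                               n_points = 960L) {
  stopifnot(burial_fraction > 0, burial_fraction < 1,
            exposure_fraction > 0, exposure_fraction < 1)
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (!all(c("WT", "VARIANT") %in% names(transition_midpoint)))
    stop("transition_midpoint needs WT and VARIANT entries")
  if (transition_midpoint[["VARIANT"]] < transition_midpoint[["WT"]])
    stop("VARIANT transition midpoint must be >= WT's")
  sc <- list(n_residues = as.integer(n_residues),
             states = c("O", "J", "S"),
             transition_midpoint = transition_midpoint,
             transition_gap = transition_gap,
             transition_rate = transition_rate,
             midpoint_jitter = midpoint_jitter,
             noise_sd = noise_sd,
             buried_loop = as.integer(buried_loop),
             burial_fraction = burial_fraction,
             exposed_motif = as.integer(exposed_motif),
             exposure_fraction = exposure_fraction,
             n_frames = as.integer(n_frames),
             n_repeats = as.integer(n_repeats),
             probe_radius = probe_radius,
             n_points = as.integer(n_points),
             calibration = NULL)
  class(sc) <- "conformer_scenario"
  sc
}

# Backbone-bead (CA) positions of a state geometry.
# O: equally spaced on a circle of radius 3.8 / (2 sin(pi/n)) so that
#    neighbour spacing is 3.8 A.
# J: straight line at 3.8 A spacing with the last ceil(n/6) residues bent
#    90 degrees.
# S: line with two opposite 90-degree bends over the last two ceil(n/6)
#    segments.
state_backbone <- function(state, n) {
  m <- ceiling(n / 6)
  if (state == "O") {
    R <- 3.8 / (2 * sin(pi / n))
    th <- 2 * pi * (seq_len(n) - 1) / n
    return(cbind(R * cos(th), R * sin(th), 0))
  }
  dirs <- matrix(rep(c(1, 0, 0), n), ncol = 3, byrow = TRUE)
  if (state == "J") {
    if (m >= 1) dirs[seq(n - m + 1, n), ] <- rep(c(0, 1, 0), each = m)
  } else if (state == "S") {
    dirs[seq(n - 2 * m + 1, n - m), ] <- rep(c(0, 1, 0), each = m)
    dirs[seq(n - m + 1, n), ] <- rep(c(1, 0, 0), each = m)
  } else stop("unknown state ", state)
  ca <- apply(dirs * 3.8, 2, cumsum)
  sweep(ca, 2, ca[1, ])   # start at the origin
}

# Full two-bead geometry of a state.  Side beads sit 2.5 A from their CA:
# radially outward on the circle, along +z on the extended states.  In the
# extended states the buried-loop side beads protrude a further 2 A in both
# models (the membrane-insertion-loop analogue: a hydrophobic loop that
# sticks out of the solvated surface); in the VARIANT they are pulled from
# that protruded position toward the midpoint of the flanking backbone
# beads by the calibrated tuck factor, and exposed-motif side beads are
# pushed further out by the calibrated extra offset.
state_geometry <- function(state, scenario, model, tuck = 0, push = 0) {
  n <- scenario$n_residues
  ca <- state_backbone(state, n)
  if (state == "O") {
    R <- 3.8 / (2 * sin(pi / n))
    cb <- ca * (R + 2.5) / R
    cb[, 3] <- 0
  } else {
    cb <- ca
    cb[, 3] <- cb[, 3] + 2.5
    cb[scenario$buried_loop, 3] <- cb[scenario$buried_loop, 3] + 2
    if (model == "VARIANT") {
      for (i in scenario$buried_loop) {
        j <- if (i < n) i + 1L else i - 1L
        q <- (ca[i, ] + ca[j, ]) / 2
        cb[i, ] <- (1 - tuck) * cb[i, ] + tuck * q
      }
      cb[scenario$exposed_motif, 3] <- cb[scenario$exposed_motif, 3] + push
    }
  }
  coords <- matrix(0, 2 * n, 3)
  coords[seq(1, 2 * n, 2), ] <- ca
  coords[seq(2, 2 * n, 2), ] <- cb
  coords
}

# Correlation between two equal-threshold indicator variables generated by
# thresholding standard bivariate normals with latent correlation r.
indicator_corr <- function(r, threshold) {
  if (r >= 1) return(1)
  if (abs(r) < 1e-12) return(0)
  p <- pnorm(threshold)
  p11 <- stats::integrate(function(x)
    dnorm(x) * pnorm((threshold - r * x) / sqrt(1 - r^2)),
    -8, threshold, rel.tol = 1e-9)$value
  (p11 - p^2) / (p * (1 - p))
}

# Latent correlation needed for a target indicator (= dosage) correlation.
latent_corr_for_indicator <- function(target, threshold) {
  if (target <= 1e-6) return(target)
  stats::uniroot(function(r) indicator_corr(r, threshold) - target,
                 c(target, 1 - 1e-9), tol = 1e-6)$root
}

# Noiseless motif SASA of a single geometry, residue-level sum.
motif_sasa_of_geometry <- function(coords, topology, residues, scenario) {
  pa <- sasa_per_atom_cpp(coords, topology$vdw_radius,
                          scenario$probe_radius,
                          golden_spiral_points(scenario$n_points))
  sum(pa[topology$residue_index %in% residues])
}

#' Calibrate the planted burial and exposure geometry of a scenario
#'
#' Solves, on the noiseless J-state geometry, for (i) the side-bead tuck
#' factor that makes the buried loop's SASA equal `(1 - burial_fraction)`
#' times its WT value and (ii) the extra side-bead offset that makes the
#' exposed motif's SASA equal `(1 + exposure_fraction)` times WT.  Stored
#' in the scenario and reused by every trajectory so the planted deltas are
#' consistent across repeats.
#'
#' @param scenario a [conformer_scenario()].
#' @return the scenario with `$calibration = list(tuck, push)` filled in.
#' @export
calibrate_scenario <- function(scenario) {
  if (!is.null(scenario$calibration)) return(scenario)
  top <- make_toy_topology(scenario$n_residues)
  wt <- state_geometry("J", scenario, "WT")
  wt_buried <- motif_sasa_of_geometry(wt, top, scenario$buried_loop, scenario)
  wt_exposed <- motif_sasa_of_geometry(wt, top, scenario$exposed_motif, scenario)
  f_tuck <- function(t) {
    g <- state_geometry("J", scenario, "VARIANT", tuck = t, push = 0)
    motif_sasa_of_geometry(g, top, scenario$buried_loop, scenario) /
      wt_buried - (1 - scenario$burial_fraction)
  }
  f_push <- function(s) {
    g <- state_geometry("J", scenario, "VARIANT", tuck = 0, push = s)
    motif_sasa_of_geometry(g, top, scenario$exposed_motif, scenario) /
      wt_exposed - (1 + scenario$exposure_fraction)
  }
  tuck <- if (f_tuck(1) > 0) {
    warning("maximum side-bead tuck cannot reach the burial target; using 1")
    1
  } else stats::uniroot(f_tuck, c(0, 1), tol = 1e-4)$root
  push <- if (f_push(6) < 0) {
    warning("maximum side-bead push cannot reach the exposure target; using 6")
    6
  } else stats::uniroot(f_push, c(0, 6), tol = 1e-4)$root
  scenario$calibration <- list(tuck = tuck, push = push)
  scenario
}

#' Simulate one conformer trajectory with ground truth
#'
#' Circular starts follow a logistic O-to-J-to-S schedule (linear
#' interpolation between consecutive state geometries, weighted by logistic
#' switches at the model's midpoints) plus isotropic Gaussian noise; linear
#' starts stay pinned at the J geometry throughout.  The VARIANT model
#' carries the calibrated buried-loop / exposed-motif side-bead changes in
#' its extended-state geometries.
#'
#' @param scenario a [conformer_scenario()] (calibrated automatically if
#'   needed).
#' @param model `"WT"` or `"VARIANT"`.
#' @param start_shape `"circular"` or `"linear"`.
#' @param repeat_id replicate id recorded in the provenance.
#' @param seed RNG seed; fixed seed reproduces coordinates bit-identically.
#' @return list with `trajectory` (frames at 0.1 ns spacing) and `truth`
#'   (per-frame state labels, per-residue exposure classes, planted
#'   fractions and calibration).
#' @export
simulate_conformer_trajectory <- function(scenario, model = "WT",
                                          start_shape = "circular",
                                          repeat_id = 1L, seed = 1L) {
  stopifnot(inherits(scenario, "conformer_scenario"))
  model <- match.arg(model, c("WT", "VARIANT"))
  start_shape <- match.arg(start_shape, c("circular", "linear"))
  scenario <- calibrate_scenario(scenario)
  cal <- if (model == "VARIANT") scenario$calibration else list(tuck = 0, push = 0)
  top <- make_toy_topology(scenario$n_residues)
  g_o <- state_geometry("O", scenario, model)
  g_j <- state_geometry("J", scenario, model, cal$tuck, cal$push)
  g_s <- state_geometry("S", scenario, model, cal$tuck, cal$push)
  nf <- scenario$n_frames
  t_idx <- seq_len(nf)
  set.seed(seed)
  coords <- array(0, c(nrow(top), 3, nf))
  if (start_shape == "linear") {
    state <- rep("J", nf)
    for (f in t_idx)
      coords[, , f] <- g_j + matrix(rnorm(3 * nrow(top), 0, scenario$noise_sd),
                                    ncol = 3)
  } else {
    # Midpoints are snapped to half-integer frame indices so the switch is
    # half-complete *between* two saved frames: every saved frame sits at a
    # state geometry (plus noise), matching the metastable-hop picture in
    # which the transit time is short against the coordinate-save interval.
    m1 <- round(scenario$transition_midpoint[[model]] +
                  rnorm(1, 0, scenario$midpoint_jitter)) + 0.5
    m2 <- round(m1 + scenario$transition_gap +
                  rnorm(1, 0, scenario$midpoint_jitter)) + 0.5
    w1 <- stats::plogis(scenario$transition_rate * (t_idx - m1))
    w2 <- stats::plogis(scenario$transition_rate * (t_idx - m2))
    state <- ifelse(w1 < 0.5, "O", ifelse(w2 < 0.5, "J", "S"))
    for (f in t_idx) {
      pos <- g_o + w1[f] * (g_j - g_o) + w2[f] * (g_s - g_j)
      coords[, , f] <- pos + matrix(rnorm(3 * nrow(top), 0, scenario$noise_sd),
                                    ncol = 3)
    }
  }
  res_class <- rep("neutral", scenario$n_residues)
  res_class[scenario$buried_loop] <- "buried_in_variant"
  res_class[scenario$exposed_motif] <- "exposed_in_variant"
  traj <- trajectory(top, coords, time = 0.1 * t_idx, model_label = model,
                     start_shape = start_shape, repeat_id = repeat_id)
  list(trajectory = traj,
       truth = list(state = state,
                    residue_class = res_class,
                    burial_fraction = scenario$burial_fraction,
                    exposure_fraction = scenario$exposure_fraction,
                    calibration = scenario$calibration))
}

#' Simulate the full default conformer ensemble
#'
#' All (model, start shape, repeat) combinations of the scenario, combined
#' into one ensemble with per-frame ground-truth state labels.
#'
#' @param scenario a [conformer_scenario()].
#' @param seed base seed; each trajectory draws a derived sub-seed.
#' @param models,start_shapes subsets to generate.
#' @return list with `ensemble` (a `conf_ensemble`), `truth_state`
#'   (per-frame planted state label), `residue_class`, and the calibrated
#'   `scenario`.
#' @export
simulate_conformer_ensemble <- function(scenario, seed = 1L,
                                        models = c("WT", "VARIANT"),
                                        start_shapes = c("circular", "linear")) {
  scenario <- calibrate_scenario(scenario)
  trajs <- list()
  states <- list()
  res_class <- NULL
  k <- 0L
  for (model in models) for (shape in start_shapes)
    for (rep_i in seq_len(scenario$n_repeats)) {
      k <- k + 1L
      sim <- simulate_conformer_trajectory(scenario, model, shape, rep_i,
                                           seed = derive_seed(seed, k))
      trajs[[k]] <- sim$trajectory
      states[[k]] <- sim$truth$state
      res_class <- sim$truth$residue_class
    }
  list(ensemble = combine_trajectories(trajs),
       truth_state = unlist(states),
       residue_class = res_class,
       scenario = scenario)
}

#' Simulate two-trait GWAS summary statistics with known causal structure
#'
#' Genotypes are drawn by thresholding a latent Gaussian at the locus
#' allele frequency (two independent latent draws per individual = two
#' Hardy-Weinberg alleles); the latent correlations are calibrated so the
#' realized *dosage* correlations approximate the AR(1) target
#' `ld_rho^|i-j|`.  Each trait is the causal variant's dosage scaled to the
#' stated variance explained plus standard normal noise, and per-variant
#' marginal regressions give beta/se/p.  With `shared = FALSE` the second
#' trait's causal variant is drawn at least 20 positions away.
#'
#' @param m_variants number of variants.
#' @param n sample count per trait (independent cohorts).
#' @param ld_rho AR(1) latent correlation between adjacent variants.
#' @param causal_index causal variant of trait 1 (default: middle).
#' @param shared if `TRUE` both traits share the causal variant.
#' @param variance_explained fraction of trait variance from the causal
#'   dosage (0 plants a null trait pair).
#' @param maf_range range the locus-level minor-allele frequency is drawn
#'   from (shared by all variants of the block, as in a real tight LD
#'   block).
#' @param seed RNG seed.
#' @return list with `trait1`, `trait2` (summary-stat data frames),
#'   `genotypes1`, `genotypes2` (dosage matrices), and `truth`
#'   (causal indices, true effects, `shared`).
#' @export
simulate_two_trait_summary_stats <- function(m_variants = 50L, n = 5000L,
                                             ld_rho = 0.9,
                                             causal_index = NULL,
                                             shared = TRUE,
                                             variance_explained = 0.01,
                                             maf_range = c(0.05, 0.5),
                                             seed = 1L) {
  set.seed(seed)
  m <- as.integer(m_variants)
  if (is.null(causal_index)) causal_index <- ceiling(m / 2)
  stopifnot(causal_index >= 1L, causal_index <= m)
  # One locus-level MAF shared by all variants: variants in a tight LD
  # block carry near-identical allele frequencies (a target correlation of
  # rho between binary dosages is only attainable when the frequencies
  # match).  The latent Gaussian correlation is then calibrated per lag so
  # the *realized dosage* correlation approximates rho^|i-j|, undoing the
  # attenuation that thresholding causes.
  maf <- rep(runif(1, maf_range[1], maf_range[2]), m)
  thr <- qnorm(maf[1])
  lag_target <- ld_rho^seq_len(m - 1)
  lag_latent <- vapply(lag_target, latent_corr_for_indicator,
                       numeric(1), threshold = thr)
  Sigma <- diag(m)
  for (k in seq_len(m - 1)) {
    idx <- cbind(seq_len(m - k), seq_len(m - k) + k)
    Sigma[idx] <- lag_latent[k]
    Sigma[idx[, 2:1, drop = FALSE]] <- lag_latent[k]
  }
  U <- tryCatch(chol(Sigma),
                error = function(e) chol(Sigma + diag(1e-6, m)))
  draw_genotypes <- function() {
    a1 <- matrix(rnorm(n * m), n, m) %*% U < thr
    a2 <- matrix(rnorm(n * m), n, m) %*% U < thr
    G <- a1 + a2
    colnames(G) <- sprintf("var%02d", seq_len(m))
    storage.mode(G) <- "numeric"
    G
  }
  marginal_stats <- function(G, y) {
    gc <- scale(G, scale = FALSE)
    yc <- y - mean(y)
    sxx <- colSums(gc^2)
    beta <- colSums(gc * yc) / sxx
    rss <- sum(yc^2) - beta^2 * sxx
    se <- sqrt(pmax(rss, 0) / (n - 2) / sxx)
    z <- beta / se
    data.frame(variant_id = colnames(G), chromosome = "1",
               position = 1000L * seq_len(m),
               effect_allele = "A", other_allele = "G",
               eaf = colMeans(G) / 2,
               beta = beta, se = se,
               p = 2 * stats::pt(-abs(z), df = n - 2),
               n = n, stringsAsFactors = FALSE, row.names = NULL)
  }
  make_trait <- function(G, causal) {
    g <- G[, causal]
    if (variance_explained > 0 && var(g) > 0) {
      b <- sqrt(variance_explained / var(g))
      y <- b * g + rnorm(n, 0, sqrt(1 - variance_explained))
    } else {
      b <- 0
      y <- rnorm(n)
    }
    list(stats = marginal_stats(G, y), b = b)
  }
  causal2 <- causal_index
  if (!shared) {
    far <- which(abs(seq_len(m) - causal_index) >= 20L)
    if (length(far) == 0L) stop("no variant >= 20 positions from causal_index")
    causal2 <- if (length(far) == 1L) far else sample(far, 1L)
  }
  G1 <- draw_genotypes()
  G2 <- draw_genotypes()
  t1 <- make_trait(G1, causal_index)
  t2 <- make_trait(G2, causal2)
  list(trait1 = t1$stats, trait2 = t2$stats,
       genotypes1 = G1, genotypes2 = G2,
       truth = list(causal_index1 = causal_index, causal_index2 = causal2,
                    true_beta1 = t1$b, true_beta2 = t2$b, shared = shared,
                    maf = maf, ld_rho = ld_rho))
}
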