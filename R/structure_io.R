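#' Trajectory container
#'
#' A trajectory couples a topology (one row per atom) with an ordered stack
#' of coordinate frames and provenance labels.  Residue numbering is 1-based
#' and follows the convention that *includes* the signal peptide: the Domain
#' V tryptophan at the phospholipid-binding loop is residue 335 here (it is
#' residue 316 in numbering schemes that drop the 19-residue signal
#' peptide).  Coordinates are in angstrom, time labels in nanoseconds.
#'
#' @param topology data frame with columns `atom_index`, `atom_name`,
#'   `element`, `residue_index`, `residue_name`, `chain_id`, `vdw_radius`.
#' @param coords numeric array `n_atoms x 3 x n_frames` (angstrom).
#' @param time numeric vector of per-frame time labels in ns; defaults to
#'   the frame ordinal.
#' @param model_label `"WT"` or `"VARIANT"`.
#' @param start_shape `"circular"` or `"linear"` starting conformation.
#' @param repeat_id integer replicate identifier.
#' @return an object of class `"trajectory"`.
#' @export
trajectory <- function(topology, coords, time = NULL,
                       model_label = "WT", start_shape = "circular",
                       repeat_id = 1L) {
  topology <- validate_topology(topology)
  if (length(dim(coords)) == 2L) coords <- array(coords, c(dim(coords), 1L))
  stopifnot(length(dim(coords)) == 3L, dim(coords)[2] == 3L)
  if (dim(coords)[1] != nrow(topology))
    stop("coordinate rows (", dim(coords)[1], ") do not match topology atoms (",
         nrow(topology), ")")
  if (dim(coords)[3] < 1L) stop("trajectory must contain at least one frame")
  if (!all(is.finite(coords))) stop("non-finite coordinates in trajectory")
  if (is.null(time)) time <- seq_len(dim(coords)[3])
  if (length(time) != dim(coords)[3])
    stop("time labels must match frame count")
  structure(list(topology = topology, coords = coords, time = as.numeric(time),
                 model_label = model_label, start_shape = start_shape,
                 repeat_id = as.integer(repeat_id)),
            class = "trajectory")
}

validate_topology <- function(top) {
  need <- c("atom_index", "atom_name", "element", "residue_index",
            "residue_name", "chain_id", "vdw_radius")
  miss <- setdiff(need, names(top))
  if (length(miss)) stop("topology missing column(s): ", paste(miss, collapse = ", "))
  if (any(diff(top$atom_index) <= 0))
    stop("atom_index must be strictly increasing")
  if (any(diff(top$residue_index) < 0))
    stop("residue_index must be non-decreasing")
  if (any(top$vdw_radius <= 0)) stop("vdw_radius must be positive")
  top
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d atoms, %d residues, %d frames [%s, %s start, repeat %d]\n",
              nrow(x$topology), length(unique(x$topology$residue_index)),
              n_frames(x), x$model_label, x$start_shape, x$repeat_id))
  invisible(x)
}

#' Number of frames in a trajectory or ensemble
#' @param x a `trajectory` or `conf_ensemble`.
#' @return integer frame count.
#' @export
n_frames <- function(x) dim(x$coords)[3]

# -- multi-model PDB -------------------------------------------------------

# Pre-scan a PDB file: per-MODEL ATOM/HETATM counts and basic sanity, so we
# can report the offending MODEL by number (bio3d's own error would not).
scan_pdb_models <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  model_starts <- grep("^MODEL", lines)
  if (any(is_atom)) {
    icode <- substr(lines[is_atom], 27, 27)
    if (any(icode != " ")) {
      bad <- which(is_atom)[which(icode != " ")[1]]
      stop("insertion codes are not supported (line ", bad, ")")
    }
    # coordinate fields must parse as numbers
    xyz <- cbind(substr(lines[is_atom], 31, 38),
                 substr(lines[is_atom], 39, 46),
                 substr(lines[is_atom], 47, 54))
    bad <- which(!is.finite(suppressWarnings(as.numeric(xyz))))
    if (length(bad)) {
      row <- ((bad[1] - 1) %% sum(is_atom)) + 1
      stop("unparseable ATOM coordinates at line ", which(is_atom)[row])
    }
  }
  if (length(model_starts) == 0L) {
    counts <- sum(is_atom)
    if (counts == 0L) stop("no ATOM records found in ", path)
    return(list(n_models = 1L, counts = counts))
  }
  model_id <- findInterval(seq_along(lines), model_starts)
  counts <- tabulate(model_id[is_atom], nbins = length(model_starts))
  if (length(unique(counts)) > 1L) {
    ref <- counts[1]
    off <- which(counts != ref)[1]
    stop(sprintf(
      "inconsistent atom count across models: MODEL %d has %d atoms, expected %d",
      off, counts[off], ref))
  }
  list(n_models = length(model_starts), counts = counts[1])
}

#' Read a multi-model PDB file as a trajectory
#'
#' Each `MODEL`/`ENDMDL` block becomes one frame; a plain single-structure
#' file yields a one-frame trajectory.  Parsing is delegated to
#' [bio3d::read.pdb()] after a pre-scan that rejects frame-to-frame topology
#' mismatches (reporting the offending model) and insertion codes.  Only the
#' first altLoc is kept.  A missing element column is inferred from the atom
#' name.
#'
#' @param path PDB file path.
#' @param radius_set `"element"` assigns van der Waals radii from the
#'   built-in element table; `"bead"` assigns the two-bead toy radii (CA
#'   1.9 A, CB 2.0 A) used by the synthetic conformer generator, so that a
#'   written toy trajectory reads back with its generating radii.
#' @param model_label,start_shape,repeat_id provenance labels attached to
#'   the returned trajectory.
#' @param time per-frame time labels in ns (default frame ordinals).
#' @return a [trajectory()].
#' @export
read_multi_model_pdb <- function(path, radius_set = c("element", "bead"),
                                 model_label = "WT", start_shape = "circular",
                                 repeat_id = 1L, time = NULL) {
  radius_set <- match.arg(radius_set)
  if (!file.exists(path)) stop("file not found: ", path)
  scan <- scan_pdb_models(path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  atom <- pdb$atom
  # keep first altLoc only
  if (!is.null(atom$alt) && any(!is.na(atom$alt) & atom$alt != "")) {
    keep <- is.na(atom$alt) | atom$alt == "" | atom$alt == "A"
    atom <- atom[keep, , drop = FALSE]
  }
  n_atoms <- nrow(atom)
  elem <- atom$elesy
  if (is.null(elem) || any(is.na(elem) | trimws(elem) == ""))
    elem <- infer_element(atom$elety)
  elem <- toupper(trimws(elem))
  radii <- if (radius_set == "bead") {
    ifelse(atom$elety == "CB", 2.0, 1.9)
  } else {
    vdw_radius(elem)
  }
  top <- data.frame(atom_index = atom$eleno,
                    atom_name = atom$elety,
                    element = elem,
                    residue_index = atom$resno,
                    residue_name = atom$resid,
                    chain_id = atom$chain,
                    vdw_radius = radii,
                    stringsAsFactors = FALSE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  nf <- nrow(xyz)
  if (nf != scan$n_models)
    stop("parsed ", nf, " models but file declares ", scan$n_models)
  coords <- array(0, c(n_atoms, 3, nf))
  for (f in seq_len(nf))
    coords[, , f] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
  trajectory(top, coords, time = time, model_label = model_label,
             start_shape = start_shape, repeat_id = repeat_id)
}

#' Write a trajectory as a multi-model PDB file
#'
#' Fixed-width PDB output via [bio3d::write.pdb()]; coordinates survive a
#' round trip to 3 decimals (the format's precision).
#'
#' @param traj a [trajectory()].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_multi_model_pdb <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  if (n_frames(traj) < 1L) stop("empty frame list")
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("unwritable path (no such directory): ", dir)
  top <- traj$topology
  nf <- n_frames(traj)
  xyz <- t(apply(traj$coords, 3, function(m) as.numeric(t(m))))
  if (nf == 1L) xyz <- matrix(xyz, nrow = 1)
  chain <- top$chain_id
  chain[is.na(chain) | chain == ""] <- "A"
  bio3d::write.pdb(file = path, xyz = xyz,
                   resno = top$residue_index, resid = top$residue_name,
                   eleno = top$atom_index, elety = top$atom_name,
                   chain = chain, elesy = top$element)
  invisible(path)
}

# -- region / motif configuration ------------------------------------------

parse_residue_spec <- function(spec, row) {
  parts <- trimws(strsplit(spec, ",")[[1]])
  parts <- parts[parts != ""]
  out <- integer(0)
  for (p in parts) {
    if (grepl("^[0-9]+$", p)) {
      out <- c(out, as.integer(p))
    } else if (grepl("^[0-9]+-[0-9]+$", p)) {
      ab <- as.integer(strsplit(p, "-")[[1]])
      if (ab[1] > ab[2])
        stop("malformed range '", p, "' in region config row ", row,
             " (start > end)")
      out <- c(out, seq(ab[1], ab[2]))
    } else {
      stop("malformed residue spec '", p, "' in region config row ", row)
    }
  }
  sort(unique(out))
}

#' Load motif/region definitions from a TSV config
#'
#' The config has columns `name`, `domain_tag`, `residues`, where
#' `residues` is a comma-separated list of 1-based residue indices and/or
#' `start-end` ranges.  The default config shipped with the package
#' (`system.file("extdata", "regions_b2gpi.tsv", package = "conformgen")`)
#' defines the Domain V phospholipid-binding loops (aPL loop 1 = 303,305,306;
#' aPL loop 2 = 332,334,335; anti-A1 loop = 301,327,336; K269-K270) and five
#' Domain I-II epitope motifs (29-36, 35-43, 58-62, 69-77, 84-91).
#'
#' @param path TSV file path; defaults to the shipped config.
#' @return named list of motif definitions, each a list with `name`,
#'   `residue_indices` (sorted integer vector) and `domain_tag`.
#' @export
load_region_config <- function(path = default_region_config()) {
  df <- read_tsv(path)
  need <- c("name", "domain_tag", "residues")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("region config missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(df$name))
    stop("duplicate motif name(s): ",
         paste(unique(df$name[duplicated(df$name)]), collapse = ", "))
  motifs <- lapply(seq_len(nrow(df)), function(i) {
    idx <- parse_residue_spec(df$residues[i], i)
    if (length(idx) == 0L) stop("empty residue set in region config row ", i)
    list(name = df$name[i], residue_indices = idx, domain_tag = df$domain_tag[i])
  })
  names(motifs) <- df$name
  motifs
}

#' @rdname load_region_config
#' @export
default_region_config <- function() {
  system.file("extdata", "regions_b2gpi.tsv", package = "conformgen",
              mustWork = TRUE)
}
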