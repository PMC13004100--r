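#' Built-in element tables
#'
#' Bondi-style van der Waals radii (in angstrom) and standard atomic masses
#' (in dalton) for the elements found in cleaned protein structures.  Any
#' element absent from the table falls back to 1.7 angstrom (carbon-like)
#' with a warning.
#'
#' @name element_tables
#' @keywords internal
NULL

.vdw_radii <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52,
                S = 1.80, P = 1.80, SE = 1.90, F = 1.47,
                CL = 1.75, BR = 1.85, I = 1.98)

.atomic_masses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                    S = 32.06, P = 30.974, SE = 78.971, F = 18.998,
                    CL = 35.45, BR = 79.904, I = 126.904)

#' Look up van der Waals radii by element symbol
#'
#' @param element character vector of element symbols (case-insensitive).
#' @return numeric vector of radii in angstrom; unknown elements default to
#'   1.7 with a single warning listing them.
#' @export
vdw_radius <- function(element) {
  key <- toupper(trimws(element))
  r <- .vdw_radii[key]
  if (anyNA(r)) {
    unknown <- unique(key[is.na(r)])
    warning("unknown element(s) ", paste(unknown, collapse = ", "),
            "; using default vdW radius 1.7 A", call. = FALSE)
    r[is.na(r)] <- 1.7
  }
  unname(r)
}

#' Look up atomic masses by element symbol
#'
#' @param element character vector of element symbols (case-insensitive).
#' @return numeric vector of masses in dalton; unknown elements default to
#'   12.011 (carbon) with a warning.
#' @export
atomic_mass <- function(element) {
  key <- toupper(trimws(element))
  m <- .atomic_masses[key]
  if (anyNA(m)) {
    unknown <- unique(key[is.na(m)])
    warning("unknown element(s) ", paste(unknown, collapse = ", "),
            "; using carbon mass", call. = FALSE)
    m[is.na(m)] <- 12.011
  }
  unname(m)
}

# Infer the element symbol from a PDB atom name ("CA" -> "C", "1HB" -> "H",
# "OXT" -> "O").  Two-letter elements in ATOM records of cleaned protein
# files are rare; the first alphabetic character is the element.
infer_element <- function(atom_name) {
  nm <- gsub("[^A-Za-z]", "", atom_name)
  toupper(substr(nm, 1, 1))
}
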