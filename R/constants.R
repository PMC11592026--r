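#' Ideal peptide-plate geometry constants
#'
#' Bond lengths (Angstrom) and planar angles (degrees) used to build the
#' rigid peptide-plate templates, in the Engh--Huber style of idealized
#' protein stereochemistry. A generic (alanine-like) plate is used for all
#' residue types except proline, which carries its own C--N and N--CA values.
#' Any entry can be overridden, e.g. from a key-value config file read with
#' \code{\link{read_config}}.
#'
#' @param overrides Named list (or named numeric vector) replacing individual
#'   entries; names as in the returned list.
#' @return Named list of geometry constants with entries:
#'   \describe{
#'     \item{ca_c}{CA1--C bond, 1.525 A}
#'     \item{c_o}{C=O bond, 1.231 A}
#'     \item{c_n}{peptide C--N bond, 1.329 A (proline: \code{c_n_pro} 1.341)}
#'     \item{n_ca}{N--CA2 bond, 1.458 A (proline: \code{n_ca_pro} 1.466)}
#'     \item{ang_ca_c_n}{CA1-C-N planar angle, 116.2 deg}
#'     \item{ang_ca_c_o}{CA1-C-O planar angle, 120.8 deg}
#'     \item{ang_c_n_ca}{C-N-CA2 planar angle, 121.7 deg
#'       (proline: \code{ang_c_n_ca_pro} 122.6)}
#'     \item{ang_c_n_h}{C-N-H planar angle, 119.0 deg; \code{n_h} N-H bond 1.0 A}
#'   }
#' @export
ideal_geometry <- function(overrides = NULL) {
  g <- list(
    ca_c         = 1.525,
    c_o          = 1.231,
    c_n          = 1.329,
    n_ca         = 1.458,
    c_n_pro      = 1.341,
    n_ca_pro     = 1.466,
    ang_ca_c_n   = 116.2,
    ang_ca_c_o   = 120.8,
    ang_c_n_ca   = 121.7,
    ang_c_n_ca_pro = 122.6,
    ang_c_n_h    = 119.0,
    n_h          = 1.00
  )
  if (!is.null(overrides)) {
    overrides <- as.list(overrides)
    bad <- setdiff(names(overrides), names(g))
    if (length(bad)) stop("unknown geometry constant(s): ", paste(bad, collapse = ", "))
    g[names(overrides)] <- lapply(overrides, as.numeric)
  }
  g
}

# Cis/trans classification threshold on the CA(i)-CA(i+1) pseudo-bond (A):
# pseudo-bonds strictly shorter than this are cis.
CIS_THRESHOLD <- 3.5

# Chain-break window on consecutive CA-CA distances (A). The lower bound
# admits cis pseudo-bonds (~2.9 A); the upper bound rejects gaps.
CA_DIST_MIN <- 2.6
CA_DIST_MAX <- 4.3

# Stereochemistry screen: backbone bond lengths within this tolerance (A)
# of the ideal constants, otherwise the chain is flagged.
BOND_TOL <- 0.2

# Minimum chain length (feature window needs offsets up to +/-5).
MIN_RESIDUES <- 6

# Canonical residue order for the 21-slot one-hot block (alphabetical
# three-letter codes; slot 21 is 'X' for anything else).
AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL")

# Reference lambda values (radians) of regular conformations, derived once
# from backbones built with standard dihedrals (alpha helix phi=-57,
# psi=-47; antiparallel beta strand phi=-119, psi=113; left-handed helix
# phi=57, psi=47) on the ideal plate geometry above, then frozen
# (data-raw/derive_constants.R). Used by the fixture generators.
LAMBDA_HELIX  <- -1.9045276742
LAMBDA_STRAND <- -1.5790803642
LAMBDA_TURN   <-  1.9045276742  # left-handed (alpha-L) conformation
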