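#' Build an ideal peptide-plate template
#'
#' Constructs the rigid planar peptide unit \{CA1, C, O, N, CA2, (H)\} in a
#' canonical local frame: CA1 at the origin, CA1->CA2 along +x, all atoms in
#' the z = 0 plane. Bond lengths and planar angles come from
#' \code{\link{ideal_geometry}}; the omega torsion CA1-C-N-CA2 is pi for a
#' trans plate and 0 for cis.
#'
#' @param residue_class \code{"generic"} (alanine-like, used for every amino
#'   acid except proline) or \code{"proline"}.
#' @param isomer \code{"trans"} or \code{"cis"}.
#' @param include_h Also place the amide hydrogen of the second residue.
#' @param constants Geometry table from \code{\link{ideal_geometry}}.
#' @return Object of class \code{plate_template}: a list with \code{atoms}
#'   (named matrix of local coordinates, rows CA1/C/O/N/CA2 and optionally H),
#'   \code{residue_class}, \code{isomer}, \code{ca_ca} (template CA1-CA2
#'   distance) and the constants used.
#' @export
plate_template <- function(residue_class = c("generic", "proline"),
                           isomer = c("trans", "cis"),
                           include_h = FALSE,
                           constants = ideal_geometry()) {
  residue_class <- match.arg(residue_class)
  isomer <- match.arg(isomer)
  g <- constants
  deg <- pi / 180
  c_n  <- if (residue_class == "proline") g$c_n_pro  else g$c_n
  n_ca <- if (residue_class == "proline") g$n_ca_pro else g$n_ca
  ang_cnca <- if (residue_class == "proline") g$ang_c_n_ca_pro else g$ang_c_n_ca

  rot2 <- function(v, a) c(cos(a) * v[1] - sin(a) * v[2],
                           sin(a) * v[1] + cos(a) * v[2])
  # 2D chain walk in the plate plane. Trans: opposite turn directions at C
  # and N give the extended zigzag (omega = pi); cis: same direction.
  ca1 <- c(0, 0)
  u0 <- c(1, 0)
  C <- ca1 + g$ca_c * u0
  d1 <- pi - g$ang_ca_c_n * deg
  u1 <- rot2(u0, d1)
  N <- C + c_n * u1
  d2 <- pi - ang_cnca * deg
  u2 <- rot2(u1, if (isomer == "trans") -d2 else d2)
  ca2 <- N + n_ca * u2
  # carbonyl O on the far side of the CA1-C-N bend
  O <- C + g$c_o * rot2(u0, -(pi - g$ang_ca_c_o * deg))
  atoms2 <- rbind(CA1 = ca1, C = C, O = O, N = N, CA2 = ca2)
  if (include_h) {
    dh <- pi - g$ang_c_n_h * deg
    H <- N + g$n_h * rot2(u1, if (isomer == "trans") dh else -dh)
    atoms2 <- rbind(atoms2, H = H)
  }
  # canonical frame: rotate so CA2 sits on the +x axis
  phi <- atan2(atoms2["CA2", 2], atoms2["CA2", 1])
  atoms2 <- t(apply(atoms2, 1, rot2, a = -phi))
  atoms <- cbind(atoms2, 0)
  colnames(atoms) <- c("x", "y", "z")
  structure(list(atoms = atoms,
                 residue_class = residue_class,
                 isomer = isomer,
                 ca_ca = sqrt(sum(atoms["CA2", ]^2)),
                 constants = g),
            class = "plate_template")
}

#' Classify a peptide pseudo-bond as cis or trans
#'
#' The CA(i)-CA(i+1) distance diagnoses the peptide-bond isomer: pseudo-bonds
#' strictly shorter than 3.5 Angstrom are cis, everything else trans.
#'
#' @param ca_a,ca_b Either two 3-vectors (single pseudo-bond) or, if
#'   \code{ca_b} is missing, a numeric vector of distances.
#' @return Character vector of \code{"cis"} / \code{"trans"}.
#' @export
classify_isomer <- function(ca_a, ca_b) {
  d <- if (missing(ca_b)) as.numeric(ca_a) else dist3(ca_a, ca_b)
  ifelse(d < CIS_THRESHOLD, "cis", "trans")
}

# Local orthonormal frame of plate p: ex along the CA axis, ey0 towards the
# reference CA (the lambda = 0 half-plane), ez0 completing the right-handed
# triad. The lambda rotation moves ey0 towards ez0.
plate_frame <- function(ca_p, ca_next, ref) {
  ex <- unit3(ca_next - ca_p)
  r <- ref - ca_p
  r_perp <- r - sum(r * ex) * ex
  if (sqrt(sum(r_perp^2)) < 1e-8)
    stop("degenerate geometry: reference CA collinear with the plate axis")
  ey0 <- unit3(r_perp)
  ez0 <- cross3(ex, ey0)
  list(ex = ex, ey0 = ey0, ez0 = ez0)
}

#' Place one ideal peptide plate in the global frame
#'
#' Maps the template so its CA1 lands on \code{ca_p} and its +x axis on the
#' unit vector \code{ca_p -> ca_next}, then rotates the plate about that axis
#' by \code{lambda}. At \code{lambda = 0} the plate lies in the plane spanned
#' by the axis and the reference CA, with the plate's +y side towards the
#' reference.
#'
#' @param template A \code{\link{plate_template}}.
#' @param ca_p,ca_next Global CA positions bounding the plate (3-vectors).
#' @param lambda Rotation angle about the CA-CA axis, radians.
#' @param reference_ca Global position of the reference CA defining lambda = 0;
#'   must not be collinear with the axis.
#' @return Matrix of global coordinates with rows C, O, N (and H if the
#'   template has one).
#' @export
place_plate <- function(template, ca_p, ca_next, lambda, reference_ca) {
  fr <- plate_frame(ca_p, ca_next, reference_ca)
  ey <- cos(lambda) * fr$ey0 + sin(lambda) * fr$ez0
  at <- template$atoms
  keep <- setdiff(rownames(at), c("CA1", "CA2"))
  out <- t(vapply(keep, function(nm) {
    ca_p + at[nm, "x"] * fr$ex + at[nm, "y"] * ey
  }, numeric(3)))
  rownames(out) <- keep
  colnames(out) <- c("x", "y", "z")
  out
}

# Reference CA index for plate p of a K-residue chain: the native
# reference is CA(p+2); the last plate (no CA(p+2)) falls back to CA(p-1).
plate_reference_index <- function(p, K) {
  if (p + 2 <= K) p + 2 else p - 1
}

# Template cache for the four (class, isomer) combinations.
plate_template_set <- function(constants = ideal_geometry(), include_h = FALSE) {
  list(
    generic_trans = plate_template("generic", "trans", include_h, constants),
    generic_cis   = plate_template("generic", "cis",   include_h, constants),
    proline_trans = plate_template("proline", "trans", include_h, constants),
    proline_cis   = plate_template("proline", "cis",   include_h, constants)
  )
}

template_key <- function(next_resname, isomer) {
  cls <- ifelse(next_resname == "PRO", "proline", "generic")
  paste(cls, isomer, sep = "_")
}

#' Reconstruct all heavy backbone atoms from a CA trace and lambda series
#'
#' Deterministic second stage of the method: for every plate p (between
#' CA(p) and CA(p+1), p = 1..K-1) an ideal planar peptide template (proline
#' template when residue p+1 is proline; cis template when the pseudo-bond is
#' cis) is aligned to the CA-CA axis and rotated by lambda(p). C(p) and O(p)
#' belong to residue p, N(p+1) to residue p+1. The first residue's N and the
#' last residue's C/O have no defining plate and are left missing.
#'
#' @param trace A \code{\link{ca_trace}}.
#' @param lambdas A \code{\link{lambda_series}} for plates 1..K-1 (a bare
#'   numeric vector is accepted); undefined entries are filled by copying the
#'   nearest defined plate (0 if none is defined).
#' @param constants Geometry table from \code{\link{ideal_geometry}}.
#' @param include_h Also build amide hydrogens.
#' @return A \code{\link{backbone_structure}}; CA coordinates are the input
#'   trace coordinates, untouched.
#' @export
reconstruct_backbone <- function(trace, lambdas,
                                 constants = ideal_geometry(),
                                 include_h = FALSE) {
  stopifnot(inherits(trace, "ca_trace"))
  K <- nrow(trace$xyz)
  if (is.numeric(lambdas)) lambdas <- lambda_series(lambdas)
  stopifnot(inherits(lambdas, "lambda_series"))
  if (length(lambdas$values) != K - 1)
    stop("lambda series must cover plates 1..K-1 (K-1 = ", K - 1, ")")
  lam <- fill_undefined(lambdas$values, lambdas$defined)
  d_ca <- sqrt(rowSums((trace$xyz[-1, , drop = FALSE] -
                        trace$xyz[-K, , drop = FALSE])^2))
  isomers <- lambdas$isomers
  if (is.null(isomers)) isomers <- classify_isomer(d_ca)
  tmpl <- plate_template_set(constants, include_h)

  n_xyz <- matrix(NA_real_, K, 3)
  c_xyz <- matrix(NA_real_, K, 3)
  o_xyz <- matrix(NA_real_, K, 3)
  h_xyz <- if (include_h) matrix(NA_real_, K, 3) else NULL
  for (p in seq_len(K - 1)) {
    ref <- trace$xyz[plate_reference_index(p, K), ]
    tm <- tmpl[[template_key(trace$sequence[p + 1], isomers[p])]]
    at <- place_plate(tm, trace$xyz[p, ], trace$xyz[p + 1, ], lam[p], ref)
    c_xyz[p, ] <- at["C", ]
    o_xyz[p, ] <- at["O", ]
    n_xyz[p + 1, ] <- at["N", ]
    if (include_h && trace$sequence[p + 1] != "PRO")
      h_xyz[p + 1, ] <- at["H", ]
  }
  backbone_structure(sequence = trace$sequence,
                     ca = trace$xyz, n = n_xyz, c = c_xyz, o = o_xyz,
                     h = h_xyz,
                     chain_id = trace$chain_id, resno = trace$resno,
                     lambda = lam, isomers = isomers)
}

fill_undefined <- function(values, defined) {
  if (all(defined)) return(values)
  if (!any(defined)) return(rep(0, length(values)))
  idx <- seq_along(values)
  near <- vapply(idx, function(i) {
    dd <- abs(idx[defined] - i)
    idx[defined][which.min(dd)]
  }, integer(1))
  out <- values
  out[!defined] <- values[near[!defined]]
  out
}

#' Extract the lambda dihedral series from a full backbone
#'
#' For each plate p the angle is measured as the rotation about the
#' CA(p)->CA(p+1) axis that best superposes the ideal template's C, O and
#' N atoms onto the observed ones (closed-form one-parameter least squares),
#' with lambda = 0 meaning the plate lies in the plane through the reference
#' CA -- the same convention \code{\link{place_plate}} uses, so extraction
#' and placement are exact inverses.
#'
#' @param backbone A \code{\link{backbone_structure}} (e.g. from
#'   \code{\link{as_backbone}} on a parsed chain).
#' @param constants Geometry table from \code{\link{ideal_geometry}}.
#' @return A \code{\link{lambda_series}} with per-plate values in
#'   \code{[-pi, pi)}, a defined mask (FALSE where the plate's C/O/N or the
#'   reference CA is missing) and per-plate isomers from
#'   \code{\link{classify_isomer}}.
#' @export
lambda_from_backbone <- function(backbone, constants = ideal_geometry()) {
  stopifnot(inherits(backbone, "backbone_structure"))
  K <- nrow(backbone$ca)
  if (K < 3) stop("need at least 3 residues to define lambda")
  tmpl <- plate_template_set(constants)
  vals <- rep(NA_real_, K - 1)
  defined <- rep(FALSE, K - 1)
  d_ca <- sqrt(rowSums((backbone$ca[-1, , drop = FALSE] -
                        backbone$ca[-K, , drop = FALSE])^2))
  isomers <- classify_isomer(d_ca)
  for (p in seq_len(K - 1)) {
    ca_p <- backbone$ca[p, ]
    ca_next <- backbone$ca[p + 1, ]
    ref <- backbone$ca[plate_reference_index(p, K), ]
    obs <- rbind(C = backbone$c[p, ], O = backbone$o[p, ], N = backbone$n[p + 1, ])
    if (anyNA(obs) || anyNA(ca_p) || anyNA(ca_next) || anyNA(ref)) next
    tm <- tmpl[[template_key(backbone$sequence[p + 1], isomers[p])]]
    fr <- tryCatch(plate_frame(ca_p, ca_next, ref), error = function(e) NULL)
    if (is.null(fr)) next
    yk <- tm$atoms[c("C", "O", "N"), "y"]
    dk <- sweep(obs, 2, ca_p)
    s <- sum(yk * (dk %*% fr$ez0))
    cval <- sum(yk * (dk %*% fr$ey0))
    if (s^2 + cval^2 < 1e-20) next
    vals[p] <- wrap_angle(atan2(s, cval))
    defined[p] <- TRUE
  }
  lambda_series(vals, defined, isomers)
}

#' Per-plate lambda angle container
#'
#' @param values Numeric vector, radians, one entry per plate (plate p sits
#'   between CA(p) and CA(p+1)).
#' @param defined Logical mask, same length; defaults to \code{!is.na(values)}.
#' @param isomers Optional character vector of \code{"trans"}/\code{"cis"}.
#' @return Object of class \code{lambda_series}.
#' @export
lambda_series <- function(values, defined = !is.na(values), isomers = NULL) {
  values <- as.numeric(values)
  stopifnot(length(defined) == length(values))
  if (!is.null(isomers)) stopifnot(length(isomers) == length(values),
                                   all(isomers %in% c("trans", "cis")))
  if (any(defined & !is.finite(values)))
    stop("lambda values must be finite where defined")
  values[defined] <- wrap_angle(values[defined])
  structure(list(values = values, defined = defined, isomers = isomers),
            class = "lambda_series")
}

#' @export
print.lambda_series <- function(x, ...) {
  cat("lambda_series:", length(x$values), "plates,",
      sum(x$defined), "defined\n")
  if (any(x$defined))
    cat(sprintf("  range [%.3f, %.3f] rad, mean %.3f rad\n",
                min(x$values[x$defined]), max(x$values[x$defined]),
                mean(x$values[x$defined])))
  invisible(x)
}

#' Backbone structure container
#'
#' Per-residue N/CA/C/O (optionally amide H) coordinates plus provenance of
#' the plates used for reconstruction. Missing atoms are rows of NA (the
#' first residue's N and the last residue's C/O are never defined by a plate).
#'
#' @param sequence Character vector of 3-letter residue names, length K.
#' @param ca,n,c,o K x 3 coordinate matrices (Angstrom); NA rows for missing.
#' @param h Optional K x 3 matrix of amide hydrogens.
#' @param chain_id Chain identifier.
#' @param resno Residue numbers (defaults to 1..K).
#' @param lambda,isomers Optional per-plate provenance (length K-1).
#' @return Object of class \code{backbone_structure}.
#' @export
backbone_structure <- function(sequence, ca, n, c, o, h = NULL,
                               chain_id = "A", resno = NULL,
                               lambda = NULL, isomers = NULL) {
  K <- length(sequence)
  stopifnot(nrow(ca) == K, nrow(n) == K, nrow(c) == K, nrow(o) == K)
  if (is.null(resno)) resno <- seq_len(K)
  structure(list(sequence = sequence, ca = ca, n = n, c = c, o = o, h = h,
                 chain_id = chain_id, resno = resno,
                 lambda = lambda, isomers = isomers),
            class = "backbone_structure")
}

#' @export
print.backbone_structure <- function(x, ...) {
  K <- length(x$sequence)
  n_at <- sum(!is.na(x$ca[, 1])) + sum(!is.na(x$n[, 1])) +
    sum(!is.na(x$c[, 1])) + sum(!is.na(x$o[, 1]))
  cat("backbone_structure: chain", x$chain_id, "-", K, "residues,",
      n_at, "heavy backbone atoms\n")
  invisible(x)
}
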