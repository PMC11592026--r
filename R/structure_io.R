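#' CA trace container
#'
#' The method's only structural input: ordered alpha-carbon coordinates and
#' residue identities of one protein chain.
#'
#' @param sequence Character vector of 3-letter residue names (length K >= 6).
#' @param xyz K x 3 coordinate matrix, Angstrom.
#' @param chain_id Chain identifier.
#' @param resno Residue numbers (defaults 1..K).
#' @param validate Enforce the trace invariants (K >= 6, all consecutive
#'   CA-CA distances inside the chain-break window [2.6, 4.3] A).
#' @return Object of class \code{ca_trace}.
#' @export
ca_trace <- function(sequence, xyz, chain_id = "A", resno = NULL,
                     validate = TRUE) {
  xyz <- as.matrix(xyz)
  K <- length(sequence)
  stopifnot(nrow(xyz) == K, ncol(xyz) == 3)
  if (is.null(resno)) resno <- seq_len(K)
  if (validate) {
    if (K < MIN_RESIDUES)
      stop("too-short: trace has ", K, " residues (minimum ", MIN_RESIDUES, ")")
    if (!all(is.finite(xyz))) stop("trace coordinates must be finite")
    d <- sqrt(rowSums((xyz[-1, , drop = FALSE] - xyz[-K, , drop = FALSE])^2))
    bad <- which(d < CA_DIST_MIN | d > CA_DIST_MAX)
    if (length(bad))
      stop("chain-break: CA-CA distance outside [", CA_DIST_MIN, ", ",
           CA_DIST_MAX, "] A at position(s) ", paste(bad, collapse = ", "))
  }
  structure(list(sequence = sequence, xyz = unname(xyz),
                 chain_id = chain_id, resno = resno),
            class = "ca_trace")
}

#' @export
print.ca_trace <- function(x, ...) {
  cat("ca_trace: chain", x$chain_id, "-", length(x$sequence), "residues\n")
  invisible(x)
}

BACKBONE_ATOMS <- c("N", "CA", "C", "O")

#' Read a protein structure from PDB or mmCIF
#'
#' Parses via bio3d, keeps protein ATOM records of the first model only,
#' drops waters and heteroatoms, and resolves alternate locations by keeping
#' the highest-occupancy conformer (flagging the chain). Residues are
#' renumbered by order of appearance so insertion codes become distinct
#' positions.
#'
#' @param path File path.
#' @param format \code{"auto"} (by extension), \code{"pdb"} or \code{"mmcif"}.
#' @return Named list of chains; each chain is a data frame of atom records
#'   with columns \code{residue_index}, \code{resno}, \code{resname},
#'   \code{atom}, \code{x}, \code{y}, \code{z}, \code{occ}, \code{altloc},
#'   and an \code{altloc_flag} attribute.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read file: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.cif(\\.gz)?$", path, ignore.case = TRUE))
      "mmcif" else "pdb"
  }
  pdb <- if (format == "mmcif")
    bio3d::read.cif(path, verbose = FALSE, rm.alt = FALSE)
  else bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE)
  at <- pdb$atom
  at <- at[at$type == "ATOM" & !(at$resid %in% c("HOH", "WAT", "DOD")), ,
           drop = FALSE]
  if (!nrow(at)) stop("no protein chain found in ", path)
  chains <- list()
  for (ch in unique(at$chain)) {
    a <- at[at$chain %in% ch, , drop = FALSE]
    alt <- !is.na(a$alt) & a$alt != "" & a$alt != " "
    altloc_flag <- any(alt)
    # residue key in file order; insertion codes distinct
    ins <- ifelse(is.na(a$insert) | a$insert == " ", "", a$insert)
    key <- paste(a$resno, ins, sep = "|")
    ridx <- match(key, unique(key))
    a$residue_index <- ridx
    if (altloc_flag) {
      # keep the highest-occupancy conformer per (residue, atom)
      grp <- paste(ridx, a$elety, sep = "@")
      occ <- ifelse(is.na(a$o), 1, a$o)
      keep <- unlist(lapply(split(seq_len(nrow(a)), grp), function(ii) {
        ii[which.max(occ[ii])]
      }), use.names = FALSE)
      a <- a[sort(keep), , drop = FALSE]
    }
    rec <- data.frame(residue_index = a$residue_index,
                      resno = a$resno,
                      resname = a$resid,
                      atom = a$elety,
                      x = a$x, y = a$y, z = a$z,
                      occ = ifelse(is.na(a$o), 1, a$o),
                      altloc = ifelse(is.na(a$alt), "", a$alt),
                      stringsAsFactors = FALSE)
    attr(rec, "chain_id") <- if (is.na(ch)) "A" else ch
    attr(rec, "altloc_flag") <- altloc_flag
    chains[[attr(rec, "chain_id")]] <- rec
  }
  if (!length(chains)) stop("no protein chain found in ", path)
  chains
}

#' Extract a validated CA trace from a parsed chain
#'
#' @param chain Atom-record data frame from \code{\link{read_structure}}.
#' @return A \code{\link{ca_trace}}; fails with a tagged error when the chain
#'   is too short or has a break (consecutive CA-CA outside [2.6, 4.3] A).
#' @export
extract_ca_trace <- function(chain) {
  ca <- chain[chain$atom == "CA", , drop = FALSE]
  ca <- ca[order(ca$residue_index), , drop = FALSE]
  ca <- ca[!duplicated(ca$residue_index), , drop = FALSE]
  if (nrow(ca) < MIN_RESIDUES)
    stop("too-short: chain has ", nrow(ca), " CA atoms (minimum ",
         MIN_RESIDUES, ")")
  ca_trace(sequence = ca$resname,
           xyz = as.matrix(ca[, c("x", "y", "z")]),
           chain_id = attr(chain, "chain_id") %||% "A",
           resno = ca$resno)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Training-set quality filter for one chain
#'
#' Accepts a chain only if every residue carries a complete backbone
#' (N, CA, C, O), there is no chain break, no alternate locations, all
#' backbone bond lengths are within 0.2 A of the ideal constants
#' (stereochemistry screen), and the chain has at least 6 residues.
#'
#' @param chain Atom-record data frame from \code{\link{read_structure}}.
#' @param constants Geometry table from \code{\link{ideal_geometry}}.
#' @return List of class \code{chain_quality_report} with \code{accepted}
#'   (logical) and \code{reasons} (character vector drawn from
#'   \code{missing-residue}, \code{missing-backbone-atom}, \code{alt-loc},
#'   \code{stereochemical-error}, \code{too-short}).
#' @export
chain_quality_filter <- function(chain, constants = ideal_geometry()) {
  reasons <- character(0)
  if (isTRUE(attr(chain, "altloc_flag"))) reasons <- c(reasons, "alt-loc")
  ridx <- sort(unique(chain$residue_index))
  K <- length(ridx)
  if (K < MIN_RESIDUES) reasons <- c(reasons, "too-short")
  get_atom <- function(i, nm) {
    r <- chain[chain$residue_index == i & chain$atom == nm, c("x", "y", "z")]
    if (nrow(r) == 0) return(NULL)
    as.numeric(r[1, ])
  }
  missing_bb <- FALSE
  for (i in ridx) {
    have <- BACKBONE_ATOMS %in% chain$atom[chain$residue_index == i]
    if (!all(have)) { missing_bb <- TRUE; break }
  }
  if (missing_bb) reasons <- c(reasons, "missing-backbone-atom")
  # chain break / missing residue: consecutive CA distances
  ca <- chain[chain$atom == "CA", , drop = FALSE]
  ca <- ca[order(ca$residue_index), , drop = FALSE]
  if (nrow(ca) >= 2) {
    xyz <- as.matrix(ca[, c("x", "y", "z")])
    d <- sqrt(rowSums((xyz[-1, , drop = FALSE] -
                       xyz[-nrow(xyz), , drop = FALSE])^2))
    if (any(d < CA_DIST_MIN | d > CA_DIST_MAX))
      reasons <- c(reasons, "missing-residue")
  }
  # stereochemistry screen on backbone bond lengths
  if (!missing_bb && K >= 2) {
    g <- constants
    bad <- FALSE
    for (j in seq_len(K)) {
      i <- ridx[j]
      n_i <- get_atom(i, "N"); ca_i <- get_atom(i, "CA")
      c_i <- get_atom(i, "C"); o_i <- get_atom(i, "O")
      resname <- chain$resname[chain$residue_index == i][1]
      n_ca_ideal <- if (identical(resname, "PRO")) g$n_ca_pro else g$n_ca
      if (abs(dist3(n_i, ca_i) - n_ca_ideal) > BOND_TOL ||
          abs(dist3(ca_i, c_i) - g$ca_c) > BOND_TOL ||
          abs(dist3(c_i, o_i) - g$c_o) > BOND_TOL) { bad <- TRUE; break }
      if (j < K) {
        n_next <- get_atom(ridx[j + 1], "N")
        res_next <- chain$resname[chain$residue_index == ridx[j + 1]][1]
        c_n_ideal <- if (identical(res_next, "PRO")) g$c_n_pro else g$c_n
        if (abs(dist3(c_i, n_next) - c_n_ideal) > BOND_TOL) { bad <- TRUE; break }
      }
    }
    if (bad) reasons <- c(reasons, "stereochemical-error")
  }
  structure(list(accepted = length(reasons) == 0, reasons = reasons),
            class = "chain_quality_report")
}

#' @export
print.chain_quality_report <- function(x, ...) {
  if (x$accepted) cat("chain accepted\n")
  else cat("chain rejected:", paste(x$reasons, collapse = ", "), "\n")
  invisible(x)
}

#' Convert parsed atom records to a backbone_structure
#'
#' @param chain Atom-record data frame from \code{\link{read_structure}}.
#' @return A \code{\link{backbone_structure}} with NA rows for atoms absent
#'   from the file.
#' @export
as_backbone <- function(chain) {
  ridx <- sort(unique(chain$residue_index))
  K <- length(ridx)
  seqn <- character(K)
  mats <- lapply(BACKBONE_ATOMS, function(a) matrix(NA_real_, K, 3))
  names(mats) <- BACKBONE_ATOMS
  resno <- integer(K)
  for (j in seq_len(K)) {
    rows <- chain[chain$residue_index == ridx[j], , drop = FALSE]
    seqn[j] <- rows$resname[1]
    resno[j] <- rows$resno[1]
    for (a in BACKBONE_ATOMS) {
      r <- rows[rows$atom == a, , drop = FALSE]
      if (nrow(r)) mats[[a]][j, ] <- as.numeric(r[1, c("x", "y", "z")])
    }
  }
  backbone_structure(sequence = seqn, ca = mats$CA, n = mats$N,
                     c = mats$C, o = mats$O,
                     chain_id = attr(chain, "chain_id") %||% "A",
                     resno = resno)
}

#' Write a backbone structure as a PDB file
#'
#' Emits ATOM records for the defined N/CA/C/O (and H) atoms in residue
#' order with element symbols; no OXT, no TER-side extras. The output is
#' parseable by \code{\link{read_structure}} and round-trips coordinates to
#' PDB fixed-point precision (1e-3 A).
#'
#' @param backbone A \code{\link{backbone_structure}}.
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
write_backbone <- function(backbone, path) {
  stopifnot(inherits(backbone, "backbone_structure"))
  K <- length(backbone$sequence)
  atoms <- c(BACKBONE_ATOMS, if (!is.null(backbone$h)) "H")
  mats <- list(N = backbone$n, CA = backbone$ca, C = backbone$c,
               O = backbone$o, H = backbone$h)
  elety <- character(0); resid <- character(0); resno <- integer(0)
  xyz <- numeric(0); elesy <- character(0)
  order_in_res <- c("N", "CA", "C", "O", "H")
  for (j in seq_len(K)) {
    for (a in order_in_res) {
      m <- mats[[a]]
      if (is.null(m) || anyNA(m[j, ])) next
      elety <- c(elety, a)
      resid <- c(resid, backbone$sequence[j])
      resno <- c(resno, backbone$resno[j])
      elesy <- c(elesy, substr(a, 1, 1))
      xyz <- c(xyz, m[j, ])
    }
  }
  if (!length(elety)) stop("empty backbone: nothing to write")
  if (!all(is.finite(xyz))) stop("backbone coordinates must be finite")
  chain <- backbone$chain_id
  if (is.null(chain) || is.na(chain) || !nzchar(chain)) chain <- "A"
  bio3d::write.pdb(file = path, xyz = xyz, resno = resno, resid = resid,
                   eleno = seq_along(elety), elety = elety,
                   chain = rep(substr(chain, 1, 1), length(elety)),
                   elesy = elesy, end = TRUE)
  invisible(path)
}
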