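# Synthetic ground-truth structure generators: every other module is
# testable against these without any external structure files.

# Frozen CA pseudo-geometry of regular conformations: pseudo bond angle
# theta(i-1,i,i+1) and pseudo torsion alpha(i..i+3) in radians, derived
# once from backbones built with standard dihedrals (helix phi=-57,
# psi=-47; antiparallel strand phi=-119, psi=113; the left-handed state is
# the mirror image of the helix), then frozen
# (see data-raw/derive_constants.R).
HELIX_CA_ANGLE    <- 1.6032082221
HELIX_CA_TORSION  <- 0.8991012666
STRAND_CA_ANGLE   <- 2.0723695248
STRAND_CA_TORSION <- 3.0979602854
TURN_CA_ANGLE     <- 1.6032082221
TURN_CA_TORSION   <- -0.8991012666

# NeRF placement: position of the next atom given three predecessors and
# internal coordinates (bond, planar angle at c, torsion a-b-c-new).
nerf_place <- function(a, b, c, bond, angle, torsion) {
  bc <- unit3(c - b)
  n <- unit3(cross3(b - a, bc))
  m <- cross3(n, bc)
  d <- c(-bond * cos(angle), bond * sin(angle) * cos(torsion),
         bond * sin(angle) * sin(torsion))
  c + d[1] * bc + d[2] * m + d[3] * n
}

# Build a CA trace from per-step internal coordinates (lengths K-1, K-2, K-3).
ca_from_internal <- function(bonds, angles, torsions) {
  K <- length(bonds) + 1L
  xyz <- matrix(0, K, 3)
  xyz[2, ] <- c(bonds[1], 0, 0)
  if (K >= 3)
    xyz[3, ] <- xyz[2, ] + bonds[2] *
      c(-cos(angles[1]), sin(angles[1]), 0)
  if (K >= 4) for (i in 4:K) {
    xyz[i, ] <- nerf_place(xyz[i - 3, ], xyz[i - 2, ], xyz[i - 1, ],
                           bonds[i - 1], angles[i - 2], torsions[i - 3])
  }
  xyz
}

new_synthetic_chain <- function(trace, lambda, states = NULL) {
  backbone <- reconstruct_backbone(trace, lambda)
  structure(list(trace = trace, backbone = backbone, lambda = lambda,
                 sse = assign_secondary_structure(trace),
                 states = states),
            class = "synthetic_chain")
}

#' @export
print.synthetic_chain <- function(x, ...) {
  cat("synthetic_chain:", length(x$trace$sequence), "residues;",
      sum(x$lambda$defined), "defined plates\n")
  invisible(x)
}

#' Ideal alpha-helix test structure
#'
#' CA trace generated from the frozen helical pseudo-geometry, backbone
#' realized by placing ideal trans plates at the constant helical lambda.
#' All bond lengths equal the ideal constants and the stored lambda series
#' round-trips exactly through \code{\link{lambda_from_backbone}}.
#'
#' @param n_residues Chain length (>= 6).
#' @param sequence Optional 3-letter residue names (default poly-ALA).
#' @return Object of class \code{synthetic_chain} with elements
#'   \code{trace}, \code{backbone}, \code{lambda}, \code{sse}.
#' @export
make_ideal_helix <- function(n_residues, sequence = NULL) {
  if (n_residues < MIN_RESIDUES)
    stop("need at least ", MIN_RESIDUES, " residues")
  if (is.null(sequence)) sequence <- rep("ALA", n_residues)
  stopifnot(length(sequence) == n_residues)
  b <- plate_template("generic", "trans")$ca_ca
  xyz <- ca_from_internal(rep(b, n_residues - 1),
                          rep(HELIX_CA_ANGLE, n_residues - 2),
                          rep(HELIX_CA_TORSION, n_residues - 3))
  trace <- ca_trace(sequence, xyz)
  lam <- lambda_series(rep(LAMBDA_HELIX, n_residues - 1),
                       isomers = rep("trans", n_residues - 1))
  new_synthetic_chain(trace, lam, states = rep("H", n_residues - 1))
}

#' Ideal two-strand antiparallel hairpin
#'
#' Two extended zigzag strands 4.8 A apart joined by a single-residue turn;
#' the paired regions satisfy the strand criteria of the CA-only secondary
#' structure assigner and carry strand-type H-bond partners. Plates are
#' placed at the constant strand lambda.
#'
#' @param n_per_strand Residues per strand (>= 4).
#' @return A \code{synthetic_chain}.
#' @export
make_ideal_sheet <- function(n_per_strand = 6) {
  if (n_per_strand < 4) stop("need at least 4 residues per strand")
  n <- n_per_strand
  dx <- 3.55
  z0 <- 0.65
  b <- sqrt(dx^2 + (2 * z0)^2)          # consecutive CA distance in a strand
  gap <- 4.8                            # inter-strand CA-CA distance
  x_e <- (n - 1) * dx
  s1 <- cbind((seq_len(n) - 1) * dx, 0, z0 * (-1)^seq_len(n))
  # one turn residue equidistant (= b) from both strand ends
  c_off <- sqrt(b^2 - (gap / 2)^2 - z0^2)
  turn <- c(x_e + c_off, gap / 2, 0)
  s2 <- cbind(x_e - (seq_len(n) - 1) * dx, gap, z0 * (-1)^seq_len(n))
  xyz <- rbind(s1, turn, s2)
  K <- nrow(xyz)
  trace <- ca_trace(rep("ALA", K), xyz)
  lam <- lambda_series(rep(LAMBDA_STRAND, K - 1),
                       isomers = rep("trans", K - 1))
  states <- rep("E", K - 1)
  states[n:(n + 1)] <- "C"
  new_synthetic_chain(trace, lam, states = states)
}

#' Random synthetic chain with a known lambda series
#'
#' Emulates a protein-like chain as a hidden Markov process over three
#' conformational states -- helix (H), extended (E) and a short-lived
#' left-handed turn state (L) -- matching the bimodal lambda distribution of
#' experimental structures (a narrow mode at the helical lambda, a broad
#' extended mode, and a minor mode at the mirrored left-handed value).
#' Each state draws both the local CA pseudo-geometry and the plate lambda
#' from state-specific distributions, so the trace geometry is predictive
#' of lambda, as in real structures. Self-intersecting chains (any CA pair
#' at sequence separation >= 2 closer than 3 A) are resampled.
#'
#' @param k Number of residues (>= 6).
#' @param cis_fraction Probability that a plate is a cis peptide (its
#'   pseudo-bond is set to the cis template CA-CA distance).
#' @param seed Integer seed; generation is fully reproducible.
#' @param transitions 3x3 row-stochastic Markov matrix over states
#'   (H, E, L); defaults give mean runs of ~8 (H) and ~6 (E) residues and a
#'   ~5\% stationary share of L.
#' @param lambda_sd Named vector of lambda spread (radians) per state.
#' @param max_retry Resampling limit for self-intersecting chains.
#' @return A \code{synthetic_chain}; \code{states} holds the hidden
#'   per-plate state ("H"/"E"/"L").
#' @export
make_synthetic_chain <- function(k, cis_fraction = 0.01, seed = 1,
                                 transitions = NULL,
                                 lambda_sd = c(H = 0.08, E = 0.35, L = 0.25),
                                 max_retry = 100) {
  if (k < MIN_RESIDUES) stop("need at least ", MIN_RESIDUES, " residues")
  states <- c("H", "E", "L")
  if (is.null(transitions)) {
    transitions <- rbind(H = c(0.875, 0.100, 0.025),
                         E = c(0.125, 0.833, 0.042),
                         L = c(0.230, 0.470, 0.300))
    colnames(transitions) <- states
  }
  stopifnot(all(abs(rowSums(transitions) - 1) < 1e-8))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  b_trans <- plate_template("generic", "trans")$ca_ca
  b_cis <- plate_template("generic", "cis")$ca_ca
  deg <- pi / 180
  st_angle <- c(H = HELIX_CA_ANGLE, E = STRAND_CA_ANGLE, L = TURN_CA_ANGLE)
  st_torsion <- c(H = HELIX_CA_TORSION, E = STRAND_CA_TORSION,
                  L = TURN_CA_TORSION)
  st_angle_sd <- c(H = 2, E = 8, L = 3) * deg
  st_torsion_sd <- c(H = 4, E = 25, L = 6) * deg
  st_lambda <- c(H = LAMBDA_HELIX, E = LAMBDA_STRAND, L = LAMBDA_TURN)
  for (attempt in seq_len(max_retry)) {
    # hidden conformational state per plate
    st <- character(k - 1)
    st[1] <- sample(c("H", "E"), 1)
    for (p in 2:(k - 1))
      st[p] <- sample(states, 1, prob = transitions[st[p - 1], ])
    cis <- stats::runif(k - 1) < cis_fraction
    bonds <- ifelse(cis, b_cis, pmin(pmax(
      stats::rnorm(k - 1, b_trans, 0.03), b_trans - 0.08), b_trans + 0.08))
    # pseudo angle at residue i+1 and torsion ending at i+2 follow the state
    # of the plate they extend
    angles <- stats::rnorm(k - 2, st_angle[st[-1]], st_angle_sd[st[-1]])
    angles <- pmin(pmax(angles, 60 * deg), 170 * deg)
    torsions <- wrap_angle(stats::rnorm(k - 3, st_torsion[st[-(1:2)]],
                                        st_torsion_sd[st[-(1:2)]]))
    xyz <- ca_from_internal(bonds, angles, torsions)
    dmat <- as.matrix(stats::dist(xyz))
    sep <- abs(outer(seq_len(k), seq_len(k), "-"))
    if (any(dmat[sep >= 2] < 3.0)) next
    lam <- wrap_angle(stats::rnorm(k - 1, st_lambda[st], lambda_sd[st]))
    seqn <- sample(AA3, k, replace = TRUE)
    trace <- ca_trace(seqn, xyz)
    ls <- lambda_series(lam, isomers = ifelse(cis, "cis", "trans"))
    return(new_synthetic_chain(trace, ls, states = st))
  }
  stop("generation error: self-intersection retry limit (", max_retry,
       ") exceeded")
}

#' Export a synthetic backbone as atom records
#'
#' Converts a \code{\link{backbone_structure}} to the atom-record data frame
#' produced by \code{\link{read_structure}}, for exercising the quality
#' filter and writer without touching disk. Because the first residue's N
#' and the last residue's C/O are never defined by a plate, only residues
#' with a complete backbone are exported by default.
#'
#' @param backbone A \code{backbone_structure}.
#' @param complete_only Drop residues missing any of N/CA/C/O.
#' @return Atom-record data frame with a \code{chain_id} attribute.
#' @export
as_atom_records <- function(backbone, complete_only = TRUE) {
  K <- length(backbone$sequence)
  mats <- list(N = backbone$n, CA = backbone$ca, C = backbone$c,
               O = backbone$o)
  keep <- seq_len(K)
  if (complete_only) {
    full <- vapply(seq_len(K), function(j)
      !anyNA(c(mats$N[j, ], mats$CA[j, ], mats$C[j, ], mats$O[j, ])),
      logical(1))
    keep <- which(full)
  }
  rows <- list()
  for (new_idx in seq_along(keep)) {
    j <- keep[new_idx]
    for (a in c("N", "CA", "C", "O")) {
      if (anyNA(mats[[a]][j, ])) next
      rows[[length(rows) + 1L]] <- data.frame(
        residue_index = new_idx, resno = backbone$resno[j],
        resname = backbone$sequence[j], atom = a,
        x = mats[[a]][j, 1], y = mats[[a]][j, 2], z = mats[[a]][j, 3],
        occ = 1, altloc = "", stringsAsFactors = FALSE)
    }
  }
  rec <- do.call(rbind, rows)
  attr(rec, "chain_id") <- backbone$chain_id
  attr(rec, "altloc_flag") <- FALSE
  rec
}

#' Introduce one documented defect into a chain
#'
#' Corruption operators for testing the training-set quality filter: delete
#' a middle residue entirely, delete a single carbonyl O, or stretch one
#' C-N peptide bond by displacing the N along the bond direction.
#'
#' @param chain A \code{synthetic_chain} or an atom-record data frame.
#' @param mode One of \code{"delete-residue"}, \code{"delete-atom"},
#'   \code{"stretch-bond"}.
#' @param seed Seed selecting the affected site.
#' @param stretch Displacement along the bond for \code{stretch-bond} (A).
#' @return Corrupted atom-record data frame.
#' @export
corrupt_chain <- function(chain, mode = c("delete-residue", "delete-atom",
                                          "stretch-bond"),
                          seed = 1, stretch = 0.5) {
  mode <- match.arg(mode)
  rec <- if (inherits(chain, "synthetic_chain"))
    as_atom_records(chain$backbone) else chain
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  ridx <- sort(unique(rec$residue_index))
  mid <- ridx[ridx > min(ridx) & ridx < max(ridx)]
  target <- mid[sample.int(length(mid), 1)]
  out <- switch(mode,
    "delete-residue" = rec[rec$residue_index != target, , drop = FALSE],
    "delete-atom" = {
      drop <- which(rec$residue_index == target & rec$atom == "O")[1]
      rec[-drop, , drop = FALSE]
    },
    "stretch-bond" = {
      i_c <- which(rec$residue_index == target & rec$atom == "C")[1]
      i_n <- which(rec$residue_index == target + 1 & rec$atom == "N")[1]
      v <- unit3(as.numeric(rec[i_n, c("x", "y", "z")]) -
                 as.numeric(rec[i_c, c("x", "y", "z")]))
      rec[i_n, c("x", "y", "z")] <- rec[i_n, c("x", "y", "z")] + stretch * v
      rec
    })
  attr(out, "chain_id") <- attr(rec, "chain_id")
  attr(out, "altloc_flag") <- FALSE
  out
}
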