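#' One-hot encoding of residue identities
#'
#' Canonical residues occupy fixed alphabetical slots (ALA..VAL); anything
#' else (e.g. MSE) falls into the 21st 'X' slot.
#'
#' @param sequence Character vector of 3-letter residue names.
#' @return K x 21 binary matrix; each row sums to exactly 1.
#' @export
one_hot_residues <- function(sequence) {
  K <- length(sequence)
  m <- matrix(0L, K, 21)
  colnames(m) <- c(AA3, "X")
  slot <- match(sequence, AA3)
  slot[is.na(slot)] <- 21L
  m[cbind(seq_len(K), slot)] <- 1L
  m
}

#' Sequence-local CA-CA distances
#'
#' Distances |CA(i) - CA(i +/- j)| for j in \{3, 4, 5\}; offsets falling
#' outside the chain are reported as the sentinel 0.0 (distinguishable from
#' any real CA distance, which is >= ~2.6 A).
#'
#' @param trace A \code{\link{ca_trace}}.
#' @return K x 6 matrix, columns \code{dm3, dm4, dm5, dp3, dp4, dp5}
#'   (offsets -3, -4, -5, +3, +4, +5), Angstrom.
#' @export
local_ca_distances <- function(trace) {
  xyz <- trace$xyz
  K <- nrow(xyz)
  offs <- c(-3, -4, -5, 3, 4, 5)
  m <- matrix(0, K, 6)
  colnames(m) <- c("dm3", "dm4", "dm5", "dp3", "dp4", "dp5")
  for (col in seq_along(offs)) {
    j <- offs[col]
    i <- seq_len(K)
    ok <- i + j >= 1 & i + j <= K
    m[ok, col] <- sqrt(rowSums((xyz[i[ok] + j, , drop = FALSE] -
                                xyz[i[ok], , drop = FALSE])^2))
  }
  m
}

#' Spatial CA neighbor counts
#'
#' Number of CA atoms (any sequence separation, self excluded) strictly
#' within 4, 4.5, 5 and 6 Angstrom of each CA.
#'
#' @param trace A \code{\link{ca_trace}}.
#' @return K x 4 integer matrix, columns \code{n4, n4.5, n5, n6};
#'   monotonically non-decreasing with radius.
#' @export
neighbor_counts <- function(trace) {
  xyz <- trace$xyz
  K <- nrow(xyz)
  d <- as.matrix(stats::dist(xyz))
  diag(d) <- Inf
  radii <- c(4, 4.5, 5, 6)
  m <- vapply(radii, function(r) as.integer(rowSums(d < r)), integer(K))
  colnames(m) <- c("n4", "n4.5", "n5", "n6")
  m
}

# Pairwise CA distance matrix with Inf diagonal (shared helper).
ca_dist_matrix <- function(trace) {
  d <- as.matrix(stats::dist(trace$xyz))
  diag(d) <- Inf
  d
}

# Tunable thresholds of the CA-only secondary-structure assigner and the
# coarse-grained H-bond detector. These stand in for external references
# whose algorithms are not published; values were fixed against the ideal
# helix/sheet generators and are config, not literature, constants.
sse_config <- function() {
  list(helix_d13 = c(4.5, 6.0),   # d(i,i+3) window for helix (A)
       helix_d14 = c(5.5, 6.9),   # d(i,i+4) window for helix (A)
       helix_min_run = 3,
       strand_d13_min = 6.3,      # d(i,i+2) lower bound for extended (A)
       strand_min_run = 2,
       hb_helix = c(4.5, 6.5),    # CA-CA window of helix H-bond partners (A)
       hb_strand = c(4.2, 5.6),   # CA-CA window of strand H-bond partners (A)
       strand_min_sep = 3)        # minimum |i-j| for a strand partner
}

#' CA-only secondary structure assignment (H/E/C)
#'
#' A geometric stand-in for a helix/strand/coil assigner working from the
#' CA trace alone. Residue i is a helix candidate when d(i,i+3) and d(i,i+4)
#' fall in compact helix windows; runs of >= 3 candidates become H. A strand
#' candidate has extended local geometry (d(i,i+2) > 6.3 A); runs of >= 2
#' candidates that additionally have a strand-type spatial partner
#' (|i-j| >= 3, CA distance in [4.2, 5.6] A, partner also a candidate)
#' become E. Everything else is coil.
#'
#' @param trace A \code{\link{ca_trace}}.
#' @param config Threshold list, see \code{replate:::sse_config}.
#' @return Character vector of per-residue labels in \{"H","E","C"\},
#'   covering every residue.
#' @export
assign_secondary_structure <- function(trace, config = sse_config()) {
  K <- nrow(trace$xyz)
  ld <- local_ca_distances(trace)
  lab <- rep("C", K)

  helix_cand <- ld[, "dp3"] >= config$helix_d13[1] &
    ld[, "dp3"] <= config$helix_d13[2] &
    ld[, "dp4"] >= config$helix_d14[1] &
    ld[, "dp4"] <= config$helix_d14[2]
  helix_cand[is.na(helix_cand)] <- FALSE
  helix <- runs_at_least(helix_cand, config$helix_min_run)
  # a residue whose window starts a helix run covers itself; extend the label
  # over the i..i+4 span the windows describe would over-reach, so keep the
  # run residues plus the two that complete the last turn
  helix_lab <- helix
  idx <- which(helix)
  if (length(idx)) helix_lab[pmin(K, c(idx + 1, idx + 2, idx + 3))] <- TRUE
  lab[helix_lab] <- "H"

  d2 <- numeric(K)
  i <- seq_len(K - 2)
  d2[i] <- sqrt(rowSums((trace$xyz[i + 2, , drop = FALSE] -
                         trace$xyz[i, , drop = FALSE])^2))
  ext_cand <- d2 > config$strand_d13_min
  ext_cand[(K - 1):K] <- FALSE
  ext_run <- runs_at_least(ext_cand, config$strand_min_run)
  dmat <- ca_dist_matrix(trace)
  sep <- abs(outer(seq_len(K), seq_len(K), "-"))
  partner_ok <- dmat >= config$hb_strand[1] & dmat <= config$hb_strand[2] &
    sep >= config$strand_min_sep
  has_partner <- vapply(seq_len(K), function(i) {
    any(partner_ok[i, ] & ext_run)
  }, logical(1))
  strand <- ext_run & has_partner & lab != "H"
  lab[strand] <- "E"
  lab
}

# TRUE for positions belonging to a run of at least n consecutive TRUEs.
runs_at_least <- function(x, n) {
  r <- rle(x)
  r$values <- r$values & r$lengths >= n
  inverse.rle(r)
}

#' Coarse-grained hydrogen-bond counts in regular secondary structure
#'
#' Counts putative H-bond partners per residue, gated by the secondary
#' structure labels so that (like a mean-field CG H-bond potential) bonds are
#' detected only inside regular elements: helix partners at sequence
#' separation 3 or 4 with CA distance in [4.5, 6.5] A and both residues H;
#' strand partners at separation >= 3 with CA distance in [4.2, 5.6] A and
#' both residues E.
#'
#' @param trace A \code{\link{ca_trace}}.
#' @param sse Labels from \code{\link{assign_secondary_structure}}.
#' @param config Threshold list, see \code{replate:::sse_config}.
#' @return K x 2 integer matrix, columns \code{hb_helix}, \code{hb_strand}.
#' @export
hbond_counts <- function(trace, sse = assign_secondary_structure(trace),
                         config = sse_config()) {
  K <- nrow(trace$xyz)
  dmat <- ca_dist_matrix(trace)
  sep <- abs(outer(seq_len(K), seq_len(K), "-"))
  is_h <- sse == "H"
  is_e <- sse == "E"
  helix_pair <- (sep == 3 | sep == 4) &
    dmat >= config$hb_helix[1] & dmat <= config$hb_helix[2] &
    outer(is_h, is_h, "&")
  strand_pair <- sep >= config$strand_min_sep &
    dmat >= config$hb_strand[1] & dmat <= config$hb_strand[2] &
    outer(is_e, is_e, "&")
  m <- cbind(hb_helix = as.integer(rowSums(helix_pair)),
             hb_strand = as.integer(rowSums(strand_pair)))
  m
}

#' Cis peptide-bond flags
#'
#' Flag is 1 for residue i when the pseudo-bond CA(i)-CA(i+1) is classified
#' cis (< 3.5 A); the last residue has no following bond and is always 0.
#'
#' @param trace A \code{\link{ca_trace}}.
#' @return K x 1 binary matrix, column \code{cis}.
#' @export
cis_flags <- function(trace) {
  xyz <- trace$xyz
  K <- nrow(xyz)
  d <- sqrt(rowSums((xyz[-1, , drop = FALSE] - xyz[-K, , drop = FALSE])^2))
  m <- matrix(c(as.integer(classify_isomer(d) == "cis"), 0L), ncol = 1)
  colnames(m) <- "cis"
  m
}

#' Assemble the K x 37 network input
#'
#' Column layout (fixed, also used as the TSV header): 21 one-hot residue
#' slots, 6 local CA distances (offsets -3,-4,-5,+3,+4,+5), 4 neighbor
#' counts (radii 4/4.5/5/6 A), 3 secondary-structure one-hots (H,E,C), 1 cis
#' flag for bond (i,i+1), and 2 H-bond counts (helix, strand).
#'
#' @param trace A \code{\link{ca_trace}}.
#' @param standardize Per-column standardization switch (off by default; the
#'   network consumes raw Angstrom / count values).
#' @return K x 37 numeric matrix of class \code{feature_matrix} with named
#'   columns and an \code{sse} attribute carrying the labels used.
#' @export
build_feature_matrix <- function(trace, standardize = FALSE) {
  sse <- assign_secondary_structure(trace)
  sse_oh <- matrix(0L, length(sse), 3, dimnames = list(NULL, c("H", "E", "C")))
  sse_oh[cbind(seq_along(sse), match(sse, c("H", "E", "C")))] <- 1L
  m <- cbind(one_hot_residues(trace$sequence),
             local_ca_distances(trace),
             neighbor_counts(trace),
             sse_oh,
             cis_flags(trace),
             hbond_counts(trace, sse))
  if (standardize) {
    mu <- colMeans(m)
    sdv <- apply(m, 2, stats::sd)
    sdv[sdv < 1e-8] <- 1
    m <- sweep(sweep(m, 2, mu), 2, sdv, "/")
  }
  structure(m, sse = sse, class = c("feature_matrix", class(m)))
}

#' Export a feature matrix as TSV
#'
#' @param features Matrix from \code{\link{build_feature_matrix}}.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_features_tsv <- function(features, path) {
  utils::write.table(as.data.frame(unclass(features)), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
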