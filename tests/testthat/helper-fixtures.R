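# Shared test helpers: tiny hand-written PDB fixtures and utilities.

# Two-residue ALA-GLY fixture, 8 backbone atoms, written by hand.
# Coordinates are an arbitrary but stereochemically sane dipeptide.
tiny_pdb_text <- function(altloc = FALSE) {
  c(
    "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00 10.00           N",
    sprintf("ATOM      2  CA %sALA A   1      11.639   6.071  -5.147  %s 10.00           C",
            if (altloc) "A" else " ", if (altloc) "0.60" else "1.00"),
    if (altloc)
      "ATOM      3  CA BALA A   1      11.700   6.100  -5.100  0.40 10.00           C",
    "ATOM      4  C   ALA A   1      12.685   7.161  -4.937  1.00 10.00           C",
    "ATOM      5  O   ALA A   1      13.339   7.615  -5.877  1.00 10.00           O",
    "ATOM      6  N   GLY A   2      12.824   7.572  -3.675  1.00 10.00           N",
    "ATOM      7  CA  GLY A   2      13.791   8.617  -3.355  1.00 10.00           C",
    "ATOM      8  C   GLY A   2      15.197   8.102  -3.570  1.00 10.00           C",
    "ATOM      9  O   GLY A   2      15.902   8.512  -4.481  1.00 10.00           O",
    "END")
}

write_tiny_pdb <- function(path, altloc = FALSE) {
  writeLines(tiny_pdb_text(altloc), path)
  path
}

# Drop the terminal residues of a reconstructed backbone so every remaining
# residue carries a complete N/CA/C/O set (the first N and last C/O are
# never defined by a plate).
trim_backbone <- function(bb) {
  K <- length(bb$sequence)
  idx <- 2:(K - 1)
  backbone_structure(sequence = bb$sequence[idx],
                     ca = bb$ca[idx, , drop = FALSE],
                     n = bb$n[idx, , drop = FALSE],
                     c = bb$c[idx, , drop = FALSE],
                     o = bb$o[idx, , drop = FALSE],
                     chain_id = bb$chain_id, resno = seq_along(idx))
}

dist3 <- function(a, b) sqrt(sum((a - b)^2))

# Independent brute-force dihedral via explicit plane normals:
# magnitude from acos of the normal dot product, sign from the determinant.
brute_torsion <- function(p1, p2, p3, p4) {
  cr <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                         a[3] * b[1] - a[1] * b[3],
                         a[1] * b[2] - a[2] * b[1])
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cr(b1, b2); n2 <- cr(b2, b3)
  cosv <- sum(n1 * n2) / sqrt(sum(n1^2) * sum(n2^2))
  ang <- acos(pmin(1, pmax(-1, cosv)))
  s <- sign(det(rbind(b1, b2, b3)))
  if (s < 0) -ang else ang
}

expect_angles_equal <- function(a, b, tol = 1e-9) {
  expect_lt(max(abs(wrap_angle(a - b))), tol)
}
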