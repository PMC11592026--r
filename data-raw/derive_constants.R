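# Derivation of the frozen secondary-structure constants in R/constants.R and
# R/fixtures.R: builds full backbones from standard dihedrals (helix
# phi=-57, psi=-47; antiparallel strand phi=-119, psi=113) with the ideal
# plate geometry, then measures the lambda angle and the CA pseudo-geometry.
# Run from the package root: Rscript data-raw/derive_constants.R
pkgload::load_all(".", quiet = TRUE)

build_backbone_phipsi <- function(n, phi, psi, g = ideal_geometry()) {
  deg <- pi / 180
  # atom sequence N1 CA1 C1 N2 CA2 C2 ... with O added afterwards
  at <- list()
  at[["N1"]] <- c(0, 0, 0)
  at[["CA1"]] <- c(g$n_ca, 0, 0)
  ang_ncac <- 111.2 * deg
  at[["C1"]] <- at[["CA1"]] + g$ca_c * c(-cos(ang_ncac), sin(ang_ncac), 0)
  place <- replate:::nerf_place
  for (i in 2:n) {
    at[[paste0("N", i)]] <- place(at[[paste0("N", i - 1)]],
                                  at[[paste0("CA", i - 1)]],
                                  at[[paste0("C", i - 1)]],
                                  g$c_n, g$ang_ca_c_n * deg, psi * deg)
    at[[paste0("CA", i)]] <- place(at[[paste0("CA", i - 1)]],
                                   at[[paste0("C", i - 1)]],
                                   at[[paste0("N", i)]],
                                   g$n_ca, g$ang_c_n_ca * deg, pi)  # omega
    at[[paste0("C", i)]] <- place(at[[paste0("C", i - 1)]],
                                  at[[paste0("N", i)]],
                                  at[[paste0("CA", i)]],
                                  g$ca_c, 111.2 * deg, phi * deg)
  }
  n_xyz <- t(sapply(1:n, function(i) at[[paste0("N", i)]]))
  ca_xyz <- t(sapply(1:n, function(i) at[[paste0("CA", i)]]))
  c_xyz <- t(sapply(1:n, function(i) at[[paste0("C", i)]]))
  o_xyz <- matrix(NA_real_, n, 3)
  for (i in 1:(n - 1)) {
    o_xyz[i, ] <- place(n_xyz[i, ], ca_xyz[i, ], c_xyz[i, ],
                        g$c_o, g$ang_ca_c_o * deg,
                        replate::wrap_angle(psi * deg + pi))
  }
  backbone_structure(rep("ALA", n), ca = ca_xyz, n = n_xyz,
                     c = c_xyz, o = o_xyz)
}

summarise <- function(name, phi, psi) {
  bb <- build_backbone_phipsi(30, phi, psi)
  lam <- lambda_from_backbone(bb)
  ca <- bb$ca
  K <- nrow(ca)
  d <- sqrt(rowSums((ca[-1, ] - ca[-K, ])^2))
  ang <- sapply(2:(K - 1), function(i) {
    v1 <- ca[i - 1, ] - ca[i, ]; v2 <- ca[i + 1, ] - ca[i, ]
    acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2)))
  })
  tor <- sapply(1:(K - 3), function(i)
    torsion_angle(ca[i, ], ca[i + 1, ], ca[i + 2, ], ca[i + 3, ]))
  # interior plates only (terminal plate uses the fallback reference)
  lam_int <- lam$values[3:(K - 3)]
  cat(sprintf("%s: lambda = %.10f (sd %.2e)\n", name, mean(lam_int), sd(lam_int)))
  cat(sprintf("  ca-ca dist  = %.10f (sd %.2e)\n", mean(d), sd(d)))
  cat(sprintf("  ca angle    = %.10f rad (%.3f deg, sd %.2e)\n",
              mean(ang[2:(length(ang)-1)]), mean(ang[2:(length(ang)-1)])/pi*180,
              sd(ang[2:(length(ang)-1)])))
  cat(sprintf("  ca torsion  = %.10f rad (%.3f deg, sd %.2e)\n",
              mean(tor[2:(length(tor)-1)]), mean(tor[2:(length(tor)-1)])/pi*180,
              sd(tor[2:(length(tor)-1)])))
  invisible(list(bb = bb, lam = lam))
}

h <- summarise("helix  (phi=-57, psi=-47)", -57, -47)
s <- summarise("strand (phi=-119, psi=113)", -119, 113)
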