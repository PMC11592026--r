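test_that("plate templates are planar with ideal internal geometry", {
  g <- ideal_geometry()
  for (cls in c("generic", "proline")) for (iso in c("trans", "cis")) {
    tm <- plate_template(cls, iso, include_h = TRUE)
    at <- tm$atoms
    expect_true(all(abs(at[, "z"]) < 1e-9))   # coplanar by construction
    om <- torsion_angle(at["CA1", ], at["C", ], at["N", ], at["CA2", ])
    if (iso == "trans") expect_lt(abs(abs(om) - pi), 1e-9)
    else expect_lt(abs(om), 1e-9)
    expect_equal(dist3(at["CA1", ], at["C", ]), g$ca_c, tolerance = 1e-12)
    expect_equal(dist3(at["C", ], at["O", ]), g$c_o, tolerance = 1e-12)
    cn <- if (cls == "proline") g$c_n_pro else g$c_n
    nca <- if (cls == "proline") g$n_ca_pro else g$n_ca
    expect_equal(dist3(at["C", ], at["N", ]), cn, tolerance = 1e-12)
    expect_equal(dist3(at["N", ], at["CA2", ]), nca, tolerance = 1e-12)
  }
})

test_that("cis templates are compatible with the distance-based isomer rule", {
  tt <- plate_template("generic", "trans")
  tc <- plate_template("generic", "cis")
  expect_gt(tt$ca_ca, 3.5)
  expect_lt(tc$ca_ca, 3.5)
  expect_equal(tt$ca_ca, 3.804, tolerance = 1e-3)
})

test_that("classify_isomer applies the 3.5 A threshold with a strict <", {
  expect_equal(classify_isomer(3.0), "cis")
  expect_equal(classify_isomer(3.8), "trans")
  expect_equal(classify_isomer(3.5), "trans")
  expect_equal(classify_isomer(c(0, 0, 0), c(2.9, 0, 0)), "cis")
})

test_that("place_plate is 2*pi periodic and inverted exactly by extraction", {
  tm <- plate_template("generic", "trans")
  ca_p <- c(1, 2, 3); ca_next <- ca_p + c(3.0, 2.0, 1.2)
  ref <- c(-2, 0.5, 4)
  a1 <- place_plate(tm, ca_p, ca_next, 0.77, ref)
  a2 <- place_plate(tm, ca_p, ca_next, 0.77 + 2 * pi, ref)
  expect_lt(max(abs(a1 - a2)), 1e-12)
  expect_error(place_plate(tm, ca_p, ca_p, 0, ref), "degenerate")
  expect_error(place_plate(tm, ca_p, ca_next, 0, ca_p + 0.5 * (ca_next - ca_p)),
               "degenerate")
})

test_that("lambda extraction recovers the placement angle on synthetic chains", {
  for (s in 1:5) {
    ch <- make_synthetic_chain(30, seed = s, cis_fraction = 0.05)
    lam <- lambda_from_backbone(ch$backbone)
    expect_true(all(lam$defined))
    expect_angles_equal(lam$values, ch$lambda$values, tol = 1e-9)
    # CA positions pass through reconstruction untouched
    expect_identical(ch$backbone$ca, ch$trace$xyz)
  }
})

test_that("lambda is invariant and reconstruction equivariant under rigid motion", {
  ch <- make_synthetic_chain(25, seed = 7)
  set.seed(42)
  for (i in 1:5) {
    tf <- random_rigid_transform()
    bb2 <- ch$backbone
    for (slot in c("ca", "n", "c", "o")) {
      ok <- stats::complete.cases(bb2[[slot]])
      bb2[[slot]][ok, ] <- apply_rigid(bb2[[slot]][ok, , drop = FALSE], tf)
    }
    lam2 <- lambda_from_backbone(bb2)
    expect_angles_equal(lam2$values, ch$lambda$values, tol = 1e-9)
    tr2 <- ca_trace(ch$trace$sequence, apply_rigid(ch$trace$xyz, tf))
    rec2 <- reconstruct_backbone(tr2, ch$lambda)
    for (slot in c("n", "c", "o")) {
      ok <- stats::complete.cases(ch$backbone[[slot]])
      expect_lt(max(abs(rec2[[slot]][ok, ] -
                        apply_rigid(ch$backbone[[slot]][ok, , drop = FALSE],
                                    tf))), 1e-9)
    }
  }
})

test_that("every reconstructed plate is planar with the ideal omega", {
  ch <- make_synthetic_chain(40, seed = 3, cis_fraction = 0.1)
  bb <- ch$backbone
  K <- length(bb$sequence)
  for (p in seq_len(K - 1)) {
    om <- torsion_angle(bb$ca[p, ], bb$c[p, ], bb$n[p + 1, ], bb$ca[p + 1, ])
    if (bb$isomers[p] == "trans") expect_lt(abs(abs(om) - pi), 1e-6)
    else expect_lt(abs(om), 1e-6)
  }
})

test_that("an ideal helix has near-constant lambda along interior plates", {
  h <- make_ideal_helix(25)
  lam <- lambda_from_backbone(h$backbone)
  interior <- lam$values[3:20]
  expect_lt(stats::sd(interior), 0.02)
  expect_angles_equal(mean(interior), -1.9045277, tol = 1e-4)
})

test_that("proline plates use the proline template consistently", {
  seqn <- rep("ALA", 12); seqn[6] <- "PRO"
  ch <- make_ideal_helix(12, sequence = seqn)
  g <- ideal_geometry()
  # plate 5 feeds proline's N: its C-N bond carries the proline length
  expect_equal(dist3(ch$backbone$c[5, ], ch$backbone$n[6, ]), g$c_n_pro,
               tolerance = 1e-9)
  expect_equal(dist3(ch$backbone$c[6, ], ch$backbone$n[7, ]), g$c_n,
               tolerance = 1e-9)
  lam <- lambda_from_backbone(ch$backbone)
  expect_angles_equal(lam$values, ch$lambda$values, tol = 1e-9)
})

test_that("undefined lambda entries are filled from the nearest defined plate", {
  h <- make_ideal_helix(10)
  vals <- h$lambda$values
  vals[4] <- NA
  lam <- lambda_series(vals)
  expect_false(lam$defined[4])
  bb <- reconstruct_backbone(h$trace, lam)
  # nearest neighbor carries the same constant angle, so the backbone matches
  expect_lt(max(abs(bb$c - h$backbone$c), na.rm = TRUE), 1e-9)
})

test_that("terminal residues have no plate-defined atoms", {
  ch <- make_synthetic_chain(15, seed = 2)
  bb <- ch$backbone
  expect_true(all(is.na(bb$n[1, ])))
  expect_true(all(is.na(bb$c[15, ])))
  expect_true(all(is.na(bb$o[15, ])))
  expect_true(all(stats::complete.cases(bb$n[-1, ])))
})
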