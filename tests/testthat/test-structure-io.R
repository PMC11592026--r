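test_that("a hand-written two-residue PDB parses into 8 atom records", {
  f <- withr::local_tempfile(fileext = ".pdb")
  write_tiny_pdb(f)
  chains <- read_structure(f)
  expect_length(chains, 1)
  ch <- chains[[1]]
  expect_equal(nrow(ch), 8)
  expect_equal(sort(unique(ch$resname)), c("ALA", "GLY"))
  expect_equal(unique(ch$residue_index), 1:2)
  expect_false(attr(ch, "altloc_flag"))
})

test_that("alternate locations keep the highest-occupancy conformer and flag", {
  f <- withr::local_tempfile(fileext = ".pdb")
  write_tiny_pdb(f, altloc = TRUE)
  ch <- read_structure(f)[[1]]
  expect_true(attr(ch, "altloc_flag"))
  ca1 <- ch[ch$residue_index == 1 & ch$atom == "CA", ]
  expect_equal(nrow(ca1), 1)
  expect_equal(ca1$x, 11.639)  # conformer A (occupancy 0.60)
  expect_false(chain_quality_filter(ch)$accepted)
  expect_true("alt-loc" %in% chain_quality_filter(ch)$reasons)
})

test_that("unreadable paths and empty results raise I/O errors", {
  expect_error(read_structure("/nonexistent/file.pdb"), "cannot read")
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("HETATM    1  O   HOH A   1       0.000   0.000   0.000  1.00  0.00           O",
               "END"), f)
  expect_error(read_structure(f), "no protein chain")
})

test_that("write_backbone / read_structure round-trips to PDB precision", {
  ch <- make_synthetic_chain(12, seed = 5)
  bb <- trim_backbone(ch$backbone)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_backbone(bb, f)
  back <- as_backbone(read_structure(f)[[1]])
  expect_equal(nrow(back$ca), 10)
  for (slot in c("ca", "n", "c", "o"))
    expect_lt(max(abs(back[[slot]] - bb[[slot]])), 1e-3)
  # 4 atoms per residue
  expect_equal(sum(grepl("^ATOM", readLines(f))), 40)
  expect_error(write_backbone(backbone_structure("ALA",
    matrix(NA_real_, 1, 3), matrix(NA_real_, 1, 3),
    matrix(NA_real_, 1, 3), matrix(NA_real_, 1, 3)), f), "empty backbone")
})

test_that("extract_ca_trace validates length and chain breaks", {
  h <- make_ideal_helix(10)
  rec <- as_atom_records(h$backbone, complete_only = FALSE)
  trace <- extract_ca_trace(rec)
  expect_length(trace$sequence, 10)
  d <- sqrt(rowSums(diff(trace$xyz)^2))
  expect_true(all(abs(d - 3.804) < 0.01))
  # deleting residue 5 opens a > 4.3 A gap
  expect_error(extract_ca_trace(rec[rec$residue_index != 5, ]),
               "chain-break")
  # a 5-residue chain is too short
  expect_error(extract_ca_trace(rec[rec$residue_index <= 5, ]), "too-short")
})

test_that("quality filter accepts clean fixtures and tags each corruption", {
  ch <- make_synthetic_chain(20, seed = 8)
  rec <- as_atom_records(ch$backbone)
  expect_true(chain_quality_filter(rec)$accepted)
  r1 <- chain_quality_filter(corrupt_chain(ch, "delete-residue", seed = 2))
  expect_false(r1$accepted)
  expect_true("missing-residue" %in% r1$reasons)
  r2 <- chain_quality_filter(corrupt_chain(ch, "delete-atom", seed = 2))
  expect_false(r2$accepted)
  expect_true("missing-backbone-atom" %in% r2$reasons)
  r3 <- chain_quality_filter(corrupt_chain(ch, "stretch-bond", seed = 2))
  expect_false(r3$accepted)
  expect_true("stereochemical-error" %in% r3$reasons)
})

test_that("true-lambda reconstruction of an experimental X-ray structure", {
  # hen egg-white lysozyme shipped with bio3d; regression value frozen from
  # the first computation with the released geometry constants
  f <- system.file("examples/1hel.pdb", package = "bio3d")
  res <- cmd_true_lambda(f, verbose = FALSE)
  expect_equal(res[[1]]$report$crmsd_all, 0.0648, tolerance = 0.02)
})
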