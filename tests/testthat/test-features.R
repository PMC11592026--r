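collinear_trace <- function(K, spacing = 3.8) {
  ca_trace(rep("GLY", K), cbind(spacing * (seq_len(K) - 1), 0, 0),
           validate = FALSE)
}

test_that("residue one-hot uses fixed slots with X for noncanonical types", {
  m <- one_hot_residues(c("ALA", "MSE", "VAL"))
  expect_equal(dim(m), c(3, 21))
  expect_equal(unname(m[1, "ALA"]), 1L)
  expect_equal(unname(m[2, "X"]), 1L)
  expect_equal(unname(m[3, "VAL"]), 1L)
  set.seed(1)
  seqn <- sample(c(replate:::AA3, "UNK", "MSE"), 50, replace = TRUE)
  expect_true(all(rowSums(one_hot_residues(seqn)) == 1))
})

test_that("local CA distances use the 0.0 sentinel outside the chain", {
  tr <- collinear_trace(12)
  m <- local_ca_distances(tr)
  expect_equal(m[1, c("dm3", "dm4", "dm5")], c(dm3 = 0, dm4 = 0, dm5 = 0))
  expect_equal(m[2, "dp3"], c(dp3 = 11.4))
  expect_equal(m[12, c("dp3", "dp4", "dp5")], c(dp3 = 0, dp4 = 0, dp5 = 0))
  # helix local distances are compact compared to the extended chain
  h <- make_ideal_helix(15)
  mh <- local_ca_distances(h$trace)
  expect_true(all(mh[2:10, "dp3"] > 5.0 & mh[2:10, "dp3"] < 5.6))
})

test_that("neighbor counts match a strict-< rule and a brute-force oracle", {
  tr3 <- collinear_trace(3)
  m <- neighbor_counts(tr3)
  expect_equal(unname(m[2, ]), c(2L, 2L, 2L, 2L))
  expect_equal(unname(m[1, ]), c(1L, 1L, 1L, 1L))
  # exactly 4.0 A is not counted at radius 4 but is at 4.5
  tr2 <- ca_trace(rep("ALA", 6),
                  cbind(c(0, 4, 8, 12, 16, 20), 0, 0), validate = FALSE)
  m2 <- neighbor_counts(tr2)
  expect_equal(unname(m2[1, ]), c(0L, 1L, 1L, 1L))
  ch <- make_synthetic_chain(100, seed = 31)
  got <- neighbor_counts(ch$trace)
  xyz <- ch$trace$xyz
  for (i in seq_len(100)) {
    d <- sqrt(colSums((t(xyz) - xyz[i, ])^2))
    d[i] <- Inf
    expect_equal(unname(got[i, ]),
                 vapply(c(4, 4.5, 5, 6), function(r) sum(d < r), integer(1)))
  }
  expect_true(all(got[, 1] <= got[, 2] & got[, 2] <= got[, 3] &
                  got[, 3] <= got[, 4]))
})

test_that("secondary structure labels are total and match the fixtures", {
  h <- make_ideal_helix(20)
  expect_true(all(h$sse[2:16] == "H"))
  s <- make_ideal_sheet(6)
  expect_true(any(s$sse == "E"))
  expect_true(all(s$sse %in% c("H", "E", "C")))
  ch <- make_synthetic_chain(6, seed = 4)
  lab <- assign_secondary_structure(ch$trace)
  expect_length(lab, 6)
  expect_true(all(lab %in% c("H", "E", "C")))
})

test_that("H-bond counts are gated by the secondary structure labels", {
  # all-coil chain: both columns zero regardless of geometry
  ch <- make_synthetic_chain(20, seed = 12)
  hb <- hbond_counts(ch$trace, sse = rep("C", 20))
  expect_true(all(hb == 0))
  h <- make_ideal_helix(20)
  hb_h <- hbond_counts(h$trace, h$sse)
  expect_true(all(hb_h[5:14, "hb_helix"] >= 1))
  expect_true(all(hb_h[, "hb_strand"] == 0))
  s <- make_ideal_sheet(6)
  hb_s <- hbond_counts(s$trace, s$sse)
  expect_true(any(hb_s[, "hb_strand"] >= 1))
})

test_that("cis flags mark compressed pseudo-bonds and end with 0", {
  tr <- collinear_trace(8)
  expect_true(all(cis_flags(tr) == 0))
  xyz <- tr$xyz
  xyz[5, 1] <- xyz[4, 1] + 2.9  # compress bond 4-5
  xyz[6:8, 1] <- xyz[6:8, 1] - (3.8 - 2.9)
  tr2 <- ca_trace(tr$sequence, xyz)
  fl <- cis_flags(tr2)
  expect_equal(which(fl == 1), 4L)
  expect_equal(fl[8, 1], c(cis = 0))
})

test_that("the assembled feature matrix has the documented 37-column layout", {
  ch <- make_synthetic_chain(30, seed = 21)
  m <- build_feature_matrix(ch$trace)
  expect_equal(dim(m), c(30, 37))
  expect_equal(colnames(m)[22:27], c("dm3", "dm4", "dm5", "dp3", "dp4", "dp5"))
  expect_equal(colnames(m)[28:31], c("n4", "n4.5", "n5", "n6"))
  expect_equal(colnames(m)[32:34], c("H", "E", "C"))
  expect_equal(colnames(m)[35], "cis")
  expect_equal(colnames(m)[36:37], c("hb_helix", "hb_strand"))
  expect_true(all(rowSums(m[, 1:21]) == 1))
  expect_true(all(rowSums(m[, 32:34]) == 1))
  # permuting residue identities touches only the one-hot block
  tr2 <- ca_trace(rev(ch$trace$sequence), ch$trace$xyz)
  m2 <- build_feature_matrix(tr2)
  expect_identical(unclass(m)[, 22:37], unclass(m2)[, 22:37])
})

test_that("all features are invariant under rigid motion of the trace", {
  ch <- make_synthetic_chain(40, seed = 22)
  m <- unclass(build_feature_matrix(ch$trace))
  set.seed(5)
  for (i in 1:3) {
    tf <- random_rigid_transform()
    tr2 <- ca_trace(ch$trace$sequence, apply_rigid(ch$trace$xyz, tf))
    expect_lt(max(abs(unclass(build_feature_matrix(tr2)) - m)), 1e-9)
  }
})

test_that("feature TSV export carries a full header", {
  ch <- make_synthetic_chain(10, seed = 2)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_features_tsv(build_feature_matrix(ch$trace), f)
  tab <- utils::read.delim(f, check.names = FALSE)
  expect_equal(ncol(tab), 37)
  expect_equal(nrow(tab), 10)
})
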