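test_that("a hand-written one-residue PDB parses to the right fields", {
  tmp <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1      11.639   6.071  -5.147  1.00  0.00           C",
    "END"), tmp)
  s <- read_pdb(tmp)
  expect_s3_class(s, "structure3d")
  expect_equal(nrow(s$atoms), 2)
  expect_equal(s$atoms$elety, c("N", "CA"))
  expect_equal(s$atoms$resno, c(1L, 1L))
  expect_equal(s$atoms$x, c(11.104, 11.639))
  expect_equal(s$atoms$element, c("N", "C"))
})

test_that("write/read round trip preserves atoms and coordinates to 1e-3 A", {
  sol <- make_solenoid(solenoid_spec(seed = 11))
  tmp <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(sol$structure, tmp)
  back <- read_pdb(tmp)
  expect_equal(nrow(back$atoms), nrow(sol$structure$atoms))
  expect_identical(back$atoms$elety, sol$structure$atoms$elety)
  expect_identical(back$atoms$resno, sol$structure$atoms$resno)
  expect_lt(max(abs(as.matrix(back$atoms[, c("x", "y", "z")]) -
                      as.matrix(sol$structure$atoms[, c("x", "y", "z")]))),
            1e-3 + 1e-12)
})

test_that("duplicate atom serials are accepted with a warning", {
  tmp <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00  0.00           N",
    "ATOM      1  CA  ALA A   1      11.639   6.071  -5.147  1.00  0.00           C",
    "END"), tmp)
  expect_warning(s <- read_pdb(tmp), "duplicate atom serial")
  expect_equal(nrow(s$atoms), 2)
})

test_that("malformed and empty PDB inputs error", {
  expect_error(read_pdb(tempfile()), "not found")
  tmp <- withr::local_tempfile(fileext = ".pdb")
  writeLines("REMARK nothing here", tmp)
  expect_error(read_pdb(tmp))
})

test_that("structure3d enforces its invariants", {
  base <- data.frame(chain = "A", resno = 1, resid = "ALA", elety = "CA",
                     element = "C", x = 0, y = 0, z = 0)
  expect_error(structure3d(base[0, ]), "empty")
  bad <- base; bad$x <- NA_real_
  expect_error(structure3d(bad), "non-finite")
  dec <- rbind(base, transform(base, resno = 0))
  expect_error(structure3d(dec), "decrease")
})

test_that("kabsch_superpose recovers identity and a known rigid motion", {
  set.seed(1)
  A <- matrix(rnorm(30, sd = 4), 10, 3)
  self <- kabsch_superpose(A, A)
  expect_equal(self$rmsd, 0, tolerance = 1e-9)
  expect_equal(self$transform$R, diag(3), tolerance = 1e-9)

  Rz90 <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  B <- A %*% t(Rz90) + matrix(c(3, -2, 7), 10, 3, byrow = TRUE)
  sup <- kabsch_superpose(A, B)
  expect_equal(sup$rmsd, 0, tolerance = 1e-9)
  expect_equal(sup$transform$R, Rz90, tolerance = 1e-9)
  expect_equal(sup$transform$t, c(3, -2, 7), tolerance = 1e-9)
  expect_equal(det(sup$transform$R), 1, tolerance = 1e-9)
})

test_that("kabsch rmsd matches the quaternion oracle on noisy point sets", {
  set.seed(7)
  for (i in 1:25) {
    A <- matrix(rnorm(30, sd = 5), 10, 3)
    ang <- runif(1, 0, 2 * pi)
    Rz <- matrix(c(cos(ang), -sin(ang), 0, sin(ang), cos(ang), 0, 0, 0, 1),
                 3, 3, byrow = TRUE)
    B <- A %*% t(Rz) + matrix(runif(3, -10, 10), 10, 3, byrow = TRUE) +
      matrix(rnorm(30, sd = 0.4), 10, 3)
    expect_equal(kabsch_superpose(A, B)$rmsd, qcp_rmsd(A, B),
                 tolerance = 1e-6)
  }
})

test_that("kabsch rejects degenerate input and never reflects", {
  expect_error(kabsch_superpose(diag(3)[1:2, ], diag(3)[1:2, ]),
               "at least 3")
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line, line), "collinear")
  # mirror-image target must still yield a proper rotation
  set.seed(2)
  A <- matrix(rnorm(24, sd = 3), 8, 3)
  B <- A; B[, 1] <- -B[, 1]
  sup <- kabsch_superpose(A, B)
  expect_equal(det(sup$transform$R), 1, tolerance = 1e-9)
})

test_that("kabsch rmsd is invariant under a joint rigid motion", {
  set.seed(3)
  A <- matrix(rnorm(36, sd = 5), 12, 3)
  B <- A + matrix(rnorm(36, sd = 0.5), 12, 3)
  base <- kabsch_superpose(A, B)$rmsd
  tf <- rigid_transform(matrix(c(0, 0, 1, 1, 0, 0, 0, 1, 0), 3, 3,
                               byrow = TRUE), c(5, 6, -7))
  moved <- kabsch_superpose(apply_transform(A, tf), apply_transform(B, tf))
  expect_equal(moved$rmsd, base, tolerance = 1e-9)
})

test_that("rigid transforms validate, invert and compose", {
  expect_error(rigid_transform(diag(c(1, 1, -1))), "determinant")
  expect_error(rigid_transform(matrix(1, 3, 3)), "orthonormal")
  tf <- rigid_transform(matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3,
                               byrow = TRUE), c(1, 2, 3))
  x <- matrix(rnorm(15), 5, 3)
  expect_equal(apply_transform(apply_transform(x, tf), invert_transform(tf)),
               x, tolerance = 1e-9)
  tf2 <- rigid_transform(matrix(c(1, 0, 0, 0, 0, -1, 0, 1, 0), 3, 3,
                               byrow = TRUE), c(-4, 0, 2))
  expect_equal(apply_transform(x, compose_transform(tf2, tf)),
               apply_transform(apply_transform(x, tf), tf2),
               tolerance = 1e-9)
})

test_that("an ideal 12-residue helix is assigned as one segment", {
  h <- assign_helices(ca_only_helix(12))
  expect_equal(nrow(h), 1)
  expect_equal(h$start, 1)
  expect_equal(h$end, 12)
  ax <- attr(h, "axes")
  expect_equal(abs(ax[1, 3]), 1, tolerance = 0.05)  # axis along z
})

test_that("an extended chain contains no helices", {
  expect_equal(nrow(assign_helices(ca_only_extended(15))), 0)
})

test_that("helix assignment errors on missing Calpha and is deterministic", {
  s <- ca_only_helix(12)
  s$atoms$elety[5] <- "N"
  expect_error(assign_helices(s), "missing Calpha.*5")
  sol <- make_solenoid(solenoid_spec(seed = 19))
  expect_identical(assign_helices(sol$structure),
                   assign_helices(sol$structure))
})

test_that("helix boundaries on the synthetic solenoid match construction within 1 residue", {
  sol <- make_solenoid(solenoid_spec(seed = 23))
  h <- assign_helices(sol$structure)
  expect_equal(nrow(h), nrow(sol$helices))
  expect_true(all(abs(h$start - sol$helices$start) <= 1))
  expect_true(all(abs(h$end - sol$helices$end) <= 1))
})

test_that("overlapping-UBA decomposition follows the (n-1)/2 rule", {
  hel <- function(n) {
    d <- data.frame(chain = "A", start = (seq_len(n) - 1) * 14 + 1,
                    end = (seq_len(n) - 1) * 14 + 11,
                    length = 11)
    class(d) <- c("helix_segments", "data.frame")
    d
  }
  u3 <- decompose_overlapping_ubas(hel(3))
  expect_equal(nrow(u3), 1)
  u5 <- decompose_overlapping_ubas(hel(5))
  expect_equal(nrow(u5), 2)
  expect_equal(u5$h3[1], u5$h1[2])  # shared helix 3
  expect_equal(u5$h3[1], 3)
  expect_error(decompose_overlapping_ubas(hel(4)), "odd")
  expect_error(decompose_overlapping_ubas(hel(1)), "odd")
  # coverage: shared helices appear in exactly two consecutive units
  u7 <- decompose_overlapping_ubas(hel(7))
  counts <- table(c(u7$h1, u7$h2, u7$h3))
  expect_equal(as.integer(counts[as.character(c(3, 5))]), c(2L, 2L))
  expect_true(all(counts[as.character(c(1, 2, 4, 6, 7))] == 1))
})

test_that("signature-motif scan finds canonical and KGF variants", {
  expect_equal(scan_signature_motifs("MGF"),
               data.frame(position = 1L, motif = "MGF"))
  expect_equal(scan_signature_motifs("AAKGFAA"),
               data.frame(position = 3L, motif = "KGF"))
  hits <- scan_signature_motifs("MGFLGYKGF")
  expect_equal(hits$position, c(1L, 4L, 7L))
  expect_equal(hits$motif, c("MGF", "LGY", "KGF"))
  expect_equal(nrow(scan_signature_motifs("AAAA")), 0)
  expect_error(scan_signature_motifs("MGXF"), "position 3")
})

test_that("FASTA sequences round-trip into the motif scanner", {
  tmp <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">toy", "AAMGFAAKGFAA"), tmp)
  seqs <- read_fasta_sequences(tmp)
  expect_named(seqs, "toy")
  expect_equal(scan_signature_motifs(seqs[[1]])$position, c(3L, 8L))
})

test_that("chain_sequence reads back the generated sequence", {
  sol <- make_solenoid(solenoid_spec(seed = 31))
  expect_equal(chain_sequence(sol$structure, "A"), sol$sequence)
})
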