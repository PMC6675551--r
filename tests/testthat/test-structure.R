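toy_pdb_lines <- function() {
  c("HEADER    TOY",
    "ATOM      1  N   ALA C   1      11.104   6.134  -6.504  1.00  0.00           N",
    "ATOM      2  CA  ALA C   1      11.639   6.071  -5.147  1.00  0.00           C",
    "TER",
    "END")
}

test_that("PDB reading parses coordinates, keeps MODEL 1, reports bad lines", {
  path <- withr::local_tempfile(fileext = ".pdb")
  lines <- toy_pdb_lines()
  # need both chains for the model container; add a one-atom MHC chain
  lines <- append(lines,
                  "ATOM      3  CA  GLY A   1       0.000   0.000   0.000  1.00  0.00           C",
                  after = 3)
  writeLines(lines, path)
  m <- read_pdb_model(path, peptide_chain = "C", mhc_chain = "A")
  expect_equal(nrow(m$atoms), 3)
  expect_equal(m$atoms$x[1], 11.104)
  expect_equal(m$atoms$name[1:2], c("N", "CA"))

  # multi-model: only MODEL 1 atoms are used
  path2 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("MODEL     1", lines[2:4], "ENDMDL",
               "MODEL     2", sub("11.104", "99.999", lines[2]), lines[3:4],
               "ENDMDL", "END"), path2)
  m2 <- read_pdb_model(path2, peptide_chain = "C", mhc_chain = "A")
  expect_equal(nrow(m2$atoms), 3)
  expect_equal(m2$atoms$x[1], 11.104)

  # malformed ATOM record: error naming the line
  path3 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(lines[1:2], "ATOM garbage", lines[3:4]), path3)
  expect_error(read_pdb_model(path3, "C", "A"), "line 3")
})

test_that("peptide RMSD is zero for self and for rigid motions, d/sqrt(N) for one displaced atom", {
  tm <- gen_toy_pmhc("TGAARFDEF", sim_config(seed = 5))
  self <- peptide_rmsd(tm$reference, tm$reference, "backbone")
  expect_equal(self$rmsd, 0)

  # perturbed copy is a rigid motion of the whole complex
  rigid <- peptide_rmsd(tm$reference, tm$perturbed, "common_heavy")
  expect_equal(rigid$rmsd, 0, tolerance = 1e-8)

  d <- 2.5
  tm2 <- gen_toy_pmhc("TGAARFDEF",
                      sim_config(seed = 5, structure = list(displacement = d)))
  r <- peptide_rmsd(tm2$reference, tm2$perturbed, "backbone")
  expect_equal(r$rmsd, d / sqrt(r$n_atoms), tolerance = 1e-8)
  # symmetric in its arguments
  r_swap <- peptide_rmsd(tm2$perturbed, tm2$reference, "backbone")
  expect_equal(r_swap$rmsd, r$rmsd, tolerance = 1e-8)

  short <- gen_toy_pmhc("TGAARFDE", sim_config(seed = 5))
  expect_error(peptide_rmsd(tm$reference, short$reference), "length mismatch")
})

test_that("Shrake-Rupley SASA matches analytic spheres and converges", {
  one <- data.frame(x = 0, y = 0, z = 0, radius = 1.7)
  analytic <- 4 * pi * (1.7 + 1.4)^2
  expect_equal(sasa(one, n_points = 960), analytic, tolerance = 1e-6)
  # convergence: doubling the point count moves the area by < 1%
  a1 <- sasa(one, n_points = 480)
  a2 <- sasa(one, n_points = 960)
  expect_lt(abs(a2 - a1) / a2, 0.01)

  two_same <- data.frame(x = c(0, 0), y = c(0, 0), z = c(0, 0),
                         radius = c(1.7, 1.7))
  expect_equal(sum(sasa(two_same, n_points = 960)), analytic,
               tolerance = 0.02 * analytic)

  two_far <- data.frame(x = c(0, 100), y = c(0, 0), z = c(0, 0),
                        radius = c(1.7, 1.7))
  expect_equal(sum(sasa(two_far, n_points = 960)), 2 * analytic,
               tolerance = 1e-6)
  expect_error(sasa(one, n_points = 50), "at least 100")
})

test_that("hydrophobic exposed area is bounded by peptide total and vanishes when buried", {
  tm <- gen_toy_pmhc("TGAARFDEF", sim_config(seed = 8))
  rep <- sasa_report(tm$reference, n_points = 240)
  expect_gte(rep$peptide_hydrophobic, 0)
  expect_lte(rep$peptide_hydrophobic, rep$peptide_total)

  # a peptide tightly caged by large occluders has ~zero exposed surface
  pep <- tm$reference$atoms[tm$reference$atoms$chain == "C", , drop = FALSE]
  cage_pts <- expand.grid(x = seq(-5, 36, by = 3), y = seq(-6, 12, by = 3),
                          z = seq(-6, 8, by = 3))
  keep <- apply(cage_pts, 1, function(p) {
    min(sqrt((pep$x - p[1])^2 + (pep$y - p[2])^2 + (pep$z - p[3])^2)) > 2.5
  })
  cage <- data.frame(name = "CA", element = "C", resid = "GLY",
                     resno = seq_len(sum(keep)) + 100, chain = "A",
                     x = cage_pts$x[keep], y = cage_pts$y[keep],
                     z = cage_pts$z[keep])
  buried <- pmhc_model(rbind(pep[, names(cage)], cage), "C", "A")
  rep2 <- sasa_report(buried, n_points = 240)
  expect_lt(rep2$peptide_total, 0.05 * rep$peptide_total)
})

test_that("relative surface change reproduces simple arithmetic", {
  expect_equal(relative_change(100, 125), 0.25)
  expect_equal(relative_change(200, 100), -0.5)
  expect_error(relative_change(0, 10), "positive")
})

salt_bridge_model <- function(d, two_n = FALSE) {
  atoms <- data.frame(
    name = c("NH1", if (two_n) "NH2", "OD1", "CA"),
    element = c("N", if (two_n) "N", "O", "C"),
    resid = c("ARG", if (two_n) "ARG", "ASP", "GLY"),
    resno = c(5L, if (two_n) 5L, 77L, 1L),
    chain = c("C", if (two_n) "C", "A", "A"),
    x = c(0, if (two_n) 0.5, d, 20),
    y = 0, z = 0, stringsAsFactors = FALSE
  )
  pmhc_model(atoms, "C", "A")
}

test_that("salt bridges are detected under the cutoff with per-pair deduplication", {
  hit <- detect_salt_bridges(salt_bridge_model(3.5))
  expect_equal(nrow(hit), 1)
  expect_equal(hit$basic_resid, "ARG")
  expect_equal(hit$acidic_resno, 77L)
  expect_equal(hit$distance, 3.5)

  expect_equal(nrow(detect_salt_bridges(salt_bridge_model(5.0))), 0)

  # both guanidinium nitrogens in range: one record at the minimum distance
  dup <- detect_salt_bridges(salt_bridge_model(3.5, two_n = TRUE))
  expect_equal(nrow(dup), 1)
  expect_equal(dup$distance, 3.0)
})

test_that("the salt-bridge list is invariant under global rigid motion", {
  m <- salt_bridge_model(3.5, two_n = TRUE)
  th <- 1.1
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  xyz <- t(R %*% t(as.matrix(m$atoms[, c("x", "y", "z")]))) +
    matrix(c(7, -4, 2), nrow(m$atoms), 3, byrow = TRUE)
  m2 <- m
  m2$atoms$x <- xyz[, 1]
  m2$atoms$y <- xyz[, 2]
  m2$atoms$z <- xyz[, 3]
  a <- detect_salt_bridges(m)
  b <- detect_salt_bridges(m2)
  expect_equal(a$distance, b$distance, tolerance = 1e-9)
  expect_equal(a[, 1:6], b[, 1:6])
})
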