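toy_atoms <- function(xyz, element = "C", chain = "A") {
  n <- nrow(xyz)
  data.frame(chain = rep_len(chain, n), resno = seq_len(n), resid = "GLY",
             elety = "CA", element = rep_len(element, n),
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             stringsAsFactors = FALSE)
}

test_that("PDB reading round-trips a tiny hand-written file", {
  tmp <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  GLY A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  GLY A   2       3.500   0.000   0.000  1.00  0.00           C",
    "END"), tmp)
  m <- read_structure(tmp)
  expect_equal(nrow(m$atoms), 2)
  expect_equal(m$atoms$x, c(0, 3.5))
  expect_equal(m$atoms$element, c("C", "C"))
  expect_error(read_structure("no/such/file.pdb"), "cannot read")
})

test_that("contact detection honours the distance threshold exactly", {
  xyz <- rbind(c(0, 0, 0), c(3.9, 0, 0))
  m <- structure_model(rbind(toy_atoms(xyz[1, , drop = FALSE], chain = "A"),
                             toy_atoms(xyz[2, , drop = FALSE], chain = "B")))
  expect_equal(nrow(contact_map(m, "A", "B", 4)), 1)
  xyz2 <- rbind(c(0, 0, 0), c(4.1, 0, 0))
  m2 <- structure_model(rbind(toy_atoms(xyz2[1, , drop = FALSE], chain = "A"),
                              toy_atoms(xyz2[2, , drop = FALSE], chain = "B")))
  expect_equal(nrow(contact_map(m2, "A", "B", 4)), 0)
  expect_error(contact_map(m, "A", "A", 4), "disjoint")
  expect_error(contact_map(m, "A", "Z", 4), "empty")
})

test_that("grid-accelerated contacts equal brute force on a random cloud", {
  set.seed(3)
  xyz <- matrix(runif(500 * 3, 0, 30), ncol = 3)
  at <- rbind(toy_atoms(xyz[1:250, ], chain = "A"),
              toy_atoms(xyz[251:500, ], chain = "B"))
  at$resno <- seq_len(nrow(at))
  m <- structure_model(at)
  g <- contact_map(m, "A", "B", 4, method = "grid")
  b <- contact_map(m, "A", "B", 4, method = "brute")
  expect_equal(g, b)
  expect_gt(nrow(g), 0)
  # cutoff monotonicity
  g3 <- contact_map(m, "A", "B", 3, method = "grid")
  key <- function(d) paste(d$resno_a, d$resno_b)
  expect_true(all(key(g3) %in% key(g)))
})

test_that("SASA matches the analytic sphere and behaves additively", {
  one <- toy_atoms(matrix(c(0, 0, 0), 1), element = "O")
  expect_equal(sasa(one, probe = 1.4), 4 * pi * (1.52 + 1.4)^2,
               tolerance = 1e-9)
  # two fully separated atoms: additive
  two <- toy_atoms(rbind(c(0, 0, 0), c(50, 0, 0)), element = "C")
  expect_equal(sum(sasa(two)), 2 * 4 * pi * (1.7 + 1.4)^2, tolerance = 1e-9)
  # an atom enclosed by a dense cubic shell is fully buried
  shell <- as.matrix(expand.grid(x = c(-2, 0, 2), y = c(-2, 0, 2),
                                 z = c(-2, 0, 2)))
  shell <- shell[rowSums(abs(shell)) > 0, ]
  at <- toy_atoms(rbind(c(0, 0, 0), shell), element = "C")
  a <- sasa(at)
  expect_equal(a[1], 0, tolerance = 1e-9)
  expect_error(sasa(toy_atoms(matrix(0, 1, 3), element = "XX")), "radius")
})

test_that("SASA quadrature converges under point doubling", {
  m <- gen_toy_complex(d = 51)
  sub <- m$atoms[m$atoms$chain %in% c("A", "E"), ]
  s1 <- sum(sasa(sub, n_points = 480))
  s2 <- sum(sasa(sub, n_points = 960))
  expect_lt(abs(s1 - s2) / s2, 0.01)
})

test_that("interface area is zero for separated groups and rigid-motion invariant", {
  far <- rbind(toy_atoms(matrix(c(0, 0, 0), 1), chain = "A"),
               toy_atoms(matrix(c(60, 0, 0), 1), chain = "B"))
  m_far <- structure_model(far)
  ia0 <- interface_area(m_far, "A", "B")
  expect_equal(ia0$bsa_total, 0, tolerance = 1e-9)

  m <- gen_toy_complex(d = 51)
  ia <- interface_area(m, "A", c("E", "F"))
  expect_gt(ia$bsa_total, 0)
  m_rot <- transform_model(m, seed = 7)
  ia_rot <- interface_area(m_rot, "A", c("E", "F"))
  expect_equal(ia_rot$bsa_total, ia$bsa_total, tolerance = 0.02)
  # per-chain shares sum to one on the buried side
  expect_equal(sum(ia$share_sideB), 1, tolerance = 1e-9)
})

test_that("anchor distances resolve unique atoms and round-trip the generator", {
  m <- gen_toy_complex(d = 40)
  expect_equal(anchor_distance(m, list(chain = "E", resno = 217),
                               list(chain = "I", resno = 217)), 40,
               tolerance = 1e-9)
  d_adj <- anchor_distance(m, list(chain = "E", resno = 217),
                           list(chain = "G", resno = 217))
  expect_false(isTRUE(all.equal(d_adj, 40)))
  expect_equal(anchor_distance(m, list(chain = "E", resno = 217),
                               list(chain = "E", resno = 217)), 0)
  expect_error(anchor_distance(m, list(chain = "E", resno = 999),
                               list(chain = "I", resno = 217)), "resolves")
})

test_that("bound-Fab counting uses the 4 A contact rule", {
  m <- gen_toy_complex(d = 51)
  expect_equal(count_bound_fabs(m), 4L)
  # pull one Fab far away: count drops
  far <- m
  move <- far$atoms$chain %in% c("E", "F")
  far$atoms$z[move] <- far$atoms$z[move] + 100
  expect_equal(count_bound_fabs(far), 3L)
  expect_error(count_bound_fabs(structure_model(m$atoms)), "role")
})

test_that("Kabsch RMSD is invariant under rigid motion and matches closed forms", {
  set.seed(5)
  X <- matrix(rnorm(36), 12, 3)
  expect_equal(kabsch_rmsd(X, X), 0, tolerance = 1e-12)
  Y <- rigid_motion(X, seed = 9)
  expect_lt(kabsch_rmsd(X, Y), 1e-6)
  # 3-point closed form: collinear stretch, optimal rotation is identity
  A <- rbind(c(-1, 0, 0), c(1, 0, 0), c(0, 0, 0))
  B <- rbind(c(-2, 0, 0), c(2, 0, 0), c(0, 0, 0))
  expect_equal(kabsch_rmsd(A, B), sqrt(2 / 3), tolerance = 1e-12)
  expect_error(kabsch_rmsd(X, X[1:5, ]), "equal-size")
})

test_that("Kabsch RMSD agrees with an independent superposition implementation", {
  set.seed(8)
  X <- matrix(rnorm(60), 20, 3)
  Y <- rigid_motion(X, seed = 2) + matrix(rnorm(60, sd = 0.3), 20, 3)
  ours <- kabsch_rmsd(X, Y)
  ref <- bio3d::rmsd(as.vector(t(X)), as.vector(t(Y)), fit = TRUE)
  expect_equal(ours, ref, tolerance = 1e-3)
})

test_that("main-chain extraction orders atoms by residue", {
  m <- gen_toy_complex(d = 51)
  xyz <- main_chain_coords(m, "A", atoms = "CA")
  expect_equal(nrow(xyz), sum(m$atoms$chain == "A"))
  expect_equal(kabsch_rmsd(xyz, xyz), 0)
})
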