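test_that("the synthetic cubane parses to 4 Fe and 4 inorganic S plus cysteines", {
  atoms <- parse_structure(synthetic_cubane_pdb())
  cl <- atoms[atoms$resid == "SF4", ]
  expect_equal(sum(cl$element == "FE"), 4L)
  expect_equal(sum(cl$element == "S"), 4L)
  expect_equal(sum(atoms$resid == "CYS" & atoms$name == "SG"), 4L)
})

test_that("altLoc records resolve to the highest occupancy and empty files error", {
  lines <- c(
    "ATOM      1  CA AALA A   1       0.000   0.000   0.000  0.60  0.00           C",
    "ATOM      2  CA BALA A   1       5.000   0.000   0.000  0.40  0.00           C",
    "END")
  atoms <- parse_structure(lines)
  expect_equal(nrow(atoms), 1L)
  expect_equal(atoms$x, 0)
  expect_error(parse_structure(c("HEADER    EMPTY", "END")))
})

test_that("the idealized cubane yields 12 core + 4 thiolate bonds of 2.30 A", {
  # bond tolerances reflect the 3-decimal coordinate precision of PDB
  geom <- extract_cluster(parse_structure(synthetic_cubane_pdb(2.30)))
  expect_equal(sum(geom$bonds$class == "core"), 12L)
  expect_equal(sum(geom$bonds$class == "thiolate"), 4L)
  expect_equal(mean(geom$bonds$length), 2.30, tolerance = 1e-3)
  s <- geom$summary
  expect_equal(s$mean[s$class == "core"], 2.30, tolerance = 1e-3)
  expect_equal(s$mean[s$class == "thiolate"], 2.30, tolerance = 1e-3)
})

test_that("a cutoff below the construction length finds no bonds and warns", {
  atoms <- parse_structure(synthetic_cubane_pdb(2.30))
  expect_warning(geom <- extract_cluster(atoms, bond_cutoff = 2.0),
                 "malformed cubane")
  expect_equal(nrow(geom$bonds), 0L)
})

test_that("displacing one Fe along a bond lengthens exactly that bond", {
  # Fe1 sits at the origin with a core S at (2.30, 0, 0); moving Fe1 by
  # -0.15 x extends that pair to 2.45 (recomputed directly)
  geom <- extract_cluster(parse_structure(
    synthetic_cubane_pdb(2.30, displace_fe = c(-0.15, 0, 0))))
  core <- geom$bonds[geom$bonds$class == "core", ]
  moved <- core[core$fe == "FE1" & core$partner == "S1", ]
  expect_equal(moved$length, 2.45, tolerance = 1e-3)
  untouched <- core[core$fe != "FE1", ]
  expect_equal(untouched$length, rep(2.30, nrow(untouched)),
               tolerance = 1e-3)
})

test_that("cluster geometry is invariant under rotation and translation", {
  atoms <- parse_structure(synthetic_cubane_pdb(2.30))
  theta <- 0.7; phi <- 1.1
  Rz <- matrix(c(cos(theta), -sin(theta), 0,
                 sin(theta), cos(theta), 0, 0, 0, 1), 3, 3)
  Rx <- matrix(c(1, 0, 0, 0, cos(phi), -sin(phi),
                 0, sin(phi), cos(phi)), 3, 3)
  xyz <- as.matrix(atoms[, c("x", "y", "z")]) %*% t(Rz %*% Rx)
  moved <- atoms
  moved[, c("x", "y", "z")] <- sweep(xyz, 2, c(11, -4, 3.5), "+")
  g0 <- extract_cluster(atoms)
  g1 <- extract_cluster(moved)
  expect_equal(sort(g1$bonds$length), sort(g0$bonds$length),
               tolerance = 1e-9)
})

test_that("atomic distances respect the triangle inequality", {
  atoms <- parse_structure(synthetic_complex_pdb())
  set.seed(13)
  for (i in 1:25) {
    tri <- atoms[sample(nrow(atoms), 3), ]
    d12 <- sqrt(sum((tri[1, c("x", "y", "z")] - tri[2, c("x", "y", "z")])^2))
    d23 <- sqrt(sum((tri[2, c("x", "y", "z")] - tri[3, c("x", "y", "z")])^2))
    d13 <- sqrt(sum((tri[1, c("x", "y", "z")] - tri[3, c("x", "y", "z")])^2))
    expect_lte(d13, d12 + d23 + 1e-12)
  }
})

test_that("protein-DNA distances follow the donor/acceptor rule and cardinality", {
  # 3-4-5 check: one backbone N donor at the origin, one P at (3, 4, 0)
  lines <- c(
    "ATOM      1  N   GLY A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  P    DA B   1       3.000   4.000   0.000  1.00  0.00           P",
    "END")
  ds <- protein_dna_distances(parse_structure(lines), n_shortest = 1)
  expect_equal(ds$pairs$distance, 5.0, tolerance = 1e-9)

  atoms <- parse_structure(synthetic_complex_pdb(closest = 7.5))
  # 13 donors (5 backbone N + 8 cluster atoms) x 10 acceptors = 130 pairs
  ds50 <- protein_dna_distances(atoms, n_shortest = 50)
  expect_equal(nrow(ds50$pairs), 50L)
  expect_false(is.unsorted(ds50$pairs$distance))
  expect_equal(min(ds50$pairs$distance), 7.5, tolerance = 1e-6)
  expect_error(protein_dna_distances(atoms, n_shortest = 200), "exceeds")

  no_dna <- parse_structure(synthetic_cubane_pdb())
  expect_error(protein_dna_distances(no_dna), "nucleic")
})

test_that("distance histograms conserve counts and bin as expected", {
  h1 <- distance_histogram(rep(5, 50), bin_width = 1)
  expect_equal(sum(h1$table$count), 50L)
  expect_equal(sum(h1$table$count > 0), 1L)

  set.seed(21)
  d <- runif(500, 7, 16)
  h <- distance_histogram(d, bin_width = 1)
  expect_equal(sum(h$table$count), 500L)
  expect_equal(sum(h$table$count > 0), 9L)
  expect_equal(h$summary$n, 500L)
  expect_error(distance_histogram(numeric(0)), "empty")
  expect_error(distance_histogram(d, bin_width = 0), "bin_width")
})
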