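toy_pdb <- function() system.file("extdata", "toy_contacts.pdb",
                                  package = "manbatools")

test_that("PDB reading separates residues and ligands", {
  s <- read_structure(toy_pdb())
  expect_identical(sort(unique(s$atoms$resno)), c(100L, 455L, 505L, 641L, 709L))
  expect_identical(nrow(s$atoms), 20L)
  expect_identical(nrow(s$ligands), 1L)   # one HETATM mannose atom
  empty <- tempfile(fileext = ".pdb")
  file.create(empty)
  expect_error(read_structure(empty), "empty")
  expect_error(read_structure(tempfile(fileext = ".pdb")), "not found")
})

test_that("minimum residue distance matches hand geometry and the oracle", {
  s345 <- point_structure(rbind(c(0, 0, 0), c(3, 4, 0)), resno = c(1L, 2L))
  expect_equal(min_residue_distance(s345, 1, 2), 5.0)
  expect_equal(min_residue_distance(s345, 1, 1), 0.0)
  expect_error(min_residue_distance(s345, 1, 99), "99")
  # multi-atom residues against the exhaustive all-pairs oracle
  set.seed(31)
  for (k in 1:25) {
    n_res <- sample(3:6, 1)
    atoms <- do.call(rbind, lapply(seq_len(n_res), function(r) {
      n_at <- sample(1:4, 1)
      data.frame(resno = r, resid = "ALA",
                 elety = paste0("C", seq_len(n_at)), elesy = "C",
                 x = stats::rnorm(n_at, 5 * r), y = stats::rnorm(n_at),
                 z = stats::rnorm(n_at), stringsAsFactors = FALSE)
    }))
    s <- structure_model(atoms)
    i <- sample(n_res, 1); j <- sample(n_res, 1)
    expect_equal(min_residue_distance(s, i, j),
                 brute_force_min_distance(s, i, j), tolerance = 1e-12)
    # symmetry
    expect_equal(min_residue_distance(s, i, j), min_residue_distance(s, j, i))
  }
  # triangle inequality on single-atom residues
  set.seed(32)
  for (k in 1:20) {
    s3 <- point_structure(matrix(stats::rnorm(9, sd = 10), 3, 3))
    d12 <- min_residue_distance(s3, 1, 2)
    d13 <- min_residue_distance(s3, 1, 3)
    d23 <- min_residue_distance(s3, 2, 3)
    expect_lte(d13, d12 + d23 + 1e-12)
  }
})

test_that("active-site distance takes the minimum with lowest-residue ties", {
  as_def <- active_site_definition(catalytic = c(10L, 20L),
                                   binding = c(30L))
  coords <- rbind(c(0, 0, 0),    # residue 5: the query
                  c(2, 0, 0),    # residue 10: 2 A away
                  c(20, 0, 0),   # residue 20
                  c(30, 0, 0))   # residue 30
  s <- point_structure(coords, resno = c(5L, 10L, 20L, 30L))
  d <- distance_to_active_site(s, 5, as_def)
  expect_equal(d$distance_A, 2.0)
  expect_identical(d$nearest, 10L)
  # an active-site residue itself is at distance zero
  d0 <- distance_to_active_site(s, 20, as_def)
  expect_equal(d0$distance_A, 0.0)
  # ties break towards the lower residue number
  tie <- point_structure(rbind(c(0, 0, 0), c(3, 0, 0), c(-3, 0, 0)),
                         resno = c(5L, 10L, 20L))
  dt <- distance_to_active_site(tie, 5, active_site_definition(
    catalytic = c(10L, 20L), binding = integer()))
  expect_identical(dt$nearest, 10L)
  # no active-site member in the model
  expect_error(distance_to_active_site(s, 5, active_site_definition(
    catalytic = 999L, binding = integer())), "no active-site")
  # consistency with per-member distances
  expect_lte(d$distance_A, min_residue_distance(s, 5, 30))
})

test_that("proximity classification is boundary-inclusive", {
  expect_identical(proximity_class(0, 8), "close")
  expect_identical(proximity_class(8, 8), "close")
  expect_identical(proximity_class(8.0001, 8), "away")
  expect_identical(proximity_class(25, 8), "away")
  expect_error(proximity_class(-1, 8), "non-negative")
})

test_that("contact detection applies the distance-only criteria", {
  s <- read_structure(toy_pdb())
  sb <- detect_contacts(s, 641, 709)
  expect_true("salt_bridge" %in% sb$classes)   # NH1-OD1 at 3.2 A
  hb <- detect_contacts(s, 505, 455)
  expect_true("hbond_candidate" %in% hb$classes)  # OG-OD1 at 2.9 A
  expect_false("salt_bridge" %in% hb$classes)     # no basic/acidic pair
  none <- detect_contacts(s, 641, 100)
  expect_identical(none$classes, "none")          # ~50 A apart
  # glycine-like residue without side-chain atoms warns and yields none
  gly <- structure_model(data.frame(
    resno = c(1L, 1L, 2L, 2L), resid = "GLY",
    elety = c("N", "CA", "N", "CA"), elesy = c("N", "C", "N", "C"),
    x = c(0, 1, 3, 4), y = 0, z = 0, stringsAsFactors = FALSE))
  expect_warning(cr <- detect_contacts(gly, 1, 2), "side-chain")
  expect_identical(cr$classes, "none")
})

test_that("distances and contacts are rigid-body invariant", {
  s <- read_structure(toy_pdb())
  set.seed(17)
  for (k in 1:5) {
    s2 <- transform_structure(s, random_rotation(), stats::rnorm(3, sd = 50))
    expect_equal(min_residue_distance(s2, 641, 709),
                 min_residue_distance(s, 641, 709), tolerance = 1e-9)
    expect_identical(detect_contacts(s2, 641, 709)$classes,
                     detect_contacts(s, 641, 709)$classes)
    expect_identical(detect_contacts(s2, 505, 455)$classes,
                     detect_contacts(s, 505, 455)$classes)
  }
})

test_that("synthetic structures survive a PDB round trip", {
  sp <- synthetic_spec(seed = 12, n_residues = 40, signal_len = 17,
                       active_site_positions = c(20L, 21L, 25L))
  tp <- generate_transcript(sp)
  s <- generate_structure(sp, tp$protein)
  path <- tempfile(fileext = ".pdb")
  write_structure_pdb(s, path)
  s2 <- read_structure(path)
  expect_identical(length(unique(s2$atoms$resno)), 40L)
  # PDB columns carry 3 decimals; distances survive to that precision
  expect_equal(min_residue_distance(s2, 1, 40),
               min_residue_distance(s, 1, 40), tolerance = 1e-2)
})
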