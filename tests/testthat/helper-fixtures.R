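# Fixture builders shared across the test files. Everything is constructed in
# code; file-format fixtures are written as text into tempdir().

toy_structure <- function(coords, elements, bonds = NULL, charges = NULL,
                          role = "ligand") {
  coords <- as.matrix(coords)
  if (is.null(charges)) charges <- rep(0.01, nrow(coords))
  atoms <- data.frame(element = elements, x = coords[, 1], y = coords[, 2],
                      z = coords[, 3], charge = charges, role = role,
                      atom_index = seq_len(nrow(coords)) - 1L)
  pose_structure(atoms, bonds)
}

# benzene with explicit hydrogens; aromatic ring bonds
benzene_structure <- function() {
  r <- 1.4 / (2 * sin(pi / 6))
  ang <- seq(0, 2 * pi, length.out = 7)[-7]
  cring <- cbind(r * cos(ang), r * sin(ang), 0)
  hring <- cbind((r + 1.09) * cos(ang), (r + 1.09) * sin(ang), 0)
  bonds <- rbind(
    data.frame(i = 0:5, j = c(1:5, 0L), order = "ar"),
    data.frame(i = 0:5, j = 6:11, order = "1")
  )
  toy_structure(rbind(cring, hring), c(rep("C", 6), rep("H", 6)), bonds,
                charges = c(rep(-0.1, 6), rep(0.1, 6)))
}

toy_pose <- function(st, entity = "tst", rank = 1L, ...) {
  pose_entry(entity, rank, st, ...)
}

# a random featurized instance (coordinates + plausible feature block) for
# graph/backbone property tests; no chemistry needed
random_instance <- function(n = 20L, spread = 4.0) {
  coords <- matrix(stats::rnorm(3 * n, sd = spread), n, 3)
  feats <- cbind(
    t(stats::rmultinom(n, 1, c(.02, .6, .12, .12, .02, .08, .02, .01, .01))),
    sample(0:3, n, TRUE), sample(0:4, n, TRUE), sample(0:2, n, TRUE),
    matrix(stats::rbinom(5 * n, 1, 0.3), n, 5),
    stats::rnorm(n, 0, 0.2), stats::runif(n, 1.4, 2.0)
  )
  role <- sample(c("protein", "ligand"), n, TRUE)
  lig <- which(role == "ligand")
  if (!length(lig)) { role[1] <- "ligand"; lig <- 1L }
  coords <- sweep(coords, 2, colMeans(coords[lig, , drop = FALSE]))
  structure(list(coords = coords, features = feats, role = role,
                 entity_id = "rnd", pose_rank = 1L, charge_model = "file"),
            class = "featurized_instance")
}

# small text fixtures in standard formats
write_format_fixtures <- function(dir = tempfile("fmt")) {
  dir.create(dir, showWarnings = FALSE)
  writeLines(c(
    "ethanol", "  fixture", "",
    "  9  8  0  0  0  0  0  0  0  0999 V2000",
    "   -0.8876    0.1696    0.0181 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    0.4672   -0.5043    0.0181 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    1.5225    0.4617    0.0181 O   0  0  0  0  0  0  0  0  0  0  0  0",
    "   -1.6881   -0.5725    0.0181 H   0  0  0  0  0  0  0  0  0  0  0  0",
    "   -0.9756    0.7922    0.9092 H   0  0  0  0  0  0  0  0  0  0  0  0",
    "   -0.9756    0.7922   -0.8730 H   0  0  0  0  0  0  0  0  0  0  0  0",
    "    0.5536   -1.1340    0.9041 H   0  0  0  0  0  0  0  0  0  0  0  0",
    "    0.5536   -1.1340   -0.8679 H   0  0  0  0  0  0  0  0  0  0  0  0",
    "    2.3842   -0.0166    0.0181 H   0  0  0  0  0  0  0  0  0  0  0  0",
    "  1  2  1  0  0  0  0", "  1  4  1  0  0  0  0", "  1  5  1  0  0  0  0",
    "  1  6  1  0  0  0  0", "  2  3  1  0  0  0  0", "  2  7  1  0  0  0  0",
    "  2  8  1  0  0  0  0", "  3  9  1  0  0  0  0",
    "M  END", "$$$$"), file.path(dir, "ethanol.sdf"))
  writeLines(c(
    "@<TRIPOS>MOLECULE", "waterA", " 3 2 0 0 0", "SMALL", "USER_CHARGES",
    "@<TRIPOS>ATOM",
    "      1 O1    0.0000  0.0000  0.0000 O.3   1 HOH1  -0.4100",
    "      2 H1    0.9572  0.0000  0.0000 H     1 HOH1   0.2050",
    "      3 H2   -0.2400  0.9270  0.0000 H     1 HOH1   0.2050",
    "@<TRIPOS>BOND", "     1    1    2   1", "     2    1    3   1",
    "@<TRIPOS>MOLECULE", "waterB", " 3 2 0 0 0", "SMALL", "USER_CHARGES",
    "@<TRIPOS>ATOM",
    "      1 O1    1.0000  0.0000  0.0000 O.3   1 HOH1  -0.4100",
    "      2 H1    1.9572  0.0000  0.0000 H     1 HOH1   0.2050",
    "      3 H2    0.7600  0.9270  0.0000 H     1 HOH1   0.2050",
    "@<TRIPOS>BOND", "     1    1    2   1", "     2    1    3   1"),
    file.path(dir, "two_waters.mol2"))
  writeLines(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       2.009   1.420   0.000  1.00  0.00           C",
    "ATOM      4  O   ALA A   1       1.251   2.390   0.000  1.00  0.00           O",
    "END"), file.path(dir, "mini.pdb"))
  writeLines("REMARK empty", file.path(dir, "empty.pdb"))
  dir
}

# a tiny complete dataset for pipeline-level tests
tiny_dataset <- function(n = 8L, seed = 11L, ...) {
  generate_dataset(synthetic_spec(n_entities = n, seed = seed,
                                  test_fraction = 0.25, ...))
}
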