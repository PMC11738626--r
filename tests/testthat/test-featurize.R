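# 19-dimensional atom featurization and pocket truncation.

test_that("feature vector matches independent perception on aromatic/polar fixtures", {
  # expectations verified against a cheminformatics toolkit on the same
  # molecules: aromatic ring carbon is sp2, in-ring, hydrophobic, 2 heavy
  # neighbors; hydroxyl O is an acceptor and donor
  bz <- benzene_structure()
  f <- poseMIL:::.atom_features(bz)
  cring <- f[1:6, ]
  expect_true(all(cring[, "el_C"] == 1))
  expect_true(all(cring[, "hybridization"] == 2))
  expect_true(all(cring[, "heavy_neighbors"] == 2))
  expect_true(all(cring[, "hetero_neighbors"] == 0))
  expect_true(all(cring[, "aromatic"] == 1))
  expect_true(all(cring[, "ring"] == 1))
  expect_true(all(cring[, "hydrophobic"] == 1))
  expect_true(all(cring[, "acceptor"] == 0))
  expect_true(all(cring[, "donor"] == 0))
  expect_true(all(cring[, "vdw_radius"] == 1.70))

  # ethanol: C(sp3, 1 heavy nb), C (2 heavy nb, 1 hetero), O (acceptor+donor)
  dir <- write_format_fixtures()
  eth <- read_structure(file.path(dir, "ethanol.sdf"), "sdf", "ligand")[[1]]
  eth$atoms$charge <- 0
  fe <- poseMIL:::.atom_features(eth)
  expect_equal(unname(fe[1, c("hybridization", "heavy_neighbors",
                              "hetero_neighbors", "hydrophobic", "ring")]),
               c(3, 1, 0, 1, 0))
  expect_equal(unname(fe[2, c("heavy_neighbors", "hetero_neighbors",
                              "hydrophobic")]), c(2, 1, 0))
  expect_equal(unname(fe[3, c("el_O", "acceptor", "donor", "aromatic")]),
               c(1, 1, 1, 0))
})

test_that("featurization centers on the ligand centroid and prunes the pocket", {
  # 2-atom ligand at (0,0,0),(2,0,0); receptor at 3, 7, 12 A from atom 1
  lig <- toy_structure(rbind(c(0, 0, 0), c(2, 0, 0)), c("C", "C"),
                       data.frame(i = 0L, j = 1L, order = "1"))
  prot <- toy_structure(rbind(c(-3, 0, 0), c(-7, 0, 0), c(-12, 0, 0)),
                        c("N", "O", "C"), role = "protein")
  fi <- featurize_complex(prot, toy_pose(lig), pocket_radius = 8)
  expect_equal(sum(fi$role == "protein"), 2L)    # 12 A atom dropped
  licoords <- fi$coords[fi$role == "ligand", ]
  expect_equal(licoords, rbind(c(-1, 0, 0), c(1, 0, 0)),
               ignore_attr = TRUE)
  expect_lt(sqrt(sum(colMeans(licoords)^2)), 1e-6)
  expect_equal(ncol(fi$features), 19L)
})

test_that("featurization is invariant to global translation", {
  set.seed(21)
  ds <- tiny_dataset(2)
  bag <- ds$bags[[1]]
  fi1 <- featurize_complex(bag$protein, bag$instances[[1]])
  shift <- c(13.7, -4.2, 8.8)
  bag2 <- bag
  for (w in c("x", "y", "z")) {
    k <- match(w, c("x", "y", "z"))
    bag2$protein$atoms[[w]] <- bag2$protein$atoms[[w]] + shift[k]
    bag2$instances[[1]]$structure$atoms[[w]] <-
      bag2$instances[[1]]$structure$atoms[[w]] + shift[k]
  }
  fi2 <- featurize_complex(bag2$protein, bag2$instances[[1]])
  expect_equal(fi1$coords, fi2$coords, tolerance = 1e-12)
  expect_identical(fi1$features, fi2$features)
})

test_that("ligand centroid sits at the origin across random synthetic complexes", {
  ds <- generate_dataset(synthetic_spec(n_entities = 10, seed = 31))
  worst <- 0
  for (b in ds$bags) {
    for (inst in b$instances) {
      fi <- featurize_complex(b$protein, inst)
      cen <- colMeans(fi$coords[fi$role == "ligand", , drop = FALSE])
      worst <- max(worst, sqrt(sum(cen^2)))
      expect_equal(ncol(fi$features), 19L)
    }
  }
  expect_lt(worst, 1e-6)
})

test_that("unclassifiable elements keep an all-zero one-hot with a warning", {
  lig <- toy_structure(rbind(c(0, 0, 0), c(1.5, 0, 0)), c("C", "Si"),
                       data.frame(i = 0L, j = 1L, order = "1"))
  prot <- toy_structure(matrix(c(-3, 0, 0), 1, 3), "C", role = "protein")
  w <- capture_warnings(fi <- featurize_complex(prot, toy_pose(lig)))
  expect_match(w, "one-hot", all = FALSE)
  expect_match(w, "vdW", all = FALSE)            # Si also lacks a radius entry
  si <- fi$features[fi$role == "ligand", ][2, ]
  expect_equal(sum(si[1:9]), 0)
  expect_gt(si["vdw_radius"], 0)
})

test_that("empty ligand and disabled charge model raise errors", {
  hlig <- toy_structure(matrix(0, 1, 3), "H")
  prot <- toy_structure(matrix(c(-3, 0, 0), 1, 3), "C", role = "protein")
  expect_error(featurize_complex(prot, toy_pose(hlig)), "empty ligand")
  lig <- toy_structure(rbind(c(0, 0, 0), c(1.5, 0, 0)), c("C", "C"),
                       charges = c(NA, NA))
  expect_error(featurize_complex(prot, toy_pose(lig), charge_model = "none"),
               "charge error")
})

test_that("Gasteiger charges are computed for charge-free inputs", {
  dir <- write_format_fixtures()
  eth <- read_structure(file.path(dir, "ethanol.sdf"), "sdf", "ligand")[[1]]
  ch <- compute_gasteiger_charges(eth)
  expect_length(ch, 9L)
  expect_lt(ch[3], 0)                            # hydroxyl O negative
  expect_equal(sum(ch), 0, tolerance = 0.02)     # neutral molecule
})
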