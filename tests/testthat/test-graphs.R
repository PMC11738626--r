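# Spatial graph construction and pose RMSD.

two_atom_instance <- function(d) {
  structure(list(coords = rbind(c(-d / 2, 0, 0), c(d / 2, 0, 0)),
                 features = matrix(0, 2, 19), role = c("protein", "ligand"),
                 entity_id = "t", pose_rank = 1L, charge_model = "file"),
            class = "featurized_instance")
}

test_that("covalent/noncovalent thresholds classify pairs at 1.5/4.5 A", {
  g <- build_sgcnn_graph(two_atom_instance(1.2))
  expect_equal(nrow(g$covalent), 2L)             # stored symmetrically
  expect_equal(nrow(g$noncovalent), 0L)
  expect_equal(g$covalent$d, c(1.2, 1.2))

  g <- build_sgcnn_graph(two_atom_instance(3.0))
  expect_equal(nrow(g$covalent), 0L)
  expect_equal(nrow(g$noncovalent), 2L)

  g <- build_sgcnn_graph(two_atom_instance(5.0))
  expect_equal(nrow(g$covalent) + nrow(g$noncovalent), 0L)

  # boundary convention: cutoffs are inclusive
  expect_equal(nrow(build_sgcnn_graph(two_atom_instance(1.5))$covalent), 2L)
  expect_equal(nrow(build_sgcnn_graph(two_atom_instance(4.5))$noncovalent), 2L)
  expect_equal(nrow(build_radius_graph(two_atom_instance(5.0))$radius), 2L)
})

test_that("radius graph connects an equilateral triangle iff within cutoff", {
  tri <- structure(list(
    coords = rbind(c(0, 0, 0), c(4, 0, 0), c(2, 2 * sqrt(3), 0)),
    features = matrix(0, 3, 19), role = rep("ligand", 3),
    entity_id = "t", pose_rank = 1L, charge_model = "file"),
    class = "featurized_instance")
  g <- build_radius_graph(tri, cutoff = 5)
  expect_equal(nrow(g$radius), 6L)               # 3 pairs, both directions
  expect_equal(unique(round(g$radius$d, 10)), 4)
  expect_equal(nrow(build_radius_graph(tri, cutoff = 3.9)$radius), 0L)
})

test_that("edge sets equal a brute-force all-pairs scan on random instances", {
  set.seed(77)
  brute <- function(coords, lo, hi) {
    hits <- 0L
    for (i in seq_len(nrow(coords) - 1)) {
      for (j in (i + 1):nrow(coords)) {
        d <- sqrt(sum((coords[i, ] - coords[j, ])^2))
        if (d > lo && d <= hi) hits <- hits + 1L
      }
    }
    hits
  }
  for (rep in 1:50) {
    inst <- random_instance(n = sample(5:30, 1), spread = 3)
    gs <- build_sgcnn_graph(inst)
    gr <- build_radius_graph(inst)
    expect_identical(nrow(gs$covalent) / 2, brute(inst$coords, 0, 1.5) * 1.0)
    expect_identical(nrow(gs$noncovalent) / 2,
                     brute(inst$coords, 1.5, 4.5) * 1.0)
    expect_identical(nrow(gr$radius) / 2, brute(inst$coords, 0, 5.0) * 1.0)
    # symmetry, disjointness, distance correctness
    for (e in list(gs$covalent, gs$noncovalent, gr$radius)) {
      if (!nrow(e)) next
      key <- paste(e$i, e$j)
      rev <- paste(e$j, e$i)
      expect_setequal(key, rev)
      expect_true(all(abs(e$d - sqrt(rowSums(
        (inst$coords[e$i, , drop = FALSE] -
           inst$coords[e$j, , drop = FALSE])^2))) < 1e-6))
      expect_true(all(e$i != e$j))
    }
    expect_length(intersect(paste(gs$covalent$i, gs$covalent$j),
                            paste(gs$noncovalent$i, gs$noncovalent$j)), 0)
  }
})

test_that("the training-path lean builder matches the public builders", {
  set.seed(78)
  canon <- function(e) {
    o <- order(e$i, e$j)
    list(i = as.integer(e$i[o]), j = as.integer(e$j[o]), d = e$d[o])
  }
  for (rep in 1:10) {
    inst <- random_instance(sample(6:25, 1), spread = 3)
    lf <- poseMIL:::lean_build(inst, "sgcnn")
    gs <- poseMIL:::lean_graph(build_sgcnn_graph(inst))
    expect_equal(canon(lf$covalent), canon(gs$covalent))
    expect_equal(canon(lf$noncovalent), canon(gs$noncovalent))
    lr <- poseMIL:::lean_build(inst, "egnn")
    gr <- poseMIL:::lean_graph(build_radius_graph(inst))
    expect_equal(canon(lr$radius), canon(gr$radius))
    expect_identical(lf$X, gs$X)
  }
})

test_that("single-atom instances are rejected as degenerate", {
  one <- structure(list(coords = matrix(0, 1, 3), features = matrix(0, 1, 19),
                        role = "ligand", entity_id = "t", pose_rank = 1L,
                        charge_model = "file"),
                   class = "featurized_instance")
  expect_error(build_sgcnn_graph(one), "degenerate")
  expect_error(build_radius_graph(one), "degenerate")
})

test_that("pose RMSD follows closed-form displacement cases", {
  st <- toy_structure(rbind(c(0, 0, 0), c(1.5, 0, 0), c(3, 0, 0), c(4.5, 0, 0)),
                      rep("C", 4))
  p1 <- toy_pose(st)
  expect_equal(pose_rmsd(p1, p1), 0)

  shift <- st
  shift$atoms$x <- shift$atoms$x + 3
  shift$atoms$y <- shift$atoms$y + 4
  expect_equal(pose_rmsd(p1, toy_pose(shift, rank = 2L)), 5)

  # per-atom displacements of 1 A each
  unit <- st
  unit$atoms$z <- unit$atoms$z + 1
  expect_equal(pose_rmsd(p1, toy_pose(unit, rank = 3L)), 1)

  # hydrogens are excluded from the match
  sth <- toy_structure(rbind(c(0, 0, 0), c(1.5, 0, 0), c(0.5, 0.9, 0)),
                       c("C", "C", "H"))
  sth2 <- sth
  sth2$atoms$x <- sth2$atoms$x + 2
  sth2$atoms$x[3] <- sth2$atoms$x[3] + 50       # H moved arbitrarily
  expect_equal(pose_rmsd(toy_pose(sth), toy_pose(sth2, rank = 2L)), 2)

  bad <- toy_structure(matrix(0, 2, 3), c("C", "C"))
  expect_error(pose_rmsd(p1, toy_pose(bad, rank = 4L)), "matching error")
})
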