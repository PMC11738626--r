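# The synthetic complex generator: pose RMSD control, label recoverability,
# split semantics, file emission, reproducibility.

test_that("good/bad pose composition follows the requested counts", {
  ds_all <- generate_dataset(synthetic_spec(n_entities = 3, seed = 40,
                                            n_informative = 10,
                                            poses_per_entity = 10))
  expect_true(all(ds_all$truth$rmsd < 2.5))
  expect_true(all(ds_all$entities$n_good == 10L))
  groups <- vapply(split(ds_all$truth$rmsd, ds_all$truth$entity_id),
                   function(r) count_good_poses(r)$group, "")
  expect_true(all(groups == ">4"))

  ds_none <- generate_dataset(synthetic_spec(n_entities = 3, seed = 41,
                                             n_informative = 0))
  expect_true(all(ds_none$truth$rmsd >= 4.0))
  expect_true(all(vapply(split(ds_none$truth$rmsd, ds_none$truth$entity_id),
                         function(r) count_good_poses(r)$group, "") == "none"))
})

test_that("decoy construction hits the requested RMSD on the nose", {
  set.seed(42)
  for (i in 1:20) {
    st <- poseMIL:::.make_ligand_template(sample(8:20, 1))
    target <- runif(1, 0.3, 10)
    dec <- poseMIL:::.perturb_pose(st, target)
    got <- pose_rmsd(toy_pose(st), toy_pose(dec, rank = 2L))
    expect_lt(abs(got - target) / target, 0.05)  # within 5 percent (exact here)
    expect_equal(got, target, tolerance = 1e-9)
  }
  # generator-recorded RMSDs agree with the matched-order oracle
  ds <- generate_dataset(synthetic_spec(n_entities = 2, seed = 43,
                                        include_crystal = TRUE))
  for (b in ds$bags) {
    crystal <- b$instances[[1]]
    expect_true(crystal$is_crystal)
    tr <- ds$truth[ds$truth$entity_id == b$entity_id, ]
    for (inst in b$instances[-1]) {
      expect_equal(pose_rmsd(crystal, inst),
                   tr$rmsd[match(inst$pose_rank, tr$pose_rank)],
                   tolerance = 1e-9)
    }
  }
})

test_that("labels are recoverable from true-pose contacts (signal exists)", {
  ds <- generate_dataset(synthetic_spec(n_entities = 120, seed = 44,
                                        label_noise_sd = 0.1))
  fit <- stats::lm(label ~ I(contacts / n_ligand_heavy), data = ds$entities)
  expect_gte(summary(fit)$r.squared, 0.95)
})

test_that("pooled RMSD histogram is bimodal under the mixture composition", {
  ds <- generate_dataset(synthetic_spec(n_entities = 60, seed = 45,
                                        n_informative = "mixture",
                                        mixture_weights = c(0.3, 0.3, 0.4)))
  r <- ds$truth$rmsd
  h <- hist(r, breaks = seq(0, 15, 0.5), plot = FALSE)
  peak_good <- max(h$density[h$mids < 2.0])
  gap <- max(h$density[h$mids > 2.0 & h$mids < 4.0])
  peak_bad <- max(h$density[h$mids > 4.0])
  expect_gt(peak_good, gap)                       # mode inside good range
  expect_gt(peak_bad, gap)                        # mode inside bad range
})

test_that("dataset generation is reproducible and splits behave", {
  spec <- synthetic_spec(n_entities = 12, seed = 46)
  d1 <- generate_dataset(spec)
  d2 <- generate_dataset(spec)
  expect_identical(d1$entities, d2$entities)
  expect_identical(d1$truth, d2$truth)
  expect_identical(d1$split, d2$split)
  expect_length(d1$split$test, round(12 * 2 / 7))
  expect_length(intersect(d1$split$train, d1$split$test), 0L)

  # group split keeps every ligand family wholly on one side
  gspec <- synthetic_spec(n_entities = 20, seed = 47, split = "group",
                          n_families = 5L)
  dg <- generate_dataset(gspec)
  fam <- stats::setNames(dg$entities$family, dg$entities$entity_id)
  expect_length(intersect(unique(fam[dg$split$train]),
                          unique(fam[dg$split$test])), 0L)
})

test_that("written datasets are byte-stable and countable", {
  dir1 <- tempfile("gen1"); dir2 <- tempfile("gen2")
  spec <- synthetic_spec(n_entities = 4, seed = 48, poses_per_entity = 10)
  g1 <- generate_dataset(spec, dir = dir1)
  g2 <- generate_dataset(spec, dir = dir2)
  expect_identical(sub(dir1, "", readLines(g1$index_path), fixed = TRUE),
                   sub(dir2, "", readLines(g2$index_path), fixed = TRUE))
  expect_identical(readLines(g1$split_path), readLines(g2$split_path))
  expect_length(list.files(dir1, pattern = "pose.*\\.mol2$"), 40L)
  expect_length(list.files(dir1, pattern = "receptor\\.pdb$"), 4L)

  # round trip: assembled bags reproduce the generator's structure
  bags <- assemble_bags(read_bag_index(g1$index_path), g1$receptor_paths)
  expect_setequal(names(bags), names(g1$bags))
  expect_equal(vapply(bags, function(b) length(b$instances), 1L),
               vapply(g1$bags, function(b) length(b$instances), 1L)[names(bags)])
  expect_equal(unname(vapply(bags, `[[`, 1.0, "label")),
               unname(vapply(g1$bags[names(bags)], `[[`, 1.0, "label")),
               tolerance = 1e-9)
})

test_that("group split with a single family is rejected", {
  spec <- synthetic_spec(n_entities = 6, seed = 49, split = "group",
                         n_families = 1L)
  expect_error(generate_dataset(spec), "at least 2")
})
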