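# Synthetic protein-ligand entities: pose bags with controlled good/bad pose
# composition and labels that are a deterministic function of the true pose
# geometry. Chemistry realism is deliberately minimal -- point atoms with
# element labels, distance-plausible bonds and random partial charges --
# sufficient to exercise featurization, graph construction and the MIL
# training contracts end to end.

#' Specification of a synthetic dataset
#'
#' Labels are generated from the TRUE pose only:
#' `y = alpha * contacts(true)/n_ligand_heavy + beta + N(0, label_noise_sd)`,
#' where `contacts` counts protein-ligand heavy-atom pairs within 4.5
#' Angstrom. Decoy poses are perturbed copies of the true pose hitting a
#' prescribed RMSD, so only poses drawn from `good_rmsd_range` carry the
#' label signal -- the premise MIL is meant to exploit.
#'
#' @param n_entities number of protein-ligand entities.
#' @param poses_per_entity docking poses per bag.
#' @param n_informative how many poses per bag are "good": a scalar, an
#'   integer vector sampled uniformly per entity, or `"mixture"` for the
#'   all-good / all-bad / mixed composition (weights `mixture_weights`).
#' @param mixture_weights probabilities of (all-good, all-bad, mixed bag)
#'   used when `n_informative = "mixture"`; mixed bags get 1-4 good poses.
#' @param good_rmsd_range,bad_rmsd_range target RMSD intervals (Angstrom) for
#'   good and bad poses.
#' @param ligand_size_range,pocket_size_range heavy-atom count intervals.
#' @param label_noise_sd Gaussian label noise, pK units.
#' @param label_alpha,label_beta fixed constants of the label model.
#' @param include_crystal add the true pose as a crystal instance (rank 0).
#' @param split `"random"` or `"group"` (ligand template families are kept
#'   wholly on one side, the scaffold-split analog).
#' @param test_fraction fraction of entities (or families) held out.
#' @param n_families number of ligand template families.
#' @param seed RNG seed; everything is reproducible from it.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_entities = 100L, poses_per_entity = 10L,
                           n_informative = 1:3,
                           mixture_weights = c(0.3, 0.3, 0.4),
                           good_rmsd_range = c(0.3, 2.0),
                           bad_rmsd_range = c(4.0, 10.0),
                           ligand_size_range = c(8L, 24L),
                           pocket_size_range = c(30L, 80L),
                           label_noise_sd = 0.1,
                           label_alpha = 0.6, label_beta = 1.0,
                           include_crystal = FALSE,
                           split = c("random", "group"),
                           test_fraction = 2 / 7,
                           n_families = NULL, seed = 0L) {
  split <- match.arg(split)
  stopifnot(diff(good_rmsd_range) >= 0, diff(bad_rmsd_range) >= 0,
            good_rmsd_range[1] > 0,
            all(n_informative == "mixture" | n_informative <= poses_per_entity))
  if (is.null(n_families)) n_families <- max(2L, n_entities %/% 10L)
  structure(list(
    n_entities = as.integer(n_entities),
    poses_per_entity = as.integer(poses_per_entity),
    n_informative = n_informative, mixture_weights = mixture_weights,
    good_rmsd_range = good_rmsd_range, bad_rmsd_range = bad_rmsd_range,
    ligand_size_range = as.integer(ligand_size_range),
    pocket_size_range = as.integer(pocket_size_range),
    label_noise_sd = label_noise_sd,
    label_alpha = label_alpha, label_beta = label_beta,
    include_crystal = include_crystal,
    split = split, test_fraction = test_fraction,
    n_families = as.integer(n_families), seed = as.integer(seed)
  ), class = "synthetic_spec")
}

.runif_int <- function(n, range) {
  if (range[1] == range[2]) rep(range[1], n) else sample(range[1]:range[2], n, replace = TRUE)
}

.rand_unit <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

.rot_matrix <- function(axis, theta) {
  a <- axis / sqrt(sum(axis^2))
  c_ <- cos(theta); s <- sin(theta); C <- 1 - c_
  matrix(c(
    a[1]^2 * C + c_, a[1] * a[2] * C - a[3] * s, a[1] * a[3] * C + a[2] * s,
    a[2] * a[1] * C + a[3] * s, a[2]^2 * C + c_, a[2] * a[3] * C - a[1] * s,
    a[3] * a[1] * C - a[2] * s, a[3] * a[2] * C + a[1] * s, a[3]^2 * C + c_
  ), 3L, 3L, byrow = TRUE)
}

# ligand template: optional aromatic 6-ring plus a self-avoiding random walk
.make_ligand_template <- function(n_heavy) {
  coords <- matrix(numeric(), 0L, 3L)
  bonds <- data.frame(i = integer(), j = integer(), order = character())
  element <- character()
  if (n_heavy >= 10L && stats::runif(1) < 0.5) {
    ang <- seq(0, 2 * pi, length.out = 7L)[-7L]
    ring <- cbind(1.4 / (2 * sin(pi / 6)) * cos(ang),
                  1.4 / (2 * sin(pi / 6)) * sin(ang), 0)
    R <- .rot_matrix(.rand_unit(), stats::runif(1, 0, 2 * pi))
    coords <- ring %*% t(R)
    element <- rep("C", 6L)
    bonds <- data.frame(i = 0:5, j = c(1:5, 0L), order = "ar")
  }
  while (nrow(coords) < n_heavy) {
    if (nrow(coords) == 0L) {
      coords <- matrix(0, 1L, 3L)
      element <- sample(c("C", "N", "O"), 1L, prob = c(0.8, 0.1, 0.1))
      next
    }
    anchor <- sample(nrow(coords), 1L)
    placed <- FALSE
    for (try in 1:30) {
      pos <- coords[anchor, ] + .rand_unit() * 1.5
      d <- sqrt(rowSums(sweep(coords, 2L, pos)^2))
      if (all(d >= 1.1)) {
        coords <- rbind(coords, pos)
        element <- c(element, sample(c("C", "N", "O", "S"), 1L,
                                     prob = c(0.7, 0.12, 0.12, 0.06)))
        ord <- if (stats::runif(1) < 0.1) "2" else "1"
        bonds <- rbind(bonds, data.frame(i = anchor - 1L,
                                         j = nrow(coords) - 1L, order = ord))
        placed <- TRUE
        break
      }
    }
    if (!placed) next  # resample an anchor
  }
  # explicit hydrogens on some N/O so the donor bit has coverage
  n0 <- nrow(coords)
  h_at <- which(element %in% c("N", "O") & stats::runif(n0) < 0.6)
  for (a in h_at) {
    coords <- rbind(coords, coords[a, ] + .rand_unit() * 1.0)
    element <- c(element, "H")
    bonds <- rbind(bonds, data.frame(i = a - 1L, j = nrow(coords) - 1L,
                                     order = "1"))
  }
  coords <- sweep(coords, 2L, colMeans(coords[element != "H", , drop = FALSE]))
  charge <- round(stats::rnorm(nrow(coords), 0, 0.15), 4)
  charge[element == "H"] <- abs(round(stats::rnorm(sum(element == "H"), 0.1, 0.05), 4))
  atoms <- data.frame(element = element, x = coords[, 1L], y = coords[, 2L],
                      z = coords[, 3L], charge = charge, role = "ligand",
                      atom_index = seq_len(nrow(coords)) - 1L)
  pose_structure(atoms, bonds)
}

# pocket: points in a shell around the ligand, mutually >= 1.7 A apart.
# `near_frac` controls the fraction of atoms in the contact shell
# (2.6-4.2 A from the nearest ligand atom) versus the outer shell
# (4.6-6.5 A): it sets how snugly the true pose sits, so the label's
# contact count is a property of the true placement rather than of the
# pocket's size -- a decoy pose displaced out of the site cannot simply
# read it off the receptor.
.make_pocket <- function(lig_heavy_xyz, n_atoms, near_frac = 0.4) {
  rmax <- max(sqrt(rowSums(lig_heavy_xyz^2))) + 6.5
  m <- max(4000L, n_atoms * 120L)
  dirs <- matrix(stats::rnorm(3L * m), m, 3L)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  cand <- dirs * (rmax * stats::runif(m)^(1 / 3))
  dl <- sqrt(.row_min(.cross_dist2(cand, lig_heavy_xyz)))
  near_pool <- cand[dl >= 2.6 & dl <= 4.2, , drop = FALSE]
  far_pool <- cand[dl > 4.6 & dl <= 6.5, , drop = FALSE]
  n_near <- round(n_atoms * near_frac)
  coords <- matrix(numeric(), 0L, 3L)
  fill <- function(pool, want, coords) {
    for (r in seq_len(nrow(pool))) {
      if (want <= 0L) break
      pos <- pool[r, ]
      if (nrow(coords) && min(rowSums(sweep(coords, 2L, pos)^2)) < 1.7^2) next
      coords <- rbind(coords, pos)
      want <- want - 1L
    }
    coords
  }
  coords <- fill(near_pool, n_near, coords)
  coords <- fill(far_pool, n_atoms - nrow(coords), coords)
  element <- sample(c("C", "N", "O", "S"), nrow(coords), replace = TRUE,
                    prob = c(0.55, 0.15, 0.2, 0.1))
  atoms <- data.frame(element = element, x = coords[, 1L], y = coords[, 2L],
                      z = coords[, 3L],
                      charge = round(stats::rnorm(nrow(coords), 0, 0.15), 4),
                      role = "protein",
                      atom_index = seq_len(nrow(coords)) - 1L)
  pose_structure(atoms, .infer_bonds(atoms))
}

.contact_count <- function(prot_xyz, lig_xyz, cutoff = 4.5) {
  sum(.cross_dist2(prot_xyz, lig_xyz) <= cutoff^2)
}

# perturb the true pose to an exact heavy-atom RMSD: small rotation about the
# centroid plus a translation, then a global rescale of the displacement
.perturb_pose <- function(st, target_rmsd) {
  at <- st$atoms
  xyz <- as.matrix(at[, c("x", "y", "z")])
  heavy <- at$element != "H"
  ctr <- colMeans(xyz[heavy, , drop = FALSE])
  rg <- sqrt(mean(rowSums(sweep(xyz[heavy, , drop = FALSE], 2L, ctr)^2)))
  theta <- stats::runif(1, 0, min(pi, target_rmsd / max(rg, 0.5)))
  R <- .rot_matrix(.rand_unit(), theta)
  rot <- sweep(sweep(xyz, 2L, ctr) %*% t(R), 2L, ctr, "+")
  rmsd_rot <- sqrt(mean(rowSums((rot[heavy, , drop = FALSE] -
                                   xyz[heavy, , drop = FALSE])^2)))
  t_mag <- sqrt(max(target_rmsd^2 - rmsd_rot^2, 0))
  moved <- sweep(rot, 2L, .rand_unit() * t_mag, "+")
  delta <- moved - xyz
  cur <- sqrt(mean(rowSums(delta[heavy, , drop = FALSE]^2)))
  if (cur > 0) delta <- delta * (target_rmsd / cur)
  out <- st
  out$atoms$x <- xyz[, 1L] + delta[, 1L]
  out$atoms$y <- xyz[, 2L] + delta[, 2L]
  out$atoms$z <- xyz[, 3L] + delta[, 3L]
  out
}

.n_good_for_entity <- function(spec) {
  ni <- spec$n_informative
  if (identical(ni, "mixture")) {
    mode <- sample(3L, 1L, prob = spec$mixture_weights)
    switch(mode, spec$poses_per_entity, 0L, sample(1:4, 1L))
  } else if (length(ni) > 1L) {
    sample(ni, 1L)
  } else {
    as.integer(ni)
  }
}

#' Generate one synthetic entity
#'
#' Draws a ligand conformer from its template family, builds a pocket around
#' it, derives the label from the true pose's contact count, and emits
#' `poses_per_entity` decoys at prescribed RMSDs (exact by construction).
#' Docking scores are a noisy decreasing function of pose contact count, so
#' pose ranks are weakly informative, as docking ranks are in practice.
#'
#' @param spec a [synthetic_spec()].
#' @param template ligand template `pose_structure` for this entity's family.
#' @param entity_id identifier.
#' @param family integer family id.
#' @return list with the protein, the true pose, the `pose_entry` decoys (in
#'   rank order), the label, per-pose true RMSDs, and bookkeeping fields.
#' @export
generate_entity <- function(spec, template, entity_id, family) {
  lig <- template
  jit <- matrix(stats::rnorm(3L * nrow(lig$atoms), 0, 0.12), ncol = 3L)
  lig$atoms$x <- lig$atoms$x + jit[, 1L]
  lig$atoms$y <- lig$atoms$y + jit[, 2L]
  lig$atoms$z <- lig$atoms$z + jit[, 3L]
  heavy <- lig$atoms$element != "H"
  lx <- as.matrix(lig$atoms[heavy, c("x", "y", "z")])
  pocket_n <- .runif_int(1L, spec$pocket_size_range)
  protein <- .make_pocket(lx, pocket_n, near_frac = stats::runif(1, 0.15, 0.75))
  px <- as.matrix(protein$atoms[, c("x", "y", "z")])
  contacts <- .contact_count(px, lx)
  label <- spec$label_alpha * contacts / nrow(lx) + spec$label_beta +
    stats::rnorm(1, 0, spec$label_noise_sd)

  n_good <- .n_good_for_entity(spec)
  K <- spec$poses_per_entity
  targets <- c(stats::runif(n_good, spec$good_rmsd_range[1], spec$good_rmsd_range[2]),
               stats::runif(K - n_good, spec$bad_rmsd_range[1], spec$bad_rmsd_range[2]))
  targets <- sample(targets)
  poses <- lapply(targets, function(tr) .perturb_pose(lig, tr))
  # docking-style scores: decreasing in pose contact count but with noise on
  # the order of the signal itself, so ranks are only weakly informative
  # (the top-ranked pose is often not the best one)
  scores <- vapply(poses, function(p) {
    hp <- p$atoms$element != "H"
    -(.contact_count(px, as.matrix(p$atoms[hp, c("x", "y", "z")])) / nrow(lx)) +
      stats::rnorm(1, 0, 3.5)
  }, 1.0)
  ranks <- rank(scores, ties.method = "first")
  entries <- lapply(order(ranks), function(k) {
    pose_entry(entity_id, ranks[k], poses[[k]], docking_score = scores[k])
  })
  true_rmsd <- targets[order(ranks)]
  list(entity_id = entity_id, family = family, protein = protein,
       true_pose = lig, poses = entries, label = label,
       true_rmsd = true_rmsd, n_good = sum(true_rmsd < 2.5),
       contacts = contacts)
}

#' Generate a synthetic dataset of pose bags
#'
#' Fully reproducible from `spec$seed`. With `dir = NULL` the bags are built
#' in memory; with a directory, receptor PDBs, per-pose Mol2 files, the
#' tab-separated bag index and the split manifest are written in the same
#' layout real docking data would use, consumable by [assemble_bags()].
#'
#' @param spec a [synthetic_spec()].
#' @param dir optional output directory.
#' @return list with `bags` (named list of `pose_bag`), `entities`
#'   (data.frame of per-entity truth: label, family, good-pose count,
#'   contacts), `truth` (per-pose data.frame with true RMSDs), `split`
#'   (character vectors `train` / `test`), and when written, `dir`,
#'   `index_path`, `split_path`.
#' @export
generate_dataset <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  templates <- lapply(seq_len(spec$n_families), function(i) {
    .make_ligand_template(.runif_int(1L, spec$ligand_size_range))
  })
  family <- sample(rep_len(seq_len(spec$n_families), spec$n_entities))
  ids <- sprintf("E%04d", seq_len(spec$n_entities))
  ents <- lapply(seq_len(spec$n_entities), function(i) {
    generate_entity(spec, templates[[family[i]]], ids[i], family[i])
  })

  bags <- lapply(ents, function(e) {
    inst <- e$poses
    if (spec$include_crystal) {
      inst <- c(list(pose_entry(e$entity_id, 0L, e$true_pose,
                                is_crystal = TRUE)), inst)
    }
    pose_bag(e$entity_id, e$label, e$protein, inst)
  })
  names(bags) <- ids

  entities <- data.frame(
    entity_id = ids, family = family,
    label = vapply(ents, `[[`, 1.0, "label"),
    n_good = vapply(ents, `[[`, 1L, "n_good"),
    contacts = vapply(ents, `[[`, 1L, "contacts"),
    n_ligand_heavy = vapply(ents, function(e) sum(e$true_pose$atoms$element != "H"), 1L)
  )
  truth <- do.call(rbind, lapply(ents, function(e) {
    data.frame(entity_id = e$entity_id,
               pose_rank = vapply(e$poses, `[[`, 1L, "pose_rank"),
               rmsd = e$true_rmsd, good = e$true_rmsd < 2.5)
  }))

  n_test <- max(1L, round(spec$n_entities * spec$test_fraction))
  if (spec$split == "random") {
    test_ids <- sample(ids, n_test)
  } else {
    fams <- sample(unique(family))
    if (length(fams) < 2L) stop("group split needs at least 2 ligand families")
    cum <- cumsum(table(factor(family, levels = fams)))
    k <- which(cum >= n_test)[1L]
    test_ids <- ids[family %in% fams[seq_len(k)]]
  }
  split <- list(train = setdiff(ids, test_ids), test = sort(test_ids))

  out <- list(spec = spec, bags = bags, entities = entities, truth = truth,
              split = split)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    index <- do.call(rbind, lapply(ents, function(e) {
      pdb <- file.path(dir, paste0(e$entity_id, "_receptor.pdb"))
      write_pdb_file(e$protein, pdb)
      rows <- lapply(e$poses, function(p) {
        mp <- file.path(dir, sprintf("%s_pose%02d.mol2", e$entity_id, p$pose_rank))
        write_mol2_file(p$structure, mp,
                        names = sprintf("%s_pose%02d", e$entity_id, p$pose_rank))
        data.frame(entity_id = e$entity_id, label = e$label, pose_path = mp,
                   pose_rank = p$pose_rank, docking_score = p$docking_score,
                   is_crystal = FALSE)
      })
      if (spec$include_crystal) {
        cp <- file.path(dir, paste0(e$entity_id, "_crystal.mol2"))
        write_mol2_file(e$true_pose, cp, names = paste0(e$entity_id, "_crystal"))
        rows <- c(list(data.frame(entity_id = e$entity_id, label = e$label,
                                  pose_path = cp, pose_rank = 0L,
                                  docking_score = NA_real_, is_crystal = TRUE)),
                  rows)
      }
      do.call(rbind, rows)
    }))
    out$index_path <- write_bag_index(index, file.path(dir, "index.tsv"))
    split_df <- data.frame(
      entity_id = c(split$train, split$test),
      side = c(rep("train", length(split$train)), rep("test", length(split$test))))
    utils::write.table(split_df, file.path(dir, "split.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    out$split_path <- file.path(dir, "split.tsv")
    out$receptor_paths <- stats::setNames(
      file.path(dir, paste0(ids, "_receptor.pdb")), ids)
    out$dir <- dir
  }
  out
}
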