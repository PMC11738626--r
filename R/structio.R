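# Structure file IO, bag assembly, and the embedding store.

.known_elements <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na", "Mg", "Al",
  "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Mn", "Fe", "Co", "Ni", "Cu", "Zn",
  "Se", "Br", "Kr", "Rb", "Sr", "Mo", "Ru", "Rh", "Pd", "Ag", "Cd", "I",
  "Xe", "Cs", "Ba", "Pt", "Au", "Hg", "At"
)

#' Construct a structure from atom and bond tables
#'
#' @param atoms data.frame with columns `element`, `x`, `y`, `z`, `charge`
#'   (NA when the source format carries none), `role` (`"protein"` or
#'   `"ligand"`), `atom_index` (0-based file order).
#' @param bonds data.frame with columns `i`, `j` (0-based `atom_index` of the
#'   endpoints) and `order` (`"1"`, `"2"`, `"3"`, `"ar"`, `"am"`), or NULL.
#' @return a `pose_structure`.
#' @export
pose_structure <- function(atoms, bonds = NULL) {
  stopifnot(is.data.frame(atoms))
  req <- c("element", "x", "y", "z", "charge", "role", "atom_index")
  missing_cols <- setdiff(req, names(atoms))
  if (length(missing_cols)) {
    stop("atoms table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(atoms) == 0L) stop("empty structure: no atoms")
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop("non-finite atom coordinates")
  }
  if (anyDuplicated(atoms$atom_index)) stop("duplicate atom_index values")
  bad <- setdiff(unique(atoms$element), .known_elements)
  if (length(bad)) {
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "))
  }
  if (is.null(bonds)) {
    bonds <- data.frame(i = integer(), j = integer(), order = character())
  }
  structure(list(atoms = atoms, bonds = bonds), class = "pose_structure")
}

#' One docking-pose instance of an entity
#'
#' @param entity_id entity identifier shared by all poses of one complex.
#' @param pose_rank integer rank, 1 = top docking pose; 0 is reserved for a
#'   crystal instance.
#' @param structure the ligand `pose_structure`.
#' @param docking_score optional docking score (kcal/mol, lower is better).
#' @param is_crystal whether this instance is the crystal ligand.
#' @param source_path provenance path, if the pose came from a file.
#' @return a `pose_entry`.
#' @export
pose_entry <- function(entity_id, pose_rank, structure, docking_score = NA_real_,
                       is_crystal = FALSE, source_path = NA_character_) {
  stopifnot(inherits(structure, "pose_structure"))
  structure(list(entity_id = entity_id, pose_rank = as.integer(pose_rank),
                 docking_score = docking_score, is_crystal = is_crystal,
                 structure = structure, source_path = source_path),
            class = "pose_entry")
}

#' Read a molecular structure file
#'
#' Thin dispatch over bio3d (PDB, Mol2) and ChemmineR (SDF). Hydrogens are
#' retained as read. Partial charges are taken from the file when the dialect
#' carries them (Mol2); otherwise they are marked `NA` for downstream
#' computation. PDB files carry no bond table, so bonds are inferred with a
#' 2.0 Angstrom heavy-atom distance rule (1.3 Angstrom for hydrogens); these
#' inferred bonds only feed neighbor-count features.
#'
#' @param path file path.
#' @param format one of `"pdb"`, `"mol2"`, `"sdf"`.
#' @param role `"protein"` or `"ligand"`, stamped on every atom.
#' @return a list of `pose_structure` objects, one per conformer
#'   (multi-molecule Mol2 / multi-record SDF give several; PDB gives one).
#' @export
read_structure <- function(path, format = c("pdb", "mol2", "sdf"),
                           role = c("ligand", "protein")) {
  format <- match.arg(format)
  role <- match.arg(role)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format,
    pdb = list(.read_pdb(path, role)),
    mol2 = .read_mol2(path, role),
    sdf = .read_sdf(path, role)
  )
}

.read_pdb <- function(path, role) {
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) stop("format error reading PDB ", path,
                                           ": ", conditionMessage(e)))
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0L) stop("empty-input: no ATOM/HETATM records in ", path)
  el <- trimws(at$elesy)
  el[el == "" | is.na(el)] <- .element_from_name(at$elety[el == "" | is.na(el)])
  atoms <- data.frame(
    element = .normalize_element(el),
    x = at$x, y = at$y, z = at$z,
    charge = NA_real_, role = role,
    atom_index = seq_len(nrow(at)) - 1L
  )
  bonds <- .infer_bonds(atoms)
  pose_structure(atoms, bonds)
}

.read_mol2 <- function(path, role) {
  m <- tryCatch(bio3d::read.mol2(path),
                error = function(e) stop("format error reading Mol2 ", path,
                                         ": ", conditionMessage(e)))
  if (inherits(m, "mol2")) m <- list(m)
  # bio3d folds identical-topology molecules (the multi-conformer docking
  # case) into one record with multi-row xyz; expand each row to a conformer
  out <- list()
  for (one in m) {
    at <- one$atom
    if (is.null(at) || nrow(at) == 0L) stop("empty-input: no atoms in ", path)
    charges <- as.numeric(at$charge)
    if (all(!is.na(charges)) && all(charges == 0)) charges <- NA_real_
    bonds <- if (!is.null(one$bond) && nrow(one$bond)) {
      data.frame(i = one$bond$origin - 1L, j = one$bond$target - 1L,
                 order = as.character(one$bond$type))
    } else NULL
    xyz <- one$xyz
    if (is.null(xyz) || !is.matrix(xyz)) xyz <- matrix(c(t(as.matrix(at[, c("x", "y", "z")]))), 1L)
    for (k in seq_len(nrow(xyz))) {
      co <- matrix(xyz[k, ], ncol = 3L, byrow = TRUE)
      atoms <- data.frame(
        element = .normalize_element(sub("\\..*$", "", at$elety)),
        x = co[, 1L], y = co[, 2L], z = co[, 3L],
        charge = charges, role = role,
        atom_index = seq_len(nrow(at)) - 1L
      )
      out[[length(out) + 1L]] <- pose_structure(atoms, bonds)
    }
  }
  out
}

.read_sdf <- function(path, role) {
  sdfs <- tryCatch(ChemmineR::read.SDFset(path),
                   error = function(e) stop("format error reading SDF ", path,
                                            ": ", conditionMessage(e)))
  lapply(ChemmineR::SDFset2SDF(sdfs), function(sdf) {
    ab <- ChemmineR::atomblock(sdf)
    if (nrow(ab) == 0L) stop("empty-input: no atoms in ", path)
    bb <- ChemmineR::bondblock(sdf)
    atoms <- data.frame(
      element = .normalize_element(sub("_.*$", "", rownames(ab))),
      x = ab[, 1L], y = ab[, 2L], z = ab[, 3L],
      charge = NA_real_, role = role,
      atom_index = seq_len(nrow(ab)) - 1L
    )
    bonds <- if (!is.null(bb) && nrow(bb)) {
      data.frame(i = as.integer(bb[, 1L]) - 1L, j = as.integer(bb[, 2L]) - 1L,
                 order = ifelse(bb[, 3L] == 4, "ar", as.character(bb[, 3L])))
    } else NULL
    pose_structure(atoms, bonds)
  })
}

.normalize_element <- function(el) {
  el <- trimws(el)
  paste0(toupper(substr(el, 1L, 1L)), tolower(substr(el, 2L, nchar(el))))
}

.element_from_name <- function(name) {
  sub("[0-9'].*$", "", trimws(name))
}

# distance-rule bonds for formats without a bond table
.infer_bonds <- function(atoms, heavy_cutoff = 2.0, h_cutoff = 1.3) {
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  dm <- as.matrix(stats::dist(xyz))
  idx <- which(upper.tri(dm), arr.ind = TRUE)
  is_h <- atoms$element == "H"
  cut <- ifelse(is_h[idx[, 1L]] | is_h[idx[, 2L]], h_cutoff, heavy_cutoff)
  keep <- dm[idx] <= cut & dm[idx] > 0
  data.frame(i = atoms$atom_index[idx[keep, 1L]],
             j = atoms$atom_index[idx[keep, 2L]],
             order = rep("1", sum(keep)))
}

#' Assemble labeled pose bags from an index table
#'
#' One bag per entity: the shared receptor, the entity's affinity label in pK
#' units, and its pose instances sorted by docking rank. Entities with more
#' docking poses than `max_poses` are truncated to the best-ranked ones; a
#' crystal instance (when present and `include_crystal`) is kept regardless of
#' the cap and carries rank 0.
#'
#' @param index_table data.frame with columns `entity_id`, `label`,
#'   `pose_path`, `pose_rank`, `docking_score`, `is_crystal`. `pose_path` may
#'   name Mol2 or SDF files (by extension).
#' @param receptor_paths named character vector mapping entity_id to a
#'   receptor PDB path.
#' @param max_poses cap on docking poses per bag.
#' @param include_crystal whether crystal instances in the index are kept.
#' @return list of `pose_bag` objects.
#' @export
assemble_bags <- function(index_table, receptor_paths, max_poses = 10L,
                          include_crystal = TRUE) {
  req <- c("entity_id", "label", "pose_path", "pose_rank", "docking_score",
           "is_crystal")
  missing_cols <- setdiff(req, names(index_table))
  if (length(missing_cols)) {
    stop("index table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (!is.numeric(index_table$label) || anyNA(index_table$label)) {
    stop("labels must be numeric and present for every row")
  }
  receptor_cache <- new.env(parent = emptyenv())
  lapply(split(index_table, index_table$entity_id), function(rows) {
    eid <- rows$entity_id[1L]
    docking <- rows[!rows$is_crystal, , drop = FALSE]
    if (nrow(docking) == 0L && !include_crystal) {
      stop("missing-pose: entity ", eid, " has a label but no docking poses")
    }
    if (anyDuplicated(rows$pose_rank)) {
      stop("duplicate-rank: entity ", eid, " repeats a pose_rank")
    }
    if (!is.na(match(eid, names(receptor_paths)))) {
      rpath <- receptor_paths[[eid]]
    } else {
      stop("missing receptor path for entity ", eid)
    }
    if (any(!is.na(docking$docking_score)) &&
        1L %in% docking$pose_rank) {
      s1 <- docking$docking_score[docking$pose_rank == 1L]
      if (!is.na(s1) && any(docking$docking_score < s1, na.rm = TRUE)) {
        stop("rank/score inconsistency: entity ", eid,
             " rank-1 pose does not have the minimum docking score")
      }
    }
    docking <- docking[order(docking$pose_rank), , drop = FALSE]
    if (nrow(docking) > max_poses) docking <- docking[seq_len(max_poses), , drop = FALSE]
    keep <- if (include_crystal) {
      rbind(rows[rows$is_crystal, , drop = FALSE], docking)
    } else docking
    keep <- keep[order(keep$pose_rank), , drop = FALSE]
    key <- rpath
    if (is.null(receptor_cache[[key]])) {
      receptor_cache[[key]] <- read_structure(rpath, "pdb", "protein")[[1L]]
    }
    instances <- lapply(seq_len(nrow(keep)), function(k) {
      fmt <- if (grepl("\\.sdf$", keep$pose_path[k], ignore.case = TRUE)) "sdf" else "mol2"
      st <- read_structure(keep$pose_path[k], fmt, "ligand")[[1L]]
      pose_entry(eid, keep$pose_rank[k], st,
                 docking_score = keep$docking_score[k],
                 is_crystal = keep$is_crystal[k],
                 source_path = keep$pose_path[k])
    })
    pose_bag(eid, rows$label[1L], receptor_cache[[key]], instances)
  })
}

#' Construct a pose bag
#'
#' @param entity_id entity identifier.
#' @param label binding affinity in pK units.
#' @param protein shared receptor `pose_structure`.
#' @param instances list of `pose_entry`, ordered by pose_rank.
#' @return a `pose_bag`.
#' @export
pose_bag <- function(entity_id, label, protein, instances) {
  if (!is.finite(label)) stop("bag label must be finite")
  if (length(instances) < 1L) stop("bag must contain at least one instance")
  structure(list(entity_id = entity_id, label = label, protein = protein,
                 instances = instances), class = "pose_bag")
}

#' @export
print.pose_bag <- function(x, ...) {
  cat(sprintf("<pose_bag> %s: K=%d poses, label=%.3f pK\n",
              x$entity_id, length(x$instances), x$label))
  invisible(x)
}

# ---- embedding store ---------------------------------------------------

#' Create an embedding store
#'
#' In-memory store of per-pose embeddings, grouped per entity with one record
#' per pose rank, persistable to disk with [embedding_store_save()] with a
#' bit-exact round trip. All embeddings in one store share a dimension.
#'
#' @return an `embedding_store`.
#' @export
embedding_store <- function() {
  st <- new.env(parent = emptyenv())
  st$data <- list()
  st$dim <- NULL
  class(st) <- "embedding_store"
  st
}

#' Write one pose embedding
#'
#' @param store an [embedding_store()].
#' @param entity_id entity identifier.
#' @param pose_rank pose rank within the entity.
#' @param embedding numeric vector; must match the store dimension.
#' @export
embedding_store_write <- function(store, entity_id, pose_rank, embedding) {
  embedding <- as.numeric(embedding)
  if (is.null(store$dim)) store$dim <- length(embedding)
  if (length(embedding) != store$dim) {
    stop("dimension error: store holds D=", store$dim, " but got D=",
         length(embedding))
  }
  key <- as.character(entity_id)
  if (is.null(store$data[[key]])) store$data[[key]] <- list()
  store$data[[key]][[as.character(pose_rank)]] <- embedding
  invisible(store)
}

# bulk write: one assignment into the store per call, not per record
.embedding_store_bulk <- function(store, entity_ids, pose_ranks, emb) {
  if (is.null(store$dim)) store$dim <- ncol(emb)
  if (ncol(emb) != store$dim) {
    stop("dimension error: store holds D=", store$dim, " but got D=", ncol(emb))
  }
  rows <- split(seq_len(nrow(emb)), entity_ids)
  add <- lapply(rows, function(r) {
    stats::setNames(lapply(r, function(k) emb[k, ]),
                    as.character(pose_ranks[r]))
  })
  for (key in names(add)) {
    store$data[[key]] <- c(store$data[[key]], add[[key]])
  }
  invisible(store)
}

#' Read all pose embeddings of one entity
#'
#' @inheritParams embedding_store_write
#' @return list with `pose_rank` (integer vector, ascending) and `embeddings`
#'   (matrix, one row per pose in rank order).
#' @export
embedding_store_read <- function(store, entity_id) {
  key <- as.character(entity_id)
  recs <- store$data[[key]]
  if (is.null(recs)) stop("missing-key: no embeddings for entity ", entity_id)
  ranks <- sort(as.integer(names(recs)))
  list(pose_rank = ranks,
       embeddings = do.call(rbind, lapply(as.character(ranks),
                                          function(r) recs[[r]])))
}

#' @rdname embedding_store_read
#' @export
embedding_store_entities <- function(store) names(store$data)

#' Persist / restore an embedding store
#'
#' Serialized with R's binary RDS format (one group per entity, one record per
#' pose rank); the round trip is bit-exact.
#'
#' @inheritParams embedding_store_write
#' @param path file path.
#' @export
embedding_store_save <- function(store, path) {
  saveRDS(list(data = store$data, dim = store$dim), path)
  invisible(path)
}

#' @rdname embedding_store_save
#' @export
embedding_store_load <- function(path) {
  x <- readRDS(path)
  st <- embedding_store()
  st$data <- x$data
  st$dim <- x$dim
  st
}

# ---- writers (used by the synthetic generator) -------------------------

#' Write a structure as PDB
#'
#' @param st a `pose_structure`.
#' @param path output path.
#' @export
write_pdb_file <- function(st, path) {
  at <- st$atoms
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
    resno = rep(1L, nrow(at)), resid = rep("POC", nrow(at)),
    eleno = seq_len(nrow(at)), elety = paste0(at$element, seq_len(nrow(at)) %% 10),
    elesy = at$element, chain = rep("A", nrow(at))
  )
  invisible(path)
}

#' Write one or more structures as a (multi-molecule) Mol2 file
#'
#' Emits `@<TRIPOS>MOLECULE/ATOM/BOND` blocks with per-atom partial charges.
#'
#' @param structures a `pose_structure` or list of them.
#' @param path output path.
#' @param names molecule names, recycled.
#' @export
write_mol2_file <- function(structures, path, names = "MOL") {
  if (inherits(structures, "pose_structure")) structures <- list(structures)
  names <- rep_len(names, length(structures))
  con <- file(path, "w")
  on.exit(close(con))
  for (s in seq_along(structures)) {
    st <- structures[[s]]
    at <- st$atoms
    bd <- st$bonds
    writeLines(c(
      "@<TRIPOS>MOLECULE", names[s],
      sprintf(" %d %d 0 0 0", nrow(at), nrow(bd)),
      "SMALL", "USER_CHARGES", "@<TRIPOS>ATOM"), con)
    chg <- ifelse(is.na(at$charge), 0, at$charge)
    writeLines(sprintf("%7d %-8s %9.4f %9.4f %9.4f %-5s %5d %-8s %9.4f",
                       seq_len(nrow(at)), paste0(at$element, seq_len(nrow(at))),
                       at$x, at$y, at$z, at$element, 1L, "LIG1", chg), con)
    if (nrow(bd)) {
      writeLines("@<TRIPOS>BOND", con)
      bi <- match(bd$i, at$atom_index)
      bj <- match(bd$j, at$atom_index)
      writeLines(sprintf("%6d %5d %5d %4s", seq_len(nrow(bd)), bi, bj,
                         bd$order), con)
    }
  }
  invisible(path)
}

#' Write / read a bag index table (tab-separated)
#'
#' @param index data.frame as accepted by [assemble_bags()].
#' @param path file path.
#' @export
write_bag_index <- function(index, path) {
  utils::write.table(index, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_bag_index
#' @export
read_bag_index <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}
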