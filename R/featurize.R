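# Atom featurization: one pose with its receptor pocket -> centered
# coordinates plus a 19-dimensional per-atom feature matrix.

# Bondi-style van der Waals radii (Angstrom); unknown elements fall back to
# 1.7 with a warning.
.vdw_radii <- c(
  H = 1.20, B = 1.92, C = 1.70, N = 1.55, O = 1.52, F = 1.47, P = 1.80,
  S = 1.80, Cl = 1.75, Se = 1.90, Br = 1.85, I = 1.98,
  Li = 1.82, Na = 2.27, K = 2.75, Mg = 1.73, Ca = 2.31, Zn = 1.39,
  Fe = 1.94, Mn = 1.97, Cu = 1.40, Ni = 1.63, Co = 1.92, Cd = 1.58,
  Hg = 1.55
)

.halogens <- c("F", "Cl", "Br", "I", "At")
.metals <- c("Li", "Na", "K", "Rb", "Cs", "Mg", "Ca", "Sr", "Ba", "Zn",
             "Fe", "Mn", "Cu", "Ni", "Co", "Cd", "Hg", "Al")

.feature_names <- c(
  "el_B", "el_C", "el_N", "el_O", "el_P", "el_S", "el_Se", "el_halogen",
  "el_metal", "hybridization", "heavy_neighbors", "hetero_neighbors",
  "hydrophobic", "aromatic", "acceptor", "donor", "ring",
  "partial_charge", "vdw_radius"
)

#' Featurize one protein-ligand pose instance
#'
#' Truncates the receptor to a pocket around the ligand, centers all
#' coordinates on the ligand heavy-atom centroid, and computes the
#' 19-dimensional per-atom feature vector: a 9-slot element one-hot
#' (B, C, N, O, P, S, Se, halogen, metal), hybridization code (1/2/3 for
#' sp/sp2/sp3, 0 if undefined), heavy- and hetero-neighbor counts, five
#' binary property bits (hydrophobic, aromatic, acceptor, donor, ring),
#' partial charge (elementary charges) and van der Waals radius (Angstrom).
#' Hydrogens never become nodes; they still count for the donor bit, and
#' neighbor counts consider heavy atoms only. Elements outside the nine
#' one-hot classes keep an all-zero one-hot (with a warning) and stay in the
#' graph.
#'
#' @param protein a `pose_structure` for the receptor.
#' @param pose a `pose_entry` holding the ligand pose.
#' @param pocket_radius receptor atoms farther than this (Angstrom) from every
#'   ligand heavy atom are dropped.
#' @param charge_model what to do when partial charges are absent from the
#'   input: `"gasteiger"` computes Gasteiger charges through the OpenBabel
#'   command-line tool, `"none"` raises an error.
#' @return a `featurized_instance`: `coords` (N x 3, Angstrom, ligand centroid
#'   at the origin), `features` (N x 19), `role` (per-atom `"protein"` /
#'   `"ligand"`), and provenance fields (`entity_id`, `pose_rank`,
#'   `charge_model`).
#' @export
featurize_complex <- function(protein, pose, pocket_radius = 8.0,
                              charge_model = c("gasteiger", "none"),
                              .protein_features = NULL,
                              .ligand_features = NULL) {
  charge_model <- match.arg(charge_model)
  stopifnot(inherits(protein, "pose_structure"), inherits(pose, "pose_entry"))
  lig <- pose$structure
  lig_heavy <- lig$atoms$element != "H"
  if (!any(lig_heavy)) stop("empty ligand: pose has no heavy atoms")

  lig <- .ensure_charges(lig, charge_model)
  prot <- .ensure_charges(protein, charge_model)

  lx <- as.matrix(lig$atoms[lig_heavy, c("x", "y", "z")])
  prot_heavy <- prot$atoms$element != "H"
  px <- as.matrix(prot$atoms[prot_heavy, c("x", "y", "z")])
  # pocket: receptor heavy atoms within pocket_radius of any ligand heavy atom
  if (nrow(px)) {
    d2 <- .cross_dist2(px, lx)
    keep <- sqrt(.row_min(d2)) <= pocket_radius
  } else {
    keep <- logical(0)
  }
  # per-atom features depend only on topology, not coordinates, so callers
  # looping over poses of one entity may pass them in precomputed
  pf_full <- if (is.null(.protein_features)) .atom_features(prot) else .protein_features
  lf_full <- if (is.null(.ligand_features)) .atom_features(lig) else .ligand_features
  pf <- pf_full[prot_heavy, , drop = FALSE][keep, , drop = FALSE]
  lf <- lf_full[lig_heavy, , drop = FALSE]
  centroid <- colMeans(lx)
  coords <- rbind(px[keep, , drop = FALSE], lx)
  coords <- sweep(coords, 2L, centroid)
  colnames(coords) <- c("x", "y", "z")
  used_model <- c(
    if (attr(prot, "computed_charges") %||% FALSE) "gasteiger" else "file",
    if (attr(lig, "computed_charges") %||% FALSE) "gasteiger" else "file"
  )
  structure(list(
    coords = coords,
    features = rbind(pf, lf),
    role = c(rep("protein", sum(keep)), rep("ligand", nrow(lx))),
    entity_id = pose$entity_id,
    pose_rank = pose$pose_rank,
    charge_model = paste(unique(used_model), collapse = "+")
  ), class = "featurized_instance")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.cross_dist2 <- function(a, b) {
  outer(rowSums(a^2), rep(1, nrow(b))) +
    outer(rep(1, nrow(a)), rowSums(b^2)) - 2 * a %*% t(b)
}

.row_min <- function(m) {
  do.call(pmin, lapply(seq_len(ncol(m)), function(j) m[, j]))
}

.ensure_charges <- function(st, charge_model) {
  if (!anyNA(st$atoms$charge)) return(st)
  if (charge_model == "none") {
    stop("charge error: partial charges absent and charge model disabled")
  }
  st$atoms$charge <- compute_gasteiger_charges(st)
  attr(st, "computed_charges") <- TRUE
  st
}

# 19-column feature matrix for every atom of a structure (including H rows,
# which callers drop). Perception is rule-based from elements and the bond
# table: hybridization from incident bond orders, aromaticity from "ar"
# bonds, ring membership from cycle-containing biconnected components,
# donors/acceptors from N/O environments, hydrophobicity for carbons and
# halogens without hetero heavy neighbors.
.atom_features <- function(st) {
  at <- st$atoms
  n <- nrow(at)
  el <- at$element
  bonds <- st$bonds
  # directed incidence vectors: each bond contributes one entry per endpoint
  if (!is.null(bonds) && nrow(bonds)) {
    bi <- match(bonds$i, at$atom_index)
    bj <- match(bonds$j, at$atom_index)
    inc_at <- c(bi, bj)                   # atom seeing the bond
    inc_nb <- c(bj, bi)                   # its neighbor across the bond
    inc_ord <- c(bonds$order, bonds$order)
  } else {
    inc_at <- integer(); inc_nb <- integer(); inc_ord <- character()
  }
  cnt <- function(sel) tabulate(inc_at[sel], nbins = n)
  nb_el <- el[inc_nb]
  heavy_sel <- nb_el != "H"
  n_all <- cnt(TRUE)
  n_heavy <- cnt(heavy_sel)
  n_hetero <- cnt(heavy_sel & !nb_el %in% "C")
  n_h <- n_all - n_heavy
  n_double <- cnt(inc_ord == "2")
  n_triple <- cnt(inc_ord == "3")
  n_arom <- cnt(inc_ord == "ar")
  ring <- .ring_atoms(n, bonds, at$atom_index)

  hyb <- ifelse(n_all == 0L, 0,
         ifelse(n_triple > 0L | n_double >= 2L, 1,
         ifelse(n_double > 0L | n_arom > 0L, 2, 3)))
  slot <- match(el, c("B", "C", "N", "O", "P", "S", "Se"))
  slot[el %in% .halogens] <- 8L
  slot[el %in% .metals] <- 9L
  onehot <- matrix(0, n, 9L)
  onehot[cbind(which(!is.na(slot)), slot[!is.na(slot)])] <- 1
  unknown <- unique(el[is.na(slot) & el != "H"])
  vdw <- unname(.vdw_radii[el])
  feat <- cbind(
    onehot, hyb, n_heavy, n_hetero,
    as.numeric((el == "C" | el %in% .halogens) & n_hetero == 0L),
    as.numeric(n_arom > 0L),
    as.numeric(el == "O" | (el == "N" & n_all <= 3L)),
    as.numeric(el %in% c("N", "O") & n_h > 0L),
    as.numeric(ring),
    at$charge,
    ifelse(is.na(vdw), 1.7, vdw)
  )
  colnames(feat) <- .feature_names
  if (length(unknown)) {
    warning("elements outside the 9 one-hot classes kept with all-zero ",
            "one-hot: ", paste(unknown, collapse = ", "))
  }
  if (any(is.na(vdw) & el != "H")) {
    warning("unknown element vdW radius; using 1.7 A fallback")
  }
  feat
}

# ring atoms = vertices of biconnected components that contain a cycle
.ring_atoms <- function(n, bonds, atom_index) {
  ring <- rep(FALSE, n)
  if (is.null(bonds) || nrow(bonds) < 3L) return(ring)
  g <- igraph::graph_from_edgelist(cbind(
    match(bonds$i, atom_index), match(bonds$j, atom_index)), directed = FALSE)
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  bc <- igraph::biconnected_components(g)
  for (comp in bc$components) {
    if (length(comp) >= 3L) ring[as.integer(comp)] <- TRUE
  }
  ring
}

#' Gasteiger partial charges via OpenBabel
#'
#' Writes the structure to a V2000 SD block, runs the `obabel` command-line
#' tool with `--partialcharge gasteiger`, and parses the per-atom charges
#' from its Mol2 output. Requires `obabel` on the PATH.
#'
#' @param st a `pose_structure`.
#' @return numeric vector of per-atom charges in file atom order.
#' @export
compute_gasteiger_charges <- function(st) {
  if (Sys.which("obabel") == "") {
    stop("charge error: obabel not found on PATH; cannot compute Gasteiger ",
         "charges")
  }
  tmp_in <- tempfile(fileext = ".sdf")
  tmp_out <- tempfile(fileext = ".mol2")
  on.exit(unlink(c(tmp_in, tmp_out)), add = TRUE)
  writeLines(.sdf_block(st), tmp_in)
  status <- suppressWarnings(system2(
    "obabel", c(tmp_in, "-omol2", "--partialcharge", "gasteiger",
                "-O", tmp_out),
    stdout = FALSE, stderr = FALSE))
  if (status != 0L || !file.exists(tmp_out)) {
    stop("charge error: obabel failed")
  }
  m <- bio3d::read.mol2(tmp_out)
  if (is.list(m) && !inherits(m, "mol2")) m <- m[[1L]]
  as.numeric(m$atom$charge)
}

# minimal V2000 SD block from an atom/bond table
.sdf_block <- function(st) {
  at <- st$atoms
  bonds <- st$bonds
  nb <- if (is.null(bonds)) 0L else nrow(bonds)
  order_code <- function(o) switch(o, "1" = 1L, "2" = 2L, "3" = 3L,
                                   "ar" = 4L, "am" = 1L, 1L)
  lines <- c(
    "poseMIL", "  poseMIL", "",
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", nrow(at), nb)
  )
  lines <- c(lines, sprintf(
    "%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
    at$x, at$y, at$z, at$element))
  if (nb) {
    bi <- match(bonds$i, at$atom_index)
    bj <- match(bonds$j, at$atom_index)
    lines <- c(lines, sprintf("%3d%3d%3d  0  0  0  0", bi, bj,
                              vapply(bonds$order, order_code, 1L)))
  }
  c(lines, "M  END", "$$$$")
}
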