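# Spatial graph construction from featurized pose instances, and pose RMSD.

#' Build the two-edge-type spatial graph of a pose instance
#'
#' Constructs the covalent/noncovalent distance graph used by the spatial
#' graph convolutional backbone. A pair of atoms is connected by a covalent
#' edge when their Euclidean distance d satisfies 0 < d <= `covalent_cutoff`,
#' and by a noncovalent edge when `covalent_cutoff` < d <= `noncovalent_cutoff`
#' (cutoffs inclusive). Edges are undirected and stored symmetrically (both
#' directions); the two edge sets are disjoint by construction. Edge
#' classification is purely distance-based; the file bond table only feeds the
#' neighbor-count features, so unusually long covalent bonds (e.g. S-S at
#' about 2.05 A) land in the noncovalent set.
#'
#' @param instance a `featurized_instance` from [featurize_complex()].
#' @param covalent_cutoff covalent edge threshold in Angstrom.
#' @param noncovalent_cutoff noncovalent edge threshold in Angstrom.
#' @return a `complex_graph`: node features (N x 19), node coordinates
#'   (N x 3, Angstrom), `covalent` and `noncovalent` edge tables with columns
#'   `i`, `j`, `d` (1-based endpoints, Euclidean distance), an empty `radius`
#'   edge table, and the per-node role mask.
#' @seealso [build_radius_graph()] for the radius graph flavor.
#' @export
build_sgcnn_graph <- function(instance, covalent_cutoff = 1.5,
                              noncovalent_cutoff = 4.5) {
  stopifnot(inherits(instance, "featurized_instance"))
  n <- nrow(instance$coords)
  if (n < 2L) stop("degenerate graph: instance has fewer than 2 atoms")
  dm <- as.matrix(stats::dist(instance$coords))
  idx <- which(upper.tri(dm), arr.ind = TRUE)
  d <- dm[idx]
  cov <- d > 0 & d <= covalent_cutoff
  non <- d > covalent_cutoff & d <= noncovalent_cutoff
  g <- structure(list(
    node_features = instance$features,
    node_coords = instance$coords,
    covalent = .sym_edges(idx[cov, , drop = FALSE], d[cov]),
    noncovalent = .sym_edges(idx[non, , drop = FALSE], d[non]),
    radius = .sym_edges(matrix(integer(), 0L, 2L), numeric()),
    role = instance$role
  ), class = "complex_graph")
  g
}

#' Build the radius graph of a pose instance
#'
#' Connects every atom pair with 0 < d <= `cutoff`; the Euclidean distance d
#' is the single scalar edge feature, as used by the E(n)-invariant backbone.
#'
#' @inheritParams build_sgcnn_graph
#' @param cutoff radius in Angstrom.
#' @return a `complex_graph` with only `radius` edges populated.
#' @export
build_radius_graph <- function(instance, cutoff = 5.0) {
  stopifnot(inherits(instance, "featurized_instance"))
  n <- nrow(instance$coords)
  if (n < 2L) stop("degenerate graph: instance has fewer than 2 atoms")
  dm <- as.matrix(stats::dist(instance$coords))
  idx <- which(upper.tri(dm), arr.ind = TRUE)
  d <- dm[idx]
  keep <- d > 0 & d <= cutoff
  structure(list(
    node_features = instance$features,
    node_coords = instance$coords,
    covalent = .sym_edges(matrix(integer(), 0L, 2L), numeric()),
    noncovalent = .sym_edges(matrix(integer(), 0L, 2L), numeric()),
    radius = .sym_edges(idx[keep, , drop = FALSE], d[keep]),
    role = instance$role
  ), class = "complex_graph")
}

# store an undirected edge list symmetrically (i->j and j->i)
.sym_edges <- function(pairs, d) {
  if (nrow(pairs) == 0L) {
    return(data.frame(i = integer(), j = integer(), d = numeric()))
  }
  data.frame(
    i = c(pairs[, 1L], pairs[, 2L]),
    j = c(pairs[, 2L], pairs[, 1L]),
    d = c(d, d)
  )
}

#' Heavy-atom RMSD between two poses of the same ligand
#'
#' Plain matched-order root-mean-square deviation over heavy atoms, with no
#' superposition: both poses are assumed to live in the shared receptor
#' coordinate frame, as docking output does. Atoms are matched by their file
#' order (canonical index), so topologically symmetric ligands whose symmetry
#' a graph-aware RMSD would correct are reported with the plain value.
#'
#' @param pose_a,pose_b `pose_entry` objects for the same entity with equal
#'   heavy-atom counts.
#' @return RMSD in Angstrom (>= 0).
#' @export
pose_rmsd <- function(pose_a, pose_b) {
  xa <- .heavy_coords(pose_a)
  xb <- .heavy_coords(pose_b)
  if (nrow(xa) != nrow(xb)) {
    stop("atom matching error: poses have ", nrow(xa), " vs ", nrow(xb),
         " heavy atoms")
  }
  sqrt(mean(rowSums((xa - xb)^2)))
}

.heavy_coords <- function(pose) {
  at <- pose$structure$atoms
  heavy <- at$element != "H"
  as.matrix(at[heavy, c("x", "y", "z")])
}
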