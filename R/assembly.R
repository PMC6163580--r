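#' Single-linkage clustering of molecules
#'
#' Molecules (one chain = one molecule) are joined into one aggregate when
#' any inter-molecule bead pair lies within `cutoff` (minimum image).
#' Connected components are computed on the resulting contact graph, which
#' is exactly single-linkage clustering at the cutoff. Cluster labels are
#' deterministic: each cluster is labelled by its lowest molecule index.
#'
#' @param frame a [cg_frame()].
#' @param system a [bead_system()].
#' @param molecule_group group name (or selection) whose chains are the
#'   molecules, e.g. `"detergent"`.
#' @param cutoff contact distance, nm (> 0).
#' @return An object of class `cluster_set`: list with `molecules`
#'   (data.frame `molecule`, `chain_id`, `cluster`), `sizes` (named integer
#'   vector, molecule counts per cluster) and `n_clusters`.
#' @export
cluster_molecules <- function(frame, system, molecule_group, cutoff = 0.6) {
  if (cutoff <= 0) stop("cutoff must be > 0", call. = FALSE)
  sel <- resolve_selection(system, molecule_group)
  if (!length(sel)) stop("empty molecule group", call. = FALSE)
  rows <- match(sel, system$beads$index)
  chain <- system$beads$chain_id[rows]
  chains <- unique(chain)
  nmol <- length(chains)
  mol_of <- match(chain, chains)

  D <- min_image_dist(frame$xyz[rows, , drop = FALSE],
                      frame$xyz[rows, , drop = FALSE], frame$box)
  edges <- NULL
  if (nmol > 1) {
    hit <- which(D <= cutoff, arr.ind = TRUE)
    ma <- mol_of[hit[, 1]]; mb <- mol_of[hit[, 2]]
    keep <- ma < mb
    edges <- unique(cbind(ma[keep], mb[keep]))
  }
  g <- igraph::make_empty_graph(n = nmol, directed = FALSE)
  if (!is.null(edges) && nrow(edges)) g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)$membership
  # relabel by lowest molecule index in each component
  label <- vapply(comp, function(cc) min(which(comp == cc)), integer(1))
  sizes <- table(label)
  structure(list(
    molecules = data.frame(molecule = seq_len(nmol), chain_id = chains,
                           cluster = label, stringsAsFactors = FALSE),
    sizes = setNames(as.integer(sizes), names(sizes)),
    n_clusters = length(sizes)
  ), class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat("cluster_set:", nrow(x$molecules), "molecules in", x$n_clusters,
      "clusters; sizes:", paste(sort(x$sizes, decreasing = TRUE),
                                collapse = ", "), "\n")
  invisible(x)
}

#' Residue-level contact map between two groups
#'
#' All residue pairs (one residue from each group) whose minimum bead-bead
#' distance is at most `cutoff`.
#'
#' @param frame,system frame and system.
#' @param groupA,groupB disjoint selections.
#' @param cutoff contact distance, nm.
#' @return data.frame of class `contact_map`: `chainA`, `resA`, `chainB`,
#'   `resB`, `min_dist_nm`.
#' @export
contact_residues <- function(frame, system, groupA, groupB, cutoff = 0.6) {
  a <- resolve_selection(system, groupA)
  b <- resolve_selection(system, groupB)
  if (length(intersect(a, b))) stop("groups must be disjoint", call. = FALSE)
  ra <- match(a, system$beads$index)
  rb <- match(b, system$beads$index)
  D <- min_image_dist(frame$xyz[ra, , drop = FALSE],
                      frame$xyz[rb, , drop = FALSE], frame$box)
  resA <- paste(system$beads$chain_id[ra], system$beads$residue_index[ra])
  resB <- paste(system$beads$chain_id[rb], system$beads$residue_index[rb])
  hit <- which(D <= cutoff, arr.ind = TRUE)
  out <- data.frame(chainA = character(0), resA = integer(0),
                    chainB = character(0), resB = integer(0),
                    min_dist_nm = numeric(0))
  if (nrow(hit)) {
    key <- paste(resA[hit[, 1]], "|", resB[hit[, 2]])
    mins <- tapply(D[hit], key, min)
    parts <- strsplit(names(mins), " \\| ")
    pa <- strsplit(vapply(parts, `[`, "", 1), " ")
    pb <- strsplit(vapply(parts, `[`, "", 2), " ")
    out <- data.frame(
      chainA = vapply(pa, `[`, "", 1),
      resA = as.integer(vapply(pa, `[`, "", 2)),
      chainB = vapply(pb, `[`, "", 1),
      resB = as.integer(vapply(pb, `[`, "", 2)),
      min_dist_nm = as.numeric(mins), stringsAsFactors = FALSE
    )
    out <- out[order(out$chainA, out$resA, out$chainB, out$resB), ]
    rownames(out) <- NULL
  }
  class(out) <- c("contact_map", class(out))
  out
}

#' Hydrophobic burial fraction of a group
#'
#' How much of the hydrophobic surface of a group is buried in its
#' assembled context: `1 - SASA_hydrophobic(in group context) /
#' sum(isolated single-bead reference areas)`, clamped at 0. An isolated
#' hydrophobic bead scores 0; a fully caged one approaches 1.
#'
#' @param frame,system frame and system.
#' @param group selection containing at least one hydrophobic-class bead.
#' @param params a [sasa_params()].
#' @return fraction in [0, 1].
#' @export
hydrophobic_burial <- function(frame, system, group, params = sasa_params()) {
  sel <- resolve_selection(system, group)
  rows <- match(sel, system$beads$index)
  hyd <- sel[system$beads$class[rows] == "hydrophobic"]
  if (!length(hyd)) {
    stop("group contains no hydrophobic-class beads", call. = FALSE)
  }
  s <- sasa(frame, system, sel, params)
  ctx <- sum(s$per_bead$area_nm2[s$per_bead$index %in% hyd])
  rad <- s$per_bead$radius[s$per_bead$index %in% hyd]
  ref <- sum(4 * pi * (rad + params$probe_radius)^2)
  max(0, 1 - ctx / ref)
}

#' Export a cluster set as CSV
#' @param clusters a [cluster_molecules()] result.
#' @param path output file.
#' @export
write_cluster_csv <- function(clusters, path) {
  m <- clusters$molecules
  rows <- lapply(sort(unique(m$cluster)), function(cl) {
    data.frame(cluster_id = cl, size = sum(m$cluster == cl),
               member_chains = paste(m$chain_id[m$cluster == cl],
                                     collapse = ";"))
  })
  write.table(do.call(rbind, rows), path, sep = ",", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
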