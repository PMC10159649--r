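# Conformational clustering: all-versus-all RMSD matrix over a backbone
# atom selection, agglomerative hierarchical clustering, dendrogram cut,
# medoid representatives and the cluster-versus-time series.

#' Default superposition selection
#'
#' Coarse backbone anchors covering both polymer classes: CA for amino
#' acids and C1' for nucleotides.
#' @export
DEFAULT_SELECTION <- c("CA", "C1'")

#' All-versus-all RMSD matrix of an ensemble
#'
#' Entry (a, b) is the Kabsch-minimal RMSD between states a and b over
#' the selected atoms common to every state. Each pair of states is
#' superposed independently (reference-free, pairwise-optimal); set
#' `reference` to instead superpose every state onto one reference state
#' and measure deviations in that common frame.
#'
#' @param ensemble an `rin_ensemble` with >= 2 states.
#' @param selection atom-name set for superposition
#'   (default [DEFAULT_SELECTION]).
#' @param reference `NULL` for pairwise-optimal mode (default), or a
#'   state index (0-based) for reference-based mode.
#' @return symmetric numeric matrix (Angstrom) with zero diagonal,
#'   dimnames `S0, S1, ...`.
#' @export
#' @examples
#' ens <- make_two_basin_ensemble(4, seed = 1)$ensemble
#' rmsd_matrix(ens)
rmsd_matrix <- function(ensemble, selection = DEFAULT_SELECTION,
                        reference = NULL) {
  n <- n_states(ensemble)
  if (n < 2) stop("an RMSD matrix needs at least 2 states")
  mats <- lapply(ensemble$states, coordinate_matrix, selection = selection)
  # identical residue sequences make per-state key lists equal; intersect
  # guards against per-state missing atoms
  idsets <- lapply(mats, function(m) paste(m$keys, m$atom_names))
  common_ids <- Reduce(intersect, idsets)
  coords <- lapply(seq_along(mats), function(k)
    mats[[k]]$coords[match(common_ids, idsets[[k]]), , drop = FALSE])
  if (length(common_ids) < 3)
    stop("selection error: fewer than 3 atoms common to all states")
  m <- matrix(0, n, n, dimnames = list(paste0("S", 0:(n - 1)),
                                       paste0("S", 0:(n - 1))))
  if (is.null(reference)) {
    for (a in seq_len(n - 1)) {
      for (b in (a + 1):n) {
        r <- kabsch(coords[[a]], coords[[b]])$rmsd
        m[a, b] <- r
        m[b, a] <- r
      }
    }
  } else {
    ref <- as.integer(reference) + 1L
    if (ref < 1 || ref > n) stop("reference state out of range")
    fitted <- lapply(seq_len(n), function(k)
      apply_transform(kabsch(coords[[ref]], coords[[k]]), coords[[k]]))
    for (a in seq_len(n - 1)) {
      for (b in (a + 1):n) {
        r <- sqrt(mean(rowSums((fitted[[a]] - fitted[[b]])^2)))
        m[a, b] <- r
        m[b, a] <- r
      }
    }
  }
  m
}

#' Hierarchical clustering of an RMSD matrix
#'
#' Agglomerative clustering on the distance matrix with average,
#' complete or single linkage (all produce monotone merge heights).
#'
#' @param matrix symmetric RMSD matrix with zero diagonal.
#' @param linkage `"average"`, `"complete"` or `"single"`.
#' @return object of class `rin_dendrogram`: list with the underlying
#'   `hclust` tree, `n` leaves and the `linkage` used. Leaves are state
#'   indices (0-based).
#' @export
hierarchical_cluster <- function(matrix,
                                 linkage = c("average", "complete",
                                             "single")) {
  linkage <- match.arg(linkage)
  if (!isSymmetric(unname(matrix), tol = 1e-8))
    stop("RMSD matrix must be symmetric")
  if (any(diag(matrix) != 0)) stop("RMSD matrix must have a zero diagonal")
  h <- stats::hclust(stats::as.dist(matrix), method = linkage)
  structure(list(hclust = h, n = nrow(matrix), linkage = linkage),
            class = "rin_dendrogram")
}

#' @export
print.rin_dendrogram <- function(x, ...) {
  cat(sprintf("Dendrogram: %d states, %s linkage, root height %.3f A\n",
              x$n, x$linkage, max(x$hclust$height)))
  invisible(x)
}

#' Cut a dendrogram at a height cutoff
#'
#' Merges strictly below the cutoff join; merges at or above it split.
#' Cluster ids are 1-based and numbered by first occurrence in state
#' (time) order.
#'
#' @param dendrogram result of [hierarchical_cluster()].
#' @param cutoff height in Angstrom, > 0.
#' @return object of class `rin_clusters`: list with `cluster` (integer
#'   per state, state order), `cutoff_used` and `n_clusters`.
#' @export
cut_dendrogram <- function(dendrogram, cutoff) {
  if (cutoff <= 0) stop("cutoff must be > 0")
  h <- dendrogram$hclust
  n <- dendrogram$n
  # union-find over the merge list, joining only below the cutoff
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  groups <- vector("list", n - 1)   # leaf sets of internal nodes
  for (k in seq_len(max(0, n - 1))) {
    members <- integer(0)
    for (side in h$merge[k, ]) {
      members <- c(members,
                   if (side < 0) -side else groups[[side]])
    }
    groups[[k]] <- members
    if (h$height[k] < cutoff) {
      roots <- unique(vapply(members, find, integer(1)))
      for (r in roots[-1]) parent[r] <- roots[1]
    }
  }
  root_of <- vapply(seq_len(n), find, integer(1))
  cluster <- match(root_of, unique(root_of))
  structure(list(cluster = cluster, cutoff_used = cutoff,
                 n_clusters = max(cluster)),
            class = "rin_clusters")
}

#' Medoid representatives of each cluster
#'
#' The representative of a cluster is its medoid: the member state
#' minimizing the summed RMSD to all cluster members (ties go to the
#' lowest state index).
#'
#' @param assignment result of [cut_dendrogram()].
#' @param matrix the RMSD matrix the clustering was built from.
#' @return data.frame with `cluster`, `representative` (0-based state
#'   index), `size`, `mean_intra_rmsd`.
#' @export
representatives <- function(assignment, matrix) {
  cl <- assignment$cluster
  if (length(cl) != nrow(matrix))
    stop("assignment and matrix sizes disagree")
  out <- lapply(sort(unique(cl)), function(k) {
    members <- which(cl == k)
    sub <- matrix[members, members, drop = FALSE]
    sums <- rowSums(sub)
    med <- members[which.min(sums)]   # which.min takes the first minimum
    mean_intra <- if (length(members) > 1) {
      mean(sub[upper.tri(sub)])
    } else 0
    data.frame(cluster = k, representative = med - 1L,
               size = length(members), mean_intra_rmsd = mean_intra)
  })
  do.call(rbind, out)
}

#' Cluster-versus-time series
#'
#' Cluster assignment in state (time) order plus the number of
#' transitions (consecutive states in different clusters), the substrate
#' for conformational-transition timelines.
#'
#' @param assignment result of [cut_dendrogram()].
#' @return list with `timeline` (data.frame `state`, `cluster`) and
#'   `transitions` (integer).
#' @export
cluster_timeline <- function(assignment) {
  cl <- assignment$cluster
  timeline <- data.frame(state = seq_along(cl) - 1L, cluster = cl)
  transitions <- if (length(cl) > 1) sum(diff(cl) != 0) else 0L
  list(timeline = timeline, transitions = as.integer(transitions))
}

#' Export a dendrogram as Newick text
#'
#' Leaves are labeled `S<state index>` (0-based); branch lengths derive
#' from the merge heights in Angstrom, so the tree distance between two
#' leaves equals their merge height.
#'
#' @param dendrogram result of [hierarchical_cluster()].
#' @param path optional output path; when `NULL` the Newick string is
#'   returned.
#' @return the Newick string, invisibly when written to a file.
#' @export
dendrogram_newick <- function(dendrogram, path = NULL) {
  h <- dendrogram$hclust
  h$labels <- paste0("S", seq_len(dendrogram$n) - 1L)
  phy <- ape::as.phylo(h)
  txt <- ape::write.tree(phy)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Write a cluster assignment to TSV
#'
#' Columns: State (0-based index, time order), Cluster.
#'
#' @param assignment result of [cut_dendrogram()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_assignment_tsv <- function(assignment, path) {
  tl <- cluster_timeline(assignment)$timeline
  write_tsv(data.frame(State = tl$state, Cluster = tl$cluster), path)
  invisible(path)
}
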