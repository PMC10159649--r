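# Typed non-covalent interaction detection. Each detector implements one
# geometric rule on heavy-atom coordinates; detect_interactions() unions
# them into the residue interaction network of one state.
#
# Candidate pairs come from the cell-list neighbor search; the rules
# themselves are pure distance/angle gates, so every detector is testable
# against an exhaustive all-pairs evaluation of the same written rule.

empty_edges <- function() {
  data.frame(source = character(0), target = character(0),
             type = character(0), source_atom = character(0),
             target_atom = character(0), distance = numeric(0),
             angle = numeric(0), state_index = integer(0),
             stringsAsFactors = FALSE)
}

new_network <- function(state_index, nodes, edges) {
  structure(list(state_index = as.integer(state_index), nodes = nodes,
                 edges = edges),
            class = "rin_network")
}

#' @export
print.rin_network <- function(x, ...) {
  cat(sprintf("Interaction network (state %d): %d nodes, %d edges\n",
              x$state_index, length(x$nodes), nrow(x$edges)))
  if (nrow(x$edges)) print(table(x$edges$type))
  invisible(x)
}

# Angle at vertex b for row-paired coordinate matrices, degrees.
angle_rows <- function(a, b, c) {
  u <- a - b
  v <- c - b
  nu <- sqrt(rowSums(u^2))
  nv <- sqrt(rowSums(v^2))
  cosang <- rowSums(u * v) / (nu * nv)
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

# --- per-state chemistry features -----------------------------------------

# Resolve the chemistry table against one state's atoms: donor/acceptor
# atom rows, charged-group centroids (including chain termini) and
# aromatic ring planes. Groups and rings require all member atoms.
state_features <- function(state, chemistry, warn_unknown = FALSE) {
  a <- state$atoms
  ri <- atom_residue_index(state)
  rt <- residue_table(state)
  xyz <- as.matrix(a[, c("x", "y", "z")])
  atom_id <- paste(ri, a$name)
  lookup <- function(res, name) match(paste(res, name), atom_id)

  if (warn_unknown) {
    unknown <- setdiff(unique(rt$name),
                       c(AMINO_ACIDS, NUCLEOTIDES, WATER_NAMES))
    if (length(unknown)) {
      warning("residues without typed chemistry (vdW only): ",
              paste(unknown, collapse = ", "), call. = FALSE)
    }
  }

  # hydrogen-bond donors
  don_res <- integer(0); don_row <- integer(0); don_ant <- integer(0)
  for (rn in intersect(names(chemistry$donors), unique(rt$name))) {
    spec <- chemistry$donors[[rn]]
    res_idx <- which(rt$name == rn)
    for (k in seq_along(spec)) {
      dr <- lookup(res_idx, names(spec)[k])
      ar <- lookup(res_idx, spec[[k]])
      ok <- !is.na(dr) & !is.na(ar)
      don_res <- c(don_res, res_idx[ok])
      don_row <- c(don_row, dr[ok])
      don_ant <- c(don_ant, ar[ok])
    }
  }
  donors <- data.frame(res = don_res, row = don_row, ant = don_ant)

  # acceptors
  acc_res <- integer(0); acc_row <- integer(0)
  for (rn in intersect(names(chemistry$acceptors), unique(rt$name))) {
    res_idx <- which(rt$name == rn)
    for (nm in chemistry$acceptors[[rn]]) {
      r <- lookup(res_idx, nm)
      ok <- !is.na(r)
      acc_res <- c(acc_res, res_idx[ok])
      acc_row <- c(acc_row, r[ok])
    }
  }
  acceptors <- data.frame(res = acc_res, row = acc_row)

  group_features <- function(spec_list) {
    res <- integer(0); label <- character(0)
    cx <- numeric(0); cy <- numeric(0); cz <- numeric(0)
    rows_list <- list()
    for (rn in intersect(names(spec_list), unique(rt$name))) {
      res_idx <- which(rt$name == rn)
      for (grp in spec_list[[rn]]) {
        for (r in res_idx) {
          rows <- lookup(rep(r, length(grp)), grp)
          if (anyNA(rows)) next
          cen <- colMeans(xyz[rows, , drop = FALSE])
          res <- c(res, r); label <- c(label, grp[1])
          cx <- c(cx, cen[1]); cy <- c(cy, cen[2]); cz <- c(cz, cen[3])
          rows_list[[length(rows_list) + 1L]] <- rows
        }
      }
    }
    list(df = data.frame(res = res, label = label, cx = cx, cy = cy,
                         cz = cz, stringsAsFactors = FALSE),
         rows = rows_list)
  }

  cat_feat <- group_features(chemistry$cations)
  ani_feat <- group_features(chemistry$anions)
  cations <- cat_feat$df
  anions <- ani_feat$df
  cat_rows <- cat_feat$rows
  ani_rows <- ani_feat$rows

  # chain termini: free amine at the first amino-acid residue of a chain;
  # carboxylate at the last when the terminal OXT atom is present.
  for (ch in unique(rt$chain)) {
    aa_idx <- which(rt$chain == ch & rt$polymer_class == "amino_acid")
    if (!length(aa_idx)) next
    first <- aa_idx[1]; last <- aa_idx[length(aa_idx)]
    nrow_ <- lookup(first, "N")
    if (!is.na(nrow_)) {
      cations <- rbind(cations, data.frame(
        res = first, label = "N", cx = xyz[nrow_, 1], cy = xyz[nrow_, 2],
        cz = xyz[nrow_, 3], stringsAsFactors = FALSE))
      cat_rows[[length(cat_rows) + 1L]] <- nrow_
    }
    oxt <- lookup(last, "OXT")
    if (!is.na(oxt)) {
      rows <- c(lookup(last, "O"), oxt)
      rows <- rows[!is.na(rows)]
      cen <- colMeans(xyz[rows, , drop = FALSE])
      anions <- rbind(anions, data.frame(
        res = last, label = "OXT", cx = cen[1], cy = cen[2], cz = cen[3],
        stringsAsFactors = FALSE))
      ani_rows[[length(ani_rows) + 1L]] <- rows
    }
  }

  # aromatic ring planes
  ring_res <- integer(0); ring_label <- character(0)
  ring_rows <- list()
  ring_cen <- matrix(numeric(0), ncol = 3)
  ring_nrm <- matrix(numeric(0), ncol = 3)
  for (rn in intersect(names(chemistry$rings), unique(rt$name))) {
    res_idx <- which(rt$name == rn)
    for (grp in chemistry$rings[[rn]]) {
      for (r in res_idx) {
        rows <- lookup(rep(r, length(grp)), grp)
        if (anyNA(rows)) next
        pl <- tryCatch(fit_ring_plane(xyz[rows, , drop = FALSE], grp),
                       error = function(e) NULL)
        if (is.null(pl)) next
        ring_res <- c(ring_res, r); ring_label <- c(ring_label, grp[1])
        ring_rows[[length(ring_rows) + 1L]] <- rows
        ring_cen <- rbind(ring_cen, pl$centroid)
        ring_nrm <- rbind(ring_nrm, pl$normal)
      }
    }
  }
  rings <- list(res = ring_res, label = ring_label, rows = ring_rows,
                centroid = ring_cen, normal = ring_nrm)

  # canonical rank of each residue under the residue-key total order
  rank <- integer(nrow(rt))
  rank[residue_key_order(rt$key)] <- seq_len(nrow(rt))

  list(atoms = a, xyz = xyz, ri = ri, rt = rt, rank = rank,
       donors = donors, acceptors = acceptors,
       cations = cations, anions = anions,
       cat_rows = cat_rows, ani_rows = ani_rows, rings = rings,
       has_h = any(toupper(a$element) == "H"))
}

# Re-evaluate the numeric side of a feature set (coordinates, group
# centroids, ring planes) for another state with an identical atom
# topology. Lets ensemble runs resolve chemistry once.
refresh_features <- function(f, state) {
  xyz <- as.matrix(state$atoms[, c("x", "y", "z")])
  f$xyz <- xyz
  group_centroids <- function(rows_list) {
    if (!length(rows_list)) return(matrix(numeric(0), ncol = 3))
    t(vapply(rows_list, function(rows)
      colMeans(xyz[rows, , drop = FALSE]), numeric(3)))
  }
  if (nrow(f$cations)) {
    cen <- group_centroids(f$cat_rows)
    f$cations$cx <- cen[, 1]; f$cations$cy <- cen[, 2]
    f$cations$cz <- cen[, 3]
  }
  if (nrow(f$anions)) {
    cen <- group_centroids(f$ani_rows)
    f$anions$cx <- cen[, 1]; f$anions$cy <- cen[, 2]
    f$anions$cz <- cen[, 3]
  }
  for (k in seq_along(f$rings$res)) {
    pl <- fit_ring_plane(xyz[f$rings$rows[[k]], , drop = FALSE])
    f$rings$centroid[k, ] <- pl$centroid
    f$rings$normal[k, ] <- pl$normal
  }
  f
}

# TRUE when two states have identical atom identities (so feature
# topology can be reused across them).
same_topology <- function(a, b) {
  identical(a$atoms$name, b$atoms$name) &&
    identical(a$atoms$chain, b$atoms$chain) &&
    identical(a$atoms$resno, b$atoms$resno) &&
    identical(a$atoms$insert, b$atoms$insert) &&
    identical(a$atoms$resname, b$atoms$resname)
}

# Sequence-separation gate: residues must differ, and within one chain
# their author numbers must differ by at least min_sep (insertion codes
# are not counted as separation).
pair_allowed <- function(f, res_i, res_j, min_sep) {
  same_res <- res_i == res_j
  same_chain <- f$rt$chain[res_i] == f$rt$chain[res_j]
  sep <- abs(f$rt$number[res_i] - f$rt$number[res_j])
  !same_res & (!same_chain | sep >= min_sep)
}

# Assemble canonically oriented edges (source precedes target under the
# residue-key total order; participating atoms swap along).
make_edges <- function(f, res_i, res_j, type, atom_i, atom_j,
                       distance, angle, state_index) {
  if (!length(res_i)) return(empty_edges())
  swap <- f$rank[res_i] > f$rank[res_j]
  si <- ifelse(swap, res_j, res_i)
  ti <- ifelse(swap, res_i, res_j)
  sa <- ifelse(swap, atom_j, atom_i)
  ta <- ifelse(swap, atom_i, atom_j)
  data.frame(source = f$rt$key[si], target = f$rt$key[ti], type = type,
             source_atom = sa, target_atom = ta,
             distance = distance, angle = angle,
             state_index = state_index, stringsAsFactors = FALSE)
}

# Keep the geometrically best (smallest-distance) instance per
# (source, target, type); deterministic tie-break on atom names.
dedup_edges <- function(edges, multi_edge = FALSE) {
  if (!nrow(edges)) return(edges)
  ord <- order(edges$source, edges$target, edges$type, edges$distance,
               edges$source_atom, edges$target_atom, method = "radix")
  edges <- edges[ord, , drop = FALSE]
  if (!multi_edge) {
    id <- paste(edges$source, edges$target, edges$type)
    edges <- edges[!duplicated(id), , drop = FALSE]
  }
  rownames(edges) <- NULL
  edges
}

# --- detectors -------------------------------------------------------------

#' Detect hydrogen bonds in one state
#'
#' A candidate is a donor heavy atom D and acceptor A with
#' `d(D, A) <= hbond_max_da` and angle(antecedent - D - A) `>=
#' hbond_min_angle`; when explicit hydrogens bonded to D are present the
#' D-H-A angle (best hydrogen) is gated instead. Per donor atom only the
#' closest admissible acceptor is kept, then the closest instance per
#' residue pair.
#'
#' @param state an `rin_state`.
#' @param criteria a [geometric_criteria()] object.
#' @param chemistry a [default_chemistry()] table.
#' @param features precomputed [state_features] (internal reuse).
#' @return edge data.frame (see [detect_interactions()]).
#' @export
detect_hbond <- function(state, criteria = geometric_criteria(),
                         chemistry = default_chemistry(),
                         features = NULL) {
  f <- features %||% state_features(state, chemistry)
  don <- f$donors; acc <- f$acceptors
  if (!nrow(don) || !nrow(acc)) return(empty_edges())
  np <- neighbor_pairs(f$xyz[don$row, , drop = FALSE],
                       f$xyz[acc$row, , drop = FALSE],
                       criteria$hbond_max_da)
  if (!nrow(np)) return(empty_edges())
  res_d <- don$res[np$i]; res_a <- acc$res[np$j]
  keep <- pair_allowed(f, res_d, res_a, criteria$min_seq_separation)
  np <- np[keep, , drop = FALSE]
  if (!nrow(np)) return(empty_edges())
  drow <- don$row[np$i]; arow <- acc$row[np$j]; antrow <- don$ant[np$i]
  ang <- angle_rows(f$xyz[antrow, , drop = FALSE],
                    f$xyz[drow, , drop = FALSE],
                    f$xyz[arow, , drop = FALSE])
  if (f$has_h) {
    # explicit hydrogens on a donor override the antecedent surrogate:
    # gate the best D-H-A angle instead
    h_rows <- which(toupper(f$atoms$element) == "H")
    for (k in seq_len(nrow(np))) {
      hs <- h_rows[f$ri[h_rows] == f$ri[drow[k]]]
      if (!length(hs)) next
      dh <- sqrt(rowSums((f$xyz[hs, , drop = FALSE] -
        matrix(f$xyz[drow[k], ], length(hs), 3, byrow = TRUE))^2))
      hs <- hs[dh <= 1.25]
      if (!length(hs)) next
      ang[k] <- max(angle_rows(
        matrix(f$xyz[drow[k], ], length(hs), 3, byrow = TRUE),
        f$xyz[hs, , drop = FALSE],
        matrix(f$xyz[arow[k], ], length(hs), 3, byrow = TRUE)))
    }
  }
  ok <- ang >= criteria$hbond_min_angle
  np <- np[ok, , drop = FALSE]; ang <- ang[ok]
  if (!nrow(np)) return(empty_edges())
  # per donor atom, keep the closest admissible acceptor
  ord <- order(np$i, np$distance, np$j)
  np <- np[ord, , drop = FALSE]; ang <- ang[ord]
  first <- !duplicated(np$i)
  np <- np[first, , drop = FALSE]; ang <- ang[first]
  edges <- make_edges(f, don$res[np$i], acc$res[np$j], "HBOND",
                      f$atoms$name[don$row[np$i]],
                      f$atoms$name[acc$row[np$j]],
                      np$distance, ang, state$index)
  dedup_edges(edges, criteria$multi_edge)
}

#' Detect ionic bonds (salt bridges) in one state
#'
#' Centroid of an anionic group within `ionic_max_dist` of the centroid
#' of a cationic group. Charged groups are sidechain carboxylates,
#' guanidinium/ammonium groups, nucleotide phosphates, and chain termini
#' when their atoms are present.
#'
#' @inheritParams detect_hbond
#' @return edge data.frame.
#' @export
detect_ionic <- function(state, criteria = geometric_criteria(),
                         chemistry = default_chemistry(),
                         features = NULL) {
  f <- features %||% state_features(state, chemistry)
  cats <- f$cations; anis <- f$anions
  if (!nrow(cats) || !nrow(anis)) return(empty_edges())
  np <- neighbor_pairs(as.matrix(cats[, c("cx", "cy", "cz")]),
                       as.matrix(anis[, c("cx", "cy", "cz")]),
                       criteria$ionic_max_dist)
  if (!nrow(np)) return(empty_edges())
  keep <- pair_allowed(f, cats$res[np$i], anis$res[np$j],
                       criteria$min_seq_separation)
  np <- np[keep, , drop = FALSE]
  edges <- make_edges(f, cats$res[np$i], anis$res[np$j], "IONIC",
                      cats$label[np$i], anis$label[np$j],
                      np$distance, NA_real_, state$index)
  dedup_edges(edges, criteria$multi_edge)
}

#' Detect pi-cation interactions in one state
#'
#' Cationic-group centroid within `pication_max_dist` of an aromatic ring
#' centroid, and within `pication_max_angle` degrees of the ring normal
#' as seen from the centroid (angle folded to \[0, 90\]).
#'
#' @inheritParams detect_hbond
#' @return edge data.frame.
#' @export
detect_pication <- function(state, criteria = geometric_criteria(),
                            chemistry = default_chemistry(),
                            features = NULL) {
  f <- features %||% state_features(state, chemistry)
  cats <- f$cations; rg <- f$rings
  if (!nrow(cats) || !length(rg$res)) return(empty_edges())
  np <- neighbor_pairs(as.matrix(cats[, c("cx", "cy", "cz")]),
                       rg$centroid, criteria$pication_max_dist)
  if (!nrow(np)) return(empty_edges())
  keep <- pair_allowed(f, cats$res[np$i], rg$res[np$j],
                       criteria$min_seq_separation)
  np <- np[keep, , drop = FALSE]
  if (!nrow(np)) return(empty_edges())
  dirs <- as.matrix(cats[np$i, c("cx", "cy", "cz")]) - rg$centroid[np$j, , drop = FALSE]
  ang <- vapply(seq_len(nrow(np)), function(k)
    folded_angle_deg(dirs[k, ], rg$normal[np$j[k], ]), numeric(1))
  ok <- ang <= criteria$pication_max_angle
  np <- np[ok, , drop = FALSE]; ang <- ang[ok]
  edges <- make_edges(f, cats$res[np$i], rg$res[np$j], "PICATION",
                      cats$label[np$i], rg$label[np$j],
                      np$distance, ang, state$index)
  dedup_edges(edges, criteria$multi_edge)
}

#' Detect pi-pi stacks in one state
#'
#' Two aromatic rings with centroid distance within `pipi_max_centroid`
#' and inter-plane angle (folded to \[0, 90\] degrees) either within
#' `pipi_max_planar_angle` of parallel or within the same tolerance of
#' perpendicular (T-shaped stack).
#'
#' @inheritParams detect_hbond
#' @return edge data.frame.
#' @export
detect_pipistack <- function(state, criteria = geometric_criteria(),
                             chemistry = default_chemistry(),
                             features = NULL) {
  f <- features %||% state_features(state, chemistry)
  rg <- f$rings
  if (length(rg$res) < 2) return(empty_edges())
  np <- neighbor_pairs(rg$centroid, rg$centroid, criteria$pipi_max_centroid)
  np <- np[np$i < np$j, , drop = FALSE]
  if (!nrow(np)) return(empty_edges())
  keep <- pair_allowed(f, rg$res[np$i], rg$res[np$j],
                       criteria$min_seq_separation)
  np <- np[keep, , drop = FALSE]
  if (!nrow(np)) return(empty_edges())
  ang <- vapply(seq_len(nrow(np)), function(k)
    folded_angle_deg(rg$normal[np$i[k], ], rg$normal[np$j[k], ]),
    numeric(1))
  ok <- ang <= criteria$pipi_max_planar_angle |
        ang >= 90 - criteria$pipi_max_planar_angle
  np <- np[ok, , drop = FALSE]; ang <- ang[ok]
  edges <- make_edges(f, rg$res[np$i], rg$res[np$j], "PIPISTACK",
                      rg$label[np$i], rg$label[np$j],
                      np$distance, ang, state$index)
  dedup_edges(edges, criteria$multi_edge)
}

#' Detect van der Waals contacts in one state
#'
#' Heavy-atom pairs with distance within the sum of element van der
#' Waals radii plus `vdw_slack`, excluding residue pairs already
#' explained by a hydrogen bond or ionic bond between the same pair.
#'
#' @inheritParams detect_hbond
#' @param exclude_pairs character vector of `"source|target"` residue-key
#'   pairs to suppress; computed from the state's own hydrogen/ionic
#'   bonds when `NULL`.
#' @return edge data.frame.
#' @export
detect_vdw <- function(state, criteria = geometric_criteria(),
                       chemistry = default_chemistry(),
                       features = NULL, exclude_pairs = NULL) {
  f <- features %||% state_features(state, chemistry)
  if (is.null(exclude_pairs)) {
    hb <- detect_hbond(state, criteria, chemistry, features = f)
    io <- detect_ionic(state, criteria, chemistry, features = f)
    exclude_pairs <- unique(c(paste(hb$source, hb$target, sep = "|"),
                              paste(io$source, io$target, sep = "|")))
  }
  heavy <- which(toupper(f$atoms$element) != "H")
  if (length(heavy) < 2) return(empty_edges())
  radii <- vdw_radius_of(f$atoms$element[heavy], chemistry)
  max_cut <- 2 * max(radii) + criteria$vdw_slack
  np <- neighbor_pairs(f$xyz[heavy, , drop = FALSE],
                       f$xyz[heavy, , drop = FALSE], max_cut)
  np <- np[np$i < np$j, , drop = FALSE]
  if (!nrow(np)) return(empty_edges())
  ok <- np$distance <= radii[np$i] + radii[np$j] + criteria$vdw_slack
  np <- np[ok, , drop = FALSE]
  if (!nrow(np)) return(empty_edges())
  res_i <- f$ri[heavy[np$i]]; res_j <- f$ri[heavy[np$j]]
  keep <- pair_allowed(f, res_i, res_j, criteria$min_seq_separation)
  np <- np[keep, , drop = FALSE]
  res_i <- res_i[keep]; res_j <- res_j[keep]
  edges <- make_edges(f, res_i, res_j, "VDW",
                      f$atoms$name[heavy[np$i]], f$atoms$name[heavy[np$j]],
                      np$distance, NA_real_, state$index)
  if (nrow(edges) && length(exclude_pairs)) {
    edges <- edges[!(paste(edges$source, edges$target, sep = "|") %in%
                       exclude_pairs), , drop = FALSE]
  }
  dedup_edges(edges, criteria$multi_edge)
}

#' Detect disulphide bonds in one state
#'
#' Cysteine SG-SG pairs within `ssbond_max_ss`; exempt from the
#' sequence-separation rule (but never within one residue).
#'
#' @inheritParams detect_hbond
#' @return edge data.frame.
#' @export
detect_ssbond <- function(state, criteria = geometric_criteria(),
                          chemistry = default_chemistry(),
                          features = NULL) {
  f <- features %||% state_features(state, chemistry)
  sg <- which(f$atoms$name == "SG" &
              f$rt$name[f$ri] == "CYS")
  if (length(sg) < 2) return(empty_edges())
  np <- neighbor_pairs(f$xyz[sg, , drop = FALSE],
                       f$xyz[sg, , drop = FALSE], criteria$ssbond_max_ss)
  np <- np[np$i < np$j, , drop = FALSE]
  if (!nrow(np)) return(empty_edges())
  res_i <- f$ri[sg[np$i]]; res_j <- f$ri[sg[np$j]]
  keep <- res_i != res_j
  np <- np[keep, , drop = FALSE]
  res_i <- res_i[keep]; res_j <- res_j[keep]
  edges <- make_edges(f, res_i, res_j, "SSBOND", "SG", "SG",
                      np$distance, NA_real_, state$index)
  dedup_edges(edges, criteria$multi_edge)
}

#' Detect all typed interactions in one state
#'
#' Runs every detector (hydrogen bond, ionic, pi-pi stack, pi-cation,
#' van der Waals, disulphide) and assembles the residue interaction
#' network of the state. Per residue pair and type only the
#' geometrically best (closest) instance is kept unless
#' `criteria$multi_edge` is set. Residue pairs closer in sequence than
#' `min_seq_separation` within one chain are excluded (disulphides
#' exempt). Residues with no typed chemistry participate only in van der
#' Waals contacts.
#'
#' @param state an `rin_state`.
#' @param criteria a [geometric_criteria()] object.
#' @param chemistry a [default_chemistry()] table.
#' @param warn_unknown logical; warn once about residue names without
#'   typed chemistry.
#' @param features precomputed [state_features] for this state
#'   (internal reuse across ensemble states).
#' @return object of class `rin_network`: list with `state_index`,
#'   `nodes` (all residue keys of the state, in residue order) and
#'   `edges` (data.frame with columns `source`, `target`, `type`,
#'   `source_atom`, `target_atom`, `distance`, `angle`, `state_index`).
#' @export
#' @examples
#' sb <- make_salt_bridge()$ensemble
#' detect_interactions(sb$states[[1]])$edges
detect_interactions <- function(state, criteria = geometric_criteria(),
                                chemistry = default_chemistry(),
                                warn_unknown = FALSE, features = NULL) {
  f <- features %||% state_features(state, chemistry,
                                    warn_unknown = warn_unknown)
  hb <- detect_hbond(state, criteria, chemistry, features = f)
  io <- detect_ionic(state, criteria, chemistry, features = f)
  pp <- detect_pipistack(state, criteria, chemistry, features = f)
  pc <- detect_pication(state, criteria, chemistry, features = f)
  ss <- detect_ssbond(state, criteria, chemistry, features = f)
  excl <- unique(c(paste(hb$source, hb$target, sep = "|"),
                   paste(io$source, io$target, sep = "|")))
  vw <- detect_vdw(state, criteria, chemistry, features = f,
                   exclude_pairs = excl)
  edges <- rbind(hb, io, pp, pc, vw, ss)
  edges <- dedup_edges(edges, multi_edge = TRUE)  # already unique per type
  new_network(state$index, f$rt$key, edges)
}

#' Detect interactions for every state of an ensemble
#'
#' @param ensemble an `rin_ensemble`.
#' @inheritParams detect_interactions
#' @return list of `rin_network`, one per state, in state order.
#' @export
network_for_ensemble <- function(ensemble, criteria = geometric_criteria(),
                                 chemistry = default_chemistry()) {
  states <- ensemble$states
  shared <- all(vapply(states, same_topology, logical(1),
                       b = states[[1]]))
  if (!shared) {
    return(lapply(states, detect_interactions, criteria = criteria,
                  chemistry = chemistry))
  }
  # identical atom topology across states: resolve chemistry once and
  # only re-evaluate coordinates per state
  f0 <- state_features(states[[1]], chemistry)
  lapply(states, function(st)
    detect_interactions(st, criteria, chemistry,
                        features = refresh_features(f0, st)))
}

#' Filter a network by chain scope and interaction types
#'
#' @param network an `rin_network`.
#' @param scope `"all"`, `"intra_chain"` or `"inter_chain"`.
#' @param types subset of interaction types to keep (default: all).
#' @return filtered `rin_network`; nodes pruned to edge endpoints.
#' @export
filter_network <- function(network,
                           scope = c("all", "intra_chain", "inter_chain"),
                           types = INTERACTION_TYPES) {
  scope <- match.arg(scope)
  e <- network$edges
  e <- e[e$type %in% types, , drop = FALSE]
  if (scope != "all" && nrow(e)) {
    same <- parse_residue_key(e$source)$chain ==
            parse_residue_key(e$target)$chain
    e <- e[if (scope == "intra_chain") same else !same, , drop = FALSE]
  }
  rownames(e) <- NULL
  nodes <- network$nodes[network$nodes %in% c(e$source, e$target)]
  new_network(network$state_index, nodes, e)
}

# --- writers ---------------------------------------------------------------

#' Write edge lists to a TSV file
#'
#' Tab-separated columns: NodeId1, Interaction, NodeId2, Atom1, Atom2,
#' Distance, Angle, State.
#'
#' @param networks one `rin_network` or a list of them.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_edges_tsv <- function(networks, path) {
  if (inherits(networks, "rin_network")) networks <- list(networks)
  e <- do.call(rbind, c(lapply(networks, `[[`, "edges"),
                        list(empty_edges())))
  out <- data.frame(NodeId1 = e$source, Interaction = e$type,
                    NodeId2 = e$target, Atom1 = e$source_atom,
                    Atom2 = e$target_atom,
                    Distance = round(e$distance, 3),
                    Angle = round(e$angle, 1), State = e$state_index)
  write_tsv(out, path)
  invisible(path)
}

#' Write node lists to a TSV file
#'
#' One row per residue per state with its chain and per-type degree.
#'
#' @inheritParams write_edges_tsv
#' @return invisibly, `path`.
#' @export
write_nodes_tsv <- function(networks, path) {
  if (inherits(networks, "rin_network")) networks <- list(networks)
  rows <- lapply(networks, function(net) {
    deg <- sapply(INTERACTION_TYPES, function(tp) {
      e <- net$edges[net$edges$type == tp, , drop = FALSE]
      tab <- table(factor(c(e$source, e$target), levels = net$nodes))
      as.integer(tab)
    })
    if (!length(net$nodes)) return(NULL)
    deg <- matrix(deg, nrow = length(net$nodes),
                  dimnames = list(NULL, INTERACTION_TYPES))
    data.frame(ResidueKey = net$nodes,
               Chain = parse_residue_key(net$nodes)$chain,
               State = net$state_index, deg,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(ResidueKey = character(0), Chain = character(0),
                      State = integer(0))
  }
  write_tsv(out, path)
  invisible(path)
}
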