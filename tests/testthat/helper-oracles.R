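# Independent oracle implementations used to verify the package's
# detectors and kernels. These deliberately avoid the package's candidate
# generation (cell lists, feature tables): candidates come from dense
# all-pairs distance matrices and chemistry is re-resolved with plain
# per-residue loops, so implementation and oracle share only the written
# rule and the chemistry reference tables.

# --- brute-force neighbor search ------------------------------------------

brute_neighbor_pairs <- function(a, b, cutoff) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!nrow(a) || !nrow(b)) {
    return(data.frame(i = integer(0), j = integer(0),
                      distance = numeric(0)))
  }
  d2 <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  hit <- which(d2 <= cutoff^2 + 1e-12, arr.ind = TRUE)
  ord <- order(hit[, 1], hit[, 2])
  data.frame(i = as.integer(hit[ord, 1]), j = as.integer(hit[ord, 2]),
             distance = sqrt(d2[hit][ord]))
}

# --- oracle chemistry resolution ------------------------------------------

oracle_features <- function(state, chemistry) {
  a <- state$atoms
  rt <- residue_table(state)
  n <- nrow(rt)
  res_atoms <- vector("list", n)
  id <- paste(a$chain, a$resno, a$insert, a$resname, sep = "\r")
  rid <- paste(rt$chain, rt$number, rt$insertion, rt$name, sep = "\r")
  for (r in seq_len(n)) res_atoms[[r]] <- which(id == rid[r])
  get_xyz <- function(r, name) {
    rows <- res_atoms[[r]]
    hit <- rows[a$name[rows] == name]
    if (length(hit) != 1) return(NULL)
    c(a$x[hit], a$y[hit], a$z[hit])
  }
  donors <- list(); acceptors <- list()
  cations <- list(); anions <- list(); rings <- list()
  for (r in seq_len(n)) {
    rn <- rt$name[r]
    dsp <- chemistry$donors[[rn]]
    if (!is.null(dsp)) {
      for (k in seq_along(dsp)) {
        dz <- get_xyz(r, names(dsp)[k]); az <- get_xyz(r, dsp[[k]])
        if (!is.null(dz) && !is.null(az)) {
          donors[[length(donors) + 1]] <-
            list(res = r, name = names(dsp)[k], xyz = dz, ant = az)
        }
      }
    }
    for (nm in chemistry$acceptors[[rn]]) {
      az <- get_xyz(r, nm)
      if (!is.null(az)) {
        acceptors[[length(acceptors) + 1]] <-
          list(res = r, name = nm, xyz = az)
      }
    }
    grab_groups <- function(groups) {
      out <- list()
      for (grp in groups) {
        pts <- lapply(grp, function(nm) get_xyz(r, nm))
        if (any(vapply(pts, is.null, logical(1)))) next
        out[[length(out) + 1]] <-
          list(res = r, name = grp[1],
               centroid = colMeans(do.call(rbind, pts)),
               coords = do.call(rbind, pts))
      }
      out
    }
    cations <- c(cations, grab_groups(chemistry$cations[[rn]]))
    anions <- c(anions, grab_groups(chemistry$anions[[rn]]))
    for (g in grab_groups(chemistry$rings[[rn]])) {
      ctr <- colMeans(g$coords)
      sv <- svd(sweep(g$coords, 2, ctr))
      g$normal <- sv$v[, 3]
      rings[[length(rings) + 1]] <- g
    }
  }
  # chain termini, same written rule as the detector documentation
  for (ch in unique(rt$chain)) {
    aa <- which(rt$chain == ch & rt$polymer_class == "amino_acid")
    if (!length(aa)) next
    nz <- get_xyz(aa[1], "N")
    if (!is.null(nz)) {
      cations[[length(cations) + 1]] <-
        list(res = aa[1], name = "N", centroid = nz)
    }
    last <- aa[length(aa)]
    oxt <- get_xyz(last, "OXT")
    if (!is.null(oxt)) {
      o <- get_xyz(last, "O")
      pts <- rbind(oxt, if (!is.null(o)) o)
      anions[[length(anions) + 1]] <-
        list(res = last, name = "OXT", centroid = colMeans(pts))
    }
  }
  rank <- integer(n)
  rank[order(rt$chain, rt$number, rt$insertion, rt$name,
             method = "radix")] <- seq_len(n)
  list(rt = rt, atoms = a, res_atoms = res_atoms, rank = rank,
       donors = donors, acceptors = acceptors, cations = cations,
       anions = anions, rings = rings)
}

oracle_pair_ok <- function(rt, ri, rj, min_sep) {
  if (ri == rj) return(FALSE)
  if (rt$chain[ri] != rt$chain[rj]) return(TRUE)
  abs(rt$number[ri] - rt$number[rj]) >= min_sep
}

oracle_angle <- function(a, b, c_) {
  u <- a - b; v <- c_ - b
  acos(max(-1, min(1, sum(u * v) / sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
}

oracle_fold <- function(u, v) {
  acos(min(1, abs(sum(u * v) / sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
}

# Canonical edge orientation + per-(pair, type) minimum-distance pruning.
oracle_edge_frame <- function(f, rows) {
  if (!length(rows)) {
    return(data.frame(source = character(0), target = character(0),
                      type = character(0), distance = numeric(0),
                      stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, lapply(rows, function(e) {
    i <- e$ri; j <- e$rj
    if (f$rank[i] > f$rank[j]) { tmp <- i; i <- j; j <- tmp }
    data.frame(source = f$rt$key[i], target = f$rt$key[j], type = e$type,
               distance = e$distance, stringsAsFactors = FALSE)
  }))
  df <- df[order(df$source, df$target, df$type, df$distance,
                 method = "radix"), , drop = FALSE]
  df <- df[!duplicated(paste(df$source, df$target, df$type)), , drop = FALSE]
  rownames(df) <- NULL
  df
}

oracle_hbond <- function(state, crit, chem, f = oracle_features(state, chem)) {
  rows <- list()
  if (length(f$donors) && length(f$acceptors)) {
    dm <- t(vapply(f$donors, `[[`, numeric(3), "xyz"))
    am <- t(vapply(f$acceptors, `[[`, numeric(3), "xyz"))
    antm <- t(vapply(f$donors, `[[`, numeric(3), "ant"))
    dres <- vapply(f$donors, function(e) as.integer(e$res), integer(1))
    ares <- vapply(f$acceptors, function(e) as.integer(e$res), integer(1))
    d2 <- outer(rowSums(dm^2), rowSums(am^2), `+`) - 2 * tcrossprod(dm, am)
    d2[d2 < 0] <- 0
    allowed <- outer(dres, ares, `!=`) &
      (outer(f$rt$chain[dres], f$rt$chain[ares], `!=`) |
         abs(outer(f$rt$number[dres], f$rt$number[ares], `-`)) >=
           crit$min_seq_separation)
    hit <- which(allowed & d2 <= crit$hbond_max_da^2 + 1e-12,
                 arr.ind = TRUE)
    if (nrow(hit)) {
      ang <- vapply(seq_len(nrow(hit)), function(k)
        oracle_angle(antm[hit[k, 1], ], dm[hit[k, 1], ],
                     am[hit[k, 2], ]), numeric(1))
      hit <- hit[ang >= crit$hbond_min_angle, , drop = FALSE]
    }
    if (nrow(hit)) {
      dist <- sqrt(d2[hit])
      ordk <- order(hit[, 1], dist, hit[, 2])
      hit <- hit[ordk, , drop = FALSE]
      dist <- dist[ordk]
      first <- !duplicated(hit[, 1])     # best acceptor per donor
      hit <- hit[first, , drop = FALSE]
      dist <- dist[first]
      rows <- lapply(seq_len(nrow(hit)), function(k)
        list(ri = dres[hit[k, 1]], rj = ares[hit[k, 2]], type = "HBOND",
             distance = dist[k]))
    }
  }
  oracle_edge_frame(f, rows)
}

oracle_ionic <- function(state, crit, chem, f = oracle_features(state, chem)) {
  rows <- list()
  for (ca in f$cations) {
    for (an in f$anions) {
      if (!oracle_pair_ok(f$rt, ca$res, an$res, crit$min_seq_separation)) next
      dist <- sqrt(sum((ca$centroid - an$centroid)^2))
      if (dist <= crit$ionic_max_dist + 1e-12) {
        rows[[length(rows) + 1]] <-
          list(ri = ca$res, rj = an$res, type = "IONIC", distance = dist)
      }
    }
  }
  oracle_edge_frame(f, rows)
}

oracle_pipistack <- function(state, crit, chem,
                             f = oracle_features(state, chem)) {
  rows <- list()
  rg <- f$rings
  if (length(rg) >= 2) {
    for (i in seq_len(length(rg) - 1)) {
      for (j in (i + 1):length(rg)) {
        if (!oracle_pair_ok(f$rt, rg[[i]]$res, rg[[j]]$res,
                            crit$min_seq_separation)) next
        dist <- sqrt(sum((rg[[i]]$centroid - rg[[j]]$centroid)^2))
        if (dist > crit$pipi_max_centroid + 1e-12) next
        ang <- oracle_fold(rg[[i]]$normal, rg[[j]]$normal)
        if (ang <= crit$pipi_max_planar_angle ||
            ang >= 90 - crit$pipi_max_planar_angle) {
          rows[[length(rows) + 1]] <-
            list(ri = rg[[i]]$res, rj = rg[[j]]$res, type = "PIPISTACK",
                 distance = dist)
        }
      }
    }
  }
  oracle_edge_frame(f, rows)
}

oracle_pication <- function(state, crit, chem,
                            f = oracle_features(state, chem)) {
  rows <- list()
  for (ca in f$cations) {
    for (rg in f$rings) {
      if (!oracle_pair_ok(f$rt, ca$res, rg$res,
                          crit$min_seq_separation)) next
      dist <- sqrt(sum((ca$centroid - rg$centroid)^2))
      if (dist > crit$pication_max_dist + 1e-12) next
      if (oracle_fold(ca$centroid - rg$centroid, rg$normal) >
          crit$pication_max_angle) next
      rows[[length(rows) + 1]] <-
        list(ri = ca$res, rj = rg$res, type = "PICATION", distance = dist)
    }
  }
  oracle_edge_frame(f, rows)
}

oracle_vdw <- function(state, crit, chem, f = oracle_features(state, chem)) {
  a <- f$atoms
  heavy <- which(toupper(a$element) != "H")
  xyz <- as.matrix(a[heavy, c("x", "y", "z")])
  rad <- unname(chem$vdw_radii[toupper(a$element[heavy])])
  rad[is.na(rad)] <- chem$vdw_default
  ri <- integer(nrow(a))
  for (r in seq_along(f$res_atoms)) ri[f$res_atoms[[r]]] <- r
  ri <- ri[heavy]
  d2 <- outer(rowSums(xyz^2), rowSums(xyz^2), `+`) - 2 * tcrossprod(xyz)
  d2[d2 < 0] <- 0
  lim <- outer(rad, rad, `+`) + crit$vdw_slack
  hit <- which(upper.tri(d2) & d2 <= lim^2 + 1e-12, arr.ind = TRUE)
  excl <- rbind(oracle_hbond(state, crit, chem, f),
                oracle_ionic(state, crit, chem, f))
  excl_id <- paste(excl$source, excl$target)
  rows <- list()
  for (k in seq_len(nrow(hit))) {
    i <- hit[k, 1]; j <- hit[k, 2]
    if (!oracle_pair_ok(f$rt, ri[i], ri[j], crit$min_seq_separation)) next
    ii <- ri[i]; jj <- ri[j]
    if (f$rank[ii] > f$rank[jj]) { tmp <- ii; ii <- jj; jj <- tmp }
    if (paste(f$rt$key[ii], f$rt$key[jj]) %in% excl_id) next
    rows[[length(rows) + 1]] <-
      list(ri = ri[i], rj = ri[j], type = "VDW", distance = sqrt(d2[i, j]))
  }
  oracle_edge_frame(f, rows)
}

oracle_ssbond <- function(state, crit, chem,
                          f = oracle_features(state, chem)) {
  a <- f$atoms
  sg <- which(a$name == "SG")
  sg <- sg[vapply(sg, function(k) {
    r <- which(vapply(f$res_atoms, function(rows) k %in% rows, logical(1)))
    f$rt$name[r] == "CYS"
  }, logical(1))]
  rows <- list()
  if (length(sg) >= 2) {
    for (u in seq_len(length(sg) - 1)) {
      for (v in (u + 1):length(sg)) {
        i <- sg[u]; j <- sg[v]
        dist <- sqrt((a$x[i] - a$x[j])^2 + (a$y[i] - a$y[j])^2 +
                     (a$z[i] - a$z[j])^2)
        if (dist > crit$ssbond_max_ss + 1e-12) next
        ri <- which(vapply(f$res_atoms, function(rows) i %in% rows,
                           logical(1)))
        rj <- which(vapply(f$res_atoms, function(rows) j %in% rows,
                           logical(1)))
        if (ri == rj) next
        rows[[length(rows) + 1]] <-
          list(ri = ri, rj = rj, type = "SSBOND", distance = dist)
      }
    }
  }
  oracle_edge_frame(f, rows)
}

# Comparable canonical form of an edge frame.
edge_set <- function(edges) {
  df <- data.frame(source = edges$source, target = edges$target,
                   type = edges$type, distance = edges$distance,
                   stringsAsFactors = FALSE)
  df <- df[order(df$source, df$target, df$type, method = "radix"), ]
  rownames(df) <- NULL
  df
}

expect_edges_match_oracle <- function(impl, oracle) {
  a <- edge_set(impl)
  b <- edge_set(oracle)
  expect_identical(a[, c("source", "target", "type")],
                   b[, c("source", "target", "type")])
  expect_equal(a$distance, b$distance, tolerance = 1e-8)
}

# --- naive agglomerative clustering ---------------------------------------

# Straightforward agglomerative clustering on a distance matrix with
# list-of-members bookkeeping; returns merge heights (ascending) and the
# flat partition at a cutoff (merges strictly below the cutoff join).
naive_agglomerative <- function(d, method = "average", cutoff = Inf) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  labels <- seq_len(n)
  linkdist <- function(a, b) {
    vals <- d[a, b, drop = FALSE]
    switch(method, average = mean(vals), complete = max(vals),
           single = min(vals))
  }
  while (length(clusters) > 1) {
    best <- NULL
    for (p in seq_len(length(clusters) - 1)) {
      for (q in (p + 1):length(clusters)) {
        h <- linkdist(clusters[[p]], clusters[[q]])
        if (is.null(best) || h < best$h) best <- list(p = p, q = q, h = h)
      }
    }
    heights <- c(heights, best$h)
    if (best$h < cutoff) {
      labels[clusters[[best$q]]] <- labels[clusters[[best$p]]][1]
    }
    clusters[[best$p]] <- c(clusters[[best$p]], clusters[[best$q]])
    clusters[[best$q]] <- NULL
  }
  list(heights = heights, partition = match(labels, unique(labels)))
}

# Label-invariant partition comparison.
same_partition <- function(a, b) {
  identical(match(a, unique(a)), match(b, unique(b)))
}
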