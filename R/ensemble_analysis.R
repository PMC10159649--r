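# Multi-state statistics over per-state interaction networks: edge
# frequencies, probabilistic contact maps, contact-count matrices and
# Pearson contact correlations across states.

check_networks <- function(networks) {
  if (inherits(networks, "rin_network")) networks <- list(networks)
  if (!length(networks)) stop("at least one network is required")
  nodes <- networks[[1]]$nodes
  for (net in networks[-1]) {
    if (!identical(net$nodes, nodes))
      stop("all networks must share the ensemble's residue ordering")
  }
  networks
}

scope_edges <- function(net, type_scope) {
  e <- net$edges
  if (!identical(type_scope, "all")) {
    e <- e[e$type %in% type_scope, , drop = FALSE]
  }
  e
}

#' Edge frequencies across an ensemble
#'
#' One row per distinct (source, target, type) edge observed in any
#' state; `count` is the number of states containing it and
#' `frequency = count / n_states`. High frequencies mark stable
#' contacts; intermediate ones mark dynamic contacts.
#'
#' @param networks list of `rin_network` (one per state).
#' @return data.frame of class `rin_edge_freq` with columns `source`,
#'   `target`, `type`, `count`, `frequency`, sorted by decreasing
#'   frequency then key order; attribute `n_states`.
#' @export
#' @examples
#' nets <- network_for_ensemble(make_salt_bridge(n_states = 3)$ensemble)
#' edge_frequencies(nets)
edge_frequencies <- function(networks) {
  networks <- check_networks(networks)
  n <- length(networks)
  all_edges <- do.call(rbind, c(lapply(networks, `[[`, "edges"),
                                list(empty_edges())))
  if (!nrow(all_edges)) {
    out <- data.frame(source = character(0), target = character(0),
                      type = character(0), count = integer(0),
                      frequency = numeric(0))
  } else {
    id <- paste(all_edges$source, all_edges$target, all_edges$type,
                sep = "\t")
    tab <- table(id)
    parts <- strsplit(names(tab), "\t", fixed = TRUE)
    out <- data.frame(
      source = vapply(parts, `[`, character(1), 1L),
      target = vapply(parts, `[`, character(1), 2L),
      type = vapply(parts, `[`, character(1), 3L),
      count = as.integer(tab), stringsAsFactors = FALSE)
    out$frequency <- out$count / n
    out <- out[order(-out$frequency, out$source, out$target, out$type), ]
    rownames(out) <- NULL
  }
  attr(out, "n_states") <- n
  class(out) <- c("rin_edge_freq", class(out))
  out
}

#' Filter an edge-frequency table by frequency band
#'
#' Keeps rows with `min_freq <= frequency <= max_freq` (both ends
#' inclusive). Setting `max_freq` just below 1 filters out contacts that
#' never change across the ensemble.
#'
#' @param table result of [edge_frequencies()].
#' @param min_freq,max_freq frequency band, `0 <= min <= max <= 1`.
#' @return filtered table (same class and attributes).
#' @export
frequency_filter <- function(table, min_freq = 0, max_freq = 1) {
  if (min_freq > max_freq) stop("min_freq must not exceed max_freq")
  if (min_freq < 0 || max_freq > 1) stop("frequencies lie in [0, 1]")
  keep <- table$frequency >= min_freq & table$frequency <= max_freq
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_states") <- attr(table, "n_states")
  out
}

#' Probabilistic contact map
#'
#' Square matrix over all residues (fixed ensemble order); entry (i, j)
#' is the fraction of states in which residues i and j share at least
#' one edge of the requested scope. Symmetric with zero diagonal.
#'
#' @param networks list of `rin_network`.
#' @param type_scope `"all"` or a subset of interaction types.
#' @return numeric matrix with residue-key dimnames; attribute
#'   `type_scope`.
#' @export
contact_probability_map <- function(networks, type_scope = "all") {
  networks <- check_networks(networks)
  nodes <- networks[[1]]$nodes
  n <- length(nodes)
  p <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (net in networks) {
    e <- scope_edges(net, type_scope)
    if (!nrow(e)) next
    i <- match(e$source, nodes)
    j <- match(e$target, nodes)
    pair <- unique(cbind(pmin(i, j), pmax(i, j)))
    p[pair] <- p[pair] + 1
  }
  p <- p / length(networks)
  p <- p + t(p)
  diag(p) <- 0
  attr(p, "type_scope") <- type_scope
  p
}

#' Contact-count matrix
#'
#' One row per sequence position (residue, fixed ensemble order) and one
#' column per state; each entry counts the edges of the requested scope
#' incident to that residue in that state, so each edge contributes to
#' both endpoint rows and every column sums to twice the state's edge
#' count.
#'
#' @inheritParams contact_probability_map
#' @param binary logical; record edge presence (0/1 per incident
#'   position) instead of counts.
#' @return integer matrix, rows named by residue key, columns `S0...`.
#' @export
contact_count_matrix <- function(networks, type_scope = "all",
                                 binary = FALSE) {
  networks <- check_networks(networks)
  nodes <- networks[[1]]$nodes
  cc <- matrix(0L, length(nodes), length(networks),
               dimnames = list(nodes,
                               paste0("S", vapply(networks, `[[`,
                                                  integer(1), "state_index"))))
  for (k in seq_along(networks)) {
    e <- scope_edges(networks[[k]], type_scope)
    if (!nrow(e)) next
    tab <- table(factor(c(e$source, e$target), levels = nodes))
    cc[, k] <- as.integer(tab)
  }
  if (binary) cc <- (cc > 0L) * 1L
  cc
}

#' Edge-presence matrix
#'
#' Binary matrix with one row per distinct edge (over the whole
#' ensemble) and one column per state; the edge-level substrate for
#' contact correlations.
#'
#' @param networks list of `rin_network`.
#' @return 0/1 integer matrix, rows named `"source|target|type"`.
#' @export
edge_presence_matrix <- function(networks) {
  networks <- check_networks(networks)
  freq <- edge_frequencies(networks)
  ids <- paste(freq$source, freq$target, freq$type, sep = "|")
  m <- matrix(0L, length(ids), length(networks),
              dimnames = list(ids, paste0("S", seq_along(networks) - 1L)))
  for (k in seq_along(networks)) {
    e <- networks[[k]]$edges
    here <- paste(e$source, e$target, e$type, sep = "|")
    m[ids %in% here, k] <- 1L
  }
  m
}

#' Pearson contact correlations across states
#'
#' Correlates the per-position contact-count series across states for
#' every position pair. Positions whose counts never vary carry no
#' correlation information: such pairs are flagged `defined = FALSE`
#' with `r = NA` rather than silently reported as zero. Fewer than
#' three states leaves every pair undefined.
#'
#' @param counts matrix from [contact_count_matrix()] (or
#'   [edge_presence_matrix()] for edge-level correlations): rows are
#'   positions, columns are states.
#' @return data.frame of class `rin_correlation` with columns
#'   `position_i`, `position_j`, `r`, `n_states`, `defined`, one row per
#'   unordered pair (i < j in row order).
#' @export
contact_correlation <- function(counts) {
  n_pos <- nrow(counts)
  n_st <- ncol(counts)
  labels <- rownames(counts) %||% as.character(seq_len(n_pos))
  idx <- which(upper.tri(matrix(0, n_pos, n_pos)), arr.ind = TRUE)
  out <- data.frame(position_i = labels[idx[, 1]],
                    position_j = labels[idx[, 2]],
                    r = NA_real_, n_states = n_st,
                    defined = FALSE, stringsAsFactors = FALSE)
  if (n_st >= 3) {
    v <- apply(counts, 1, stats::var)
    ok_pair <- v[idx[, 1]] > 0 & v[idx[, 2]] > 0
    if (any(ok_pair)) {
      cm <- suppressWarnings(stats::cor(t(counts[v > 0, , drop = FALSE])))
      pos <- match(seq_len(n_pos), which(v > 0))
      ri <- pos[idx[ok_pair, 1]]
      rj <- pos[idx[ok_pair, 2]]
      out$r[ok_pair] <- cm[cbind(ri, rj)]
      out$defined[ok_pair] <- TRUE
    }
  }
  class(out) <- c("rin_correlation", class(out))
  out
}

#' Ranked correlation report
#'
#' Defined rows sorted by decreasing absolute correlation (ties broken
#' by lexicographic position order), filtered by sign, truncated to the
#' top `k`.
#'
#' @param table result of [contact_correlation()].
#' @param top_k maximum rows to return.
#' @param sign `"both"`, `"positive"` or `"negative"`.
#' @return the ranked, truncated data.frame.
#' @export
correlation_report <- function(table, top_k = 20,
                               sign = c("both", "positive", "negative")) {
  sign <- match.arg(sign)
  if (!nrow(table)) stop("empty correlation table")
  t <- table[table$defined, , drop = FALSE]
  t <- switch(sign,
              both = t,
              positive = t[t$r > 0, , drop = FALSE],
              negative = t[t$r < 0, , drop = FALSE])
  t <- t[order(-abs(t$r), t$position_i, t$position_j), , drop = FALSE]
  out <- utils::head(t, top_k)
  rownames(out) <- NULL
  out
}

#' Per-edge presence trajectories
#'
#' The time-dependent network trajectory: for each distinct edge, its
#' 0/1 presence across states in time order.
#'
#' @param networks list of `rin_network`.
#' @return data.frame with `edge` id and one `S<k>` column per state.
#' @export
edge_trajectories <- function(networks) {
  m <- edge_presence_matrix(networks)
  data.frame(edge = rownames(m), m, check.names = FALSE,
             stringsAsFactors = FALSE)
}

# --- writers ---------------------------------------------------------------

#' Write an edge-frequency table to TSV
#' @param table result of [edge_frequencies()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_frequencies_tsv <- function(table, path) {
  write_tsv(as.data.frame(table), path)
  invisible(path)
}

#' Write a contact-probability map to TSV
#'
#' Dense numeric matrix with residue keys as row and column headers.
#'
#' @param map result of [contact_probability_map()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_probability_map_tsv <- function(map, path) {
  df <- data.frame(ResidueKey = rownames(map), map, check.names = FALSE)
  write_tsv(df, path)
  invisible(path)
}

#' Write a correlation table to TSV, sorted by |r|
#' @param table result of [contact_correlation()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_correlations_tsv <- function(table, path) {
  t <- table[order(!table$defined, -abs(table$r)), , drop = FALSE]
  write_tsv(as.data.frame(t), path)
  invisible(path)
}
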