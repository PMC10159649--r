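# Internal helpers shared across modules.

#' Format residue keys
#'
#' A residue key is the canonical string `"chain:number[insertion]:name"`
#' identifying one residue, e.g. `"A:42:LYS"` or `"B:100A:GLY"`. Keys
#' round-trip losslessly through [parse_residue_key()].
#'
#' @param chain chain identifier(s).
#' @param number author residue number(s), integer.
#' @param insertion insertion code(s), `""` when absent.
#' @param name residue name(s) (3-letter amino-acid or nucleotide code).
#' @return character vector of keys.
#' @export
#' @examples
#' format_residue_key("A", 42, "", "LYS")
format_residue_key <- function(chain, number, insertion, name) {
  insertion[is.na(insertion)] <- ""
  paste0(chain, ":", number, insertion, ":", name)
}

#' Parse residue keys
#'
#' @param key character vector of keys produced by [format_residue_key()].
#' @return data.frame with columns `chain`, `number`, `insertion`, `name`.
#' @export
parse_residue_key <- function(key) {
  parts <- strsplit(key, ":", fixed = TRUE)
  bad <- vapply(parts, length, integer(1)) != 3L
  if (any(bad)) {
    stop("malformed residue key: ", key[bad][1])
  }
  chain <- vapply(parts, `[`, character(1), 1L)
  mid <- vapply(parts, `[`, character(1), 2L)
  name <- vapply(parts, `[`, character(1), 3L)
  number <- as.integer(sub("^(-?[0-9]+).*$", "\\1", mid))
  insertion <- sub("^-?[0-9]+", "", mid)
  data.frame(chain = chain, number = number, insertion = insertion,
             name = name, stringsAsFactors = FALSE)
}

# Total order on residue keys: (chain, number, insertion, name).
# Returns the order() permutation of `key`.
residue_key_order <- function(key) {
  p <- parse_residue_key(key)
  order(p$chain, p$number, p$insertion, p$name, method = "radix")
}

# TRUE where key a precedes key b under the canonical total order.
residue_key_lt <- function(a, b) {
  pa <- parse_residue_key(a)
  pb <- parse_residue_key(b)
  lt <- rep(FALSE, length(a))
  for (i in seq_along(a)) {
    x <- c(pa$chain[i], pa$number[i], pa$insertion[i], pa$name[i])
    y <- c(pb$chain[i], pb$number[i], pb$insertion[i], pb$name[i])
    if (x[1] != y[1]) { lt[i] <- x[1] < y[1]; next }
    if (pa$number[i] != pb$number[i]) { lt[i] <- pa$number[i] < pb$number[i]; next }
    if (x[3] != y[3]) { lt[i] <- x[3] < y[3]; next }
    lt[i] <- x[4] < y[4]
  }
  lt
}

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

vec_norm <- function(v) sqrt(sum(v * v))

unit <- function(v) v / vec_norm(v)

# Angle at vertex b of the triangle a-b-c, degrees in [0, 180].
angle_deg <- function(a, b, c) {
  u <- a - b
  v <- c - b
  cosang <- sum(u * v) / (vec_norm(u) * vec_norm(v))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

# Angle between two direction vectors folded to [0, 90] degrees
# (sign of either vector is immaterial).
folded_angle_deg <- function(u, v) {
  cosang <- abs(sum(u * v) / (vec_norm(u) * vec_norm(v)))
  acos(pmin(1, cosang)) * 180 / pi
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
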