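# Geometry kernel: cell-list neighbor search, least-squares ring planes,
# Kabsch superposition. Everything works on plain n x 3 coordinate
# matrices in Angstrom.

#' Neighbor pairs within a distance cutoff
#'
#' Finds all pairs (i, j) with `coords_a[i, ]` within `cutoff` of
#' `coords_b[j, ]` using a uniform spatial grid (cell list) with cell edge
#' equal to the cutoff, so only the 27 neighboring cells of each point are
#' scanned. Expected linear time in the number of atoms for typical
#' molecular densities; exactly equivalent to the quadratic all-pairs scan.
#'
#' @param coords_a,coords_b numeric matrices with 3 columns (Angstrom).
#' @param cutoff positive distance cutoff in Angstrom (inclusive).
#' @return data.frame with columns `i`, `j`, `distance`, sorted by
#'   `(i, j)`. Empty inputs yield an empty frame.
#' @export
#' @examples
#' a <- rbind(c(0, 0, 0))
#' b <- rbind(c(3, 0, 0), c(10, 0, 0))
#' neighbor_pairs(a, b, 3.5)
neighbor_pairs <- function(coords_a, coords_b, cutoff) {
  if (cutoff <= 0) stop("cutoff must be > 0")
  empty <- data.frame(i = integer(0), j = integer(0), distance = numeric(0))
  coords_a <- as_coord_matrix(coords_a)
  coords_b <- as_coord_matrix(coords_b)
  na <- nrow(coords_a)
  nb <- nrow(coords_b)
  if (na == 0 || nb == 0) return(empty)

  if (na * nb <= 4096) {
    # small problem: the dense scan beats grid bookkeeping
    d2 <- outer(rowSums(coords_a^2), rowSums(coords_b^2), `+`) -
      2 * tcrossprod(coords_a, coords_b)
    d2[d2 < 0] <- 0
    hit <- which(d2 <= cutoff^2 + 1e-12)
    if (!length(hit)) return(empty)
    i <- ((hit - 1L) %% na) + 1L
    j <- ((hit - 1L) %/% na) + 1L
    ord <- order(i, j)
    return(data.frame(i = i[ord], j = j[ord],
                      distance = sqrt(d2[hit][ord])))
  }

  cell_a <- floor(coords_a / cutoff)
  cell_b <- floor(coords_b / cutoff)
  # affine integer encoding of grid cells (padded so +-1 offsets stay
  # inside the coding range)
  lo <- pmin(apply(cell_a, 2, min), apply(cell_b, 2, min)) - 1
  hi <- pmax(apply(cell_a, 2, max), apply(cell_b, 2, max)) + 1
  span <- hi - lo + 1
  encode <- function(m) {
    (m[, 1] - lo[1]) + span[1] * ((m[, 2] - lo[2]) +
                                    span[2] * (m[, 3] - lo[3]))
  }
  key_a <- encode(cell_a)
  key_b <- encode(cell_b)
  ub <- sort(unique(key_b))
  buckets <- split(seq_len(nb), factor(key_b, levels = ub))
  is <- vector("list", 27L)
  js <- vector("list", 27L)
  o <- 0L
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    o <- o + 1L
    shift <- dx + span[1] * (dy + span[2] * dz)
    bi <- match(key_a + shift, ub)
    sel <- which(!is.na(bi))
    if (!length(sel)) next
    hit <- buckets[bi[sel]]
    is[[o]] <- rep.int(sel, lengths(hit))
    js[[o]] <- unlist(hit, use.names = FALSE)
  }
  i <- unlist(is, use.names = FALSE)
  j <- unlist(js, use.names = FALSE)
  if (!length(i)) return(empty)
  d2 <- (coords_a[i, 1] - coords_b[j, 1])^2 +
        (coords_a[i, 2] - coords_b[j, 2])^2 +
        (coords_a[i, 3] - coords_b[j, 3])^2
  keep <- d2 <= cutoff^2 + 1e-12
  i <- i[keep]; j <- j[keep]; d <- sqrt(d2[keep])
  ord <- order(i, j)
  data.frame(i = i[ord], j = j[ord], distance = d[ord])
}

as_coord_matrix <- function(x) {
  if (is.null(x) || length(x) == 0) return(matrix(numeric(0), ncol = 3))
  x <- as.matrix(x)
  if (ncol(x) != 3) stop("coordinates must have 3 columns")
  storage.mode(x) <- "double"
  x
}

#' Least-squares plane through a ring of atoms
#'
#' Fits the total-least-squares plane through at least three non-collinear
#' points (singular value decomposition of the centered coordinates; the
#' normal is the right singular vector of the smallest singular value).
#' The normal's sign is fixed deterministically: positive dot product with
#' +z, falling back to +y then +x when orthogonal, so downstream angles
#' are reproducible. All pi-stack angles are folded to \[0, 90\] degrees,
#' making the sign convention immaterial to detection results.
#'
#' @param coords numeric matrix, >= 3 rows x 3 columns (Angstrom).
#' @param member_atom_names optional character vector of atom names.
#' @return object of class `rin_plane`: list with `centroid` (3-vector),
#'   `normal` (unit 3-vector) and `member_atom_names`.
#' @export
#' @examples
#' hexagon <- t(sapply(0:5, function(k)
#'   c(cos(k * pi / 3), sin(k * pi / 3), 0)))
#' fit_ring_plane(hexagon)$normal
fit_ring_plane <- function(coords, member_atom_names = NULL) {
  coords <- as_coord_matrix(coords)
  if (nrow(coords) < 3) stop("ring plane needs >= 3 points")
  centroid <- colMeans(coords)
  centered <- sweep(coords, 2, centroid)
  s <- svd(centered)
  # collinear/degenerate: second singular value vanishes relative to first
  if (s$d[2] < 1e-8 * max(s$d[1], 1e-12)) {
    stop("degenerate (collinear) ring coordinates: plane undefined")
  }
  normal <- s$v[, 3]
  normal <- normal / vec_norm(normal)
  for (axis in list(c(0, 0, 1), c(0, 1, 0), c(1, 0, 0))) {
    dp <- sum(normal * axis)
    if (abs(dp) > 1e-9) {
      if (dp < 0) normal <- -normal
      break
    }
  }
  structure(list(centroid = centroid, normal = normal,
                 member_atom_names = member_atom_names),
            class = "rin_plane")
}

#' Kabsch superposition
#'
#' Optimal least-squares rigid superposition of two paired point sets.
#' Returns the proper rotation `R` (no reflection) and translation `t`
#' minimizing the root-mean-square deviation of `R %*% y + t` against
#' `x` over all rows, together with the minimal RMSD.
#'
#' @param x,y numeric matrices, n x 3 with the same n >= 3; row i of `y`
#'   is paired with row i of `x`.
#' @return object of class `rin_transform`: list with `rotation` (3 x 3,
#'   `det = +1`), `translation` (3-vector) and `rmsd` (Angstrom).
#' @export
#' @examples
#' x <- matrix(rnorm(30), ncol = 3)
#' kabsch(x, x)$rmsd
kabsch <- function(x, y) {
  x <- as_coord_matrix(x)
  y <- as_coord_matrix(y)
  if (nrow(x) != nrow(y)) stop("point sets must have equal size")
  if (nrow(x) < 3) stop("superposition needs >= 3 points")
  cx <- colMeans(x)
  cy <- colMeans(y)
  xc <- sweep(x, 2, cx)
  yc <- sweep(y, 2, cy)
  h <- crossprod(yc, xc)             # 3x3 covariance t(yc) %*% xc
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  trans <- cx - as.vector(rot %*% cy)
  fitted <- yc %*% t(rot)
  rmsd <- sqrt(mean(rowSums((xc - fitted)^2)))
  structure(list(rotation = rot, translation = trans, rmsd = rmsd),
            class = "rin_transform")
}

#' Apply a rigid transform to coordinates
#'
#' @param transform object from [kabsch()].
#' @param coords n x 3 coordinate matrix.
#' @return transformed n x 3 matrix.
#' @export
apply_transform <- function(transform, coords) {
  coords <- as_coord_matrix(coords)
  sweep(coords %*% t(transform$rotation), 2, transform$translation, `+`)
}
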