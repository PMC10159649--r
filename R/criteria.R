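#' Geometric criteria for interaction detection
#'
#' Bundles the distance and angle thresholds used by the typed-interaction
#' detectors. All thresholds are plain geometric gates on heavy-atom
#' coordinates; none require hydrogens (explicit hydrogens refine the
#' hydrogen-bond angle test when present). Defaults follow common
#' geometric-rule practice for residue interaction networks and every
#' value can be overridden.
#'
#' @param hbond_max_da maximum donor-acceptor heavy-atom distance
#'   (Angstrom) for a hydrogen bond.
#' @param hbond_min_angle minimum angle (degrees) at the donor between its
#'   covalent antecedent and the acceptor; when an explicit hydrogen on the
#'   donor is present the donor-H-acceptor angle is gated instead.
#' @param ionic_max_dist maximum distance (Angstrom) between the centroids
#'   of a cationic and an anionic group.
#' @param pipi_max_centroid maximum aromatic ring centroid-centroid
#'   distance (Angstrom).
#' @param pipi_max_planar_angle maximum deviation (degrees) from parallel
#'   (or, symmetrically, from perpendicular for T-shaped stacks) of the two
#'   ring planes; the inter-plane angle is folded to \[0, 90\] degrees.
#' @param pication_max_dist maximum cation-to-ring-centroid distance
#'   (Angstrom).
#' @param pication_max_angle maximum angle (degrees) between the ring
#'   normal and the centroid-to-cation direction.
#' @param vdw_slack distance slack (Angstrom) added to the sum of van der
#'   Waals radii.
#' @param ssbond_max_ss maximum S-S distance (Angstrom) for a disulphide.
#' @param min_seq_separation minimum residue-number separation within one
#'   chain; pairs closer in sequence are not reported (disulphides exempt).
#' @param multi_edge logical; keep every geometric instance per residue
#'   pair and type instead of only the closest one.
#' @return object of class `rin_criteria` (a validated named list).
#' @export
#' @examples
#' crit <- geometric_criteria(hbond_max_da = 3.2)
#' crit$hbond_max_da
geometric_criteria <- function(hbond_max_da = 3.5,
                               hbond_min_angle = 90,
                               ionic_max_dist = 4.0,
                               pipi_max_centroid = 6.5,
                               pipi_max_planar_angle = 30,
                               pication_max_dist = 5.0,
                               pication_max_angle = 45,
                               vdw_slack = 0.5,
                               ssbond_max_ss = 2.5,
                               min_seq_separation = 2,
                               multi_edge = FALSE) {
  crit <- list(hbond_max_da = hbond_max_da,
               hbond_min_angle = hbond_min_angle,
               ionic_max_dist = ionic_max_dist,
               pipi_max_centroid = pipi_max_centroid,
               pipi_max_planar_angle = pipi_max_planar_angle,
               pication_max_dist = pication_max_dist,
               pication_max_angle = pication_max_angle,
               vdw_slack = vdw_slack,
               ssbond_max_ss = ssbond_max_ss,
               min_seq_separation = as.integer(min_seq_separation),
               multi_edge = isTRUE(multi_edge))
  dists <- c("hbond_max_da", "ionic_max_dist", "pipi_max_centroid",
             "pication_max_dist", "ssbond_max_ss")
  for (d in dists) {
    if (!is.numeric(crit[[d]]) || crit[[d]] <= 0)
      stop("criteria: ", d, " must be a positive distance")
  }
  if (crit$vdw_slack < 0) stop("criteria: vdw_slack must be >= 0")
  for (a in c("hbond_min_angle", "pipi_max_planar_angle", "pication_max_angle")) {
    if (crit[[a]] < 0 || crit[[a]] > 180)
      stop("criteria: ", a, " must lie in [0, 180] degrees")
  }
  if (crit$min_seq_separation < 1)
    stop("criteria: min_seq_separation must be >= 1")
  structure(crit, class = "rin_criteria")
}

#' @export
print.rin_criteria <- function(x, ...) {
  cat("Geometric interaction criteria:\n")
  for (nm in setdiff(names(x), "multi_edge")) {
    cat(sprintf("  %-22s %s\n", nm, format(x[[nm]])))
  }
  cat(sprintf("  %-22s %s\n", "multi_edge", x$multi_edge))
  invisible(x)
}

# All interaction type labels, in canonical report order.
INTERACTION_TYPES <- c("HBOND", "IONIC", "PIPISTACK", "PICATION",
                       "VDW", "SSBOND")
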