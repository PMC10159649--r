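# Synthetic structure generators with known ground truth. These power
# the test suite: every geometric claim a test makes is built into the
# generated coordinates (placed at 0.85x the active cutoff when an
# interaction is "on" and at 2x when "off"), so the suite stays valid
# when criteria defaults change. All randomness flows through an
# explicit seed; geometry-only fixtures are fully deterministic.

element_from_name <- function(name) {
  first <- toupper(substr(gsub("[^A-Za-z].*$", "", name), 1, 1))
  ifelse(first %in% c("C", "N", "O", "S", "P", "H"), first, "C")
}

# Assemble an rin_state from residue descriptions: a list of lists with
# fields chain, resno, resname, atoms (named list: atom name -> 3-vector).
fx_state <- function(residues, index = 0L) {
  n_at <- vapply(residues, function(r) length(r$atoms), integer(1))
  name <- unlist(lapply(residues, function(r) names(r$atoms)),
                 use.names = FALSE)
  xyz <- do.call(rbind, lapply(residues, function(r)
    do.call(rbind, unname(r$atoms))))
  atoms <- data.frame(
    serial = seq_along(name), name = name, altloc = "",
    resname = rep(vapply(residues, `[[`, character(1), "resname"), n_at),
    chain = rep(vapply(residues, `[[`, character(1), "chain"), n_at),
    resno = rep(vapply(residues, function(r) as.integer(r$resno),
                       integer(1)), n_at),
    insert = "", element = element_from_name(name), occupancy = 1,
    is_hetero = FALSE, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    stringsAsFactors = FALSE)
  atoms$polymer_class <- polymer_class_of(atoms$resname)
  new_state(atoms, index)
}

rand_unit <- function() {
  repeat {
    v <- stats::rnorm(3)
    n <- vec_norm(v)
    if (n > 1e-6) return(v / n)
  }
}

# Planar ring of n atoms around `center` with the given unit `normal`.
ring_coords <- function(center, normal, n = 6, radius = 1.39, phase = 0) {
  normal <- unit(normal)
  ref <- if (abs(normal[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- unit(ref - sum(ref * normal) * normal)
  e2 <- c(normal[2] * e1[3] - normal[3] * e1[2],
          normal[3] * e1[1] - normal[1] * e1[3],
          normal[1] * e1[2] - normal[2] * e1[1])
  t(sapply(seq_len(n) - 1, function(k) {
    a <- phase + 2 * pi * k / n
    center + radius * (cos(a) * e1 + sin(a) * e2)
  }))
}

# --- NeRF backbone building ------------------------------------------------

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Natural extension reference frame: place atom D from A-B-C with the
# given bond length |CD|, bond angle B-C-D and dihedral A-B-C-D.
nerf_place <- function(a, b, c_, bond, angle, dihedral) {
  ang <- angle * pi / 180
  dih <- dihedral * pi / 180
  bc <- unit(c_ - b)
  nv <- unit(cross3(b - a, bc))
  m <- cbind(bc, cross3(nv, bc), nv)
  d_local <- c(-bond * cos(ang), bond * sin(ang) * cos(dih),
               bond * sin(ang) * sin(dih))
  as.vector(c_ + m %*% d_local)
}

# Ideal peptide backbone with fixed (phi, psi, omega); returns a list of
# per-residue coordinate lists (N, CA, C, O).
build_backbone <- function(n_res, phi, psi, omega = 180) {
  b_n_ca <- 1.458; b_ca_c <- 1.525; b_c_n <- 1.329; b_c_o <- 1.231
  a_n_ca_c <- 111.2; a_ca_c_n <- 116.2; a_c_n_ca <- 121.7; a_ca_c_o <- 120.8
  res <- vector("list", n_res)
  n1 <- c(0, 0, 0); ca1 <- c(b_n_ca, 0, 0)
  c1 <- nerf_place(c(-1, 1, 0), n1, ca1, b_ca_c, a_n_ca_c, phi)
  res[[1]] <- list(N = n1, CA = ca1, C = c1)
  for (i in seq_len(n_res)[-1]) {
    prev <- res[[i - 1]]
    ni <- nerf_place(prev$N, prev$CA, prev$C, b_c_n, a_ca_c_n, psi)
    cai <- nerf_place(prev$CA, prev$C, ni, b_n_ca, a_c_n_ca, omega)
    ci <- nerf_place(prev$C, ni, cai, b_ca_c, a_n_ca_c, phi)
    res[[i]] <- list(N = ni, CA = cai, C = ci)
  }
  for (i in seq_len(n_res)) {
    r <- res[[i]]
    res[[i]]$O <- nerf_place(r$N, r$CA, r$C, b_c_o, a_ca_c_o, psi + 180)
  }
  res
}

# --- fixture generators ----------------------------------------------------

#' Ideal alpha-helix fixture
#'
#' Backbone-only (N, CA, C, O) polyalanine helix built from ideal
#' peptide geometry at (phi, psi) = (-57, -47) degrees, placing every
#' N(i+4)...O(i) donor-acceptor pair near 3.1 Angstrom, inside the
#' default hydrogen-bond cutoff. Deterministic (no randomness).
#'
#' The ground truth lists the alpha-helical (i, i+4) hydrogen bonds for
#' all admissible i, plus two N-terminal boundary contacts: in this
#' geometry N(3)...O(1) (3.37 A) and N(4)...O(1) (3.21 A) both satisfy
#' the distance and donor-angle rule, and neither donor has a closer
#' acceptor (interior donors prefer their 3.09 A (i, i+4) partner), so
#' the helix start genuinely carries two tighter-turn hydrogen bonds
#' under the default criteria.
#'
#' @param n_res number of residues, >= 6.
#' @return list with `ensemble` (1 state) and `truth`: `hbond_pairs`
#'   (two-column matrix of residue numbers) and `helical_pairs` (the
#'   (i, i+4) subset).
#' @export
make_ideal_helix <- function(n_res = 18) {
  if (n_res < 6) stop("an ideal helix fixture needs >= 6 residues")
  bb <- build_backbone(n_res, phi = -57, psi = -47)
  residues <- lapply(seq_len(n_res), function(i)
    list(chain = "A", resno = i, resname = "ALA", atoms = bb[[i]]))
  state <- fx_state(residues)
  helical <- cbind(seq_len(n_res - 4), seq_len(n_res - 4) + 4)
  truth <- list(
    helical_pairs = helical,
    hbond_pairs = rbind(c(1, 3), c(1, 4), helical)
  )
  list(ensemble = new_ensemble(list(state)), truth = truth)
}

#' Salt-bridge fixture
#'
#' A lysine ammonium group facing a glutamate carboxylate, with the
#' cation-to-anion-centroid distance placed at `distance` (default
#' 0.85x the ionic cutoff: inside the rule).
#'
#' @param distance NZ-to-carboxylate-centroid distance in Angstrom;
#'   `NULL` for 0.85x `criteria$ionic_max_dist`.
#' @param criteria a [geometric_criteria()] object.
#' @param n_states number of identical states to replicate (handy for
#'   frequency arithmetic tests).
#' @return list with `ensemble` (1 state) and `truth` (`pair` of
#'   residue keys, `distance`).
#' @export
make_salt_bridge <- function(distance = NULL,
                             criteria = geometric_criteria(),
                             n_states = 1) {
  d <- distance %||% (0.85 * criteria$ionic_max_dist)
  residues <- salt_bridge_residues(origin = c(0, 0, 0), d = d)
  states <- lapply(seq_len(n_states) - 1L, function(k)
    fx_state(residues, k))
  list(ensemble = new_ensemble(states),
       truth = list(pair = c("A:1:LYS", "A:3:GLU"), distance = d))
}

salt_bridge_residues <- function(origin, d, chain = "A", resno = c(1, 3)) {
  list(
    list(chain = chain, resno = resno[1], resname = "LYS", atoms = list(
      CA = origin + c(0, 8, 0),
      CE = origin + c(-1.5, 0, 0),
      NZ = origin)),
    list(chain = chain, resno = resno[2], resname = "GLU", atoms = list(
      CA = origin + c(d, 8, 0),
      CD = origin + c(d + 1.25, 0, 0),
      OE1 = origin + c(d, 1.1, 0),
      OE2 = origin + c(d, -1.1, 0)))
  )
}

#' Stacked aromatic rings fixture
#'
#' Two phenylalanine rings with a set centroid-centroid distance and
#' inter-plane angle (0 = parallel stack; 90 = T-shaped).
#'
#' @param centroid_dist centroid separation in Angstrom; `NULL` for
#'   0.85x `criteria$pipi_max_centroid`.
#' @param plane_angle inter-plane angle in degrees.
#' @param criteria a [geometric_criteria()] object.
#' @return list with `ensemble` and `truth`.
#' @export
make_stacked_rings <- function(centroid_dist = NULL, plane_angle = 0,
                               criteria = geometric_criteria()) {
  d <- centroid_dist %||% (0.85 * criteria$pipi_max_centroid)
  residues <- stacked_ring_residues(c(0, 0, 0), d, plane_angle)
  list(ensemble = new_ensemble(list(fx_state(residues))),
       truth = list(pair = c("A:1:PHE", "A:3:PHE"), distance = d,
                    plane_angle = plane_angle))
}

stacked_ring_residues <- function(origin, d, plane_angle = 0,
                                  chain = "A", resno = c(1, 3)) {
  ring_names <- c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")
  nrm2 <- c(sin(plane_angle * pi / 180), 0, cos(plane_angle * pi / 180))
  r1 <- ring_coords(origin, c(0, 0, 1))
  r2 <- ring_coords(origin + c(0, 0, d), nrm2)
  as_atoms <- function(m) {
    a <- lapply(seq_len(6), function(k) m[k, ])
    names(a) <- ring_names
    a
  }
  a1 <- as_atoms(r1); a1$CA <- origin + c(0, 8, 0)
  a2 <- as_atoms(r2); a2$CA <- origin + c(0, 8, d)
  list(list(chain = chain, resno = resno[1], resname = "PHE", atoms = a1),
       list(chain = chain, resno = resno[2], resname = "PHE", atoms = a2))
}

#' Pi-cation fixture
#'
#' A lysine ammonium nitrogen placed at a set distance from a
#' phenylalanine ring centroid and at a set angle from the ring normal
#' (0 = directly above the ring face).
#'
#' @param distance NZ-to-centroid distance; `NULL` for 0.85x
#'   `criteria$pication_max_dist`.
#' @param angle_from_normal degrees off the ring normal.
#' @param criteria a [geometric_criteria()] object.
#' @return list with `ensemble` and `truth`.
#' @export
make_pication_pair <- function(distance = NULL, angle_from_normal = 0,
                               criteria = geometric_criteria()) {
  d <- distance %||% (0.85 * criteria$pication_max_dist)
  th <- angle_from_normal * pi / 180
  ring_names <- c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")
  r1 <- ring_coords(c(0, 0, 0), c(0, 0, 1))
  a1 <- lapply(seq_len(6), function(k) r1[k, ])
  names(a1) <- ring_names
  a1$CA <- c(0, 8, 0)
  nz <- c(d * sin(th), 0, d * cos(th))
  residues <- list(
    list(chain = "A", resno = 1, resname = "PHE", atoms = a1),
    list(chain = "A", resno = 3, resname = "LYS", atoms = list(
      CA = nz + c(0, 8, 0), CE = nz + c(0, 0, 1.5), NZ = nz)))
  list(ensemble = new_ensemble(list(fx_state(residues))),
       truth = list(pair = c("A:1:PHE", "A:3:LYS"), distance = d,
                    angle_from_normal = angle_from_normal))
}

#' Two-basin conformational ensemble
#'
#' Each state is one of two reference conformations plus iid Gaussian
#' coordinate noise. The base conformation is a 20-residue CA trace;
#' the second basin displaces alternating residues by `basin_shift`
#' in opposite directions -- an internal deformation that rigid
#' superposition cannot remove, so the pairwise RMSD between basins
#' stays close to `basin_shift` while within-basin RMSD scales with
#' `noise_sd`.
#'
#' @param n_states number of states, >= 2.
#' @param basin_shift deformation amplitude (Angstrom) between basins.
#' @param noise_sd per-coordinate Gaussian noise (Angstrom).
#' @param switch_script integer vector (1/2) of basin labels per state;
#'   `NULL` for first half / second half.
#' @param seed RNG seed.
#' @param n_res residues in the CA trace.
#' @return list with `ensemble` and `truth` (`labels`, plus the two
#'   reference coordinate matrices).
#' @export
make_two_basin_ensemble <- function(n_states, basin_shift = 6,
                                    noise_sd = 0.3, switch_script = NULL,
                                    seed = 1, n_res = 20) {
  if (n_states < 2) stop("a two-basin ensemble needs >= 2 states")
  if (basin_shift <= 0) stop("basin_shift must be > 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  labels <- switch_script %||%
    rep(1:2, c(ceiling(n_states / 2), floor(n_states / 2)))
  if (length(labels) != n_states)
    stop("switch_script length must equal n_states")
  bb <- build_backbone(n_res, phi = -57, psi = -47)
  base <- t(vapply(bb, `[[`, numeric(3), "CA"))
  alt <- base
  alt[, 1] <- alt[, 1] + basin_shift * rep_len(c(1, -1), n_res)
  refs <- list(base, alt)
  states <- with_seed(seed, lapply(seq_len(n_states), function(k) {
    xyz <- refs[[labels[k]]] +
      matrix(stats::rnorm(3 * n_res, sd = noise_sd), n_res, 3)
    residues <- lapply(seq_len(n_res), function(i)
      list(chain = "A", resno = i, resname = "ALA",
           atoms = list(CA = xyz[i, ])))
    fx_state(residues, k - 1L)
  }))
  list(ensemble = new_ensemble(states),
       truth = list(labels = labels, basin_refs = refs))
}

#' Scripted-contact ensemble
#'
#' Three independent interaction modules in one chain -- a salt bridge
#' (LYS 1 / GLU 3), a parallel pi-pi stack (PHE 5 / PHE 7) and a
#' sidechain hydrogen bond (SER 9 / ASN 11) -- each switched on or off
#' per state by a script. "On" places the pair at 0.85x its cutoff,
#' "off" at 2x, so the detected typed edges equal the script exactly.
#' Modules are separated by 60 Angstrom and never interact with each
#' other.
#'
#' @param script logical matrix, `n_states` rows and columns named among
#'   `"ionic"`, `"pipi"`, `"hbond"`.
#' @param criteria a [geometric_criteria()] object.
#' @return list with `ensemble` and `truth`: per-state expected typed
#'   edges (`edges[[state]]`: data.frame source, target, type), the
#'   `script`, and `module_keys` (residue keys per module).
#' @export
make_scripted_contact_ensemble <- function(script,
                                           criteria = geometric_criteria()) {
  script <- as.matrix(script)
  if (!nrow(script)) stop("script must have at least one state")
  if (is.null(colnames(script)) ||
      !all(colnames(script) %in% c("ionic", "pipi", "hbond")))
    stop("script columns must be named among ionic, pipi, hbond")
  mode(script) <- "logical"
  n <- nrow(script)
  on_d <- list(ionic = 0.85 * criteria$ionic_max_dist,
               pipi = 0.85 * criteria$pipi_max_centroid,
               hbond = 0.85 * criteria$hbond_max_da)
  off_d <- list(ionic = 2 * criteria$ionic_max_dist,
                pipi = 2 * criteria$pipi_max_centroid,
                hbond = 2 * criteria$hbond_max_da)
  module_keys <- list(ionic = c("A:1:LYS", "A:3:GLU"),
                      pipi = c("A:5:PHE", "A:7:PHE"),
                      hbond = c("A:9:SER", "A:11:ASN"))
  module_type <- c(ionic = "IONIC", pipi = "PIPISTACK", hbond = "HBOND")
  states <- vector("list", n)
  truth_edges <- vector("list", n)
  for (k in seq_len(n)) {
    residues <- list()
    expected <- list()
    for (mod in colnames(script)) {
      on <- script[k, mod]
      d <- if (on) on_d[[mod]] else off_d[[mod]]
      origin <- switch(mod, ionic = c(0, 0, 0), pipi = c(60, 0, 0),
                       hbond = c(120, 0, 0))
      residues <- c(residues, switch(
        mod,
        ionic = salt_bridge_residues(origin, d),
        pipi = stacked_ring_residues(origin, d, resno = c(5, 7)),
        hbond = hbond_pair_residues(origin, d)))
      if (on) {
        expected[[mod]] <- data.frame(source = module_keys[[mod]][1],
                                      target = module_keys[[mod]][2],
                                      type = module_type[[mod]],
                                      stringsAsFactors = FALSE)
      }
    }
    # keep chain numbering order stable regardless of script column order
    ord <- order(vapply(residues, function(r) as.numeric(r$resno),
                        numeric(1)))
    states[[k]] <- fx_state(residues[ord], k - 1L)
    truth_edges[[k]] <- if (length(expected)) {
      e <- do.call(rbind, expected)
      e[order(e$source, e$target), , drop = FALSE]
    } else {
      data.frame(source = character(0), target = character(0),
                 type = character(0))
    }
  }
  list(ensemble = new_ensemble(states),
       truth = list(edges = truth_edges, script = script,
                    module_keys = module_keys))
}

hbond_pair_residues <- function(origin, d, chain = "A", resno = c(9, 11)) {
  list(
    list(chain = chain, resno = resno[1], resname = "SER", atoms = list(
      CA = origin + c(0, 8, 0),
      CB = origin + c(-1.4, 0, 0),
      OG = origin)),
    list(chain = chain, resno = resno[2], resname = "ASN", atoms = list(
      CA = origin + c(d, 8, 0),
      CG = origin + c(d + 1.25, 0.6, 0),
      OD1 = origin + c(d, 0, 0)))
  )
}

#' Random decoy state
#'
#' A dense random arrangement of residues with full typed chemistry
#' (charged sidechains, aromatic rings, donors/acceptors, a cysteine
#' pool), used to exercise every detector against exhaustive
#' rule-evaluation oracles. Residue centers are uniform in a cubic box;
#' sidechain groups get plausible local geometry with random
#' orientation. Two chains (A, B) so inter-chain edges occur.
#'
#' @param n_res number of residues.
#' @param seed RNG seed.
#' @param box box edge in Angstrom (density control).
#' @return an `rin_state`.
#' @export
make_decoy_state <- function(n_res = 200, seed = 1, box = 40) {
  pool <- c("ALA", "LYS", "ARG", "ASP", "GLU", "PHE", "TYR", "HIS",
            "TRP", "SER", "THR", "ASN", "GLN", "CYS", "MET", "GLY")
  with_seed(seed, {
    types <- sample(pool, n_res, replace = TRUE)
    residues <- lapply(seq_len(n_res), function(i) {
      ctr <- stats::runif(3, 0, box)
      atoms <- decoy_sidechain(types[i], ctr)
      # backbone around the center
      ca <- ctr
      n_ <- ca + rand_unit() * 1.46
      c_ <- ca + rand_unit() * 1.53
      o_ <- c_ + rand_unit() * 1.23
      atoms <- c(list(N = n_, CA = ca, C = c_, O = o_), atoms)
      chain <- if (i <= ceiling(n_res / 2)) "A" else "B"
      resno <- if (chain == "A") i else i - ceiling(n_res / 2)
      list(chain = chain, resno = resno, resname = types[i], atoms = atoms)
    })
    fx_state(residues)
  })
}

decoy_sidechain <- function(type, ctr) {
  u <- rand_unit()
  ring_atoms <- function(names6, center, phase = 0) {
    m <- ring_coords(center, rand_unit(), n = length(names6),
                     radius = if (length(names6) == 6) 1.39 else 1.17,
                     phase = phase)
    a <- lapply(seq_along(names6), function(k) m[k, ])
    names(a) <- names6
    a
  }
  switch(type,
    LYS = { ce <- ctr + u * 2.5; list(CE = ce, NZ = ce + rand_unit() * 1.49) },
    ARG = {
      cz <- ctr + u * 3
      list(CD = cz + rand_unit() * 2.4, CZ = cz,
           NE = cz + rand_unit() * 1.33, NH1 = cz + rand_unit() * 1.33,
           NH2 = cz + rand_unit() * 1.33)
    },
    ASP = {
      cg <- ctr + u * 1.8
      v <- rand_unit()
      list(CG = cg, OD1 = cg + v * 1.25,
           OD2 = cg + rand_unit() * 1.25)
    },
    GLU = {
      cd <- ctr + u * 2.4
      list(CD = cd, OE1 = cd + rand_unit() * 1.25,
           OE2 = cd + rand_unit() * 1.25)
    },
    PHE = ring_atoms(c("CG", "CD1", "CE1", "CZ", "CE2", "CD2"),
                     ctr + u * 2.4),
    TYR = {
      a <- ring_atoms(c("CG", "CD1", "CE1", "CZ", "CE2", "CD2"),
                      ctr + u * 2.4)
      a$OH <- a$CZ + rand_unit() * 1.38
      a
    },
    HIS = ring_atoms(c("CG", "ND1", "CE1", "NE2", "CD2"), ctr + u * 2.2),
    TRP = {
      five <- ring_atoms(c("CG", "CD1", "NE1", "CE2", "CD2"), ctr + u * 2.2)
      six <- ring_atoms(c("CE3", "CZ3", "CH2", "CZ2"), ctr + u * 2.2 +
                          rand_unit() * 2.1)
      # complete the 6-ring with the shared CD2/CE2 edge
      c(five, six)
    },
    SER = { cb <- ctr + u * 1.5; list(CB = cb, OG = cb + rand_unit() * 1.42) },
    THR = { cb <- ctr + u * 1.5; list(CB = cb, OG1 = cb + rand_unit() * 1.42) },
    ASN = {
      cg <- ctr + u * 1.9
      list(CG = cg, OD1 = cg + rand_unit() * 1.23,
           ND2 = cg + rand_unit() * 1.33)
    },
    GLN = {
      cd <- ctr + u * 2.4
      list(CD = cd, OE1 = cd + rand_unit() * 1.23,
           NE2 = cd + rand_unit() * 1.33)
    },
    CYS = { cb <- ctr + u * 1.5; list(CB = cb, SG = cb + rand_unit() * 1.81) },
    MET = list(SD = ctr + u * 2.5),
    list()
  )
}
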