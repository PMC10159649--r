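# Structure input/output: multi-model PDB and mmCIF files are read into a
# uniform in-memory ensemble (ordered states, each a flat atom table).
# File parsing and PDB writing are delegated to bio3d; this module
# normalizes altlocs, waters and residue identity on top of it.

WATER_NAMES <- c("HOH", "WAT", "DOD")

new_state <- function(atoms, index = 0L) {
  stopifnot(is.data.frame(atoms))
  rownames(atoms) <- NULL
  structure(list(index = as.integer(index), atoms = atoms),
            class = "rin_state")
}

new_ensemble <- function(states, source_path = NA_character_,
                         format = NA_character_) {
  if (length(states) < 1) stop("an ensemble needs at least one state")
  for (i in seq_along(states)) states[[i]]$index <- i - 1L
  structure(list(states = states, source_path = source_path,
                 format = format),
            class = "rin_ensemble")
}

#' Number of states in an ensemble
#' @param ensemble an `rin_ensemble`.
#' @return integer count of states.
#' @export
n_states <- function(ensemble) length(ensemble$states)

#' @export
print.rin_state <- function(x, ...) {
  rt <- residue_table(x)
  cat(sprintf("State %d: %d residues, %d atoms, %d chain(s)\n",
              x$index, nrow(rt), nrow(x$atoms),
              length(unique(x$atoms$chain))))
  invisible(x)
}

#' @export
print.rin_ensemble <- function(x, ...) {
  cat(sprintf("Ensemble of %d state(s) [%s]\n", n_states(x),
              x$format %||% "memory"))
  print(x$states[[1]])
  invisible(x)
}

#' Residue table of a state
#'
#' One row per residue, in atom-record order, with the canonical residue
#' key and the atom-row span of each residue.
#'
#' @param state an `rin_state`.
#' @return data.frame with columns `key`, `chain`, `number`, `insertion`,
#'   `name`, `polymer_class`, `first_atom`, `n_atoms`.
#' @export
residue_table <- function(state) {
  a <- state$atoms
  id <- paste(a$chain, a$resno, a$insert, a$resname, sep = "\r")
  first <- which(!duplicated(id))
  counts <- as.vector(table(factor(id, levels = id[first])))
  data.frame(
    key = format_residue_key(a$chain[first], a$resno[first],
                             a$insert[first], a$resname[first]),
    chain = a$chain[first],
    number = a$resno[first],
    insertion = a$insert[first],
    name = a$resname[first],
    polymer_class = a$polymer_class[first],
    first_atom = first,
    n_atoms = counts,
    stringsAsFactors = FALSE
  )
}

#' Residue keys of a state, in residue order
#' @param state an `rin_state`.
#' @return character vector of canonical keys.
#' @export
residue_keys <- function(state) residue_table(state)$key

# Map each atom row to its residue index within residue_table(state).
atom_residue_index <- function(state) {
  a <- state$atoms
  id <- paste(a$chain, a$resno, a$insert, a$resname, sep = "\r")
  match(id, unique(id))
}

# --- parsing ---------------------------------------------------------------

# Normalize one bio3d atom table + coordinate vector into an rin_state.
state_from_bio3d <- function(atom, xyz, index, keep_waters, keep_hydrogens) {
  blank <- function(v) { v <- as.character(v); v[is.na(v)] <- ""; v }
  element <- blank(atom$elesy)
  guess <- toupper(substr(gsub("[^A-Za-z].*$", "", atom$elety), 1, 1))
  element[element == ""] <- guess[element == ""]
  atoms <- data.frame(
    serial = as.integer(atom$eleno),
    name = as.character(atom$elety),
    altloc = blank(atom$alt),
    resname = as.character(atom$resid),
    chain = blank(atom$chain),
    resno = as.integer(atom$resno),
    insert = blank(atom$insert),
    element = element,
    occupancy = ifelse(is.na(atom$o), 1, as.numeric(atom$o)),
    is_hetero = atom$type == "HETATM",
    stringsAsFactors = FALSE
  )
  atoms$x <- xyz[seq(1, length(xyz), by = 3)]
  atoms$y <- xyz[seq(2, length(xyz), by = 3)]
  atoms$z <- xyz[seq(3, length(xyz), by = 3)]
  if (!keep_waters) atoms <- atoms[!(atoms$resname %in% WATER_NAMES), ]
  if (!keep_hydrogens) atoms <- atoms[!(toupper(atoms$element) %in% c("H", "D")), ]
  atoms <- resolve_altlocs(atoms)
  atoms$polymer_class <- polymer_class_of(atoms$resname)
  if (!nrow(atoms)) stop("no atoms left after filtering")
  if (any(!is.finite(c(atoms$x, atoms$y, atoms$z))))
    stop("non-finite coordinates in input")
  new_state(atoms, index)
}

# Keep one altloc per atom site: highest occupancy, ties broken by the
# alphabetically first altloc identifier (blank sorts first).
resolve_altlocs <- function(atoms) {
  if (!any(atoms$altloc != "")) return(atoms)
  site <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$resname,
                atoms$name, sep = "\r")
  ord <- order(site, -atoms$occupancy, atoms$altloc)
  keep_rows <- ord[!duplicated(site[ord])]
  atoms[sort(keep_rows), , drop = FALSE]
}

# Enforce identical residue sequences across states; report the first
# difference as an ensemble-consistency error.
check_ensemble_consistency <- function(states) {
  ref <- residue_keys(states[[1]])
  for (i in seq_along(states)[-1]) {
    keys <- residue_keys(states[[i]])
    n <- max(length(ref), length(keys))
    a <- c(ref, rep(NA, n - length(ref)))
    b <- c(keys, rep(NA, n - length(keys)))
    diff <- which(is.na(a) | is.na(b) | a != b)
    if (length(diff)) {
      d <- diff[1]
      stop(sprintf(
        "ensemble-consistency error: state %d differs from state 0 at residue %d (%s vs %s)",
        i - 1L, d, a[d] %||% "<absent>", b[d] %||% "<absent>"))
    }
  }
  invisible(TRUE)
}

#' Parse a structure file into an ensemble
#'
#' Reads a single- or multi-model PDB or mmCIF file. Each MODEL record
#' (PDB) or `pdbx_PDB_model_num` value (mmCIF) becomes one state; model
#' order is preserved and interpreted as time order for trajectories.
#' Waters are excluded by default, alternate locations are collapsed to
#' the highest-occupancy conformer, hydrogens are kept if present, and
#' HETATM residues are retained with polymer class `other`. All states of
#' a multi-model file must share the same residue sequence; the first
#' differing residue is reported otherwise.
#'
#' @param path file path.
#' @param format `"pdb"`, `"mmcif"` or `"auto"` (decide from the file
#'   extension, defaulting to PDB).
#' @param keep_waters logical; retain water residues.
#' @param keep_hydrogens logical; retain hydrogen/deuterium atoms.
#' @return an `rin_ensemble`.
#' @export
parse_structure <- function(path, format = c("auto", "pdb", "mmcif"),
                            keep_waters = FALSE, keep_hydrogens = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "mmcif" else "pdb"
  }
  states <- if (format == "pdb") {
    parse_pdb_states(path, keep_waters, keep_hydrogens)
  } else {
    parse_mmcif_states(path, keep_waters, keep_hydrogens)
  }
  check_ensemble_consistency(states)
  new_ensemble(states, source_path = path, format = format)
}

parse_pdb_states <- function(path, keep_waters, keep_hydrogens) {
  lines <- readLines(path, warn = FALSE)
  model_starts <- grep("^MODEL", lines)
  blocks <- if (length(model_starts) == 0) {
    list(lines)
  } else {
    ends <- grep("^ENDMDL", lines)
    if (length(ends) != length(model_starts))
      stop("parse error: unbalanced MODEL/ENDMDL records in ", path)
    lapply(seq_along(model_starts), function(k)
      lines[(model_starts[k] + 1L):(ends[k] - 1L)])
  }
  states <- vector("list", length(blocks))
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp))
  for (k in seq_along(blocks)) {
    block <- grep("^(ATOM|HETATM|TER)", blocks[[k]], value = TRUE)
    if (!length(block))
      stop("parse error: model ", k, " of ", path, " has no atom records")
    writeLines(c(block, "END"), tmp)
    pdb <- tryCatch(
      bio3d::read.pdb(tmp, verbose = FALSE, rm.alt = FALSE),
      error = function(e) stop("parse error in ", path, " (model ", k,
                               "): ", conditionMessage(e)))
    states[[k]] <- state_from_bio3d(pdb$atom, as.vector(pdb$xyz), k - 1L,
                                    keep_waters, keep_hydrogens)
  }
  states
}

parse_mmcif_states <- function(path, keep_waters, keep_hydrogens) {
  cif <- tryCatch(
    suppressWarnings(bio3d::read.cif(path, multi = TRUE, verbose = FALSE,
                                     rm.alt = FALSE)),
    error = function(e) stop("parse error (or ensemble-consistency error) in ",
                             path, ": ", conditionMessage(e)))
  xyz <- cif$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  lapply(seq_len(nrow(xyz)), function(k)
    state_from_bio3d(cif$atom, xyz[k, ], k - 1L, keep_waters,
                     keep_hydrogens))
}

# --- writing ---------------------------------------------------------------

#' Write one state to a PDB file
#'
#' The written file re-parses to an equal state at PDB fixed-width
#' precision (coordinates to 1e-3 Angstrom).
#'
#' @param state an `rin_state`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_state <- function(state, path) {
  write_states_pdb(list(state), path)
}

#' Write an ensemble to a multi-model PDB file
#'
#' @param ensemble an `rin_ensemble`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_ensemble <- function(ensemble, path) {
  write_states_pdb(ensemble$states, path)
}

write_states_pdb <- function(states, path) {
  a <- states[[1]]$atoms
  xyz <- do.call(rbind, lapply(states, function(s)
    as.vector(t(as.matrix(s$atoms[, c("x", "y", "z")])))))
  blank_na <- function(v) { v[v == ""] <- NA; v }
  tryCatch(
    bio3d::write.pdb(file = path, xyz = xyz,
                     type = ifelse(a$is_hetero, "HETATM", "ATOM"),
                     eleno = a$serial, elety = a$name,
                     resid = a$resname, chain = blank_na(a$chain),
                     resno = a$resno, insert = blank_na(a$insert),
                     o = a$occupancy, b = rep(0, nrow(a)),
                     elesy = a$element),
    error = function(e) stop("I/O error writing ", path, ": ",
                             conditionMessage(e)))
  invisible(path)
}

# Minimal mmCIF writer (atom_site loop only), used to exercise the mmCIF
# reading path on fixture structures.
write_states_mmcif <- function(states, path, entry_id = "rinens") {
  quote_cif <- function(v) ifelse(grepl("['\" ]", v), paste0('"', v, '"'), v)
  rows <- character(0)
  for (s in states) {
    a <- s$atoms
    dotify <- function(v) ifelse(v == "", ".", v)
    rows <- c(rows, sprintf(
      "%s %d %s %s %s %s %s 1 %d %s %.3f %.3f %.3f %.2f 0.00 %d %s %s %s %d",
      ifelse(a$is_hetero, "HETATM", "ATOM"), a$serial, a$element,
      quote_cif(a$name), dotify(a$altloc), a$resname, dotify(a$chain),
      a$resno, dotify(a$insert), a$x, a$y, a$z, a$occupancy,
      a$resno, a$resname, dotify(a$chain), quote_cif(a$name),
      s$index + 1L))
  }
  header <- c(
    paste0("data_", entry_id),
    "#", "loop_",
    paste0("_atom_site.", c(
      "group_PDB", "id", "type_symbol", "label_atom_id", "label_alt_id",
      "label_comp_id", "label_asym_id", "label_entity_id", "label_seq_id",
      "pdbx_PDB_ins_code", "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
      "B_iso_or_equiv", "auth_seq_id", "auth_comp_id", "auth_asym_id",
      "auth_atom_id", "pdbx_PDB_model_num")))
  writeLines(c(header, rows, "#"), path)
  invisible(path)
}

# --- coordinate extraction -------------------------------------------------

#' Coordinate matrix for a named-atom selection
#'
#' Extracts one coordinate row per matching atom, ordered by
#' (chain, residue number, insertion code, atom name). Residues that lack
#' every selected atom are skipped and reported.
#'
#' @param state an `rin_state`.
#' @param selection character set of atom names, e.g. `c("CA", "C1'")`.
#' @return list with `coords` (m x 3 matrix), `keys` (residue key per
#'   row) and `skipped` (keys of residues contributing no atom).
#' @export
#' @examples
#' hx <- make_ideal_helix(8)$ensemble
#' dim(coordinate_matrix(hx$states[[1]], "CA")$coords)
coordinate_matrix <- function(state, selection) {
  if (length(selection) == 0) stop("selection error: empty atom selection")
  a <- state$atoms
  hit <- a$name %in% selection
  if (!any(hit)) stop("selection error: no atoms match selection")
  sel <- a[hit, , drop = FALSE]
  ord <- order(sel$chain, sel$resno, sel$insert, sel$name, method = "radix")
  sel <- sel[ord, , drop = FALSE]
  keys <- format_residue_key(sel$chain, sel$resno, sel$insert, sel$resname)
  all_keys <- residue_keys(state)
  list(coords = as.matrix(sel[, c("x", "y", "z")]),
       keys = keys,
       atom_names = sel$name,
       skipped = setdiff(all_keys, keys))
}
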