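#' System topology: atoms, united atoms, monomers, molecules
#'
#' An \code{eemcc_topology} describes the static hierarchy of a simulated
#' system. Every atom belongs to exactly one united atom (a heavy atom plus
#' its bonded hydrogens), one monomer (a residue, an excipient molecule, a
#' water, an ion) and one molecule. Monomers carry a chemical-class label and
#' molecules a species role; roles are data, not hard-coded names, so the
#' same pipeline handles any excipient.
#'
#' @section Fields:
#' \describe{
#'   \item{atoms}{data.frame: index, element, mass (amu), charge (e),
#'     ua_id, monomer_id, molecule_id.}
#'   \item{monomers}{data.frame: monomer_id, molecule_id, class (one of
#'     \code{"acidic"}, \code{"basic"}, \code{"uncharged-polar"},
#'     \code{"non-polar"}, \code{"n/a"}).}
#'   \item{molecules}{data.frame: molecule_id, species_role (e.g.
#'     \code{"protein"}, \code{"polyanion"}, \code{"buffer"},
#'     \code{"cation"}, \code{"anion"}, \code{"water"}), formal_charge.}
#'   \item{bonds}{two-column integer matrix of atom index pairs.}
#'   \item{dihedrals}{data.frame of ordered atom quadruples (a1..a4) plus the
#'     owning monomer_id.}
#' }
#' @name eemcc_topology
NULL

MONOMER_CLASSES <- c("acidic", "basic", "uncharged-polar", "non-polar", "n/a")

new_topology <- function(atoms, monomers, molecules, bonds, dihedrals) {
  structure(
    list(atoms = atoms, monomers = monomers, molecules = molecules,
         bonds = bonds, dihedrals = dihedrals),
    class = "eemcc_topology"
  )
}

#' Construct a topology from atom-level tables
#'
#' Lower-level constructor used by the file reader and by the synthetic
#' generators. Validates the hierarchy invariants and derives the monomer
#' and molecule tables from per-atom labels.
#'
#' @param atoms data.frame with columns index, element, mass, charge, ua_id,
#'   monomer_id, molecule_id, monomer_class, species_role, formal_charge.
#' @param bonds two-column matrix/data.frame of atom index pairs (may have
#'   zero rows).
#' @param dihedrals data.frame with columns a1, a2, a3, a4 (atom indices) or
#'   NULL.
#' @return an \code{eemcc_topology}.
#' @export
as_topology <- function(atoms, bonds = NULL, dihedrals = NULL) {
  req <- c("index", "element", "mass", "charge", "ua_id", "monomer_id",
           "molecule_id", "monomer_class", "species_role", "formal_charge")
  miss <- setdiff(req, names(atoms))
  if (length(miss))
    stop("atom table is missing columns: ", paste(miss, collapse = ", "))
  atoms <- atoms[order(atoms$index), , drop = FALSE]
  rownames(atoms) <- NULL
  if (anyDuplicated(atoms$index)) stop("duplicate atom indices")
  bad <- which(!is.finite(atoms$mass) | atoms$mass <= 0)
  if (length(bad))
    stop("atom ", atoms$index[bad[1]], " has missing or non-positive mass")
  bad <- which(!is.finite(atoms$charge))
  if (length(bad))
    stop("atom ", atoms$index[bad[1]], " has missing charge")
  for (col in c("ua_id", "monomer_id", "molecule_id")) {
    bad <- which(is.na(atoms[[col]]))
    if (length(bad))
      stop("atom ", atoms$index[bad[1]], " has no ", col, " assignment")
  }
  if (!all(atoms$monomer_class %in% MONOMER_CLASSES))
    stop("unknown monomer class label; expected one of: ",
         paste(MONOMER_CLASSES, collapse = ", "))

  # one heavy atom per united atom, hydrogens ride along
  heavy <- tapply(atoms$element != "H", atoms$ua_id, sum)
  if (any(heavy != 1L))
    stop("united atom ", names(heavy)[which(heavy != 1L)[1]],
         " must contain exactly one heavy atom")

  # monomers nest in molecules, united atoms in monomers
  chk <- unique(atoms[, c("ua_id", "monomer_id")])
  if (anyDuplicated(chk$ua_id)) stop("a united atom spans two monomers")
  chk <- unique(atoms[, c("monomer_id", "molecule_id")])
  if (anyDuplicated(chk$monomer_id)) stop("a monomer spans two molecules")

  monomers <- unique(atoms[, c("monomer_id", "molecule_id", "monomer_class")])
  names(monomers)[3] <- "class"
  rownames(monomers) <- NULL
  molecules <- unique(atoms[, c("molecule_id", "species_role", "formal_charge")])
  if (anyDuplicated(molecules$molecule_id))
    stop("inconsistent species_role or formal_charge within a molecule")
  rownames(molecules) <- NULL

  nat <- tapply(atoms$index, atoms$molecule_id, length)
  wat <- molecules$molecule_id[molecules$species_role == "water"]
  if (length(wat) && any(nat[as.character(wat)] != 3L))
    stop("water molecules must have exactly 3 atoms")

  if (is.null(bonds)) bonds <- matrix(integer(0), ncol = 2)
  bonds <- as.matrix(bonds)
  if (ncol(bonds) != 2) stop("bonds must have two columns")
  storage.mode(bonds) <- "integer"
  if (nrow(bonds) && !all(bonds %in% atoms$index))
    stop("dangling bond: bond references an atom index not in the topology")

  if (is.null(dihedrals)) {
    dihedrals <- data.frame(monomer_id = character(0), a1 = integer(0),
                            a2 = integer(0), a3 = integer(0), a4 = integer(0))
  } else {
    dihedrals <- as.data.frame(dihedrals)
    if (!all(c("a1", "a2", "a3", "a4") %in% names(dihedrals)))
      stop("dihedral table needs columns a1..a4")
    idx <- as.matrix(dihedrals[, c("a1", "a2", "a3", "a4")])
    if (nrow(idx) && !all(idx %in% atoms$index))
      stop("dangling dihedral: references an atom index not in the topology")
    mono <- atoms$monomer_id[match(dihedrals$a2, atoms$index)]
    dihedrals <- data.frame(monomer_id = mono, dihedrals[, c("a1","a2","a3","a4")])
  }
  new_topology(atoms, monomers, molecules, bonds, dihedrals)
}

#' Read a topology from a PDB file plus a TSV sidecar
#'
#' The PDB dialect carries names, elements, residue numbers and CONECT
#' bonds; the sidecar supplies everything PDB cannot express. Mandatory
#' sidecar columns: \code{atom_index}, \code{mass}, \code{charge},
#' \code{ua_id}, \code{monomer_class}, \code{species_role},
#' \code{formal_charge}. Optional columns \code{monomer_id} and
#' \code{molecule_id} override the default derivation (monomer from
#' chain+resno, molecule from chain). Lines starting with '#' are comments.
#'
#' @param path PDB file.
#' @param sidecar TSV sidecar file.
#' @param dihedrals optional TSV with columns a1, a2, a3, a4 listing ordered
#'   atom quadruples.
#' @return an \code{eemcc_topology}.
#' @export
read_topology <- function(path, sidecar, dihedrals = NULL) {
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom
  side <- utils::read.table(sidecar, header = TRUE, sep = "\t",
                            comment.char = "#", stringsAsFactors = FALSE)
  req <- c("atom_index", "mass", "charge", "ua_id", "monomer_class",
           "species_role", "formal_charge")
  miss <- setdiff(req, names(side))
  if (length(miss))
    stop("sidecar is missing columns: ", paste(miss, collapse = ", "))
  idx <- at$eleno
  m <- match(idx, side$atom_index)
  if (anyNA(m))
    stop("sidecar has no row for atom ", idx[which(is.na(m))[1]])
  side <- side[m, , drop = FALSE]

  elem <- at$elesy
  if (is.null(elem) || all(is.na(elem)) || all(elem == ""))
    elem <- substr(gsub("[0-9]", "", trimws(at$elety)), 1, 1)
  monomer_id <- if ("monomer_id" %in% names(side)) side$monomer_id
                else paste0(at$chain, ":", at$resno)
  molecule_id <- if ("molecule_id" %in% names(side)) side$molecule_id
                 else at$chain

  atoms <- data.frame(
    index = idx, element = trimws(elem), mass = side$mass,
    charge = side$charge, ua_id = side$ua_id,
    monomer_id = monomer_id, molecule_id = molecule_id,
    monomer_class = side$monomer_class, species_role = side$species_role,
    formal_charge = side$formal_charge, stringsAsFactors = FALSE
  )
  bonds <- read_conect(path)
  dih <- NULL
  if (!is.null(dihedrals))
    dih <- utils::read.table(dihedrals, header = TRUE, sep = "\t",
                             comment.char = "#")
  as_topology(atoms, bonds = bonds, dihedrals = dih)
}

# CONECT records are not parsed by the PDB reader we build on; the records
# are fixed-width (columns 7-11, then 5-wide neighbour fields).
read_conect <- function(path) {
  lines <- readLines(path)
  lines <- lines[startsWith(lines, "CONECT")]
  if (!length(lines)) return(matrix(integer(0), ncol = 2))
  pairs <- do.call(rbind, lapply(lines, function(l) {
    flds <- strsplit(trimws(substring(l, 7)), "\\s+")[[1]]
    ids <- suppressWarnings(as.integer(flds))
    ids <- ids[!is.na(ids)]
    if (length(ids) < 2) return(NULL)
    cbind(ids[1], ids[-1])
  }))
  # keep each undirected bond once
  pairs <- unique(t(apply(pairs, 1, sort)))
  matrix(as.integer(pairs), ncol = 2)
}

#' Write a topology to the PDB + sidecar dialect
#'
#' @param topology an \code{eemcc_topology}.
#' @param path output PDB file.
#' @param sidecar output TSV sidecar.
#' @param dihedrals optional output TSV for dihedral quadruples.
#' @param xyz optional 3-column coordinate matrix written into the PDB
#'   records (zeros otherwise).
#' @return invisibly, the paths written.
#' @export
write_topology <- function(topology, path, sidecar, dihedrals = NULL,
                           xyz = NULL) {
  at <- topology$atoms
  n <- nrow(at)
  if (is.null(xyz)) xyz <- matrix(0, n, 3)
  resno <- as.integer(factor(at$monomer_id, levels = unique(at$monomer_id)))
  chain <- rep("A", n)
  lines <- sprintf(
    "ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
    at$index, substr(paste0(at$element, at$index %% 100), 1, 4), "MOL",
    chain, resno %% 10000, xyz[, 1], xyz[, 2], xyz[, 3], at$element
  )
  con <- character(0)
  if (nrow(topology$bonds)) {
    con <- apply(topology$bonds, 1, function(b)
      sprintf("CONECT%5d%5d", b[1], b[2]))
  }
  writeLines(c(lines, con, "END"), path)

  side <- data.frame(
    atom_index = at$index, mass = at$mass, charge = at$charge,
    ua_id = at$ua_id, monomer_class = at$monomer_class,
    species_role = at$species_role, formal_charge = at$formal_charge,
    monomer_id = at$monomer_id, molecule_id = at$molecule_id
  )
  utils::write.table(side, sidecar, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(dihedrals) && nrow(topology$dihedrals)) {
    utils::write.table(topology$dihedrals[, c("a1", "a2", "a3", "a4")],
                       dihedrals, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(c(path, sidecar))
}

#' @export
print.eemcc_topology <- function(x, ...) {
  cat("eemcc topology:", nrow(x$atoms), "atoms,",
      length(unique(x$atoms$ua_id)), "united atoms,",
      nrow(x$monomers), "monomers,", nrow(x$molecules), "molecules\n")
  cat("species:", paste(sprintf("%s (%d)",
      names(table(x$molecules$species_role)),
      as.integer(table(x$molecules$species_role))), collapse = ", "), "\n")
  invisible(x)
}

#' United-atom summary table
#'
#' One row per united atom: its heavy atom, owning monomer/molecule, the
#' molecule's species role and the monomer class.
#'
#' @param topology an \code{eemcc_topology}.
#' @return data.frame with columns ua_id, heavy_index, monomer_id,
#'   molecule_id, species_role, monomer_class.
#' @export
ua_table <- function(topology) {
  at <- topology$atoms
  heavy <- at[at$element != "H", ]
  data.frame(
    ua_id = heavy$ua_id, heavy_index = heavy$index,
    monomer_id = heavy$monomer_id, molecule_id = heavy$molecule_id,
    species_role = heavy$species_role, monomer_class = heavy$monomer_class,
    stringsAsFactors = FALSE
  )
}

#' Average formal charge per molecule of each species role
#'
#' Reported alongside contact tables as metadata (e.g. a polyanion present
#' in two protonation states averages to a fractional charge).
#'
#' @param topology an \code{eemcc_topology}.
#' @return data.frame with columns species_role, n_molecules, mean_formal_charge.
#' @export
mean_formal_charge <- function(topology) {
  mol <- topology$molecules
  agg <- aggregate(formal_charge ~ species_role, mol, mean)
  cnt <- aggregate(molecule_id ~ species_role, mol, length)
  data.frame(species_role = agg$species_role,
             n_molecules = cnt$molecule_id[match(agg$species_role, cnt$species_role)],
             mean_formal_charge = agg$formal_charge)
}
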