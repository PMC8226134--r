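#' Conformer peak detection on a dihedral angle series
#'
#' Angles are discretised into twelve periodic 30-degree bins. A peak is a
#' bin strictly more populated than both circular neighbours; if two peaks
#' lie closer than 60 degrees apart the more populated one survives (ties
#' break to the lower bin index). Every angle is then assigned to the
#' nearest surviving peak under the periodic distance. A flat histogram with
#' no qualifying bin collapses to a single conformer with a warning.
#'
#' @param angles dihedral angle series in degrees, in [-180, 180).
#' @param weights optional per-observation weights.
#' @return an \code{eemcc_conformers}: list with \code{centers} (peak bin
#'   centres, degrees), \code{assignment} (integer conformer index per
#'   angle) and \code{probs} (weighted conformer probabilities).
#' @export
find_conformers <- function(angles, weights = NULL) {
  if (!length(angles)) stop("empty dihedral series")
  if (is.null(weights)) weights <- rep(1, length(angles))
  a <- ((angles + 180) %% 360) - 180
  bin <- floor((a + 180) / 30) + 1L
  bin[bin == 13L] <- 1L  # a == 180 wraps
  h <- vapply(1:12, function(b) sum(weights[bin == b]), numeric(1))
  centers_all <- seq(-165, 165, by = 30)
  nxt <- c(2:12, 1); prv <- c(12, 1:11)
  peaks <- which(h > h[nxt] & h > h[prv])
  if (length(peaks) > 1) {
    # suppress peaks closer than 60 degrees (periodic), keep the taller
    ok <- rep(TRUE, length(peaks))
    for (i in seq_along(peaks)) for (j in seq_along(peaks)) {
      if (i == j || !ok[i] || !ok[j]) next
      dd <- abs(centers_all[peaks[i]] - centers_all[peaks[j]])
      dd <- min(dd, 360 - dd)
      if (dd < 60) {
        drop <- if (h[peaks[i]] != h[peaks[j]])
          which.min(c(h[peaks[i]], h[peaks[j]])) else 2L
        ok[c(i, j)[drop]] <- FALSE
      }
    }
    peaks <- peaks[ok]
  }
  if (!length(peaks)) {
    warning("no conformer peak found (flat dihedral histogram); ",
            "collapsing to a single conformer")
    return(structure(list(centers = 0,
                          assignment = rep(1L, length(a)),
                          probs = 1),
                     class = "eemcc_conformers"))
  }
  centers <- centers_all[peaks]
  dmat <- abs(outer(a, centers, "-"))
  dmat <- pmin(dmat, 360 - dmat)
  assignment <- max.col(-dmat, ties.method = "first")
  probs <- vapply(seq_along(centers), function(k)
    sum(weights[assignment == k]), numeric(1))
  probs <- probs / sum(probs)
  structure(list(centers = centers, assignment = assignment, probs = probs),
            class = "eemcc_conformers")
}

#' Shannon conformational entropy of joint conformer states
#'
#' The monomer's conformational state in a frame is the vector of conformer
#' assignments over all its dihedrals; the entropy is
#' S = -kB sum p_i log p_i over the weighted joint-state probabilities.
#'
#' @param assignments matrix of conformer indices, frames x dihedrals (a
#'   vector is treated as a single dihedral).
#' @param weights optional per-frame weights.
#' @param constants \code{\link{eemcc_constants}}.
#' @return entropy in J/K/mol.
#' @export
conformational_entropy <- function(assignments, weights = NULL,
                                   constants = eemcc_constants()) {
  if (is.null(dim(assignments)))
    assignments <- matrix(assignments, ncol = 1)
  nf <- nrow(assignments)
  if (is.null(weights)) weights <- rep(1, nf)
  states <- apply(assignments, 1, paste, collapse = ",")
  p <- tapply(weights, states, sum)
  p <- p / sum(p)
  -constants$kB_entropy * sum(p * log(p))
}

#' Dihedral angle time series from trajectory coordinates
#'
#' @param frames an \code{eemcc_frames}.
#' @param quad integer vector of four atom indices (ordered).
#' @return numeric vector of angles in degrees, one per frame, in
#'   [-180, 180).
#' @export
dihedral_series <- function(frames, quad) {
  stopifnot(length(quad) == 4)
  vapply(seq_len(frames$n_frames), function(f) {
    p <- frames$positions[quad, , f]
    ang <- bio3d::torsion.xyz(as.numeric(t(p)))
    ((ang + 180) %% 360) - 180
  }, numeric(1))
}

#' Conformational entropy per monomer from registered dihedrals
#'
#' For every monomer owning at least one dihedral quadruple in the topology,
#' computes the angle series of each dihedral, detects conformer peaks,
#' forms the per-frame joint state over the monomer's dihedrals and returns
#' its Shannon entropy. Frame weights are applied to non-protein molecules
#' only unless \code{weight_protein} is set.
#'
#' @param frames an \code{eemcc_frames}.
#' @param topology an \code{eemcc_topology}.
#' @param weights optional per-frame weights.
#' @param constants \code{\link{eemcc_constants}}.
#' @param weight_protein apply weights to protein monomers too.
#' @return data.frame: monomer_id, molecule_id, species_role, class,
#'   n_dihedrals, n_conformer_states, S (J/K/mol).
#' @export
monomer_conformational_entropy <- function(frames, topology, weights = NULL,
                                           constants = eemcc_constants(),
                                           weight_protein = FALSE) {
  dih <- topology$dihedrals
  if (!nrow(dih)) return(NULL)
  mono <- topology$monomers
  out <- list()
  for (m in unique(dih$monomer_id)) {
    rows <- dih[dih$monomer_id == m, , drop = FALSE]
    mol <- mono$molecule_id[mono$monomer_id == m]
    role <- topology$molecules$species_role[
      topology$molecules$molecule_id == mol]
    w <- if (role == "protein" && !weight_protein) NULL else weights
    asn <- sapply(seq_len(nrow(rows)), function(k) {
      ang <- dihedral_series(frames, as.integer(rows[k, c("a1","a2","a3","a4")]))
      find_conformers(ang, weights = w)$assignment
    })
    asn <- matrix(asn, nrow = frames$n_frames)
    S <- conformational_entropy(asn, weights = w, constants = constants)
    nstate <- length(unique(apply(asn, 1, paste, collapse = ",")))
    out[[length(out) + 1]] <- data.frame(
      monomer_id = m, molecule_id = mol, species_role = role,
      class = mono$class[mono$monomer_id == m],
      n_dihedrals = nrow(rows), n_conformer_states = nstate, S = S,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
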