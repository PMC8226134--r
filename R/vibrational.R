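#' Vibrational entropy from force and torque covariance matrices
#'
#' Quasi-harmonic vibrational entropy of a unit (united atom, monomer or
#' whole molecule) is obtained from the eigenvalues of its mass-weighted
#' force covariance matrix and inertia-weighted torque covariance matrix,
#' converted to frequencies and fed through the quantum harmonic oscillator
#' entropy. At every level below a molecule's highest, the six
#' lowest-frequency force modes are removed: they re-express the rigid-body
#' translation and rotation already counted one level up.
#'
#' @name vibrational_entropy_module
NULL

# units of a molecule at a given level: list of integer atom-index vectors
level_units <- function(topology, molecule_id, level) {
  at <- topology$atoms
  at <- at[at$molecule_id == molecule_id, , drop = FALSE]
  key <- switch(level,
                UA = at$ua_id,
                M = at$monomer_id,
                P = rep("P", nrow(at)),
                stop("unknown level: ", level))
  split(at$index, factor(key, levels = unique(key)))
}

#' Length scales declared for a species
#'
#' Proteins are analysed at united-atom, monomer and polymer levels;
#' multi-atom solutes (excipients, buffers) at united-atom and monomer
#' levels; water and monatomic species at the united-atom level only. The
#' last element is the molecule's highest level (no mode removal there).
#'
#' @param topology an \code{eemcc_topology}.
#' @param molecule_id a molecule id.
#' @return character vector of levels, lowest to highest.
#' @export
declared_levels <- function(topology, molecule_id) {
  mol <- topology$molecules
  role <- mol$species_role[mol$molecule_id == molecule_id]
  at <- topology$atoms[topology$atoms$molecule_id == molecule_id, ]
  n_heavy <- sum(at$element != "H")
  if (role == "protein") return(c("UA", "M", "P"))
  if (role == "water" || n_heavy <= 1) return("UA")
  c("UA", "M")
}

# local reference frame of a unit in one frame.
# Units with >= 2 atoms: instantaneous principal axes of inertia, each axis
# sign-fixed so its largest-magnitude component is positive (keeps the frame
# continuous enough across frames for covariance accumulation).
# Monatomic units: identity.
unit_frame <- function(pos, mass) {
  if (nrow(pos) < 2) return(diag(3))
  com <- colSums(pos * mass) / sum(mass)
  r <- sweep(pos, 2, com)
  I3 <- diag(3) * sum(mass * rowSums(r * r)) - crossprod(r * sqrt(mass),
                                                         r * sqrt(mass))
  e <- eigen(I3, symmetric = TRUE)
  # axes ordered by ascending principal moment, matching unit_moments()
  ax <- t(e$vectors[, order(e$values)])
  for (k in 1:3) {
    j <- which.max(abs(ax[k, ]))
    if (ax[k, j] < 0) ax[k, ] <- -ax[k, ]
  }
  ax
}

# principal moments of inertia (amu Angstrom^2), ascending
unit_moments <- function(pos, mass) {
  if (nrow(pos) < 2) return(c(0, 0, 0))
  com <- colSums(pos * mass) / sum(mass)
  r <- sweep(pos, 2, com)
  I3 <- diag(3) * sum(mass * rowSums(r * r)) - crossprod(r * sqrt(mass),
                                                         r * sqrt(mass))
  sort(eigen(I3, symmetric = TRUE, only.values = TRUE)$values)
}

# rotational degrees of freedom of a unit: 3 nonlinear, 2 linear, 0 monatomic
unit_rot_dof <- function(pos, mass, tol = 1e-6) {
  if (nrow(pos) < 2) return(0L)
  mom <- unit_moments(pos, mass)
  if (mom[1] < tol * max(mom[3], 1)) return(2L)
  3L
}

#' Accumulate force and torque covariance matrices for one molecule
#'
#' Per frame, each unit's net force is rotated into the unit's local frame
#' and divided by the square root of the unit mass; its net torque about the
#' unit centre of mass is rotated likewise and divided by the square root of
#' the matching principal moment of inertia. In the mean-field
#' approximation, forces at the polymer level and torques at all levels are
#' halved before accumulation. The covariance spans all units of the
#' molecule at the level (3M x 3M for forces).
#'
#' @param frames an \code{eemcc_frames} (at least two frames).
#' @param topology an \code{eemcc_topology}.
#' @param molecule_id molecule to analyse.
#' @param level \code{"UA"}, \code{"M"} or \code{"P"}.
#' @param weights optional per-frame weights (default uniform). Protein
#'   molecules are conventionally analysed unweighted; that policy belongs
#'   to the caller.
#' @return an \code{eemcc_covariances}: list with \code{fcov}, \code{tcov}
#'   (possibly 0 x 0), \code{rot_dof} per unit, unit count, sample count and
#'   weight sum.
#' @export
build_covariances <- function(frames, topology, molecule_id, level,
                              weights = NULL) {
  if (frames$n_frames < 2)
    stop("covariance undefined for a single-frame ensemble")
  units <- level_units(topology, molecule_id, level)
  nu <- length(units)
  at <- topology$atoms
  if (is.null(weights)) weights <- rep(1, frames$n_frames)
  if (length(weights) != frames$n_frames) stop("one weight per frame needed")

  masses <- lapply(units, function(ix) at$mass[match(ix, at$index)])
  umass <- vapply(masses, sum, numeric(1))

  rot_dof <- integer(nu)
  p1 <- frames$positions[, , 1, drop = FALSE]; dim(p1) <- dim(frames$positions)[1:2]
  for (u in seq_len(nu))
    rot_dof[u] <- unit_rot_dof(p1[units[[u]], , drop = FALSE], masses[[u]])
  nrot <- sum(rot_dof)

  fmat <- matrix(0, frames$n_frames, 3 * nu)
  tmat <- if (nrot > 0) matrix(0, frames$n_frames, nrot) else
    matrix(0, frames$n_frames, 0)
  fhalf <- if (level == "P") 0.5 else 1
  for (f in seq_len(frames$n_frames)) {
    pos <- frames$positions[, , f, drop = FALSE]; dim(pos) <- dim(frames$positions)[1:2]
    frc <- frames$forces[, , f, drop = FALSE]; dim(frc) <- dim(frames$forces)[1:2]
    col_t <- 0L
    for (u in seq_len(nu)) {
      ix <- units[[u]]; m <- masses[[u]]
      p <- pos[ix, , drop = FALSE]; fo <- frc[ix, , drop = FALSE]
      R <- unit_frame(p, m)
      Ftot <- colSums(fo)
      fmat[f, (3 * u - 2):(3 * u)] <- fhalf * as.numeric(R %*% Ftot) /
        sqrt(umass[u])
      if (rot_dof[u] > 0) {
        com <- colSums(p * m) / sum(m)
        rr <- sweep(p, 2, com)
        tau <- colSums(cbind(rr[, 2] * fo[, 3] - rr[, 3] * fo[, 2],
                             rr[, 3] * fo[, 1] - rr[, 1] * fo[, 3],
                             rr[, 1] * fo[, 2] - rr[, 2] * fo[, 1]))
        tau_loc <- as.numeric(R %*% tau)
        mom <- unit_moments(p, m)
        sel <- if (rot_dof[u] == 2L) 2:3 else 1:3
        tmat[f, (col_t + 1):(col_t + rot_dof[u])] <-
          0.5 * tau_loc[sel] / sqrt(mom[sel])
        col_t <- col_t + rot_dof[u]
      }
    }
  }
  wcov <- function(m) {
    if (ncol(m) == 0) return(matrix(0, 0, 0))
    w <- weights / sum(weights)
    mu <- colSums(m * w)
    mc <- sweep(m, 2, mu)
    crossprod(mc * w, mc) / (1 - sum(w^2)) * 1  # weighted, unbiased-style
  }
  structure(
    list(molecule_id = molecule_id, level = level,
         fcov = wcov(fmat), tcov = wcov(tmat),
         rot_dof = rot_dof, n_units = nu,
         n_frames = frames$n_frames, weight_sum = sum(weights)),
    class = "eemcc_covariances"
  )
}

#' Quasi-harmonic mode frequencies from covariance eigenvalues
#'
#' Each eigenvalue lambda of the mass-weighted force (or inertia-weighted
#' torque) covariance matrix maps to a frequency
#' nu = (1/2 pi) sqrt(lambda / (kB T)). Slightly negative eigenvalues from
#' finite sampling are clamped to zero; an eigenvalue below \code{-tol}
#' (relative to the spectral radius) signals a broken covariance and is a
#' hard error.
#'
#' @param cov an \code{eemcc_covariances}.
#' @param constants \code{\link{eemcc_constants}}.
#' @param tol relative tolerance for negative eigenvalues (default 1e-8).
#' @return an \code{eemcc_modes} data.frame: columns \code{motion}
#'   (\code{"translation"}/\code{"rotation"}), \code{nu} (1/s, ascending
#'   within motion) and \code{removed} (all FALSE here).
#' @export
mode_frequencies <- function(cov, constants = eemcc_constants(),
                             tol = 1e-8) {
  freq_of <- function(mat) {
    if (!nrow(mat)) return(numeric(0))
    if (max(abs(mat - t(mat))) > 1e-8 * max(abs(mat), 1))
      stop("covariance matrix is not symmetric")
    lam <- eigen((mat + t(mat)) / 2, symmetric = TRUE,
                 only.values = TRUE)$values
    floor_ <- -tol * max(abs(lam), 1)
    if (any(lam < floor_))
      stop("covariance has a significantly negative eigenvalue (",
           signif(min(lam), 4), ")")
    lam[lam < 0] <- 0
    sort(sqrt(lam / (constants$kB * constants$T) * constants$freq2) / (2 * pi))
  }
  nt <- freq_of(cov$fcov)
  nr <- freq_of(cov$tcov)
  structure(
    data.frame(
      motion = c(rep("translation", length(nt)), rep("rotation", length(nr))),
      nu = c(nt, nr), removed = FALSE, stringsAsFactors = FALSE),
    class = c("eemcc_modes", "data.frame"),
    molecule_id = cov$molecule_id, level = cov$level
  )
}

#' Flag the six lowest translational force modes for removal
#'
#' At every level below the molecule's highest, the six smallest
#' frequencies of the force covariance spectrum duplicate the rigid-body
#' translation and rotation counted at the next level up and are removed.
#' At the highest level the spectrum is returned unchanged. Torque modes are
#' never removed.
#'
#' @param modes an \code{eemcc_modes}.
#' @param highest TRUE if this is the molecule's highest level.
#' @return the spectrum with \code{removed} flags set.
#' @export
remove_lowest_modes <- function(modes, highest) {
  if (highest) return(modes)
  tr <- which(modes$motion == "translation")
  if (length(tr) < 7)
    stop("fewer than 7 translational modes at a non-highest level: ",
         "unit is ill-posed for mode removal")
  modes$removed[tr[order(modes$nu[tr])[1:6]]] <- TRUE
  modes
}

#' Quantum harmonic oscillator vibrational entropy of a mode spectrum
#'
#' S = kB * sum over retained modes of
#' (x / (exp(x) - 1) - log(1 - exp(-x))) with x = h nu / kB T. Modes at
#' exactly zero frequency contribute zero with a warning (a surviving zero
#' frequency means a rigid-body mode escaped removal or a direction is
#' unsampled).
#'
#' @param modes an \code{eemcc_modes} (removed modes are excluded).
#' @param constants \code{\link{eemcc_constants}}.
#' @param motion optionally restrict to \code{"translation"} or
#'   \code{"rotation"}.
#' @return entropy in J/K/mol.
#' @export
svib <- function(modes, constants = eemcc_constants(), motion = NULL) {
  keep <- !modes$removed
  if (!is.null(motion)) keep <- keep & modes$motion == motion
  nu <- modes$nu[keep]
  if (!length(nu)) return(0)
  if (any(nu == 0)) {
    warning(sum(nu == 0), " zero-frequency mode(s) contribute no entropy")
    nu <- nu[nu > 0]
  }
  x <- constants$h * nu / (constants$kB * constants$T)
  constants$kB_entropy * sum(x / expm1(x) - log1p(-exp(-x)))
}

#' Vibrational entropy table for every molecule at its declared levels
#'
#' Drives \code{\link{build_covariances}}, \code{\link{mode_frequencies}},
#' \code{\link{remove_lowest_modes}} and \code{\link{svib}} over all
#' molecules. Frame weights are applied only to molecules whose species role
#' is not \code{"protein"} unless \code{weight_protein = TRUE} (protein
#' conformations are not bias-sampled, so their statistics stay unweighted).
#'
#' @param frames an \code{eemcc_frames}.
#' @param topology an \code{eemcc_topology}.
#' @param weights optional per-frame weights.
#' @param constants \code{\link{eemcc_constants}}.
#' @param weight_protein apply weights to proteins too (default FALSE).
#' @return data.frame: molecule_id, species_role, level, motion, S
#'   (J/K/mol).
#' @export
vibrational_entropy <- function(frames, topology, weights = NULL,
                                constants = eemcc_constants(),
                                weight_protein = FALSE) {
  mol <- topology$molecules
  out <- list()
  for (i in seq_len(nrow(mol))) {
    mid <- mol$molecule_id[i]
    role <- mol$species_role[i]
    w <- if (role == "protein" && !weight_protein) NULL else weights
    lv <- declared_levels(topology, mid)
    for (l in lv) {
      cv <- build_covariances(frames, topology, mid, l, weights = w)
      md <- mode_frequencies(cv, constants)
      md <- remove_lowest_modes(md, highest = (l == lv[length(lv)]))
      for (mo in c("translation", "rotation")) {
        ndof <- sum(md$motion == mo)
        if (mo == "rotation" && ndof == 0) next
        out[[length(out) + 1]] <- data.frame(
          molecule_id = mid, species_role = role, level = l, motion = mo,
          S = svib(md, constants, motion = mo), stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}
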