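#' Per-unit enthalpy from per-atom energies
#'
#' The enthalpy of a unit in a frame is the sum of per-atom kinetic plus
#' potential energies over its atoms (the pressure-volume term is
#' negligible and ignored). Multi-body potential terms are assumed
#' pre-divided over the involved atoms by the trajectory producer; this
#' module treats the per-atom energies as ground truth, which makes the
#' bookkeeping exactly additive over any partition of the atoms.
#'
#' @param frames an \code{eemcc_frames}.
#' @param atom_indices atom indices of the unit.
#' @return numeric vector: H (kJ/mol) per frame.
#' @export
unit_enthalpy <- function(frames, atom_indices) {
  e <- frames$pe[atom_indices, , drop = FALSE] +
    frames$ke[atom_indices, , drop = FALSE]
  colSums(e)
}

#' Weighted energy ledger over molecules, species, classes and water types
#'
#' Computes the weighted mean enthalpy per molecule, per species role and
#' per monomer class, and - when a water-environment classification is given
#' - per water environment, with the frame-local label deciding which
#' environment a water's enthalpy counts toward in each frame. Per-water
#' samples are retained for histogram export.
#'
#' @param frames an \code{eemcc_frames}.
#' @param topology an \code{eemcc_topology}.
#' @param weights optional per-frame weights.
#' @param water_env optional \code{eemcc_water_env} from
#'   \code{\link{classify_water}}.
#' @return an \code{eemcc_energy_ledger}: list of data.frames
#'   \code{by_molecule}, \code{by_species}, \code{by_class}, and (if
#'   classified) \code{by_water_env} plus \code{water_samples}
#'   (environment, H, weight).
#' @export
aggregate_energy <- function(frames, topology, weights = NULL,
                             water_env = NULL) {
  nf <- frames$n_frames
  if (is.null(weights)) weights <- rep(1, nf)
  w <- weights / sum(weights)
  at <- topology$atoms

  mol_ids <- topology$molecules$molecule_id
  Hmol <- t(vapply(mol_ids, function(m)
    unit_enthalpy(frames, at$index[at$molecule_id == m]),
    numeric(nf)))
  mH <- as.numeric(Hmol %*% w)
  by_molecule <- data.frame(molecule_id = mol_ids,
                            species_role = topology$molecules$species_role,
                            H = mH, stringsAsFactors = FALSE)
  by_species <- aggregate(H ~ species_role, by_molecule, sum)

  mono <- topology$monomers
  Hmono <- vapply(mono$monomer_id, function(m)
    sum(unit_enthalpy(frames, at$index[at$monomer_id == m]) * w),
    numeric(1))
  by_class <- aggregate(
    data.frame(H = Hmono),
    by = list(class = mono$class), FUN = sum)

  out <- list(by_molecule = by_molecule, by_species = by_species,
              by_class = by_class)
  if (!is.null(water_env) && length(water_env$water_molecules)) {
    wm <- water_env$water_molecules
    Hw <- t(vapply(wm, function(m)
      unit_enthalpy(frames, at$index[at$molecule_id == m]), numeric(nf)))
    dim(Hw) <- c(length(wm), nf)
    env <- as.vector(water_env$labels)
    samples <- data.frame(environment = env,
                          H = as.vector(Hw),
                          weight = rep(w, each = length(wm)))
    tot <- aggregate(weight ~ environment, samples, sum)
    wm2 <- aggregate(cbind(Hw = H * weight) ~ environment, samples, sum)
    by_env <- data.frame(environment = tot$environment,
                         H = wm2$Hw[match(tot$environment,
                                          wm2$environment)] / tot$weight,
                         mean_count = tot$weight * length(wm) /
                           sum(tot$weight))
    out$by_water_env <- by_env
    out$water_samples <- samples
  }
  structure(out, class = "eemcc_energy_ledger")
}

#' Export per-water-environment energy histograms as CSV
#'
#' @param ledger an \code{eemcc_energy_ledger} built with a water
#'   classification.
#' @param path output CSV.
#' @param breaks number of bins or a vector of bin edges.
#' @return invisibly, the histogram data.frame (environment, bin_lo,
#'   bin_hi, weighted_count).
#' @export
export_energy_histograms <- function(ledger, path, breaks = 30) {
  s <- ledger$water_samples
  if (is.null(s)) stop("ledger has no water samples; classify waters first")
  edges <- if (length(breaks) == 1)
    seq(min(s$H), max(s$H), length.out = breaks + 1) else breaks
  out <- list()
  for (env in unique(s$environment)) {
    sel <- s[s$environment == env, ]
    bin <- cut(sel$H, edges, include.lowest = TRUE, labels = FALSE)
    cnt <- vapply(seq_len(length(edges) - 1), function(b)
      sum(sel$weight[bin == b]), numeric(1))
    out[[env]] <- data.frame(environment = env,
                             bin_lo = edges[-length(edges)],
                             bin_hi = edges[-1], weighted_count = cnt)
  }
  out <- do.call(rbind, out)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}
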