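#' Water-environment classification from coordination shells
#'
#' Each water molecule, each frame, is labelled by the solutes whose united
#' atoms sit in its first coordination shell: \code{WP} (exactly one protein,
#' no excipient/counterion), \code{WPP} (two distinct proteins, no
#' excipient/counterion), \code{WEP} (one protein plus any
#' excipient/counterion), \code{WEPP} (two proteins plus any
#' excipient/counterion), \code{WE} (excipient/counterion only) and
#' \code{bulk} (waters only). Any non-water, non-protein species role
#' (polyanion, buffer, cation, anion, ...) counts as excipient/counterion.
#' Neighbouring waters never trigger a solute category. The labels are
#' exhaustive and mutually exclusive, so per frame they partition the
#' waters.
#'
#' @param shells an \code{eemcc_shells}.
#' @param topology an \code{eemcc_topology}.
#' @return an \code{eemcc_water_env}: list with \code{labels}, an
#'   n_waters x n_frames character matrix, and \code{water_molecules}, the
#'   molecule ids of the rows.
#' @export
classify_water <- function(shells, topology) {
  ua <- shells$ua
  wrow <- which(ua$species_role == "water")
  wmol <- ua$molecule_id[wrow]
  labels <- matrix("bulk", length(wrow), shells$n_frames)
  for (f in seq_len(shells$n_frames)) {
    fr <- shells$shells[[f]]
    for (k in seq_along(wrow)) {
      sh <- fr[[wrow[k]]]
      if (!length(sh)) next
      roles <- ua$species_role[sh]
      prot <- length(unique(ua$molecule_id[sh][roles == "protein"]))
      exc <- any(!(roles %in% c("water", "protein")))
      labels[k, f] <-
        if (prot >= 2 && exc) "WEPP"
        else if (prot >= 2) "WPP"
        else if (prot == 1 && exc) "WEP"
        else if (prot == 1) "WP"
        else if (exc) "WE"
        else "bulk"
    }
  }
  structure(list(labels = labels, water_molecules = wmol,
                 n_frames = shells$n_frames),
            class = "eemcc_water_env")
}

WATER_ENV_LEVELS <- c("bulk", "WP", "WPP", "WEP", "WEPP", "WE")

#' Nearest-solute assignment of shell waters
#'
#' Each water, each frame, is assigned to the species role of the nearest
#' solute united atom whose coordination shell contains the water, and to
#' \code{"bulk"} when it sits in no solute shell. This is the
#' hydration-shell membership used for the per-species water rows of the
#' binding decomposition.
#'
#' @param shells an \code{eemcc_shells}.
#' @return character matrix n_waters x n_frames of species roles or
#'   \code{"bulk"}; attribute \code{"water_molecules"} carries the row
#'   molecule ids.
#' @export
water_solute_assignment <- function(shells) {
  ua <- shells$ua
  is_water <- ua$species_role == "water"
  wrow <- which(is_water)
  out <- matrix("bulk", length(wrow), shells$n_frames)
  rowmap <- match(seq_len(nrow(ua)), wrow)
  for (f in seq_len(shells$n_frames)) {
    fr <- shells$shells[[f]]
    best <- rep(Inf, length(wrow))
    for (u in which(!is_water)) {
      sh <- fr[[u]]
      d <- attr(sh, "dist")
      for (j in seq_along(sh)) {
        k <- rowmap[sh[j]]
        if (!is.na(k) && d[j] < best[k]) {
          best[k] <- d[j]
          out[k, f] <- ua$species_role[u]
        }
      }
    }
  }
  structure(out, water_molecules = ua$molecule_id[wrow])
}

#' Ensemble-average water-environment counts
#'
#' Weighted mean number of waters per environment category. The exported
#' total sums the four protein-involving categories (WP, WPP, WEP, WEPP);
#' set \code{include_we = TRUE} to add a WE column (and include it in the
#' total).
#'
#' @param env an \code{eemcc_water_env}.
#' @param weights optional per-frame weights.
#' @param include_we include the WE column (default FALSE).
#' @return one-row data.frame: WP, WPP, WEP, WEPP, (WE,) Total.
#' @export
water_environment_counts <- function(env, weights = NULL,
                                     include_we = FALSE) {
  nf <- ncol(env$labels)
  if (is.null(weights)) weights <- rep(1, nf)
  w <- weights / sum(weights)
  cats <- c("WP", "WPP", "WEP", "WEPP", if (include_we) "WE")
  counts <- vapply(cats, function(cc)
    sum(vapply(seq_len(nf), function(f)
      sum(env$labels[, f] == cc) * w[f], numeric(1))), numeric(1))
  out <- as.data.frame(as.list(counts))
  names(out) <- cats
  out$Total <- sum(counts)
  out
}

#' Rational switching-function contact count
#'
#' s(r) = (1 - x^6) / (1 - x^12) with x = (r - d0)/r0, the removable
#' singularity at x = 1 evaluating to 1/2 (the implementation uses the
#' equivalent stable form 1/(1 + x^6)). Distances at or below d0 count as a
#' full contact. Used to reproduce collective-variable style contact counts;
#' thermodynamic post-processing uses coordination shells instead.
#'
#' @param positions n x 3 coordinate matrix.
#' @param box length-3 box edges or NULL.
#' @param pairs two-column matrix of row-index pairs.
#' @param d0 offset distance, Angstrom (> 0).
#' @param r0 switching width, Angstrom (> 0).
#' @return the continuous contact count, sum of s(r) over pairs.
#' @export
switching_contacts <- function(positions, box = NULL, pairs, d0, r0) {
  stopifnot(d0 > 0, r0 > 0)
  pairs <- matrix(as.integer(pairs), ncol = 2)
  d <- positions[pairs[, 1], , drop = FALSE] -
    positions[pairs[, 2], , drop = FALSE]
  if (!is.null(box)) d <- min_image(d, box)
  r <- sqrt(rowSums(d * d))
  x <- pmax(0, (r - d0) / r0)
  sum(1 / (1 + x^6))
}

#' Species-by-species contact table from coordination shells
#'
#' A contact is an unordered pair of united atoms from two different
#' molecules linked by the shell relation in either direction. Counts are
#' aggregated to species-role pairs per frame and averaged with the frame
#' weights. The matrix is symmetric by construction.
#'
#' @param shells an \code{eemcc_shells}.
#' @param topology an \code{eemcc_topology}.
#' @param weights optional per-frame weights.
#' @return an \code{eemcc_contacts}: list with \code{counts} (role x role
#'   matrix of mean contact counts) and \code{n_molecules} (named molecule
#'   counts per role).
#' @export
contact_table <- function(shells, topology, weights = NULL) {
  ua <- shells$ua
  roles <- sort(unique(ua$species_role))
  nf <- shells$n_frames
  if (is.null(weights)) weights <- rep(1, nf)
  w <- weights / sum(weights)
  acc <- matrix(0, length(roles), length(roles),
                dimnames = list(roles, roles))
  for (f in seq_len(nf)) {
    fr <- shells$shells[[f]]
    deg <- lengths(fr)
    ctr <- rep(seq_along(fr), deg)
    nbr <- unlist(fr, use.names = FALSE)
    if (!length(nbr)) next
    keep <- ua$molecule_id[ctr] != ua$molecule_id[nbr]
    ctr <- ctr[keep]; nbr <- nbr[keep]
    if (!length(nbr)) next
    key <- paste(pmin(ctr, nbr), pmax(ctr, nbr))
    first <- !duplicated(key)
    a <- pmin(ctr, nbr)[first]; b <- pmax(ctr, nbr)[first]
    ra <- ua$species_role[a]; rb <- ua$species_role[b]
    tab <- unclass(table(factor(ra, roles), factor(rb, roles)))
    tab <- tab + t(tab)
    diag(tab) <- diag(tab) / 2
    acc <- acc + w[f] * tab
  }
  nm <- table(factor(topology$molecules$species_role, roles))
  structure(list(counts = acc, n_molecules = c(nm)),
            class = "eemcc_contacts")
}

#' Per-molecule normalised contact counts
#'
#' Divides each row of the contact table by the number of molecules of the
#' row species (e.g. total polyanion-cation contacts over five polyanions
#' gives contacts per polyanion).
#'
#' @param contacts an \code{eemcc_contacts}.
#' @return role x role matrix of contacts per molecule of the row species.
#' @export
contacts_per_molecule <- function(contacts) {
  sweep(contacts$counts, 1, pmax(contacts$n_molecules, 1), "/")
}

#' @export
print.eemcc_contacts <- function(x, ...) {
  cat("eemcc contact table (mean contacts between species):\n")
  print(round(x$counts, 1))
  invisible(x)
}
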