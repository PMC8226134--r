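#' Assemble the multiscale entropy ledger
#'
#' Slots every computed entropy component into the (species, level, type,
#' motion) bookkeeping and checks the set against what each species' length
#' scales require: vibrational translation at every declared level,
#' vibrational rotation at levels where the unit has rotational freedom,
#' topographical translation (conformational) for species with registered
#' dihedrals, and topographical rotation (orientational) for water. A
#' missing declared component or an undeclared extra is a hard error.
#'
#' @param vib data.frame from \code{\link{vibrational_entropy}} (or same
#'   shape), one row per molecule/level/motion.
#' @param topo data.frame with columns species_role, level, type, motion, S
#'   for the topographical terms (may be NULL).
#' @param topology an \code{eemcc_topology}.
#' @return an \code{eemcc_entropy_ledger}: data.frame (species_role, level,
#'   type, motion, S) with attribute \code{"total"} (J/K/mol).
#' @export
assemble_ledger <- function(vib, topo = NULL, topology) {
  vib_sp <- aggregate(S ~ species_role + level + motion, vib, sum)
  vib_sp$type <- "vibrational"
  comp <- vib_sp[, c("species_role", "level", "type", "motion", "S")]
  if (!is.null(topo) && nrow(topo))
    comp <- rbind(comp, topo[, c("species_role", "level", "type", "motion",
                                 "S")])

  # declared component set per species role
  mol <- topology$molecules
  declared <- list()
  for (role in unique(mol$species_role)) {
    mid <- mol$molecule_id[mol$species_role == role][1]
    lv <- declared_levels(topology, mid)
    for (l in lv) {
      declared[[length(declared) + 1]] <- c(role, l, "vibrational",
                                            "translation")
      # rotation exists at a level only if some unit there is polyatomic
      if (any(lengths(level_units(topology, mid, l)) >= 2))
        declared[[length(declared) + 1]] <- c(role, l, "vibrational",
                                              "rotation")
    }
    dih <- topology$dihedrals
    mono <- topology$monomers
    has_dih <- nrow(dih) > 0 &&
      any(mono$molecule_id[match(dih$monomer_id, mono$monomer_id)] %in%
            mol$molecule_id[mol$species_role == role])
    if (has_dih)
      declared[[length(declared) + 1]] <- c(role, "UA", "topographical",
                                            "translation")
    if (role == "water")
      declared[[length(declared) + 1]] <- c(role, "UA", "topographical",
                                            "rotation")
  }
  dec <- as.data.frame(do.call(rbind, declared), stringsAsFactors = FALSE)
  names(dec) <- c("species_role", "level", "type", "motion")
  keyd <- do.call(paste, dec)
  keyc <- do.call(paste, comp[, names(dec)])
  if (length(setdiff(keyd, keyc)))
    stop("missing declared entropy component(s): ",
         paste(setdiff(keyd, keyc), collapse = "; "))
  if (length(setdiff(keyc, keyd)))
    stop("undeclared entropy component(s): ",
         paste(setdiff(keyc, keyd), collapse = "; "))
  comp <- comp[order(comp$species_role, comp$level, comp$type, comp$motion), ]
  rownames(comp) <- NULL
  structure(comp, total = sum(comp$S),
            class = c("eemcc_entropy_ledger", "data.frame"))
}

#' Total entropy of a ledger
#' @param ledger an \code{eemcc_entropy_ledger}.
#' @return total S in J/K/mol.
#' @export
ledger_total <- function(ledger) attr(ledger, "total")

#' Binding free energy with hydration-water bookkeeping
#'
#' For each solute species X, the free-energy change of transferring it
#' from its dilute reference into the mixed ("bound") system is
#' G_bnd(X) N_X,bnd + G_Wbnd N_WX,bnd + G_bulk (N_WX,dil - N_WX,bnd)
#' - G_dil(X) N_X,dil - G_Wdil N_WX,dil: hydration waters that the bound
#' state no longer holds are priced at the bulk-water free energy. The same
#' bookkeeping applies to H and TS columns, so dG = dH - TdS holds row-wise
#' by construction.
#'
#' @param bound,dilute data.frames with one row per species: columns
#'   species, N (molecule count), G, H, TS (per molecule, kJ/mol), N_W
#'   (hydration-shell water count), G_W, H_W, TS_W (per hydration water,
#'   kJ/mol).
#' @param bulk named numeric with G, H, TS of a bulk water molecule.
#' @return an \code{eemcc_fe_table}: data.frame with solute and hydration
#'   rows per species plus a Total row; columns row, species, dG, dH, dTS.
#' @export
binding_delta_g <- function(bound, dilute, bulk) {
  stopifnot(all(c("G", "H", "TS") %in% names(bulk)))
  sp <- union(bound$species, dilute$species)
  b <- bound[match(sp, bound$species), ]
  d <- dilute[match(sp, dilute$species), ]
  if (any(b$N_W < 0, na.rm = TRUE) || any(d$N_W < 0, na.rm = TRUE))
    stop("negative hydration-water count")
  rows <- list()
  for (i in seq_along(sp)) {
    dn <- function(col, colW, bulkv) {
      (b[[col]][i] * b$N[i] + b[[colW]][i] * b$N_W[i] +
         bulkv * (d$N_W[i] - b$N_W[i])) -
        (d[[col]][i] * d$N[i] + d[[colW]][i] * d$N_W[i])
    }
    solute <- c(b$G[i] * b$N[i] - d$G[i] * d$N[i],
                b$H[i] * b$N[i] - d$H[i] * d$N[i],
                b$TS[i] * b$N[i] - d$TS[i] * d$N[i])
    water <- c(dn("G", "G_W", bulk[["G"]]) - solute[1],
               dn("H", "H_W", bulk[["H"]]) - solute[2],
               dn("TS", "TS_W", bulk[["TS"]]) - solute[3])
    rows[[length(rows) + 1]] <- data.frame(
      row = sp[i], species = sp[i], dG = solute[1], dH = solute[2],
      dTS = solute[3], stringsAsFactors = FALSE)
    rows[[length(rows) + 1]] <- data.frame(
      row = paste0("W_", sp[i]), species = sp[i], dG = water[1],
      dH = water[2], dTS = water[3], stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  tot <- data.frame(row = "Total", species = NA,
                    dG = sum(out$dG), dH = sum(out$dH), dTS = sum(out$dTS))
  structure(rbind(out, tot), class = c("eemcc_fe_table", "data.frame"))
}

#' @export
print.eemcc_fe_table <- function(x, ...) {
  cat("eemcc binding free-energy decomposition (kJ/mol):\n")
  y <- as.data.frame(x)
  y[c("dG", "dH", "dTS")] <- round(y[c("dG", "dH", "dTS")], 1)
  print(y[, c("row", "dG", "dH", "dTS")], row.names = FALSE)
  invisible(x)
}

#' Export a free-energy decomposition table as CSV
#'
#' Values are rounded to whole kJ/mol (the precision such tables are
#' conventionally printed at). The export first verifies the exact
#' bookkeeping identity (components sum to the Total to float precision)
#' and then that the rounded components sum to the rounded Total within the
#' rounding slack, which defaults to the worst case of half a unit per
#' component row. Internal precision is never rounded.
#'
#' @param fe an \code{eemcc_fe_table}.
#' @param path output CSV.
#' @param slack allowed |sum(rounded components) - rounded Total| (default
#'   \code{ceiling(n_components / 2)}).
#' @return invisibly, the rounded table.
#' @export
export_fe_table <- function(fe, path, slack = NULL) {
  y <- as.data.frame(fe)
  comp <- y[y$row != "Total", ]
  tot <- y[y$row == "Total", ]
  if (is.null(slack)) slack <- ceiling(nrow(comp) / 2)
  r <- function(v) round(v)
  for (col in c("dG", "dH", "dTS")) {
    if (abs(sum(comp[[col]]) - tot[[col]]) >
        1e-9 * max(1, abs(tot[[col]])))
      stop("unrounded ", col, " components do not sum to the Total")
  }
  for (col in c("dG", "dH", "dTS")) {
    if (abs(sum(r(comp[[col]])) - r(tot[[col]])) > slack)
      stop("rounded ", col, " components do not sum to the Total within ",
           slack)
  }
  out <- data.frame(row = y$row, dG = r(y$dG), dH = r(y$dH),
                    dTS = r(y$dTS))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}

#' Free energy G = H - T S per species from an energy and entropy ledger
#'
#' @param energy data.frame with species_role and H (kJ/mol).
#' @param entropy an \code{eemcc_entropy_ledger} (or data.frame with
#'   species_role and S in J/K/mol).
#' @param constants \code{\link{eemcc_constants}}.
#' @return data.frame: species_role, H, TS (kJ/mol), G = H - TS.
#' @export
species_free_energy <- function(energy, entropy,
                                constants = eemcc_constants()) {
  S <- aggregate(S ~ species_role, as.data.frame(entropy), sum)
  m <- match(energy$species_role, S$species_role)
  TS <- constants$T * S$S[m] / 1000  # J/K/mol -> kJ/mol
  TS[is.na(TS)] <- 0
  data.frame(species_role = energy$species_role, H = energy$H, TS = TS,
             G = energy$H - TS)
}

#' Grouped free-energy decomposition
#'
#' Sums per-item dG/dH/dTS values over a grouping (monomer class, residue
#' pair, ...). Items missing from \code{groups} raise an error, so the
#' grouped totals always add up to the overall total.
#'
#' @param values data.frame with columns id and any of dG, dH, dTS (or G,
#'   H, TS).
#' @param groups data.frame with columns id, group.
#' @return data.frame with one row per group plus the summed columns.
#' @export
classwise_decomposition <- function(values, groups) {
  m <- match(values$id, groups$id)
  if (anyNA(m)) stop("item(s) without a group assignment: ",
                     paste(values$id[is.na(m)], collapse = ", "))
  g <- groups$group[m]
  num <- names(values)[vapply(values, is.numeric, logical(1))]
  agg <- aggregate(values[num], by = list(group = g), FUN = sum)
  agg
}

#' Nearest-two-residue key for each shell water
#'
#' For every water and frame, the two nearest protein monomers with a
#' united atom in the water's coordination shell (by shell distance) give
#' the residue-pair key used in per-residue water decompositions; waters
#' with fewer than two protein monomers in the shell get the single monomer
#' or NA.
#'
#' @param shells an \code{eemcc_shells}.
#' @param topology an \code{eemcc_topology}.
#' @return character matrix n_waters x n_frames of keys
#'   ("class1|class2" sorted), NA where no protein contact.
#' @export
water_residue_pairs <- function(shells, topology) {
  ua <- shells$ua
  wrow <- which(ua$species_role == "water")
  keys <- matrix(NA_character_, length(wrow), shells$n_frames)
  for (f in seq_len(shells$n_frames)) {
    fr <- shells$shells[[f]]
    for (k in seq_along(wrow)) {
      sh <- fr[[wrow[k]]]
      if (!length(sh)) next
      d <- attr(sh, "dist")
      prot <- ua$species_role[sh] == "protein"
      if (!any(prot)) next
      mono <- ua$monomer_id[sh][prot]
      dd <- d[prot]
      o <- order(dd)
      picked <- unique(mono[o])[1:min(2, length(unique(mono[o])))]
      cls <- ua$monomer_class[sh][prot][match(picked, mono)]
      keys[k, f] <- paste(sort(cls), collapse = "|")
    }
  }
  keys
}

#' Standard error over groups of walkers
#'
#' Group-of-poses error estimate: the per-walker values are averaged within
#' each group and the standard error is the standard deviation of the group
#' means divided by sqrt(number of groups).
#'
#' @param values per-walker values.
#' @param groups group label per walker (at least two groups).
#' @return the standard error of the group means.
#' @export
group_standard_error <- function(values, groups) {
  gm <- tapply(values, groups, mean)
  if (length(gm) < 2) stop("need at least two groups")
  stats::sd(gm) / sqrt(length(gm))
}
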