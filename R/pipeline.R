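#' Full single-ensemble analysis
#'
#' Runs the solvent-structure, entropy and energy stages on one ensemble:
#' coordination shells, hydrogen bonds, water classification and
#' nearest-solute assignment, contact table, vibrational entropy at each
#' species' declared levels, conformational entropy of registered dihedrals,
#' water orientational entropy, and the weighted energy ledger; reduces them
#' to per-species per-molecule H, TS and G = H - TS and per-solute
#' hydration-water rows.
#'
#' @param topology an \code{eemcc_topology}.
#' @param frames an \code{eemcc_frames}.
#' @param weights optional per-frame weights (NULL for uniform).
#' @param constants \code{\link{eemcc_constants}}.
#' @param cutoff RAD candidate cutoff, Angstrom.
#' @param verbose emit per-stage INFO messages (default FALSE).
#' @return an \code{eemcc_analysis} list; see Details in the package
#'   vignette.
#' @export
analyse_ensemble <- function(topology, frames, weights = NULL,
                             constants = eemcc_constants(), cutoff = 8,
                             verbose = FALSE) {
  info <- function(...) if (verbose) message("INFO: ", ...)
  nf <- frames$n_frames
  if (is.null(weights)) weights <- rep(1, nf)
  w <- weights / sum(weights)

  shells <- build_shells(frames, topology, cutoff = cutoff)
  info("shells built for ", nrow(shells$ua), " united atoms over ", nf,
       " frames")
  hb <- assign_hbonds(frames, shells, topology)
  env <- classify_water(shells, topology)
  assign <- water_solute_assignment(shells)
  contacts <- contact_table(shells, topology, weights = weights)
  info("waters classified: ",
       paste(names(table(env$labels)), as.integer(table(env$labels)),
             collapse = ", "))

  has_water <- any(topology$molecules$species_role == "water")
  orient <- NULL; S_orient <- 0
  if (has_water) {
    orient <- donor_acceptor_probabilities(frames, shells, hb, topology,
                                           weights = weights)
    S_orient <- as.numeric(orientational_entropy(orient, constants))
    info("orientational entropy per water: ", signif(S_orient, 4),
         " J/K/mol over ", nrow(orient$shell_types), " shell types")
  }

  vib <- vibrational_entropy(frames, topology, weights = weights,
                             constants = constants)
  conf <- monomer_conformational_entropy(frames, topology,
                                         weights = weights,
                                         constants = constants)
  energy <- aggregate_energy(frames, topology, weights = weights,
                             water_env = env)

  mol <- topology$molecules
  roles <- sort(unique(mol$species_role))
  nmol <- table(factor(mol$species_role, roles))
  vibS <- aggregate(S ~ species_role, vib, sum)
  confS <- if (!is.null(conf)) aggregate(S ~ species_role, conf, sum) else NULL
  species <- data.frame(species_role = roles,
                        N = as.integer(nmol[roles]),
                        stringsAsFactors = FALSE)
  species$H <- energy$by_species$H[match(roles,
                                         energy$by_species$species_role)] /
    species$N
  Stot <- vibS$S[match(roles, vibS$species_role)]
  Stot[is.na(Stot)] <- 0
  if (!is.null(confS)) {
    add <- confS$S[match(roles, confS$species_role)]
    Stot <- Stot + ifelse(is.na(add), 0, add)
  }
  Sper <- Stot / species$N
  if (has_water) Sper[roles == "water"] <- Sper[roles == "water"] + S_orient
  species$TS <- constants$T * Sper / 1000
  species$G <- species$H - species$TS

  water_by_solute <- NULL
  if (has_water) {
    at <- topology$atoms
    wm <- attr(assign, "water_molecules")
    Hw <- t(vapply(wm, function(m)
      unit_enthalpy(frames, at$index[at$molecule_id == m]), numeric(nf)))
    dim(Hw) <- c(length(wm), nf)
    # per-water TS: molecule vibrational share plus the pooled orientational
    vib_w <- vib[vib$species_role == "water", ]
    S_vib_per_water <- sum(vib_w$S) / length(wm)
    TS_w <- constants$T * (S_vib_per_water + S_orient) / 1000
    classes <- c(setdiff(roles, "water"), "bulk")
    rows <- lapply(classes, function(cl) {
      sel <- assign == cl
      N_W <- sum(t(sel) * w)  # weighted mean count per frame
      H <- if (any(sel)) sum((t(sel) * w) * t(Hw)) / N_W else NA_real_
      data.frame(species = cl, N_W = N_W, H_W = H, TS_W = TS_w,
                 G_W = H - TS_w, stringsAsFactors = FALSE)
    })
    water_by_solute <- do.call(rbind, rows)
  }
  structure(
    list(shells = shells, hbonds = hb, water_env = env,
         assignment = assign, contacts = contacts, orient = orient,
         vibrational = vib, conformational = conf, energy = energy,
         species = species, water_by_solute = water_by_solute,
         weights = weights, constants = constants),
    class = "eemcc_analysis"
  )
}

resolve_ensemble <- function(spec, seed, constants) {
  if (!is.null(spec$generate)) {
    g <- spec$generate
    type <- g$type %||% "solvated_box"
    g$type <- NULL
    g$seed <- g$seed %||% seed
    if (type == "solvated_box") return(do.call(gen_solvated_box, g))
    if (type == "harmonic") return(do.call(gen_harmonic_ensemble, g))
    stop("unknown generator type: ", type)
  }
  p <- spec$paths
  if (is.null(p)) stop("ensemble needs either 'generate' or 'paths'")
  for (f in unlist(p)) if (!file.exists(f))
    stop("input file does not exist: ", f)
  topo <- read_topology(p$topology, p$sidecar, dihedrals = p$dihedrals)
  fr <- read_frames(p$trajectory)
  if (!is.null(p$bias)) fr <- set_bias(fr, read_bias(p$bias, fr))
  list(topology = topo, frames = fr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the configured analysis pipeline and export its tables
#'
#' Drives the whole workflow from a YAML (or list) run configuration:
#' resolve each named ensemble (generated synthetically or read from the
#' package's file dialects), convert bias to frame weights where enabled,
#' analyse every ensemble with \code{\link{analyse_ensemble}}, assemble the
#' bound-vs-dilute binding decomposition where configured, and write the
#' CSV table families plus a JSON manifest (versions, seed, config hash)
#' into the output directory.
#'
#' Config keys: \code{seed}, \code{temperature}, \code{cutoff},
#' \code{output_dir}, \code{stages} (logical toggles \code{reweight},
#' \code{entropy}, \code{energy}, \code{assemble}), \code{ensembles} (named
#' list; each entry has \code{generate} or \code{paths}), and
#' \code{assemble} (\code{bound}, \code{bulk} and a \code{dilute} map from
#' species role to ensemble name).
#'
#' @param config path to a YAML file or an equivalent list.
#' @param output_dir overrides the configured output directory.
#' @param verbose emit INFO messages (default TRUE).
#' @return invisibly, a list with the per-ensemble analyses, the binding
#'   table (if assembled) and the manifest.
#' @export
run_pipeline <- function(config, output_dir = NULL, verbose = TRUE) {
  cfg_path <- NULL
  if (is.character(config)) {
    cfg_path <- config
    config <- yaml::read_yaml(config)
  }
  seed <- config$seed %||% 1
  set.seed(seed)
  constants <- eemcc_constants(T = config$temperature %||% 298)
  cutoff <- config$cutoff %||% 8
  if (cutoff <= 0) stop("cutoff must be positive")
  out <- output_dir %||% config$output_dir %||% "eemcc_out"
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  stages <- config$stages %||% list()
  stage_on <- function(s) isTRUE(stages[[s]] %||% TRUE)
  info <- function(...) if (verbose) message("INFO: ", ...)

  analyses <- list()
  for (nm in names(config$ensembles)) {
    spec <- config$ensembles[[nm]]
    ens <- resolve_ensemble(spec, seed, constants)
    weights <- NULL
    if (stage_on("reweight") && !is.null(ens$frames$bias)) {
      weights <- as.numeric(frame_weights(ens$frames$bias, constants))
      utils::write.csv(
        data.frame(frame = seq_along(weights), time = ens$frames$time,
                   weight = weights),
        file.path(out, paste0("weights_", nm, ".csv")), row.names = FALSE)
    }
    info("analysing ensemble '", nm, "' (", ens$frames$n_frames, " frames, ",
         ens$frames$n_atoms, " atoms)")
    analyses[[nm]] <- analyse_ensemble(ens$topology, ens$frames,
                                       weights = weights,
                                       constants = constants,
                                       cutoff = cutoff, verbose = verbose)
    a <- analyses[[nm]]
    utils::write.csv(a$species,
                     file.path(out, paste0("species_", nm, ".csv")),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(a$contacts$counts),
                     file.path(out, paste0("contacts_", nm, ".csv")))
    utils::write.csv(contacts_per_molecule(a$contacts),
                     file.path(out, paste0("contacts_per_molecule_", nm,
                                           ".csv")))
    if (any(ens$topology$molecules$species_role == "water")) {
      utils::write.csv(water_environment_counts(a$water_env,
                                                weights = a$weights),
                       file.path(out, paste0("water_environments_", nm,
                                             ".csv")), row.names = FALSE)
      export_energy_histograms(a$energy,
                               file.path(out, paste0("water_energy_hist_",
                                                     nm, ".csv")))
    }
    utils::write.csv(a$vibrational,
                     file.path(out, paste0("entropy_vibrational_", nm,
                                           ".csv")), row.names = FALSE)
    if (!is.null(a$conformational))
      utils::write.csv(a$conformational,
                       file.path(out, paste0("entropy_conformational_", nm,
                                             ".csv")), row.names = FALSE)
    utils::write.csv(a$energy$by_class,
                     file.path(out, paste0("energy_by_class_", nm, ".csv")),
                     row.names = FALSE)
  }

  fe <- NULL
  if (stage_on("assemble") && !is.null(config$assemble)) {
    am <- config$assemble
    fe <- assemble_binding(analyses, bound = am$bound, bulk = am$bulk,
                           dilute_map = am$dilute)
    export_fe_table(fe, file.path(out, "binding_free_energy.csv"))
    info("binding decomposition assembled: total dG = ",
         round(fe$dG[fe$row == "Total"], 1), " kJ/mol")
  }

  manifest <- list(
    package = "eemcc",
    version = as.character(utils::packageVersion("eemcc")),
    r_version = R.version.string,
    seed = seed,
    temperature = constants$T,
    cutoff = cutoff,
    config_hash = if (!is.null(cfg_path)) unname(tools::md5sum(cfg_path))
                  else NA,
    ensembles = names(analyses),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(analyses = analyses, binding = fe, manifest = manifest,
                 output_dir = out))
}

#' Assemble the binding decomposition from analysed ensembles
#'
#' Pairs each solute species of the bound (mixed) ensemble with its dilute
#' reference ensemble, takes the bulk-water free energy from a pure-water
#' ensemble and evaluates the hydration-aware binding bookkeeping of
#' \code{\link{binding_delta_g}}.
#'
#' @param analyses named list of \code{eemcc_analysis} objects.
#' @param bound name of the mixed ensemble.
#' @param bulk name of the pure-water ensemble.
#' @param dilute_map named list mapping species role -> dilute ensemble name.
#' @return an \code{eemcc_fe_table}.
#' @export
assemble_binding <- function(analyses, bound, bulk, dilute_map) {
  b <- analyses[[bound]]
  if (is.null(b)) stop("unknown bound ensemble: ", bound)
  bw <- analyses[[bulk]]
  if (is.null(bw)) stop("unknown bulk ensemble: ", bulk)
  bulk_row <- bw$species[bw$species$species_role == "water", ]
  if (!nrow(bulk_row)) stop("bulk ensemble contains no water")
  bulk_vals <- c(G = bulk_row$G, H = bulk_row$H, TS = bulk_row$TS)

  mk_row <- function(an, role) {
    sp <- an$species[an$species$species_role == role, ]
    if (!nrow(sp)) stop("species '", role, "' absent from ensemble")
    wbs <- an$water_by_solute
    wr <- wbs[wbs$species == role, ]
    data.frame(species = role, N = sp$N, G = sp$G, H = sp$H, TS = sp$TS,
               N_W = wr$N_W,
               G_W = ifelse(is.na(wr$G_W), 0, wr$G_W),
               H_W = ifelse(is.na(wr$H_W), 0, wr$H_W),
               TS_W = wr$TS_W, stringsAsFactors = FALSE)
  }
  roles <- names(dilute_map)
  bound_df <- do.call(rbind, lapply(roles, function(r) mk_row(b, r)))
  dil_df <- do.call(rbind, lapply(roles, function(r) {
    an <- analyses[[dilute_map[[r]]]]
    if (is.null(an)) stop("unknown dilute ensemble: ", dilute_map[[r]])
    mk_row(an, r)
  }))
  binding_delta_g(bound_df, dil_df, bulk_vals)
}
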