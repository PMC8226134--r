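#' Synthetic harmonic ensemble with known spring constants
#'
#' Monatomic units with positions drawn from the exact Boltzmann
#' distribution of an isotropic harmonic well (displacement variance
#' kB T / k per axis), forces F = -k dx (force variance k kB T per axis),
#' per-atom potential energy U = k dx^2 / 2 and kinetic energy from the
#' Maxwell-Boltzmann distribution. The analytic mode frequency is
#' nu = (1/2 pi) sqrt(k/m), so the whole vibrational pipeline can be
#' validated against a closed form. Units are declared monatomic
#' highest-level species, so no mode removal applies.
#'
#' @param n_units number of independent harmonic units.
#' @param k spring constant, kJ/mol/Angstrom^2 (default 500, a stiff
#'   heavy-atom well).
#' @param m mass, amu (default 16).
#' @param T temperature, K.
#' @param n_frames frames to draw (default 5000).
#' @param box cubic box edge, Angstrom.
#' @param seed RNG seed.
#' @return list with \code{topology}, \code{frames} and \code{nu}, the
#'   analytic frequency in 1/s.
#' @export
gen_harmonic_ensemble <- function(n_units = 1, k = 500, m = 16, T = 298,
                                  n_frames = 5000, box = 50, seed = 1) {
  stopifnot(k > 0, m > 0, T > 0)
  set.seed(seed)
  const <- eemcc_constants(T)
  kBT <- const$kB * T
  centers <- matrix(stats::runif(3 * n_units, box * 0.25, box * 0.75),
                    n_units, 3)
  sd_x <- sqrt(kBT / k)
  sd_v <- sqrt(kBT / m)      # "velocity" in sqrt(kJ/mol/amu) units
  pos <- array(0, c(n_units, 3, n_frames))
  frc <- array(0, c(n_units, 3, n_frames))
  pe <- matrix(0, n_units, n_frames); ke <- matrix(0, n_units, n_frames)
  for (f in seq_len(n_frames)) {
    dx <- matrix(stats::rnorm(3 * n_units, 0, sd_x), n_units, 3)
    pos[, , f] <- centers + dx
    frc[, , f] <- -k * dx
    pe[, f] <- 0.5 * k * rowSums(dx^2)
    v <- matrix(stats::rnorm(3 * n_units, 0, sd_v), n_units, 3)
    ke[, f] <- 0.5 * m * rowSums(v^2)
  }
  atoms <- data.frame(
    index = seq_len(n_units), element = "X", mass = m, charge = 0,
    ua_id = sprintf("ua%03d", seq_len(n_units)),
    monomer_id = sprintf("m%03d", seq_len(n_units)),
    molecule_id = sprintf("mol%03d", seq_len(n_units)),
    monomer_class = "n/a", species_role = "probe", formal_charge = 0,
    stringsAsFactors = FALSE)
  topo <- as_topology(atoms)
  frames <- as_frames(seq_len(n_frames), rep(box, 3), pos, frc, pe, ke)
  list(topology = topo, frames = frames,
       nu = sqrt(k / m * const$freq2) / (2 * pi))
}

#' Synthetic dihedral series with prescribed conformer populations
#'
#' Angles are drawn from wrapped-normal peaks at the given centres with the
#' given populations, so the recovered conformational entropy has the
#' closed form -kB sum p log p.
#'
#' @param centers peak centres in degrees.
#' @param populations peak populations (must sum to 1).
#' @param sd_deg peak width (wrapped-normal sd, degrees; default 12).
#' @param n series length.
#' @param seed RNG seed.
#' @return numeric vector of angles in [-180, 180).
#' @export
gen_dihedral_series <- function(centers = c(-60, 60, 180),
                                populations = c(0.5, 0.3, 0.2),
                                sd_deg = 12, n = 2000, seed = 1) {
  if (abs(sum(populations) - 1) > 1e-8)
    stop("conformer populations must sum to 1")
  stopifnot(length(centers) == length(populations))
  set.seed(seed)
  comp <- sample.int(length(centers), n, replace = TRUE, prob = populations)
  a <- centers[comp] + stats::rnorm(n, 0, sd_deg)
  ((a + 180) %% 360) - 180
}

#' Synthetic water-shell observations with prescribed donor/acceptor bias
#'
#' Emits event-level observations for
#' \code{\link{orientational_stats_from_events}}: each observation is a
#' shell with the prescribed neighbour counts and donation/acceptance events
#' drawn from the prescribed categorical probabilities, so the recovered
#' p(Di), p(Ai) converge to the inputs with binomial error.
#'
#' @param spec data.frame with columns species, Ni, pD, pA; pD and pA must
#'   each sum to 1.
#' @param n_obs number of water-frame observations.
#' @param events_per_obs donation and acceptance events per observation
#'   (default 2, one per water hydrogen).
#' @param seed RNG seed.
#' @return list(shell, donations, acceptances, weights) ready for the
#'   accumulator.
#' @export
gen_water_shells <- function(spec, n_obs = 2000, events_per_obs = 2,
                             seed = 1) {
  stopifnot(all(c("species", "Ni", "pD", "pA") %in% names(spec)))
  if (abs(sum(spec$pD) - 1) > 1e-8 || abs(sum(spec$pA) - 1) > 1e-8)
    stop("pD and pA must each be normalised over species")
  set.seed(seed)
  counts <- stats::setNames(as.numeric(spec$Ni), spec$species)
  shell <- rep(list(counts), n_obs)
  draw <- function(p) replicate(n_obs, sample(spec$species, events_per_obs,
                                              replace = TRUE, prob = p),
                                simplify = FALSE)
  list(shell = shell, donations = draw(spec$pD),
       acceptances = draw(spec$pA), weights = rep(1, n_obs))
}

#' Symmetric or tilted double-well potential
#'
#' U(x) = h (x^2 - 1)^2 + (delta/2) x, giving wells near x = -1 and x = +1
#' with U(+1) - U(-1) = delta.
#'
#' @param h barrier scale, kJ/mol.
#' @param delta well asymmetry, kJ/mol (0 for the symmetric well).
#' @return list with functions \code{U(x)} and \code{dU(x)}.
#' @export
double_well <- function(h = 7, delta = 0) {
  list(U = function(x) h * (x^2 - 1)^2 + 0.5 * delta * x,
       dU = function(x) 4 * h * x * (x^2 - 1) + 0.5 * delta)
}

#' Toy well-tempered metadynamics sampler on an analytic 1-D potential
#'
#' Overdamped Langevin dynamics
#' dx = -(D / kB T) (U'(x) + V'(x, t)) dt + sqrt(2 D dt) xi
#' with Gaussian hills of width sigma deposited every \code{stride} steps at
#' the walker's position, with well-tempered height decay
#' W = W0 exp(-V(x, t) / (kB DeltaT)) and DeltaT = (gamma - 1) T. With
#' W0 = 0 the bias is identically zero. The saved per-frame bias is the
#' instantaneous deposited-hill sum V(x_t, t) evaluated at the frame's
#' position, the quantity \code{\link{frame_weights}} consumes.
#'
#' @param potential list with \code{U} and \code{dU} functions (see
#'   \code{\link{double_well}}).
#' @param x0 starting position.
#' @param n_steps integration steps.
#' @param dt time step.
#' @param D diffusion coefficient (position^2 / time).
#' @param T temperature, K.
#' @param W0 initial hill height, kJ/mol (default 1.5).
#' @param sigma hill width (default 0.2).
#' @param stride steps between depositions (default 500).
#' @param gamma bias factor (> 1; default 20).
#' @param save_stride steps between saved frames (default 10).
#' @param seed RNG seed.
#' @return list with \code{time}, \code{x}, \code{bias} (per saved frame),
#'   \code{hills} (data.frame center, height), \code{gamma}, \code{sigma}
#'   and \code{bias_fn(x)}, the final bias as a function.
#' @export
toy_wtmtd <- function(potential, x0 = -1, n_steps = 2e5, dt = 5e-3, D = 1,
                      T = 298, W0 = 1.5, sigma = 0.2, stride = 500,
                      gamma = 20, save_stride = 10, seed = 1) {
  if (gamma <= 1) stop("bias factor gamma must exceed 1")
  set.seed(seed)
  const <- eemcc_constants(T)
  kBT <- const$kB * T
  dT <- (gamma - 1) * T
  kBdT <- const$kB * dT
  centers <- numeric(0); heights <- numeric(0)
  Vb <- function(x) if (length(centers))
    sum(heights * exp(-(x - centers)^2 / (2 * sigma^2))) else 0
  dVb <- function(x) if (length(centers))
    sum(heights * exp(-(x - centers)^2 / (2 * sigma^2)) *
          (-(x - centers) / sigma^2)) else 0
  x <- x0
  n_save <- floor(n_steps / save_stride)
  xs <- numeric(n_save); bs <- numeric(n_save); ts <- numeric(n_save)
  noise_sd <- sqrt(2 * D * dt)
  kk <- 0L
  for (s in seq_len(n_steps)) {
    if (W0 > 0 && s %% stride == 0) {
      w <- W0 * exp(-Vb(x) / kBdT)
      centers <- c(centers, x); heights <- c(heights, w)
    }
    x <- x - D / kBT * (potential$dU(x) + dVb(x)) * dt +
      stats::rnorm(1, 0, noise_sd)
    if (s %% save_stride == 0) {
      kk <- kk + 1L
      xs[kk] <- x; bs[kk] <- Vb(x); ts[kk] <- s * dt
    }
  }
  list(time = ts, x = xs, bias = bs,
       hills = data.frame(center = centers, height = heights),
       gamma = gamma, sigma = sigma,
       bias_fn = function(q) vapply(q, Vb, numeric(1)))
}

#' Free-energy profile read from a converged well-tempered bias
#'
#' A well-tempered bias converges to -(1 - 1/gamma) G(s) + C, so the free
#' energy estimate is G(s) = -gamma/(gamma - 1) V(s) up to a constant.
#'
#' @param run a \code{\link{toy_wtmtd}} result.
#' @param grid positions to evaluate at.
#' @return data.frame with columns x and G (kJ/mol, min-shifted to zero).
#' @export
bias_free_energy <- function(run, grid) {
  G <- -run$gamma / (run$gamma - 1) * run$bias_fn(grid)
  data.frame(x = grid, G = G - min(G))
}

#' Blocked standard error of a weighted population estimate
#'
#' Splits the series into contiguous blocks, computes the weighted estimate
#' per block and returns the standard error of the block means; a simple
#' guard against serial correlation in sampler output.
#'
#' @param indicator logical/0-1 vector (e.g. x < 0).
#' @param weights per-frame weights (default uniform).
#' @param n_blocks number of blocks (default 5).
#' @return list(estimate, se).
#' @export
blocked_population <- function(indicator, weights = NULL, n_blocks = 5) {
  n <- length(indicator)
  if (is.null(weights)) weights <- rep(1, n)
  blk <- cut(seq_len(n), n_blocks, labels = FALSE)
  bm <- vapply(seq_len(n_blocks), function(b)
    weighted_mean_batch(indicator[blk == b], weights[blk == b]), numeric(1))
  list(estimate = weighted_mean_batch(indicator, weights),
       se = stats::sd(bm) / sqrt(n_blocks))
}

# place atom D given A, B, C with bond length r (C-D), angle theta (B-C-D,
# degrees) and torsion tau (A-B-C-D, degrees)
place_atom <- function(A, B, C, r, theta, tau) {
  th <- theta * pi / 180; ta <- tau * pi / 180
  bc <- C - B; bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d <- c(-r * cos(th), r * sin(th) * cos(ta), r * sin(th) * sin(ta))
  C + d[1] * bc + d[2] * m + d[3] * n
}

#' Synthetic solvated box for end-to-end pipeline runs
#'
#' A minimal mixed system in the package's dialects: two small model
#' proteins (chains of four-heavy-atom monomers with an amide-like donor, a
#' carbonyl-like acceptor and one registered backbone dihedral each), five
#' polyanions, buffer molecules, neutralising counterions and a shell of
#' three-site waters. Frames carry harmonic jitter about the built
#' geometry with consistent forces and per-atom energies; each protein
#' monomer's dihedral is resampled per frame from prescribed conformer
#' populations, and water orientations are re-randomised per frame so the
#' hydrogen-bond statistics are exercised. Molecule counts default to the
#' study-like composition (two proteins, five polyanions with formal
#' charges -4, -5, -5, -5, -5, three buffers) with the solvent scaled to
#' desk size.
#'
#' @param n_protein number of protein molecules (default 2).
#' @param monomers_per_protein monomers per protein (default 4).
#' @param n_polyanion number of polyanion molecules (default 5).
#' @param polyanion_charges formal charges (default one -4 and the rest -5).
#' @param n_buffer buffer molecules (default 3).
#' @param n_water water molecules (default 60).
#' @param box cubic box edge, Angstrom (default 26).
#' @param n_frames frames (default 100; keep above 3x the largest unit
#'   count per level so the force covariances are full rank).
#' @param T temperature, K.
#' @param k_jitter harmonic jitter spring constant, kJ/mol/Angstrom^2
#'   (default 250).
#' @param conformer_pops dihedral conformer populations at -60/60/180
#'   degrees (default c(0.5, 0.3, 0.2)).
#' @param seed RNG seed.
#' @return list with \code{topology} and \code{frames}.
#' @export
gen_solvated_box <- function(n_protein = 2, monomers_per_protein = 4,
                             n_polyanion = 5, polyanion_charges = NULL,
                             n_buffer = 3, n_water = 60, box = 26,
                             n_frames = 100, T = 298, k_jitter = 250,
                             conformer_pops = c(0.5, 0.3, 0.2), seed = 1) {
  set.seed(seed)
  if (is.null(polyanion_charges) && n_polyanion > 0)
    polyanion_charges <- c(-4, rep(-5, n_polyanion - 1))
  const <- eemcc_constants(T)
  kBT <- const$kB * T

  atoms <- list(); bonds <- list(); dih <- list()
  sites <- list()          # per-atom reference positions
  idx <- 0L; ua <- 0L; mono <- 0L; molc <- 0L
  add_atom <- function(el, mass, q, uaid, mid, molid, cls, role, fc, p) {
    idx <<- idx + 1L
    atoms[[idx]] <<- data.frame(
      index = idx, element = el, mass = mass, charge = q, ua_id = uaid,
      monomer_id = mid, molecule_id = molid, monomer_class = cls,
      species_role = role, formal_charge = fc, stringsAsFactors = FALSE)
    sites[[idx]] <<- p
    idx
  }
  occupied <- matrix(numeric(0), 0, 3)
  place_center <- function(min_sep) {
    repeat {
      p <- stats::runif(3, 4, box - 4)
      if (!nrow(occupied)) break
      d <- sweep(occupied, 2, p)
      d <- min_image(d, rep(box, 3))
      if (min(sqrt(rowSums(d * d))) > min_sep) break
    }
    occupied <<- rbind(occupied, p)
    p
  }

  classes <- c("basic", "acidic", "uncharged-polar", "non-polar")
  # proteins: monomers are N(H)-C-C-O chains, one dihedral per monomer
  for (pr in seq_len(n_protein)) {
    molc <- molc + 1L
    molid <- sprintf("prot%d", pr)
    base <- place_center(9)
    dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
    for (mm in seq_len(monomers_per_protein)) {
      mono <- mono + 1L
      mid <- sprintf("%s:res%d", molid, mm)
      cls <- classes[(mm - 1) %% 4 + 1]
      org <- base + (mm - 1) * 4.0 * dir
      perp <- stats::rnorm(3); perp <- perp - sum(perp * dir) * dir
      perp <- perp / sqrt(sum(perp^2))
      pN <- org
      pC2 <- org + 1.47 * perp
      pC3 <- pC2 + 1.53 * dir
      pC4 <- place_atom(pN, pC2, pC3, 1.43, 109.5, -60)
      pH <- pN + 1.01 * (pN - pC2) / sqrt(sum((pN - pC2)^2))
      ua <- ua + 1L; u1 <- sprintf("ua%04d", ua)
      aN <- add_atom("N", 14.007, -0.42, u1, mid, molid, cls, "protein", 8, pN)
      aH <- add_atom("H", 1.008, 0.32, u1, mid, molid, cls, "protein", 8, pH)
      ua <- ua + 1L
      aC2 <- add_atom("C", 12.011, 0.10, sprintf("ua%04d", ua), mid, molid,
                      cls, "protein", 8, pC2)
      ua <- ua + 1L
      aC3 <- add_atom("C", 12.011, 0.10, sprintf("ua%04d", ua), mid, molid,
                      cls, "protein", 8, pC3)
      ua <- ua + 1L
      aO <- add_atom("O", 15.999, -0.50, sprintf("ua%04d", ua), mid, molid,
                     cls, "protein", 8, pC4)
      bonds[[length(bonds) + 1]] <- rbind(c(aN, aH), c(aN, aC2),
                                          c(aC2, aC3), c(aC3, aO))
      dih[[length(dih) + 1]] <- data.frame(a1 = aN, a2 = aC2, a3 = aC3,
                                           a4 = aO)
    }
  }
  # polyanions: three O- chain
  for (pa in seq_len(n_polyanion)) {
    molid <- sprintf("pa%d", pa)
    mid <- paste0(molid, ":1")
    org <- place_center(6)
    prev <- integer(0)
    for (j in 1:3) {
      ua <- ua + 1L
      a <- add_atom("O", 15.999, -0.85, sprintf("ua%04d", ua), mid, molid,
                    "n/a", "polyanion", polyanion_charges[pa],
                    org + c(1.5 * (j - 1), 0, 0))
      if (length(prev)) bonds[[length(bonds) + 1]] <- rbind(c(prev, a))
      prev <- a
    }
  }
  # buffer: N(H)-C-O
  for (bu in seq_len(n_buffer)) {
    molid <- sprintf("buf%d", bu)
    mid <- paste0(molid, ":1")
    org <- place_center(6)
    ua <- ua + 1L; u1 <- sprintf("ua%04d", ua)
    aN <- add_atom("N", 14.007, -0.30, u1, mid, molid, "n/a", "buffer", 1,
                   org)
    aH <- add_atom("H", 1.008, 0.33, u1, mid, molid, "n/a", "buffer", 1,
                   org + c(0, 0, 1.01))
    ua <- ua + 1L
    aC <- add_atom("C", 12.011, 0.12, sprintf("ua%04d", ua), mid, molid,
                   "n/a", "buffer", 1, org + c(1.5, 0, 0))
    ua <- ua + 1L
    aO <- add_atom("O", 15.999, -0.45, sprintf("ua%04d", ua), mid, molid,
                   "n/a", "buffer", 1, org + c(3.0, 0, 0))
    bonds[[length(bonds) + 1]] <- rbind(c(aN, aH), c(aN, aC), c(aC, aO))
  }
  # counterions: neutralise polyanions with cations, proteins+buffer with anions
  n_cation <- if (n_polyanion) sum(-polyanion_charges) else 0
  n_anion <- n_protein * 8 + n_buffer * 1
  for (i in seq_len(n_cation)) {
    molid <- sprintf("na%d", i); ua <- ua + 1L
    add_atom("Na", 22.99, 1, sprintf("ua%04d", ua), paste0(molid, ":1"),
             molid, "n/a", "cation", 1, place_center(3.2))
  }
  for (i in seq_len(n_anion)) {
    molid <- sprintf("cl%d", i); ua <- ua + 1L
    add_atom("Cl", 35.45, -1, sprintf("ua%04d", ua), paste0(molid, ":1"),
             molid, "n/a", "anion", -1, place_center(3.2))
  }
  # waters
  for (i in seq_len(n_water)) {
    molid <- sprintf("w%d", i)
    org <- place_center(2.9)
    ua <- ua + 1L; u1 <- sprintf("ua%04d", ua)
    aO <- add_atom("O", 15.999, -0.834, u1, paste0(molid, ":1"), molid,
                   "n/a", "water", 0, org)
    aH1 <- add_atom("H", 1.008, 0.417, u1, paste0(molid, ":1"), molid,
                    "n/a", "water", 0, org + c(0.9572, 0, 0))
    aH2 <- add_atom("H", 1.008, 0.417, u1, paste0(molid, ":1"), molid,
                    "n/a", "water", 0,
                    org + 0.9572 * c(cos(104.52 * pi / 180),
                                     sin(104.52 * pi / 180), 0))
    bonds[[length(bonds) + 1]] <- rbind(c(aO, aH1), c(aO, aH2))
  }

  atoms <- do.call(rbind, atoms)
  topo <- as_topology(atoms, bonds = do.call(rbind, bonds),
                      dihedrals = do.call(rbind, dih))
  ref <- do.call(rbind, sites)

  # frames: harmonic jitter + dihedral resampling + water reorientation
  n_at <- nrow(atoms)
  sd_x <- sqrt(kBT / k_jitter)
  pos <- array(0, c(n_at, 3, n_frames)); frc <- array(0, c(n_at, 3, n_frames))
  pe <- matrix(0, n_at, n_frames); ke <- matrix(0, n_at, n_frames)
  dihdf <- topo$dihedrals
  wat_o <- atoms$index[atoms$species_role == "water" & atoms$element == "O"]
  conf_centers <- c(-60, 60, 180)
  rand_rot <- function() {
    q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
    matrix(c(1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] - q[1] * q[4]),
             2 * (q[2] * q[4] + q[1] * q[3]),
             2 * (q[2] * q[3] + q[1] * q[4]), 1 - 2 * (q[2]^2 + q[4]^2),
             2 * (q[3] * q[4] - q[1] * q[2]),
             2 * (q[2] * q[4] - q[1] * q[3]),
             2 * (q[3] * q[4] + q[1] * q[2]), 1 - 2 * (q[2]^2 + q[3]^2)),
           3, 3, byrow = TRUE)
  }
  for (f in seq_len(n_frames)) {
    p <- ref
    # dihedral conformers
    for (r in seq_len(nrow(dihdf))) {
      tgt <- conf_centers[sample.int(3, 1, prob = conformer_pops)] +
        stats::rnorm(1, 0, 10)
      p[dihdf$a4[r], ] <- place_atom(p[dihdf$a1[r], ], p[dihdf$a2[r], ],
                                     p[dihdf$a3[r], ], 1.43, 109.5, tgt)
    }
    # water orientations
    for (o in wat_o) {
      R <- rand_rot()
      for (hh in c(o + 1L, o + 2L))
        p[hh, ] <- p[o, ] + as.numeric(R %*% (ref[hh, ] - ref[o, ]))
    }
    dx <- matrix(stats::rnorm(3 * n_at, 0, sd_x), n_at, 3)
    pos[, , f] <- p + dx
    frc[, , f] <- -k_jitter * dx
    pe[, f] <- 0.5 * k_jitter * rowSums(dx^2)
    v <- matrix(stats::rnorm(3 * n_at, 0, 1), n_at, 3) *
      sqrt(kBT / atoms$mass)
    ke[, f] <- 0.5 * atoms$mass * rowSums(v^2)
  }
  frames <- as_frames(seq_len(n_frames), rep(box, 3), pos, frc, pe, ke)
  list(topology = topo, frames = frames)
}
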