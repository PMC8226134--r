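# Shared fixtures and independent oracles, built in code at test time.

# independent brute-force evaluation of the shell blocking criterion:
# j is retained iff for every closer candidate k,
# 1/r_ij^2 >= (1/r_ik^2) * cos(theta_jik). Deliberately written as plain
# nested loops with acos-free dot products, independent of rad_shell().
brute_rad <- function(positions, box = NULL, center, cutoff = 8) {
  cand <- setdiff(seq_len(nrow(positions)), center)
  d <- sweep(positions[cand, , drop = FALSE], 2, positions[center, ], "-")
  if (!is.null(box)) d <- eemcc::min_image(d, box)
  r <- sqrt(rowSums(d * d))
  keep <- r <= cutoff
  cand <- cand[keep]; d <- d[keep, , drop = FALSE]; r <- r[keep]
  retained <- integer(0)
  for (jj in seq_along(cand)) {
    blocked <- FALSE
    for (kk in seq_along(cand)) {
      if (kk == jj || r[kk] >= r[jj]) next
      cosang <- sum(d[jj, ] * d[kk, ]) / (r[jj] * r[kk])
      if (1 / r[jj]^2 < cosang / r[kk]^2) { blocked <- TRUE; break }
    }
    if (!blocked) retained <- c(retained, cand[jj])
  }
  sort(retained)
}

# minimal atom-table builder for hand-made topologies
atom_row <- function(index, element, mass, charge, ua, mono, mol,
                     cls = "n/a", role = "water", fc = 0) {
  data.frame(index = index, element = element, mass = mass, charge = charge,
             ua_id = ua, monomer_id = mono, molecule_id = mol,
             monomer_class = cls, species_role = role, formal_charge = fc,
             stringsAsFactors = FALSE)
}

# a single three-site water topology
water_topology <- function() {
  atoms <- rbind(
    atom_row(1, "O", 15.999, -0.834, "w1", "w1:1", "w1"),
    atom_row(2, "H", 1.008, 0.417, "w1", "w1:1", "w1"),
    atom_row(3, "H", 1.008, 0.417, "w1", "w1:1", "w1"))
  as_topology(atoms, bonds = rbind(c(1, 2), c(1, 3)))
}

# hand-made frames: positions array from a list of n x 3 matrices
frames_from_positions <- function(poslist, box = 50, forces = NULL,
                                  pe = NULL, ke = NULL) {
  na <- nrow(poslist[[1]]); nf <- length(poslist)
  pos <- array(0, c(na, 3, nf))
  for (f in seq_len(nf)) pos[, , f] <- poslist[[f]]
  as_frames(seq_len(nf), rep(box, 3), pos, forces, pe, ke)
}

# quantum harmonic oscillator entropy at frequency nu (independent of svib)
qho_entropy <- function(nu, constants = eemcc_constants()) {
  x <- constants$h * nu / (constants$kB * constants$T)
  constants$kB_entropy * sum(x / (exp(x) - 1) - log(1 - exp(-x)))
}
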