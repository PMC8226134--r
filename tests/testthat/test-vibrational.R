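test_that("frozen units have zero force covariance", {
  h <- gen_harmonic_ensemble(n_units = 1, n_frames = 10, seed = 1)
  fr <- h$frames
  for (f in 2:fr$n_frames) {
    fr$positions[, , f] <- fr$positions[, , 1]
    fr$forces[, , f] <- fr$forces[, , 1]
  }
  cv <- build_covariances(fr, h$topology, "mol001", "UA")
  expect_equal(max(abs(cv$fcov)), 0)
})

test_that("harmonic force variance matches k kB T", {
  const <- eemcc_constants()
  k <- 400; m <- 12
  h <- gen_harmonic_ensemble(n_units = 1, k = k, m = m, n_frames = 8000,
                             seed = 3)
  cv <- build_covariances(h$frames, h$topology, "mol001", "UA")
  # mass-weighted: expect k kB T / m on the diagonal
  expect_equal(mean(diag(cv$fcov)), k * const$kB * const$T / m,
               tolerance = 0.05)
})

test_that("doubling masses at fixed forces halves the weighted covariance", {
  h <- gen_harmonic_ensemble(n_units = 2, n_frames = 200, seed = 5)
  cv1 <- build_covariances(h$frames, h$topology, "mol001", "UA")
  topo2 <- h$topology
  topo2$atoms$mass <- topo2$atoms$mass * 2
  cv2 <- build_covariances(h$frames, topo2, "mol001", "UA")
  expect_equal(cv2$fcov, cv1$fcov / 2, tolerance = 1e-12)
})

test_that("single-frame covariance is a hard error", {
  h <- gen_harmonic_ensemble(n_units = 1, n_frames = 5, seed = 1)
  fr1 <- as_frames(1, h$frames$box[1, ],
                   h$frames$positions[, , 1, drop = FALSE],
                   h$frames$forces[, , 1, drop = FALSE],
                   h$frames$pe[, 1, drop = FALSE],
                   h$frames$ke[, 1, drop = FALSE])
  expect_error(build_covariances(fr1, h$topology, "mol001", "UA"),
               "single-frame")
})

test_that("eigenvalue-to-frequency inversion recovers a planted frequency", {
  const <- eemcc_constants()
  nu0 <- 5e12
  lam <- (2 * pi * nu0)^2 * const$kB * const$T / const$freq2
  cv <- structure(list(molecule_id = "x", level = "UA",
                       fcov = diag(rep(lam, 3)), tcov = matrix(0, 0, 0),
                       rot_dof = 0L, n_units = 1, n_frames = 100,
                       weight_sum = 100),
                  class = "eemcc_covariances")
  md <- mode_frequencies(cv, const)
  expect_equal(md$nu, rep(nu0, 3), tolerance = 1e-12)
  # zero matrix -> all zero frequencies
  cv$fcov <- matrix(0, 3, 3)
  expect_equal(mode_frequencies(cv, const)$nu, rep(0, 3))
  # significantly negative eigenvalue -> error
  cv$fcov <- diag(c(lam, lam, -lam))
  expect_error(mode_frequencies(cv, const), "negative eigenvalue")
})

test_that("pipeline frequency matches the analytic harmonic frequency", {
  k <- 500; m <- 16
  h <- gen_harmonic_ensemble(n_units = 1, k = k, m = m, n_frames = 5000,
                             seed = 7)
  cv <- build_covariances(h$frames, h$topology, "mol001", "UA")
  md <- mode_frequencies(cv)
  expect_equal(mean(md$nu), h$nu, tolerance = 0.02)
})

test_that("six lowest translational modes are removed below the top level", {
  md <- structure(data.frame(
    motion = rep("translation", 12),
    nu = c(1:12) * 1e12, removed = FALSE), class = c("eemcc_modes",
                                                     "data.frame"))
  out <- remove_lowest_modes(md, highest = FALSE)
  expect_equal(sum(out$removed), 6)
  expect_equal(which(out$removed), 1:6)
  # highest level: identity
  expect_equal(sum(remove_lowest_modes(md, highest = TRUE)$removed), 0)
  # too few modes is ill-posed
  md6 <- md[1:6, ]
  expect_error(remove_lowest_modes(md6, highest = FALSE), "fewer than 7")
})

test_that("oscillator entropy hits landmarks and is additive and monotone", {
  const <- eemcc_constants()
  # hnu/kBT = 1
  nu1 <- const$kB * const$T / const$h
  md <- structure(data.frame(motion = "translation", nu = nu1,
                             removed = FALSE),
                  class = c("eemcc_modes", "data.frame"))
  expect_equal(svib(md, const) / const$kB_entropy,
               1 / (exp(1) - 1) - log(1 - exp(-1)), tolerance = 1e-12)
  expect_equal(svib(md, const) / const$kB_entropy, 1.0407, tolerance = 1e-4)
  # two identical modes double the entropy exactly
  md2 <- rbind(md, md)
  class(md2) <- class(md)
  expect_equal(svib(md2, const), 2 * svib(md, const))
  # stiff limit vanishes
  mdstiff <- md; mdstiff$nu <- 1e16
  expect_lt(svib(mdstiff, const), 1e-8)
  # per-mode entropy strictly decreasing in frequency
  nus <- 10^seq(11, 14, length.out = 12)
  s <- vapply(nus, qho_entropy, numeric(1))
  expect_true(all(diff(s) < 0))
  # removed modes are excluded
  md2$removed[1] <- TRUE
  expect_equal(svib(md2, const), svib(md, const))
})

test_that("end-to-end harmonic entropy matches the closed form within 2%", {
  k <- 500; m <- 16
  h <- gen_harmonic_ensemble(n_units = 1, k = k, m = m, n_frames = 5000,
                             seed = 11)
  vib <- vibrational_entropy(h$frames, h$topology)
  expect_equal(sum(vib$S), qho_entropy(rep(h$nu, 3)), tolerance = 0.02)
})

test_that("vibrational entropy is invariant under rigid rotation of frames", {
  h <- gen_harmonic_ensemble(n_units = 2, n_frames = 600, seed = 13)
  S0 <- sum(vibrational_entropy(h$frames, h$topology)$S)
  th <- 1.1
  R <- rbind(c(cos(th), 0, sin(th)), c(0, 1, 0), c(-sin(th), 0, cos(th)))
  fr <- h$frames
  for (f in seq_len(fr$n_frames)) {
    fr$positions[, , f] <- fr$positions[, , f] %*% t(R)
    fr$forces[, , f] <- fr$forces[, , f] %*% t(R)
  }
  S1 <- sum(vibrational_entropy(fr, h$topology)$S)
  expect_equal(S1, S0, tolerance = 1e-9)
})

test_that("levels are declared per species as the theory prescribes", {
  box <- gen_solvated_box(n_water = 5, n_frames = 2, seed = 1)
  topo <- box$topology
  prot <- topo$molecules$molecule_id[topo$molecules$species_role == "protein"][1]
  pa <- topo$molecules$molecule_id[topo$molecules$species_role == "polyanion"][1]
  wat <- topo$molecules$molecule_id[topo$molecules$species_role == "water"][1]
  ion <- topo$molecules$molecule_id[topo$molecules$species_role == "cation"][1]
  expect_equal(declared_levels(topo, prot), c("UA", "M", "P"))
  expect_equal(declared_levels(topo, pa), c("UA", "M"))
  expect_equal(declared_levels(topo, wat), "UA")
  expect_equal(declared_levels(topo, ion), "UA")
})
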