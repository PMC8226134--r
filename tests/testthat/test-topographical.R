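kB <- eemcc_constants()$kB_entropy

test_that("single-bin series yields one peak at that bin centre", {
  cf <- find_conformers(rnorm(200, 75, 3))  # all mass in the [60, 90) bin
  expect_equal(cf$centers, 75)
  expect_true(all(cf$assignment == 1L))
  expect_equal(cf$probs, 1)
})

test_that("well-separated trimodal series recovers three peak centres", {
  ang <- gen_dihedral_series(centers = c(-75, 45, 165),
                             populations = c(1, 1, 1) / 3, sd_deg = 8,
                             n = 3000, seed = 2)
  cf <- find_conformers(ang)
  expect_equal(sort(cf$centers), c(-75, 45, 165))
  expect_equal(length(cf$centers), 3)
  # every angle is assigned to exactly one peak
  expect_true(all(cf$assignment %in% seq_along(cf$centers)))
  expect_equal(sum(cf$probs), 1)
})

test_that("a flat histogram collapses to a single conformer with a warning", {
  ang <- seq(-180, 179.9, length.out = 1200)
  expect_warning(cf <- find_conformers(ang), "flat")
  expect_equal(length(cf$centers), 1)
  expect_equal(conformational_entropy(cf$assignment), 0)
  expect_error(find_conformers(numeric(0)), "empty")
})

test_that("conformational entropy reproduces Shannon landmarks", {
  # single state
  expect_equal(conformational_entropy(rep(1L, 50)), 0)
  # p = (0.5, 0.3, 0.2): S/kB ~ 1.0297 via direct weighted states
  asn <- c(rep(1, 5), rep(2, 3), rep(3, 2))
  S <- conformational_entropy(asn)
  expect_equal(S / kB, -sum(c(.5, .3, .2) * log(c(.5, .3, .2))),
               tolerance = 1e-12)
  expect_equal(S / kB, 1.0297, tolerance = 1e-4)
  # two independent uniform 3-state dihedrals: joint S/kB = log 9
  grid <- expand.grid(1:3, 1:3)
  S2 <- conformational_entropy(as.matrix(grid))
  expect_equal(S2 / kB, log(9), tolerance = 1e-12)
  # upper bound kB log(Nconf), equality iff uniform
  S3 <- conformational_entropy(c(1, 1, 2, 3))
  expect_lt(S3, kB * log(3))
})

test_that("generated dihedral populations recover the prescribed entropy", {
  pops <- c(0.5, 0.3, 0.2)
  n <- 4000
  ang <- gen_dihedral_series(populations = pops, n = n, seed = 4)
  cf <- find_conformers(ang)
  S <- conformational_entropy(cf$assignment) / kB
  S_true <- -sum(pops * log(pops))
  # 3 sigma multinomial error propagated through the Shannon sum
  se <- sqrt(sum((log(pops) + 1)^2 * pops * (1 - pops)) / n)
  expect_lt(abs(S - S_true), 3 * se + 0.01)
  # permuting peak labels leaves the entropy unchanged
  ang_sw <- gen_dihedral_series(centers = c(180, -60, 60),
                                populations = pops, n = n, seed = 4)
  cf_sw <- find_conformers(ang_sw)
  expect_equal(conformational_entropy(cf_sw$assignment) / kB, S,
               tolerance = 0.02)
  expect_error(gen_dihedral_series(populations = c(0.7, 0.6)), "sum to 1")
})

test_that("orientational entropy reproduces the bulk-water limit", {
  st <- orientational_stats_from_events(
    shell = rep(list(c(bulk = 4)), 50),
    donations = rep(list(rep("bulk", 2)), 50),
    acceptances = rep(list(rep("bulk", 2)), 50))
  row <- st$shell_types
  expect_equal(row$Nc, 4)
  expect_equal(row$p_HBav, 0.25)
  expect_equal(row$Neff, 4)
  S <- orientational_entropy(st)
  expect_equal(as.numeric(S) / kB, log((4 * pi)^1.5 * 0.25 / 2),
               tolerance = 1e-12)
  expect_equal(as.numeric(S) / kB, 1.717, tolerance = 1e-3)
})

test_that("hydrogen-bond bias follows the donor/acceptor fractions", {
  # fully donor-biased neighbour type: pHB = 0, Neff = 0
  st <- orientational_stats_from_events(
    shell = rep(list(c(solute = 4)), 20),
    donations = rep(list(rep("solute", 2)), 20),
    acceptances = rep(list(character(0)), 20))
  expect_equal(st$by_species$pHB, 0)
  expect_equal(st$shell_types$Neff, 0)
  # pD = pA = 0.5 across two types gives the unbiased 0.25 per type
  st2 <- orientational_stats_from_events(
    shell = rep(list(c(a = 2, b = 2)), 20),
    donations = rep(list(c("a", "b")), 20),
    acceptances = rep(list(c("a", "b")), 20))
  expect_equal(st2$by_species$pHB, c(0.25, 0.25))
  expect_equal(st2$shell_types$Neff, 4)
  # 3:1 acceptance split on a hand-made 4-observation fixture
  st3 <- orientational_stats_from_events(
    shell = rep(list(c(a = 3, b = 1)), 4),
    donations = rep(list(c("a", "b")), 4),
    acceptances = list(c("a", "a"), c("a", "a"), c("a", "a"), c("b", "b")))
  bs <- st3$by_species
  expect_equal(bs$pA[bs$species == "a"], 0.75)
  expect_equal(bs$pA[bs$species == "b"], 0.25)
})

test_that("the bias is symmetric under donor/acceptor exchange and maximal when unbiased", {
  pD <- c(0.7, 0.3); pA <- c(0.2, 0.8)
  phb <- function(d, a) ifelse(d + a > 0, d * a / (d + a)^2, 0)
  expect_equal(phb(pD, pA), phb(pA, pD))
  # p(HB) is maximised at the unbiased point 0.25
  d <- runif(50); a <- runif(50)
  expect_true(all(phb(d, a) <= 0.25 + 1e-12))
  expect_equal(phb(0.4, 0.4), 0.25)
})

test_that("recovered donor/acceptor fractions match generator inputs within 3 sigma", {
  spec <- data.frame(species = c("bulk", "solute"), Ni = c(3, 1),
                     pD = c(0.8, 0.2), pA = c(0.6, 0.4))
  n_obs <- 3000
  ev <- gen_water_shells(spec, n_obs = n_obs, seed = 6)
  st <- orientational_stats_from_events(ev$shell, ev$donations,
                                        ev$acceptances, ev$weights)
  bs <- st$by_species
  n_ev <- 2 * n_obs
  for (i in seq_len(nrow(spec))) {
    seD <- sqrt(spec$pD[i] * (1 - spec$pD[i]) / n_ev)
    seA <- sqrt(spec$pA[i] * (1 - spec$pA[i]) / n_ev)
    expect_lt(abs(bs$pD[bs$species == spec$species[i]] - spec$pD[i]), 3 * seD)
    expect_lt(abs(bs$pA[bs$species == spec$species[i]] - spec$pA[i]), 3 * seA)
  }
  # Neff agrees with the closed form on the generator inputs
  pHB <- spec$pD * spec$pA / (spec$pD + spec$pA)^2
  Neff_true <- sum(pHB * spec$Ni) / 0.25
  expect_equal(st$shell_types$Neff, Neff_true, tolerance = 0.05)
})

test_that("orientational entropy decreases away from the unbiased point", {
  mk <- function(pD1) {
    # species 1 with pD = pD1, pA = 1 - pD1 (so pHB = pD1 (1 - pD1));
    # species 2 unbiased at 0.25
    pHB <- c(pD1 * (1 - pD1), 0.25)
    Ni <- c(2, 2)
    Neff <- sum(pHB * Ni) / 0.25
    pav <- sum(pHB * Ni) / sum(Ni)
    log((Neff * pi)^1.5 * pav / 2)
  }
  vals <- vapply(c(0.5, 0.4, 0.3, 0.2, 0.1), mk, numeric(1))
  expect_true(all(diff(vals) < 0))
})
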