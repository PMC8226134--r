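test_that("two isolated atoms are each other's sole neighbour", {
  pos <- rbind(c(0, 0, 0), c(3, 0, 0))
  expect_equal(as.integer(rad_shell(pos, NULL, 1)), 2L)
  expect_equal(as.integer(rad_shell(pos, NULL, 2)), 1L)
})

test_that("a collinear intermediate atom blocks the farther one", {
  pos <- rbind(c(0, 0, 0), c(2, 0, 0), c(1, 0, 0))
  # from centre 1: atom 3 (r=1) blocks atom 2 (r=2), cos(theta)=1
  expect_equal(as.integer(rad_shell(pos, NULL, 1)), 3L)
})

test_that("all twelve FCC nearest neighbours are retained", {
  a <- 1 / sqrt(2)
  nn <- rbind(c(1, 1, 0), c(1, -1, 0), c(-1, 1, 0), c(-1, -1, 0),
              c(1, 0, 1), c(1, 0, -1), c(-1, 0, 1), c(-1, 0, -1),
              c(0, 1, 1), c(0, 1, -1), c(0, -1, 1), c(0, -1, -1)) * a
  pos <- rbind(c(0, 0, 0), nn)
  expect_equal(sort(as.integer(rad_shell(pos, NULL, 1, cutoff = 3))), 2:13)
})

test_that("shells match the brute-force blocking oracle on random instances", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(5:20, 1)
    box <- c(12, 12, 12)
    pos <- matrix(runif(3 * n, 0, 12), n, 3)
    for (center in seq_len(min(n, 5))) {
      got <- sort(as.integer(rad_shell(pos, box, center, cutoff = 6)))
      expect_identical(got, brute_rad(pos, box, center, cutoff = 6))
    }
  }
})

test_that("coincident positions are a hard error", {
  pos <- rbind(c(0, 0, 0), c(0, 0, 0), c(1, 1, 1))
  expect_error(rad_shell(pos, NULL, 1), "coincident")
})

test_that("hydrogen bonds pick the most negative qDqA/r^2 acceptor", {
  # donor H (q=+0.4) at origin; acceptor A (q=-0.8, r=2) beats B (q=-0.4, r=1.5)
  expect_lt(0.4 * -0.8 / 2^2, 0.4 * -0.4 / 1.5^2)
  atoms <- rbind(
    atom_row(1, "O", 15.999, -0.3, "d", "d:1", "d"),
    atom_row(2, "H", 1.008, 0.4, "d", "d:1", "d"),
    atom_row(3, "O", 15.999, -0.8, "a", "a:1", "a"),
    atom_row(4, "O", 15.999, -0.4, "b", "b:1", "b"))
  atoms$species_role <- c("buffer", "buffer", "anion", "anion")
  atoms$monomer_class <- "n/a"
  topo <- as_topology(atoms, bonds = rbind(c(1, 2)))
  pos <- rbind(c(0.2, 0, 0), c(0, 0, 0), c(2, 0, 0), c(0, 1.5, 0))
  fr <- frames_from_positions(list(pos), box = 30)
  sh <- build_shells(fr, topo)
  hb <- assign_hbonds(fr, sh, topo)
  acc <- hb$frames[[1]]
  expect_equal(nrow(acc), 1)  # the single donor hydrogen
  expect_equal(sh$ua$ua_id[acc$acceptor_ua], "a")
})

test_that("no acceptor is assigned when all products are non-negative", {
  atoms <- rbind(
    atom_row(1, "N", 14.007, -0.3, "d", "d:1", "d"),
    atom_row(2, "H", 1.008, 0.4, "d", "d:1", "d"),
    atom_row(3, "Na", 22.99, 1.0, "a", "a:1", "a"))
  atoms$species_role <- c("buffer", "buffer", "cation")
  topo <- as_topology(atoms, bonds = rbind(c(1, 2)))
  pos <- rbind(c(0.5, 0, 0), c(0, 0, 0), c(2, 0, 0))
  fr <- frames_from_positions(list(pos), box = 30)
  hb <- assign_hbonds(fr, build_shells(fr, topo), topo)
  expect_true(is.na(hb$frames[[1]]$acceptor_ua))
})

test_that("water environments follow the shell composition and partition", {
  box <- gen_solvated_box(n_water = 25, n_frames = 4, seed = 9)
  sh <- build_shells(box$frames, box$topology)
  env <- classify_water(sh, box$topology)
  # partition: every water has exactly one label per frame
  expect_true(all(env$labels %in% c("bulk", "WP", "WPP", "WEP", "WEPP",
                                    "WE")))
  expect_equal(dim(env$labels), c(25, 4))
  counts <- water_environment_counts(env, include_we = TRUE)
  bulk_mean <- mean(colSums(env$labels == "bulk"))
  expect_equal(counts$Total + bulk_mean, 25)
})

test_that("hand-built shells classify to the defined categories", {
  # two proteins + waters; water shells assembled geometrically
  atoms <- rbind(
    atom_row(1, "C", 12, 0, "p1", "p1:1", "prot1", "non-polar", "protein", 0),
    atom_row(2, "C", 12, 0, "p2", "p2:1", "prot2", "non-polar", "protein", 0),
    atom_row(3, "Na", 23, 1, "na", "na:1", "na1", "n/a", "cation", 1),
    atom_row(4, "O", 15.999, -0.834, "w1", "w1:1", "w1"),
    atom_row(5, "H", 1.008, 0.417, "w1", "w1:1", "w1"),
    atom_row(6, "H", 1.008, 0.417, "w1", "w1:1", "w1"),
    atom_row(7, "O", 15.999, -0.834, "w2", "w2:1", "w2"),
    atom_row(8, "H", 1.008, 0.417, "w2", "w2:1", "w2"),
    atom_row(9, "H", 1.008, 0.417, "w2", "w2:1", "w2"))
  topo <- as_topology(atoms, bonds = rbind(c(4, 5), c(4, 6), c(7, 8), c(7, 9)))
  # w1 between both proteins and the cation -> WEPP; w2 far away -> bulk
  pos <- rbind(c(-2.5, 0, 0), c(2.5, 0, 0), c(0, 2.5, 0),
               c(0, 0, 0), c(0.96, 0, 0), c(-0.24, 0.93, 0),
               c(20, 20, 20), c(20.96, 20, 20), c(19.76, 20.93, 20))
  fr <- frames_from_positions(list(pos), box = 60)
  env <- classify_water(build_shells(fr, topo), topo)
  expect_equal(env$labels[, 1], c("WEPP", "bulk"))
  # remove the cation: the same geometry becomes WPP
  topo2 <- as_topology(atoms[-3, ],
                       bonds = rbind(c(4, 5), c(4, 6), c(7, 8), c(7, 9)))
  fr2 <- frames_from_positions(list(pos[-3, ]), box = 60)
  env2 <- classify_water(build_shells(fr2, topo2), topo2)
  expect_equal(env2$labels[, 1], c("WPP", "bulk"))
})

test_that("switching function hits its landmark values", {
  pos <- rbind(c(0, 0, 0), c(5, 0, 0))
  expect_equal(switching_contacts(pos, NULL, rbind(c(1, 2)), d0 = 5,
                                  r0 = 1.5), 1)
  expect_equal(switching_contacts(pos, NULL, rbind(c(1, 2)), d0 = 3.5,
                                  r0 = 1.5), 0.5)
  pos2 <- rbind(c(0, 0, 0), c(500, 0, 0))
  expect_lt(switching_contacts(pos2, NULL, rbind(c(1, 2)), d0 = 5,
                               r0 = 1.5), 1e-12)
  # distances below d0 saturate at a full contact
  pos3 <- rbind(c(0, 0, 0), c(1, 0, 0))
  expect_equal(switching_contacts(pos3, NULL, rbind(c(1, 2)), d0 = 5,
                                  r0 = 1.5), 1)
})

test_that("contact counts are invariant under rigid motion and normalise", {
  box <- gen_solvated_box(n_water = 15, n_frames = 3, seed = 5)
  sh <- build_shells(box$frames, box$topology)
  ct <- contact_table(sh, box$topology)
  expect_true(isSymmetric(ct$counts))
  expect_true(all(ct$counts >= 0))
  # global translation (with wrap) leaves the table unchanged
  fr2 <- box$frames
  fr2$positions <- fr2$positions + 3.7
  ct2 <- contact_table(build_shells(fr2, box$topology), box$topology)
  expect_equal(ct2$counts, ct$counts)
  # global rotation: compare in a box large enough that nothing wraps
  big <- function(pos_arr) as_frames(seq_len(dim(pos_arr)[3]), rep(200, 3),
                                     pos_arr)
  ct_big <- contact_table(build_shells(big(box$frames$positions),
                                       box$topology), box$topology)
  th <- 0.83
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  rot <- box$frames$positions
  for (f in seq_len(dim(rot)[3])) rot[, , f] <- rot[, , f] %*% t(R)
  ct3 <- contact_table(build_shells(big(rot), box$topology), box$topology)
  expect_equal(ct3$counts, ct_big$counts, tolerance = 1e-12)
  # per-molecule normalisation divides by the row-species molecule count
  pm <- contacts_per_molecule(ct)
  expect_equal(pm["polyanion", "cation"],
               ct$counts["polyanion", "cation"] / 5)
})

test_that("a single close pair counts as one contact", {
  atoms <- rbind(
    atom_row(1, "Na", 23, 1, "na", "na:1", "na1", "n/a", "cation", 1),
    atom_row(2, "Cl", 35.45, -1, "cl", "cl:1", "cl1", "n/a", "anion", -1))
  topo <- as_topology(atoms)
  fr <- frames_from_positions(list(rbind(c(0, 0, 0), c(2.8, 0, 0))), box = 40)
  ct <- contact_table(build_shells(fr, topo), topo)
  expect_equal(ct$counts["anion", "cation"], 1)
})
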