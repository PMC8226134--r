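test_that("the entropy ledger demands exactly the declared components", {
  box <- gen_solvated_box(n_water = 6, n_frames = 60, seed = 2)
  suppressWarnings({
    vib <- vibrational_entropy(box$frames, box$topology)
    conf <- monomer_conformational_entropy(box$frames, box$topology)
  })
  topo_rows <- rbind(
    data.frame(species_role = "protein", level = "UA",
               type = "topographical", motion = "translation",
               S = sum(conf$S[conf$species_role == "protein"])),
    data.frame(species_role = "water", level = "UA",
               type = "topographical", motion = "rotation", S = 4.2))
  led <- assemble_ledger(vib, topo_rows, box$topology)
  expect_equal(ledger_total(led), sum(led$S))
  # water appears at the united-atom level only
  expect_equal(unique(led$level[led$species_role == "water"]), "UA")
  # dropping the protein polymer-level entry is a hard error
  vib_missing <- vib[!(vib$species_role == "protein" & vib$level == "P"), ]
  expect_error(assemble_ledger(vib_missing, topo_rows, box$topology),
               "missing declared")
  # an undeclared extra component is rejected
  extra <- rbind(topo_rows, data.frame(
    species_role = "cation", level = "UA", type = "topographical",
    motion = "rotation", S = 1))
  expect_error(assemble_ledger(vib, extra, box$topology), "undeclared")
})

test_that("binding decomposition is zero for identical states and antisymmetric", {
  st <- data.frame(species = c("polyanion", "buffer"), N = c(5, 3),
                   G = c(-20, -10), H = c(-25, -12), TS = c(-5, -2),
                   N_W = c(40, 15), G_W = c(-30, -29), H_W = c(-40, -38),
                   TS_W = c(-10, -9))
  bulk <- c(G = -31, H = -41, TS = -10)
  fe0 <- binding_delta_g(st, st, bulk)
  expect_true(all(abs(fe0$dG) < 1e-12))
  expect_true(all(abs(fe0$dH) < 1e-12))
  # a perturbed bound state
  bnd <- st
  bnd$G <- st$G - 4; bnd$H <- st$H - 6; bnd$TS <- st$TS - 2
  bnd$N_W <- c(30, 12); bnd$G_W <- c(-32, -28)
  bnd$H_W <- c(-43, -37); bnd$TS_W <- c(-11, -9)
  fe <- binding_delta_g(bnd, st, bulk)
  swapped <- binding_delta_g(st, bnd, bulk)
  expect_equal(fe$dG, -swapped$dG, tolerance = 1e-12)
  expect_equal(fe$dH, -swapped$dH, tolerance = 1e-12)
  expect_equal(fe$dTS, -swapped$dTS, tolerance = 1e-12)
  expect_error(binding_delta_g(transform(bnd, N_W = c(-1, 12)), st, bulk),
               "negative")
})

test_that("binding decomposition reproduces a hand-computed two-species case", {
  bnd <- data.frame(species = c("a", "b"), N = c(2, 1), G = c(-5, 3),
                    H = c(-6, 2), TS = c(-1, -1), N_W = c(10, 4),
                    G_W = c(-30, -28), H_W = c(-39, -36),
                    TS_W = c(-9, -8))
  dil <- data.frame(species = c("a", "b"), N = c(2, 1), G = c(-4, 1),
                    H = c(-5, 1), TS = c(-1, 0), N_W = c(12, 6),
                    G_W = c(-29, -27), H_W = c(-38, -36),
                    TS_W = c(-9, -9))
  bulk <- c(G = -31, H = -41, TS = -10)
  fe <- binding_delta_g(bnd, dil, bulk)
  # species a, by hand: solute 2(-5) - 2(-4) = -2
  expect_equal(fe$dG[fe$row == "a"], -2)
  # water a: 10(-30) + (12-10)(-31) - 12(-29) = -300 - 62 + 348 = -14
  expect_equal(fe$dG[fe$row == "W_a"], -14)
  # species b: 1(3) - 1(1) = 2; water b: 4(-28) + 2(-31) - 6(-27) = -12
  expect_equal(fe$dG[fe$row == "b"], 2)
  expect_equal(fe$dG[fe$row == "W_b"], -12)
  expect_equal(fe$dG[fe$row == "Total"], -2 - 14 + 2 - 12)
  # G = H - TS holds row-wise
  expect_equal(fe$dG, fe$dH - fe$dTS, tolerance = 1e-12)
})

test_that("exported tables keep the component-sum identity", {
  bnd <- data.frame(species = "a", N = 1, G = -5.4, H = -6.2, TS = -0.8,
                    N_W = 3, G_W = -30.1, H_W = -39.6, TS_W = -9.5)
  dil <- transform(bnd, G = -4.1, H = -5.0, TS = -0.9, N_W = 5)
  fe <- binding_delta_g(bnd, dil, c(G = -31, H = -41, TS = -10))
  path <- tempfile(fileext = ".csv")
  out <- export_fe_table(fe, path)
  expect_true(file.exists(path))
  expect_equal(out$dG, round(fe$dG))
  # a corrupted total fails the export
  fe_bad <- fe
  fe_bad$dG[fe_bad$row == "Total"] <- fe_bad$dG[fe_bad$row == "Total"] + 3
  expect_error(export_fe_table(fe_bad, path), "do not sum")
})

test_that("species free energy obeys G = H - T S", {
  const <- eemcc_constants()
  en <- data.frame(species_role = c("water", "cation"), H = c(-40, -12))
  entropy <- data.frame(species_role = c("water", "cation"), S = c(60, 25))
  fe <- species_free_energy(en, entropy, const)
  expect_equal(fe$G, fe$H - fe$TS, tolerance = 1e-12)
  expect_equal(fe$TS, const$T * c(60, 25) / 1000, tolerance = 1e-12)
})

test_that("grouped decompositions sum to the overall totals", {
  vals <- data.frame(id = sprintf("r%d", 1:6), dG = c(1, -2, 3, 4, -5, 6),
                     dH = c(0, 1, 1, 2, 2, 3))
  grp <- data.frame(id = sprintf("r%d", 1:6),
                    group = c("acidic", "basic", "acidic", "non-polar",
                              "basic", "non-polar"))
  dec <- classwise_decomposition(vals, grp)
  expect_equal(sum(dec$dG), sum(vals$dG))
  expect_equal(dec$dG[dec$group == "acidic"], 4)
  # one class holding everything reproduces the total
  grp1 <- transform(grp, group = "all")
  expect_equal(classwise_decomposition(vals, grp1)$dG, sum(vals$dG))
  # unassigned items are an error
  expect_error(classwise_decomposition(vals, grp[-1, ]), "without a group")
})

test_that("group standard errors follow the group-mean formula", {
  expect_equal(group_standard_error(c(1, 1, 1, 1), c("a", "a", "b", "b")), 0)
  expect_equal(group_standard_error(c(0, 0, 2, 2), c("a", "a", "b", "b")), 1)
  # permuting walkers within groups changes nothing
  v <- c(3, 1, 4, 1, 5, 9)
  g <- c("a", "a", "a", "b", "b", "b")
  expect_equal(group_standard_error(v, g),
               group_standard_error(v[c(3, 1, 2, 6, 5, 4)], g))
  expect_error(group_standard_error(1:4, rep("a", 4)), "two groups")
})

test_that("per-species formal charges average correctly", {
  box <- gen_solvated_box(n_water = 4, n_frames = 2, seed = 6)
  mfc <- mean_formal_charge(box$topology)
  expect_equal(mfc$mean_formal_charge[mfc$species_role == "polyanion"],
               mean(c(-4, -5, -5, -5, -5)))
  expect_equal(mfc$n_molecules[mfc$species_role == "polyanion"], 5)
})

test_that("water residue-pair keys pick the two nearest shell residues", {
  atoms <- rbind(
    atom_row(1, "C", 12, 0, "p1", "r1", "prot", "acidic", "protein", 0),
    atom_row(2, "C", 12, 0, "p2", "r2", "prot", "basic", "protein", 0),
    atom_row(3, "C", 12, 0, "p3", "r3", "prot", "non-polar", "protein", 0),
    atom_row(4, "O", 15.999, -0.834, "w", "w:1", "w1"),
    atom_row(5, "H", 1.008, 0.417, "w", "w:1", "w1"),
    atom_row(6, "H", 1.008, 0.417, "w", "w:1", "w1"))
  topo <- as_topology(atoms, bonds = rbind(c(4, 5), c(4, 6)))
  pos <- rbind(c(3, 0, 0), c(0, 3.5, 0), c(0, 0, 7.5),
               c(0, 0, 0), c(0.96, 0, 0), c(-0.24, 0.93, 0))
  fr <- frames_from_positions(list(pos), box = 40)
  keys <- water_residue_pairs(build_shells(fr, topo), topo)
  expect_equal(keys[1, 1], "acidic|basic")
})
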