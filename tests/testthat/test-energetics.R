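ion <- function(q = 1, radius = 2, xyz = c(0, 0, 0), element = "NA") {
  Structure(make_atoms(xyz, element = element, charge = q, radius = radius,
                       sigma = 0, eps = 0))
}

test_that("coulomb_energy: closed form, zero charge, symmetry", {
  a <- ion(1); b <- ion(1, xyz = c(1, 0, 0))
  expect_equal(coulomb_energy(a, b, dielectric = 1), 332.0636)
  expect_equal(coulomb_energy(a, ion(0, xyz = c(1, 0, 0))), 0)
  expect_error(coulomb_energy(a, ion(1, xyz = c(0, 0, 0))), "singularity")
  expect_equal(coulomb_energy(a, b, dielectric = 4), 332.0636 / 4)
})

test_that("coulomb and LJ match a naive double-loop oracle", {
  a <- random_structure(20, seed = 61)
  b <- random_structure(15, seed = 62)
  b$atoms$x <- b$atoms$x + 25  # keep the sets apart
  a <- apply_params(a); b <- apply_params(b)
  ec <- 0; ev <- 0
  for (i in seq_len(20)) for (j in seq_len(15)) {
    dx <- c(a$atoms$x[i] - b$atoms$x[j], a$atoms$y[i] - b$atoms$y[j],
            a$atoms$z[i] - b$atoms$z[j])
    r <- sqrt(sum(dx^2))
    ec <- ec + 332.0636 * a$atoms$charge[i] * b$atoms$charge[j] / r
    sij <- (a$atoms$lj_sigma[i] + b$atoms$lj_sigma[j]) / 2
    eij <- sqrt(a$atoms$lj_epsilon[i] * b$atoms$lj_epsilon[j])
    ev <- ev + 4 * eij * ((sij / r)^12 - (sij / r)^6)
  }
  expect_equal(coulomb_energy(a, b), ec, tolerance = 1e-10)
  expect_equal(lj_energy(a, b), ev, tolerance = 1e-10)
  expect_equal(coulomb_energy(b, a), coulomb_energy(a, b))
  expect_equal(lj_energy(b, a), lj_energy(a, b))
})

test_that("LJ root and minimum sit where the potential says", {
  mk <- function(r) list(
    a = Structure(make_atoms(c(0, 0, 0), sigma = 3.4, eps = 0.2)),
    b = Structure(make_atoms(c(r, 0, 0), sigma = 3.4, eps = 0.2)))
  at_sigma <- mk(3.4)
  expect_equal(lj_energy(at_sigma$a, at_sigma$b), 0, tolerance = 1e-12)
  at_min <- mk(2^(1 / 6) * 3.4)
  expect_equal(lj_energy(at_min$a, at_min$b), -0.2, tolerance = 1e-12)
})

test_that("SASA: isolated sphere, additivity at distance, refinement", {
  p <- SolvationParams()
  s1 <- ion(0, radius = 1.7)
  expect_equal(sasa(s1, p)$total, 4 * pi * (1.7 + 1.4)^2,
               tolerance = 0.01)
  two <- Structure(make_atoms(rbind(c(0, 0, 0), c(500, 0, 0)),
                              radius = c(1.7, 1.52)))
  expect_equal(sasa(two, p)$total,
               4 * pi * ((1.7 + 1.4)^2 + (1.52 + 1.4)^2), tolerance = 0.01)
  # fused dimer vs high-resolution refinement
  dimer <- Structure(make_atoms(rbind(c(0, 0, 0), c(1.8, 0, 0)),
                                radius = 1.7))
  lo <- sasa(dimer, p)
  hi <- sasa(dimer, SolvationParams(n_sphere_points = 10000))
  expect_lt(abs(lo$total - hi$total) / hi$total, 0.005)
  expect_equal(sum(lo$per_atom), lo$total)
  expect_error(sasa(ion(0, radius = 0), p), "degenerate")
})

test_that("nonpolar solvation is the exact linear form", {
  expect_equal(nonpolar_solvation(123, SolvationParams(gamma = 0, b = 0)), 0)
  expect_equal(nonpolar_solvation(100, SolvationParams(gamma = 0.005,
                                                       b = 0.86)), 1.36)
  p <- SolvationParams(gamma = 0.0072, b = 0.4)
  g <- function(a) nonpolar_solvation(a, p)
  expect_equal(g(30 + 45) - p$b, (g(30) - p$b) + (g(45) - p$b))
  expect_error(nonpolar_solvation(-1, p), ">= 0")
})

test_that("surrogate polar solver hits the Born closed form for one ion", {
  p <- SolvationParams(solute_dielectric = 1, solvent_dielectric = 80)
  for (q in c(1, -1, 0.5)) for (a in c(1.5, 2, 3)) {
    got <- polar_solvation(ion(q, radius = a), p)$total
    expect_equal(got, -166.0318 * (1 - 1 / 80) * q^2 / a,
                 tolerance = 1e-9)
  }
  expect_equal(polar_solvation(ion(0), p)$total, 0)
})

test_that("distant ions are additive; per-atom shares sum to total", {
  p <- SolvationParams(solute_dielectric = 1)
  pair <- Structure(make_atoms(rbind(c(0, 0, 0), c(50, 0, 0)),
                               charge = c(1, -1), radius = 2))
  single <- polar_solvation(ion(1), p)$total
  got <- polar_solvation(pair, p)
  expect_lt(abs(got$total - 2 * single) / abs(2 * single), 0.01)
  expect_equal(sum(got$per_atom), got$total)
  # a broken solver is rejected
  expect_error(polar_solvation(ion(1), p, solver = function(s, p)
    list(total = 1, per_atom = c(2))), "do not sum")
})

test_that("free_energy and binding_delta arithmetic", {
  expect_equal(free_energy(EnergyComponents(E_bonded = -30, E_elec = -15,
                                            E_vdw = -5, G_polar = -10,
                                            G_nonpolar = 2)), -58)
  expect_equal(free_energy(EnergyComponents()), 0)
  with_ts <- EnergyComponents(E_elec = -10, TS = 5)
  without <- EnergyComponents(E_elec = -10)
  expect_equal(free_energy(with_ts) - free_energy(without), -5)
  expect_equal(binding_delta(-100, -60, -30), -10)
  expect_equal(binding_delta(0, 0, 0), 0)
  # adding a constant to all three shifts the difference by -c
  expect_equal(binding_delta(-100 + 7, -60 + 7, -30 + 7),
               binding_delta(-100, -60, -30) - 7)
})

test_that("single-trajectory shortcut equals the full end-state route", {
  tc <- gen_toy_complex(4, seed = 71)
  # moderate LJ parameters keep intra-unit magnitudes small enough that the
  # exact cancellation is visible at 1e-9 despite summation-order noise
  tc$receptor$atoms$lj_sigma <- 2.0; tc$receptor$atoms$lj_epsilon <- 0.1
  tc$ligand$atoms$lj_sigma <- 2.0; tc$ligand$atoms$lj_epsilon <- 0.1
  tr <- gen_trajectory(tc, n_frames = 2, noise_sd = 0, seed = 71)
  p <- SolvationParams()
  be <- single_traj_binding(tr$series, tr$rec_idx, tr$lig_idx, p,
                            n_snapshots = 1)
  frame <- tr$series$frames[[1]]
  rec <- Structure(frame$atoms[tr$rec_idx, ], role = "receptor")
  lig <- Structure(frame$atoms[tr$lig_idx, ], role = "ligand")
  # full route: identical intra-unit MM terms enter all three species and
  # cancel; represent them explicitly with the same bonded constant
  intra <- function(s) {
    n <- n_atoms(s)
    e <- 0
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      ai <- Structure(s$atoms[i, ]); aj <- Structure(s$atoms[j, ])
      e <- e + coulomb_energy(ai, aj) + lj_energy(ai, aj)
    }
    e
  }
  g_of <- function(s, bonded) {
    free_energy(EnergyComponents(
      E_bonded = bonded, E_elec = 0, E_vdw = intra(s),
      G_polar = polar_solvation(s, p)$total,
      G_nonpolar = nonpolar_solvation(sasa(s, p)$total, p)))
  }
  full <- binding_delta(g_of(frame, 12.3),
                        g_of(rec, 10.0), g_of(lig, 2.3))
  expect_equal(be$delta_G, full, tolerance = 1e-9)
  expect_equal(be$delta_G, sum(be$components), tolerance = 1e-9)
})

test_that("constant-energy frames give SEM zero; windows select frames", {
  tc <- gen_toy_complex(3, seed = 72)
  tr <- gen_trajectory(tc, n_frames = 10, noise_sd = 0, seed = 72)
  be <- single_traj_binding(tr$series, tr$rec_idx, tr$lig_idx,
                            window = c(0, 9), n_snapshots = 5)
  expect_equal(be$sem, 0, tolerance = 1e-12)
  expect_equal(be$n_snapshots, 5)
  expect_error(single_traj_binding(tr$series, tr$rec_idx, tr$lig_idx,
                                   window = c(50, 60)), "no frames")
  expect_error(single_traj_binding(tr$series, tr$rec_idx,
                                   tr$lig_idx[-1]), "partition")
})

test_that("window convergence measures the planted drift", {
  tc <- gen_toy_complex(3, seed = 73)
  tr <- gen_trajectory(tc, n_frames = 12, noise_sd = 0, drift = 2,
                       seed = 73)
  early <- single_traj_binding(tr$series, tr$rec_idx, tr$lig_idx,
                               window = c(0, 2), n_snapshots = 3)
  late <- single_traj_binding(tr$series, tr$rec_idx, tr$lig_idx,
                              window = c(9, 11), n_snapshots = 3)
  wc <- window_convergence(early, late, tolerance = 1e-6)
  expect_false(wc$converged)
  expect_gt(wc$difference, 0)
  same <- window_convergence(early, early, tolerance = 0.5)
  expect_true(same$converged)
  expect_equal(same$difference, 0)
  expect_equal(window_convergence(
    structure(list(delta_G = -10), class = "BindingEnergy"),
    structure(list(delta_G = -12), class = "BindingEnergy"),
    tolerance = 1)$difference, 2)
})

test_that("per-residue contributions conserve the total binding energy", {
  for (seed in c(81, 82, 83)) {
    tc <- gen_toy_complex(5, seed = seed)
    tr <- gen_trajectory(tc, n_frames = 3, noise_sd = 0.05, seed = seed)
    be <- single_traj_binding(tr$series, tr$rec_idx, tr$lig_idx,
                              n_snapshots = 3)
    pr <- per_residue_decompose(tr$series, tr$rec_idx, tr$lig_idx,
                                n_snapshots = 3)
    expect_equal(sum(pr$energy_kcal), be$delta_G, tolerance = 1e-6)
    expect_equal(sum(pr$is_ligand), 1L)
  }
})

test_that("a lone charged residue carries the whole Coulomb interaction", {
  # two residues: one charged close by, one neutral far away
  rec_at <- rbind(make_atoms(c(0, 0, 4), charge = 0.4, resno = 1L),
                  make_atoms(c(0, 0, 40), charge = 0, resno = 2L))
  rec_at$serial <- 1:2
  lig_at <- make_atoms(c(0, 0, 0), charge = -0.4, chain = "L",
                       resname = "LIG")
  complex_at <- rbind(rec_at, lig_at)
  complex_at$serial <- 1:3
  fr <- function() Structure(complex_at)
  ser <- SnapshotSeries(list(fr(), fr()))
  pr <- per_residue_decompose(ser, 1:2, 3L, n_snapshots = 1,
                              p = SolvationParams(gamma = 0, b = 0))
  near <- pr[pr$residue_key == "A:1:RES", ]
  far <- pr[pr$residue_key == "A:2:RES", ]
  e_near_mm <- 332.0636 * 0.4 * -0.4 / 4
  # polar-desolvation shares are small here; the Coulomb term dominates
  expect_equal(near$energy_kcal, e_near_mm, tolerance = 0.5)
  expect_lt(abs(far$energy_kcal), 1e-3)
  expect_equal(near$min_dist_A, 4)
})

test_that("energy table writer round-trips the per-frame series", {
  tc <- gen_toy_complex(3, seed = 84)
  tr <- gen_trajectory(tc, n_frames = 4, noise_sd = 0.05, seed = 84)
  be <- single_traj_binding(tr$series, tr$rec_idx, tr$lig_idx,
                            n_snapshots = 4)
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_energy_table(be, tmp)
  df <- utils::read.table(tmp, header = TRUE, sep = "\t")
  expect_equal(df$dG, be$frame_dG, tolerance = 1e-9)
})
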