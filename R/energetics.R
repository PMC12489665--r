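#' @title MM-PBSA energy bookkeeping
#'
#' @description End-state binding free energies follow the standard MM-PBSA
#' decomposition: the binding free energy is the free energy of the complex
#' minus those of the isolated receptor and ligand, each free energy being
#' the molecular-mechanics energy plus polar and nonpolar solvation terms
#' (optionally minus a conformational entropy term, omitted by default).
#' Under the single-trajectory approximation all three species share the
#' complex's coordinates, so bonded and intra-unit nonbonded terms cancel
#' exactly in the difference and only the receptor-ligand interaction terms
#' and the solvation differences survive. The nonpolar solvation term is the
#' usual linear function of solvent-accessible surface area, gamma * A + b;
#' the polar term is delegated to a pluggable solver (the bundled solver is
#' an analytic Born-with-descreening surrogate, not a Poisson-Boltzmann
#' solver; see [born_polar_solver()]).
#' @name energetics
NULL

# Coulomb constant in kcal * Angstrom / (mol * e^2)
K_COULOMB <- 332.0636

#' Solvation / surface parameters
#'
#' @param gamma surface-tension coefficient, kcal/(mol A^2).
#' @param b fitting constant of the nonpolar term, kcal/mol.
#' @param probe_radius solvent probe radius, Angstrom.
#' @param n_sphere_points sphere-sampling resolution for numeric SASA.
#' @param solvent_dielectric,solute_dielectric relative permittivities.
#' @return an object of class `SolvationParams`.
#' @export
SolvationParams <- function(gamma = 0.0054, b = 0.92, probe_radius = 1.4,
                            n_sphere_points = 960, solvent_dielectric = 80,
                            solute_dielectric = 2) {
  if (gamma < 0) stop("gamma must be >= 0")
  if (probe_radius < 0) stop("probe_radius must be >= 0")
  if (n_sphere_points < 12) stop("n_sphere_points must be >= 12")
  if (solvent_dielectric < 1 || solute_dielectric < 1)
    stop("dielectric constants must be >= 1")
  structure(list(gamma = gamma, b = b, probe_radius = probe_radius,
                 n_sphere_points = n_sphere_points,
                 solvent_dielectric = solvent_dielectric,
                 solute_dielectric = solute_dielectric),
            class = "SolvationParams")
}

.pair_distances <- function(a, b) {
  # n_a x n_b distance matrix
  xa <- .as_coords(a); xb <- .as_coords(b)
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), `+`) - 2 * tcrossprod(xa, xb)
  sqrt(pmax(d2, 0))
}

#' Intermolecular Coulomb energy
#'
#' Sum of pairwise point-charge interactions between the atoms of `a` and
#' the atoms of `b`, screened by a uniform dielectric; no cutoff unless
#' `cutoff` is given.
#'
#' @param a,b `Structure`s with populated charges.
#' @param dielectric uniform relative permittivity (default 1).
#' @param cutoff optional distance cutoff in Angstrom.
#' @return energy in kcal/mol.
#' @export
coulomb_energy <- function(a, b, dielectric = 1, cutoff = NULL) {
  qa <- a$atoms$charge; qb <- b$atoms$charge
  if (all(qa == 0) || all(qb == 0)) return(0)
  r <- .pair_distances(a, b)
  if (any(r < 1e-9)) stop("coincident atoms: Coulomb singularity")
  e <- K_COULOMB * outer(qa, qb) / (dielectric * r)
  if (!is.null(cutoff)) e[r > cutoff] <- 0
  sum(e)
}

#' Intermolecular Lennard-Jones energy
#'
#' 12-6 potential with Lorentz-Berthelot combining rules (arithmetic-mean
#' sigma, geometric-mean epsilon).
#'
#' @param a,b `Structure`s with populated sigma/epsilon.
#' @param cutoff optional distance cutoff in Angstrom.
#' @return energy in kcal/mol.
#' @export
lj_energy <- function(a, b, cutoff = NULL) {
  r <- .pair_distances(a, b)
  if (any(r < 1e-9)) stop("coincident atoms: Lennard-Jones singularity")
  sig <- outer(a$atoms$lj_sigma, b$atoms$lj_sigma, `+`) / 2
  eps <- sqrt(outer(a$atoms$lj_epsilon, b$atoms$lj_epsilon))
  sr6 <- (sig / r)^6
  e <- 4 * eps * (sr6^2 - sr6)
  if (!is.null(cutoff)) e[r > cutoff] <- 0
  sum(e)
}

# deterministic near-uniform unit-sphere points (Fibonacci spiral)
.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (3 - sqrt(5)) * (seq_len(n) - 1)
  z <- 1 - 2 * i / n
  rho <- sqrt(pmax(1 - z^2, 0))
  cbind(rho * cos(phi), rho * sin(phi), z)
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Numeric SASA: each atom's solvent-accessible sphere (radius + probe) is
#' sampled with a deterministic Fibonacci spiral of `n_sphere_points`
#' points; points falling inside any neighbouring atom's accessible sphere
#' are buried. The per-atom areas sum to the total by construction. Atoms
#' with zero radius contribute zero area (a fully zero-radius structure is
#' rejected as degenerate).
#'
#' @param s a `Structure` with populated radii.
#' @param p a [SolvationParams()] (probe radius and point count are used).
#' @return list with `total` (A^2) and `per_atom` (A^2 vector).
#' @export
sasa <- function(s, p = SolvationParams()) {
  n <- n_atoms(s)
  rad <- s$atoms$radius + p$probe_radius
  if (all(s$atoms$radius <= 0))
    stop("degenerate input: all atomic radii are zero")
  xyz <- coords(s)
  pts <- .sphere_points(p$n_sphere_points)
  per_atom <- numeric(n)
  d <- .pair_distances(xyz, xyz)
  for (i in seq_len(n)) {
    if (s$atoms$radius[i] <= 0) next
    neigh <- which(d[i, ] < rad[i] + rad & seq_len(n) != i & rad > p$probe_radius)
    surf <- sweep(pts * rad[i], 2, xyz[i, ], `+`)
    if (length(neigh) > 0L) {
      acc <- rep(TRUE, nrow(surf))
      for (j in neigh) {
        dj2 <- (surf[, 1] - xyz[j, 1])^2 + (surf[, 2] - xyz[j, 2])^2 +
          (surf[, 3] - xyz[j, 3])^2
        acc <- acc & dj2 >= rad[j]^2
        if (!any(acc)) break
      }
      frac <- sum(acc) / nrow(surf)
    } else frac <- 1
    per_atom[i] <- 4 * pi * rad[i]^2 * frac
  }
  list(total = sum(per_atom), per_atom = per_atom)
}

#' Nonpolar solvation energy from surface area
#'
#' The linear SASA model: `gamma * A + b`.
#'
#' @param area SASA in A^2 (>= 0).
#' @param p a [SolvationParams()].
#' @return energy in kcal/mol.
#' @export
nonpolar_solvation <- function(area, p = SolvationParams()) {
  if (any(area < 0)) stop("area must be >= 0")
  p$gamma * area + p$b
}

#' Bundled polar-solvation surrogate (Born with pairwise descreening)
#'
#' An analytic stand-in for a polar solvation solver, satisfying the
#' pluggable-solver contract: each atom contributes a Born self-energy
#' `-(k/2) * tau * q^2 / a_eff`, where `tau = 1/eps_solute - 1/eps_solvent`
#' and the effective radius `a_eff` grows as neighbouring atoms descreen the
#' atom from solvent (`1/a_eff = 1/a - sum_j a_j^3 / (2 r_ij^4)`, floored at
#' `1/(30 A)`). For a single ion this reduces exactly to the Born closed
#' form; for well-separated groups it is additive. It is a documented
#' surrogate, not a Poisson-Boltzmann solver; any function with the same
#' signature can replace it.
#'
#' @param s a `Structure` with charges and radii populated.
#' @param p a [SolvationParams()].
#' @return list with `total` (kcal/mol) and `per_atom` vector summing to it.
#' @export
born_polar_solver <- function(s, p = SolvationParams()) {
  q <- s$atoms$charge
  a <- s$atoms$radius
  n <- n_atoms(s)
  tau <- 1 / p$solute_dielectric - 1 / p$solvent_dielectric
  per_atom <- numeric(n)
  live <- which(a > 0)
  if (length(live) > 0L) {
    xyz <- coords(s)
    inv_a <- numeric(n)
    if (length(live) == 1L) {
      inv_a[live] <- 1 / a[live]
    } else {
      d <- .pair_distances(xyz[live, , drop = FALSE],
                           xyz[live, , drop = FALSE])
      diag(d) <- Inf
      descreen <- (outer(rep(1, length(live)), a[live]^3) / (2 * d^4))
      inv_a[live] <- pmax(1 / a[live] - rowSums(descreen), 1 / 30)
    }
    per_atom[live] <- -(K_COULOMB / 2) * tau * q[live]^2 * inv_a[live]
  }
  list(total = sum(per_atom), per_atom = per_atom)
}

#' Polar solvation energy via a pluggable solver
#'
#' @param s a `Structure` with charges and radii populated.
#' @param p a [SolvationParams()].
#' @param solver a function `(Structure, SolvationParams) -> list(total,
#'   per_atom)`; defaults to the bundled [born_polar_solver()] surrogate.
#' @return list with `total` and `per_atom`.
#' @export
polar_solvation <- function(s, p = SolvationParams(),
                            solver = born_polar_solver) {
  res <- tryCatch(solver(s, p), error = function(e)
    stop("polar solver failed: ", conditionMessage(e)))
  if (!is.list(res) || is.null(res$total) || is.null(res$per_atom))
    stop("polar solver must return list(total, per_atom)")
  if (abs(sum(res$per_atom) - res$total) > 1e-6 * max(1, abs(res$total)))
    stop("polar solver per-atom energies do not sum to total")
  res
}

#' Energy components of one species
#'
#' @param E_bonded,E_elec,E_vdw molecular-mechanics terms, kcal/mol.
#' @param G_polar,G_nonpolar solvation terms, kcal/mol.
#' @param TS entropy times temperature, kcal/mol (optional; `NA` = absent).
#' @param T_kelvin temperature, K.
#' @return an object of class `EnergyComponents` with `E_MM` precomputed.
#' @export
EnergyComponents <- function(E_bonded = 0, E_elec = 0, E_vdw = 0,
                             G_polar = 0, G_nonpolar = 0, TS = NA_real_,
                             T_kelvin = 310.15) {
  vals <- c(E_bonded, E_elec, E_vdw, G_polar, G_nonpolar)
  if (!all(is.finite(vals))) stop("energy components must be finite")
  structure(list(E_MM = E_bonded + E_elec + E_vdw, E_bonded = E_bonded,
                 E_elec = E_elec, E_vdw = E_vdw, G_polar = G_polar,
                 G_nonpolar = G_nonpolar, TS = TS, T_kelvin = T_kelvin),
            class = "EnergyComponents")
}

#' Free energy of one species
#'
#' `G = E_MM + G_polar + G_nonpolar - TS`; an absent entropy term is treated
#' as zero.
#' @param c an [EnergyComponents()].
#' @return free energy, kcal/mol.
#' @export
free_energy <- function(c) {
  ts <- if (is.na(c$TS)) 0 else c$TS
  c$E_MM + c$G_polar + c$G_nonpolar - ts
}

#' Binding free energy difference
#'
#' `delta_G = G_complex - (G_protein + G_ligand)`.
#' @param complex,protein,ligand free energies, kcal/mol.
#' @return kcal/mol.
#' @export
binding_delta <- function(complex, protein, ligand) {
  if (!all(is.finite(c(complex, protein, ligand))))
    stop("free energies must be finite")
  complex - (protein + ligand)
}

.subset_structure <- function(s, idx, role = "complex") {
  Structure(s$atoms[idx, , drop = FALSE], source = s$meta$source,
            state = s$meta$state, role = role)
}

.frame_components <- function(frame, rec_idx, lig_idx, p, solver) {
  rec <- .subset_structure(frame, rec_idx, "receptor")
  lig <- .subset_structure(frame, lig_idx, "ligand")
  e_elec <- coulomb_energy(rec, lig, dielectric = 1)
  e_vdw <- lj_energy(rec, lig)
  gp_c <- polar_solvation(frame, p, solver)
  gp_r <- polar_solvation(rec, p, solver)
  gp_l <- polar_solvation(lig, p, solver)
  sa_c <- sasa(frame, p); sa_r <- sasa(rec, p); sa_l <- sasa(lig, p)
  gn_c <- nonpolar_solvation(sa_c$total, p)
  gn_r <- nonpolar_solvation(sa_r$total, p)
  gn_l <- nonpolar_solvation(sa_l$total, p)
  list(E_elec = e_elec, E_vdw = e_vdw,
       dG_polar = gp_c$total - gp_r$total - gp_l$total,
       dG_nonpolar = gn_c - gn_r - gn_l,
       polar_atoms = list(complex = gp_c$per_atom, receptor = gp_r$per_atom,
                          ligand = gp_l$per_atom),
       sasa_atoms = list(complex = sa_c$per_atom, receptor = sa_r$per_atom,
                         ligand = sa_l$per_atom))
}

.window_frames <- function(series, window, n_snapshots) {
  in_win <- which(series$times >= window[1] & series$times <= window[2])
  if (length(in_win) == 0L)
    stop(sprintf("no frames in window [%g, %g] ns", window[1], window[2]))
  n_take <- min(n_snapshots, length(in_win))
  pick <- unique(round(seq(1, length(in_win), length.out = n_take)))
  in_win[pick]
}

#' Single-trajectory MM-PBSA binding energy over a snapshot window
#'
#' Selects `n_snapshots` evenly spaced frames within the time window and,
#' per frame, accumulates the interaction terms that survive the
#' single-trajectory cancellation: intermolecular Coulomb and Lennard-Jones
#' energies plus the polar and nonpolar solvation differences between the
#' complex and its isolated parts (evaluated at the complex's coordinates).
#' Bonded and intra-unit nonbonded terms are identical in the complex and
#' its parts and are not computed. The result is the mean over frames with
#' its standard error.
#'
#' @param series a `SnapshotSeries` of complex frames.
#' @param rec_idx,lig_idx integer atom indices partitioning every frame into
#'   receptor and ligand.
#' @param p a [SolvationParams()].
#' @param window `(start, end)` in ns.
#' @param n_snapshots number of evenly spaced frames to use (default 100).
#' @param solver polar-solvation solver (default [born_polar_solver()]).
#' @return an object of class `BindingEnergy` with `delta_G`, per-term
#'   component means, `sem`, `window`, `n_snapshots`, and the per-frame
#'   `frame_dG` series.
#' @export
single_traj_binding <- function(series, rec_idx, lig_idx,
                                p = SolvationParams(),
                                window = c(series$times[1],
                                           series$times[n_frames(series)]),
                                n_snapshots = 100,
                                solver = born_polar_solver) {
  natoms <- n_atoms(series$frames[[1]])
  if (!setequal(c(rec_idx, lig_idx), seq_len(natoms)) ||
      length(intersect(rec_idx, lig_idx)) > 0)
    stop("rec_idx and lig_idx must partition all atoms")
  take <- .window_frames(series, window, n_snapshots)
  comps <- lapply(series$frames[take], .frame_components,
                  rec_idx = rec_idx, lig_idx = lig_idx, p = p,
                  solver = solver)
  term <- function(nm) vapply(comps, `[[`, numeric(1), nm)
  dg <- term("E_elec") + term("E_vdw") + term("dG_polar") +
    term("dG_nonpolar")
  nf <- length(take)
  structure(list(
    delta_G = mean(dg),
    components = c(dE_elec = mean(term("E_elec")),
                   dE_vdw = mean(term("E_vdw")),
                   dG_polar = mean(term("dG_polar")),
                   dG_nonpolar = mean(term("dG_nonpolar"))),
    sem = if (nf > 1) stats::sd(dg) / sqrt(nf) else 0,
    window = window, n_snapshots = nf, frame_dG = dg),
    class = "BindingEnergy")
}

#' @export
print.BindingEnergy <- function(x, ...) {
  cat(sprintf(
    "BindingEnergy: %.3f +/- %.3f kcal/mol (%d snapshots, %g-%g ns)\n",
    x$delta_G, x$sem, x$n_snapshots, x$window[1], x$window[2]))
  comp <- x$components
  cat(sprintf("  dE_elec %.3f  dE_vdw %.3f  dG_polar %.3f  dG_nonpolar %.3f\n",
              comp["dE_elec"], comp["dE_vdw"], comp["dG_polar"],
              comp["dG_nonpolar"]))
  invisible(x)
}

#' Convergence check between two snapshot windows
#'
#' Two windows of the same trajectory have converged when their binding
#' energies agree within a tolerance.
#'
#' @param e1,e2 `BindingEnergy` objects for the two windows.
#' @param tolerance kcal/mol.
#' @return list with `converged` and `difference` (kcal/mol).
#' @export
window_convergence <- function(e1, e2, tolerance = 1.0) {
  difference <- abs(e1$delta_G - e2$delta_G)
  list(converged = difference <= tolerance, difference = difference)
}

#' Per-residue decomposition of the binding energy
#'
#' Splits the single-trajectory binding energy into per-residue
#' contributions: each receptor residue carries its atoms' Coulomb and
#' Lennard-Jones interactions with the ligand plus its atoms' shares of the
#' polar and nonpolar solvation differences (per-atom shares summed into
#' residues). The ligand's own solvation shares (including the `-b` constant
#' of the linear SASA model) are reported as one additional `ligand` row so
#' that contributions sum exactly to the total binding energy. Each residue
#' also reports its mean minimum heavy-atom distance to the ligand, the
#' radial coordinate used by the profile stage.
#'
#' @inheritParams single_traj_binding
#' @return data.frame of class `ResidueContributions` with columns
#'   `residue_key`, `energy_kcal`, `min_dist_A`, `is_ligand`.
#' @export
per_residue_decompose <- function(series, rec_idx, lig_idx,
                                  p = SolvationParams(),
                                  window = c(series$times[1],
                                             series$times[n_frames(series)]),
                                  n_snapshots = 100,
                                  solver = born_polar_solver) {
  natoms <- n_atoms(series$frames[[1]])
  if (!setequal(c(rec_idx, lig_idx), seq_len(natoms)) ||
      length(intersect(rec_idx, lig_idx)) > 0)
    stop("rec_idx and lig_idx must partition all atoms")
  take <- .window_frames(series, window, n_snapshots)
  f1 <- series$frames[[take[1]]]
  rkeys_atoms <- atom_residue_keys(f1)[rec_idx]
  rkeys <- unique(rkeys_atoms)
  acc <- matrix(0, nrow = length(rkeys) + 1L, ncol = 1)
  dist_acc <- numeric(length(rkeys))
  for (fr in take) {
    frame <- series$frames[[fr]]
    rec <- .subset_structure(frame, rec_idx, "receptor")
    lig <- .subset_structure(frame, lig_idx, "ligand")
    comp <- .frame_components(frame, rec_idx, lig_idx, p, solver)
    # MM interaction terms per receptor atom
    r <- .pair_distances(rec, lig)
    elec_at <- K_COULOMB * outer(rec$atoms$charge, lig$atoms$charge) / r
    sig <- outer(rec$atoms$lj_sigma, lig$atoms$lj_sigma, `+`) / 2
    eps <- sqrt(outer(rec$atoms$lj_epsilon, lig$atoms$lj_epsilon))
    sr6 <- (sig / r)^6
    vdw_at <- 4 * eps * (sr6^2 - sr6)
    mm_atom <- rowSums(elec_at) + rowSums(vdw_at)
    # solvation deltas per atom (complex minus isolated unit)
    dpol <- comp$polar_atoms$complex
    dpol[rec_idx] <- dpol[rec_idx] - comp$polar_atoms$receptor
    dpol[lig_idx] <- dpol[lig_idx] - comp$polar_atoms$ligand
    dnp <- p$gamma * comp$sasa_atoms$complex
    dnp[rec_idx] <- dnp[rec_idx] - p$gamma * comp$sasa_atoms$receptor
    dnp[lig_idx] <- dnp[lig_idx] - p$gamma * comp$sasa_atoms$ligand
    atom_total <- dpol + dnp
    atom_total[rec_idx] <- atom_total[rec_idx] + mm_atom
    res_e <- vapply(rkeys, function(k)
      sum(atom_total[rec_idx][rkeys_atoms == k]), numeric(1))
    # the b constants of complex/receptor/ligand leave a net -b
    lig_e <- sum(atom_total[lig_idx]) - p$b
    acc <- acc + c(res_e, lig_e)
    # min heavy-atom distance residue -> ligand
    heavy_r <- rec$atoms$element != "H"
    heavy_l <- lig$atoms$element != "H"
    rh <- r[heavy_r, heavy_l, drop = FALSE]
    kh <- rkeys_atoms[heavy_r]
    dist_acc <- dist_acc + vapply(rkeys, function(k) {
      rows <- kh == k
      if (!any(rows)) return(NA_real_)
      min(rh[rows, , drop = FALSE])
    }, numeric(1))
  }
  nfr <- length(take)
  out <- data.frame(
    residue_key = c(rkeys, "ligand"),
    energy_kcal = as.numeric(acc) / nfr,
    min_dist_A = c(dist_acc / nfr, 0),
    is_ligand = c(rep(FALSE, length(rkeys)), TRUE),
    stringsAsFactors = FALSE)
  class(out) <- c("ResidueContributions", "data.frame")
  out
}

#' Write a per-snapshot energy table
#' @param be a `BindingEnergy`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_energy_table <- function(be, path) {
  df <- data.frame(snapshot = seq_along(be$frame_dG), dG = be$frame_dG)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read a per-residue contribution table
#'
#' Delimited text with columns `residue_key`, `energy_kcal`, `min_dist_A`
#' (and `is_ligand`), the interchange format between the decomposition and
#' radial-profile stages.
#' @param contribs a `ResidueContributions` data.frame.
#' @param path file path.
#' @return invisibly `path` (write); the data.frame (read).
#' @export
write_residue_table <- function(contribs, path) {
  utils::write.table(contribs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_residue_table
#' @export
read_residue_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("residue_key", "energy_kcal", "min_dist_A") %in% names(df)))
    stop("residue table must have residue_key, energy_kcal, min_dist_A")
  if (is.null(df$is_ligand)) df$is_ligand <- FALSE
  class(df) <- c("ResidueContributions", "data.frame")
  df
}
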