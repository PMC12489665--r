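#' @title Seeded synthetic-data generators
#'
#' @description Deterministic generators producing every input the pipeline
#' consumes, with planted ground truth so downstream stages can be tested
#' by parameter recovery: screening libraries with a bivariate-normal score
#' model, cross-docking success matrices whose exact minimal cover is
#' planted, toy receptor/ligand complexes with shell-placed residues,
#' biflavonoid-like two-ring structures with a settable interflavonoid
#' torsion, per-residue energy tables constructed to first converge at a
#' planted radius, and noisy/drifting snapshot series. Every generator is a
#' pure function of its arguments and seed (bit-identical reruns), and every
#' planted truth is re-verified by the consuming module's own check at
#' generation time; infeasible plants fail loudly.
#' @name synthgen
NULL

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Generate a synthetic screening library
#'
#' Emulates a natural-product docking screen: per-target docking scores are
#' drawn from a bivariate normal (mean -7, sd 1.5 kcal/mol per target,
#' inter-target correlation `rho`), descriptors span rule-of-five regimes
#' (log-normal MW around 350 g/mol, normal logP around 3, Poisson donor and
#' acceptor counts).
#'
#' @param n number of compounds (default 1745, a realistic library size).
#' @param seed integer seed.
#' @param rho inter-target score correlation in `[0, 1)` (default 0.6).
#' @param mean_score,sd_score score model parameters, kcal/mol.
#' @return data.frame with columns `id`, `name`, `score_pi3ka`,
#'   `score_mtor`, `MW`, `logP`, `HBD`, `HBA`.
#' @export
gen_library <- function(n = 1745, seed = 1, rho = 0.6,
                        mean_score = -7, sd_score = 1.5) {
  if (n < 1) stop("n must be >= 1")
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)")
  .with_seed(seed, {
    z1 <- stats::rnorm(n)
    z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
    df <- data.frame(
      id = sprintf("NP%05d", seq_len(n)),
      name = sprintf("compound_%05d", seq_len(n)),
      score_pi3ka = mean_score + sd_score * z1,
      score_mtor = mean_score + sd_score * z2,
      MW = round(stats::rlnorm(n, log(350), 0.35), 1),
      logP = round(stats::rnorm(n, 3, 1.8), 2),
      HBD = stats::rpois(n, 3),
      HBA = stats::rpois(n, 6),
      stringsAsFactors = FALSE)
    df
  })
}

#' Generate a success matrix with a planted exact minimal cover
#'
#' Builds a ligands x receptors RMSD matrix whose successful cells make the
#' planted receptor subset the unique-cardinality exact minimal cover:
#' ligands are partitioned across the planted receptors, every non-planted
#' receptor covers strictly fewer ligands than needed to replace a planted
#' one, and the construction is verified at generation time by brute-force
#' subset enumeration ([ensemble_select()] in exact mode).
#'
#' @param n_ligands,n_receptors matrix dimensions.
#' @param planted_cover receptor indices (1-based) or ids forming the
#'   intended exact cover.
#' @param seed integer seed (jitters RMSD values only).
#' @param threshold success cutoff, Angstrom.
#' @return a `SuccessMatrix`.
#' @export
gen_success_matrix <- function(n_ligands, n_receptors, planted_cover,
                               seed = 1, threshold = 3.0) {
  receptors <- sprintf("R%02d", seq_len(n_receptors))
  ligands <- sprintf("L%02d", seq_len(n_ligands))
  if (is.numeric(planted_cover)) planted_cover <- receptors[planted_cover]
  if (!all(planted_cover %in% receptors))
    stop("planted_cover outside receptor set")
  k <- length(planted_cover)
  if (k > n_ligands)
    stop("infeasible plant: more cover receptors than ligands")
  .with_seed(seed, {
    success <- matrix(FALSE, n_ligands, n_receptors,
                      dimnames = list(ligands, receptors))
    # partition ligands across the planted receptors (each gets >= 1)
    assign_to <- rep(planted_cover, length.out = n_ligands)
    assign_to <- sample(assign_to)
    for (r in planted_cover) success[assign_to == r, r] <- TRUE
    # non-planted receptors may cover strict subsets of one planted
    # receptor's block, so they can never substitute for any planted member
    others <- setdiff(receptors, planted_cover)
    for (r in others) {
      donor <- sample(planted_cover, 1)
      block <- which(assign_to == donor)
      if (length(block) > 1)
        success[sample(block, length(block) - 1L), r] <- TRUE
    }
    rmsd <- matrix(stats::runif(n_ligands * n_receptors, 4, 12),
                   n_ligands, n_receptors, dimnames = dimnames(success))
    rmsd[success] <- stats::runif(sum(success), 0.5, threshold - 0.2)
    m <- success_matrix(rmsd, threshold = threshold)
    sel <- ensemble_select(m, mode = "exact")
    if (!setequal(sel$selected, planted_cover))
      stop("infeasible plant: exact cover {",
           paste(sort(sel$selected), collapse = ","),
           "} differs from planted {",
           paste(sort(planted_cover), collapse = ","), "}")
    m
  })
}

.ring6 <- function(bond = 1.4) {
  ang <- seq(0, by = pi / 3, length.out = 6)
  r <- bond
  cbind(r * cos(ang), r * sin(ang), 0)
}

.new_atom <- function(serial, name, element, xyz, charge = 0, chain = "A",
                      resno = 1L, resname = "RES") {
  data.frame(serial = serial, name = name, element = element,
             x = xyz[1], y = xyz[2], z = xyz[3], charge = charge,
             lj_sigma = 0, lj_epsilon = 0, radius = 0,
             chain = chain, resno = as.integer(resno), resname = resname,
             stringsAsFactors = FALSE)
}

#' Generate a toy receptor/ligand complex
#'
#' A schematic binding pocket: a small rigid ligand at the origin and
#' `n_residues` three-atom residues placed on shells at known minimum
#' heavy-atom distances (drawn in 2-8 Angstrom, or supplied), with partial
#' charges drawn from a small symmetric range and Lennard-Jones/radius
#' parameters from the shipped element table. Geometry is schematic, not
#' chemically valid; the contracts downstream are geometric and energetic.
#'
#' @param n_residues number of receptor residues.
#' @param seed integer seed.
#' @param distances optional vector of planted minimum distances (Angstrom).
#' @param charged logical; draw nonzero charges (default TRUE).
#' @return list with `receptor`, `ligand` (`Structure`s) and
#'   `planted_distances` (named by residue key).
#' @export
gen_toy_complex <- function(n_residues = 5, seed = 1, distances = NULL,
                            charged = TRUE) {
  if (n_residues < 1) stop("n_residues must be >= 1")
  .with_seed(seed, {
    if (is.null(distances))
      distances <- sort(stats::runif(n_residues, 2, 8))
    if (length(distances) != n_residues)
      stop("distances length must equal n_residues")
    # ligand: 4 heavy atoms in a compact tetrahedron-ish cluster at origin
    lig_xyz <- rbind(c(0, 0, 0), c(1.4, 0, 0), c(0.7, 1.2, 0),
                     c(0.7, 0.4, 1.1))
    lig_el <- c("C", "C", "O", "N")
    lig <- do.call(rbind, lapply(seq_len(4), function(i)
      .new_atom(i, paste0(lig_el[i], i), lig_el[i], lig_xyz[i, ],
                charge = if (charged) stats::runif(1, -0.4, 0.4) else 0,
                chain = "L", resno = 1L, resname = "LIG")))
    # residues: 3 heavy atoms each; the first atom is the closest to the
    # ligand and realises the planted minimum distance exactly
    directions <- matrix(stats::rnorm(3 * n_residues), ncol = 3)
    directions <- directions / sqrt(rowSums(directions^2))
    rec_rows <- list()
    serial <- 0L
    for (i in seq_len(n_residues)) {
      # anchor on the ligand's support point along direction i: every other
      # ligand atom is then strictly farther from the placed residue, so the
      # planted minimum distance is realised exactly
      anchor <- lig_xyz[which.max(lig_xyz %*% directions[i, ]), ]
      base <- anchor + directions[i, ] * distances[i]
      offs <- rbind(c(0, 0, 0),
                    directions[i, ] * 1.5,
                    directions[i, ] * 1.5 +
                      c(directions[i, 2], -directions[i, 1], 0))
      el <- c("C", "O", "N")
      for (a in seq_len(3)) {
        serial <- serial + 1L
        rec_rows[[serial]] <- .new_atom(
          serial, paste0(el[a], a), el[a], base + offs[a, ],
          charge = if (charged) stats::runif(1, -0.4, 0.4) else 0,
          chain = "A", resno = i, resname = "RES")
      }
    }
    params <- load_param_table()
    receptor <- apply_params(Structure(do.call(rbind, rec_rows),
                                       source = "gen_toy_complex",
                                       role = "receptor"), params)
    ligand <- apply_params(Structure(lig, source = "gen_toy_complex",
                                     role = "ligand"), params)
    realised <- residue_min_distances(receptor, ligand)
    if (max(abs(realised - distances)) > 1e-9)
      stop("distance plant failed: max deviation ",
           format(max(abs(realised - distances))))
    list(receptor = receptor, ligand = ligand,
         planted_distances = realised)
  })
}

#' Generate a biflavonoid-like structure with a planted torsion
#'
#' Two planar six-membered rings joined by a single bond; the second ring is
#' rotated about the bond axis so that the dihedral defined by the returned
#' [TorsionSpec()] equals `torsion` exactly. Generation fails if the
#' measured torsion deviates from the plant by more than 1e-6 degrees.
#'
#' @param torsion planted dihedral, degrees in `[-180, 180]`.
#' @param seed integer seed (reserved; geometry is deterministic).
#' @return list with `structure` (a `Structure`) and `spec` (a
#'   [TorsionSpec()]).
#' @export
gen_biflavonoid <- function(torsion = 90, seed = 1) {
  if (abs(torsion) > 180) stop("torsion must lie in [-180, 180]")
  bond <- 1.48
  # ring 1 in the xy-plane, attachment atom C1A at origin,
  # in-ring neighbour C2A defining the first dihedral arm
  r1 <- .ring6()
  r1 <- sweep(r1, 2, r1[1, ])  # C1A at origin
  # bond axis along +x towards ring 2's attachment atom C1B
  axis_pt <- c(bond, 0, 0)
  # ring 2 drawn in the xy-plane attached at C1B, then rotated about x by
  # (torsion - planar reference angle)
  r2 <- .ring6()
  r2 <- sweep(r2, 2, r2[1, ])
  r2 <- -r2                      # point away from ring 1
  r2 <- sweep(r2, 2, axis_pt, `+`)
  th0 <- dihedral(r1[2, ], c(0, 0, 0), axis_pt, r2[2, ])
  rot_x <- function(p, deg) {
    a <- deg * pi / 180
    cbind(p[, 1], cos(a) * p[, 2] - sin(a) * p[, 3],
          sin(a) * p[, 2] + cos(a) * p[, 3])
  }
  r2 <- rot_x(sweep(r2, 2, axis_pt), -(torsion - th0))
  r2 <- sweep(r2, 2, axis_pt, `+`)
  rows <- list()
  for (i in seq_len(6))
    rows[[i]] <- .new_atom(i, paste0("C", i, "A"), "C", r1[i, ],
                           resno = 1L, resname = "FLA")
  for (i in seq_len(6))
    rows[[6 + i]] <- .new_atom(6L + i, paste0("C", i, "B"), "C", r2[i, ],
                               resno = 2L, resname = "FLB")
  s <- apply_params(Structure(do.call(rbind, rows),
                              source = "gen_biflavonoid", role = "ligand"),
                    warn_unknown = FALSE)
  spec <- TorsionSpec(list(list(resno = 1L, name = "C2A"),
                           list(resno = 1L, name = "C1A"),
                           list(resno = 2L, name = "C1B"),
                           list(resno = 2L, name = "C2B")))
  got <- measure_torsion(s, spec)
  dev <- abs(got - torsion)
  dev <- min(dev, 360 - dev)
  if (dev > 1e-6)
    stop(sprintf("torsion plant failed: wanted %g, measured %g",
                 torsion, got))
  list(structure = s, spec = spec)
}

#' Generate a per-residue energy table with a planted convergence radius
#'
#' Constructs residue energies and distances so that the cumulative radial
#' profile first satisfies the convergence criterion exactly at
#' `planted_radius`: attractive residues fill the shells up to the planted
#' radius with per-shell increments large enough to break convergence
#' earlier, and the remaining residues beyond it carry contributions small
#' enough to stay inside the tolerance band. The plant is verified by a
#' direct scan ([convergence_radius()]) at generation time.
#'
#' @param planted_radius target convergence radius on the grid, in
#'   `[2.0, 8.0]` Angstrom (8.0 is the largest radius whose 2 Angstrom
#'   forward window stays on the 10 Angstrom grid).
#' @param n_residues total residue count (>= number of filled shells + 1).
#' @param seed integer seed.
#' @param fraction,window convergence criterion parameters.
#' @return a `ResidueContributions` data.frame.
#' @export
gen_energy_profile <- function(planted_radius = 3.5, n_residues = 12,
                               seed = 1, fraction = 0.10, window = 2.0) {
  grid <- seq(2.0, 8.0, by = 0.5)
  if (!any(abs(grid - planted_radius) < 1e-9))
    stop("planted_radius must sit on the 0.5 A grid within [2, 8]")
  .with_seed(seed, {
    dists <- numeric(0); energies <- numeric(0)
    # shells below the planted radius: big increments (>10% jumps)
    below <- grid[grid < planted_radius - 1e-9]
    base <- -10
    for (r in below) {
      dists <- c(dists, r - 0.2)
      energies <- c(energies, base * stats::runif(1, 0.8, 1.2))
    }
    # one anchoring residue exactly at the planted radius with a large
    # energy so the running total is substantial there
    dists <- c(dists, planted_radius - 0.2)
    energies <- c(energies, base * 2)
    total_at_plant <- sum(energies)
    # beyond: tiny contributions, well inside 10% of the running total
    beyond <- seq(planted_radius + 0.5, 10, by = 0.5)
    n_left <- max(n_residues - length(dists), 0L)
    if (n_left > 0) {
      rs <- sample(beyond, n_left, replace = TRUE)
      tol <- fraction * abs(total_at_plant)
      for (r in rs) {
        dists <- c(dists, r - 0.2)
        energies <- c(energies,
                      stats::runif(1, -1, 1) * tol / (4 * max(n_left, 1)))
      }
    }
    out <- data.frame(
      residue_key = sprintf("A:%d:RES", seq_along(dists)),
      energy_kcal = energies, min_dist_A = dists, is_ligand = FALSE,
      stringsAsFactors = FALSE)
    class(out) <- c("ResidueContributions", "data.frame")
    prof <- convergence_radius(cumulative_profile(out), fraction = fraction,
                               window = window)
    if (is.na(prof$convergence_radius) ||
        abs(prof$convergence_radius - planted_radius) > 1e-9)
      stop(sprintf("profile plant failed: wanted %.1f, scan found %s",
                   planted_radius, format(prof$convergence_radius)))
    out
  })
}

#' Generate a noisy (optionally drifting) snapshot series
#'
#' Frames are the base complex plus isotropic Gaussian coordinate noise;
#' an optional linear drift displaces the whole ligand along +x across the
#' series, separating the means of early and late windows.
#'
#' @param base list with `receptor` and `ligand` `Structure`s (e.g. from
#'   [gen_toy_complex()]).
#' @param n_frames number of frames (>= 2).
#' @param noise_sd per-axis Gaussian noise, Angstrom.
#' @param drift total ligand displacement across the series, Angstrom
#'   (default 0).
#' @param seed integer seed.
#' @param dt frame spacing, ns.
#' @return list with `series` (a `SnapshotSeries` of complex frames),
#'   `rec_idx`, `lig_idx`.
#' @export
gen_trajectory <- function(base, n_frames = 20, noise_sd = 0.05, drift = 0,
                           seed = 1, dt = 1) {
  if (n_frames < 2) stop("n_frames must be >= 2")
  complex_atoms <- rbind(base$receptor$atoms, base$ligand$atoms)
  complex_atoms$serial <- seq_len(nrow(complex_atoms))
  rec_idx <- seq_len(nrow(base$receptor$atoms))
  lig_idx <- nrow(base$receptor$atoms) + seq_len(nrow(base$ligand$atoms))
  .with_seed(seed, {
    frames <- lapply(seq_len(n_frames), function(k) {
      at <- complex_atoms
      n <- nrow(at)
      if (noise_sd > 0) {
        at$x <- at$x + stats::rnorm(n, 0, noise_sd)
        at$y <- at$y + stats::rnorm(n, 0, noise_sd)
        at$z <- at$z + stats::rnorm(n, 0, noise_sd)
      }
      if (drift != 0)
        at$x[lig_idx] <- at$x[lig_idx] + drift * (k - 1) / (n_frames - 1)
      Structure(at, source = sprintf("gen_trajectory#%d", k),
                role = "complex")
    })
    list(series = SnapshotSeries(frames, times = dt * (seq_len(n_frames) - 1)),
         rec_idx = rec_idx, lig_idx = lig_idx)
  })
}
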