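test_that("rmsd_nofit matches the direct formula and simple geometry", {
  a <- matrix(c(0, 0, 0), ncol = 3)
  expect_equal(rmsd_nofit(a, a), 0)
  expect_equal(rmsd_nofit(a, matrix(c(3, 4, 0), ncol = 3)), 5)

  set.seed(21)
  x <- matrix(rnorm(90), ncol = 3)
  y <- matrix(rnorm(90), ncol = 3)
  oracle <- sqrt(sum((x - y)^2) / nrow(x))
  expect_equal(rmsd_nofit(x, y), oracle, tolerance = 1e-12)
  expect_equal(rmsd_nofit(y, x), rmsd_nofit(x, y))
  expect_error(rmsd_nofit(x, y[1:10, ]), "mismatch")
})

test_that("rmsd_kabsch is zero under rigid motion and bounded by nofit", {
  set.seed(22)
  x <- matrix(rnorm(60), ncol = 3)
  rot <- random_rotation(22)
  y <- x %*% t(rot)
  expect_equal(rmsd_kabsch(x, y), 0, tolerance = 1e-9)
  expect_equal(rmsd_kabsch(x, sweep(x, 2, c(5, -3, 2), `+`)), 0,
               tolerance = 1e-9)
  for (s in 1:10) {
    a <- matrix(rnorm(45, sd = 3), ncol = 3)
    b <- a + matrix(rnorm(45, sd = 0.8), ncol = 3)
    expect_lte(rmsd_kabsch(a, b), rmsd_nofit(a, b) + 1e-12)
    expect_equal(rmsd_kabsch(a, b), rmsd_kabsch(b, a), tolerance = 1e-9)
  }
})

test_that("rmsd_kabsch matches a rotation-grid oracle on 5-atom toys", {
  # exhaustive coarse Euler-angle search plus one local refinement pass
  rotm <- function(al, be, ga) {
    rz1 <- matrix(c(cos(al), sin(al), 0, -sin(al), cos(al), 0, 0, 0, 1), 3)
    ry <- matrix(c(cos(be), 0, -sin(be), 0, 1, 0, sin(be), 0, cos(be)), 3)
    rz2 <- matrix(c(cos(ga), sin(ga), 0, -sin(ga), cos(ga), 0, 0, 0, 1), 3)
    rz1 %*% ry %*% rz2
  }
  grid_oracle <- function(a, b) {
    ac <- sweep(a, 2, colMeans(a)); bc <- sweep(b, 2, colMeans(b))
    eval_at <- function(al, be, ga)
      sqrt(mean(rowSums((ac %*% rotm(al, be, ga) - bc)^2)))
    best <- c(Inf, 0, 0, 0)
    step <- 2 * pi / 24
    for (al in seq(0, 2 * pi - step, step))
      for (be in seq(0, pi, step))
        for (ga in seq(0, 2 * pi - step, step)) {
          r <- eval_at(al, be, ga)
          if (r < best[1]) best <- c(r, al, be, ga)
        }
    fine <- seq(-step, step, length.out = 17)
    for (dal in fine) for (dbe in fine) for (dga in fine) {
      r <- eval_at(best[2] + dal, best[3] + dbe, best[4] + dga)
      if (r < best[1]) best[1] <- r
    }
    best[1]
  }
  set.seed(23)
  for (s in 1:2) {
    a <- matrix(rnorm(15, sd = 2), ncol = 3)
    b <- a %*% t(random_rotation(100 + s)) +
      matrix(rnorm(15, sd = 0.1), ncol = 3)
    k <- rmsd_kabsch(a, b)
    g <- grid_oracle(a, b)
    expect_lte(k, g + 1e-9)      # Kabsch is the optimum
    expect_lt(abs(k - g), 0.05)  # grid approaches it
  }
})

test_that("rmsd_kabsch warns and falls back for degenerate input", {
  a <- matrix(c(0, 0, 0, 1, 0, 0), ncol = 3, byrow = TRUE)
  expect_warning(r <- rmsd_kabsch(a, a + 1), "degenerate")
  expect_equal(r, 0, tolerance = 1e-12)
})

test_that("selfdock_success scores the lowest-energy pose, strictly below", {
  ref <- matrix(c(0, 0, 0, 1.5, 0, 0), ncol = 3, byrow = TRUE)
  near <- ref + matrix(c(2.9, 0, 0), ncol = 3, nrow = 2, byrow = TRUE)
  far <- ref + matrix(c(10, 0, 0), ncol = 3, nrow = 2, byrow = TRUE)
  ps <- PoseSet("L1", "R1", list(
    list(coords = near, score = -8.0, run = 1),
    list(coords = ref, score = -7.5, run = 2)))
  out <- selfdock_success(ps, ref, threshold = 3.0)
  expect_equal(out$rmsd, 2.9)
  expect_true(out$success)   # 2.9 < 3.0
  expect_equal(out$best_run, 1)

  at3 <- ref + matrix(c(3, 0, 0), ncol = 3, nrow = 2, byrow = TRUE)
  ps2 <- PoseSet("L1", "R1", list(list(coords = at3, score = -9, run = 1)))
  expect_false(selfdock_success(ps2, ref)$success)  # 3.0 is a failure

  # a worse-RMSD pose with the lowest score wins the report
  ps3 <- PoseSet("L1", "R1", list(
    list(coords = ref, score = -7.0, run = 1),
    list(coords = far, score = -9.9, run = 2)))
  expect_equal(selfdock_success(ps3, ref)$rmsd, 10)
  # score tie -> lowest run index
  ps4 <- PoseSet("L1", "R1", list(
    list(coords = far, score = -9, run = 2),
    list(coords = ref, score = -9, run = 1)))
  expect_equal(selfdock_success(ps4, ref)$best_run, 1)
})

test_that("crossdock_matrix fills cells and flags missing ones", {
  ref <- list(L1 = matrix(c(0, 0, 0), ncol = 3),
              L2 = matrix(c(5, 5, 5), ncol = 3))
  mk <- function(lig, shift) PoseSet(lig, "R", list(
    list(coords = ref[[lig]] + shift, score = -5, run = 1)))
  results <- list(
    L1 = list(R1 = mk("L1", 0), R2 = mk("L1", 10)),
    L2 = list(R1 = mk("L2", 0), R2 = NULL))
  m <- crossdock_matrix(results, ref)
  expect_true(m$success["L1", "R1"])
  expect_false(m$success["L1", "R2"])   # rmsd 10*sqrt(3) -> failure
  expect_true(is.na(m$rmsd["L2", "R2"]))
  expect_equal(m$missing, "L2/R2")
  expect_error(crossdock_matrix(results, ref["L1"]), "L2")
})

test_that("ensemble_select: identity matrix needs all receptors", {
  rmsd <- matrix(10, 3, 3); diag(rmsd) <- 1
  m <- success_matrix(rmsd)
  expect_setequal(ensemble_select(m, mode = "exact")$selected,
                  c("R1", "R2", "R3"))
})

test_that("greedy picks the receptor covering most ligands first", {
  # receptor A recovers 7 of 9 ligands, receptor B 6 of 9
  rmsd <- matrix(10, 9, 2, dimnames = list(paste0("L", 1:9), c("A", "B")))
  rmsd[1:7, "A"] <- 1
  rmsd[4:9, "B"] <- 1
  sel <- ensemble_select(success_matrix(rmsd), mode = "greedy")
  expect_equal(sel$selected[1], "A")
  expect_setequal(sel$selected, c("A", "B"))
})

test_that("exact cover beats or equals greedy; planted cover recovered", {
  rmsd <- matrix(10, 6, 3, dimnames = list(paste0("L", 1:6),
                                           c("A", "B", "C")))
  rmsd[1:4, "A"] <- 1; rmsd[5:6, "B"] <- 1; rmsd[1:2, "C"] <- 1
  m <- success_matrix(rmsd)
  expect_equal(sort(ensemble_select(m, mode = "exact")$selected),
               c("A", "B"))
  expect_equal(sort(ensemble_select(m, mode = "greedy")$selected),
               c("A", "B"))
})

test_that("forced receptors are always included; uncoverable reported", {
  rmsd <- matrix(10, 3, 2, dimnames = list(c("L1", "L2", "L3"),
                                           c("A", "B")))
  rmsd[1, "A"] <- 1   # L2, L3 unrecoverable
  sel <- ensemble_select(success_matrix(rmsd), must_include = "B",
                         mode = "exact")
  expect_true("B" %in% sel$selected)
  expect_setequal(sel$unrecoverable, c("L2", "L3"))
  expect_equal(sel$covered, "L1")
  expect_error(ensemble_select(success_matrix(rmsd), must_include = "Z"),
               "unknown receptor")
})

test_that("exact set cover matches brute-force enumeration on random 6x6", {
  brute_min_cover <- function(m) {
    sets <- lapply(seq_along(m$receptors), function(j) which(m$success[, j]))
    coverable <- sort(unique(unlist(sets)))
    if (length(coverable) == 0) return(0L)
    for (k in 1:6) {
      for (cmb in utils::combn(6, k, simplify = FALSE))
        if (all(coverable %in% unlist(sets[cmb]))) return(k)
    }
    6L
  }
  set.seed(31)
  for (i in 1:60) {
    rmsd <- matrix(ifelse(runif(36) < 0.35, 1, 10), 6, 6,
                   dimnames = list(paste0("L", 1:6), paste0("R", 1:6)))
    m <- success_matrix(rmsd)
    ex <- ensemble_select(m, mode = "exact")
    gr <- ensemble_select(m, mode = "greedy")
    expect_equal(length(ex$selected), brute_min_cover(m))
    expect_lte(length(ex$selected), length(gr$selected))
    # both cover everything coverable
    expect_equal(ex$uncovered, character(0))
    expect_equal(gr$uncovered, character(0))
  }
})

test_that("adding a receptor column never decreases coverage", {
  set.seed(32)
  for (i in 1:20) {
    rmsd <- matrix(ifelse(runif(30) < 0.4, 1, 10), 6, 5,
                   dimnames = list(paste0("L", 1:6), paste0("R", 1:5)))
    cov5 <- length(ensemble_select(success_matrix(rmsd),
                                   mode = "greedy")$covered)
    extra <- cbind(rmsd, R6 = ifelse(runif(6) < 0.4, 1, 10))
    cov6 <- length(ensemble_select(success_matrix(extra),
                                   mode = "greedy")$covered)
    expect_gte(cov6, cov5)
  }
})

test_that("traj_rmsd is zero for static/rigidly-moved series", {
  base <- gen_toy_complex(3, seed = 41)
  static <- gen_trajectory(base, n_frames = 5, noise_sd = 0, seed = 41)
  expect_equal(traj_rmsd(static$series), rep(0, 5), tolerance = 1e-9)

  # rigid translation of one frame vanishes after superposition
  s <- static$series
  s$frames[[3]]$atoms$x <- s$frames[[3]]$atoms$x + 4
  expect_equal(traj_rmsd(s)[3], 0, tolerance = 1e-9)
  expect_error(traj_rmsd(s, selection = integer(0)), "empty")
})

test_that("a planted drifting ligand reproduces its displacement profile", {
  base <- gen_toy_complex(3, seed = 42)
  tr <- gen_trajectory(base, n_frames = 6, noise_sd = 0, drift = 5,
                       seed = 42)
  # only the ligand moves; rmsd over ligand atoms without receptor anchor
  # equals 0 after fit, so measure nofit displacement directly
  lig0 <- coords(tr$series$frames[[1]])[tr$lig_idx, ]
  d <- vapply(1:6, function(k)
    rmsd_nofit(coords(tr$series$frames[[k]])[tr$lig_idx, ], lig0),
    numeric(1))
  expect_equal(d, 5 * (0:5) / 5, tolerance = 1e-6)
})

test_that("traj_rmsf: two-frame oscillation gives the closed form", {
  # one atom at the anchor centroid oscillates +/-0.3 along z; a large,
  # centro-symmetric anchor shell keeps the frame superposition from
  # absorbing the motion (no net translation or torque)
  set.seed(24)
  half <- matrix(rnorm(90, sd = 8), ncol = 3)
  anchors <- rbind(half, -half)
  at <- make_atoms(rbind(c(0, 0, 0), anchors))
  up <- at; up$z[1] <- 0.3
  dn <- at; dn$z[1] <- -0.3
  s <- SnapshotSeries(list(Structure(up), Structure(dn)))
  rmsf <- traj_rmsf(s)
  expect_equal(rmsf[1], 0.3, tolerance = 0.02)
  expect_lt(max(rmsf[-1]), 0.05)
  expect_error(traj_rmsf(SnapshotSeries(list(Structure(at)))), "two frames")
})

test_that("success matrix round-trips through its text format", {
  m <- gen_success_matrix(6, 6, planted_cover = c(2, 5), seed = 51)
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_success_matrix(m, tmp)
  m2 <- read_success_matrix(tmp)
  expect_equal(m2$rmsd, m$rmsd, tolerance = 1e-12)
  expect_identical(m2$success, m$success)
})
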