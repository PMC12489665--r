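#' @title Pose-accuracy metrics and receptor-ensemble selection
#'
#' @description Docking poses are judged against the crystallographic
#' reference by heavy-atom, order-matched RMSD in the shared docking frame
#' (no superposition), the convention used when the receptor is held fixed.
#' A self- or cross-docking cell is successful when the lowest-score pose
#' lies strictly below the RMSD threshold (default 3 Angstrom). The minimal
#' receptor ensemble is the smallest receptor set whose successful cells
#' cover every coverable ligand.
#' @name posemetrics
NULL

.as_coords <- function(a) {
  if (inherits(a, "Structure")) a <- coords(a)
  a <- as.matrix(a)
  if (ncol(a) != 3) stop("coordinates must be an n x 3 matrix")
  storage.mode(a) <- "double"
  a
}

#' RMSD without superposition
#'
#' Root-mean-square deviation between two order-matched coordinate sets in a
#' shared frame; no rotation or translation is applied.
#'
#' @param a,b n x 3 coordinate matrices (or `Structure`s) with identical atom
#'   ordering.
#' @return RMSD in Angstrom.
#' @export
rmsd_nofit <- function(a, b) {
  a <- .as_coords(a); b <- .as_coords(b)
  if (nrow(a) != nrow(b))
    stop("atom count mismatch: ", nrow(a), " vs ", nrow(b))
  sqrt(mean(rowSums((a - b)^2)))
}

#' Optimal-superposition (Kabsch) RMSD
#'
#' Minimal RMSD over rigid rotations and translations, via the Kabsch
#' singular-value-decomposition solution with the usual determinant
#' correction against improper rotations. Degenerate inputs (< 3 atoms or
#' collinear sets) fall back to translation-only superposition with a
#' warning.
#'
#' @param a,b n x 3 coordinate matrices (or `Structure`s).
#' @return minimal RMSD in Angstrom.
#' @export
rmsd_kabsch <- function(a, b) {
  a <- .as_coords(a); b <- .as_coords(b)
  if (nrow(a) != nrow(b))
    stop("atom count mismatch: ", nrow(a), " vs ", nrow(b))
  ac <- sweep(a, 2, colMeans(a))
  bc <- sweep(b, 2, colMeans(b))
  h <- crossprod(ac, bc)
  sv <- svd(h)
  rank_def <- sum(sv$d > max(sv$d[1], .Machine$double.eps) * 1e-8) < 2
  if (nrow(a) < 3 || rank_def) {
    warning("degenerate atom set; translation-only superposition")
    return(sqrt(mean(rowSums((ac - bc)^2))))
  }
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  sqrt(mean(rowSums((bc - ac %*% t(rot))^2)))
}

#' Pose set for one (ligand, receptor) docking cell
#'
#' @param ligand_id,receptor_id identifiers.
#' @param poses list of entries `list(coords =, score =, run =)`; scores in
#'   kcal/mol (lower is better), `run` the repeat index.
#' @return an object of class `PoseSet`.
#' @export
PoseSet <- function(ligand_id, receptor_id, poses) {
  if (length(poses) < 1L) stop("a PoseSet needs at least one pose")
  n <- nrow(.as_coords(poses[[1]]$coords))
  for (p in poses) {
    if (nrow(.as_coords(p$coords)) != n)
      stop("poses differ in atom count")
    if (is.null(p$score) || is.null(p$run))
      stop("each pose needs a score and a run index")
  }
  structure(list(ligand_id = ligand_id, receptor_id = receptor_id,
                 poses = poses), class = "PoseSet")
}

#' Self-docking success for one pose set
#'
#' The best pose is the one with the lowest docking score across all pooled
#' repeats (ties broken by lowest run index, then file order); success is
#' strict: RMSD < threshold.
#'
#' @param p a [PoseSet()].
#' @param reference reference (crystallographic) ligand coordinates.
#' @param threshold success cutoff in Angstrom (default 3.0).
#' @return list with `rmsd`, `success`, `best_run`, `best_score`.
#' @export
selfdock_success <- function(p, reference, threshold = 3.0) {
  if (!inherits(p, "PoseSet")) stop("p must be a PoseSet")
  scores <- vapply(p$poses, `[[`, numeric(1), "score")
  runs <- vapply(p$poses, function(x) as.numeric(x$run), numeric(1))
  best <- order(scores, runs)[1]
  r <- rmsd_nofit(p$poses[[best]]$coords, reference)
  list(rmsd = r, success = r < threshold,
       best_run = runs[best], best_score = scores[best])
}

#' Cross-docking success matrix
#'
#' Applies [selfdock_success()] to every (ligand, receptor) cell. Cells with
#' no pose set must be flagged explicitly with `NULL` entries; they appear as
#' `NA` RMSD and are reported in `missing`, never silently treated as
#' failures.
#'
#' @param results nested list `results[[ligand]][[receptor]]` of [PoseSet()]s
#'   (or `NULL` for explicitly missing cells).
#' @param references named list of reference coordinates, one per ligand.
#' @param threshold success cutoff in Angstrom.
#' @return an object of class `SuccessMatrix` with `rmsd` and `success`
#'   matrices (ligands x receptors), the `threshold`, and `missing` cells.
#' @export
crossdock_matrix <- function(results, references, threshold = 3.0) {
  ligands <- names(results)
  if (is.null(ligands)) stop("results must be a named list by ligand")
  receptors <- unique(unlist(lapply(results, names)))
  absent <- setdiff(ligands, names(references))
  if (length(absent) > 0)
    stop("missing reference coordinates for ligand(s): ",
         paste(absent, collapse = ", "))
  rmsd <- matrix(NA_real_, length(ligands), length(receptors),
                 dimnames = list(ligands, receptors))
  missing <- character(0)
  for (li in ligands) for (ri in receptors) {
    cell <- results[[li]][[ri]]
    if (is.null(cell)) {
      missing <- c(missing, paste(li, ri, sep = "/"))
      next
    }
    rmsd[li, ri] <- selfdock_success(cell, references[[li]], threshold)$rmsd
  }
  success_matrix(rmsd, threshold = threshold, missing = missing)
}

#' Construct a SuccessMatrix from an RMSD matrix
#'
#' @param rmsd ligands x receptors matrix of best-pose RMSD (Angstrom); `NA`
#'   marks explicitly missing cells.
#' @param threshold success cutoff (strict `<`).
#' @param missing character labels of missing cells, for reporting.
#' @return an object of class `SuccessMatrix`.
#' @export
success_matrix <- function(rmsd, threshold = 3.0, missing = character(0)) {
  if (is.null(dimnames(rmsd)))
    dimnames(rmsd) <- list(paste0("L", seq_len(nrow(rmsd))),
                           paste0("R", seq_len(ncol(rmsd))))
  success <- rmsd < threshold
  success[is.na(rmsd)] <- FALSE
  structure(list(ligands = rownames(rmsd), receptors = colnames(rmsd),
                 rmsd = rmsd, success = success, threshold = threshold,
                 missing = missing),
            class = "SuccessMatrix")
}

#' @export
print.SuccessMatrix <- function(x, ...) {
  cat(sprintf("SuccessMatrix: %d ligands x %d receptors, threshold %.2f A\n",
              length(x$ligands), length(x$receptors), x$threshold))
  cat(sprintf("  recovered cells: %d/%d\n", sum(x$success),
              length(x$success)))
  if (length(x$missing) > 0)
    cat("  missing cells:", paste(x$missing, collapse = ", "), "\n")
  invisible(x)
}

.cover_sets <- function(m) {
  # receptor -> set of ligand indices it recovers
  lapply(seq_along(m$receptors), function(j) which(m$success[, j]))
}

#' Minimal receptor-ensemble selection (set cover)
#'
#' Finds a receptor set whose successful docking cells cover every coverable
#' ligand. `exact` mode enumerates receptor subsets in increasing cardinality
#' (guaranteed minimum beyond the forced members; intended for <= 20
#' receptors) preferring the lexicographically smallest among equal-size
#' covers; `greedy` repeatedly adds the receptor recovering the most
#' still-uncovered ligands, ties broken lexicographically by receptor id.
#' Forced receptors (e.g. apo structures retained for binding-site diversity)
#' are seeded into the selection before either strategy runs. Ligands no
#' receptor recovers are reported in `uncovered`, not raised as errors.
#'
#' @param m a `SuccessMatrix`.
#' @param must_include receptor ids always included.
#' @param mode `"greedy"` or `"exact"`.
#' @return an object of class `EnsembleSelection` with `selected`, `covered`,
#'   `uncovered`, `forced`, `mode`.
#' @export
ensemble_select <- function(m, must_include = character(0),
                            mode = c("greedy", "exact")) {
  mode <- match.arg(mode)
  if (!all(must_include %in% m$receptors))
    stop("must_include contains unknown receptor id(s): ",
         paste(setdiff(must_include, m$receptors), collapse = ", "))
  sets <- .cover_sets(m)
  names(sets) <- m$receptors
  coverable <- sort(unique(unlist(sets)))
  forced <- sort(must_include)
  covered0 <- sort(unique(unlist(sets[forced])))
  need <- setdiff(coverable, covered0)
  free <- setdiff(m$receptors, forced)
  # order free receptors lexicographically so subset enumeration and greedy
  # tie-breaks are deterministic
  free <- sort(free)

  chosen <- character(0)
  if (length(need) > 0L && length(free) > 0L) {
    if (mode == "exact") {
      found <- NULL
      for (k in seq_along(free)) {
        combs <- utils::combn(free, k, simplify = FALSE)
        for (cmb in combs) {
          if (all(need %in% unlist(sets[cmb]))) { found <- cmb; break }
        }
        if (!is.null(found)) break
      }
      chosen <- if (is.null(found)) character(0) else found
      if (is.null(found) && length(need) > 0L) {
        # cover as much as possible: fall back to greedy on the coverable part
        chosen <- Recall(m, must_include, "greedy")$selected
        chosen <- setdiff(chosen, forced)
      }
    } else {
      uncovered <- need
      while (length(uncovered) > 0L) {
        gain <- vapply(free, function(r)
          length(intersect(sets[[r]], uncovered)), integer(1))
        if (all(gain == 0L)) break
        pick <- free[order(-gain, free)][1]
        chosen <- c(chosen, pick)
        uncovered <- setdiff(uncovered, sets[[pick]])
        free <- setdiff(free, pick)
      }
    }
  }
  selected <- c(forced, chosen)
  covered_idx <- sort(unique(unlist(sets[selected])))
  structure(list(selected = selected,
                 covered = m$ligands[covered_idx],
                 uncovered = m$ligands[setdiff(coverable, covered_idx)],
                 unrecoverable = m$ligands[setdiff(seq_along(m$ligands),
                                                   coverable)],
                 forced = forced, mode = mode),
            class = "EnsembleSelection")
}

#' @export
print.EnsembleSelection <- function(x, ...) {
  cat(sprintf("EnsembleSelection (%s): {%s}\n", x$mode,
              paste(x$selected, collapse = ", ")))
  cat(sprintf("  covers %d ligand(s)", length(x$covered)))
  if (length(x$unrecoverable) > 0)
    cat("; unrecoverable:", paste(x$unrecoverable, collapse = ", "))
  cat("\n")
  invisible(x)
}

#' Per-frame RMSD of a trajectory against a reference frame
#'
#' Each frame is optimally superposed (Kabsch) on the reference frame over
#' the selected atoms before the deviation is measured.
#'
#' @param s a `SnapshotSeries`.
#' @param reference_frame frame index used as reference (default 1).
#' @param selection integer atom indices (default all atoms).
#' @return numeric vector of per-frame RMSD (Angstrom).
#' @export
traj_rmsd <- function(s, reference_frame = 1L, selection = NULL) {
  if (reference_frame < 1L || reference_frame > n_frames(s))
    stop("reference_frame out of range")
  if (is.null(selection)) selection <- seq_len(n_atoms(s$frames[[1]]))
  if (length(selection) == 0L) stop("empty atom selection")
  ref <- coords(s$frames[[reference_frame]])[selection, , drop = FALSE]
  vapply(s$frames, function(f)
    rmsd_kabsch(coords(f)[selection, , drop = FALSE], ref), numeric(1))
}

#' Per-atom root-mean-square fluctuation
#'
#' Frames are first superposed on the mean structure (iterating the mean once
#' after an initial superposition on frame 1); the RMSF of atom i is the root
#' mean square of its displacement from its mean position.
#'
#' @param s a `SnapshotSeries` with at least two frames.
#' @param selection integer atom indices (default all).
#' @return numeric per-atom RMSF (Angstrom), one value per selected atom.
#' @export
traj_rmsf <- function(s, selection = NULL) {
  if (n_frames(s) < 2L) stop("RMSF needs at least two frames")
  if (is.null(selection)) selection <- seq_len(n_atoms(s$frames[[1]]))
  if (length(selection) == 0L) stop("empty atom selection")
  mats <- lapply(s$frames, function(f)
    coords(f)[selection, , drop = FALSE])
  fit_onto <- function(x, ref) {
    xc <- sweep(x, 2, colMeans(x))
    rc <- sweep(ref, 2, colMeans(ref))
    if (nrow(x) < 3) return(sweep(xc, 2, colMeans(rc), `+`) + 0)
    h <- crossprod(xc, rc)
    sv <- svd(h)
    d <- sign(det(sv$v %*% t(sv$u)))
    rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
    xc %*% t(rot)
  }
  aligned <- lapply(mats, fit_onto, ref = mats[[1]])
  mean_str <- Reduce(`+`, aligned) / length(aligned)
  aligned <- lapply(mats, fit_onto, ref = mean_str)
  mean_str <- Reduce(`+`, aligned) / length(aligned)
  dev2 <- lapply(aligned, function(x) rowSums((x - mean_str)^2))
  sqrt(Reduce(`+`, dev2) / length(dev2))
}

#' Write a success matrix as delimited text
#'
#' Long format: `ligand`, `receptor`, `rmsd_A`, `success`; missing cells keep
#' `NA` RMSD.
#' @param m a `SuccessMatrix`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_success_matrix <- function(m, path) {
  df <- expand.grid(ligand = m$ligands, receptor = m$receptors,
                    stringsAsFactors = FALSE)
  df$rmsd_A <- m$rmsd[cbind(df$ligand, df$receptor)]
  df$success <- m$success[cbind(df$ligand, df$receptor)]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a success matrix written by [write_success_matrix()]
#' @param path input path.
#' @param threshold success cutoff used to rebuild the boolean matrix.
#' @return a `SuccessMatrix`.
#' @export
read_success_matrix <- function(path, threshold = 3.0) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  ligands <- unique(df$ligand)
  receptors <- unique(df$receptor)
  rmsd <- matrix(NA_real_, length(ligands), length(receptors),
                 dimnames = list(ligands, receptors))
  rmsd[cbind(df$ligand, df$receptor)] <- df$rmsd_A
  success_matrix(rmsd, threshold = threshold,
                 missing = with(df[is.na(df$rmsd_A), , drop = FALSE],
                                paste(ligand, receptor, sep = "/")))
}
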