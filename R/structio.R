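#' @title Molecular structure container
#'
#' @description A `Structure` is an ordered atom table plus metadata. Atoms
#' carry Cartesian coordinates (Angstrom), a partial charge (e), Lennard-Jones
#' parameters (sigma in Angstrom, epsilon in kcal/mol) and an intrinsic
#' (van der Waals) radius used for surface-area calculations. Residue identity
#' is the triple (chain, residue number, residue name); the residue index
#' enumerates residues in first-appearance order and is stable across
#' read/write round trips.
#'
#' @param atoms data.frame with columns `serial`, `name`, `element`, `x`, `y`,
#'   `z`, `charge`, `lj_sigma`, `lj_epsilon`, `radius`, `chain`, `resno`,
#'   `resname`.
#' @param source identifier of the originating file or generator.
#' @param state `"bound"` or `"apo"`.
#' @param role `"receptor"`, `"ligand"` or `"complex"`.
#' @return An object of class `Structure`.
#' @export
Structure <- function(atoms, source = NA_character_, state = "bound",
                      role = "complex") {
  required <- c("serial", "name", "element", "x", "y", "z", "charge",
                "lj_sigma", "lj_epsilon", "radius", "chain", "resno",
                "resname")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols) > 0L)
    stop("Structure atoms table lacks columns: ",
         paste(missing_cols, collapse = ", "))
  if (nrow(atoms) > 0L) {
    xyz <- as.matrix(atoms[, c("x", "y", "z")])
    if (!all(is.finite(xyz))) stop("non-finite coordinates in atom table")
    if (any(atoms$radius < 0)) stop("negative atomic radius")
    if (any(atoms$lj_sigma < 0) || any(atoms$lj_epsilon < 0))
      stop("negative Lennard-Jones parameter")
  }
  state <- match.arg(state, c("bound", "apo"))
  role <- match.arg(role, c("receptor", "ligand", "complex"))
  rownames(atoms) <- NULL
  structure(list(atoms = atoms,
                 meta = list(source = source, state = state, role = role)),
            class = "Structure")
}

#' Number of atoms in a Structure
#' @param s a `Structure`.
#' @return integer atom count.
#' @export
n_atoms <- function(s) nrow(s$atoms)

#' Coordinate matrix of a Structure
#' @param s a `Structure`.
#' @return numeric n x 3 matrix (Angstrom).
#' @export
coords <- function(s) {
  m <- as.matrix(s$atoms[, c("x", "y", "z")])
  dimnames(m) <- list(NULL, c("x", "y", "z"))
  m
}

#' Residue keys of a Structure in first-appearance order
#'
#' @param s a `Structure`.
#' @return character vector of keys `"chain:resno:resname"`.
#' @export
residue_keys <- function(s) {
  if (nrow(s$atoms) == 0L) return(character(0))
  k <- paste(s$atoms$chain, s$atoms$resno, s$atoms$resname, sep = ":")
  unique(k)
}

#' Per-atom residue key vector
#' @param s a `Structure`.
#' @return character vector, one key per atom.
#' @export
atom_residue_keys <- function(s) {
  paste(s$atoms$chain, s$atoms$resno, s$atoms$resname, sep = ":")
}

#' @export
print.Structure <- function(x, ...) {
  cat(sprintf("Structure: %d atoms, %d residues (%s, %s)\n",
              n_atoms(x), length(residue_keys(x)),
              x$meta$role, x$meta$state))
  if (!is.na(x$meta$source)) cat("  source:", x$meta$source, "\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Nonbonded parameter table

#' Load an element parameter table
#'
#' PDB/PDBQT files carry no force-field parameters; Lennard-Jones sigma and
#' epsilon and intrinsic radii are supplied by a plain-text lookup shipped with
#' the package (columns: `element`, `sigma_A`, `epsilon_kcal`, `radius_A`).
#' The shipped values are generic surrogates in the style of common
#' biomolecular force fields, not a reproduction of any published parameter
#' set.
#'
#' @param path optional path to an alternative table.
#' @return data.frame with one row per element.
#' @export
load_param_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "atom_params.tsv", package = "atroscreen")
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("element", "sigma_A", "epsilon_kcal", "radius_A")
  if (!all(need %in% names(tab)))
    stop("parameter table must have columns ", paste(need, collapse = ", "))
  tab
}

#' Attach Lennard-Jones parameters and radii by element
#'
#' @param s a `Structure`.
#' @param params parameter table from [load_param_table()].
#' @param warn_unknown warn for elements absent from the table (they keep
#'   zero parameters).
#' @return the `Structure` with `lj_sigma`, `lj_epsilon`, `radius` filled.
#' @export
apply_params <- function(s, params = load_param_table(), warn_unknown = TRUE) {
  idx <- match(toupper(s$atoms$element), toupper(params$element))
  unknown <- unique(s$atoms$element[is.na(idx)])
  if (warn_unknown && length(unknown) > 0L)
    warning("no parameters for element(s): ",
            paste(unknown, collapse = ", "), "; left at 0")
  ok <- !is.na(idx)
  s$atoms$lj_sigma[ok] <- params$sigma_A[idx[ok]]
  s$atoms$lj_epsilon[ok] <- params$epsilon_kcal[idx[ok]]
  s$atoms$radius[ok] <- params$radius_A[idx[ok]]
  s
}

#' Convert kJ/mol to kcal/mol and back
#'
#' All energies in this package are kcal/mol; these helpers convert values
#' produced by tools that report kJ/mol.
#' @param x numeric energy values.
#' @return converted numeric values.
#' @export
kj_to_kcal <- function(x) x / 4.184

#' @rdname kj_to_kcal
#' @export
kcal_to_kj <- function(x) x * 4.184

# ---------------------------------------------------------------------------
# PDB / PDBQT fixed-column I/O
#
# Only ATOM/HETATM/MODEL/ENDMDL/TER/END records are interpreted. PDBQT places
# the partial charge in columns 67-76 (after the occupancy/B-factor slots);
# plain PDB has no charge column and charges default to 0 with a warning.

.parse_atom_line <- function(line, lineno, dialect) {
  pad <- function(x, n) formatC(x, width = n, flag = "-")
  if (nchar(line) < 54)
    stop(sprintf("malformed %s record at line %d: too short", dialect, lineno))
  line <- pad(line, 80)
  serial <- suppressWarnings(as.integer(substr(line, 7, 11)))
  name <- trimws(substr(line, 13, 16))
  resname <- trimws(substr(line, 18, 21))
  chain <- trimws(substr(line, 22, 22))
  if (chain == "") chain <- "A"
  resno <- suppressWarnings(as.integer(substr(line, 23, 26)))
  x <- suppressWarnings(as.numeric(substr(line, 31, 38)))
  y <- suppressWarnings(as.numeric(substr(line, 39, 46)))
  z <- suppressWarnings(as.numeric(substr(line, 47, 54)))
  if (any(is.na(c(serial, resno, x, y, z))))
    stop(sprintf("malformed %s record at line %d: unparsable field",
                 dialect, lineno))
  altloc <- substr(line, 17, 17)
  icode <- substr(line, 27, 27)
  charge <- NA_real_
  element <- trimws(substr(line, 77, 78))
  if (dialect == "pdbqt") {
    charge <- suppressWarnings(as.numeric(substr(line, 67, 76)))
    # PDBQT's final column is the AutoDock atom type, not the element
    adtype <- trimws(substr(line, 78, 80))
    if (element == "" && adtype != "") element <- adtype
  }
  if (element == "") {
    # fall back on the atom-name convention: first alphabetic character(s)
    element <- sub("^[0-9]*", "", name)
    element <- substr(element, 1, 1)
  }
  element <- toupper(substr(element, 1, 2))
  if (nchar(element) == 2 && !element %in% c("CL", "BR", "NA", "MG", "ZN",
                                             "FE", "MN", "SE"))
    element <- substr(element, 1, 1)
  list(serial = serial, name = name, element = element,
       x = x, y = y, z = z, charge = charge,
       chain = chain, resno = resno, resname = resname,
       altloc = altloc, icode = icode)
}

.atoms_from_lines <- function(lines, linenos, dialect) {
  parsed <- lapply(seq_along(lines), function(i)
    .parse_atom_line(lines[[i]], linenos[[i]], dialect))
  df <- data.frame(
    serial = vapply(parsed, `[[`, integer(1), "serial"),
    name = vapply(parsed, `[[`, character(1), "name"),
    element = vapply(parsed, `[[`, character(1), "element"),
    x = vapply(parsed, `[[`, numeric(1), "x"),
    y = vapply(parsed, `[[`, numeric(1), "y"),
    z = vapply(parsed, `[[`, numeric(1), "z"),
    charge = vapply(parsed, `[[`, numeric(1), "charge"),
    chain = vapply(parsed, `[[`, character(1), "chain"),
    resno = vapply(parsed, `[[`, integer(1), "resno"),
    resname = vapply(parsed, `[[`, character(1), "resname"),
    stringsAsFactors = FALSE)
  altloc <- vapply(parsed, `[[`, character(1), "altloc")
  icode <- vapply(parsed, `[[`, character(1), "icode")
  # alternate locations / insertion codes: first occurrence wins
  alt_dup <- altloc != " " & altloc != "" & altloc != "A"
  if (any(alt_dup)) {
    warning("alternate location indicators found; keeping first occurrence")
    df <- df[!alt_dup, , drop = FALSE]
    icode <- icode[!alt_dup]
  }
  if (any(icode != " " & icode != ""))
    warning("insertion codes found; residues distinguished by number only")
  if (dialect == "pdb") {
    df$charge <- 0
  } else if (anyNA(df$charge)) {
    warning("PDBQT records missing charge column; defaulting to 0")
    df$charge[is.na(df$charge)] <- 0
  }
  df$lj_sigma <- 0
  df$lj_epsilon <- 0
  df$radius <- 0
  rownames(df) <- NULL
  df
}

#' Read a molecular structure from PDB or PDBQT
#'
#' @param path file path.
#' @param dialect `"pdb"` or `"pdbqt"`. PDBQT partial charges are captured
#'   into the `charge` field; plain PDB charges default to 0 with a warning
#'   (suppressable via `quiet`).
#' @param role,state metadata for the returned [Structure()].
#' @param quiet suppress the missing-charge warning for plain PDB.
#' @return a `Structure`.
#' @export
read_structure <- function(path, dialect = c("pdb", "pdbqt"),
                           role = "complex", state = "bound", quiet = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  sel <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(sel)) stop("no ATOM/HETATM records in ", path)
  atoms <- .atoms_from_lines(lines[sel], which(sel), dialect)
  if (dialect == "pdb" && !quiet)
    warning("PDB carries no partial charges; charge set to 0 ",
            "(supply parameters via apply_params)")
  Structure(atoms, source = path, state = state, role = role)
}

.format_atom_line <- function(a, dialect) {
  # PDB atom-name column convention: names of <4 chars start in column 14
  nm <- a$name
  nm <- if (nchar(nm) >= 4) substr(nm, 1, 4) else paste0(" ", nm)
  tail_cols <- if (dialect == "pdbqt") {
    sprintf("%10.4f%-2s", a$charge, a$element)
  } else {
    sprintf("          %2s", a$element)
  }
  sprintf("%-6s%5d %-4s%1s%-4s%1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f%s",
          "ATOM", a$serial %% 100000L, nm, " ",
          substr(a$resname, 1, 4), substr(a$chain, 1, 1), a$resno %% 10000L,
          " ", a$x, a$y, a$z, 1.00, 0.00, tail_cols)
}

#' Write a Structure to PDB or PDBQT
#'
#' Coordinates are written at the format's 0.001 Angstrom precision; PDBQT
#' output carries partial charges, plain PDB does not.
#'
#' @param s a non-empty `Structure`.
#' @param path output path.
#' @param dialect `"pdb"` or `"pdbqt"`.
#' @return invisibly, `path`.
#' @export
write_structure <- function(s, path, dialect = c("pdb", "pdbqt")) {
  dialect <- match.arg(dialect)
  if (n_atoms(s) == 0L) stop("refusing to write an empty structure")
  lines <- vapply(seq_len(n_atoms(s)), function(i)
    .format_atom_line(as.list(s$atoms[i, ]), dialect), character(1))
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot open for writing: ", path))
  on.exit(close(con))
  writeLines(c(lines, "END"), con)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Snapshot series (multi-model PDB)

#' Snapshot series container
#'
#' An MD-style series of frames with identical atom ordering and strictly
#' increasing times (ns).
#'
#' @param frames list of `Structure`s with identical atom count and ordering.
#' @param times numeric times in ns, strictly increasing; defaults to
#'   `0, 1, ...`.
#' @return an object of class `SnapshotSeries`.
#' @export
SnapshotSeries <- function(frames, times = NULL) {
  if (length(frames) == 0L) stop("empty snapshot series")
  n0 <- n_atoms(frames[[1]])
  names0 <- frames[[1]]$atoms$name
  for (f in frames) {
    if (n_atoms(f) != n0)
      stop("frames differ in atom count (", n_atoms(f), " vs ", n0, ")")
    if (!identical(f$atoms$name, names0))
      stop("frames differ in atom ordering")
  }
  if (is.null(times)) times <- seq_along(frames) - 1
  if (length(times) != length(frames))
    stop("times length must match frame count")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  structure(list(frames = frames, times = as.numeric(times)),
            class = "SnapshotSeries")
}

#' @export
print.SnapshotSeries <- function(x, ...) {
  cat(sprintf("SnapshotSeries: %d frames x %d atoms, t = %.3g..%.3g ns\n",
              length(x$frames), n_atoms(x$frames[[1]]),
              x$times[1], x$times[length(x$times)]))
  invisible(x)
}

#' Number of frames in a series
#' @param s a `SnapshotSeries`.
#' @return integer frame count.
#' @export
n_frames <- function(s) length(s$frames)

#' Read a multi-model PDB as a snapshot series
#'
#' One frame per MODEL record; a file without MODEL records yields a single
#' frame. Times are taken from `REMARK TIME <ns>` lines when present,
#' otherwise uniform 1 ns spacing from 0.
#'
#' @param path multi-model PDB path.
#' @param dialect coordinate dialect, as in [read_structure()].
#' @return a `SnapshotSeries`.
#' @export
read_snapshots <- function(path, dialect = c("pdb", "pdbqt")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  model_starts <- grep("^MODEL", lines)
  times <- NULL
  tl <- grep("^REMARK TIME", lines, value = TRUE)
  if (length(tl) > 0)
    times <- as.numeric(sub("^REMARK TIME +", "", tl))
  if (length(model_starts) == 0L) {
    sel <- grepl("^(ATOM  |HETATM)", lines)
    atoms <- .atoms_from_lines(lines[sel], which(sel), dialect)
    return(SnapshotSeries(list(Structure(atoms, source = path)),
                          times = times))
  }
  model_ends <- grep("^ENDMDL", lines)
  if (length(model_ends) != length(model_starts))
    stop("unbalanced MODEL/ENDMDL records in ", path)
  frames <- lapply(seq_along(model_starts), function(k) {
    block <- lines[model_starts[k]:model_ends[k]]
    sel <- grepl("^(ATOM  |HETATM)", block)
    atoms <- .atoms_from_lines(block[sel], which(sel) + model_starts[k] - 1L,
                               dialect)
    Structure(atoms, source = sprintf("%s#%d", path, k))
  })
  n <- vapply(frames, n_atoms, integer(1))
  if (length(unique(n)) != 1L)
    stop("models differ in atom count: ", paste(unique(n), collapse = ", "))
  SnapshotSeries(frames, times = times)
}

#' Write a snapshot series as a multi-model PDB
#'
#' @param s a `SnapshotSeries`.
#' @param path output path.
#' @param dialect coordinate dialect.
#' @return invisibly, `path`.
#' @export
write_snapshots <- function(s, path, dialect = c("pdb", "pdbqt")) {
  dialect <- match.arg(dialect)
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot open for writing: ", path))
  on.exit(close(con))
  for (k in seq_along(s$frames)) {
    writeLines(sprintf("REMARK TIME %.6f", s$times[k]), con)
    writeLines(sprintf("MODEL %8d", k), con)
    f <- s$frames[[k]]
    lines <- vapply(seq_len(n_atoms(f)), function(i)
      .format_atom_line(as.list(f$atoms[i, ]), dialect), character(1))
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
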