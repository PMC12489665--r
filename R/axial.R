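#' @title Axial chirality: torsion measurement and enantiopreference
#'
#' @description Biflavonoids with a hindered interflavonoid bond are
#' atropisomeric: the two senses of twist about the biaryl axis are isolable
#' Ra/Sa enantiomers. The sign of the dihedral across that bond encodes the
#' sense of axial twist; which sign corresponds to Ra and which to Sa depends
#' on the four atoms chosen and on CIP priorities, so the mapping is explicit
#' configuration here (default `positive_is_Sa`), validated for internal
#' consistency (mirror images flip the label) rather than derived from CIP
#' rules. Near-planar torsions fall inside a configurable window around 0 or
#' 180 degrees and receive no label: at the rotation barrier the axial
#' descriptor is not meaningful.
#' @name axial
NULL

#' Torsion specification
#'
#' Four atom selectors defining the dihedral across the interflavonoid bond,
#' plus the near-planar window within which no axial label is assigned.
#' A selector is a list `list(chain =, resno =, name =)`; `chain` may be
#' omitted when unambiguous.
#'
#' @param atoms list of four selectors.
#' @param near_planar_window degrees, in `[0, 45)`.
#' @return an object of class `TorsionSpec`.
#' @export
TorsionSpec <- function(atoms, near_planar_window = 15) {
  if (length(atoms) != 4L) stop("a torsion needs exactly four atom selectors")
  if (near_planar_window < 0 || near_planar_window >= 45)
    stop("near_planar_window must lie in [0, 45) degrees")
  structure(list(atoms = atoms, near_planar_window = near_planar_window),
            class = "TorsionSpec")
}

.resolve_selector <- function(s, sel) {
  hit <- rep(TRUE, n_atoms(s))
  if (!is.null(sel$chain)) hit <- hit & s$atoms$chain == sel$chain
  if (!is.null(sel$resno)) hit <- hit & s$atoms$resno == sel$resno
  if (!is.null(sel$name)) hit <- hit & s$atoms$name == sel$name
  idx <- which(hit)
  if (length(idx) == 0L)
    stop("atom selector matches nothing: ",
         paste(unlist(sel), collapse = "/"))
  if (length(idx) > 1L)
    stop("atom selector is ambiguous (", length(idx), " matches): ",
         paste(unlist(sel), collapse = "/"))
  idx
}

#' Signed dihedral angle of four points
#'
#' Standard right-hand convention: the angle between the plane (p1,p2,p3)
#' and the plane (p2,p3,p4), signed by the direction of twist about the
#' p2-p3 axis, in (-180, 180].
#'
#' @param p1,p2,p3,p4 numeric 3-vectors.
#' @return dihedral in degrees.
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  if (sum(n1^2) < 1e-18 || sum(n2^2) < 1e-18)
    stop("undefined geometry: three consecutive atoms are collinear")
  b2n <- b2 / sqrt(sum(b2^2))
  m1 <- c(n1[2] * b2n[3] - n1[3] * b2n[2],
          n1[3] * b2n[1] - n1[1] * b2n[3],
          n1[1] * b2n[2] - n1[2] * b2n[1])
  ang <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Measure the interflavonoid torsion of a structure
#'
#' @param s a `Structure`.
#' @param spec a [TorsionSpec()].
#' @return signed dihedral in degrees, in (-180, 180].
#' @export
measure_torsion <- function(s, spec) {
  if (!inherits(spec, "TorsionSpec")) stop("spec must be a TorsionSpec")
  idx <- vapply(spec$atoms, function(sel) .resolve_selector(s, sel),
                integer(1))
  if (length(unique(idx)) != 4L) stop("torsion selectors resolve to fewer ",
                                      "than four distinct atoms")
  xyz <- coords(s)
  dihedral(xyz[idx[1], ], xyz[idx[2], ], xyz[idx[3], ], xyz[idx[4], ])
}

#' Assign an axial-chirality label from a torsion
#'
#' @param torsion degrees, from [measure_torsion()].
#' @param spec a [TorsionSpec()] supplying the near-planar window.
#' @param convention `"positive_is_Sa"` (default) or `"positive_is_Ra"`:
#'   which label the positive twist sense maps to.
#' @return `"Ra"`, `"Sa"`, or `"undefined"` for near-planar torsions.
#' @export
assign_axial <- function(torsion, spec = TorsionSpec(rep(list(list()), 4)),
                         convention = c("positive_is_Sa",
                                        "positive_is_Ra")) {
  convention <- match.arg(convention)
  w <- spec$near_planar_window
  aabs <- abs(torsion)
  if (aabs < w || aabs > 180 - w) return("undefined")
  pos <- torsion > 0
  if (convention == "positive_is_Sa") {
    if (pos) "Sa" else "Ra"
  } else {
    if (pos) "Ra" else "Sa"
  }
}

#' Axial-chirality docking record
#'
#' One record per (compound, target, input configuration): the configuration
#' fed into docking and the configuration observed in the retained pose.
#'
#' @param compound,target identifiers.
#' @param input_label `"Ra"` or `"Sa"`.
#' @param output_label `"Ra"`, `"Sa"` or `"undefined"`.
#' @param torsion measured dihedral, degrees (optional).
#' @return an object of class `AxialRecord`.
#' @export
AxialRecord <- function(compound, target, input_label, output_label,
                        torsion = NA_real_) {
  input_label <- match.arg(input_label, c("Ra", "Sa"))
  output_label <- match.arg(output_label, c("Ra", "Sa", "undefined"))
  structure(list(compound = compound, target = target,
                 input_label = input_label, output_label = output_label,
                 torsion = torsion), class = "AxialRecord")
}

#' Enantiopreference verdict for one (compound, target)
#'
#' Given the two records for input Ra and input Sa: when both retained poses
#' carry the same configuration, that configuration is the binding
#' preference; when they differ, the target accepts both and there is no
#' preference; an undefined output yields no preference, with a warning.
#'
#' @param records list of exactly two [AxialRecord()]s for the same
#'   (compound, target), one per input label.
#' @return `"Ra"`, `"Sa"`, or `"none"`.
#' @export
enantio_preference <- function(records) {
  if (length(records) != 2L)
    stop("need exactly two records (input Ra and input Sa)")
  inputs <- vapply(records, `[[`, character(1), "input_label")
  if (!setequal(inputs, c("Ra", "Sa")))
    stop("records must carry one input Ra and one input Sa; got ",
         paste(inputs, collapse = ", "))
  keys <- unique(vapply(records, function(r)
    paste(r$compound, r$target), character(1)))
  if (length(keys) != 1L)
    stop("records belong to different (compound, target) pairs")
  outs <- vapply(records, `[[`, character(1), "output_label")
  if (any(outs == "undefined")) {
    warning("undefined output configuration for ", keys,
            "; no preference assigned")
    return("none")
  }
  if (outs[1] == outs[2]) outs[1] else "none"
}

#' Enantiopreference table from a label data.frame
#'
#' Convenience wrapper applying [enantio_preference()] across a table with
#' columns `compound`, `target`, `input`, `output`.
#'
#' @param df data.frame of input/output configuration labels.
#' @return data.frame with one row per (compound, target) and a `preference`
#'   column.
#' @export
enantio_preference_table <- function(df) {
  need <- c("compound", "target", "input", "output")
  if (!all(need %in% names(df)))
    stop("label table must have columns ", paste(need, collapse = ", "))
  groups <- unique(df[, c("compound", "target")])
  groups$preference <- vapply(seq_len(nrow(groups)), function(i) {
    sub <- df[df$compound == groups$compound[i] &
                df$target == groups$target[i], , drop = FALSE]
    recs <- lapply(seq_len(nrow(sub)), function(j)
      AxialRecord(sub$compound[j], sub$target[j], sub$input[j],
                  sub$output[j]))
    enantio_preference(recs)
  }, character(1))
  rownames(groups) <- NULL
  groups
}

#' Mirror a structure through the xy-plane
#'
#' Utility for chirality checks: reflection flips the sign of every torsion
#' and hence every axial label.
#' @param s a `Structure`.
#' @return the reflected `Structure`.
#' @export
mirror_structure <- function(s) {
  s$atoms$z <- -s$atoms$z
  s
}
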