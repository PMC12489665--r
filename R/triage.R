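#' @title Screening triage: deciles, dual profiles, rule-of-five, rankings
#'
#' @description Post-docking triage of a screened compound library: keep the
#' best-scoring decile per target, keep compounds with favourable scores
#' against both targets (candidate dual inhibitors), count Lipinski
#' rule-of-five violations, and rank configurations by computed binding
#' affinity. Docking scores and binding energies are kcal/mol; lower
#' (more negative) is better throughout.
#' @name triage
NULL

#' Top-decile selection by docking score
#'
#' Keeps the `floor(fraction * n)` records with the lowest scores for the
#' given target; boundary ties are broken by compound id so the selection is
#' deterministic.
#'
#' @param records data.frame with columns `id` and `score_<target>`.
#' @param target target column suffix, e.g. `"pi3ka"` or `"mtor"`.
#' @param fraction selected fraction (default 0.10).
#' @return the selected rows, ordered by score then id.
#' @export
top_decile <- function(records, target, fraction = 0.10) {
  if (nrow(records) == 0L) stop("empty library")
  col <- paste0("score_", target)
  if (!col %in% names(records)) stop("no score column ", col)
  if (anyNA(records[[col]]))
    stop("all records must be scored for target ", target)
  k <- floor(fraction * nrow(records))
  ord <- order(records[[col]], records$id)
  out <- records[ord[seq_len(k)], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Dual-inhibition profile filter
#'
#' Keeps records favourable against both targets under the configured rule:
#' `both_top_decile` (within the lowest-score decile of each target) or
#' `both_below_cutoff` (score below `cutoff` kcal/mol for each target).
#'
#' @param records data.frame with `id`, `score_pi3ka`, `score_mtor`.
#' @param rule `"both_top_decile"` or `"both_below_cutoff"`.
#' @param fraction decile fraction for `both_top_decile`.
#' @param cutoff kcal/mol for `both_below_cutoff`.
#' @param targets the two score-column suffixes.
#' @return the selected rows (original order).
#' @export
dual_profile <- function(records, rule = c("both_top_decile",
                                           "both_below_cutoff"),
                         fraction = 0.10, cutoff = -8.0,
                         targets = c("pi3ka", "mtor")) {
  rule <- match.arg(rule)
  cols <- paste0("score_", targets)
  if (!all(cols %in% names(records)))
    stop("need score columns ", paste(cols, collapse = ", "))
  if (anyNA(records[cols]))
    stop("scores for both targets must be present")
  keep <- if (rule == "both_top_decile") {
    ids1 <- top_decile(records, targets[1], fraction)$id
    ids2 <- top_decile(records, targets[2], fraction)$id
    records$id %in% intersect(ids1, ids2)
  } else {
    records[[cols[1]]] < cutoff & records[[cols[2]]] < cutoff
  }
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Lipinski rule-of-five violation count
#'
#' Counts breaches of the classic thresholds (MW <= 500 g/mol, logP <= 5,
#' H-bond donors <= 5, H-bond acceptors <= 10). The `swissadme` variant
#' replaces the logP rule with Moriguchi MLOGP <= 4.15, the rule that panel
#' applies.
#'
#' @param descriptors list or one-row data.frame with `MW`, `logP`, `HBD`,
#'   `HBA`.
#' @param variant `"classic"` or `"swissadme"`.
#' @param thresholds optional named overrides (`MW`, `logP`, `HBD`, `HBA`).
#' @return list with `count` and `violated` (rule names).
#' @export
ro5_violations <- function(descriptors, variant = c("classic", "swissadme"),
                           thresholds = NULL) {
  variant <- match.arg(variant)
  need <- c("MW", "logP", "HBD", "HBA")
  for (nm in need)
    if (is.null(descriptors[[nm]]) || is.na(descriptors[[nm]]))
      stop("missing descriptor: ", nm)
  th <- list(MW = 500, logP = if (variant == "classic") 5 else 4.15,
             HBD = 5, HBA = 10)
  if (!is.null(thresholds)) th[names(thresholds)] <- thresholds
  violated <- character(0)
  if (descriptors$MW > th$MW) violated <- c(violated, "MW")
  if (descriptors$logP > th$logP) violated <- c(violated, "logP")
  if (descriptors$HBD > th$HBD) violated <- c(violated, "HBD")
  if (descriptors$HBA > th$HBA) violated <- c(violated, "HBA")
  list(count = length(violated), violated = violated)
}

# ---------------------------------------------------------------------------
# Descriptor adapter

.sdf_graph <- function(smiles) {
  if (!requireNamespace("ChemmineR", quietly = TRUE))
    stop("ChemmineR is required to compute descriptors from SMILES")
  sdf <- ChemmineR::smiles2sdf(smiles)[[1]]
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elements <- toupper(gsub("[_0-9]+$", "", rownames(ab)))
  bonds <- data.frame(i = as.integer(bb[, 1]), j = as.integer(bb[, 2]),
                      order = as.integer(bb[, 3]))
  list(elements = elements, bonds = bonds, sdf = sdf)
}

#' Moriguchi MLOGP estimate from SMILES
#'
#' Implements the core terms of the Moriguchi topological logP regression:
#' weighted carbon/halogen count (CX), nitrogen/oxygen count (NO), the N/O
#' proximity correction (PRX, pairs at graph distance 1 or 2), unsaturated
#' bond count (UB), polar aromatic substituents (POL), a ring-presence dummy
#' and an intramolecular H-bond dummy. Corrections for quaternary nitrogen,
#' nitro/isothiocyanate groups, amphoteric and beta-lactam structures are
#' omitted; the estimator is intended for neutral polyphenols and similar
#' natural products, where those terms vanish.
#'
#' @param smiles a SMILES string.
#' @return estimated logP (unitless).
#' @export
mlogp <- function(smiles) {
  g <- .sdf_graph(smiles)
  el <- g$elements
  halo_w <- c(F = 0.5, CL = 1.0, BR = 1.5, I = 2.0)
  cx <- sum(el == "C") + sum(halo_w[el[el %in% names(halo_w)]])
  no <- sum(el %in% c("N", "O"))
  ub <- sum(g$bonds$order >= 2)
  n_atoms_g <- length(el)
  # adjacency over heavy atoms (smiles2sdf yields a hydrogen-suppressed graph)
  adj <- matrix(FALSE, n_atoms_g, n_atoms_g)
  adj[cbind(g$bonds$i, g$bonds$j)] <- TRUE
  adj[cbind(g$bonds$j, g$bonds$i)] <- TRUE
  # PRX: N/O pairs at topological distance 1 (weight 2) or 2 (weight 1)
  nos <- which(el %in% c("N", "O"))
  prx <- 0
  if (length(nos) > 1) {
    for (a in seq_along(nos)) for (b in seq_along(nos)) {
      if (b <= a) next
      i <- nos[a]; j <- nos[b]
      if (adj[i, j]) prx <- prx + 2
      else if (any(adj[i, ] & adj[j, ])) prx <- prx + 1
    }
  }
  # ring detection via cycle rank; aromatic carbons = ring atoms in
  # conjugated six-membered systems are approximated by ring membership
  n_bonds <- nrow(g$bonds)
  rng <- as.numeric(n_bonds - n_atoms_g + 1 > 0)
  # POL: N/O substituents attached to ring carbons that carry unsaturation
  ring_c <- which(el == "C" &
                    vapply(seq_len(n_atoms_g), function(i)
                      sum(adj[i, ]) >= 2, logical(1)))
  unsat <- unique(c(g$bonds$i[g$bonds$order >= 2],
                    g$bonds$j[g$bonds$order >= 2]))
  arom_c <- intersect(ring_c, unsat)
  pol <- sum(vapply(nos, function(i) any(adj[i, arom_c]), logical(1)))
  # intramolecular H-bond dummy: an O/N bearing H adjacent (distance 2-3)
  # to a carbonyl oxygen; detected as any O-C(=O) with an O/N two bonds away
  hb <- 0
  carbonyl_c <- unique(g$bonds$i[g$bonds$order == 2 &
                                   el[g$bonds$j] == "O"])
  carbonyl_c <- c(carbonyl_c,
                  unique(g$bonds$j[g$bonds$order == 2 &
                                     el[g$bonds$i] == "O"]))
  for (cc in carbonyl_c) {
    near <- which(adj[cc, ])
    second <- unique(unlist(lapply(near, function(k) which(adj[k, ]))))
    if (any(el[setdiff(second, cc)] %in% c("O", "N"))) { hb <- 1; break }
  }
  -1.014 + 1.244 * cx^0.6 - 1.017 * no^0.9 + 0.406 * prx -
    0.145 * ub^0.8 + 0.511 * hb + 0.268 * pol - 0.392 * rng
}

#' Compute Lipinski descriptors from a SMILES string
#'
#' Molecular weight, H-bond donor and acceptor counts are exact and come
#' from the cheminformatics toolkit (Open Babel via ChemmineR/ChemmineOB;
#' HBA is the Lipinski N+O count). logP depends on the estimator:
#' `"mlogp"` (default) is the Moriguchi topological estimate used by
#' SwissADME-style rule-of-five panels; `"wildman_crippen"` is the
#' atom-contribution estimate reported by Open Babel. The two can differ by
#' more than a log unit on polyphenols, which can flip the logP rule.
#'
#' @param smiles a SMILES string.
#' @param logp_method `"mlogp"` or `"wildman_crippen"`.
#' @return list with `MW`, `logP`, `HBD`, `HBA`, `formula`, `logp_method`.
#' @export
compound_descriptors <- function(smiles,
                                 logp_method = c("mlogp",
                                                 "wildman_crippen")) {
  logp_method <- match.arg(logp_method)
  if (!requireNamespace("ChemmineR", quietly = TRUE))
    stop("ChemmineR is required to compute descriptors from SMILES")
  props <- ChemmineR::propOB(ChemmineR::smiles2sdf(smiles))
  lp <- if (logp_method == "mlogp") mlogp(smiles) else props$logP[1]
  list(MW = props$MW[1], logP = lp, HBD = props$HBD[1],
       HBA = props$HBA2[1], formula = props$formula[1],
       logp_method = logp_method)
}

#' SMILES of amentoflavone
#'
#' Hand-encoded connectivity of amentoflavone (3',8''-biapigenin,
#' C30H18O10), the parent biflavonoid of the screened series. Axial
#' chirality is not encoded; this is the constitutional structure only.
#'
#' @return named character vector of SMILES.
#' @export
biflavonoid_smiles <- function() {
  c(amentoflavone = paste0(
    "Oc1ccc(cc1-c1c(O)cc(O)c2c1oc(cc2=O)-c1ccc(O)cc1)",
    "-c1cc(=O)c2c(O)cc(O)cc2o1"))
}

# ---------------------------------------------------------------------------
# Affinity tables (computed binding energies per configuration)

#' Affinity table of configurations versus targets
#'
#' Rows are ligand configurations (e.g. `"(Ra)-3"`); the two energy columns
#' are computed binding energies (kcal/mol), `NA` where the configuration
#' was not retained for that target. Named reference inhibitors are carried
#' in the same table with `is_reference = TRUE`.
#'
#' @param df data.frame with columns `id`, `pi3ka`, `mtor`, and optionally
#'   `is_reference`.
#' @return an object of class `AffinityTable`.
#' @export
AffinityTable <- function(df) {
  need <- c("id", "pi3ka", "mtor")
  if (!all(need %in% names(df)))
    stop("affinity table needs columns ", paste(need, collapse = ", "))
  if (is.null(df$is_reference)) df$is_reference <- FALSE
  if (any(is.na(df$pi3ka) & is.na(df$mtor)))
    stop("every row needs at least one energy")
  rownames(df) <- NULL
  structure(df, class = c("AffinityTable", "data.frame"))
}

#' Rank configurations by binding affinity for one target
#'
#' Ascending by energy (most negative = strongest binder first); rows
#' without an energy for the target are excluded; ties break by id.
#'
#' @param tab an [AffinityTable()].
#' @param target `"pi3ka"` or `"mtor"`.
#' @param include_references include reference inhibitors (default FALSE).
#' @return character vector of configuration ids, strongest first.
#' @export
rank_affinities <- function(tab, target = c("pi3ka", "mtor"),
                            include_references = FALSE) {
  target <- match.arg(target)
  df <- as.data.frame(tab)
  if (!include_references) df <- df[!df$is_reference, , drop = FALSE]
  df <- df[!is.na(df[[target]]), , drop = FALSE]
  if (nrow(df) == 0L) stop("no rows carry an energy for ", target)
  df$id[order(df[[target]], df$id)]
}

#' Dual-inhibitor classification from an affinity table
#'
#' Configurations whose row carries computed energies for both targets.
#'
#' @param tab an [AffinityTable()].
#' @param include_references include reference inhibitors (default FALSE).
#' @return character vector of configuration ids (table order).
#' @export
dual_classification <- function(tab, include_references = FALSE) {
  df <- as.data.frame(tab)
  if (!include_references) df <- df[!df$is_reference, , drop = FALSE]
  df$id[!is.na(df$pi3ka) & !is.na(df$mtor)]
}

#' Count distinct dual-target molecules
#'
#' Compound-level rule: configuration ids like `"(Sa)-2"` are collapsed to
#' their parent compound (`"2"`), and a compound counts as dual-target when
#' it carries an energy against each target through *some* configuration -
#' not necessarily the same one. A compound whose Ra form binds one kinase
#' and whose Sa form binds the other is dual at the molecule level even
#' though neither configuration is dual on its own.
#'
#' @param tab an [AffinityTable()].
#' @return integer count of distinct molecules.
#' @export
dual_molecule_count <- function(tab) {
  df <- as.data.frame(tab)
  df <- df[!df$is_reference, , drop = FALSE]
  cpd <- sub("^\\((Ra|Sa)\\)-", "", df$id)
  hits1 <- unique(cpd[!is.na(df$pi3ka)])
  hits2 <- unique(cpd[!is.na(df$mtor)])
  length(intersect(hits1, hits2))
}

#' Read an affinity table from delimited text
#'
#' Columns `id`, `pi3ka`, `mtor`, optional `is_reference`; empty cells are
#' `NA`.
#' @param path input path.
#' @return an [AffinityTable()].
#' @export
read_affinity_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, na.strings = c("NA", ""))
  AffinityTable(df)
}

#' Write a triage report bundle
#'
#' Emits delimited-text tables into a directory: the per-target energy
#' table with references (`affinities.tsv`), the axial input/output/
#' preference table (`axial.tsv`, when given), and a convergence-radius
#' summary (`convergence.tsv`, when given). Id mismatches between inputs
#' are reported in the returned object, not raised.
#'
#' @param tab an [AffinityTable()].
#' @param out_dir output directory (created if needed).
#' @param axial optional data.frame from [enantio_preference_table()].
#' @param profiles optional named list of `RadialProfile`s keyed by
#'   configuration id.
#' @return invisibly, list with written `paths` and `id_mismatches`.
#' @export
report_bundle <- function(tab, out_dir, axial = NULL, profiles = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  p <- file.path(out_dir, "affinities.tsv")
  utils::write.table(as.data.frame(tab), p, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- c(paths, p)
  mism <- character(0)
  if (!is.null(axial)) {
    p <- file.path(out_dir, "axial.tsv")
    utils::write.table(axial, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, p)
    known <- unique(sub("^\\((Ra|Sa)\\)-", "", tab$id[!tab$is_reference]))
    mism <- c(mism, setdiff(unique(as.character(axial$compound)), known))
  }
  if (!is.null(profiles)) {
    conv <- data.frame(
      id = names(profiles),
      convergence_radius_A = vapply(profiles, function(x)
        x$convergence_radius, numeric(1)),
      stringsAsFactors = FALSE)
    p <- file.path(out_dir, "convergence.tsv")
    utils::write.table(conv, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, p)
    mism <- c(mism, setdiff(conv$id, tab$id))
  }
  invisible(list(paths = paths, id_mismatches = unique(mism)))
}

#' Read / write a screening library table
#'
#' Delimited text with columns `id`, `name`, `score_pi3ka`, `score_mtor`,
#' `MW`, `logP`, `HBD`, `HBA`.
#' @param records library data.frame.
#' @param path file path.
#' @return invisibly `path` (write); the data.frame (read).
#' @export
write_library <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_library
#' @export
read_library <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
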