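# Shared fixture builders; everything is generated in code.

make_atoms <- function(xyz, element = "C", charge = 0, radius = 1.7,
                       sigma = 3.4, eps = 0.086, chain = "A",
                       resno = NULL, resname = "RES") {
  xyz <- matrix(xyz, ncol = 3)
  n <- nrow(xyz)
  if (is.null(resno)) resno <- rep(1L, n)
  data.frame(serial = seq_len(n),
             name = paste0(rep_len(element, n), seq_len(n)),
             element = rep_len(element, n),
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             charge = rep_len(charge, n),
             lj_sigma = rep_len(sigma, n),
             lj_epsilon = rep_len(eps, n),
             radius = rep_len(radius, n),
             chain = rep_len(chain, n), resno = as.integer(rep_len(resno, n)),
             resname = rep_len(resname, n),
             stringsAsFactors = FALSE)
}

make_structure <- function(xyz, ...) Structure(make_atoms(xyz, ...))

random_structure <- function(n, seed, charged = TRUE, spread = 10) {
  set.seed(seed)
  make_structure(matrix(runif(3 * n, -spread, spread), ncol = 3),
                 charge = if (charged) runif(n, -0.5, 0.5) else 0,
                 resno = rep(seq_len(ceiling(n / 3)), each = 3)[seq_len(n)])
}

random_rotation <- function(seed) {
  set.seed(seed)
  m <- matrix(rnorm(9), 3)
  q <- qr.Q(qr(m))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# printed per-configuration energy table (study input)
study_affinity_table <- function() {
  read_affinity_table(system.file("extdata", "affinity_table.tsv",
                                  package = "atroscreen"))
}

study_axial_labels <- function() {
  utils::read.table(system.file("extdata", "axial_labels.tsv",
                                package = "atroscreen"),
                    header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    colClasses = c(compound = "character"))
}
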