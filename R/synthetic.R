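# Synthetic backbone generator: chains with analytically known phi/psi, used
# for all pretraining/finetuning fixtures so nothing external is required.

# Standard backbone geometry (angstrom / degrees): these reproduce the
# canonical ~3.8 A consecutive Ca-Ca spacing of trans peptide bonds.
DEFAULT_BOND_LENGTHS <- c(n_ca = 1.458, ca_c = 1.525, c_n = 1.329)
DEFAULT_BOND_ANGLES <- c(c_n_ca = 121.7, n_ca_c = 111.2, ca_c_n = 116.2) * pi / 180

#' Backbone specification for the synthetic chain builder
#'
#' Holds the internal coordinates (torsions, bond lengths, bond angles) from
#' which [build_chain()] extends an N/CA/C backbone. Torsions follow the
#' biochemical convention: `phi[i]` is the torsion C(i-1)-N(i)-CA(i)-C(i) (so
#' `phi[1]` is undefined and ignored) and `psi[i]` is N(i)-CA(i)-C(i)-N(i+1)
#' (`psi[L]` ignored). The peptide-bond torsion omega defaults to trans
#' (\eqn{\pi}); cis bonds are rare and not modelled by default.
#'
#' @param n_residues Chain length L, >= 2.
#' @param phi,psi Torsions in radians; scalars are recycled to length L.
#' @param omega Peptide-bond torsion in radians (scalar or length L-1).
#' @param sequence Optional string of length L over the 20-letter alphabet;
#'   default poly-alanine.
#' @param bond_lengths Named numeric: `n_ca`, `ca_c`, `c_n` (angstrom).
#' @param bond_angles Named numeric radians: `c_n_ca`, `n_ca_c`, `ca_c_n`.
#' @return An object of class `backbone_spec`.
#' @export
backbone_spec <- function(n_residues, phi, psi, omega = pi, sequence = NULL,
                          bond_lengths = DEFAULT_BOND_LENGTHS,
                          bond_angles = DEFAULT_BOND_ANGLES) {
  if (!is.numeric(n_residues) || length(n_residues) != 1 || n_residues < 2 ||
      n_residues != round(n_residues)) {
    stop("invalid backbone_spec: n_residues must be an integer >= 2", call. = FALSE)
  }
  L <- as.integer(n_residues)
  phi <- rep_len(as.numeric(phi), L)
  psi <- rep_len(as.numeric(psi), L)
  omega <- rep_len(as.numeric(omega), max(L - 1L, 1L))
  if (is.null(sequence)) sequence <- paste(rep("A", L), collapse = "")
  chars <- strsplit(sequence, "")[[1]]
  if (length(chars) != L) {
    stop("invalid backbone_spec: sequence length must equal n_residues", call. = FALSE)
  }
  if (!all(chars %in% AA20)) {
    stop("invalid backbone_spec: sequence must use the 20-letter amino-acid alphabet", call. = FALSE)
  }
  bl <- bond_lengths[c("n_ca", "ca_c", "c_n")]
  if (anyNA(bl) || any(bl <= 0)) {
    stop("invalid backbone_spec: bond_lengths must be positive and named n_ca, ca_c, c_n", call. = FALSE)
  }
  ba <- bond_angles[c("c_n_ca", "n_ca_c", "ca_c_n")]
  if (anyNA(ba) || any(ba <= 0) || any(ba >= pi)) {
    stop("invalid backbone_spec: bond_angles must be in (0, pi) and named c_n_ca, n_ca_c, ca_c_n", call. = FALSE)
  }
  structure(
    list(
      n_residues = L, phi = phi, psi = psi, omega = omega,
      sequence = sequence, bond_lengths = bl, bond_angles = ba
    ),
    class = "backbone_spec"
  )
}

#' Build backbone coordinates from internal coordinates
#'
#' Extends the chain atom by atom (N, CA, C per residue) by the standard
#' natural-extension-of-reference-frame construction, so that recomputing
#' torsions from the placed coordinates returns the spec's interior phi/psi
#' exactly (terminal `phi[1]` and `psi[L]` are geometrically undefined).
#'
#' @param spec A [backbone_spec()].
#' @return A [protein_structure()].
#' @export
build_chain <- function(spec) {
  if (!inherits(spec, "backbone_spec")) spec <- do.call(backbone_spec, spec)
  L <- spec$n_residues
  bl <- spec$bond_lengths
  ba <- spec$bond_angles
  N <- CA <- C <- matrix(NA_real_, L, 3)
  # first residue in the xy-plane
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(bl[["n_ca"]], 0, 0)
  tau <- ba[["n_ca_c"]]
  C[1, ] <- CA[1, ] + bl[["ca_c"]] * c(-cos(tau), sin(tau), 0)
  for (i in seq_len(L - 1L) + 1L) {
    N[i, ] <- place_atom(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
      r = bl[["c_n"]], theta = ba[["ca_c_n"]], chi = spec$psi[i - 1]
    )
    CA[i, ] <- place_atom(CA[i - 1, ], C[i - 1, ], N[i, ],
      r = bl[["n_ca"]], theta = ba[["c_n_ca"]], chi = spec$omega[i - 1]
    )
    C[i, ] <- place_atom(C[i - 1, ], N[i, ], CA[i, ],
      r = bl[["ca_c"]], theta = ba[["n_ca_c"]], chi = spec$phi[i]
    )
  }
  protein_structure(spec$sequence, N, CA, C)
}

HELIX_PHI <- -57 * pi / 180
HELIX_PSI <- -47 * pi / 180
STRAND_PHI <- -120 * pi / 180
STRAND_PSI <- 120 * pi / 180

random_sequence <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")

#' Ideal secondary-structure and random-coil generators
#'
#' `make_ideal_helix()` builds an alpha-helix (phi = -57 deg, psi = -47 deg),
#' `make_ideal_strand()` an extended beta-strand (phi = -120 deg,
#' psi = +120 deg), and `make_random_coil()` a chain whose phi/psi are drawn
#' uniformly from \eqn{(-\pi, \pi]}. Sequences are drawn uniformly over the 20
#' amino acids. All three are deterministic functions of `(n, seed)`.
#'
#' @param n Number of residues, >= 3.
#' @param seed Integer RNG seed.
#' @return A [protein_structure()] with attribute `generator`.
#' @export
make_ideal_helix <- function(n, seed = 0L) {
  make_regular(n, seed, HELIX_PHI, HELIX_PSI, "helix")
}

#' @rdname make_ideal_helix
#' @export
make_ideal_strand <- function(n, seed = 0L) {
  make_regular(n, seed, STRAND_PHI, STRAND_PSI, "strand")
}

#' @rdname make_ideal_helix
#' @export
make_random_coil <- function(n, seed = 0L) {
  if (!is.numeric(n) || length(n) != 1 || n < 3) {
    stop("make_random_coil: n must be >= 3", call. = FALSE)
  }
  with_seed(seed, {
    phi <- runif(n, -pi, pi)
    psi <- runif(n, -pi, pi)
    s <- build_chain(backbone_spec(n, phi = phi, psi = psi, sequence = random_sequence(n)))
    attr(s, "generator") <- "coil"
    s
  })
}

make_regular <- function(n, seed, phi, psi, label) {
  if (!is.numeric(n) || length(n) != 1 || n < 3) {
    stop(sprintf("make_ideal_%s: n must be >= 3", label), call. = FALSE)
  }
  with_seed(seed, {
    s <- build_chain(backbone_spec(n, phi = phi, psi = psi, sequence = random_sequence(n)))
    attr(s, "generator") <- label
    s
  })
}

#' Labelled toy dataset of synthetic backbones
#'
#' Generates a balanced mixture of helix / strand / coil chains with uniform
#' random lengths. When `class_count >= 2` the label of each protein is the
#' index of its generator type (0 = helix, 1 = strand, 2 = coil), so a
#' structure-aware model can separate the classes from geometry alone.
#'
#' @param n_proteins Number of proteins, >= 1.
#' @param length_range Integer pair `c(min, max)` of residue counts.
#' @param class_count Number of generator types used (1 to 3).
#' @param seed Integer RNG seed.
#' @return A list of class `steps_dataset` with elements `structures` (list of
#'   [protein_structure()]), `labels` (integers in `[0, class_count)`) and
#'   `ids` (character).
#' @export
make_toy_dataset <- function(n_proteins, length_range = c(20L, 40L),
                             class_count = 2L, seed = 0L) {
  if (!is.numeric(n_proteins) || n_proteins < 1) {
    stop("make_toy_dataset: n_proteins must be >= 1", call. = FALSE)
  }
  gens <- list(make_ideal_helix, make_ideal_strand, make_random_coil)
  if (class_count < 1 || class_count > length(gens)) {
    stop("make_toy_dataset: class_count must be between 1 and 3 (helix/strand/coil)", call. = FALSE)
  }
  n_proteins <- as.integer(n_proteins)
  with_seed(seed, {
    span <- length_range[2] - length_range[1] + 1L
    lens <- length_range[1] + sample.int(span, n_proteins, replace = TRUE) - 1L
    # round-robin class assignment in a shuffled order keeps labels balanced
    cls <- (seq_len(n_proteins) - 1L) %% as.integer(class_count)
    cls <- cls[sample.int(n_proteins)]
    sub_seeds <- sample.int(2^30, n_proteins)
    structures <- vector("list", n_proteins)
    ids <- sprintf("synth_%04d", seq_len(n_proteins))
    for (i in seq_len(n_proteins)) {
      s <- gens[[cls[i] + 1L]](lens[i], seed = sub_seeds[i])
      s$id <- ids[i]
      structures[[i]] <- s
    }
    structure(
      list(structures = structures, labels = as.integer(cls), ids = ids),
      class = "steps_dataset"
    )
  })
}

#' @export
print.steps_dataset <- function(x, ...) {
  cat(sprintf(
    "<steps_dataset> %d proteins, %d class(es)\n",
    length(x$structures), length(unique(x$labels))
  ))
  invisible(x)
}

#' Write a backbone structure as a minimal PDB file
#'
#' Emits a single-model, single-chain PDB with ATOM records for N, CA and C
#' only (occupancy 1.00, B-factor 0.00), the minimal dialect any PDB reader
#' accepts. Coordinates are written at the format's 1e-3 angstrom precision.
#'
#' @param s A [protein_structure()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(s, path) {
  chars <- seq_chars(s)
  res3 <- ifelse(chars == "X", "UNK", bio3d::aa123(chars))
  L <- n_residues(s)
  lines <- character(3L * L)
  serial <- 0L
  # residue numbering restarts +1 after a chain break so a reader sees the gap
  resno <- seq_len(L)
  for (b in s$chain_break_after) {
    resno[(b + 1L):L] <- resno[(b + 1L):L] + 1L
  }
  atom_names <- c(" N  ", " CA ", " C  ")
  elements <- c("N", "C", "C")
  coords <- list(s$coords_N, s$coords_CA, s$coords_C)
  for (i in seq_len(L)) {
    for (k in 1:3) {
      serial <- serial + 1L
      lines[serial] <- sprintf(
        "ATOM  %5d %4s %3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial, atom_names[k], res3[i], resno[i],
        coords[[k]][i, 1], coords[[k]][i, 2], coords[[k]][i, 3],
        1.0, 0.0, elements[k]
      )
    }
  }
  writeLines(c(lines, "TER", "END"), path)
  invisible(path)
}
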