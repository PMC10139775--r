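# PDB backbone parsing and residue-graph construction.

#' Read backbone structures from a PDB file
#'
#' Parses the first model of a PDB file (via [bio3d::read.pdb()]) and returns
#' one [protein_structure()] per chain, in chain order. Only N, CA and C
#' records are used; alternate locations resolve to altLoc `' '` or `'A'`.
#' Residues lacking any of the three backbone atoms are dropped and a chain
#' break is recorded before the next kept residue; a break is also recorded at
#' gaps in residue numbering.
#'
#' @param path Path to a PDB file.
#' @return List of [protein_structure()], one per chain with at least two
#'   complete residues.
#' @export
read_pdb_backbone <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read PDB file: %s", path), call. = FALSE)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)),
    error = function(e) stop(sprintf("unreadable PDB file %s: %s", path, conditionMessage(e)), call. = FALSE)
  )
  atoms <- pdb$atom
  atoms <- atoms[atoms$type == "ATOM" & atoms$elety %in% c("N", "CA", "C"), , drop = FALSE]
  atoms <- atoms[is.na(atoms$alt) | atoms$alt %in% c("", " ", "A"), , drop = FALSE]
  if (nrow(atoms) == 0) stop(sprintf("no backbone ATOM records in %s", path), call. = FALSE)
  out <- list()
  for (ch in unique(atoms$chain)) {
    a <- atoms[atoms$chain %in% ch, , drop = FALSE]
    # residue key preserving file order
    key <- paste(a$resno, a$insert)
    resnos <- a$resno[!duplicated(key)]
    keys <- key[!duplicated(key)]
    kept_seq <- character(0)
    kept_resno <- integer(0)
    N <- CA <- C <- NULL
    dropped_before <- logical(0) # was a residue dropped just before this kept one
    pending_drop <- FALSE
    for (ki in seq_along(keys)) {
      rows <- a[key == keys[ki], , drop = FALSE]
      rows <- rows[!duplicated(rows$elety), , drop = FALSE]
      if (all(c("N", "CA", "C") %in% rows$elety)) {
        get_xyz <- function(el) {
          r <- rows[rows$elety == el, , drop = FALSE]
          c(r$x[1], r$y[1], r$z[1])
        }
        N <- rbind(N, get_xyz("N"))
        CA <- rbind(CA, get_xyz("CA"))
        C <- rbind(C, get_xyz("C"))
        aa <- bio3d::aa321(rows$resid[1])
        if (is.na(aa) || !aa %in% AA20) aa <- "X"
        kept_seq <- c(kept_seq, aa)
        kept_resno <- c(kept_resno, resnos[ki])
        dropped_before <- c(dropped_before, pending_drop)
        pending_drop <- FALSE
      } else {
        pending_drop <- TRUE
      }
    }
    Lk <- length(kept_seq)
    if (Lk == 0) stop(sprintf("chain %s in %s has no complete N/CA/C residues", ch, path), call. = FALSE)
    if (Lk < 2) next
    breaks <- integer(0)
    if (Lk > 1) {
      gap <- diff(kept_resno) != 1L
      brk <- gap | dropped_before[-1]
      breaks <- which(brk)
    }
    rownames(N) <- rownames(CA) <- rownames(C) <- NULL
    out[[length(out) + 1L]] <- protein_structure(
      paste(kept_seq, collapse = ""), N, CA, C,
      chain_break_after = breaks,
      id = paste0(basename(path), "_", ch)
    )
  }
  if (length(out) == 0) stop(sprintf("no chain with >= 2 complete residues in %s", path), call. = FALSE)
  out
}

#' Backbone phi/psi dihedrals of a structure
#'
#' phi_i is the torsion C(i-1)-N(i)-CA(i)-C(i), psi_i is N(i)-CA(i)-C(i)-N(i+1).
#' Validity flags are FALSE at the termini (phi at residue 1, psi at residue L),
#' across recorded chain breaks, and wherever the torsion is geometrically
#' degenerate (collinear atoms).
#'
#' @param s A [protein_structure()].
#' @return A list of class `dihedral_table` with numeric `phi`, `psi` (radians,
#'   `NA` where invalid) and logical `phi_valid`, `psi_valid`.
#' @export
backbone_dihedrals <- function(s) {
  L <- n_residues(s)
  phi <- psi <- rep(NA_real_, L)
  phi_valid <- psi_valid <- rep(FALSE, L)
  broken_after <- rep(FALSE, L)
  broken_after[s$chain_break_after] <- TRUE
  safe_dihedral <- function(p0, p1, p2, p3) {
    tryCatch(dihedral(p0, p1, p2, p3), error = function(e) NA_real_)
  }
  for (i in seq_len(L)) {
    if (i > 1 && !broken_after[i - 1]) {
      phi[i] <- safe_dihedral(s$coords_C[i - 1, ], s$coords_N[i, ], s$coords_CA[i, ], s$coords_C[i, ])
      phi_valid[i] <- !is.na(phi[i])
    }
    if (i < L && !broken_after[i]) {
      psi[i] <- safe_dihedral(s$coords_N[i, ], s$coords_CA[i, ], s$coords_C[i, ], s$coords_N[i + 1, ])
      psi_valid[i] <- !is.na(psi[i])
    }
  }
  structure(
    list(phi = phi, psi = psi, phi_valid = phi_valid, psi_valid = psi_valid),
    class = "dihedral_table"
  )
}

#' Pairwise C-alpha distance matrix
#'
#' @param s A [protein_structure()].
#' @return Symmetric L x L matrix of Euclidean C-alpha distances (angstrom),
#'   zero diagonal.
#' @export
ca_distance_matrix <- function(s) {
  d <- row_dist(s$coords_CA)
  diag(d) <- 0
  (d + t(d)) / 2 # enforce exact symmetry against floating-point asymmetry
}

#' Uniform distance binning for the distance-classification task
#'
#' Distances are discretized into `T` uniform bins over `[d_min, d_max)`;
#' values below `d_min` fall in bin 0 and values at or above `d_max` in bin
#' `T - 1`, so the top bin absorbs all distal pairs.
#'
#' @param T Number of classes (>= 2); default 30.
#' @param d_min,d_max Bin range in angstrom; defaults 2 and 20.
#' @return An object of class `distance_binning`.
#' @export
distance_binning <- function(T = 30L, d_min = 2.0, d_max = 20.0) {
  if (T < 2) stop("distance_binning: T must be >= 2", call. = FALSE)
  if (d_min >= d_max) stop("distance_binning: d_min must be < d_max", call. = FALSE)
  structure(
    list(T = as.integer(T), d_min = d_min, d_max = d_max, width = (d_max - d_min) / T),
    class = "distance_binning"
  )
}

#' Map distances to bin class indices
#'
#' @param d Numeric vector of distances (angstrom), >= 0.
#' @param b A [distance_binning()].
#' @return Integer class indices in `[0, T)` (0-based).
#' @export
bin_distance <- function(d, b = distance_binning()) {
  if (any(d < 0)) stop("bin_distance: distances must be non-negative", call. = FALSE)
  idx <- floor((d - b$d_min) / b$width)
  pmin(pmax(idx, 0), b$T - 1L)
}

#' Build the residue contact graph
#'
#' Nodes are residues; an unordered pair \{i, j\} is an edge iff the C-alpha
#' distance d_ij is strictly below `threshold`. Each edge carries the weight
#' 1 / d_ij^2 (inverse-square distance), and the per-residue phi/psi table is
#' attached for the node features.
#'
#' @param s A [protein_structure()].
#' @param threshold Contact threshold in angstrom; default 7.
#' @return A list of class `residue_graph` with `n_nodes`, `distance_matrix`,
#'   `edges` (E x 2 integer matrix, i < j, 1-based), `edge_weight`, `adjacency`
#'   (dense weighted L x L matrix), `dihedrals`, `sequence`, `id`.
#' @export
build_residue_graph <- function(s, threshold = 7.0) {
  D <- ca_distance_matrix(s)
  L <- nrow(D)
  off <- D[upper.tri(D)]
  if (any(off == 0)) {
    stop("build_residue_graph: duplicate C-alpha coordinates (d_ij = 0) cannot form 1/d^2 weights", call. = FALSE)
  }
  sel <- which(upper.tri(D) & D < threshold, arr.ind = TRUE)
  edges <- matrix(as.integer(sel), ncol = 2)
  edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  colnames(edges) <- c("i", "j")
  w <- if (nrow(edges)) 1 / D[edges]^2 else numeric(0)
  A <- matrix(0, L, L)
  if (nrow(edges)) {
    A[edges] <- w
    A[edges[, c(2, 1), drop = FALSE]] <- w
  }
  structure(
    list(
      n_nodes = L, distance_matrix = D, edges = edges, edge_weight = w,
      adjacency = A, dihedrals = backbone_dihedrals(s),
      sequence = s$sequence, id = s$id
    ),
    class = "residue_graph"
  )
}

#' @export
print.residue_graph <- function(x, ...) {
  cat(sprintf("<residue_graph> %d nodes, %d edges\n", x$n_nodes, nrow(x$edges)))
  invisible(x)
}

#' Export a residue graph's edge list as TSV
#'
#' Debug helper: writes columns `i`, `j`, `d_ij`, `weight` (1-based indices).
#'
#' @param g A [build_residue_graph()] result.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_edge_tsv <- function(g, path) {
  df <- data.frame(
    i = g$edges[, 1], j = g$edges[, 2],
    d_ij = g$distance_matrix[g$edges], weight = g$edge_weight
  )
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
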