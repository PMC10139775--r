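#' @keywords internal
"_PACKAGE"

# One-letter amino-acid alphabet; 'X' is the unknown-residue catch-all.
AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
AA21 <- c(AA20, "X")

#' Protein backbone structure
#'
#' The raw geometric record used throughout the package: per-residue one-letter
#' amino-acid identities plus backbone N, C-alpha and C coordinates in
#' angstrom. Chain breaks (from missing residues in a parsed file) are stored
#' as the indices after which the chain is discontinuous; dihedrals are never
#' computed across a break.
#'
#' @param sequence Single string of one-letter codes (length L, alphabet
#'   `ACDEFGHIKLMNPQRSTVWY` plus `X`).
#' @param coords_N,coords_CA,coords_C Numeric L x 3 matrices (angstrom).
#' @param chain_break_after Integer vector of residue indices (1-based) after
#'   which the chain is broken; default none.
#' @param id Optional identifier string.
#' @return An object of class `protein_structure`.
#' @export
protein_structure <- function(sequence, coords_N, coords_CA, coords_C,
                              chain_break_after = integer(0), id = NULL) {
  chars <- strsplit(sequence, "")[[1]]
  L <- length(chars)
  if (L < 2) stop("protein_structure: sequence must have length >= 2", call. = FALSE)
  if (!all(chars %in% AA21)) {
    stop("protein_structure: sequence contains characters outside the amino-acid alphabet", call. = FALSE)
  }
  for (nm in c("coords_N", "coords_CA", "coords_C")) {
    m <- get(nm)
    if (!is.matrix(m) || nrow(m) != L || ncol(m) != 3 || !is.numeric(m)) {
      stop(sprintf("protein_structure: %s must be a numeric %d x 3 matrix", nm, L), call. = FALSE)
    }
  }
  structure(
    list(
      sequence = sequence,
      coords_N = coords_N,
      coords_CA = coords_CA,
      coords_C = coords_C,
      chain_break_after = as.integer(sort(unique(chain_break_after))),
      id = id
    ),
    class = "protein_structure"
  )
}

#' @export
print.protein_structure <- function(x, ...) {
  cat(sprintf(
    "<protein_structure> %s: %d residues, %d chain break(s)\n",
    if (is.null(x$id)) "(unnamed)" else x$id,
    n_residues(x), length(x$chain_break_after)
  ))
  invisible(x)
}

#' Number of residues in a structure
#' @param s A `protein_structure`.
#' @return Integer residue count.
#' @export
n_residues <- function(s) nchar(s$sequence)

seq_chars <- function(s) strsplit(s$sequence, "")[[1]]

# Run a block with a temporary RNG state seeded by `seed`, restoring the
# caller's stream afterwards. All stochastic operations in the package route
# through this so results are pure functions of (arguments, seed).
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}
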