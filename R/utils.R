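# Shared low-level helpers: DNA alphabet handling, reverse complement,
# IUPAC matching and seeded RNG scoping.

DNA_BASES <- c("A", "C", "G", "T")

# IUPAC code -> set of concrete bases it matches. 'N' in the *genome* is
# deliberately absent everywhere: an ambiguous reference base never matches a
# guide base (conservative).
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

#' Reverse complement of DNA strings
#'
#' Thin character-vector wrapper around [Biostrings::reverseComplement()].
#'
#' @param x Character vector of DNA strings (A/C/G/T/N and IUPAC codes).
#' @return Character vector of the same length.
#' @keywords internal
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Random DNA string(s); relies on the caller having seeded the RNG.
random_dna <- function(n) {
  if (n == 0L) return("")
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# Evaluate `expr` under set.seed(seed) without clobbering the caller's RNG
# state. All user-facing stochastic operations funnel through this.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Per-position Hamming distance between two equal-length strings (raw bytes).
hamming <- function(a, b) {
  ra <- charToRaw(a)
  rb <- charToRaw(b)
  stopifnot(length(ra) == length(rb))
  sum(ra != rb)
}

# Expand an IUPAC motif (e.g. "NGG") into a list of allowed base sets,
# one per motif position.
iupac_expand <- function(motif) {
  letters <- strsplit(toupper(motif), "")[[1]]
  bad <- setdiff(letters, names(IUPAC_SETS))
  if (length(bad) > 0L)
    stop("invalid IUPAC code(s) in motif '", motif, "': ",
         paste(bad, collapse = ", "))
  lapply(letters, function(l) IUPAC_SETS[[l]])
}

# Does each 3-mer (character matrix rows: positions) match the motif?
# `chars` is a list of character vectors, one per motif position, all the
# same length n; returns logical(n).
iupac_match_positions <- function(chars, motif_sets) {
  stopifnot(length(chars) == length(motif_sets))
  ok <- rep(TRUE, length(chars[[1]]))
  for (i in seq_along(motif_sets)) {
    ok <- ok & chars[[i]] %in% motif_sets[[i]]
  }
  ok
}

`%||%` <- function(a, b) if (is.null(a)) b else a
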