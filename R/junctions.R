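# SV junction characterisation: imperfect microhomology at rearrangement
# breakpoints (the MMEJ signature) and telomere-capped chromosome
# truncations.

# Derive junction orientation from a breakend variant-call row.
junction_from_call <- function(call) {
  alt <- call$alt
  if (!grepl("\\[|\\]", alt)) stop("not a paired breakend ALT: ", alt)
  loc <- sub("^.*[][]([^]:[]+:[0-9]+)[][].*$", "\\1", alt)
  if (grepl("^[ACGTN]", alt)) {
    list(chrom_a = call$chrom, pos_a = call$pos, orient_a = "right-open",
         chrom_b = sub(":.*$", "", loc),
         pos_b = as.integer(sub("^.*:", "", loc)), orient_b = "left-open",
         junction_id = call$variant_id)
  } else {
    list(chrom_a = call$chrom, pos_a = call$pos, orient_a = "left-open",
         chrom_b = sub(":.*$", "", loc),
         pos_b = as.integer(sub("^.*:", "", loc)), orient_b = "right-open",
         junction_id = call$variant_id)
  }
}

#' Detect microhomology at an SV junction
#'
#' Reports the longest window length `L <= max_window` for which the `L`
#' reference bases ending the retained flank of breakend A agree, with at
#' most `max_mismatches` mismatches, with the corresponding `L` bases on the
#' lost side of breakend B -- the stretch an MMEJ repair event would have
#' annealed. Imperfect homology (e.g. 5 bp with two mismatches) is the
#' expected signature.
#'
#' @param junction A breakend variant-call row, or a list with `chrom_a`,
#'   `pos_a`, `orient_a`, `chrom_b`, `pos_b`, `orient_b`
#'   (orientations `"right-open"`/`"left-open"`).
#' @param genome Reference [AnnotatedGenome] (flanks are read from it).
#' @param max_window Longest homology window searched (nt).
#' @param max_mismatches Allowed mismatches inside the window.
#' @return List: `junction_id`, `mh_length`, `mh_mismatches`,
#'   `mh_sequence_a`, `mh_sequence_b`, `clipped` (window shortened at a
#'   chromosome end). `mh_length` 0 means no window qualified.
#' @export
detect_microhomology <- function(junction, genome, max_window = 25L,
                                 max_mismatches = 2L) {
  j <- if (is.data.frame(junction)) junction_from_call(junction) else junction
  sa <- chrom_seq(genome, j$chrom_a)
  sb <- chrom_seq(genome, j$chrom_b)

  flank_a <- function(L) {
    if (j$orient_a == "right-open") substr(sa, j$pos_a - L + 1L, j$pos_a)
    else substr(sa, j$pos_a, j$pos_a + L - 1L)
  }
  flank_b <- function(L) {
    if (j$orient_b == "left-open") substr(sb, j$pos_b - L, j$pos_b - 1L)
    else substr(sb, j$pos_b + 1L, j$pos_b + L)
  }
  max_a <- if (j$orient_a == "right-open") j$pos_a else
    nchar(sa) - j$pos_a + 1L
  max_b <- if (j$orient_b == "left-open") j$pos_b - 1L else
    nchar(sb) - j$pos_b
  lim <- min(max_window, max_a, max_b)
  clipped <- lim < max_window

  for (L in rev(seq_len(lim))) {
    a <- flank_a(L); b <- flank_b(L)
    d <- hamming(a, b)
    if (d <= max_mismatches)
      return(list(junction_id = j$junction_id %||% NA_character_,
                  mh_length = L, mh_mismatches = d,
                  mh_sequence_a = a, mh_sequence_b = b, clipped = clipped))
  }
  list(junction_id = j$junction_id %||% NA_character_, mh_length = 0L,
       mh_mismatches = 0L, mh_sequence_a = "", mh_sequence_b = "",
       clipped = clipped)
}

#' Plant an imperfect microhomology into a genome
#'
#' Overwrites the lost-side flank of breakend B so that it matches the
#' retained flank of breakend A at exactly `mh_length` bases with exactly
#' `mismatches` internal mismatches, and forces disagreement immediately
#' beyond the window so the planted length is recovered exactly. Used to
#' construct ground truth for junction-analysis tests.
#'
#' @param genome An [AnnotatedGenome].
#' @param chrom_a,pos_a Retained-left breakend A (right-open).
#' @param chrom_b,pos_b Retained-right breakend B (left-open).
#' @param mh_length,mismatches Planted homology length and mismatch count.
#' @param seed Integer seed (mismatch positions are drawn from the window
#'   interior).
#' @return The modified [AnnotatedGenome].
#' @export
plant_microhomology <- function(genome, chrom_a, pos_a, chrom_b, pos_b,
                                mh_length = 5L, mismatches = 2L, seed = 1L) {
  stopifnot(mismatches < mh_length, pos_b - mh_length - 3L >= 1L)
  with_seed(seed, {
    sa <- chrom_seq(genome, chrom_a)
    sb <- chrom_seq(genome, chrom_b)
    a <- substr(sa, pos_a - mh_length + 1L, pos_a)
    b <- a
    mm_at <- sample(seq_len(mh_length), mismatches)
    for (p in mm_at) {
      old <- substr(a, p, p)
      substr(b, p, p) <- sample(setdiff(DNA_BASES, old), 1L)
    }
    # write the window, then break homology just outside it
    substr(sb, pos_b - mh_length, pos_b - 1L) <- b
    for (ext in 1:3) {
      ap <- pos_a - mh_length - ext + 1L
      bp <- pos_b - mh_length - ext
      if (ap < 1L || bp < 1L) break
      if (substr(sb, bp, bp) == substr(sa, ap, ap))
        substr(sb, bp, bp) <- setdiff(DNA_BASES, substr(sa, ap, ap))[1]
    }
    chroms <- genome$chromosomes
    chroms[[chrom_b]] <- sb
    AnnotatedGenome(chroms, genome$genes)
  })
}

#' Detect telomere-capped chromosome truncation
#'
#' A truncation is called when a one-sided junction's appended sequence
#' starts with at least `min_copies` tandem copies of the telomere motif
#' (the final copy may be partial; only complete copies count towards the
#' threshold).
#'
#' @param x Either a variant-call data.frame (single-breakend records are
#'   examined; evidence `"one-sided-breakend"`) or a character vector of
#'   clipped-read consensus sequences with accompanying `chrom`/`position`
#'   (evidence `"clipped-read-consensus"`).
#' @param telomere_motif Telomere repeat motif (length >= 4); must match the
#'   simulator/analysis configuration ([default_telomere_motif()]).
#' @param min_copies Minimum complete tandem copies for a positive call.
#' @param chrom,position Junction coordinates when `x` is a consensus
#'   sequence vector.
#' @return Data frame of positive calls: `chrom`, `position` (first lost
#'   base, 1-based), `telomere_motif_copies`, `evidence`; zero rows when
#'   nothing qualifies.
#' @export
detect_truncation <- function(x, telomere_motif = default_telomere_motif(),
                              min_copies = 3L, chrom = NULL, position = NULL) {
  stopifnot(nchar(telomere_motif) >= 4L)
  if (is.data.frame(x)) {
    sel <- grepl("^[ACGTN]+.*\\.$", x$alt) & !grepl("\\[|\\]", x$alt)
    ins <- x$inserted_seq[sel]
    blank <- !nzchar(ins)
    ins[blank] <- substr(x$alt[sel][blank], 2L,
                         nchar(x$alt[sel][blank]) - 1L)
    chrom <- x$chrom[sel]
    position <- x$pos[sel] + 1L
    evidence <- "one-sided-breakend"
  } else {
    ins <- as.character(x)
    stopifnot(length(chrom) == length(ins), length(position) == length(ins))
    evidence <- "clipped-read-consensus"
  }
  copies <- vapply(ins, tandem_motif_copies, integer(1),
                   motif = telomere_motif, USE.NAMES = FALSE)
  pos_call <- copies >= min_copies
  data.frame(chrom = chrom[pos_call], position = position[pos_call],
             telomere_motif_copies = copies[pos_call],
             evidence = if (any(pos_call)) evidence else character(0),
             stringsAsFactors = FALSE)
}

# Number of complete tandem copies of `motif` at the start of `seq`
# (scanning tolerates a trailing partial copy).
tandem_motif_copies <- function(seq, motif) {
  if (!nzchar(seq)) return(0L)
  len <- nchar(motif)
  tiled <- strrep(motif, ceiling(nchar(seq) / len))
  a <- charToRaw(seq)
  b <- charToRaw(substr(tiled, 1L, nchar(seq)))
  neq <- which(a != b)
  prefix <- if (length(neq) == 0L) length(a) else neq[1] - 1L
  prefix %/% len
}
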