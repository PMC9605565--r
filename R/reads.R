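# Pooled paired-end short-read simulation emulating the study design:
# equal cell quantities from up to 5 colonies per pool, ~550 bp fragments,
# 150 bp mates sequenced from both fragment ends, uniform substitution
# errors, constant base qualities.

#' Simulate paired-end reads from a pool of edited genomes
#'
#' Fragments are drawn multinomially across pool members with probability
#' proportional to genome size — the fragment pool produced by mixing equal
#' cell quantities of each colony — so per-locus depth is equal across
#' members and, for equal-sized genomes, every colony receives an equal
#' expected share of fragments. Within a genome, chromosomes are drawn
#' proportionally to length, start positions uniformly, fragment lengths
#' from a Gaussian. Mate 1 is the first `read_length` bases of the fragment
#' strand; mate 2 is the reverse complement of the other end.
#'
#' @param genomes List of 1--5 [AnnotatedGenome] objects (one per colony).
#'   Names are used as colony ids (default `colony1..k`).
#' @param coverage Target mean fold-coverage of the pool.
#' @param read_length Mate length in bp.
#' @param fragment_mean,fragment_sd Fragment length distribution (bp).
#' @param error_rate Per-base substitution probability (no indel errors, no
#'   quality decay).
#' @param seed Integer seed.
#' @param quality Constant Phred quality for every base.
#' @return A `ReadSet`: data.frame with columns `read_id`, `seq1`, `seq2`,
#'   `colony`, `chrom`, `pos` (fragment start, 1-based, on the *edited*
#'   genome) plus attributes `read_length` and `quality_char`.
#' @export
simulate_pool_reads <- function(genomes, coverage, read_length = 150L,
                                fragment_mean = 550L, fragment_sd = 60L,
                                error_rate = 0, seed = 1L, quality = 40L) {
  if (inherits(genomes, "AnnotatedGenome")) genomes <- list(genomes)
  stopifnot(length(genomes) >= 1L, length(genomes) <= 5L, coverage > 0)
  if (read_length > fragment_mean)
    stop("read_length exceeds the mean fragment size")
  if (fragment_mean < 2L * read_length)
    warning("fragment_mean < 2*read_length: mates overlap in the fragment middle")
  if (is.null(names(genomes)))
    names(genomes) <- paste0("colony", seq_along(genomes))

  with_seed(seed, {
    gsizes <- vapply(genomes, function(g) sum(chrom_lengths(g)), numeric(1))
    n_pairs <- round(coverage * mean(gsizes) / (2 * read_length))
    origin <- sample.int(length(genomes), n_pairs, replace = TRUE,
                         prob = gsizes)

    parts <- vector("list", length(genomes))
    for (k in seq_along(genomes)) {
      nk <- sum(origin == k)
      if (nk == 0L) next
      parts[[k]] <- simulate_genome_reads(genomes[[k]], names(genomes)[k], nk,
                                          read_length, fragment_mean,
                                          fragment_sd, error_rate)
    }
    reads <- do.call(rbind, parts)
    reads <- reads[sample.int(nrow(reads)), , drop = FALSE]  # interleave pool
    reads$read_id <- sprintf("read%07d", seq_len(nrow(reads)))
    rownames(reads) <- NULL
    attr(reads, "read_length") <- as.integer(read_length)
    attr(reads, "quality_char") <- rawToChar(as.raw(33L + quality))
    class(reads) <- c("ReadSet", class(reads))
    reads
  })
}

# Vectorized fragment draw + mate extraction for one genome. Assumes RNG
# already seeded by the caller.
simulate_genome_reads <- function(genome, colony_id, n_pairs, read_length,
                                  fragment_mean, fragment_sd, error_rate) {
  lens <- chrom_lengths(genome)
  usable <- lens >= read_length
  stopifnot(any(usable))
  ci <- sample.int(sum(usable), n_pairs, replace = TRUE,
                   prob = lens[usable])
  cn <- names(lens)[usable][ci]
  flen <- pmax(read_length,
               as.integer(round(stats::rnorm(n_pairs, fragment_mean,
                                             fragment_sd))))
  # shearing a linear molecule is blind to its ends: fragments overlapping a
  # chromosome terminus are clipped there (their ends pile up at it), so
  # positions within one fragment length of an end keep full mate coverage
  start <- floor(stats::runif(n_pairs) * (lens[cn] - read_length + 1L)) + 1L
  fend <- pmin(start + flen - 1L, lens[cn])

  seq1 <- character(n_pairs)
  seq2 <- character(n_pairs)
  # forward-strand fragment for half the pairs, reverse for the other half
  fwd <- stats::runif(n_pairs) < 0.5
  for (cname in unique(cn)) {
    s <- chrom_seq(genome, cname)
    sel <- cn == cname
    left <- substring(s, start[sel], start[sel] + read_length - 1L)
    right <- substring(s, fend[sel] - read_length + 1L, fend[sel])
    rc_right <- revcomp(right)
    # forward fragment: mate1 = left end (+), mate2 = rc of right end;
    # reverse fragment: mate1 = rc of right end, mate2 = left end (+)
    seq1[sel] <- ifelse(fwd[sel], left, rc_right)
    seq2[sel] <- ifelse(fwd[sel], rc_right, left)
  }
  if (error_rate > 0) {
    seq1 <- inject_errors(seq1, error_rate)
    seq2 <- inject_errors(seq2, error_rate)
  }
  data.frame(read_id = "", seq1 = seq1, seq2 = seq2, colony = colony_id,
             chrom = cn, pos = as.integer(start), stringsAsFactors = FALSE)
}

# Uniform substitution errors. Draws a per-read error count, then mutates
# those positions to one of the three other bases.
inject_errors <- function(seqs, error_rate) {
  L <- nchar(seqs)
  k <- stats::rbinom(length(seqs), L, error_rate)
  idx <- which(k > 0L)
  for (i in idx) {
    p <- sample.int(L[i], k[i])
    for (j in p) {
      old <- substr(seqs[i], j, j)
      substr(seqs[i], j, j) <- sample(setdiff(DNA_BASES, old), 1L)
    }
  }
  seqs
}

#' Write a ReadSet as paired FASTQ
#'
#' @param reads A `ReadSet` from [simulate_pool_reads()].
#' @param prefix Output prefix; files are `<prefix>_R1.fastq[.gz]` and
#'   `<prefix>_R2.fastq[.gz]`.
#' @param compress Write gzip-compressed FASTQ.
#' @return The two file paths, invisibly.
#' @export
write_fastq_pair <- function(reads, prefix, compress = FALSE) {
  ext <- if (compress) ".fastq.gz" else ".fastq"
  p1 <- paste0(prefix, "_R1", ext)
  p2 <- paste0(prefix, "_R2", ext)
  qc <- attr(reads, "quality_char") %||% "I"
  write_one <- function(seqs, ids, path) {
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- ids
    quals <- Biostrings::BStringSet(strrep(qc, nchar(seqs)))
    Biostrings::writeXStringSet(x, path, format = "fastq", qualities = quals,
                                compress = compress)
  }
  write_one(reads$seq1, paste0(reads$read_id, "/1"), p1)
  write_one(reads$seq2, paste0(reads$read_id, "/2"), p2)
  invisible(c(p1, p2))
}

#' Read paired FASTQ files into a ReadSet
#'
#' Truth-origin columns are recovered from read ids only if they follow the
#' simulator's naming; otherwise they are `NA`.
#' @param path1,path2 FASTQ paths for mate 1 and mate 2.
#' @export
read_fastq_pair <- function(path1, path2) {
  r1 <- Biostrings::readDNAStringSet(path1, format = "fastq")
  r2 <- Biostrings::readDNAStringSet(path2, format = "fastq")
  stopifnot(length(r1) == length(r2))
  df <- data.frame(read_id = sub("/1$", "", names(r1)),
                   seq1 = as.character(r1), seq2 = as.character(r2),
                   colony = NA_character_, chrom = NA_character_,
                   pos = NA_integer_, stringsAsFactors = FALSE)
  attr(df, "read_length") <- if (nrow(df)) nchar(df$seq1[1]) else NA_integer_
  class(df) <- c("ReadSet", class(df))
  df
}
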