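# Independent oracles and fixture builders, deliberately written with
# different primitives (character vectors, regexes, per-base masks) than the
# implementation they check.

# reverse complement via chartr + rev (independent of Biostrings)
rc_chr <- function(x) {
  vapply(x, function(s)
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = ""),
    character(1), USE.NAMES = FALSE)
}

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# Naive exhaustive binding-site scan: per-position character comparison on
# both strands, PAM matched with a regex.
brute_force_sites <- function(genome, protospacer, max_mm, pam_motifs) {
  k <- nchar(protospacer)
  gch <- strsplit(protospacer, "")[[1]]
  pam_re <- paste0("^(", paste(gsub("N", "[ACGT]", pam_motifs),
                               collapse = "|"), ")$")
  out <- list()
  scan1 <- function(seq, chrom, strand, L) {
    chars <- strsplit(seq, "")[[1]]
    n <- length(chars) - k - 2L
    if (n < 1L) return(NULL)
    mm <- integer(n)
    for (j in seq_len(k)) mm <- mm + (chars[seq_len(n) + j - 1L] != gch[j])
    for (p in which(mm <= max_mm)) {
      pam <- paste(chars[(p + k):(p + k + 2L)], collapse = "")
      if (!grepl(pam_re, pam)) next
      g_start <- if (strand == "+") p else L - (p + k + 2L) + 1L
      out[[length(out) + 1L]] <<- data.frame(
        chrom = chrom, start = g_start, end = g_start + k + 2L,
        strand = strand, mm = mm[p], stringsAsFactors = FALSE)
    }
  }
  for (cn in names(genome$chromosomes)) {
    s <- genome$chromosomes[[cn]]
    scan1(s, cn, "+", nchar(s))
    scan1(rc_chr(s), cn, "-", nchar(s))
  }
  df <- do.call(rbind, c(out, list(data.frame(
    chrom = character(0), start = integer(0), end = integer(0),
    strand = character(0), mm = integer(0)))))
  df[order(df$chrom, df$start, df$strand), , drop = FALSE]
}

# Per-base boolean-mask scan for essential-free regions.
brute_force_ne_regions <- function(genome, min_length) {
  out <- list()
  for (cn in names(genome$chromosomes)) {
    L <- nchar(genome$chromosomes[[cn]])
    mask <- logical(L)
    ess <- genome$genes[genome$genes$essential & genome$genes$chrom == cn, ]
    for (i in seq_len(nrow(ess))) mask[ess$start[i]:ess$end[i]] <- TRUE
    r <- rle(mask)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- !r$values & r$lengths >= min_length
    if (any(keep))
      out[[cn]] <- data.frame(chrom = cn, start = starts[keep],
                              end = ends[keep], stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, c(unname(out), list(data.frame(
    chrom = character(0), start = integer(0), end = integer(0)))))
  rownames(df) <- NULL
  df[order(df$chrom, df$start), , drop = FALSE]
}

# Exhaustive microhomology search by direct string slicing.
brute_force_microhomology <- function(sa, pos_a, sb, pos_b, max_window,
                                      max_mm) {
  count_mm <- function(a, b) {
    ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
    sum(ca != cb)
  }
  for (L in rev(seq_len(min(max_window, pos_a, pos_b - 1L)))) {
    a <- substr(sa, pos_a - L + 1L, pos_a)
    b <- substr(sb, pos_b - L, pos_b - 1L)
    if (count_mm(a, b) <= max_mm) return(c(L, count_mm(a, b)))
  }
  c(0L, 0L)
}

# Independent restatement of the genotype classification rule table.
rule_table_class <- function(net, is_snv = FALSE, is_breakend = FALSE) {
  if (is_breakend) return("SV")
  if (is_snv) return("substitution")
  a <- abs(net)
  if (a == 0) "WT" else if (a >= 50) "SV" else if (net %% 3 == 0) "in-frame"
  else "frameshift"
}

# A small annotated genome with at least one usable guide per requested
# chromosome; cached per options to keep the suite fast.
make_test_genome <- function(lengths = c(60000L, 40000L), n_genes = 40L,
                             essential_fraction = 0.2, seed = 3L) {
  generate_genome(lengths, n_genes, essential_fraction, seed = seed)
}

# First enumerable guide of the first non-essential gene on `chrom`,
# restricted to + strand guides cutting in the first 40% of the CDS when
# possible (falls back to any guide on the gene).
pick_guide <- function(genome, chrom, strand = "+") {
  genes <- genome$genes[!genome$genes$essential &
                        genome$genes$chrom == chrom, ]
  for (i in seq_len(nrow(genes))) {
    g <- enumerate_protospacers(genome, genes[i, ])
    g <- g[g$strand == strand & g$cut_locus > 2000 &
           g$cut_locus < nchar(genome$chromosomes[[chrom]]) - 2000, ]
    if (nrow(g) > 0L) return(g[1, ])
  }
  stop("no usable guide on ", chrom)
}
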