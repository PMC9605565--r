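# AnnotatedGenome: named chromosome sequences plus a gene table carrying
# essentiality flags. This is the coordinate frame for every other module.
# All serialized coordinates are 1-based inclusive.

#' Construct an annotated genome
#'
#' Bundles chromosome sequences with a gene/CDS table. Genes are modelled as
#' single-exon CDS intervals (the compact-yeast case): the gene interval *is*
#' the coding sequence, so its length must be a positive multiple of 3.
#'
#' @param chromosomes Named character vector of chromosome sequences
#'   (alphabet A/C/G/T).
#' @param genes A `data.frame` with columns `gene_id`, `chrom`, `start`,
#'   `end` (1-based inclusive), `strand` (`"+"`/`"-"`) and `essential`
#'   (logical). May have zero rows.
#' @return An object of class `AnnotatedGenome`: a list with elements
#'   `chromosomes` and `genes`.
#' @export
AnnotatedGenome <- function(chromosomes, genes = empty_gene_table()) {
  if (is.null(names(chromosomes)) || anyDuplicated(names(chromosomes)))
    stop("chromosomes must be uniquely named")
  if (!all(grepl("^[ACGT]*$", chromosomes)))
    stop("chromosome sequences must use the A/C/G/T alphabet only")
  genes <- as.data.frame(genes)
  needed <- c("gene_id", "chrom", "start", "end", "strand", "essential")
  if (!all(needed %in% names(genes)))
    stop("gene table must have columns: ", paste(needed, collapse = ", "))
  if (nrow(genes) > 0L) {
    if (anyDuplicated(genes$gene_id)) stop("gene ids must be unique")
    if (!all(genes$chrom %in% names(chromosomes)))
      stop("gene on unknown chromosome: ",
           paste(setdiff(genes$chrom, names(chromosomes)), collapse = ", "))
    if (any(genes$start > genes$end)) stop("gene start must be <= end")
    if (any(genes$start < 1L) ||
        any(genes$end > nchar(chromosomes)[match(genes$chrom, names(chromosomes))]))
      stop("gene interval outside chromosome bounds")
    len <- genes$end - genes$start + 1L
    if (any(len %% 3L != 0L) || any(len <= 0L))
      stop("CDS length must be a positive multiple of 3")
    if (!all(genes$strand %in% c("+", "-"))) stop("gene strand must be + or -")
    if (!is.logical(genes$essential)) stop("essential flag must be logical")
  }
  structure(list(chromosomes = chromosomes, genes = genes),
            class = "AnnotatedGenome")
}

empty_gene_table <- function() {
  data.frame(gene_id = character(0), chrom = character(0),
              start = integer(0), end = integer(0),
              strand = character(0), essential = logical(0),
              stringsAsFactors = FALSE)
}

#' @export
print.AnnotatedGenome <- function(x, ...) {
  cat("AnnotatedGenome:", length(x$chromosomes), "chromosome(s),",
      sum(nchar(x$chromosomes)), "bp,", nrow(x$genes), "gene(s) (",
      sum(x$genes$essential), "essential )\n")
  invisible(x)
}

chrom_lengths <- function(genome) nchar(genome$chromosomes)

chrom_seq <- function(genome, chrom) {
  s <- genome$chromosomes[[chrom]]
  if (is.null(s)) stop("unknown chromosome: ", chrom)
  s
}

#' Generate a random annotated genome
#'
#' Draws uniform-random chromosome sequences and places non-overlapping
#' single-exon genes with Bernoulli essentiality flags. Deterministic for a
#' fixed seed.
#'
#' @param chromosome_lengths Integer vector of chromosome lengths in bp
#'   (each >= 10 kb); chromosome names are `chr1`, `chr2`, ...
#' @param n_genes Number of genes to place (non-overlapping).
#' @param essential_fraction Probability that a gene is flagged essential.
#' @param seed Integer seed controlling all randomness.
#' @param gene_length_range Range (bp) gene lengths are drawn from; lengths
#'   are rounded to multiples of 3.
#' @param max_tries Placement retries per gene before giving up.
#' @return An [AnnotatedGenome].
#' @examples
#' g <- generate_genome(c(50000, 30000), n_genes = 20,
#'                      essential_fraction = 0.3, seed = 1)
#' @export
generate_genome <- function(chromosome_lengths, n_genes, essential_fraction,
                            seed, gene_length_range = c(300, 1500),
                            max_tries = 1000L) {
  stopifnot(length(chromosome_lengths) >= 1L, n_genes >= 0L,
            essential_fraction >= 0, essential_fraction <= 1)
  if (any(chromosome_lengths < 10000L))
    stop("chromosome lengths must be >= 10 kb")
  with_seed(seed, {
    chroms <- vapply(chromosome_lengths, random_dna, character(1))
    names(chroms) <- paste0("chr", seq_along(chroms))
    genes <- empty_gene_table()
    if (n_genes > 0L) {
      sizes <- seq(gene_length_range[1], gene_length_range[2], by = 3L)
      occupied <- lapply(chroms, function(s) IRanges::IRanges())
      rows <- vector("list", n_genes)
      for (i in seq_len(n_genes)) {
        placed <- FALSE
        for (try in seq_len(max_tries)) {
          ci <- sample.int(length(chroms), 1L, prob = chromosome_lengths)
          len <- sizes[sample.int(length(sizes), 1L)]
          if (chromosome_lengths[ci] <= len) next
          start <- sample.int(chromosome_lengths[ci] - len, 1L)
          cand <- IRanges::IRanges(start, start + len - 1L)
          if (IRanges::countOverlaps(cand, occupied[[ci]]) == 0L) {
            occupied[[ci]] <- c(occupied[[ci]], cand)
            rows[[i]] <- data.frame(
              gene_id = sprintf("gene%04d", i),
              chrom = names(chroms)[ci],
              start = start, end = start + len - 1L,
              strand = sample(c("+", "-"), 1L),
              essential = as.logical(stats::rbinom(1L, 1L, essential_fraction)),
              stringsAsFactors = FALSE)
            placed <- TRUE
            break
          }
        }
        if (!placed)
          stop("gene placement failed after ", max_tries,
               " retries (genome too crowded for ", n_genes, " genes)")
      }
      genes <- do.call(rbind, rows)
    }
    AnnotatedGenome(chroms, genes)
  })
}

#' Write / read genome FASTA
#'
#' @param genome An [AnnotatedGenome].
#' @param path Output FASTA path.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(genome$chromosomes), filepath = path)
  invisible(path)
}

#' @rdname write_genome_fasta
#' @param gff_path Optional GFF3 annotation to attach on reading.
#' @export
read_genome_fasta <- function(path, gff_path = NULL) {
  ss <- Biostrings::readDNAStringSet(path)
  chroms <- as.character(ss)
  names(chroms) <- sub("\\s.*$", "", names(ss))
  genes <- if (is.null(gff_path)) empty_gene_table() else read_annotation_gff3(gff_path)
  AnnotatedGenome(chroms, genes)
}

#' Write / read gene annotation as GFF3
#'
#' Genes are emitted as `gene` features with `ID` and `essential=true|false`
#' attributes (single-exon CDS model, so no child features are written).
#'
#' @param genome An [AnnotatedGenome].
#' @param path GFF3 file path.
#' @export
write_annotation_gff3 <- function(genome, path) {
  g <- genome$genes
  gr <- GenomicRanges::GRanges(
    seqnames = if (nrow(g)) g$chrom else character(0),
    ranges = IRanges::IRanges(start = g$start, end = g$end),
    strand = if (nrow(g)) g$strand else character(0))
  gr$type <- rep("gene", nrow(g))
  gr$ID <- g$gene_id
  gr$essential <- ifelse(g$essential, "true", "false")
  GenomeInfoDb::seqlengths(gr) <-
    chrom_lengths(genome)[GenomeInfoDb::seqlevels(gr)]
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @rdname write_annotation_gff3
#' @return `read_annotation_gff3` returns the gene `data.frame`.
#' @export
read_annotation_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "gene"]
  if (length(gr) == 0L) return(empty_gene_table())
  data.frame(
    gene_id = as.character(gr$ID),
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = BiocGenerics::start(gr),
    end = BiocGenerics::end(gr),
    strand = as.character(BiocGenerics::strand(gr)),
    essential = tolower(as.character(gr$essential)) == "true",
    stringsAsFactors = FALSE)
}
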