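# Guide enumeration within coding sequences, CDS-window + uniqueness
# filtering, and identification of long genomic regions free of essential
# genes.

#' Enumerate candidate protospacers in a gene
#'
#' Scans both strands of the gene's genomic context for PAM-adjacent
#' protospacers and reports, for each, the blunt-cut locus (3 bp from the
#' PAM) and its fractional position along the coding sequence (5' to 3' on
#' the gene strand). Only guides whose cut locus falls inside the CDS are
#' returned.
#'
#' @param genome An [AnnotatedGenome].
#' @param gene A gene id present in `genome$genes`, or a single-row gene
#'   data.frame.
#' @param pam_motif IUPAC PAM motif (default `"NGG"`).
#' @param spacer_length Protospacer length in nt (17--20).
#' @return A guide data.frame: `guide_id`, `protospacer`, `pam`, `chrom`,
#'   `cut_locus`, `strand`, `cds_fraction`. The protospacer is reported 5'
#'   to 3' on the strand carrying the PAM.
#' @export
enumerate_protospacers <- function(genome, gene, pam_motif = "NGG",
                                   spacer_length = 20L) {
  stopifnot(spacer_length >= 17L, spacer_length <= 20L)
  if (is.character(gene)) {
    g <- genome$genes[genome$genes$gene_id == gene, , drop = FALSE]
    if (nrow(g) == 0L) stop("gene not found: ", gene)
  } else g <- as.data.frame(gene)
  if (nrow(g) != 1L) stop("exactly one gene expected")
  if (g$end - g$start + 1L <= 0L) {
    warning("gene without CDS: ", g$gene_id)
    return(empty_guide_table())
  }
  seq <- chrom_seq(genome, g$chrom)
  L <- nchar(seq)
  plen <- nchar(pam_motif)
  site_len <- spacer_length + plen
  # scan a context wide enough that any guide cutting inside the CDS is seen
  lo <- max(1L, g$start - site_len)
  hi <- min(L, g$end + site_len)
  window <- substr(seq, lo, hi)

  hits <- rbind(
    scan_pam_sites(window, pam_motif, spacer_length, "+"),
    scan_pam_sites(revcomp(window), pam_motif, spacer_length, "-"))
  if (nrow(hits) == 0L) return(empty_guide_table())

  # map window coordinates back to the genome; minus-strand scan coords are
  # on the reverse complement of the window
  wlen <- nchar(window)
  out <- lapply(seq_len(nrow(hits)), function(i) {
    h <- hits[i, ]
    if (h$strand == "+") {
      sp_start <- lo + h$start - 1L                 # protospacer 5' (genomic)
      pam_start <- sp_start + spacer_length
      cut <- sp_start + spacer_length - 3L          # 3 bp upstream of PAM
    } else {
      sp_end_rc <- h$start + spacer_length - 1L
      sp_start <- lo + (wlen - sp_end_rc)           # genomic left end
      pam_start <- sp_start - plen
      cut <- sp_start + 2L                          # 3 bp from PAM, genomic
    }
    data.frame(protospacer = h$protospacer, pam = h$pam, chrom = g$chrom,
               cut_locus = cut, strand = h$strand,
               sp_start = sp_start, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[out$cut_locus >= g$start & out$cut_locus <= g$end, , drop = FALSE]
  if (nrow(out) == 0L) return(empty_guide_table())
  cds_len <- g$end - g$start + 1L
  out$cds_fraction <- if (g$strand == "+") {
    (out$cut_locus - g$start + 1L) / cds_len
  } else {
    (g$end - out$cut_locus + 1L) / cds_len
  }
  out <- out[order(out$cut_locus, out$strand), , drop = FALSE]
  data.frame(guide_id = sprintf("%s_g%02d", g$gene_id, seq_len(nrow(out))),
             protospacer = out$protospacer, pam = out$pam, chrom = out$chrom,
             cut_locus = out$cut_locus, strand = out$strand,
             cds_fraction = out$cds_fraction, stringsAsFactors = FALSE)
}

empty_guide_table <- function() {
  data.frame(guide_id = character(0), protospacer = character(0),
             pam = character(0), chrom = character(0), cut_locus = integer(0),
             strand = character(0), cds_fraction = numeric(0),
             stringsAsFactors = FALSE)
}

# Find protospacer+PAM sites on the given (already oriented) sequence.
# Returns 1-based start of the protospacer within `seq`.
scan_pam_sites <- function(seq, pam_motif, spacer_length, strand) {
  plen <- nchar(pam_motif)
  n <- nchar(seq) - spacer_length - plen + 1L
  if (n < 1L)
    return(data.frame(start = integer(0), protospacer = character(0),
                      pam = character(0), strand = character(0)))
  sets <- iupac_expand(pam_motif)
  pam_pos <- seq_len(n) + spacer_length
  chars <- lapply(seq_len(plen) - 1L,
                  function(off) substring(seq, pam_pos + off, pam_pos + off))
  ok <- which(iupac_match_positions(chars, sets))
  if (length(ok) == 0L)
    return(data.frame(start = integer(0), protospacer = character(0),
                      pam = character(0), strand = character(0)))
  data.frame(start = ok,
             protospacer = substring(seq, ok, ok + spacer_length - 1L),
             pam = substring(seq, ok + spacer_length,
                             ok + spacer_length + plen - 1L),
             strand = strand, stringsAsFactors = FALSE)
}

#' Filter guides by CDS window and genome-wide uniqueness
#'
#' Retains guides whose cut locus lies in the configured fraction window of
#' the coding sequence and that have no secondary binding site beyond their
#' own design locus under the uniqueness scan supplied.
#'
#' @param candidates Guide data.frame from [enumerate_protospacers()].
#' @param cds_window `c(low, high)` fraction window (default the first 40%
#'   of the CDS).
#' @param uniqueness_scan Named list mapping guide_id to a binding-site
#'   data.frame from [find_binding_sites()] (typically run with a mismatch
#'   budget of 0).
#' @param max_allowed_secondary_sites Maximum number of binding sites other
#'   than the design locus (default 0: verbatim-unique guides only).
#' @return The retained subset of `candidates`.
#' @export
filter_guides <- function(candidates, cds_window = c(0, 0.4),
                          uniqueness_scan = NULL,
                          max_allowed_secondary_sites = 0L) {
  stopifnot(cds_window[1] < cds_window[2])
  keep <- candidates$cds_fraction >= cds_window[1] &
    candidates$cds_fraction <= cds_window[2]
  out <- candidates[keep, , drop = FALSE]
  if (!is.null(uniqueness_scan) && nrow(out) > 0L) {
    n_secondary <- vapply(seq_len(nrow(out)), function(i) {
      g <- out[i, ]
      sites <- uniqueness_scan[[g$guide_id]]
      if (is.null(sites) || nrow(sites) == 0L) return(0L)
      own <- sites$chrom == g$chrom & sites$strand == g$strand &
        sites$start <= g$cut_locus & sites$end >= g$cut_locus
      sum(!own)
    }, integer(1))
    out <- out[n_secondary <= max_allowed_secondary_sites, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Find long regions free of essential genes
#'
#' Returns all maximal intervals that contain no base of any essential gene
#' and are at least `min_length` bp long, sorted by chromosome then start.
#' Essential genes are treated strand-agnostically; a region boundary is the
#' base adjacent to the nearest essential gene (or the chromosome end).
#'
#' @param genome An [AnnotatedGenome] with essentiality flags.
#' @param min_length Minimum region length in bp (the study design used
#'   50 kb).
#' @return Data frame `chrom`, `start`, `end`, `length`,
#'   `contained_gene_ids` (comma-separated non-essential genes fully inside
#'   the region).
#' @export
find_nonessential_regions <- function(genome, min_length = 50000L) {
  lens <- chrom_lengths(genome)
  ess <- genome$genes[genome$genes$essential, , drop = FALSE]
  out <- lapply(names(lens), function(cn) {
    blocked <- ess[ess$chrom == cn, , drop = FALSE]
    ir <- IRanges::reduce(IRanges::IRanges(blocked$start, blocked$end))
    free <- IRanges::setdiff(IRanges::IRanges(1L, lens[[cn]]), ir)
    free <- free[IRanges::width(free) >= min_length]
    if (length(free) == 0L) return(NULL)
    ne <- genome$genes[!genome$genes$essential & genome$genes$chrom == cn, ,
                       drop = FALSE]
    contained <- vapply(seq_along(free), function(i) {
      inside <- ne$start >= IRanges::start(free)[i] &
        ne$end <= IRanges::end(free)[i]
      paste(ne$gene_id[inside], collapse = ",")
    }, character(1))
    data.frame(chrom = cn, start = IRanges::start(free),
               end = IRanges::end(free), length = IRanges::width(free),
               contained_gene_ids = contained, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(out, list(data.frame(
    chrom = character(0), start = integer(0), end = integer(0),
    length = integer(0), contained_gene_ids = character(0)))))
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Write guides TSV / regions BED
#'
#' Guides use 1-based inclusive coordinates; BED follows its own 0-based
#' half-open standard.
#' @param guides Guide data.frame.
#' @param path Output path.
#' @export
write_guides_tsv <- function(guides, path) {
  utils::write.table(guides, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_guides_tsv
#' @export
read_guides_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

#' @rdname write_guides_tsv
#' @param regions Region data.frame from [find_nonessential_regions()].
#' @export
write_regions_bed <- function(regions, path) {
  gr <- GenomicRanges::GRanges(regions$chrom,
                               IRanges::IRanges(regions$start, regions$end))
  gr$name <- sprintf("NE_region_%02d", seq_len(nrow(regions)))
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}
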