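# Exhaustive enumeration of candidate CRISPR binding sites under a Hamming
# mismatch budget with strict PAM matching (no mismatches inside the PAM,
# no bulges), seed-region annotation, and intersection of sites with
# observed variants.

#' Find all binding sites of a guide in a genome
#'
#' Slides the protospacer over both strands of every chromosome, counting
#' mismatches over the protospacer only; any deviation of the adjacent 3-mer
#' from the allowed PAM motifs excludes the site. Equivalent to a naive
#' per-position Hamming scan.
#'
#' @param genome An [AnnotatedGenome].
#' @param guide A single-row guide data.frame (or list) with at least
#'   `protospacer`; `guide_id` is carried through if present.
#' @param max_mismatches Mismatch budget over the protospacer (must be less
#'   than the protospacer length). The study scanned up to 10.
#' @param pam_motifs Character vector of allowed 3-nt IUPAC PAM motifs
#'   (canonical NGG, tolerated NAG).
#' @param seed_length Seed-region length used to annotate `seed_mismatches`.
#' @return Binding-site data.frame: `guide_id`, `chrom`, `start`, `end`
#'   (1-based inclusive span of protospacer+PAM), `strand`, `pam_observed`,
#'   `mismatch_count`, `mismatch_offsets` (comma-separated distances from
#'   the PAM-proximal protospacer base, 1 = adjacent to the PAM) and
#'   `seed_mismatches` (offsets within the 5-base seed).
#' @export
find_binding_sites <- function(genome, guide, max_mismatches = 10L,
                               pam_motifs = c("NGG", "NAG"),
                               seed_length = 5L) {
  guide <- as.list(guide)
  sp <- toupper(guide$protospacer)
  k <- nchar(sp)
  if (max_mismatches >= k)
    stop("max_mismatches must be smaller than the protospacer length ",
         "(everything would match)")
  if (any(nchar(pam_motifs) != 3L)) stop("PAM motifs must be 3 nt")
  pam_sets <- lapply(pam_motifs, iupac_expand)
  gid <- guide$guide_id %||% "guide"

  res <- list()
  for (cn in names(genome$chromosomes)) {
    s <- genome$chromosomes[[cn]]
    L <- nchar(s)
    if (L < k + 3L) next
    fw <- scan_oriented(s, sp, max_mismatches, pam_sets)
    if (nrow(fw) > 0L) {
      fw$chrom <- cn; fw$strand <- "+"
      fw$g_start <- fw$start_scan               # protospacer+PAM left end
      res[[length(res) + 1L]] <- fw
    }
    rv <- scan_oriented(revcomp(s), sp, max_mismatches, pam_sets)
    if (nrow(rv) > 0L) {
      rv$chrom <- cn; rv$strand <- "-"
      rv$g_start <- L - (rv$start_scan + k + 3L - 1L) + 1L
      res[[length(res) + 1L]] <- rv
    }
  }
  if (length(res) == 0L) return(empty_site_table())
  res <- do.call(rbind, res)
  out <- data.frame(guide_id = gid, chrom = res$chrom,
                    start = res$g_start, end = res$g_start + k + 3L - 1L,
                    strand = res$strand, pam_observed = res$pam,
                    mismatch_count = res$mm,
                    mismatch_offsets = res$offsets,
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start, out$strand), , drop = FALSE]
  out$site_id <- sprintf("%s_site%04d", gid, seq_len(nrow(out)))
  out$seed_mismatches <- count_seed_mismatches(out, seed_length)
  rownames(out) <- NULL
  out
}

empty_site_table <- function() {
  data.frame(guide_id = character(0), chrom = character(0),
             start = integer(0), end = integer(0), strand = character(0),
             pam_observed = character(0), mismatch_count = integer(0),
             mismatch_offsets = character(0), site_id = character(0),
             seed_mismatches = integer(0), stringsAsFactors = FALSE)
}

# Scan one orientation of one chromosome. `seq` is already oriented so the
# protospacer reads 5'->3' with the PAM immediately 3' of it. Coordinates
# returned are 1-based starts within `seq`.
scan_oriented <- function(seq, sp, max_mm, pam_sets) {
  k <- nchar(sp)
  n <- nchar(seq) - k - 3L + 1L
  if (n < 1L)
    return(data.frame(start_scan = integer(0), mm = integer(0),
                      pam = character(0), offsets = character(0)))
  sraw <- charToRaw(seq)
  graw <- charToRaw(sp)
  mm <- integer(n)
  idx <- seq_len(n)
  for (j in seq_len(k)) mm <- mm + (sraw[idx + j - 1L] != graw[j])
  cand <- which(mm <= max_mm)
  if (length(cand) == 0L)
    return(data.frame(start_scan = integer(0), mm = integer(0),
                      pam = character(0), offsets = character(0)))
  pam_chars <- lapply(0:2, function(off)
    substring(seq, cand + k + off, cand + k + off))
  pam_ok <- rep(FALSE, length(cand))
  for (sets in pam_sets) pam_ok <- pam_ok | iupac_match_positions(pam_chars, sets)
  cand <- cand[pam_ok]
  if (length(cand) == 0L)
    return(data.frame(start_scan = integer(0), mm = integer(0),
                      pam = character(0), offsets = character(0)))
  pam <- paste0(substring(seq, cand + k, cand + k),
                substring(seq, cand + k + 1L, cand + k + 1L),
                substring(seq, cand + k + 2L, cand + k + 2L))
  offsets <- vapply(cand, function(p) {
    site <- charToRaw(substr(seq, p, p + k - 1L))
    where <- which(site != graw)
    paste(rev(k - where + 1L), collapse = ",")   # 1 = PAM-proximal
  }, character(1))
  data.frame(start_scan = cand, mm = mm[cand], pam = pam, offsets = offsets,
             stringsAsFactors = FALSE)
}

#' Count mismatches in the seed region
#'
#' The seed is the `seed_length` protospacer bases adjacent to the PAM,
#' where mismatches most strongly block cleavage.
#'
#' @param sites Binding-site data.frame (or anything with a
#'   `mismatch_offsets` comma-string column).
#' @param seed_length Seed length in nt (default 5).
#' @return Integer vector: mismatch offsets `<= seed_length` per site.
#' @export
count_seed_mismatches <- function(sites, seed_length = 5L) {
  vapply(sites$mismatch_offsets, function(s) {
    if (is.na(s) || s == "") return(0L)
    sum(as.integer(strsplit(s, ",")[[1]]) <= seed_length)
  }, integer(1), USE.NAMES = FALSE)
}

#' Intersect binding sites with observed variants
#'
#' Emits a hit for every (site, variant) pair whose reference spans are
#' within `window` bp of each other; pairs whose spans intersect (the PAM is
#' part of the site span) are upgraded to `overlaps-site`. Following VCF
#' semantics, an insertion's variant range is its single anchor base.
#'
#' @param sites Binding-site data.frame from [find_binding_sites()].
#' @param variants Variant-call data.frame.
#' @param window Distance in bp (the study used 30 up- and downstream).
#' @return Data frame `site_id`, `variant_id`, `relationship`
#'   (`"overlaps-site"` or `"within-window"`).
#' @export
sites_near_variants <- function(sites, variants, window = 30L) {
  empty <- data.frame(site_id = character(0), variant_id = character(0),
                      relationship = character(0), stringsAsFactors = FALSE)
  if (nrow(sites) == 0L || nrow(variants) == 0L) return(empty)
  vs <- variant_ref_span(variants)
  out <- list()
  for (cn in unique(sites$chrom)) {
    si <- which(sites$chrom == cn)
    vi <- which(vs$chrom == cn)
    if (length(vi) == 0L) next
    sr <- IRanges::IRanges(sites$start[si], sites$end[si])
    vr <- IRanges::IRanges(vs$start[vi], vs$end[vi])
    # the flanking windows span `window` bases beyond the variant range, so
    # qualifying pairs are separated by at most window - 1 gap bases
    near <- IRanges::findOverlaps(sr, vr, maxgap = window - 1L)
    if (length(near) == 0L) next
    qh <- S4Vectors::queryHits(near); sh <- S4Vectors::subjectHits(near)
    touch <- IRanges::start(sr)[qh] <= IRanges::end(vr)[sh] &
      IRanges::start(vr)[sh] <= IRanges::end(sr)[qh]
    out[[length(out) + 1L]] <- data.frame(
      site_id = sites$site_id[si[qh]],
      variant_id = variants$variant_id[vi[sh]],
      relationship = ifelse(touch, "overlaps-site", "within-window"),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, c(out, list(empty)))
  rownames(out) <- NULL
  out
}

#' Write binding sites / hits as TSV
#' @param x Data frame.
#' @param path Output path.
#' @export
write_sites_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
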