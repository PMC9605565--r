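# On-target genotype reconstruction and read-support quantification:
# classify repair outcomes, rebuild local mutant sequences around each target,
# assign reads to the best-matching genotype model, and summarise relative
# read support and targeting efficiency.

GENOTYPE_CLASSES <- c("WT", "in-frame", "frameshift", "SV", "substitution")

#' Classify a repair genotype
#'
#' Implements the four-way on-target scheme: small indels (1--49 bp) are
#' `in-frame` when the net length change is a multiple of 3 and `frameshift`
#' otherwise; indels of at least 50 bp and any breakend, inversion,
#' duplication or translocation are `SV`; single-nucleotide substitutions get
#' their own `substitution` label; no change is `WT`.
#'
#' @param net_length_change Signed net length change(s) in bp.
#' @param variant_type Optional type vector (`"SNV"` forces `substitution`).
#' @param breakend Logical vector: call is a breakend/symbolic SV.
#' @return Data frame with `class` and `frame_preserving`
#'   (`net %% 3 == 0`; reported for SVs too, e.g. a 57 bp deletion is an SV
#'   that preserves the reading frame).
#' @export
classify_genotype <- function(net_length_change, variant_type = NULL,
                              breakend = FALSE) {
  n <- length(net_length_change)
  if (!is.numeric(net_length_change) || any(!is.finite(net_length_change)))
    stop("net_length_change must be finite numeric")
  variant_type <- rep_len(variant_type %||% NA_character_, n)
  breakend <- rep_len(breakend, n)
  net <- as.integer(net_length_change)
  cls <- ifelse(breakend, "SV",
         ifelse(!is.na(variant_type) & variant_type == "SNV", "substitution",
         ifelse(net == 0L, "WT",
         ifelse(abs(net) >= 50L, "SV",
         ifelse(net %% 3L == 0L, "in-frame", "frameshift")))))
  data.frame(class = cls, frame_preserving = net %% 3L == 0L,
             stringsAsFactors = FALSE)
}

classify_calls <- function(calls) {
  brk <- is_breakend_alt(calls$alt) | startsWith(calls$alt, "<")
  classify_genotype(calls$net_len, calls$type, brk)$class
}

#' Reconstruct per-genotype local sequences at a target
#'
#' Builds the reference window around the cut locus (the wildtype model) and
#' one mutant model per distinct variant: indels splice the window,
#' breakends concatenate the two partner flanks in junction orientation,
#' single breakends append their inserted sequence (e.g. telomere repeats),
#' and inversions append the reverse-complemented far flank. These are the
#' multi-FASTA genotype references that reads are assigned against.
#'
#' @param genome Reference [AnnotatedGenome].
#' @param target Single-row guide data.frame (`chrom`, `cut_locus`,
#'   `guide_id`).
#' @param variants Variant-call data.frame; every variant must lie within
#'   `flank` of the cut locus or be a breakend anchored there.
#' @param flank Window half-width in bp (default 1000, comfortably beyond
#'   the reach of a 550 bp fragment).
#' @return Data frame of genotype models: `genotype_id`, `target_id`,
#'   `class`, `seq`, `variant_pos` (1-based in the window),
#'   `source_variant_id` (`NA` for WT).
#' @export
reconstruct_genotype_sequences <- function(genome, target, variants = NULL,
                                           flank = 1000L) {
  target <- as.list(target)
  chrom <- target$chrom
  cut <- target$cut_locus
  s <- chrom_seq(genome, chrom)
  L <- nchar(s)
  wstart <- max(1L, cut - flank)
  wend <- min(L, cut + flank)
  wt_seq <- substr(s, wstart, wend)
  tid <- target$guide_id %||% "target"
  models <- data.frame(genotype_id = paste0(tid, "_WT"), target_id = tid,
                       class = "WT", seq = wt_seq,
                       variant_pos = cut - wstart + 1L,
                       source_variant_id = NA_character_,
                       stringsAsFactors = FALSE)
  if (!is.null(variants) && nrow(variants) > 0L) {
    for (i in seq_len(nrow(variants))) {
      v <- variants[i, ]
      m <- build_variant_model(genome, v, chrom, cut, wstart, wend, flank)
      if (is.null(m)) next
      models <- rbind(models, data.frame(
        genotype_id = paste0(tid, "_", v$variant_id), target_id = tid,
        class = classify_calls(v), seq = m$seq, variant_pos = m$vp,
        source_variant_id = v$variant_id, stringsAsFactors = FALSE))
    }
  }
  dup <- duplicated(models$seq)
  if (any(dup)) {
    warning("collapsing ", sum(dup), " duplicate genotype model(s) at ", tid)
    models <- models[!dup, , drop = FALSE]
  }
  rownames(models) <- NULL
  models
}

build_variant_model <- function(genome, v, chrom, cut, wstart, wend, flank) {
  s <- chrom_seq(genome, chrom)
  wt <- substr(s, wstart, wend)
  alt <- v$alt
  if (grepl("\\[|\\]", alt)) {                       # paired breakend
    loc <- sub("^.*[][]([^]:[]+:[0-9]+)[][].*$", "\\1", alt)
    chr2 <- sub(":.*$", "", loc)
    p2 <- as.integer(sub("^.*:", "", loc))
    s2 <- chrom_seq(genome, chr2)
    lead <- sub("[][].*$", "", alt)                  # seq before first bracket
    if (grepl("^[ACGTN]", alt)) {                    # t[p[ : retained left
      if (v$chrom != chrom || abs(v$pos - cut) > flank) return(NULL)
      ins <- substr(lead, 2L, nchar(lead))           # after the REF anchor
      seq <- paste0(substr(s, wstart, v$pos), ins,
                    substr(s2, p2, min(nchar(s2), p2 + flank - 1L)))
      vp <- v$pos - wstart + 1L
    } else {                                         # ]p]t : retained right
      if (v$chrom != chrom || abs(v$pos - cut) > flank) return(NULL)
      tail_seq <- sub("^.*[][]", "", alt)
      ins <- substr(tail_seq, 1L, nchar(tail_seq) - 1L)
      left <- substr(s2, max(1L, p2 - flank + 1L), p2)
      seq <- paste0(left, ins, substr(s, v$pos, wend))
      vp <- nchar(left) + 1L
    }
    return(list(seq = seq, vp = vp))
  }
  if (grepl("^[ACGTN]+.*\\.$", alt)) {               # single breakend
    if (abs(v$pos - cut) > flank) return(NULL)
    ins <- substr(alt, 2L, nchar(alt) - 1L)
    return(list(seq = paste0(substr(s, wstart, v$pos), ins),
                vp = v$pos - wstart + 1L))
  }
  if (startsWith(alt, "<")) {                        # symbolic (inversion)
    if (alt != "<INV>" || is.na(v$end))
      stop("unsupported symbolic ALT: ", alt)
    if (abs(v$pos - cut) > flank) return(NULL)
    inv <- revcomp(substr(s, v$pos + 1L, v$end))
    seq <- paste0(substr(s, wstart, v$pos),
                  substr(inv, 1L, min(nchar(inv), flank)))
    return(list(seq = seq, vp = v$pos - wstart + 1L))
  }
  # explicit-allele SNV / indel
  if (v$pos < wstart || v$pos + nchar(v$ref) - 1L > wend)
    stop("variant ", v$variant_id, " outside the flank window")
  rel <- v$pos - wstart + 1L
  stopifnot(substr(wt, rel, rel + nchar(v$ref) - 1L) == v$ref)
  seq <- paste0(substr(wt, 1L, rel - 1L), v$alt,
                substr(wt, rel + nchar(v$ref), nchar(wt)))
  list(seq = seq, vp = rel)
}

#' Write genotype models as multi-FASTA
#' @param models Model data.frame.
#' @param path FASTA path.
#' @export
write_genotype_fasta <- function(models, path) {
  x <- Biostrings::DNAStringSet(models$seq)
  names(x) <- models$genotype_id
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Assign reads to genotype models
#'
#' A purpose-built best-match classifier over short genotype windows (not a
#' general aligner): each mate is anchored into the models by exact k-mer
#' lookup, scored by Hamming distance at the implied offset on both strands,
#' and assigned to the unique model with the strictly best score, provided
#' the alignment covers the model's variant position with at least
#' `min_overlap` bases on both sides. Ties across models are discarded as
#' ambiguous (mirroring multimapped-read removal); reads matching no model
#' within budget are unassigned.
#'
#' @param reads A `ReadSet` (both mates are used independently).
#' @param models Genotype models from [reconstruct_genotype_sequences()].
#' @param max_mismatches_per_read Mismatch budget per mate.
#' @param min_overlap Minimum bases on each side of the variant position.
#' @param anchor_k Anchor k-mer length.
#' @return List: `counts` (reads per genotype), `ambiguous`, `noncovering`,
#'   `unassigned`, `retained`, `total_mates`.
#' @export
assign_reads <- function(reads, models, max_mismatches_per_read = 8L,
                         min_overlap = 5L, anchor_k = 25L) {
  stopifnot(nrow(models) >= 1L, !anyDuplicated(models$seq))
  mates <- c(reads$seq1, reads$seq2)
  total <- length(mates)
  L <- attr(reads, "read_length") %||% nchar(mates[1])
  k <- min(anchor_k, L)
  anchor_offs <- seq(1L, L - k + 1L, by = k)
  if (length(anchor_offs) > 3L) anchor_offs <- anchor_offs[1:3]

  # one alignment target per model strand
  targets <- list()
  for (i in seq_len(nrow(models))) {
    targets[[paste0(i, "+")]] <- list(model = i, strand = "+",
                                      seq = models$seq[i])
    targets[[paste0(i, "-")]] <- list(model = i, strand = "-",
                                      seq = revcomp(models$seq[i]))
  }
  tkmers <- lapply(targets, function(t) {
    n <- nchar(t$seq)
    if (n < k) return(character(0))
    substring(t$seq, 1:(n - k + 1L), k:n)
  })
  union_kmers <- unique(unlist(tkmers, use.names = FALSE))

  # candidate mates: any anchor k-mer occurs in any model strand
  cand <- rep(FALSE, total)
  anchor_seqs <- vector("list", length(anchor_offs))
  for (a in seq_along(anchor_offs)) {
    anchor_seqs[[a]] <- substr(mates, anchor_offs[a],
                               anchor_offs[a] + k - 1L)
    cand <- cand | (anchor_seqs[[a]] %in% union_kmers)
  }
  ci <- which(cand)
  n_cand <- length(ci)
  counts <- stats::setNames(integer(nrow(models)), models$genotype_id)
  ambiguous <- 0L; noncovering <- 0L; assigned_total <- 0L

  if (n_cand > 0L) {
    mm <- matrix(Inf, nrow = n_cand, ncol = length(targets))
    off_mat <- matrix(NA_integer_, nrow = n_cand, ncol = length(targets))
    cand_mates <- mates[ci]
    anchor_cand <- lapply(anchor_seqs, function(x) x[ci])
    for (ti in seq_along(targets)) {
      tseq <- targets[[ti]]$seq
      tn <- nchar(tseq)
      if (tn < L) next
      # each anchor proposes an offset; keep the best-verifying one (repeat
      # sequence such as a telomere tract can misanchor a single k-mer)
      best_mm <- rep(Inf, n_cand)
      best_off <- rep(NA_integer_, n_cand)
      for (a in seq_along(anchor_offs)) {
        offs <- match(anchor_cand[[a]], tkmers[[ti]]) - anchor_offs[a] + 1L
        ok <- which(!is.na(offs) & offs >= 1L & offs + L - 1L <= tn &
                    (is.na(best_off) | offs != best_off))
        if (length(ok) == 0L) next
        refs <- substring(tseq, offs[ok], offs[ok] + L - 1L)
        mmv <- mapply(hamming, refs, cand_mates[ok], USE.NAMES = FALSE)
        upd <- mmv < best_mm[ok]
        best_mm[ok[upd]] <- mmv[upd]
        best_off[ok[upd]] <- offs[ok][upd]
      }
      mm[, ti] <- best_mm
      off_mat[, ti] <- best_off
    }
    # collapse strands: best score per model
    n_models <- nrow(models)
    mm_model <- matrix(Inf, n_cand, n_models)
    for (w in seq_len(n_models))
      mm_model[, w] <- pmin(mm[, 2L * w - 1L], mm[, 2L * w])
    best <- suppressWarnings(apply(mm_model, 1L, min))
    for (r in seq_len(n_cand)) {
      if (!is.finite(best[r]) || best[r] > max_mismatches_per_read) next
      winners <- which(mm_model[r, ] == best[r])
      if (length(winners) > 1L) { ambiguous <- ambiguous + 1L; next }
      w <- winners[1]
      ti <- if (mm[r, 2L * w - 1L] <= mm[r, 2L * w]) 2L * w - 1L else 2L * w
      off <- off_mat[r, ti]
      tn <- nchar(targets[[ti]]$seq)
      span <- if (targets[[ti]]$strand == "+") c(off, off + L - 1L) else
        c(tn - (off + L - 1L) + 1L, tn - off + 1L)
      vp <- models$variant_pos[w]
      if (vp - span[1] + 1L >= min_overlap && span[2] - vp + 1L >= min_overlap) {
        counts[w] <- counts[w] + 1L
        assigned_total <- assigned_total + 1L
      } else noncovering <- noncovering + 1L
    }
  }
  list(counts = data.frame(genotype_id = models$genotype_id,
                           reads = unname(counts),
                           stringsAsFactors = FALSE),
       ambiguous = ambiguous, noncovering = noncovering,
       unassigned = total - assigned_total - ambiguous - noncovering,
       retained = assigned_total, total_mates = total)
}

#' Summarise read support per genotype and class
#'
#' Relative support is computed over retained (assigned) reads only;
#' class-level support sums genotype fractions per class; targeting
#' efficiency is the summed relative read support of all non-wildtype
#' genotypes (1 minus the WT fraction).
#'
#' @param assignments Output of [assign_reads()].
#' @param models The genotype models the assignment used.
#' @param min_reads Genotypes below this absolute read count are flagged
#'   `minor_genotype` (mixed colonies that retained the CRISPR plasmid) but
#'   never dropped.
#' @return List: `per_genotype`, `per_class`, `targeting_efficiency`,
#'   `no_coverage`, `discarded_ambiguous`, `discarded_unassigned`.
#' @export
support_table <- function(assignments, models, min_reads = 5L) {
  ct <- merge(assignments$counts,
              models[, c("genotype_id", "class")], by = "genotype_id",
              sort = FALSE)
  tot <- sum(ct$reads)
  if (tot == 0L) {
    return(list(per_genotype = transform(ct, relative_support = NA_real_,
                                         minor_genotype = NA),
                per_class = NULL, targeting_efficiency = NA_real_,
                no_coverage = TRUE,
                discarded_ambiguous = assignments$ambiguous,
                discarded_unassigned = assignments$unassigned))
  }
  ct$relative_support <- ct$reads / tot
  ct$minor_genotype <- ct$reads > 0L & ct$reads < min_reads
  pc <- stats::aggregate(cbind(reads, relative_support) ~ class, data = ct,
                         FUN = sum)
  pc$n_genotypes <- stats::aggregate(reads ~ class, data = ct,
                                     FUN = function(x) sum(x > 0L))$reads
  wt <- ct$relative_support[ct$class == "WT"]
  eff <- 1 - sum(wt)
  list(per_genotype = ct, per_class = pc, targeting_efficiency = eff,
       no_coverage = FALSE,
       discarded_ambiguous = assignments$ambiguous,
       discarded_unassigned = assignments$unassigned)
}
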