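# Caller-agnostic variant-call records mirroring VCF 4.2 semantics, plus
# serialization. Small variants are left-anchored REF/ALT records; SVs are
# paired BND records (MATEID), symbolic <INV> records, or single breakends
# ("...xxx." ALT) for one-sided junctions such as telomere-capped truncations.

#' Construct a variant-call table
#'
#' A zero-argument call returns the empty prototype; otherwise all vector
#' arguments are recycled to a common length.
#'
#' @param variant_id,sample_id,chrom,pos,ref,alt Core VCF-like fields
#'   (1-based `pos`).
#' @param type One of `"SNV"`, `"insertion"`, `"deletion"`, `"SV"`.
#' @param net_len Signed net length change in bp (0 for SNV/BND).
#' @param end END coordinate for symbolic SVs (`NA` otherwise).
#' @param mate_id MATEID of the partner breakend (`NA` otherwise).
#' @param chrom2,pos2 Partner locus of a breakend/symbolic SV.
#' @param inserted_seq Sequence inserted at a junction (may be `""`).
#' @param telomere_capped Logical truncation flag.
#' @param support_reads Supporting-read count (NA when unknown).
#' @param colony_mode `"single"` or `"pooled-5"`.
#' @return A `data.frame` with one row per call.
#' @export
variant_call_table <- function(variant_id = character(0),
                               sample_id = character(0),
                               chrom = character(0), pos = integer(0),
                               ref = character(0), alt = character(0),
                               type = character(0), net_len = integer(0),
                               end = NA_integer_, mate_id = NA_character_,
                               chrom2 = NA_character_, pos2 = NA_integer_,
                               inserted_seq = "", telomere_capped = FALSE,
                               support_reads = NA_integer_,
                               colony_mode = "pooled-5") {
  n <- max(length(variant_id), length(chrom), length(pos))
  if (n == 0L) {
    return(data.frame(variant_id = character(0), sample_id = character(0),
                      chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      type = character(0), net_len = integer(0),
                      end = integer(0), mate_id = character(0),
                      chrom2 = character(0), pos2 = integer(0),
                      inserted_seq = character(0),
                      telomere_capped = logical(0),
                      support_reads = integer(0),
                      colony_mode = character(0), stringsAsFactors = FALSE))
  }
  data.frame(variant_id = rep_len(variant_id, n),
             sample_id = rep_len(sample_id, n),
             chrom = rep_len(chrom, n), pos = rep_len(as.integer(pos), n),
             ref = rep_len(ref, n), alt = rep_len(alt, n),
             type = rep_len(type, n), net_len = rep_len(as.integer(net_len), n),
             end = rep_len(as.integer(end), n),
             mate_id = rep_len(mate_id, n),
             chrom2 = rep_len(chrom2, n), pos2 = rep_len(as.integer(pos2), n),
             inserted_seq = rep_len(inserted_seq, n),
             telomere_capped = rep_len(telomere_capped, n),
             support_reads = rep_len(as.integer(support_reads), n),
             colony_mode = rep_len(colony_mode, n),
             stringsAsFactors = FALSE)
}

# 1-based inclusive reference span of each call. Insertions occupy their
# single anchor base; breakends occupy their locus base; symbolic SVs span
# POS..END.
variant_ref_span <- function(calls) {
  start <- calls$pos
  end <- calls$pos
  plain <- !grepl("[][<.]", calls$alt) | calls$alt == "."
  end[plain] <- calls$pos[plain] + nchar(calls$ref[plain]) - 1L
  sym <- startsWith(calls$alt, "<") & !is.na(calls$end)
  end[sym] <- calls$end[sym]
  data.frame(chrom = calls$chrom, start = start, end = end)
}

is_breakend_alt <- function(alt) {
  grepl("\\[|\\]", alt) | (grepl("^[ACGTN]+\\.$", alt) | grepl("^\\.[ACGTN]+$", alt))
}

#' Write variant calls as VCF 4.2
#'
#' @param calls Variant-call data.frame (see [variant_call_table()]).
#' @param path Output path (plain text).
#' @param genome Optional [AnnotatedGenome] for contig header lines.
#' @param sample_id Value for the single sample column; defaults to the
#'   calls' `sample_id` (which must then be constant).
#' @export
vcf_write <- function(calls, path, genome = NULL, sample_id = NULL) {
  if (is.null(sample_id)) {
    sample_id <- unique(calls$sample_id)
    if (length(sample_id) == 0L) sample_id <- "sample"
    if (length(sample_id) > 1L)
      stop("calls span several samples; write one VCF per sample")
  }
  hdr <- c("##fileformat=VCFv4.2",
           "##source=editAftermath",
           '##INFO=<ID=SVTYPE,Number=1,Type=String,Description="SV class">',
           '##INFO=<ID=END,Number=1,Type=Integer,Description="End of symbolic SV">',
           '##INFO=<ID=MATEID,Number=1,Type=String,Description="Partner breakend">',
           '##INFO=<ID=NETLEN,Number=1,Type=Integer,Description="Signed net length change">',
           '##INFO=<ID=TELCAP,Number=0,Type=Flag,Description="Telomere-capped truncation junction">',
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           '##FORMAT=<ID=AD,Number=1,Type=Integer,Description="Supporting reads">')
  if (!is.null(genome))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(genome$chromosomes), chrom_lengths(genome)))
  hdr <- c(hdr, paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", sample_id, sep = "\t"))
  calls <- calls[order(calls$chrom, calls$pos), , drop = FALSE]
  info <- vapply(seq_len(nrow(calls)), function(i) {
    x <- calls[i, ]
    parts <- c(sprintf("NETLEN=%d", x$net_len))
    if (x$type == "SV") {
      svtype <- if (!is.na(x$mate_id)) "BND"
        else if (startsWith(x$alt, "<")) gsub("[<>]", "", x$alt)
        else "BND"
      parts <- c(sprintf("SVTYPE=%s", svtype), parts)
    }
    if (!is.na(x$end)) parts <- c(parts, sprintf("END=%d", x$end))
    if (!is.na(x$mate_id)) parts <- c(parts, sprintf("MATEID=%s", x$mate_id))
    if (isTRUE(x$telomere_capped)) parts <- c(parts, "TELCAP")
    paste(parts, collapse = ";")
  }, character(1))
  ad <- ifelse(is.na(calls$support_reads), ".", calls$support_reads)
  body <- sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\t%s\tGT:AD\t./.:%s",
                  calls$chrom, calls$pos, calls$variant_id, calls$ref,
                  calls$alt, info, ad)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a VCF into a variant-call table
#'
#' Format parsing is delegated to [vcfR::read.vcfR()]; breakend/symbolic ALT
#' semantics (partner locus, inserted sequence, net length) are interpreted
#' here.
#'
#' @param path VCF path.
#' @param sample_id Sample label to assign (default: file stem).
#' @param colony_mode `"single"` or `"pooled-5"`.
#' @return A variant-call data.frame.
#' @export
vcf_read <- function(path, sample_id = NULL,
                     colony_mode = "pooled-5") {
  if (is.null(sample_id))
    sample_id <- sub("\\.vcf(\\.gz)?$", "", basename(path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (nrow(fx) == 0L) return(variant_call_table())
  info_get <- function(key, numeric = FALSE) {
    x <- vcfR::extract.info(v, element = key)
    if (numeric) suppressWarnings(as.integer(x)) else x
  }
  netlen <- info_get("NETLEN", numeric = TRUE)
  endv <- info_get("END", numeric = TRUE)
  mate <- info_get("MATEID")
  telcap <- !is.na(vcfR::extract.info(v, element = "TELCAP"))
  ad <- tryCatch({
    m <- vcfR::extract.gt(v, element = "AD")
    suppressWarnings(as.integer(m[, 1]))
  }, error = function(e) rep(NA_integer_, nrow(fx)))

  alt <- fx$ALT
  ref <- fx$REF
  pos <- as.integer(fx$POS)
  bnd <- grepl("\\[|\\]", alt)
  single_bnd <- grepl("^[ACGTN]+.*\\.$", alt) & !bnd
  symbolic <- startsWith(alt, "<")
  type <- ifelse(bnd | single_bnd | symbolic, "SV",
          ifelse(nchar(ref) == 1L & nchar(alt) == 1L, "SNV",
          ifelse(nchar(alt) > nchar(ref), "insertion", "deletion")))
  if (any(is.na(netlen)))
    netlen[is.na(netlen)] <-
      ifelse(type[is.na(netlen)] %in% c("insertion", "deletion"),
             nchar(alt[is.na(netlen)]) - nchar(ref[is.na(netlen)]), 0L)
  # partner locus from bracketed ALT
  chrom2 <- rep(NA_character_, length(alt))
  pos2 <- rep(NA_integer_, length(alt))
  has <- grepl("[][][^]:[]+:[0-9]+[][]", alt)
  loc <- sub("^[][]", "", sub("[][]$", "", regmatches(
    alt, regexpr("[][][^]:[]+:[0-9]+[][]", alt))))
  chrom2[has] <- sub(":.*$", "", loc)
  pos2[has] <- as.integer(sub("^.*:", "", loc))
  symp <- symbolic & !is.na(endv)
  chrom2[symp] <- fx$CHROM[symp]
  pos2[symp] <- endv[symp]
  ins <- rep("", length(alt))
  ins[single_bnd] <- substr(alt[single_bnd], 2L, nchar(alt[single_bnd]) - 1L)

  variant_call_table(
    variant_id = ifelse(is.na(fx$ID) | fx$ID == ".",
                        sprintf("var%05d", seq_along(alt)), fx$ID),
    sample_id = sample_id, chrom = fx$CHROM, pos = pos, ref = ref, alt = alt,
    type = type, net_len = netlen, end = endv, mate_id = mate,
    chrom2 = chrom2, pos2 = pos2, inserted_seq = ins,
    telomere_capped = telcap, support_reads = ad, colony_mode = colony_mode)
}
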