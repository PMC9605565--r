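# Filtering raw variant calls down to candidate de novo mutations (DNMs):
# base-strain subtraction, recurrent-SNV exclusion, blacklist masking,
# coding-effect annotation, on/off-target classification and the per-sample
# count ledger.

variant_key <- function(calls) {
  paste(calls$chrom, calls$pos, calls$ref, calls$alt, sep = "|")
}

# Breakend-aware matching: an SV matches a base-strain SV if both loci agree
# within `tolerance` bp (partner loci compared when present).
sv_matches <- function(calls, base, tolerance) {
  if (nrow(calls) == 0L || nrow(base) == 0L)
    return(rep(FALSE, nrow(calls)))
  vapply(seq_len(nrow(calls)), function(i) {
    x <- calls[i, ]
    cand <- base[base$chrom == x$chrom &
                 abs(base$pos - x$pos) <= tolerance, , drop = FALSE]
    if (nrow(cand) == 0L) return(FALSE)
    if (is.na(x$chrom2)) return(any(is.na(cand$chrom2)))
    any(!is.na(cand$chrom2) & cand$chrom2 == x$chrom2 &
        abs(cand$pos2 - x$pos2) <= tolerance)
  }, logical(1))
}

#' Subtract base-strain variants
#'
#' Removes calls already present in the sequenced base strain. Small variants
#' match on exact (chromosome, position, REF, ALT); SVs match by breakend
#' loci within a positional tolerance (caller jitter).
#'
#' @param calls,base_strain_calls Variant-call data.frames on the same
#'   reference frame.
#' @param sv_tolerance Per-breakend matching tolerance in bp.
#' @return The subset of `calls` with no base-strain match.
#' @export
subtract_base_strain <- function(calls, base_strain_calls, sv_tolerance = 10L) {
  if (nrow(calls) == 0L) return(calls)
  small <- calls$type != "SV"
  drop <- logical(nrow(calls))
  drop[small] <- variant_key(calls[small, , drop = FALSE]) %in%
    variant_key(base_strain_calls[base_strain_calls$type != "SV", ,
                                  drop = FALSE])
  drop[!small] <- sv_matches(calls[!small, , drop = FALSE],
                             base_strain_calls[base_strain_calls$type == "SV", ,
                                               drop = FALSE],
                             sv_tolerance)
  calls[!drop, , drop = FALSE]
}

#' Drop variants recurring across experiments with distinct guides
#'
#' A variant observed in at least `min_experiments` experiments is removed
#' everywhere, provided (when `require_distinct_guides`) that at least two of
#' those experiments used disjoint guide sets -- recurrence across unrelated
#' guides marks a base-strain artefact rather than a CRISPR effect.
#'
#' @param calls_by_experiment Named list of variant-call data.frames, one per
#'   experiment.
#' @param guide_sets Named list (same names) of guide-id character vectors
#'   used by each experiment.
#' @param min_experiments Occurrence threshold (default 2).
#' @param require_distinct_guides Require two occurrences with disjoint
#'   guide sets.
#' @return List with `calls` (the filtered list) and `removed` (a log of
#'   removed keys with their occurrence lists).
#' @export
drop_recurrent <- function(calls_by_experiment, guide_sets,
                           min_experiments = 2L,
                           require_distinct_guides = TRUE) {
  stopifnot(!is.null(names(calls_by_experiment)),
            all(names(calls_by_experiment) %in% names(guide_sets)))
  occ <- lapply(names(calls_by_experiment), function(ex) {
    k <- unique(variant_key(calls_by_experiment[[ex]]))
    if (length(k) == 0L) return(NULL)
    data.frame(key = k, experiment = ex, stringsAsFactors = FALSE)
  })
  occ <- do.call(rbind, occ)
  removed_keys <- character(0)
  log <- data.frame(key = character(0), experiments = character(0),
                    stringsAsFactors = FALSE)
  if (!is.null(occ)) {
    for (k in unique(occ$key)) {
      exps <- occ$experiment[occ$key == k]
      if (length(exps) < min_experiments) next
      if (require_distinct_guides) {
        gs <- guide_sets[exps]
        disjoint <- FALSE
        for (a in seq_along(gs)) for (b in seq_along(gs)) {
          if (a < b && length(intersect(gs[[a]], gs[[b]])) == 0L)
            disjoint <- TRUE
        }
        if (!disjoint) next
      }
      removed_keys <- c(removed_keys, k)
      log <- rbind(log, data.frame(key = k,
                                   experiments = paste(exps, collapse = ","),
                                   stringsAsFactors = FALSE))
    }
  }
  out <- lapply(calls_by_experiment, function(df)
    df[!(variant_key(df) %in% removed_keys), , drop = FALSE])
  list(calls = out, removed = log)
}

#' Annotate coding effect of variants
#'
#' A variant is `coding` iff its reference span intersects any CDS interval.
#' Coding indels are `frameshift` when the net length change is not a
#' multiple of 3, `in-frame` otherwise; SNVs and balanced SVs get
#' frame-effect `none`.
#'
#' @param calls Variant-call data.frame.
#' @param genome An [AnnotatedGenome] (genes are single-exon CDS records).
#' @return `calls` with added columns `coding` (logical) and `frame_effect`.
#' @export
annotate_coding_effect <- function(calls, genome) {
  if (nrow(calls) == 0L) {
    calls$coding <- logical(0); calls$frame_effect <- character(0)
    return(calls)
  }
  vs <- variant_ref_span(calls)
  g <- genome$genes
  coding <- vapply(seq_len(nrow(calls)), function(i) {
    any(g$chrom == vs$chrom[i] & g$start <= vs$end[i] & g$end >= vs$start[i])
  }, logical(1))
  indel <- calls$net_len != 0L
  frame <- ifelse(coding & indel,
                  ifelse(calls$net_len %% 3L == 0L, "in-frame", "frameshift"),
                  "none")
  calls$coding <- coding
  calls$frame_effect <- frame
  calls
}

#' Classify calls as on- or off-target
#'
#' On-target iff the variant's reference span lies within `radius` bp of any
#' experiment guide's cut locus, or the call is a breakend whose partner
#' locus does.
#'
#' @param calls Variant-call data.frame.
#' @param guides Guide data.frame (`chrom`, `cut_locus`).
#' @param on_target_radius Radius in bp around the cut locus.
#' @return Character vector `"on-target"`/`"off-target"` per call.
#' @export
classify_on_vs_off_target <- function(calls, guides, on_target_radius = 100L) {
  if (nrow(calls) == 0L) return(character(0))
  vs <- variant_ref_span(calls)
  near_cut <- function(chrom, start, end) {
    if (is.na(chrom)) return(FALSE)
    any(guides$chrom == chrom &
        guides$cut_locus >= start - on_target_radius &
        guides$cut_locus <= end + on_target_radius)
  }
  vapply(seq_len(nrow(calls)), function(i) {
    hit <- near_cut(vs$chrom[i], vs$start[i], vs$end[i]) ||
      near_cut(calls$chrom2[i], calls$pos2[i], calls$pos2[i])
    if (hit) "on-target" else "off-target"
  }, character(1))
}

# {SNV, InDel, SV} grouping used by the ledger: explicit-allele indels of
# >= 50 bp count as SVs.
variant_type_group <- function(calls) {
  ifelse(calls$type == "SNV", "SNV",
         ifelse(calls$type == "SV" | abs(calls$net_len) >= 50L, "SV", "InDel"))
}

#' Run the full DNM triage for one experiment
#'
#' Applies, in order: blacklist masking, base-strain subtraction and (when
#' several experiments are supplied to [drop_recurrent()] beforehand)
#' recurrence filtering; then annotates coding effect and on/off-target
#' status. Every input call is assigned exactly one fate.
#'
#' @param calls Variant-call data.frame for the experiment.
#' @param base_strain_calls Base-strain variant-call data.frame.
#' @param genome An [AnnotatedGenome].
#' @param guides Guide data.frame for the experiment.
#' @param blacklist Optional data.frame (`chrom`, `start`, `end`) of
#'   reference-error regions to mask (accepted as a BED file in the CLI).
#' @param on_target_radius,sv_tolerance See the respective operations.
#' @param min_support_fraction For pooled samples with a recorded
#'   supporting-read count and local depth, calls below this fraction are
#'   dropped as unsupported (default 1/10 of depth: half a colony's share
#'   in a pool of five). Ignored when depth is unknown.
#' @param depth Optional named local depth per call id.
#' @return List: `dnms` (annotated DNM calls with `target_status`),
#'   `fate_log` (one row per input call), `ledger` (see [build_ledger()]).
#' @export
triage_calls <- function(calls, base_strain_calls, genome, guides,
                         blacklist = NULL, on_target_radius = 100L,
                         sv_tolerance = 10L, min_support_fraction = 0.1,
                         depth = NULL) {
  fate <- rep(NA_character_, nrow(calls))
  names(fate) <- calls$variant_id

  if (!is.null(blacklist) && nrow(blacklist) > 0L && nrow(calls) > 0L) {
    vs <- variant_ref_span(calls)
    masked <- vapply(seq_len(nrow(calls)), function(i) {
      any(blacklist$chrom == vs$chrom[i] & blacklist$start <= vs$end[i] &
          blacklist$end >= vs$start[i])
    }, logical(1))
    fate[masked] <- "blacklisted"
  }
  live <- calls[is.na(fate), , drop = FALSE]
  kept <- subtract_base_strain(live, base_strain_calls, sv_tolerance)
  fate[setdiff(live$variant_id, kept$variant_id)] <- "pre-existing"

  if (!is.null(depth) && nrow(kept) > 0L) {
    frac <- kept$support_reads / depth[kept$variant_id]
    weak <- !is.na(frac) & frac < min_support_fraction
    fate[kept$variant_id[weak]] <- "low-support"
    kept <- kept[!weak, , drop = FALSE]
  }

  dnms <- annotate_coding_effect(kept, genome)
  dnms$target_status <- classify_on_vs_off_target(dnms, guides,
                                                  on_target_radius)
  fate[dnms$variant_id] <- paste0(dnms$target_status, "-DNM")

  fate_log <- data.frame(variant_id = calls$variant_id,
                         sample_id = calls$sample_id,
                         type_group = variant_type_group(calls),
                         fate = unname(fate[calls$variant_id]),
                         stringsAsFactors = FALSE)
  list(dnms = dnms, fate_log = fate_log,
       ledger = build_ledger(calls, dnms, fate_log))
}

#' Build the per-sample DNM count ledger
#'
#' Tabulates, per sample and variant type group (SNV / InDel / SV): total
#' calls, DNMs, on- and off-target DNMs, coding off-target DNMs and
#' CRISPR-proximal off-target DNMs (those with a candidate binding site
#' nearby, when `site_hits` is given).
#'
#' @param calls All input calls (for the totals).
#' @param dnms Annotated DNMs from [triage_calls()].
#' @param fate_log Fate log from [triage_calls()] (unused beyond validation;
#'   retained so ledgers can be rebuilt from logs).
#' @param site_hits Optional [sites_near_variants()] output.
#' @return Ledger data.frame, one row per (sample, type group).
#' @export
build_ledger <- function(calls, dnms, fate_log = NULL, site_hits = NULL) {
  groups <- c("SNV", "InDel", "SV")
  samples <- unique(calls$sample_id)
  if (length(samples) == 0L) samples <- character(0)
  rows <- list()
  tg_all <- variant_type_group(calls)
  tg_dnm <- variant_type_group(dnms)
  for (s in samples) for (g in groups) {
    in_all <- calls$sample_id == s & tg_all == g
    in_dnm <- dnms$sample_id == s & tg_dnm == g
    d <- dnms[in_dnm, , drop = FALSE]
    off <- d[d$target_status == "off-target", , drop = FALSE]
    # "counted" off-target variants must overlap the site span (PAM included)
    proximal <- if (!is.null(site_hits) && nrow(off) > 0L) {
      counted <- site_hits$variant_id[site_hits$relationship == "overlaps-site"]
      sum(off$variant_id %in% counted)
    } else NA_integer_
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = s, type = g,
      total_calls = sum(in_all),
      dnms = nrow(d),
      on_target = sum(d$target_status == "on-target"),
      off_target = nrow(off),
      coding_off_target = sum(off$coding),
      crispr_proximal_off_target = proximal,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, c(rows, list(data.frame(
    sample_id = character(0), type = character(0), total_calls = integer(0),
    dnms = integer(0), on_target = integer(0), off_target = integer(0),
    coding_off_target = integer(0),
    crispr_proximal_off_target = integer(0)))))
}

#' Read a blacklist BED file
#'
#' @param path BED path (0-based half-open, per the BED standard; returned
#'   coordinates are converted to 1-based inclusive).
#' @export
read_blacklist_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
             start = BiocGenerics::start(gr), end = BiocGenerics::end(gr),
             stringsAsFactors = FALSE)
}
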