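# Per-colony CRISPR repair outcomes: planning (stochastic draw of one outcome
# per target locus), sequence surgery (apply_edits), and conversion to
# VCF-shaped truth records.
#
# Outcome classes follow the four-way on-target taxonomy (wildtype, small
# indel < 50 bp, indel >= 50 bp, structural rearrangement) extended with
# telomere-capped truncations and exact inversions, which pooled double-target
# experiments produce.

EDIT_CLASSES <- c("none", "small_indel", "large_indel",
                  "rearrangement", "truncation", "inversion")
JOINT_CLASSES <- c("rearrangement", "inversion")

empty_edit_table <- function() {
  data.frame(edit_id = character(0), class = character(0),
             target_id = character(0),
             chrom = character(0), pos = integer(0),
             ref = character(0), alt = character(0),
             chrom2 = character(0), pos2 = integer(0),
             inserted_seq = character(0),
             net_len = integer(0), telomere_capped = logical(0),
             stringsAsFactors = FALSE)
}

edit_row <- function(edit_id, class, target_id, chrom, pos, ref = "", alt = "",
                     chrom2 = NA_character_, pos2 = NA_integer_,
                     inserted_seq = "", net_len = 0L,
                     telomere_capped = FALSE) {
  data.frame(edit_id = edit_id, class = class, target_id = target_id,
             chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
             chrom2 = chrom2, pos2 = as.integer(pos2),
             inserted_seq = inserted_seq, net_len = as.integer(net_len),
             telomere_capped = telomere_capped, stringsAsFactors = FALSE)
}

# Reference footprint of an edit, used for the mutual-overlap invariant.
edit_ref_spans <- function(edits, genome) {
  spans <- vector("list", nrow(edits))
  for (i in seq_len(nrow(edits))) {
    e <- edits[i, ]
    spans[[i]] <- switch(e$class,
      none = NULL,
      small_indel = ,
      large_indel = data.frame(chrom = e$chrom, start = e$pos,
                               end = e$pos + nchar(e$ref) - 1L),
      truncation = data.frame(chrom = e$chrom, start = e$pos,
                              end = nchar(chrom_seq(genome, e$chrom))),
      inversion = data.frame(chrom = e$chrom, start = e$pos + 1L,
                             end = e$pos2),
      rearrangement = data.frame(chrom = c(e$chrom, e$chrom2),
                                 start = c(e$pos, e$pos2),
                                 end = c(e$pos, e$pos2)))
  }
  do.call(rbind, c(spans, list(data.frame(chrom = character(0),
                                          start = integer(0),
                                          end = integer(0)))))
}

check_edit_overlap <- function(edits, genome) {
  if (nrow(edits) < 2L) return(invisible(TRUE))
  for (i in seq_len(nrow(edits) - 1L)) for (j in seq(i + 1L, nrow(edits))) {
    si <- edit_ref_spans(edits[i, ], genome)
    sj <- edit_ref_spans(edits[j, ], genome)
    if (is.null(si) || is.null(sj) || nrow(si) == 0L || nrow(sj) == 0L) next
    for (a in seq_len(nrow(si))) for (b in seq_len(nrow(sj))) {
      if (si$chrom[a] == sj$chrom[b] &&
          si$start[a] <= sj$end[b] && sj$start[b] <= si$end[a])
        stop("overlapping edits on the reference: '", edits$edit_id[i],
             "' and '", edits$edit_id[j], "'")
    }
  }
  invisible(TRUE)
}

#' Plan per-colony CRISPR repair outcomes
#'
#' Draws one repair outcome per target locus for each colony (a joint
#' rearrangement or inversion replaces both loci of a double-target
#' experiment), assigns colonies to sequencing pools, and returns the truth
#' manifest used downstream for recovery tests.
#'
#' @param genome Reference [AnnotatedGenome] (alleles are read from it).
#' @param guides Guide table (`guide_id`, `chrom`, `cut_locus`); one or two
#'   rows (single- or double-target experiment).
#' @param n_colonies Number of colonies to draw.
#' @param class_probabilities Named numeric vector/list over
#'   `r paste(EDIT_CLASSES, collapse = ", ")`; must sum to 1 (tolerance 1e-9).
#'   Joint classes (`rearrangement`, `inversion`) require two guides;
#'   `rearrangement` requires guides on different chromosomes and
#'   `inversion` guides on the same chromosome.
#' @param indel_size_model List with `small = c(min, max)` and
#'   `large = c(min, max)` uniform size ranges (bp).
#' @param deletion_prob Probability that an indel is a deletion (vs
#'   insertion), per size class: `c(small = , large = )`.
#' @param pool_size Colonies per sequencing pool (1--5; pools are filled in
#'   colony order).
#' @param telomere_motif,telomere_copies Telomere repeat appended at
#'   truncation breaks (shared configuration with [detect_truncation()]).
#' @param seed Integer seed.
#' @param experiment_id Prefix for colony ids.
#' @param design Optional fixed outcome design overriding the stochastic
#'   class draw: a list with one element per colony, each either a character
#'   vector of per-locus classes (length = number of guides) or a single
#'   joint class (`"rearrangement"`/`"inversion"`). Indel sizes and alleles
#'   are still drawn from the configured models. `n_colonies` and
#'   `class_probabilities` are ignored when `design` is given.
#' @return List of `ColonyTruth` objects: `list(colony_id, pool_id, edits)`
#'   with `edits` a data.frame of edit events.
#' @export
plan_colony_outcomes <- function(genome, guides, n_colonies,
                                 class_probabilities,
                                 indel_size_model = list(small = c(1, 10),
                                                         large = c(50, 1200)),
                                 deletion_prob = c(small = 0.6, large = 0.8),
                                 pool_size = 5L,
                                 telomere_motif = default_telomere_motif(),
                                 telomere_copies = 25L,
                                 seed = 1L,
                                 experiment_id = "exp1",
                                 design = NULL) {
  if (!is.null(design)) {
    n_colonies <- length(design)
    class_probabilities <- list(none = 1)   # placeholder; draw is bypassed
  }
  p <- unlist(class_probabilities)
  if (!all(names(p) %in% EDIT_CLASSES))
    stop("unknown outcome class(es): ",
         paste(setdiff(names(p), EDIT_CLASSES), collapse = ", "))
  if (abs(sum(p) - 1) > 1e-9) stop("class probabilities must sum to 1")
  full <- stats::setNames(numeric(length(EDIT_CLASSES)), EDIT_CLASSES)
  full[names(p)] <- p
  n_guides <- nrow(guides)
  stopifnot(n_guides %in% c(1L, 2L), pool_size >= 1L, pool_size <= 5L)
  if (sum(full[JOINT_CLASSES]) > 0 && n_guides != 2L)
    stop("rearrangement/inversion outcomes require exactly two guides")
  if (n_guides == 2L) {
    same_chrom <- guides$chrom[1] == guides$chrom[2]
    if (full["rearrangement"] > 0 && same_chrom)
      stop("rearrangement outcomes require guides on different chromosomes")
    if (full["inversion"] > 0 && !same_chrom)
      stop("inversion outcomes require guides on the same chromosome")
  }
  p_joint <- sum(full[JOINT_CLASSES])
  local_p <- full[c("none", "small_indel", "large_indel", "truncation")]
  if (p_joint < 1 && sum(local_p) <= 0)
    stop("per-locus class probabilities sum to 0 but joint probability < 1")

  with_seed(seed, {
    lapply(seq_len(n_colonies), function(ci) {
      colony_id <- sprintf("%s_colony%03d", experiment_id, ci)
      pool_id <- sprintf("%s_pool%02d", experiment_id,
                         (ci - 1L) %/% pool_size + 1L)
      for (attempt in 1:50) {
        edits <- if (is.null(design)) {
          draw_colony_edits(genome, guides, full, p_joint, local_p,
                            indel_size_model, deletion_prob,
                            telomere_motif, telomere_copies, colony_id)
        } else {
          fixed_colony_edits(genome, guides, design[[ci]], indel_size_model,
                             deletion_prob, telomere_motif, telomere_copies,
                             colony_id)
        }
        ok <- tryCatch({ check_edit_overlap(edits, genome); TRUE },
                       error = function(e) FALSE)
        if (ok) break
        if (attempt == 50L)
          stop("could not draw non-overlapping edits for ", colony_id)
      }
      structure(list(colony_id = colony_id, pool_id = pool_id, edits = edits),
                class = "ColonyTruth")
    })
  })
}

# Fixed-design counterpart of draw_colony_edits: classes are prescribed,
# sizes/alleles still drawn.
fixed_colony_edits <- function(genome, guides, classes, indel_size_model,
                               deletion_prob, telomere_motif, telomere_copies,
                               colony_id) {
  bad <- setdiff(classes, EDIT_CLASSES)
  if (length(bad) > 0L) stop("unknown class(es) in design: ",
                             paste(bad, collapse = ", "))
  if (length(classes) == 1L && classes %in% JOINT_CLASSES) {
    if (nrow(guides) != 2L)
      stop("rearrangement/inversion outcomes require exactly two guides")
    return(make_joint_edit(genome, guides, classes, colony_id))
  }
  if (length(classes) != nrow(guides))
    stop("design entry must give one class per target locus")
  rows <- lapply(seq_len(nrow(guides)), function(gi)
    make_local_edit(genome, guides[gi, ], classes[gi], indel_size_model,
                    deletion_prob, telomere_motif, telomere_copies,
                    sprintf("%s_t%d", colony_id, gi)))
  do.call(rbind, c(rows, list(empty_edit_table())))
}

draw_colony_edits <- function(genome, guides, full, p_joint, local_p,
                              indel_size_model, deletion_prob,
                              telomere_motif, telomere_copies, colony_id) {
  if (p_joint > 0 && stats::runif(1) < p_joint) {
    cls <- sample(JOINT_CLASSES, 1L, prob = full[JOINT_CLASSES])
    return(make_joint_edit(genome, guides, cls, colony_id))
  }
  pp <- local_p / sum(local_p)
  rows <- lapply(seq_len(nrow(guides)), function(gi) {
    cls <- sample(names(pp), 1L, prob = pp)
    make_local_edit(genome, guides[gi, ], cls, indel_size_model,
                    deletion_prob, telomere_motif, telomere_copies,
                    sprintf("%s_t%d", colony_id, gi))
  })
  do.call(rbind, c(rows, list(empty_edit_table())))
}

make_local_edit <- function(genome, guide, cls, indel_size_model,
                            deletion_prob, telomere_motif, telomere_copies,
                            edit_id) {
  chrom <- guide$chrom
  cut <- guide$cut_locus
  seq <- chrom_seq(genome, chrom)
  L <- nchar(seq)
  if (cls == "none") return(empty_edit_table())
  if (cls %in% c("small_indel", "large_indel")) {
    rng <- indel_size_model[[sub("_indel", "", cls)]]
    d <- sample(seq(rng[1], rng[2]), 1L)
    dp <- deletion_prob[[sub("_indel", "", cls)]]
    is_del <- stats::runif(1) < dp
    if (is_del) {
      pos <- cut - d %/% 2L - 1L          # left anchor base kept in ALT
      pos <- max(1L, min(pos, L - d))
      ref <- substr(seq, pos, pos + d)
      alt <- substr(seq, pos, pos)
      net <- -d
    } else {
      pos <- cut
      ref <- substr(seq, pos, pos)
      alt <- paste0(ref, random_dna(d))
      net <- d
    }
    return(edit_row(edit_id, cls, guide$guide_id, chrom, pos, ref, alt,
                    net_len = net))
  }
  if (cls == "truncation") {
    tel <- strrep(telomere_motif, telomere_copies)
    net <- -(L - (cut - 1L)) + nchar(tel)
    return(edit_row(edit_id, cls, guide$guide_id, chrom, cut,
                    ref = substr(seq, cut - 1L, cut - 1L),
                    inserted_seq = tel, net_len = net,
                    telomere_capped = TRUE))
  }
  stop("unhandled per-locus class: ", cls)
}

make_joint_edit <- function(genome, guides, cls, colony_id) {
  g1 <- guides[1, ]; g2 <- guides[2, ]
  id <- sprintf("%s_joint", colony_id)
  if (cls == "rearrangement" && g1$chrom == g2$chrom)
    stop("rearrangement outcomes require guides on different chromosomes")
  if (cls == "inversion" && g1$chrom != g2$chrom)
    stop("inversion outcomes require guides on the same chromosome")
  if (cls == "rearrangement") {
    return(edit_row(id, "rearrangement",
                    paste(g1$guide_id, g2$guide_id, sep = "+"),
                    chrom = g1$chrom, pos = g1$cut_locus,
                    chrom2 = g2$chrom, pos2 = g2$cut_locus))
  }
  # inversion: canonical order along the chromosome
  c1 <- min(g1$cut_locus, g2$cut_locus)
  c2 <- max(g1$cut_locus, g2$cut_locus)
  edit_row(id, "inversion", paste(g1$guide_id, g2$guide_id, sep = "+"),
           chrom = g1$chrom, pos = c1, chrom2 = g1$chrom, pos2 = c2)
}

#' Default telomere repeat motif
#'
#' The 8-mer appended (in tandem) at simulated truncation breaks and searched
#' for by [detect_truncation()]. A configuration value shared by simulator and
#' detector, not a biological claim.
#' @export
default_telomere_motif <- function() "TGGTGTGG"

#' Apply a colony's edits to a genome
#'
#' Performs whole-genome sequence surgery: indels splice the chromosome and
#' shift downstream coordinates; an inversion reverse-complements the segment
#' between the two cut sites; a reciprocal rearrangement exchanges the tails
#' of the two partner chromosomes; a truncation removes the 3' remainder and
#' appends the configured telomere repeat. Applying an empty edit list
#' returns a sequence-identical genome.
#'
#' @param genome Reference [AnnotatedGenome] the edit coordinates refer to.
#' @param truth A `ColonyTruth` (from [plan_colony_outcomes()]) or a bare
#'   edit data.frame.
#' @return An [AnnotatedGenome] with edited chromosome sequences (the gene
#'   table is dropped: post-edit gene coordinates are not tracked).
#' @export
apply_edits <- function(genome, truth) {
  edits <- if (inherits(truth, "ColonyTruth")) truth$edits else truth
  check_edit_overlap(edits, genome)
  chroms <- genome$chromosomes
  applied <- empty_edit_table()

  shift_at <- function(chrom, p) {
    sel <- applied$chrom == chrom & applied$pos < p
    if (!any(sel)) 0L else sum(applied$net_len[sel])
  }

  # 1. sequence-local indels, descending position per chromosome
  loc <- edits[edits$class %in% c("small_indel", "large_indel"), , drop = FALSE]
  if (nrow(loc) > 0L) {
    loc <- loc[order(loc$chrom, -loc$pos), , drop = FALSE]
    for (i in seq_len(nrow(loc))) {
      e <- loc[i, ]
      s <- chroms[[e$chrom]]
      stopifnot(substr(s, e$pos, e$pos + nchar(e$ref) - 1L) == e$ref)
      chroms[[e$chrom]] <- paste0(substr(s, 1L, e$pos - 1L), e$alt,
                                  substr(s, e$pos + nchar(e$ref), nchar(s)))
      applied <- rbind(applied, e)
    }
  }
  # 2. inversions
  inv <- edits[edits$class == "inversion", , drop = FALSE]
  for (i in seq_len(nrow(inv))) {
    e <- inv[i, ]
    p1 <- e$pos + shift_at(e$chrom, e$pos)
    p2 <- e$pos2 + shift_at(e$chrom, e$pos2)
    s <- chroms[[e$chrom]]
    chroms[[e$chrom]] <- paste0(substr(s, 1L, p1),
                                revcomp(substr(s, p1 + 1L, p2)),
                                substr(s, p2 + 1L, nchar(s)))
  }
  # 3. reciprocal rearrangements (tail exchange between two chromosomes)
  rea <- edits[edits$class == "rearrangement", , drop = FALSE]
  for (i in seq_len(nrow(rea))) {
    e <- rea[i, ]
    pa <- e$pos + shift_at(e$chrom, e$pos)
    pb <- e$pos2 + shift_at(e$chrom2, e$pos2)
    sa <- chroms[[e$chrom]]; sb <- chroms[[e$chrom2]]
    ins <- e$inserted_seq %||% ""
    chroms[[e$chrom]] <- paste0(substr(sa, 1L, pa), ins,
                                substr(sb, pb + 1L, nchar(sb)))
    chroms[[e$chrom2]] <- paste0(substr(sb, 1L, pb),
                                 substr(sa, pa + 1L, nchar(sa)))
  }
  # 4. truncations (+ telomere cap)
  tru <- edits[edits$class == "truncation", , drop = FALSE]
  for (i in seq_len(nrow(tru))) {
    e <- tru[i, ]
    p <- e$pos + shift_at(e$chrom, e$pos)
    s <- chroms[[e$chrom]]
    chroms[[e$chrom]] <- paste0(substr(s, 1L, p - 1L), e$inserted_seq)
  }
  AnnotatedGenome(chroms)
}

# Apply base-strain SNVs (no coordinate shifts) to a genome.
apply_snvs <- function(genome, snvs) {
  chroms <- genome$chromosomes
  for (i in seq_len(nrow(snvs))) {
    s <- chroms[[snvs$chrom[i]]]
    stopifnot(substr(s, snvs$pos[i], snvs$pos[i]) == snvs$ref[i])
    substr(s, snvs$pos[i], snvs$pos[i]) <- snvs$alt[i]
    chroms[[snvs$chrom[i]]] <- s
  }
  AnnotatedGenome(chroms, genome$genes)
}

#' Simulate base-strain variants
#'
#' Draws random SNVs distinguishing the sequenced base strain from the
#' reference assembly. These are present in every colony and must be removed
#' by [subtract_base_strain()] during triage.
#'
#' @param genome Reference [AnnotatedGenome].
#' @param n_snvs Number of SNVs.
#' @param seed Integer seed.
#' @param sample_id Sample label for the returned calls.
#' @param exclude Optional data.frame (`chrom`, `start`, `end`) of intervals
#'   SNVs must avoid (e.g. sequence-verified target windows).
#' @return A variant-call data.frame (see [variant_call_table()]).
#' @export
simulate_base_strain_variants <- function(genome, n_snvs, seed,
                                          sample_id = "base_strain",
                                          exclude = NULL) {
  with_seed(seed, {
    lens <- chrom_lengths(genome)
    draw_one <- function() {
      for (try in 1:1000) {
        cn <- sample(names(lens), 1L, prob = lens)
        p <- sample.int(lens[[cn]] - 1L, 1L) + 1L
        if (is.null(exclude) ||
            !any(exclude$chrom == cn & exclude$start <= p & exclude$end >= p))
          return(c(cn, p))
      }
      stop("could not place base-strain SNV outside excluded intervals")
    }
    drawn <- vapply(seq_len(n_snvs), function(i) draw_one(), character(2))
    chrom <- drawn[1, ]
    pos <- as.integer(drawn[2, ])
    ref <- substr(genome$chromosomes[chrom], pos, pos)
    alt <- vapply(ref, function(r) sample(setdiff(DNA_BASES, r), 1L),
                  character(1))
    df <- variant_call_table(
      variant_id = sprintf("base_snv%03d", seq_len(n_snvs)),
      sample_id = sample_id, chrom = chrom, pos = as.integer(pos),
      ref = ref, alt = alt, type = "SNV", net_len = 0L)
    df[order(df$chrom, df$pos), , drop = FALSE]
  })
}

#' Convert colony truths to VCF-shaped variant calls
#'
#' Indels become left-anchored REF/ALT records; rearrangements become two
#' pairs of BND records linked by MATEID; inversions become symbolic
#' `<INV>` records; truncations become single-breakend records whose ALT
#' carries the appended telomere sequence.
#'
#' @param truths List of `ColonyTruth` objects (one sample per pool is
#'   emitted, using the pool id as sample id, mirroring pooled sequencing).
#' @param genome Reference [AnnotatedGenome].
#' @param per_pool If `FALSE`, sample ids are colony ids instead.
#' @return A variant-call data.frame.
#' @export
truth_variants <- function(truths, genome, per_pool = TRUE) {
  rows <- list()
  for (tr in truths) {
    sid <- if (per_pool) tr$pool_id else tr$colony_id
    ed <- tr$edits
    for (i in seq_len(nrow(ed))) {
      e <- ed[i, ]
      rows[[length(rows) + 1L]] <- switch(e$class,
        small_indel = ,
        large_indel = variant_call_table(
          variant_id = e$edit_id, sample_id = sid, chrom = e$chrom,
          pos = e$pos, ref = e$ref, alt = e$alt,
          type = if (e$net_len < 0L) "deletion" else "insertion",
          net_len = e$net_len),
        rearrangement = bnd_records(e, genome, sid),
        inversion = variant_call_table(
          variant_id = e$edit_id, sample_id = sid, chrom = e$chrom,
          pos = e$pos, ref = substr(chrom_seq(genome, e$chrom), e$pos, e$pos),
          alt = "<INV>", type = "SV", net_len = 0L, end = e$pos2,
          chrom2 = e$chrom, pos2 = e$pos2),
        truncation = variant_call_table(
          variant_id = e$edit_id, sample_id = sid, chrom = e$chrom,
          pos = e$pos - 1L, ref = e$ref,
          alt = paste0(e$ref, e$inserted_seq, "."),
          type = "SV", net_len = e$net_len, inserted_seq = e$inserted_seq,
          telomere_capped = TRUE),
        NULL)
    }
  }
  out <- do.call(rbind, c(rows, list(variant_call_table())))
  rownames(out) <- NULL
  # identical events planted in several colonies of one pool collapse to one
  # call per sample, as a variant caller would report them
  out[!duplicated(out[, c("sample_id", "chrom", "pos", "ref", "alt")]), ,
      drop = FALSE]
}

# Two BND mate pairs describing a reciprocal tail exchange between
# chrom:pos (A) and chrom2:pos2 (B).
bnd_records <- function(e, genome, sid) {
  sa <- chrom_seq(genome, e$chrom); sb <- chrom_seq(genome, e$chrom2)
  ra <- substr(sa, e$pos, e$pos)
  rb1 <- substr(sb, e$pos2 + 1L, e$pos2 + 1L)
  rb <- substr(sb, e$pos2, e$pos2)
  ra1 <- substr(sa, e$pos + 1L, e$pos + 1L)
  ids <- paste0(e$edit_id, c("_a", "_b", "_c", "_d"))
  rbind(
    variant_call_table(ids[1], sid, e$chrom, e$pos, ra,
                       sprintf("%s[%s:%d[", ra, e$chrom2, e$pos2 + 1L),
                       type = "SV", net_len = 0L, mate_id = ids[2],
                       chrom2 = e$chrom2, pos2 = e$pos2 + 1L),
    variant_call_table(ids[2], sid, e$chrom2, e$pos2 + 1L, rb1,
                       sprintf("]%s:%d]%s", e$chrom, e$pos, rb1),
                       type = "SV", net_len = 0L, mate_id = ids[1],
                       chrom2 = e$chrom, pos2 = e$pos),
    variant_call_table(ids[3], sid, e$chrom2, e$pos2, rb,
                       sprintf("%s[%s:%d[", rb, e$chrom, e$pos + 1L),
                       type = "SV", net_len = 0L, mate_id = ids[4],
                       chrom2 = e$chrom, pos2 = e$pos + 1L),
    variant_call_table(ids[4], sid, e$chrom, e$pos + 1L, ra1,
                       sprintf("]%s:%d]%s", e$chrom2, e$pos2, ra1),
                       type = "SV", net_len = 0L, mate_id = ids[3],
                       chrom2 = e$chrom2, pos2 = e$pos2))
}

#' Write / read the truth manifest TSV
#'
#' One row per edit event plus `none` rows for wildtype loci-free colonies,
#' so every colony appears in the manifest.
#' @param truths List of `ColonyTruth`.
#' @param path TSV path.
#' @export
write_truth_tsv <- function(truths, path) {
  rows <- lapply(truths, function(tr) {
    ed <- tr$edits
    if (nrow(ed) == 0L)
      ed <- edit_row("-", "none", "-", "-", NA_integer_)
    cbind(colony_id = tr$colony_id, pool_id = tr$pool_id, ed)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
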