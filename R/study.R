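# End-to-end recovery study: set up the emulated double-target pooled
# sequencing experiment with known ground truth (all outcome classes
# represented, an imperfect microhomology planted at the rearrangement
# junction), run triage and on-target quantification, and measure recovery.

#' Run a plant-and-recover study
#'
#' Builds a multi-chromosome annotated genome, designs two unique guides on
#' different chromosomes, plants a 5 bp / 2-mismatch microhomology at the
#' future rearrangement junction, simulates base-strain SNVs and two pools of
#' five colonies whose repair outcomes cover every class (wildtype, small
#' indels, a large indel, a telomere-capped truncation and a reciprocal
#' rearrangement), sequences the pools, and then recovers everything with the
#' analysis modules: DNM triage against the base strain, per-genotype read
#' support, truncation detection and junction microhomology.
#'
#' @param seed Master seed for all randomness.
#' @param chromosome_lengths,n_genes,essential_fraction Genome model.
#' @param coverage,read_length,fragment_mean,fragment_sd,error_rate Pooled
#'   sequencing design (defaults: 300x, 150 bp pairs, 550 bp fragments,
#'   0.1% substitution errors).
#' @param flank Genotype window half-width for quantification.
#' @param mh_length,mh_mismatches Microhomology planted at the rearrangement
#'   junction.
#' @return A list of recovery measurements: `dnm_sensitivity` and
#'   `base_strain_specificity` (fractions), `class_table` (per pool/target:
#'   expected vs recovered class fractions with retained read counts),
#'   `max_class_deviation` and `max_allowed_deviation` (3 binomial SD),
#'   `truncation_position_error`, `mh_length`, `mh_mismatches`,
#'   `targeting_efficiency` (per pool/target) plus the underlying objects.
#' @export
run_recovery_study <- function(seed = 1L,
                               chromosome_lengths = c(600000L, 550000L,
                                                      500000L, 400000L),
                               n_genes = 400L, essential_fraction = 0.3,
                               coverage = 300, read_length = 150L,
                               fragment_mean = 550L, fragment_sd = 60L,
                               error_rate = 0.001, flank = 1000L,
                               mh_length = 5L, mh_mismatches = 2L) {
  genome <- generate_genome(chromosome_lengths, n_genes, essential_fraction,
                            seed = subseed(seed, 1L))

  guides <- pick_study_guides(genome, subseed(seed, 2L))
  ga <- guides[1, ]; gb <- guides[2, ]

  # plant the MMEJ signature at the junction the rearrangement will create
  # (derivative A': chrA[..cutA] joined to chrB[cutB+1..])
  genome <- plant_microhomology(genome, ga$chrom, ga$cut_locus,
                                gb$chrom, gb$cut_locus + 1L,
                                mh_length = mh_length,
                                mismatches = mh_mismatches,
                                seed = subseed(seed, 3L))
  # the plant rewrites part of guide B's protospacer: refresh it from the
  # genome so the guide still describes its design locus
  guides$protospacer[2] <- substr(chrom_seq(genome, gb$chrom),
                                  gb$cut_locus - 17L, gb$cut_locus + 2L)

  exclude <- data.frame(chrom = guides$chrom,
                        start = pmax(1L, guides$cut_locus - 3000L),
                        end = guides$cut_locus + 3000L)
  base_snvs <- simulate_base_strain_variants(genome, 20L, subseed(seed, 4L),
                                             exclude = exclude)
  base_genome <- apply_snvs(genome, base_snvs)

  # fixed per-pool outcome design covering every class
  pool_design <- list(c("none", "none"),
                      c("small_indel", "small_indel"),
                      c("small_indel", "large_indel"),
                      c("truncation", "small_indel"),
                      "rearrangement")
  truths <- plan_colony_outcomes(genome, guides,
                                 design = rep(pool_design, 2L),
                                 seed = subseed(seed, 5L))

  pools <- split(truths, vapply(truths, function(t) t$pool_id, character(1)))
  planted <- truth_variants(truths, genome)
  measure <- list(class_rows = list(), efficiency = list(),
                  dnm_recovered = 0L, dnm_planted = 0L, base_survivors = 0L,
                  trunc_err = integer(0), mh = NULL)

  for (pool_id in names(pools)) {
    ptruths <- pools[[pool_id]]
    genomes <- lapply(ptruths, function(tr) apply_edits(base_genome, tr))
    names(genomes) <- vapply(ptruths, function(tr) tr$colony_id, character(1))
    reads <- simulate_pool_reads(genomes, coverage, read_length,
                                 fragment_mean, fragment_sd, error_rate,
                                 seed = subseed(seed, 100L +
                                                  match(pool_id, names(pools))))
    calls <- truth_variants(ptruths, genome)
    calls <- rbind(calls, base_snvs)
    calls$sample_id <- pool_id

    tri <- triage_calls(calls, base_snvs, genome, guides)
    pk <- variant_key(truth_variants(ptruths, genome))
    dk <- variant_key(tri$dnms)
    measure$dnm_planted <- measure$dnm_planted + length(pk)
    measure$dnm_recovered <- measure$dnm_recovered + sum(pk %in% dk)
    measure$base_survivors <- measure$base_survivors +
      sum(variant_key(base_snvs) %in% dk)

    # truncation recovery: detected position vs planted cut locus
    tc <- detect_truncation(tri$dnms)
    truth_trunc <- do.call(rbind, lapply(ptruths, function(tr)
      tr$edits[tr$edits$class == "truncation", , drop = FALSE]))
    for (i in seq_len(nrow(truth_trunc))) {
      hit <- tc[tc$chrom == truth_trunc$chrom[i], , drop = FALSE]
      err <- if (nrow(hit) == 0L) NA_integer_ else
        min(abs(hit$position - truth_trunc$pos[i]))
      measure$trunc_err <- c(measure$trunc_err, err)
    }

    # microhomology at the derivative-A' junction of the rearrangement
    bnd <- tri$dnms[grepl("_joint_a$", tri$dnms$variant_id), , drop = FALSE]
    if (nrow(bnd) > 0L && is.null(measure$mh))
      measure$mh <- detect_microhomology(bnd[1, ], genome)

    # per-target class support vs the realized colony mixture
    for (gi in 1:2) {
      target <- guides[gi, ]
      expected <- expected_class_fractions(ptruths, target, gi)
      vars <- target_variants(calls, target, flank)
      models <- reconstruct_genotype_sequences(genome, target, vars, flank)
      asg <- assign_reads(reads, models)
      st <- support_table(asg, models)
      rec <- stats::setNames(st$per_class$relative_support,
                             st$per_class$class)
      for (cls in union(names(expected), names(rec))) {
        e <- if (cls %in% names(expected)) expected[[cls]] else 0
        r <- if (cls %in% names(rec)) rec[[cls]] else 0
        measure$class_rows[[length(measure$class_rows) + 1L]] <-
          data.frame(pool_id = pool_id, target_id = target$guide_id,
                     class = cls, expected = e, recovered = r,
                     n_reads = asg$retained, stringsAsFactors = FALSE)
      }
      measure$efficiency[[paste(pool_id, target$guide_id, sep = ".")]] <-
        st$targeting_efficiency
    }
  }

  ct <- do.call(rbind, measure$class_rows)
  dev <- abs(ct$recovered - ct$expected)
  bound <- 3 * sqrt(pmax(ct$expected * (1 - ct$expected), 0.2 * 0.8) /
                    ct$n_reads)
  list(genome = genome, guides = guides, truths = truths,
       n_planted = measure$dnm_planted, n_base_snvs = nrow(base_snvs),
       dnm_sensitivity = measure$dnm_recovered / measure$dnm_planted,
       base_strain_specificity = 1 - measure$base_survivors / nrow(base_snvs),
       class_table = transform(ct, deviation = dev, allowed = bound),
       max_class_deviation = max(dev),
       max_allowed_deviation = max(bound),
       class_within_3sd = all(dev <= bound),
       truncation_position_error = measure$trunc_err,
       mh_length = measure$mh$mh_length %||% NA_integer_,
       mh_mismatches = measure$mh$mh_mismatches %||% NA_integer_,
       targeting_efficiency = unlist(measure$efficiency))
}

# Two unique plus-strand guides on the two largest chromosomes, cutting in
# the first 40% of a non-essential CDS, interior enough for flanks.
pick_study_guides <- function(genome, seed) {
  lens <- sort(chrom_lengths(genome), decreasing = TRUE)
  chroms <- names(lens)[1:2]
  with_seed(seed, {
    rows <- lapply(chroms, function(cn) {
      genes <- genome$genes[!genome$genes$essential &
                            genome$genes$chrom == cn, , drop = FALSE]
      genes <- genes[sample.int(nrow(genes)), , drop = FALSE]
      for (i in seq_len(nrow(genes))) {
        gn <- genes[i, ]
        if (gn$start < 5000L || gn$end > lens[[cn]] - 5000L) next
        cands <- enumerate_protospacers(genome, gn)
        cands <- cands[cands$strand == "+", , drop = FALSE]
        cands <- filter_guides(cands, c(0, 0.4))
        for (j in seq_len(nrow(cands))) {
          scan0 <- stats::setNames(
            list(find_binding_sites(genome, cands[j, ], 0L,
                                    c("NGG", "NAG"))),
            cands$guide_id[j])
          keep <- filter_guides(cands[j, , drop = FALSE], c(0, 0.4),
                                scan0, 0L)
          if (nrow(keep) == 1L) return(keep)
        }
      }
      stop("no unique guide found on ", cn)
    })
    do.call(rbind, rows)
  })
}

# Realized per-class read-mixture expectation at one target: each colony
# contributes 1/pool share; a joint rearrangement counts as SV at both loci.
expected_class_fractions <- function(ptruths, target, locus_index) {
  n <- length(ptruths)
  classes <- vapply(ptruths, function(tr) {
    ed <- tr$edits
    if (nrow(ed) == 0L) return("WT")
    joint <- ed[ed$class %in% JOINT_CLASSES, , drop = FALSE]
    if (nrow(joint) > 0L) return("SV")
    mine <- ed[grepl(paste0("_t", locus_index, "$"), ed$edit_id), ,
               drop = FALSE]
    if (nrow(mine) == 0L) return("WT")
    classify_genotype(mine$net_len,
                      breakend = mine$class == "truncation")$class
  }, character(1))
  tab <- table(classes) / n
  stats::setNames(as.numeric(tab), names(tab))
}
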