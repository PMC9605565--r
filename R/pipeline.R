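# End-to-end orchestration: a single configuration drives simulation, guide
# design, off-target scanning, DNM triage and on-target quantification, with
# deterministic seeding, per-stage outputs and a provenance log of every
# threshold and output hash.

#' Default pipeline configuration
#'
#' Every tunable of every stage, with the sequencing design defaults of the
#' emulated study: pools of 5 colonies, 150 bp paired reads from ~550 bp
#' fragments, 300-fold pooled coverage. All thresholds are echoed into the
#' provenance log; there are no hidden defaults.
#'
#' @param seed Master seed; per-stage seeds are derived from it.
#' @return A nested configuration list.
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    genome = list(chromosome_lengths = c(600000L, 550000L, 500000L, 400000L),
                  n_genes = 400L, essential_fraction = 0.3,
                  gene_length_range = c(300L, 1500L)),
    base_strain = list(n_snvs = 20L),
    guides = list(spacer_length = 20L, pam = "NGG", cds_window = c(0, 0.4),
                  n_targets = 2L, targets_on = "different_chromosomes",
                  min_region_length = 50000L, definitions = NULL),
    experiment = list(id = "exp1", guide_ids = NULL, n_colonies = 10L,
                      pool_size = 5L,
                      class_probabilities = list(none = 0.2,
                                                 small_indel = 0.4,
                                                 large_indel = 0.15,
                                                 rearrangement = 0.15,
                                                 truncation = 0.1),
                      indel_size_model = list(small = c(1, 10),
                                              large = c(50, 1200)),
                      deletion_prob = c(small = 0.6, large = 0.8)),
    reads = list(coverage = 300, read_length = 150L, fragment_mean = 550L,
                 fragment_sd = 60L, error_rate = 0.001, quality = 40L,
                 compress = FALSE),
    offtarget = list(max_mismatches = 10L, pam = c("NGG", "NAG"),
                     window = 30L, seed_length = 5L),
    triage = list(on_target_radius = 100L, sv_tolerance = 10L,
                  min_support_fraction = 0.1),
    ontarget = list(flank = 1000L, max_mismatches_per_read = 8L,
                    min_overlap = 5L, min_reads = 5L, anchor_k = 25L),
    telomere = list(motif = default_telomere_motif(), copies = 25L,
                    min_copies = 3L),
    junctions = list(max_window = 25L, max_mismatches = 2L))
}

# Deep-merge a partial user configuration over the defaults. A few keys are
# replaced wholesale (a probability vector is one distribution, not a patch).
REPLACE_WHOLESALE <- c("class_probabilities", "definitions", "guide_ids")

merge_config <- function(user, base = default_config()) {
  for (k in names(user)) {
    if (!(k %in% REPLACE_WHOLESALE) &&
        is.list(user[[k]]) && is.list(base[[k]]) && !is.null(names(user[[k]])))
      base[[k]] <- merge_config(user[[k]], base[[k]])
    else base[[k]] <- user[[k]]
  }
  base
}

#' Load and validate a pipeline configuration
#'
#' @param x A YAML file path or a (partial) configuration list; missing
#'   entries take their defaults.
#' @return The validated full configuration.
#' @export
load_config <- function(x) {
  cfg <- if (is.character(x)) yaml::read_yaml(x) else x
  cfg <- merge_config(cfg)
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  p <- unlist(cfg$experiment$class_probabilities)
  if (abs(sum(p) - 1) > 1e-9)
    stop("config error: class probabilities must sum to 1")
  if (!is.null(cfg$experiment$guide_ids)) {
    defs <- cfg$guides$definitions
    if (is.null(defs))
      stop("config error: experiment references guide ids but no guide ",
           "definitions are provided")
    def_ids <- vapply(defs, function(d) d$guide_id, character(1))
    missing <- setdiff(cfg$experiment$guide_ids, def_ids)
    if (length(missing) > 0L)
      stop("config error: undefined guide id(s): ",
           paste(missing, collapse = ", "))
  }
  if (cfg$experiment$pool_size < 1L || cfg$experiment$pool_size > 5L)
    stop("config error: pool_size must be 1..5")
  invisible(cfg)
}

subseed <- function(seed, i) (as.integer(seed) %% 100000L) * 1000L + i

#' Run the full analysis pipeline on synthetic data
#'
#' Executes, in dependency order: genome + base-strain simulation, guide
#' design (or ingestion of configured guide definitions), off-target
#' scanning, colony-outcome simulation with pooled read generation, DNM
#' triage and on-target quantification, then renders the summary tables.
#' Rerunning with an identical configuration reproduces byte-identical
#' outputs.
#'
#' @param config Configuration list or YAML path (see [default_config()]).
#' @param outdir Run directory (created; existing files overwritten).
#' @param stages Subset of
#'   `c("simulate", "design", "offtarget", "triage", "quantify", "report")`
#'   to execute; later stages require earlier ones in the same call.
#' @return Invisibly, a list with all stage results and the output manifest.
#' @export
run_pipeline <- function(config = default_config(), outdir,
                         stages = c("simulate", "design", "offtarget",
                                    "triage", "quantify", "report")) {
  cfg <- load_config(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- cfg$seed
  res <- list(config = cfg, outdir = outdir)
  path <- function(...) file.path(outdir, paste0(...))

  ## --- simulate: reference genome and base strain ------------------------
  genome <- generate_genome(cfg$genome$chromosome_lengths,
                            cfg$genome$n_genes,
                            cfg$genome$essential_fraction,
                            seed = subseed(seed, 1L),
                            gene_length_range = cfg$genome$gene_length_range)
  write_genome_fasta(genome, path("genome.fasta"))
  write_annotation_gff3(genome, path("annotation.gff3"))
  res$genome <- genome

  ## --- design: guides and NE regions ------------------------------------
  guides <- NULL
  if (any(c("design", "offtarget", "triage", "quantify") %in% stages)) {
    ne <- find_nonessential_regions(genome, cfg$guides$min_region_length)
    if (nrow(ne) > 0L) write_regions_bed(ne, path("ne_regions.bed"))
    guides <- pick_pipeline_guides(genome, cfg, subseed(seed, 2L))
    write_guides_tsv(guides, path("guides.tsv"))
    res$ne_regions <- ne
    res$guides <- guides
  }

  ## --- base strain (placed after guide choice so SNVs avoid the target
  ##     windows; target loci are sequence-verified in the emulated design)
  exclude <- if (!is.null(guides)) {
    data.frame(chrom = guides$chrom,
               start = pmax(1L, guides$cut_locus - 3000L),
               end = guides$cut_locus + 3000L)
  } else NULL
  base_snvs <- simulate_base_strain_variants(genome, cfg$base_strain$n_snvs,
                                             subseed(seed, 3L),
                                             exclude = exclude)
  vcf_write(base_snvs, path("base_strain.vcf"), genome)
  base_genome <- apply_snvs(genome, base_snvs)
  res$base_snvs <- base_snvs

  ## --- off-target scan ---------------------------------------------------
  if (any(c("offtarget", "triage") %in% stages) && !is.null(guides)) {
    sites <- do.call(rbind, lapply(seq_len(nrow(guides)), function(i)
      find_binding_sites(genome, guides[i, ], cfg$offtarget$max_mismatches,
                         cfg$offtarget$pam, cfg$offtarget$seed_length)))
    write_sites_tsv(sites, path("offtarget_sites.tsv"))
    res$sites <- sites
  }

  ## --- colony outcomes, edited genomes, pooled reads ---------------------
  if (any(c("simulate", "triage", "quantify") %in% stages)) {
    if (is.null(guides)) guides <- pick_pipeline_guides(genome, cfg,
                                                        subseed(seed, 2L))
    truths <- plan_colony_outcomes(
      genome, guides, cfg$experiment$n_colonies,
      cfg$experiment$class_probabilities,
      indel_size_model = cfg$experiment$indel_size_model,
      deletion_prob = cfg$experiment$deletion_prob,
      pool_size = cfg$experiment$pool_size,
      telomere_motif = cfg$telomere$motif,
      telomere_copies = cfg$telomere$copies,
      seed = subseed(seed, 4L), experiment_id = cfg$experiment$id)
    write_truth_tsv(truths, path("truth.tsv"))
    res$truths <- truths

    pools <- split(truths, vapply(truths, function(t) t$pool_id, character(1)))
    res$pools <- list()
    pi <- 0L
    for (pool_id in names(pools)) {
      pi <- pi + 1L
      ptruths <- pools[[pool_id]]
      genomes <- lapply(ptruths, function(tr) apply_edits(base_genome, tr))
      names(genomes) <- vapply(ptruths, function(tr) tr$colony_id,
                               character(1))
      reads <- simulate_pool_reads(genomes, cfg$reads$coverage,
                                   cfg$reads$read_length,
                                   cfg$reads$fragment_mean,
                                   cfg$reads$fragment_sd,
                                   cfg$reads$error_rate,
                                   seed = subseed(seed, 100L + pi),
                                   quality = cfg$reads$quality)
      write_fastq_pair(reads, path(pool_id), compress = cfg$reads$compress)
      calls <- rbind(
        truth_variants(ptruths, genome),
        within(base_snvs, sample_id <- pool_id))
      calls$sample_id <- pool_id
      vcf_write(calls, path(pool_id, ".vcf"), genome)
      res$pools[[pool_id]] <- list(truths = ptruths, reads = reads,
                                   calls = calls)
    }
  }

  ## --- triage -------------------------------------------------------------
  if ("triage" %in% stages) {
    all_dnms <- list(); fate_logs <- list(); ledgers <- list()
    mh_calls <- list(); trunc_calls <- list()
    calls_by_pool <- lapply(res$pools, function(p) p$calls)
    guide_sets <- stats::setNames(
      rep(list(guides$guide_id), length(calls_by_pool)),
      names(calls_by_pool))
    rec <- drop_recurrent(calls_by_pool, guide_sets,
                          require_distinct_guides = TRUE)
    for (pool_id in names(res$pools)) {
      tri <- triage_calls(rec$calls[[pool_id]], base_snvs, genome, guides,
                          on_target_radius = cfg$triage$on_target_radius,
                          sv_tolerance = cfg$triage$sv_tolerance)
      hits <- sites_near_variants(res$sites %||% empty_site_table(),
                                  tri$dnms, cfg$offtarget$window)
      tri$ledger <- build_ledger(rec$calls[[pool_id]], tri$dnms,
                                 tri$fate_log, hits)
      vcf_write(tri$dnms, path("dnm_", pool_id, ".vcf"), genome,
                sample_id = pool_id)
      all_dnms[[pool_id]] <- tri$dnms
      fate_logs[[pool_id]] <- tri$fate_log
      ledgers[[pool_id]] <- tri$ledger

      bnd <- tri$dnms[grepl("\\[|\\]", tri$dnms$alt) &
                      tri$dnms$target_status == "on-target", , drop = FALSE]
      for (i in seq_len(nrow(bnd))) {
        mh <- detect_microhomology(bnd[i, ], genome,
                                   cfg$junctions$max_window,
                                   cfg$junctions$max_mismatches)
        mh_calls[[length(mh_calls) + 1L]] <-
          data.frame(pool_id = pool_id, junction_id = mh$junction_id,
                     mh_length = mh$mh_length,
                     mh_mismatches = mh$mh_mismatches,
                     mh_sequence_a = mh$mh_sequence_a,
                     mh_sequence_b = mh$mh_sequence_b,
                     stringsAsFactors = FALSE)
      }
      tc <- detect_truncation(tri$dnms, cfg$telomere$motif,
                              cfg$telomere$min_copies)
      if (nrow(tc) > 0L)
        trunc_calls[[length(trunc_calls) + 1L]] <- cbind(pool_id = pool_id, tc)
    }
    res$dnms <- do.call(rbind, all_dnms)
    res$fate_log <- do.call(rbind, fate_logs)
    res$ledger <- do.call(rbind, ledgers)
    res$microhomology <- do.call(rbind, c(mh_calls, list(data.frame())))
    res$truncations <- do.call(rbind, c(trunc_calls, list(data.frame())))
    rownames(res$ledger) <- rownames(res$dnms) <- NULL
    utils::write.table(res$fate_log, path("fate_log.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    if (nrow(res$microhomology %||% data.frame()) > 0L)
      utils::write.table(res$microhomology, path("microhomology.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    if (nrow(res$truncations %||% data.frame()) > 0L)
      utils::write.table(res$truncations, path("truncations.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }

  ## --- on-target quantification ------------------------------------------
  if ("quantify" %in% stages) {
    res$support <- list()
    for (pool_id in names(res$pools)) {
      pool <- res$pools[[pool_id]]
      for (gi in seq_len(nrow(guides))) {
        target <- guides[gi, ]
        vars <- target_variants(pool$calls, target, cfg$ontarget$flank)
        models <- reconstruct_genotype_sequences(genome, target, vars,
                                                 cfg$ontarget$flank)
        write_genotype_fasta(models,
                             path("genotypes_", pool_id, "_",
                                  target$guide_id, ".fasta"))
        asg <- assign_reads(pool$reads, models,
                            cfg$ontarget$max_mismatches_per_read,
                            cfg$ontarget$min_overlap, cfg$ontarget$anchor_k)
        st <- support_table(asg, models, cfg$ontarget$min_reads)
        res$support[[paste(pool_id, target$guide_id, sep = ".")]] <-
          c(st, list(pool_id = pool_id, target_id = target$guide_id))
      }
    }
  }

  ## --- report -------------------------------------------------------------
  if ("report" %in% stages)
    res <- c(res, render_summary(res, outdir))

  out_files <- sort(setdiff(list.files(outdir), "provenance.yaml"))
  hashes <- unname(tools::md5sum(file.path(outdir, out_files)))
  writeLines(yaml::as.yaml(list(
    config = cfg,
    outputs = stats::setNames(as.list(hashes), out_files))),
    path("provenance.yaml"))
  res$output_hashes <- stats::setNames(hashes, out_files)
  invisible(res)
}

# Variants relevant to one target: explicit-allele variants whose anchor is
# within the flank window, plus breakends anchored at the target locus.
# A reciprocal rearrangement produces two junctions anchored at the same cut
# site (one per derivative chromosome); only the retained-left junction is
# modelled, so each repair event yields exactly one genotype sequence per
# target and read support is not double-counted.
target_variants <- function(calls, target, flank) {
  near <- calls$chrom == target$chrom &
    abs(calls$pos - target$cut_locus) <= flank
  bnd <- grepl("\\[|\\]", calls$alt)
  left <- is_left_retained_bnd(calls$alt)
  keep <- near & (!bnd | left)
  # a right-retained breakend without a reciprocal left-retained sibling at
  # the same break is a one-sided event and is kept
  for (i in which(near & bnd & !left)) {
    sib <- near & bnd & left & calls$chrom == calls$chrom[i] &
      abs(calls$pos - calls$pos[i]) <= 5L
    if (!any(sib)) keep[i] <- TRUE
  }
  calls[keep, , drop = FALSE]
}

is_left_retained_bnd <- function(alt) grepl("^[ACGTN]", alt) & grepl("\\[|\\]", alt)

# Deterministically choose target genes and one filtered guide per gene.
pick_pipeline_guides <- function(genome, cfg, seed) {
  defs <- cfg$guides$definitions
  if (!is.null(defs)) {
    g <- do.call(rbind, lapply(defs, function(d)
      as.data.frame(d, stringsAsFactors = FALSE)))
    if (!is.null(cfg$experiment$guide_ids))
      g <- g[g$guide_id %in% cfg$experiment$guide_ids, , drop = FALSE]
    return(g)
  }
  genes <- genome$genes[!genome$genes$essential, , drop = FALSE]
  if (nrow(genes) == 0L) stop("no non-essential genes to target")
  with_seed(seed, {
    genes <- genes[sample.int(nrow(genes)), , drop = FALSE]
    chosen <- list()
    used_chroms <- character(0)
    for (i in seq_len(nrow(genes))) {
      if (length(chosen) >= cfg$guides$n_targets) break
      gn <- genes[i, ]
      if (cfg$guides$targets_on == "different_chromosomes" &&
          gn$chrom %in% used_chroms) next
      if (cfg$guides$targets_on == "same_chromosome" &&
          length(used_chroms) > 0L && gn$chrom != used_chroms[1]) next
      cands <- enumerate_protospacers(genome, gn, cfg$guides$pam,
                                      cfg$guides$spacer_length)
      cands <- filter_guides(cands, cfg$guides$cds_window)
      if (nrow(cands) == 0L) next
      # verbatim-uniqueness scan, stopping at the first unique guide
      picked <- NULL
      for (j in seq_len(nrow(cands))) {
        scan0 <- stats::setNames(
          list(find_binding_sites(genome, cands[j, ], max_mismatches = 0L,
                                  pam_motifs = cfg$guides$pam)),
          cands$guide_id[j])
        keep <- filter_guides(cands[j, , drop = FALSE], cfg$guides$cds_window,
                              scan0, 0L)
        if (nrow(keep) == 1L) { picked <- keep; break }
      }
      if (is.null(picked)) next
      chosen[[length(chosen) + 1L]] <- picked
      used_chroms <- c(used_chroms, gn$chrom)
    }
    if (length(chosen) < cfg$guides$n_targets)
      stop("could not design ", cfg$guides$n_targets,
           " unique guides under the configured constraints")
    do.call(rbind, chosen)
  })
}

#' Render summary tables
#'
#' Produces the per-sample DNM count ledger TSV and the per-target
#' class-support table (relative read support per genotype class with
#' distinct-genotype and colony counts, i.e. the data behind stacked-bar
#' figures of editing outcomes).
#'
#' @param res A [run_pipeline()] result list (triage and quantify stages
#'   must be present).
#' @param outdir Directory for the TSVs.
#' @return List with `ledger_table` and `class_support`.
#' @export
render_summary <- function(res, outdir) {
  if (is.null(res$ledger)) stop("missing stage output: triage")
  if (is.null(res$support)) stop("missing stage output: quantify")
  utils::write.table(res$ledger, file.path(outdir, "ledger.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  n_colonies_per_pool <- vapply(res$pools, function(p) length(p$truths),
                                integer(1))
  rows <- list()
  grows <- list()
  for (key in names(res$support)) {
    st <- res$support[[key]]
    if (isTRUE(st$no_coverage)) next
    pc <- st$per_class
    rows[[key]] <- data.frame(
      pool_id = st$pool_id, target_id = st$target_id, class = pc$class,
      relative_support = pc$relative_support, n_genotypes = pc$n_genotypes,
      n_colonies = n_colonies_per_pool[[st$pool_id]],
      targeting_efficiency = st$targeting_efficiency,
      stringsAsFactors = FALSE)
    g <- st$per_genotype
    grows[[key]] <- cbind(pool_id = st$pool_id, target_id = st$target_id, g)
  }
  class_support <- do.call(rbind, rows)
  genotype_support <- do.call(rbind, grows)
  rownames(class_support) <- rownames(genotype_support) <- NULL
  utils::write.table(class_support, file.path(outdir, "class_support.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(genotype_support,
                     file.path(outdir, "genotype_support.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  list(ledger_table = res$ledger, class_support = class_support,
       genotype_support = genotype_support)
}
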