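# On-target quantification: genotype classification, local sequence
# reconstruction, read assignment, support tables and junction analysis.

test_that("genotype classification matches the independent rule table over -100..100", {
  nets <- -100:100
  got <- classify_genotype(nets)
  want <- vapply(nets, rule_table_class, character(1))
  expect_equal(got$class, want)
  expect_equal(got$frame_preserving, nets %% 3L == 0L)
  # SNVs and breakends override the length rule
  expect_equal(classify_genotype(0L, variant_type = "SNV")$class,
               "substitution")
  expect_equal(classify_genotype(0L, breakend = TRUE)$class, "SV")
  expect_error(classify_genotype(NA_real_), "finite")
})

test_that("classification reproduces the observed repair-outcome spectrum", {
  # 3 bp deletion: in-frame; 57 bp deletion: SV preserving the frame;
  # inter-chromosomal breakend: SV
  expect_equal(classify_genotype(-3L)$class, "in-frame")
  c57 <- classify_genotype(-57L)
  expect_equal(c57$class, "SV")
  expect_true(c57$frame_preserving)
  expect_equal(classify_genotype(0L, breakend = TRUE)$class, "SV")
})

test_that("genotype models splice variants into the reference window", {
  g <- make_test_genome()
  gd <- pick_guide(g, "chr1")
  cut <- gd$cut_locus
  s <- g$chromosomes[["chr1"]]

  # no variants: the single WT model is the reference window
  wt_only <- reconstruct_genotype_sequences(g, gd, flank = 500L)
  expect_equal(nrow(wt_only), 1L)
  expect_equal(wt_only$class, "WT")
  expect_equal(wt_only$seq, substr(s, cut - 500L, cut + 500L))
  expect_equal(wt_only$variant_pos, 501L)

  # 10 bp deletion: model shorter by 10 relative to the WT window
  del <- variant_call_table(variant_id = "d10", sample_id = "p", chrom = "chr1",
                            pos = cut - 5L,
                            ref = substr(s, cut - 5L, cut + 5L),
                            alt = substr(s, cut - 5L, cut - 5L),
                            type = "deletion", net_len = -10L)
  models <- reconstruct_genotype_sequences(g, gd, del, flank = 500L)
  expect_equal(nrow(models), 2L)
  expect_equal(nchar(models$seq[2]), 2L * 500L + 1L - 10L)
  expect_equal(models$class[2], "frameshift")
  expect_true(!anyDuplicated(models$seq))

  # hand-constructed inter-chromosomal junction: left flank + right partner
  s2 <- g$chromosomes[["chr2"]]
  bnd <- variant_call_table(variant_id = "j", sample_id = "p", chrom = "chr1",
                            pos = cut, ref = substr(s, cut, cut),
                            alt = sprintf("%s[chr2:%d[",
                                          substr(s, cut, cut), 9000L),
                            type = "SV", net_len = 0L, mate_id = "jm",
                            chrom2 = "chr2", pos2 = 9000L)
  mj <- reconstruct_genotype_sequences(g, gd, bnd, flank = 400L)
  expect_equal(mj$seq[2],
               paste0(substr(s, cut - 400L, cut),
                      substr(s2, 9000L, 9000L + 399L)))
  expect_equal(mj$class[2], "SV")
  expect_equal(mj$variant_pos[2], 401L)
})

test_that("noiseless reads from one mutant model are fully recovered", {
  g <- make_test_genome()
  gd <- pick_guide(g, "chr1")
  cut <- gd$cut_locus
  s <- g$chromosomes[["chr1"]]
  del <- variant_call_table(variant_id = "d7", sample_id = "p", chrom = "chr1",
                            pos = cut - 3L, ref = substr(s, cut - 3L, cut + 4L),
                            alt = substr(s, cut - 3L, cut - 3L),
                            type = "deletion", net_len = -7L)
  models <- reconstruct_genotype_sequences(g, gd, del, flank = 800L)

  mutant <- apply_edits(g, data.frame(
    edit_id = "d7", class = "small_indel", target_id = gd$guide_id,
    chrom = "chr1", pos = cut - 3L, ref = del$ref, alt = del$alt,
    chrom2 = NA, pos2 = NA, inserted_seq = "", net_len = -7L,
    telomere_capped = FALSE))
  reads <- simulate_pool_reads(list(mut = mutant), coverage = 40,
                               error_rate = 0, seed = 19)
  asg <- assign_reads(reads, models)
  counts <- stats::setNames(asg$counts$reads, asg$counts$genotype_id)
  expect_gt(counts[models$genotype_id[2]], 0L)
  expect_equal(unname(counts[models$genotype_id[1]]), 0L)
  st <- support_table(asg, models)
  expect_equal(st$targeting_efficiency, 1)
})

test_that("a 50:50 wildtype/frameshift mixture is recovered within 3 binomial SD", {
  g <- make_test_genome()
  gd <- pick_guide(g, "chr1")
  cut <- gd$cut_locus
  s <- g$chromosomes[["chr1"]]
  del <- variant_call_table(variant_id = "d8", sample_id = "p", chrom = "chr1",
                            pos = cut - 4L, ref = substr(s, cut - 4L, cut + 4L),
                            alt = substr(s, cut - 4L, cut - 4L),
                            type = "deletion", net_len = -8L)
  models <- reconstruct_genotype_sequences(g, gd, del, flank = 800L)
  mutant <- apply_edits(g, data.frame(
    edit_id = "d8", class = "small_indel", target_id = gd$guide_id,
    chrom = "chr1", pos = cut - 4L, ref = del$ref, alt = del$alt,
    chrom2 = NA, pos2 = NA, inserted_seq = "", net_len = -8L,
    telomere_capped = FALSE))
  reads <- simulate_pool_reads(list(wt = g, mut = mutant), coverage = 300,
                               error_rate = 0, seed = 23)
  asg <- assign_reads(reads, models)
  st <- support_table(asg, models)
  p_hat <- st$per_genotype$relative_support[st$per_genotype$class != "WT"]
  n <- asg$retained
  expect_gt(n, 100L)
  expect_lt(abs(p_hat - 0.5), 3 * sqrt(0.25 / n))
})

test_that("raising the minimum variant overlap never increases assigned reads", {
  g <- make_test_genome()
  gd <- pick_guide(g, "chr2")
  models <- reconstruct_genotype_sequences(g, gd, flank = 600L)
  reads <- simulate_pool_reads(list(g), coverage = 30, error_rate = 0.001,
                               seed = 29)
  prev <- Inf
  for (ov in c(1L, 5L, 25L, 60L)) {
    asg <- assign_reads(reads, models, min_overlap = ov)
    expect_lte(asg$retained, prev)
    prev <- asg$retained
  }
})

test_that("support tables handle all-WT, no-WT and no-coverage cases", {
  models <- data.frame(genotype_id = c("t_WT", "t_m1"), target_id = "t",
                       class = c("WT", "frameshift"), seq = c("ACGT", "AGGT"),
                       variant_pos = 2L,
                       source_variant_id = c(NA, "m1"),
                       stringsAsFactors = FALSE)
  fake <- function(wt, mut) {
    list(counts = data.frame(genotype_id = models$genotype_id,
                             reads = c(wt, mut)),
         ambiguous = 0L, noncovering = 0L, unassigned = 0L,
         retained = wt + mut, total_mates = wt + mut)
  }
  expect_equal(support_table(fake(100L, 0L), models)$targeting_efficiency, 0)
  expect_equal(support_table(fake(0L, 80L), models)$targeting_efficiency, 1)
  empty <- support_table(fake(0L, 0L), models)
  expect_true(empty$no_coverage)
  expect_true(is.na(empty$targeting_efficiency))
  # minor-genotype flag: nonzero but below the absolute read floor
  st <- support_table(fake(100L, 3L), models)
  expect_true(st$per_genotype$minor_genotype[2])
  expect_false(st$per_genotype$minor_genotype[1])
})

test_that("microhomology detection recovers planted homologies and matches brute force", {
  g <- make_test_genome(lengths = c(30000L, 30000L), n_genes = 0L, seed = 41)

  # perfect 4 bp homology, no extension possible
  g4 <- plant_microhomology(g, "chr1", 12000L, "chr2", 15000L,
                            mh_length = 4L, mismatches = 0L, seed = 2)
  # enforce exactness: detector must not extend beyond 4 with 0 budget
  j <- list(chrom_a = "chr1", pos_a = 12000L, orient_a = "right-open",
            chrom_b = "chr2", pos_b = 15000L, orient_b = "left-open",
            junction_id = "j4")
  got4 <- detect_microhomology(j, g4, max_window = 25L, max_mismatches = 0L)
  expect_equal(got4$mh_length, 4L)
  expect_equal(got4$mh_mismatches, 0L)

  # imperfect 5 bp with 2 mismatches
  g5 <- plant_microhomology(g, "chr1", 9000L, "chr2", 21000L,
                            mh_length = 5L, mismatches = 2L, seed = 3)
  j5 <- list(chrom_a = "chr1", pos_a = 9000L, orient_a = "right-open",
             chrom_b = "chr2", pos_b = 21000L, orient_b = "left-open",
             junction_id = "j5")
  got5 <- detect_microhomology(j5, g5, max_window = 25L, max_mismatches = 2L)
  expect_equal(got5$mh_length, 5L)
  expect_equal(got5$mh_mismatches, 2L)
  expect_equal(nchar(got5$mh_sequence_a), 5L)

  # random unrelated flanks: equals the exhaustive search for many junctions
  for (k in 1:25) {
    set.seed(k)
    pa <- sample(5000:25000, 1)
    pb <- sample(5000:25000, 1)
    for (mm in 0:2) {
      j <- list(chrom_a = "chr1", pos_a = pa, orient_a = "right-open",
                chrom_b = "chr2", pos_b = pb, orient_b = "left-open",
                junction_id = "jr")
      got <- detect_microhomology(j, g, max_window = 25L,
                                  max_mismatches = mm)
      want <- brute_force_microhomology(g$chromosomes[["chr1"]], pa,
                                        g$chromosomes[["chr2"]], pb,
                                        25L, mm)
      expect_equal(c(got$mh_length, got$mh_mismatches), unname(want))
    }
  }
})

test_that("truncation calls require enough tandem telomere copies", {
  motif <- default_telomere_motif()
  mk_sbnd <- function(copies, partial = "") {
    variant_call_table(variant_id = "t", sample_id = "p", chrom = "chr3",
                       pos = 1000L, ref = "A",
                       alt = paste0("A", strrep(motif, copies), partial, "."),
                       type = "SV", net_len = 0L,
                       inserted_seq = paste0(strrep(motif, copies), partial))
  }
  pos10 <- detect_truncation(mk_sbnd(10L), motif, min_copies = 3L)
  expect_equal(nrow(pos10), 1L)
  expect_equal(pos10$position, 1001L)
  expect_equal(pos10$telomere_motif_copies, 10L)
  expect_equal(pos10$evidence, "one-sided-breakend")

  # 2 copies below the threshold of 3; a trailing partial copy doesn't count
  expect_equal(nrow(detect_truncation(mk_sbnd(2L), motif, 3L)), 0L)
  expect_equal(nrow(detect_truncation(
    mk_sbnd(2L, partial = substr(motif, 1, 5)), motif, 3L)), 0L)
  # an ordinary deletion junction has no motif and is never called
  del <- variant_call_table(variant_id = "d", sample_id = "p", chrom = "chr1",
                            pos = 50L, ref = "ACCA", alt = "A",
                            type = "deletion", net_len = -3L)
  expect_equal(nrow(detect_truncation(del, motif, 3L)), 0L)
  # clipped-read consensus route
  cons <- detect_truncation(strrep(motif, 4L), motif, 3L, chrom = "chr2",
                            position = 777L)
  expect_equal(cons$evidence, "clipped-read-consensus")
  expect_equal(cons$position, 777L)
})
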