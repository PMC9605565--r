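# Synthetic-data generator: genome construction, outcome planning, sequence
# surgery and pooled read simulation.

test_that("generate_genome handles degenerate inputs, is seed-deterministic and seed-sensitive", {
  g0 <- generate_genome(50000L, n_genes = 0L, essential_fraction = 0,
                        seed = 1)
  expect_equal(length(g0$chromosomes), 1L)
  expect_equal(nchar(g0$chromosomes[[1]]), 50000L)
  expect_equal(nrow(g0$genes), 0L)

  g1 <- generate_genome(c(100000, 80000, 60000, 50000), 200, 0.3, seed = 7,
                        gene_length_range = c(150, 600))
  g2 <- generate_genome(c(100000, 80000, 60000, 50000), 200, 0.3, seed = 7,
                        gene_length_range = c(150, 600))
  expect_identical(g1, g2)
  expect_equal(nrow(g1$genes), 200L)
  # Bernoulli(0.3) essential flags: within 4 SD of the expectation
  expect_lt(abs(sum(g1$genes$essential) - 60), 4 * sqrt(200 * 0.3 * 0.7))

  g3 <- generate_genome(c(100000, 80000, 60000, 50000), 200, 0.3, seed = 8,
                        gene_length_range = c(150, 600))
  expect_false(identical(g1$chromosomes, g3$chromosomes))

  expect_error(generate_genome(5000L, 0L, 0, seed = 1), "10 kb")
  # impossible placement: more gene bases than chromosome
  expect_error(generate_genome(10000L, 40L, 0, seed = 1,
                               gene_length_range = c(900, 900)),
               "placement failed")
})

test_that("generated genes respect the annotation invariants", {
  g <- generate_genome(c(40000, 25000), 45, 0.4, seed = 11)
  genes <- g$genes
  expect_false(anyDuplicated(genes$gene_id) > 0)
  expect_true(all(genes$start >= 1))
  expect_true(all(genes$end <=
                  nchar(g$chromosomes)[match(genes$chrom,
                                             names(g$chromosomes))]))
  expect_true(all((genes$end - genes$start + 1L) %% 3L == 0L))
  for (cn in names(g$chromosomes)) {
    gc <- genes[genes$chrom == cn, ]
    gc <- gc[order(gc$start), ]
    if (nrow(gc) > 1L)
      expect_true(all(gc$start[-1] > gc$end[-nrow(gc)]))
  }
})

test_that("plan_colony_outcomes draws the configured class spectrum", {
  g <- make_test_genome()
  gd <- pick_guide(g, "chr1")

  wt <- plan_colony_outcomes(g, gd, 20, list(none = 1), seed = 1)
  expect_true(all(vapply(wt, function(t) nrow(t$edits) == 0L, logical(1))))
  expect_equal(vapply(wt, function(t) t$pool_id, character(1))[c(1, 6)],
               c("exp1_pool01", "exp1_pool02"))

  # uniform 1..6 indel sizes: frame-preserving (3 or 6) fraction is 1/3
  tr <- plan_colony_outcomes(g, gd, 1000, list(small_indel = 1),
                             indel_size_model = list(small = c(1, 6),
                                                     large = c(50, 60)),
                             seed = 5)
  sizes <- abs(vapply(tr, function(t) t$edits$net_len[1], integer(1)))
  expect_true(all(sizes %in% 1:6))
  frac <- mean(sizes %% 3L == 0L)
  expect_lt(abs(frac - 1 / 3), 2.58 * sqrt((1 / 3) * (2 / 3) / 1000))

  expect_error(plan_colony_outcomes(g, gd, 5, list(none = 0.5)), "sum to 1")
  expect_error(plan_colony_outcomes(g, gd, 5, list(rearrangement = 1),
                                    seed = 1),
               "two guides")
})

test_that("forced rearrangements join the two cut sites across chromosomes", {
  g <- make_test_genome()
  guides <- rbind(pick_guide(g, "chr1"), pick_guide(g, "chr2"))
  tr <- plan_colony_outcomes(g, guides, 10, list(rearrangement = 1), seed = 2)
  for (t in tr) {
    e <- t$edits
    expect_equal(nrow(e), 1L)
    expect_equal(e$class, "rearrangement")
    expect_equal(sort(c(e$chrom, e$chrom2)), c("chr1", "chr2"))
    expect_equal(e$pos, guides$cut_locus[1])
    expect_equal(e$pos2, guides$cut_locus[2])
  }
  # same-chromosome rearrangements are rejected
  same <- rbind(pick_guide(g, "chr1"), pick_guide(g, "chr1"))
  expect_error(plan_colony_outcomes(g, same, 2, list(rearrangement = 1),
                                    seed = 1),
               "different chromosomes")
})

test_that("fixed designs prescribe per-colony classes exactly", {
  g <- make_test_genome()
  guides <- rbind(pick_guide(g, "chr1"), pick_guide(g, "chr2"))
  design <- list(c("none", "none"), c("small_indel", "large_indel"),
                 c("truncation", "none"), "rearrangement")
  tr <- plan_colony_outcomes(g, guides, design = design, seed = 9)
  expect_length(tr, 4L)
  expect_equal(nrow(tr[[1]]$edits), 0L)
  expect_equal(tr[[2]]$edits$class, c("small_indel", "large_indel"))
  expect_equal(tr[[3]]$edits$class, "truncation")
  expect_true(tr[[3]]$edits$telomere_capped)
  expect_equal(tr[[4]]$edits$class, "rearrangement")
})

test_that("apply_edits performs exact coordinate arithmetic", {
  g <- make_test_genome(lengths = 50000L, n_genes = 0L, seed = 21)
  s <- g$chromosomes[[1]]

  # identity
  empty <- structure(list(colony_id = "c", pool_id = "p",
                          edits = editAftermath:::empty_edit_table()),
                     class = "ColonyTruth")
  expect_identical(apply_edits(g, empty)$chromosomes, g$chromosomes)

  # 10 bp deletion at p: length shrinks by 10 and downstream shifts left
  p <- 20000L
  del <- data.frame(edit_id = "d1", class = "small_indel", target_id = "t",
                    chrom = "chr1", pos = p, ref = substr(s, p, p + 10L),
                    alt = substr(s, p, p), chrom2 = NA, pos2 = NA,
                    inserted_seq = "", net_len = -10L,
                    telomere_capped = FALSE)
  out <- apply_edits(g, del)$chromosomes[[1]]
  expect_equal(nchar(out), 49990L)
  expect_equal(substr(out, p + 1L, p + 1L), substr(s, p + 11L, p + 11L))
  expect_equal(substr(out, 1L, p), substr(s, 1L, p))

  # truncation at t with 10 motif copies
  motif <- default_telomere_motif()
  tpos <- 30000L
  tru <- data.frame(edit_id = "t1", class = "truncation", target_id = "t",
                    chrom = "chr1", pos = tpos, ref = "", alt = "",
                    chrom2 = NA, pos2 = NA,
                    inserted_seq = strrep(motif, 10L),
                    net_len = -(50000L - (tpos - 1L)) + 10L * nchar(motif),
                    telomere_capped = TRUE)
  out <- apply_edits(g, tru)$chromosomes[[1]]
  expect_equal(nchar(out), tpos - 1L + 10L * nchar(motif))
  expect_equal(substr(out, tpos, tpos + nchar(motif) - 1L), motif)
})

test_that("inversions reverse-complement the enclosed segment in place", {
  g <- make_test_genome(lengths = 50000L, n_genes = 0L, seed = 22)
  s <- g$chromosomes[[1]]
  inv <- data.frame(edit_id = "i1", class = "inversion", target_id = "t",
                    chrom = "chr1", pos = 10000L, ref = "", alt = "",
                    chrom2 = "chr1", pos2 = 15000L, inserted_seq = "",
                    net_len = 0L, telomere_capped = FALSE)
  out <- apply_edits(g, inv)$chromosomes[[1]]
  expect_equal(nchar(out), nchar(s))
  expect_equal(substr(out, 1, 10000), substr(s, 1, 10000))
  expect_equal(substr(out, 15001, 50000), substr(s, 15001, 50000))
  expect_equal(substr(out, 10001, 15000), rc_chr(substr(s, 10001, 15000)))
})

test_that("apply_edits conserves length by the sum of net changes and rejects overlaps", {
  g <- make_test_genome()
  guides <- rbind(pick_guide(g, "chr1"), pick_guide(g, "chr2"))
  truths <- plan_colony_outcomes(
    g, guides, 30, list(small_indel = 0.4, large_indel = 0.3,
                        rearrangement = 0.2, none = 0.1), seed = 13)
  for (tr in truths) {
    eg <- apply_edits(g, tr)
    expect_equal(sum(nchar(eg$chromosomes)) - sum(nchar(g$chromosomes)),
                 sum(tr$edits$net_len))
  }
  # overlapping edits are rejected with both offenders named
  s <- g$chromosomes[["chr1"]]
  ov <- rbind(
    data.frame(edit_id = "e1", class = "small_indel", target_id = "t",
               chrom = "chr1", pos = 5000L, ref = substr(s, 5000, 5010),
               alt = substr(s, 5000, 5000), chrom2 = NA, pos2 = NA,
               inserted_seq = "", net_len = -10L, telomere_capped = FALSE),
    data.frame(edit_id = "e2", class = "small_indel", target_id = "t",
               chrom = "chr1", pos = 5005L, ref = substr(s, 5005, 5015),
               alt = substr(s, 5005, 5005), chrom2 = NA, pos2 = NA,
               inserted_seq = "", net_len = -10L, telomere_capped = FALSE))
  expect_error(apply_edits(g, ov), "e1.*e2")
})

test_that("error-free reads are exact substrings of their source genome", {
  g <- make_test_genome(lengths = 30000L, n_genes = 0L, seed = 31)
  reads <- simulate_pool_reads(list(g), coverage = 10, error_rate = 0,
                               seed = 4)
  s <- g$chromosomes[[1]]
  rc <- rc_chr(s)
  idx <- seq_len(min(80L, nrow(reads)))
  for (i in idx) {
    expect_true(grepl(reads$seq1[i], s, fixed = TRUE) ||
                grepl(reads$seq1[i], rc, fixed = TRUE))
    expect_true(grepl(reads$seq2[i], s, fixed = TRUE) ||
                grepl(reads$seq2[i], rc, fixed = TRUE))
  }
})

test_that("pool members receive equal expected read shares and coverage arithmetic holds", {
  g <- make_test_genome(lengths = 100000L, n_genes = 0L, seed = 32)
  pool <- rep(list(g), 5)
  names(pool) <- paste0("c", 1:5)
  reads <- simulate_pool_reads(pool, coverage = 100, error_rate = 0,
                               seed = 6)
  n <- nrow(reads)
  # coverage * G / (2 * L) pairs, within 5%
  expect_lt(abs(n - 100 * 100000 / 300) / (100 * 100000 / 300), 0.05)
  shares <- table(reads$colony) / n
  sd3 <- 3 * sqrt(0.2 * 0.8 / n)
  expect_true(all(abs(shares - 0.2) <= sd3))

  # determinism
  r2 <- simulate_pool_reads(pool, coverage = 100, error_rate = 0, seed = 6)
  expect_identical(reads$seq1, r2$seq1)
  expect_identical(reads$seq2, r2$seq2)

  expect_error(simulate_pool_reads(list(g), 10, read_length = 600L),
               "exceeds")
  expect_warning(simulate_pool_reads(list(g), 1, read_length = 150L,
                                     fragment_mean = 200L, seed = 1),
                 "overlap")
})

test_that("genome, annotation, truth and read files round-trip", {
  g <- make_test_genome()
  d <- withr::local_tempdir()
  write_genome_fasta(g, file.path(d, "g.fasta"))
  write_annotation_gff3(g, file.path(d, "g.gff3"))
  g2 <- read_genome_fasta(file.path(d, "g.fasta"), file.path(d, "g.gff3"))
  expect_identical(g2$chromosomes, g$chromosomes)
  expect_equal(g2$genes[order(g2$genes$gene_id), ],
               g$genes[order(g$genes$gene_id), ], ignore_attr = TRUE)

  guides <- rbind(pick_guide(g, "chr1"), pick_guide(g, "chr2"))
  truths <- plan_colony_outcomes(
    g, guides, 5, list(small_indel = 0.5, large_indel = 0.2,
                       rearrangement = 0.2, truncation = 0.1), seed = 17)
  calls <- truth_variants(truths, g)
  vcf_write(calls, file.path(d, "t.vcf"), g)
  back <- vcf_read(file.path(d, "t.vcf"))
  expect_setequal(back$variant_id, calls$variant_id)
  m <- match(calls$variant_id, back$variant_id)
  expect_equal(back$pos[m], calls$pos)
  expect_equal(back$alt[m], calls$alt)
  expect_equal(back$net_len[m], calls$net_len)
  expect_equal(back$chrom2[m], calls$chrom2)
  expect_equal(back$pos2[m], calls$pos2)

  reads <- simulate_pool_reads(list(apply_edits(g, truths[[1]])),
                               coverage = 2, seed = 3)
  paths <- write_fastq_pair(reads, file.path(d, "pool"))
  back_r <- read_fastq_pair(file.path(d, "pool_R1.fastq"),
                            file.path(d, "pool_R2.fastq"))
  expect_equal(back_r$seq1, reads$seq1)
  expect_equal(back_r$seq2, reads$seq2)
  expect_equal(back_r$read_id, reads$read_id)
})
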