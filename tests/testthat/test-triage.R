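# DNM triage: base-strain subtraction, recurrence filtering, coding-effect
# annotation, on/off-target classification and the count ledger.

mk_snv <- function(id, chrom, pos, ref = "A", alt = "T", sample = "s1") {
  variant_call_table(variant_id = id, sample_id = sample, chrom = chrom,
                     pos = pos, ref = ref, alt = alt, type = "SNV",
                     net_len = 0L)
}

mk_del <- function(id, chrom, pos, d, sample = "s1") {
  variant_call_table(variant_id = id, sample_id = sample, chrom = chrom,
                     pos = pos, ref = strrep("A", d + 1L), alt = "A",
                     type = "deletion", net_len = -d)
}

mk_bnd <- function(id, chrom, pos, chrom2, pos2, sample = "s1") {
  variant_call_table(variant_id = id, sample_id = sample, chrom = chrom,
                     pos = pos, ref = "N",
                     alt = sprintf("N[%s:%d[", chrom2, pos2), type = "SV",
                     net_len = 0L, mate_id = paste0(id, "_m"),
                     chrom2 = chrom2, pos2 = pos2)
}

test_that("base-strain subtraction removes exact and jittered matches and is idempotent", {
  base <- rbind(mk_snv("b1", "chr1", 100L), mk_snv("b2", "chr1", 200L),
                mk_bnd("b3", "chr2", 5000L, "chr3", 7000L))
  # full subtraction
  expect_equal(nrow(subtract_base_strain(base, base)), 0L)
  # singleton novelty
  calls <- rbind(base, mk_snv("n1", "chr1", 300L, alt = "G"))
  out <- subtract_base_strain(calls, base)
  expect_equal(out$variant_id, "n1")
  # SV matched within tolerance despite 3 bp breakend jitter
  jitter <- mk_bnd("j1", "chr2", 5003L, "chr3", 6997L)
  expect_equal(nrow(subtract_base_strain(jitter, base, sv_tolerance = 10L)),
               0L)
  # ...but not beyond it
  far <- mk_bnd("j2", "chr2", 5020L, "chr3", 7000L)
  expect_equal(nrow(subtract_base_strain(far, base, sv_tolerance = 10L)), 1L)
  # idempotence
  once <- subtract_base_strain(calls, base)
  expect_identical(subtract_base_strain(once, base), once)
})

test_that("recurrence filter needs distinct guides across enough experiments", {
  shared <- mk_snv("r1", "chr1", 500L)
  exps <- list(e1 = rbind(shared, mk_snv("u1", "chr1", 900L)),
               e2 = shared, e3 = shared)
  # three experiments with three different guides: removed everywhere
  res <- drop_recurrent(exps, list(e1 = "gA", e2 = "gB", e3 = "gC"))
  expect_true(all(vapply(res$calls,
                         function(df) !("r1" %in% df$variant_id),
                         logical(1))))
  expect_equal(res$calls$e1$variant_id, "u1")   # singleton retained
  expect_equal(nrow(res$removed), 1L)
  expect_match(res$removed$experiments, "e1,e2,e3")

  # two experiments sharing one guide: retained under the distinct rule
  res2 <- drop_recurrent(list(e1 = shared, e2 = shared),
                         list(e1 = c("gA", "gB"), e2 = c("gB", "gC")),
                         require_distinct_guides = TRUE)
  expect_equal(nrow(res2$removed), 0L)
  # same sets, distinct requirement lifted: removed
  res3 <- drop_recurrent(list(e1 = shared, e2 = shared),
                         list(e1 = c("gA", "gB"), e2 = c("gB", "gC")),
                         require_distinct_guides = FALSE)
  expect_equal(nrow(res3$removed), 1L)
})

test_that("coding-effect annotation applies CDS intersection and mod-3 arithmetic", {
  genes <- data.frame(gene_id = "g1", chrom = "chr1", start = 1000L,
                      end = 2001L, strand = "+", essential = FALSE)
  g <- AnnotatedGenome(c(chr1 = strrep("A", 10000)), genes)
  calls <- rbind(mk_snv("s_in", "chr1", 1500L),
                 mk_snv("s_out", "chr1", 5000L),
                 mk_del("d4", "chr1", 1200L, 4L),
                 mk_del("d3", "chr1", 1400L, 3L),
                 mk_del("edge", "chr1", 995L, 20L))   # span reaches the CDS
  ann <- annotate_coding_effect(calls, g)
  expect_equal(ann$coding, c(TRUE, FALSE, TRUE, TRUE, TRUE))
  expect_equal(ann$frame_effect,
               c("none", "none", "frameshift", "in-frame", "frameshift"))
  # a 20 bp deletion is a frameshift... unless the length is a multiple of 3
  expect_equal(annotate_coding_effect(mk_del("d20", "chr1", 1100L, 20L),
                                      g)$frame_effect, "frameshift")
})

test_that("on/off-target classification respects the radius and breakend partners", {
  guides <- data.frame(guide_id = c("g1", "g2"), chrom = c("chr1", "chr2"),
                       cut_locus = c(10000L, 20000L),
                       stringsAsFactors = FALSE)
  calls <- rbind(
    mk_del("at_cut", "chr1", 10000L, 5L),
    mk_del("near", "chr1", 10090L, 5L),
    mk_del("past_radius", "chr1", 10200L, 5L),
    mk_snv("other_chrom", "chr3", 10000L),
    mk_bnd("partner_hit", "chr3", 500L, "chr2", 20010L))
  got <- classify_on_vs_off_target(calls, guides, on_target_radius = 100L)
  expect_equal(got, c("on-target", "on-target", "off-target", "off-target",
                      "on-target"))
})

test_that("triage assigns each call exactly one fate and the ledger is consistent", {
  g <- make_test_genome()
  guides <- rbind(pick_guide(g, "chr1"), pick_guide(g, "chr2"))
  base <- simulate_base_strain_variants(g, 12L, seed = 8, sample_id = "p1")
  # planted DNMs: 2 on-target indels, 5 off-target coding SNVs
  on1 <- mk_del("on1", guides$chrom[1], guides$cut_locus[1], 4L, "p1")
  on2 <- mk_del("on2", guides$chrom[2], guides$cut_locus[2] + 10L, 6L, "p1")
  away <- vapply(seq_len(nrow(g$genes)), function(i) {
    gn <- g$genes[i, ]
    !any(guides$chrom == gn$chrom &
         abs(guides$cut_locus - (gn$start + 5L)) < 2000L)
  }, logical(1))
  cds <- g$genes[!g$genes$essential & away, ][1:5, ]
  offs <- do.call(rbind, lapply(1:5, function(i)
    mk_snv(paste0("off", i), cds$chrom[i], cds$start[i] + 5L, ref = "N",
           alt = "T", sample = "p1")))
  offs$ref <- substr(g$chromosomes[offs$chrom], offs$pos, offs$pos)
  calls <- rbind(base, on1, on2, offs)
  calls$sample_id <- "p1"

  tri <- triage_calls(calls, base, g, guides)
  expect_setequal(tri$dnms$variant_id, c("on1", "on2", paste0("off", 1:5)))
  expect_equal(sum(tri$dnms$target_status == "on-target"), 2L)
  expect_equal(sum(tri$dnms$target_status == "off-target" & tri$dnms$coding),
               5L)
  # fate log covers every input call exactly once
  expect_setequal(tri$fate_log$variant_id, calls$variant_id)
  expect_false(any(is.na(tri$fate_log$fate)))
  expect_equal(sum(tri$fate_log$fate == "pre-existing"), nrow(base))

  led <- tri$ledger
  expect_true(all(led$dnms <= led$total_calls))
  expect_equal(led$on_target + led$off_target, led$dnms)
  expect_true(all(led$coding_off_target <= led$off_target))
  expect_equal(sum(led$total_calls), nrow(calls))
  expect_equal(sum(led$dnms), 7L)
  # ledger row for InDels carries the two on-target plants
  expect_equal(led$on_target[led$type == "InDel"], 2L)
  expect_equal(led$off_target[led$type == "SNV"], 5L)

  # blacklisted region masks calls before anything else
  bl <- data.frame(chrom = offs$chrom[1], start = offs$pos[1] - 2L,
                   end = offs$pos[1] + 2L)
  tri2 <- triage_calls(calls, base, g, guides, blacklist = bl)
  expect_false("off1" %in% tri2$dnms$variant_id)
  expect_equal(tri2$fate_log$fate[tri2$fate_log$variant_id == "off1"],
               "blacklisted")
})

test_that("an all-zero ledger results from zero calls and totals are additive", {
  led <- build_ledger(variant_call_table(), variant_call_table())
  expect_equal(nrow(led), 0L)

  # additivity over samples
  calls <- rbind(mk_snv("a", "chr1", 10L, sample = "s1"),
                 mk_snv("b", "chr1", 20L, sample = "s2"),
                 mk_del("c", "chr1", 30L, 3L, sample = "s2"))
  dnms <- calls
  dnms$coding <- FALSE
  dnms$frame_effect <- "none"
  dnms$target_status <- "off-target"
  led <- build_ledger(calls, dnms)
  expect_equal(sum(led$total_calls), 3L)
  expect_equal(sum(led$dnms), 3L)
  per_sample <- tapply(led$total_calls, led$sample_id, sum)
  expect_equal(as.vector(per_sample[c("s1", "s2")]), c(1L, 2L))
})
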