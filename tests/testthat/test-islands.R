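toy_systems <- function() {
  # adjacent gaps on one contig: 999 (too close), 1000, 5000, 15000, 15001
  starts <- c(1000)
  ends <- c(4000)
  gaps <- c(999, 1000, 5000, 15000, 15001)
  for (g in gaps) {
    starts <- c(starts, ends[length(ends)] + g + 1)
    ends <- c(ends, starts[length(starts)] + 2999)
  }
  df <- data.frame(genome_id = "g1", contig_id = "c1",
                   system_name = paste0("sys", seq_along(starts)),
                   start = as.integer(starts), end = as.integer(ends),
                   strand = "+", stringsAsFactors = FALSE)
  df$gene_ids <- as.list(paste0("m", seq_along(starts)))
  df
}

test_that("inter-system regions keep exactly the gaps inside [1000, 15000]", {
  sys <- toy_systems()
  genes <- protein_records("gx", "ACDEF", contig_id = "c1",
                           start = 1L, end = 5L, strand = "+")
  reg <- find_intersystem_regions(sys, genes)
  expect_equal(sort(reg$gap_bp), c(1000, 5000, 15000))  # inclusive bounds
})

test_that("only fully-contained genes count as intervening", {
  sys <- data.frame(genome_id = "g1", contig_id = "c1",
                    system_name = c("A", "B"),
                    start = c(1000L, 9001L), end = c(4000L, 12000L),
                    strand = "+", stringsAsFactors = FALSE)
  sys$gene_ids <- list("a1", "b1")
  genes <- protein_records(
    c("in1", "in2", "in3", "straddle_left", "straddle_right", "outside"),
    rep("ACDEF", 6), contig_id = "c1",
    start = c(4100L, 5000L, 7000L, 3900L, 8900L, 13000L),
    end =   c(4600L, 5500L, 7400L, 4500L, 9300L, 13400L), strand = "+")
  reg <- find_intersystem_regions(sys, genes)
  expect_equal(nrow(reg), 1)
  expect_equal(reg$gap_bp, 5000)
  expect_setequal(reg$intervening_protein_ids[[1]], c("in1", "in2", "in3"))
})

test_that("a boundary-touching gene is excluded, a boundary-adjacent one kept", {
  sys <- toy_systems()[2:3, ]   # gap of exactly 1000 between end 8000...
  sys <- data.frame(genome_id = "g1", contig_id = "c1",
                    system_name = c("A", "B"),
                    start = c(100L, 2101L), end = c(1100L, 3000L),
                    strand = "+", stringsAsFactors = FALSE)
  sys$gene_ids <- list("a", "b")
  genes <- protein_records(
    c("touch_left", "inside_tight", "touch_right"),
    rep("ACDEF", 3), contig_id = "c1",
    start = c(1100L, 1101L, 1200L), end = c(1500L, 2100L, 2101L),
    strand = "+")
  reg <- find_intersystem_regions(sys, genes)
  expect_equal(reg$intervening_protein_ids[[1]], "inside_tight")
})

test_that("only adjacent system pairs form regions; contigs never mix", {
  sys <- data.frame(genome_id = "g1",
                    contig_id = c("c1", "c1", "c1", "c2"),
                    system_name = c("A", "B", "C", "D"),
                    start = c(1000L, 7001L, 13002L, 5000L),
                    end = c(5000L, 11001L, 16002L, 9000L),
                    strand = "+", stringsAsFactors = FALSE)
  sys$gene_ids <- list("a", "b", "c", "d")
  genes <- protein_records("g0", "ACDEF", contig_id = "c1",
                           start = 6000L, end = 6500L, strand = "+")
  reg <- find_intersystem_regions(sys, genes)
  # A-B and B-C are adjacent (gap 2000 each); A-C is not a pair, c2 alone
  expect_equal(nrow(reg), 2)
  expect_equal(reg$left_system, c("A", "B"))
  expect_warning(
    find_intersystem_regions(sys,
                             protein_records("lost", "ACDEF",
                                             contig_id = "cZ", start = 1L,
                                             end = 50L, strand = "+")),
    "skipped")
})

test_that("intervening extraction deduplicates and warns on unknown ids", {
  regions <- data.frame(genome_id = "g1", contig_id = "c1",
                        left_system = "A", right_system = "B",
                        left_end = 1L, right_start = 100L, gap_bp = 98L)
  regions <- regions[rep(1, 2), ]
  regions$intervening_protein_ids <- list(c("p1", "p2"), c("p2", "ghost"))
  catalog <- protein_records(c("p1", "p2", "p3"), rep("ACDEF", 3))
  expect_warning(out <- extract_intervening_proteins(regions, catalog),
                 "ghost")
  expect_equal(out$protein_id, c("p1", "p2"))
  expect_equal(nrow(extract_intervening_proteins(regions[0, ], catalog)), 0)
})

test_that("prevalence reproduces the worked example: 21 of 7308 is 0.29%", {
  sys <- data.frame(genome_id = sprintf("m%05d", 1:7308), contig_id = "c",
                    system_name = "BREX_type_3", start = 1L, end = 10L,
                    strand = "+", stringsAsFactors = FALSE)
  sys$gene_ids <- replicate(7308, "g", simplify = FALSE)
  p <- prevalence(sys, sprintf("m%05d", 1:21), "BREX_type_3")
  expect_equal(p$carriers, 21)
  expect_equal(p$total, 7308)
  expect_equal(p$percent, 0.29)
})

test_that("prevalence edge cases: no carriers, absent system, marker-only genomes", {
  sys <- data.frame(genome_id = c("g1", "g2", "g1"), contig_id = "c",
                    system_name = c("BREX_type_3", "BREX_type_3", "RM"),
                    start = 1L, end = 10L, strand = "+",
                    stringsAsFactors = FALSE)
  sys$gene_ids <- replicate(3, "x", simplify = FALSE)
  expect_equal(prevalence(sys, character(0), "BREX_type_3")$percent, 0)
  # marker in a genome without the system is ignored on both sides
  p <- prevalence(sys, c("g2", "g99"), "BREX_type_3")
  expect_equal(p$carriers, 1)
  expect_equal(p$total, 2)
  expect_error(prevalence(sys, "g1", "Zorya"), "no genome")
})

test_that("prevalence is scale-free under duplicated annotations", {
  sys <- data.frame(genome_id = sprintf("g%02d", 1:40), contig_id = "c",
                    system_name = "BREX_type_3", start = 1L, end = 10L,
                    strand = "+", stringsAsFactors = FALSE)
  sys$gene_ids <- replicate(40, "x", simplify = FALSE)
  hits <- sprintf("g%02d", 1:3)
  p1 <- prevalence(sys, hits, "BREX_type_3")
  p2 <- prevalence(rbind(sys, sys), hits, "BREX_type_3")
  expect_equal(p1$percent, p2$percent)
  expect_equal(p1$total, p2$total)
})

test_that("gene neighborhoods window by overlap and report signed offsets", {
  genes <- protein_records(
    c("far_left", "left", "marker", "right", "far_right", "other_contig"),
    rep("ACDEF", 6),
    contig_id = c(rep("c1", 5), "c2"),
    start = c(1000L, 19000L, 30000L, 35000L, 55000L, 30000L),
    end =   c(1500L, 19500L, 31000L, 35500L, 55500L, 31000L),
    strand = "+")
  nb <- gene_neighborhood("marker", genes, window_bp = 10000)
  expect_equal(nb$protein_id, c("marker", "right"))
  expect_equal(nb$offset_bp, c(0, 5000))
  nb0 <- gene_neighborhood("marker", genes, window_bp = 0)
  expect_equal(nb0$protein_id, "marker")
  solo <- protein_records("alone", "ACDEF", contig_id = "cX",
                          start = 5L, end = 9L, strand = "+")
  expect_equal(nrow(gene_neighborhood("alone", solo)), 1)
  expect_error(gene_neighborhood("nope", genes), "not found")
})
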