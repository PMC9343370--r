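test_that("RPKM and RPK follow their formulas", {
  expect_equal(rpkm(100, 1e6, 2000), 50)
  expect_equal(rpkm(0, 1e6, 2000), 0)
  expect_equal(rpkm(100, 2e6, 2000), 25)      # doubling total halves RPKM
  expect_equal(rpk(500, 2500), 200)
  expect_equal(rpk(0, 1000), 0)
  expect_equal(rpk(500, 1250), 400)           # half width, double RPK
  expect_error(rpkm(10, 0, 100), "> 0")
  expect_error(rpk(10, 0), "> 0")
})

test_that("overlap is half-open with a 1 bp minimum", {
  a <- data.frame(chrom = "c1", start = 100, end = 200)
  expect_true(interval_overlaps(data.frame(chrom = "c1", start = 199,
                                           end = 300), a))
  expect_false(interval_overlaps(data.frame(chrom = "c1", start = 200,
                                            end = 300), a))
  expect_false(interval_overlaps(data.frame(chrom = "c2", start = 100,
                                            end = 200), a))
})

test_that("merge follows the -d gap convention and is idempotent", {
  x <- data.frame(chrom = "c", start = c(100, 1150), end = c(200, 1300))
  expect_equal(merge_peaks(x, 1000),
               data.frame(chrom = "c", start = 100, end = 1300))
  x2 <- data.frame(chrom = "c", start = c(100, 1201), end = c(200, 1300))
  expect_equal(nrow(merge_peaks(x2, 1000)), 2L) # gap 1001 stays split
  ov <- data.frame(chrom = "c", start = c(100, 150), end = c(200, 400))
  expect_equal(merge_peaks(ov, 0),
               data.frame(chrom = "c", start = 100, end = 400))
})

test_that("consensus retention is inclusive at the 50% boundary", {
  pk <- function(s, e) data.frame(chrom = "c", start = s, end = e)
  present <- pk(100, 200)
  # 2 of 4 samples -> retained
  cons <- consensus_peaks(list(present, present, pk(5000, 5100),
                               pk(7000, 7100)))
  expect_true(any(cons$start == 100 & cons$end == 200))
  # 1 of 4 -> dropped
  cons <- consensus_peaks(list(present, pk(5000, 5100), pk(6000, 6100),
                               pk(7000, 7100)))
  expect_false(any(cons$start == 100))
  # 1 of 2 -> retained
  cons <- consensus_peaks(list(present, pk(5000, 5100)))
  expect_true(any(cons$start == 100))
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0))
  expect_equal(nrow(consensus_peaks(list(empty))), 0L)
})

test_that("TSS partition and the ±3 kb window convention", {
  genes <- data.frame(gene_id = c("gA", "gB"), chrom = "c",
                      start = c(10000, 50000), end = c(20000, 60000),
                      strand = c("+", "-"))
  expect_equal(gene_tss(genes), c(gA = 10000, gB = 59999))
  # overlapping the window edge from outside
  pk <- data.frame(chrom = "c", start = c(12900, 13200, 10005, 30000),
                   end = c(13100, 13400, 10010, 30100))
  expect_equal(partition_tss(pk, genes),
               c("proximal", "distal", "proximal", "distal"))
  expect_error(gene_tss(transform(genes, strand = ".")), "strand")
})

test_that("peak annotation: nearest TSS / nearest body with tie-breaking", {
  genes <- data.frame(gene_id = c("geneA", "geneB", "geneC"), chrom = "c",
                      start = c(10000, 16000, 100000),
                      end = c(12000, 18000, 120000),
                      strand = c("+", "+", "+"))
  pk <- data.frame(chrom = "c",
                   start = c(10400, 110000, 13000 - 50),
                   end = c(10600, 110200, 13000 + 50))
  ann <- annotate_peaks(pk, genes)
  # proximal, midpoint 500 bp from geneA TSS vs 5500 from geneB
  expect_equal(ann$gene_id[1], "geneA")
  # distal peak inside geneC's body
  expect_equal(ann$tss_class[2], "distal")
  expect_equal(ann$gene_id[2], "geneC")
  expect_equal(ann$distance[2], 0)
  # midpoint 13000: equidistant (3000) from both TSSs -> lexicographic + flag
  expect_equal(ann$gene_id[3], "geneA")
  expect_true(ann$ambiguous[3])
  # no genes on the chromosome -> unassigned
  ann2 <- annotate_peaks(data.frame(chrom = "other", start = 1, end = 10),
                         genes)
  expect_true(is.na(ann2$gene_id))
})

test_that("replicate-consistent peak changes mirror the DEG rule", {
  wt <- rbind(c(10, 12), c(10, 12), c(10, 10))
  ko <- rbind(c(20, 22), c(20, 8), c(10, 10))
  expect_equal(classify_replicate_change(wt, ko),
               c("increased", "unchanged", "unchanged"))
  expect_equal(classify_replicate_change(ko, wt)[1], "decreased")
})

test_that("YY1 promoter/enhancer classification and multi-gene annotation", {
  genes <- data.frame(gene_id = c("g1", "g2"), chrom = "c",
                      start = c(200000, 201000), end = c(202000, 204000),
                      strand = c("+", "+"))
  yy1 <- data.frame(chrom = "c",
                    start = c(199000, 250000, 260000, 400000),
                    end = c(199200, 250400, 260400, 400400))
  ac <- data.frame(chrom = "c", start = c(250100, 400100),
                   end = c(250300, 400500))
  r <- classify_yy1_peaks(yy1, ac, genes)
  # peak 1: 1 kb upstream of g1 TSS -> promoter, annotated to both genes
  expect_equal(r$class[1], "promoter")
  expect_setequal(r$annotations$gene_id[r$annotations$peak == 1],
                  c("g1", "g2"))
  # peak 2: ~50 kb from TSS with H3K27ac overlap -> enhancer
  expect_equal(r$class[2], "enhancer")
  # peak 3: in the band but no H3K27ac -> other
  expect_equal(r$class[3], "other")
  # peak 4: beyond 125 kb even with H3K27ac -> other
  expect_equal(r$class[4], "other")
  # promoter and enhancer sets disjoint by construction
  expect_length(intersect(which(r$class == "promoter"),
                          which(r$class == "enhancer")), 0)
})

test_that("interval operations agree with the naive quadratic oracle", {
  set.seed(31)
  for (rep in 1:40) {
    a <- random_intervals(sample(10:80, 1))
    b <- random_intervals(sample(10:80, 1))
    expect_identical(interval_overlaps(a, b), oracle_overlaps_any(a, b))
    g <- sample(c(0, 500, 1000), 1)
    got <- merge_peaks(a, g)
    want <- oracle_merge(a, g)
    want <- want[order(want$chrom, want$start), ]
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
    # merge idempotence
    expect_equal(merge_peaks(got, g), got)
  }
})

test_that("consensus monotonicity and partition exhaustiveness (property)", {
  set.seed(37)
  for (rep in 1:20) {
    sets <- lapply(seq_len(sample(2:5, 1)), function(i)
      random_intervals(sample(5:40, 1)))
    prev <- NULL
    for (f in c(0.25, 0.5, 0.75, 1)) {
      cur <- consensus_peaks(sets, min_fraction = f)
      if (!is.null(prev))
        expect_true(all(paste(cur$chrom, cur$start, cur$end) %in%
                          paste(prev$chrom, prev$start, prev$end)))
      prev <- cur
    }
    genes <- data.frame(gene_id = sprintf("g%d", 1:5), chrom = "chr1",
                        start = seq(1000, 9000, 2000),
                        end = seq(1000, 9000, 2000) + 500,
                        strand = rep(c("+", "-"), length.out = 5))
    pk <- random_intervals(30)
    part <- partition_tss(pk, genes)
    expect_true(all(part %in% c("proximal", "distal")))
    expect_identical(part, oracle_partition(pk, genes))
  }
})
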