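# Peak-file parsing, bead-grid annotation, CTCF boundary calling, promoters.

test_that("BED and narrowPeak dialects parse with the documented column mapping", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c("track name=test", "chr1\t1000\t2000",
               "chr1\t500\t800\tx\t7\t+"), bed)
  p <- parse_peak_file(bed, "bed")
  expect_equal(nrow(p), 2)
  expect_equal(p$start, c(500, 1000))   # sorted by start
  expect_equal(p$score, c(7, 0))        # 3-column line gets score 0
  expect_equal(p$strand, c("+", "."))

  np <- tempfile(fileext = ".narrowPeak")
  writeLines("chr1\t100\t900\tpk1\t800\t.\t14.2\t5.2\t3.1\t400", np)
  q <- parse_peak_file(np, "narrowPeak")
  expect_equal(q$score, 14.2)           # signalValue, not column 5

  empty <- tempfile(); writeLines(character(), empty)
  expect_equal(nrow(parse_peak_file(empty, "bed")), 0)
})

test_that("malformed peak lines raise errors naming the line number", {
  bad <- tempfile()
  writeLines(c("chr1\t100\t200", "chr1\t500"), bad)
  expect_error(parse_peak_file(bad, "bed"), "line 2")
  bad2 <- tempfile()
  writeLines(c("chr1\t300\t100"), bad2)
  expect_error(parse_peak_file(bad2, "bed"), "line 1")
})

test_that("bead grid conversion functions are mutual inverses", {
  fr <- genome_fragment("chr1", 10000, 60000)
  expect_equal(fr$n_beads, 50)
  expect_equal(bead_of(fr, 10000), 0)
  expect_equal(bead_of(fr, 11000), 1)
  iv <- interval_of(fr, 0:(fr$n_beads - 1))
  expect_equal(bead_of(fr, iv$start), 0:(fr$n_beads - 1))
  expect_error(bead_of(fr, 60000), "outside")
  expect_error(genome_fragment("chr1", 0, 5000), "at least 10 beads")
})

test_that("a bead is flagged iff it overlaps >= 1 bp of a peak of that assay", {
  fr <- genome_fragment("chr1", 0, 10000)
  tr <- annotate_marks(fr, list(atac = peaks_df("chr1", 1500, 1600)))
  expect_equal(tr$bead[tr$atac], 1)
  tr2 <- annotate_marks(fr, list(atac = peaks_df("chr1", 900, 2100)))
  expect_equal(tr2$bead[tr2$atac], c(0, 1, 2))
  tr3 <- annotate_marks(fr, list())
  expect_false(any(tr3$atac | tr3$h3k27ac | tr3$h3k27me3 | tr3$h3k9me3))
  expect_error(annotate_marks(fr, list(h3k4me3 = peaks_df("chr1", 0, 100))),
               "unknown assay")
})

test_that("annotation is order-independent and round-trips through BED export", {
  fr <- genome_fragment("chrT", 0, 30000)
  pk <- peaks_df("chrT", c(2000, 11000, 4500), c(3500, 12000, 5100))
  t1 <- annotate_marks(fr, list(atac = pk, h3k27ac = pk[2, ]))
  t2 <- annotate_marks(fr, list(atac = pk[c(3, 1, 2), ], h3k27ac = pk[2, ]))
  expect_identical(t1$atac, t2$atac)
  dir <- tempfile()
  paths <- export_track_bed(t1, dir)
  reread <- annotate_marks(fr, list(
    atac = parse_peak_file(paths[["atac"]], "bed"),
    h3k27ac = parse_peak_file(paths[["h3k27ac"]], "bed"),
    h3k27me3 = parse_peak_file(paths[["h3k27me3"]], "bed"),
    h3k9me3 = parse_peak_file(paths[["h3k9me3"]], "bed")))
  for (m in c("atac", "h3k27ac", "h3k27me3", "h3k9me3"))
    expect_identical(t1[[m]], reread[[m]])
})

test_that("CTCF beads require RAD21 co-occupancy and a motif, with orientation", {
  fr <- genome_fragment("chr1", 0, 20000)
  tr <- annotate_marks(fr, list())
  ctcf <- peaks_df("chr1", c(3000, 9000), c(3400, 9400), score = c(10, 8))
  rad21 <- peaks_df("chr1", 3100, 3300)   # overlaps only the first peak
  ctcf$name <- c("p1", "p2")
  motifs <- data.frame(chrom = "chr1", start = c(3150, 9150), end = c(3169, 9169),
                       strand = "+", score = 12, peak_id = c("p1", "p2"))
  out <- call_ctcf_beads(tr, ctcf, rad21, motifs)
  ct <- attr(out, "ctcf")
  expect_equal(unique(ct$bead), 3)                 # second peak lacks RAD21
  expect_equal(ct$orientation, "forward")
  expect_equal(ct$prob, 1)                         # score / max score

  # no motif -> no boundary
  out2 <- call_ctcf_beads(tr, ctcf[1, ], rad21,
                          motifs[motifs$peak_id == "none", ])
  expect_equal(nrow(attr(out2, "ctcf")), 0)
})

test_that("similarly scoring opposite-strand motifs make a site bidirectional", {
  fr <- genome_fragment("chr1", 0, 20000)
  tr <- annotate_marks(fr, list())
  ctcf <- peaks_df("chr1", 5000, 5400, score = 6); ctcf$name <- "p1"
  rad21 <- peaks_df("chr1", 5000, 5400)
  equal <- data.frame(chrom = "chr1", start = c(5100, 5200), end = c(5119, 5219),
                      strand = c("+", "-"), score = c(10, 10), peak_id = "p1")
  out <- call_ctcf_beads(tr, ctcf, rad21, equal)
  expect_equal(attr(out, "ctcf")$orientation, "bidirectional")
  # clearly different scores -> best strand wins
  unequal <- equal; unequal$score <- c(10, 5)
  out2 <- call_ctcf_beads(tr, ctcf, rad21, unequal)
  expect_equal(attr(out2, "ctcf")$orientation, "forward")
  # motif outside its peak is skipped with a warning
  stray <- equal; stray$start <- c(100, 5200); stray$end <- c(119, 5219)
  expect_warning(call_ctcf_beads(tr, ctcf, rad21, stray), "outside its peak")
})

test_that("multiple peaks in one bead enumerate activation outcomes", {
  fr <- genome_fragment("chr1", 0, 20000)
  tr <- annotate_marks(fr, list())
  ctcf <- peaks_df("chr1", c(5000, 5500), c(5400, 5900), score = c(10, 5))
  ctcf$name <- c("f", "b")
  rad21 <- peaks_df("chr1", 5000, 5900)
  motifs <- data.frame(chrom = "chr1", start = c(5100, 5600), end = c(5119, 5619),
                       strand = c("+", "-"), score = 10, peak_id = c("f", "b"))
  out <- call_ctcf_beads(tr, ctcf, rad21, motifs)
  ct <- attr(out, "ctcf")
  b5 <- ct[ct$bead == 5, ]
  # outcomes: forward only (1 * 0.5), backward only (0 * ...), both ->
  # bidirectional; with p_f = 1 and p_b = 0.5 the forward-only and
  # bidirectional outcomes split 0.5 / 0.5
  expect_setequal(b5$orientation, c("forward", "bidirectional"))
  expect_equal(sum(b5$prob), 1, tolerance = 1e-12)
  expect_equal(b5$prob[b5$orientation == "bidirectional"], 0.5)
})

test_that("stochastic CTCF activation follows the per-bead probabilities", {
  fr <- genome_fragment("chr1", 0, 20000)
  tr <- annotate_marks(fr, list())
  attr(tr, "ctcf") <- data.frame(bead = c(3L, 7L, 11L),
                                 orientation = "forward",
                                 prob = c(1, 0, 0.5))
  always <- vapply(1:50, function(s) 3 %in% sample_ctcf_activation(tr, s)$bead,
                   logical(1))
  expect_true(all(always))
  never <- vapply(1:50, function(s) 7 %in% sample_ctcf_activation(tr, s)$bead,
                  logical(1))
  expect_false(any(never))
  set.seed(1)
  half <- mean(vapply(1:10000, function(s)
    11 %in% sample_ctcf_activation(tr)$bead, logical(1)))
  expect_equal(half, 0.5, tolerance = 0.02)
  # deterministic under a fixed seed
  expect_identical(sample_ctcf_activation(tr, 42), sample_ctcf_activation(tr, 42))
})

test_that("promoter beads come from interval midpoints; bad inputs are handled", {
  fr <- genome_fragment("chr1", 0, 20000)
  tr <- annotate_marks(fr, list())
  prom <- data.frame(chrom = "chr1", start = c(4500, 12000), end = c(5500, 13000),
                     gene = c("A", "B"))
  out <- annotate_promoters(tr, prom)
  expect_equal(attr(out, "promoters")$bead, c(5, 12))
  expect_true(all(out$promoter[c(6, 13)]))
  # outside the fragment: dropped with a warning
  far <- data.frame(chrom = "chr1", start = 50000, end = 51000, gene = "C")
  expect_warning(annotate_promoters(tr, far), "dropped")
  dup <- data.frame(chrom = "chr1", start = c(1000, 2000), end = c(1100, 2100),
                    gene = c("A", "A"))
  expect_error(annotate_promoters(tr, dup), "duplicate")
})
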