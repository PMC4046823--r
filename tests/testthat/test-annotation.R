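test_that("promoter windows follow the 5 kb upstream / 1 kb downstream model", {
  plus <- promoter_windows(data.frame(chrom = "chr1", position = 10000,
                                      strand = "+", gene_id = "G"))
  expect_equal(GenomicRanges::start(plus) - 1L, 5000L)   # 0-based start
  expect_equal(GenomicRanges::end(plus), 11000L)         # half-open end

  # minus strand: window mirrored around the TSS, same width
  minus <- promoter_windows(data.frame(chrom = "chr1", position = 10000,
                                       strand = "-", gene_id = "G"))
  expect_equal(GenomicRanges::width(minus), 6000L)
  expect_equal(GenomicRanges::end(minus), 15001L)

  # clamped at the chromosome start
  clamp <- promoter_windows(data.frame(chrom = "chr1", position = 2000,
                                       strand = "+", gene_id = "G"))
  expect_equal(GenomicRanges::start(clamp) - 1L, 0L)
  expect_equal(GenomicRanges::end(clamp), 3000L)

  expect_error(promoter_windows(data.frame(chrom = "chr1", position = 1,
                                           strand = ".", gene_id = "G")),
               "strand")

  # duplicate TSS records collapse to one window
  dup <- promoter_windows(data.frame(chrom = "chr1", position = c(10000, 10000),
                                     strand = "+", gene_id = c("G", "G")))
  expect_equal(length(dup), 1L)
})

test_that("annotation flags promoter peaks and records TFBS hits", {
  sc <- demo_scene()
  ann <- annotate_peaks(sc$peaks, sc$catalog, sc$promoters)
  expect_equal(ann$peaks$in_promoter, c(TRUE, FALSE, FALSE))
  expect_equal(nrow(ann$hits), 4L)
  expect_equal(sort(unique(ann$hits$matrix_id)), c("V$A_01", "V$B_01"))
  expect_equal(lengths(ann$per_tf_sites), c("V$A_01" = 2L, "V$B_01" = 2L))
  # every recorded per-TF site really overlaps some peak
  for (tf in names(ann$per_tf_sites)) {
    for (s in ann$per_tf_sites[[tf]]) {
      hit <- any(vapply(seq_along(sc$peaks), function(i) {
        interval_overlaps(sc$peaks[i], sc$catalog$sites[s])
      }, logical(1)))
      expect_true(hit)
    }
  }
})

test_that("abutting site and peak do not annotate each other", {
  peaks <- peak_set("chr1", 100, 300, name = "P")
  sites <- GenomicRanges::GRanges("chr1", IRanges::IRanges(301, 310),
                                  matrix_id = "V$X_01")  # 0-based [300,310)
  ann <- annotate_peaks(peaks, tfbs_catalog(sites),
                        promoter_windows(data.frame(chrom = character(0),
                                                    position = integer(0),
                                                    strand = character(0))))
  expect_equal(nrow(ann$hits), 0L)
})

test_that("empty catalog yields empty annotations", {
  gr <- GenomicRanges::GRanges()
  S4Vectors::mcols(gr)$matrix_id <- character(0)
  sc <- demo_scene()
  ann <- annotate_peaks(sc$peaks, tfbs_catalog(gr), sc$promoters)
  expect_equal(nrow(ann$hits), 0L)
  cnt <- count_summary(ann)
  expect_equal(cnt$n_tfbs_peaks_total, 0L)
  expect_equal(cnt$n_tfbs_total, 0L)
})

test_that("count_summary returns the six table counts", {
  sc <- demo_scene()
  ann <- annotate_peaks(sc$peaks, sc$catalog, sc$promoters)
  cnt <- count_summary(ann)
  expect_equal(unlist(cnt), c(
    n_peaks_total = 3, n_peaks_promoter = 1, n_tfbs_peaks_total = 2,
    n_tfbs_peaks_promoter = 1, n_tfbs_total = 4, n_tfbs_promoter = 2
  ))
  # invariants
  expect_lte(cnt$n_tfbs_peaks_total, cnt$n_peaks_total)
  expect_lte(cnt$n_tfbs_peaks_promoter,
             min(cnt$n_peaks_promoter, cnt$n_tfbs_peaks_total))
  expect_lte(sum(lengths(ann$per_tf_sites)), cnt$n_tfbs_total * ann$catalog$tf_count)

  # empty peak set
  e <- peak_set(character(0), integer(0), integer(0))
  cnt0 <- count_summary(annotate_peaks(e, sc$catalog, sc$promoters))
  expect_true(all(unlist(cnt0) == 0))

  # the site-centric promoter reading is available and agrees here
  cnt2 <- count_summary(ann, site_in_promoter = TRUE, promoters = sc$promoters)
  expect_equal(cnt2$n_tfbs_promoter, 2L)
})

test_that("indexed annotation matches all-pairs brute force on random scenes", {
  set.seed(21)
  for (i in 1:60) {
    peaks <- normalize_peaks(rand_peak_set(sample.int(8, 1), name = "P"))
    sites_ps <- rand_peak_set(sample.int(15, 1), max_w = 25L)
    sites <- GenomicRanges::granges(sites_ps)
    S4Vectors::mcols(sites)$matrix_id <-
      sample(c("V$A_01", "V$B_01", "V$C_01"), length(sites), replace = TRUE)
    tss <- data.frame(
      chrom = sample(names(toy_genome), 3, replace = TRUE),
      position = sample.int(3000, 3) - 1L,
      strand = sample(c("+", "-"), 3, replace = TRUE),
      gene_id = paste0("G", 1:3)
    )
    proms <- promoter_windows(tss, upstream = 500, downstream = 100)
    ann <- annotate_peaks(peaks, tfbs_catalog(sites), proms)

    pk <- as_bed_df(peaks)
    st <- as_bed_df(peak_set(as.character(GenomicRanges::seqnames(sites)),
                             GenomicRanges::start(sites) - 1L,
                             GenomicRanges::end(sites)))
    pr <- data.frame(chrom = as.character(GenomicRanges::seqnames(proms)),
                     start = GenomicRanges::start(proms) - 1L,
                     end = GenomicRanges::end(proms))
    ov_sites <- pairwise_overlap(pk, st)
    ov_proms <- pairwise_overlap(pk, pr)
    expect_equal(ann$peaks$in_promoter, apply(ov_proms, 1, any))
    got_pairs <- ann$hits[order(ann$hits$peak, ann$hits$site), c("peak", "site")]
    want_pairs <- which(ov_sites, arr.ind = TRUE)
    want_pairs <- data.frame(peak = want_pairs[, 1], site = want_pairs[, 2])
    want_pairs <- want_pairs[order(want_pairs$peak, want_pairs$site), ]
    rownames(got_pairs) <- rownames(want_pairs) <- NULL
    expect_equal(got_pairs, want_pairs)
  }
})

test_that("promoter-restriction order does not matter for promoter TFBS hits", {
  # counting sites hit by promoter peaks equals annotating only promoter peaks
  set.seed(33)
  for (i in 1:20) {
    peaks <- normalize_peaks(rand_peak_set(6, name = "P"))
    sites_ps <- rand_peak_set(12, max_w = 25L)
    sites <- GenomicRanges::granges(sites_ps)
    S4Vectors::mcols(sites)$matrix_id <- rep("V$A_01", length(sites))
    cat <- tfbs_catalog(sites)
    tss <- data.frame(chrom = "chrA", position = c(1000, 3500),
                      strand = "+", gene_id = c("G1", "G2"))
    proms <- promoter_windows(tss, upstream = 800, downstream = 200)
    ann <- annotate_peaks(peaks, cat, proms)
    full <- count_summary(ann)
    prom_only <- annotate_peaks(ann$peaks[ann$peaks$in_promoter], cat, proms)
    expect_equal(full$n_tfbs_promoter, count_summary(prom_only)$n_tfbs_total)
  }
})

test_that("matrix ids map to display names by stripping prefix and suffix", {
  expect_equal(matrix_id_to_tf_name(c("V$ELK1_02", "V$CREB_Q2",
                                      "V$CETS1P54_01", "NFY_01")),
               c("ELK1", "CREB", "CETS1P54", "NFY"))
})
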