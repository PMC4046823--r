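# Independent brute-force oracles used across the suite. These work on plain
# 0-based half-open coordinate data frames (as_bed_df output) and never call
# the interval machinery they are checking.

toy_genome <- c(chrA = 5000L, chrB = 3000L)

# Per-base membership mask: list of logical vectors, one per chromosome;
# element i is TRUE iff 0-based position i-1 is covered.
base_mask <- function(ps, genome = toy_genome) {
  ch <- as.vector(GenomicRanges::seqnames(ps))
  s1 <- GenomicRanges::start(ps)   # 1-based first covered base
  e1 <- GenomicRanges::end(ps)     # 1-based last covered base
  mask <- lapply(genome, logical)
  for (i in seq_along(ch)) {
    mask[[ch[i]]][seq.int(s1[i], e1[i])] <- TRUE
  }
  mask
}

mask_or <- function(a, b) {
  for (n in names(a)) a[[n]] <- a[[n]] | b[[n]]
  a
}
mask_and <- function(a, b) {
  for (n in names(a)) a[[n]] <- a[[n]] & b[[n]]
  a
}
mask_count <- function(m) sum(vapply(m, sum, numeric(1)))
masks_equal <- function(a, b) {
  for (n in names(a)) if (!identical(a[[n]], b[[n]])) return(FALSE)
  TRUE
}

# Random peak set on the toy genome; may contain overlapping peaks.
rand_peak_set <- function(n, genome = toy_genome, max_w = 400L,
                          name = "R") {
  if (n == 0L) return(peak_set(character(0), integer(0), integer(0), name = name))
  ch <- sample(names(genome), n, replace = TRUE)
  w <- sample.int(max_w, n, replace = TRUE)
  s <- vapply(seq_len(n), function(i) {
    sample.int(genome[[ch[i]]] - w[i], 1L) - 1L
  }, numeric(1))
  peak_set(ch, s, s + w, height = round(stats::runif(n, 1, 100), 2),
           name = name)
}

# All-pairs overlap test on 0-based half-open rows (a, b: bed-style dfs);
# returns logical matrix [nrow(a) x nrow(b)].
pairwise_overlap <- function(a, b) {
  outer(seq_len(nrow(a)), seq_len(nrow(b)), function(i, j) {
    a$chrom[i] == b$chrom[j] & a$start[i] < b$end[j] & b$start[j] < a$end[i]
  })
}

# Small deterministic annotation scene used by several tests.
demo_scene <- function() {
  peaks <- peak_set("chr1", c(5500, 20000, 40000), c(6000, 20400, 40200),
                    height = c(10, 20, 7), name = "D")
  sites <- GenomicRanges::GRanges(
    "chr1",
    IRanges::IRanges(start = c(5601, 5701, 20101, 20151, 45001),
                     end   = c(5610, 5712, 20110, 20160, 45012)),
    matrix_id = c("V$A_01", "V$A_01", "V$B_01", "V$B_01", "V$B_01")
  )
  tss <- data.frame(chrom = "chr1", position = c(10000, 24000),
                    strand = c("+", "-"), gene_id = c("G1", "G2"))
  list(peaks = peaks, catalog = tfbs_catalog(sites), tss = tss,
       promoters = promoter_windows(tss))
}
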