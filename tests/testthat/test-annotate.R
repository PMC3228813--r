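test_that("a fully member-dense record is annotated end to end", {
  seq <- random_dna(100, seed = 61)
  oligos <- substring(seq, 1:85, 16:100)
  cs <- literal_cloud_set(unique(oligos), k = 16L)
  reg <- annotate_repeats(c(chr = seq), cs)
  expect_equal(nrow(reg), 1L)
  expect_equal(reg$start, 0L)
  expect_equal(reg$end, 100L)
  expect_equal(reg$posterior, 1)
})

test_that("a 25-nt record whose ten oligos are members yields exactly [0, 25)", {
  seq <- random_dna(25, seed = 62)
  oligos <- substring(seq, 1:10, 16:25)
  cs <- literal_cloud_set(unique(oligos), k = 16L)
  reg <- annotate_repeats(c(chr = seq), cs)
  expect_equal(nrow(reg), 1L)
  expect_equal(reg$start, 0L)
  expect_equal(reg$end, 25L)
  expect_equal(reg$length, 25L)
})

test_that("no member oligos means no regions; short records are skipped with a warning", {
  cs <- literal_cloud_set("ACGTACGTACGTACGT", k = 16L)
  reg <- annotate_repeats(c(chr = strrep("T", 100)), cs)
  expect_equal(nrow(reg), 0L)
  expect_warning(
    out <- annotate_repeats(c(tiny = strrep("T", 20), ok = strrep("T", 100)), cs),
    "shorter than 25"
  )
  expect_equal(nrow(out), 0L)
})

test_that("the shortest possible annotation is window + k - 1 nt", {
  # members only at the first 8 oligo positions of a long record: exactly one
  # window reaches 8-of-10 density, giving a 25-nt region at k = 16
  set.seed(63)
  repeat {
    seq <- random_dna(80)
    head_oligos <- unique(substring(seq, 1:8, 16:23))
    tail_oligos <- substring(seq, 9:65, 24:80)
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(tail_oligos)))
    if (length(head_oligos) == 8L && !any(tail_oligos %in% head_oligos) &&
        !any(rc %in% head_oligos)) break
  }
  cs <- literal_cloud_set(head_oligos, k = 16L)
  reg <- annotate_repeats(c(chr = seq), cs)
  expect_equal(nrow(reg), 1L)
  expect_equal(reg$length, 25L)
  expect_equal(c(reg$start, reg$end), c(0L, 25L))
})

test_that("annotation is idempotent and monotone in the density threshold", {
  sim <- plant_genome(5e4, repeat_family(master_length = 200, copies = 30,
                                         divergence = 0.05, name = "f"),
                      seed = 64)
  counts <- count_oligos(sim$genome, 12)
  cs <- build_clouds(counts, cloud_params(1, 2, 4, 40, 40))
  r1 <- annotate_repeats(sim$genome, cs)
  r2 <- annotate_repeats(sim$genome, cs)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  strict <- annotate_repeats(sim$genome, cs, min_frac = 1.0)
  lax <- annotate_repeats(sim$genome, cs, min_frac = 0.5)
  expect_lte(sum(strict$length), sum(r1$length))
  expect_gte(sum(lax$length), sum(r1$length))
})

test_that("annotating the reverse complement mirrors the coordinates", {
  sim <- plant_genome(3e4, repeat_family(master_length = 150, copies = 20,
                                         divergence = 0.03), seed = 65)
  counts <- count_oligos(sim$genome, 12)
  cs <- build_clouds(counts, cloud_params(1, 2, 4, 40, 40))
  fwd <- annotate_repeats(sim$genome, cs)
  L <- nchar(sim$genome[[1]])
  rc_genome <- setNames(as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(sim$genome))), names(sim$genome))
  bwd <- annotate_repeats(rc_genome, cs)
  mirrored <- tibble::tibble(start = L - rev(bwd$end), end = L - rev(bwd$start))
  expect_equal(mirrored$start, fwd$start)
  expect_equal(mirrored$end, fwd$end)
})

test_that("windows never cross runs of ambiguous bases", {
  seq <- random_dna(60, seed = 66)
  oligos <- unique(substring(seq, 1:45, 16:60))
  cs <- literal_cloud_set(oligos, k = 16L)
  # interrupting the record with N splits it into two sub-30-nt pieces, each
  # still long enough for one window
  broken <- paste0(substr(seq, 1, 30), "NN", substr(seq, 31, 60))
  reg <- annotate_repeats(c(chr = broken), cs)
  expect_true(all(reg$length >= 25L))
  expect_true(nrow(reg) >= 1L)
  # no region spans the N gap
  expect_true(all(reg$end <= 30L | reg$start >= 32L))
})

test_that("merge_regions bridges gaps and recomputes posteriors when possible", {
  reg <- pclouds:::new_pc_regions(tibble::tibble(
    chrom = "c", start = c(0L, 25L), end = c(25L, 50L),
    length = c(25L, 25L), posterior = c(0.4, 0.9)))
  m <- merge_regions(reg, gap = 0)
  expect_equal(nrow(m), 1L)
  expect_equal(c(m$start, m$end), c(0L, 50L))
  expect_equal(m$posterior, 0.9)  # max of inputs without an FP table

  apart <- pclouds:::new_pc_regions(tibble::tibble(
    chrom = "c", start = c(0L, 30L), end = c(25L, 55L),
    length = c(25L, 25L), posterior = c(1, 1)))
  expect_equal(nrow(merge_regions(apart, gap = 0)), 2L)
  expect_equal(nrow(merge_regions(apart, gap = 5)), 1L)

  fp <- estimate_fp_table(
    tibble::tibble(length = rep(55L, 10)),
    tibble::tibble(length = rep(55L, 2))
  )
  scored <- merge_regions(apart, gap = 5, fp_table = fp)
  expect_equal(scored$posterior, 1 - 0.2)
})

test_that("BED6 output round-trips with half-up integer scores", {
  reg <- pclouds:::new_pc_regions(tibble::tibble(
    chrom = c("c1", "c2"), start = c(0L, 10L), end = c(25L, 60L),
    length = c(25L, 50L), posterior = c(0.4995, 1)))
  path <- withr::local_tempfile(fileext = ".bed")
  write_bed(reg, path)
  back <- read_bed(path)
  expect_equal(back$chrom, reg$chrom)
  expect_equal(back$start, reg$start)
  expect_equal(back$end, reg$end)
  expect_equal(back$score, c(500, 1000))  # 499.5 rounds half-up
  expect_equal(back$strand, c(".", "."))
})

test_that("masking removes intervals from the scan", {
  seq <- random_dna(100, seed = 67)
  oligos <- unique(substring(seq, 1:85, 16:100))
  cs <- literal_cloud_set(oligos, k = 16L)
  bed <- tibble::tibble(chrom = "chr", start = 0L, end = 50L)
  masked <- mask_regions(c(chr = seq), bed)
  expect_equal(substr(masked[["chr"]], 1, 50), strrep("N", 50))
  reg <- annotate_repeats(masked, cs)
  expect_true(all(reg$start >= 50L))
})
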