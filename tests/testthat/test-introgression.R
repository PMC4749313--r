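toy_loci <- function(n = 5) {
  as_loci(data.frame(
    chrom = "chr1", pos = seq_len(n) * 100L,
    ancestral_allele = "A", derived_allele = "G",
    stringsAsFactors = FALSE))
}

test_that("locus validation catches bad positions and identical alleles", {
  expect_error(as_loci(data.frame(chrom = "chr1", pos = 0L,
                                  ancestral_allele = "A",
                                  derived_allele = "G")), "1-based")
  expect_error(as_loci(data.frame(chrom = "chr1", pos = 5L,
                                  ancestral_allele = "A",
                                  derived_allele = "A")), "identical")
  expect_error(as_loci(data.frame(chrom = "chr1", pos = 5L)), "lacks column")
})

test_that("derived allele frequencies count non-missing chromosomes", {
  dos <- matrix(c(0, 1, 2,
                  2, NA, 2,
                  NA, NA, NA), nrow = 3, byrow = TRUE)
  f <- derived_allele_freq(dos)
  expect_equal(f$daf, c(3 / 6, 4 / 4, NA))
  expect_equal(f$n_chrom, c(6L, 4L, 0L))
  expect_true(f$missing[3])
  expect_error(derived_allele_freq(matrix(3, 1, 1)), "0, 1, 2 or NA")
  # column subsetting restricts to one population
  f2 <- derived_allele_freq(dos, samples = 1:2)
  expect_equal(f2$daf[1], 1 / 4)
})

test_that("threshold construction and inversion are exact inverses", {
  thr <- aisnp_thresholds(-0.011, 0.284, 2)
  expect_equal(thr$upper, -0.011 + 2 * 0.284)
  expect_equal(thr$lower, -0.011 - 2 * 0.284)
  inv <- invert_thresholds(thr$upper, thr$lower, 2)
  expect_equal(inv$genome_mean, -0.011, tolerance = 1e-15)
  expect_equal(inv$genome_sd, 0.284, tolerance = 1e-15)
  # published two-sided thresholds imply the genome-wide moments
  inv2 <- invert_thresholds(0.557, -0.579)
  expect_equal(round(inv2$genome_mean, 3), -0.011)
  expect_equal(round(inv2$genome_sd, 3), 0.284)
  expect_error(invert_thresholds(-1, 1), "upper >= lower")
})

test_that("the dDAF scan flags exactly the loci beyond mean +/- 2 SD", {
  loci <- toy_loci(12)
  fd <- c(0.9, rep(0.5, 10), 0.1)
  fw <- c(0.1, rep(0.5, 10), 0.9)
  scan <- delta_daf_scan(loci, fd, fw)
  delta <- fd - fw
  expect_equal(scan$loci$delta_daf, delta)
  expect_equal(scan$genome_mean, mean(delta))
  expect_equal(scan$genome_sd, sd(delta))
  manual <- delta > scan$upper_threshold | delta < scan$lower_threshold
  expect_equal(scan$loci$aisnp, manual)
  expect_equal(sum(scan$loci$aisnp), 2)
  # round trip: the scan's own thresholds invert to its moments
  inv <- invert_thresholds(scan$upper_threshold, scan$lower_threshold)
  expect_equal(inv$genome_mean, scan$genome_mean, tolerance = 1e-15)
  expect_equal(inv$genome_sd, scan$genome_sd, tolerance = 1e-15)
})

test_that("a zero-spread scan is degenerate and flags nothing", {
  scan <- delta_daf_scan(toy_loci(4), rep(0.6, 4), rep(0.2, 4))
  expect_true(scan$degenerate)
  expect_equal(sum(scan$loci$aisnp), 0)
  expect_error(delta_daf_scan(toy_loci(2), c(0.5, NA), c(0.1, 0.2)),
               "at least two loci")
})

test_that("gene regions use half-open windows with 1-based locus positions", {
  r <- gene_region("AMY2B", "chr6", 2000000L, 3000000L)
  expect_equal(r$window_start, 1500000)
  expect_equal(r$window_end, 3500000)
  # clamped at zero near the chromosome start
  r0 <- gene_region("G", "chr1", 100L, 200L)
  expect_equal(r0$window_start, 0)
  expect_error(gene_region("G", "chr1", 10L, 10L), "strictly below")

  # boundary loci: 1-based pos p is inside iff start <= p-1 < end
  loci <- as_loci(data.frame(
    chrom = "chr6",
    pos = c(1500000L,      # p-1 = 1499999 < start: outside
            1500001L,      # p-1 = 1500000 = start: inside
            3500000L,      # p-1 = 3499999 < end: inside
            3500001L),     # p-1 = 3500000 = end: outside
    ancestral_allele = "A", derived_allele = "G"))
  fd <- c(0.95, 0.95, 0.95, 0.95, rep(0.5, 20))
  fw <- c(0.05, 0.05, 0.05, 0.05, rep(0.5 + seq(-0.01, 0.01, length.out = 20), 1))
  all_loci <- rbind(loci, toy_loci(20))
  scan <- delta_daf_scan(all_loci, fd, fw)
  hits <- aisnps_in_region(scan, r)
  expect_equal(hits$pos, c(1500001L, 3500000L))
})

test_that("wolf-allele frequencies pick the majority wolf allele per locus", {
  # locus 1: wolf DAF 0.9 -> wolf allele is derived
  # locus 2: wolf DAF 0.1 -> wolf allele is ancestral
  fw <- c(0.9, 0.1)
  breed_dos <- list(
    Hi = matrix(c(2, 2,   0, 0), nrow = 2, byrow = TRUE),  # daf 1, 0
    Lo = matrix(c(0, 0,   2, 2), nrow = 2, byrow = TRUE))  # daf 0, 1
  wf <- wolf_allele_freq_by_breed(breed_dos, fw, 1:2)
  hi <- wf$freqs[wf$freqs$breed == "Hi", ]
  expect_equal(hi$wolf_allele, c("derived", "ancestral"))
  expect_equal(hi$wolf_allele_freq, c(1, 1))
  lo <- wf$freqs[wf$freqs$breed == "Lo", ]
  expect_equal(lo$wolf_allele_freq, c(0, 0))
  expect_equal(wf$ranking$breed, c("Hi", "Lo"))
  expect_equal(wf$ranking$mean_wolf_allele_freq, c(1, 0))

  # exact tie at 0.5 resolves to the derived allele with a warning
  expect_warning(
    tied <- wolf_allele_freq_by_breed(list(X = matrix(2, 1, 2)), 0.5, 1),
    "tied at 0.5")
  expect_equal(tied$freqs$wolf_allele, "derived")
  expect_true(tied$freqs$tie_flag)
})

test_that("chromosome control runs a Welch test against the genome", {
  sim <- simulate_genotypes(n_loci = 400, seed = 77)
  fd <- derived_allele_freq(do.call(cbind, sim$dosage_by_pop[
    setdiff(names(sim$dosage_by_pop), "wolves")]))
  fw <- derived_allele_freq(sim$dosage_by_pop$wolves)
  scan <- delta_daf_scan(sim$loci, fd, fw)
  ctl <- chromosome_control(scan, "chr1")
  expect_s3_class(ctl, "cnv_test")
  expect_equal(ctl$method, "welch_t")
  # a null chromosome should not stand out
  expect_gt(ctl$p_value, 0.001)
  expect_error(chromosome_control(scan, "chr99"), "unknown chromosome")
})

test_that("an introgressed breed is recovered at planted region aiSNPs", {
  region <- gene_region("AMY2B", "chr6", 2000000L, 3000000L)
  sim <- simulate_genotypes(introgressed_breed = "BreedD",
                            introgression_fraction = 0.5,
                            n_planted_aisnps = 3L,
                            planted_region = region, seed = 42)
  dogs <- sim$dosage_by_pop[setdiff(names(sim$dosage_by_pop), "wolves")]
  fd <- derived_allele_freq(do.call(cbind, dogs))
  fw <- derived_allele_freq(sim$dosage_by_pop$wolves)
  scan <- delta_daf_scan(sim$loci, fd, fw)
  hits <- aisnps_in_region(scan, region)
  # all three planted loci are flagged and inside the window
  planted_pos <- sim$loci$pos[sim$truth$planted_in_region]
  expect_true(all(planted_pos %in% hits$pos))
  idx <- match(paste(hits$chrom, hits$pos),
               paste(scan$loci$chrom, scan$loci$pos))
  wf <- wolf_allele_freq_by_breed(dogs, fw, idx)
  expect_equal(wf$ranking$breed[1], "BreedD")
})

test_that("BED regions round-trip through write and read", {
  rs <- list(gene_region("AMY2B", "chr6", 2000000L, 3000000L),
             gene_region("GCKR", "chr17", 100000L, 900000L))
  f <- tempfile(fileext = ".bed")
  write_regions_bed(rs, f)
  back <- read_regions_bed(f)
  expect_equal(length(back), 2)
  expect_equal(back[[1]]$gene, "AMY2B")
  expect_equal(back[[1]]$window_start, rs[[1]]$window_start)
  expect_equal(back[[2]]$window_end, rs[[2]]$window_end)
})
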