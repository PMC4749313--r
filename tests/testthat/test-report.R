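tiny_vcf <- function() {
  write_tmp_lines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\td1\td2\tw1",
    "chr1\t100\t.\tA\tG\t.\tPASS\tAA=A\tGT\t0/1\t1/1\t0/0",
    "chr1\t200\t.\tC\tT\t.\tPASS\tAA=T\tGT\t0/0\t0/1\t1|1",
    "chr1\t300\t.\tG\tA\t.\tPASS\tAA=N\tGT\t0/0\t0/1\t1/1",
    "chr1\t400\t.\tT\tC\t.\tPASS\tAA=t\tGT\t./.\t0/1\t1/1"),
    ext = ".vcf")
}

test_that("VCF reader produces derived-allele dosages", {
  expect_warning(g <- read_genotypes_vcf(tiny_vcf()),
                 "without a usable ancestral designation")
  # the AA=N record is dropped
  expect_equal(nrow(g$loci), 3)
  expect_equal(g$samples, c("d1", "d2", "w1"))
  # locus 1: AA = REF, derived = ALT, dosage = ALT count
  expect_equal(g$loci$derived_allele[1], "G")
  expect_equal(unname(g$dosage[1, ]), c(1, 2, 0))
  # locus 2: AA = ALT, derived = REF, dosage flipped to 2 - ALT count
  expect_equal(g$loci$ancestral_allele[2], "T")
  expect_equal(g$loci$derived_allele[2], "C")
  expect_equal(unname(g$dosage[2, ]), c(2, 1, 0))
  # lower-case AA is normalised; missing genotype stays NA
  expect_equal(g$loci$ancestral_allele[3], "T")
  expect_equal(g$loci$derived_allele[3], "C")
  expect_true(is.na(g$dosage[3, "d1"]))
  expect_equal(unname(g$dosage[3, c("d2", "w1")]), c(1, 2))
})

test_that("multiallelic VCF records are rejected", {
  f <- write_tmp_lines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AA,Number=1,Type=String,Description=\"x\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"x\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1",
    "chr1\t100\t.\tA\tG,T\t.\tPASS\tAA=A\tGT\t0/1"),
    ext = ".vcf")
  expect_error(read_genotypes_vcf(f), "multiallelic")
})

test_that("dosage tables and population maps round-trip", {
  sim <- simulate_genotypes(n_loci = 30, breeds = c(X = 3L, Y = 2L),
                            n_wolves = 2L, seed = 13)
  dos <- do.call(cbind, sim$dosage_by_pop)
  f <- tempfile(fileext = ".tsv")
  write.table(cbind(sim$loci, as.data.frame(dos)), f, sep = "\t",
              quote = FALSE, row.names = FALSE)
  g <- read_genotypes_dosage(f)
  expect_equal(g$loci, sim$loci)
  expect_equal(unname(g$dosage), unname(dos))

  pm <- write_tmp_lines(c("sample_id,population",
                          paste(colnames(dos),
                                rep(c("X", "Y", "wolves"), c(3, 2, 2)),
                                sep = ",")))
  pops <- read_population_map(pm)
  split <- split_by_population(g, pops)
  expect_setequal(names(split), c("X", "Y", "wolves"))
  expect_equal(ncol(split$X), 3)
  expect_error(split_by_population(g, pops[-1]), "missing from population map")
})

test_that("run_diet writes per-gene reports for the study panel", {
  sim <- simulate_breed_cnv(seed = 30)
  out <- file.path(tempdir(), "diet_out")
  res <- run_diet(sim$calls, sim$breeds, out)
  expect_named(res, "AMY2B")
  expect_true(file.exists(file.path(out, "diet_AMY2B.json")))
  expect_true(file.exists(file.path(out, "breed_summary_AMY2B.csv")))
  expect_true(file.exists(file.path(out, "diet_manifest.json")))
  rpt <- jsonlite::read_json(file.path(out, "diet_AMY2B.json"))
  expect_equal(rpt$n_high + rpt$n_low, nrow(sim$calls))
  expect_equal(rpt$mean_high, res$AMY2B$mean_high)
  expect_true(rpt$proportion_high >= 0 && rpt$proportion_high <= 1)
  unlink(out, recursive = TRUE)
})

test_that("run_latitude and run_acgh write coherent reports", {
  lsim <- simulate_latitude_dataset(seed = 31)
  out <- file.path(tempdir(), "lat_out")
  la <- run_latitude(lsim$calls, lsim$breeds, out)
  rpt <- jsonlite::read_json(file.path(out, "latitude.json"))
  expect_equal(rpt$n_below + rpt$n_above, nrow(lsim$calls))
  expect_equal(rpt$fk$p_value, la$fk$p_value)
  unlink(out, recursive = TRUE)

  asim <- simulate_acgh(seed = 32)
  out2 <- file.path(tempdir(), "acgh_out")
  oz <- run_acgh(asim$acgh, out2, focal_x = asim$focal$x,
                 focal_y = asim$focal$y)
  rpt2 <- jsonlite::read_json(file.path(out2, "acgh_outlier.json"))
  expect_equal(rpt2$orientation_y_on_x$z_score, oz$xy$z_score)
  expect_equal(rpt2$orientation_x_on_y$z_score, oz$yx$z_score)
  # both orientations agree on the direction of the deviation
  expect_gt(oz$xy$z_score, 0)
  expect_lt(oz$yx$z_score, 0)
  null_csv <- read.csv(file.path(out2, "acgh_null_sites.csv"))
  expect_equal(nrow(null_csv), oz$xy$n_null_sites)
  unlink(out2, recursive = TRUE)
})

test_that("run_introgression recovers the simulated scenario end to end", {
  out <- file.path(tempdir(), "intro_sim")
  sim <- run_simulate("introgression", seed = 33, out_dir = out)
  res <- run_introgression(file.path(out, "dosage.tsv"),
                           file.path(out, "populations.csv"),
                           file.path(out, "regions.bed"),
                           file.path(out, "intro_out"),
                           chrom_control = "chr1")
  expect_s3_class(res$scan, "daf_scan")
  amy <- res$regions$AMY2B
  expect_gte(amy$n_aisnps, 3)
  expect_equal(amy$ranking$breed[1], "BreedD")
  expect_s3_class(res$control, "cnv_test")
  rpt <- jsonlite::read_json(file.path(out, "intro_out", "introgression.json"))
  expect_equal(rpt$regions$AMY2B$ranking$breed[[1]], "BreedD")
  expect_true(file.exists(file.path(out, "intro_out", "daf_scan.tsv")))
  unlink(out, recursive = TRUE)
})

test_that("every simulation scenario replays identically for the same seed", {
  for (sc in c("study-scale", "acgh-outlier", "introgression", "latitude")) {
    d1 <- file.path(tempdir(), paste0(sc, "_r1"))
    d2 <- file.path(tempdir(), paste0(sc, "_r2"))
    run_simulate(sc, seed = 34, out_dir = d1)
    run_simulate(sc, seed = 34, out_dir = d2)
    files <- setdiff(list.files(d1), "simulate_manifest.json")
    expect_setequal(files, setdiff(list.files(d2), "simulate_manifest.json"))
    for (f in files)
      expect_identical(readLines(file.path(d1, f)),
                       readLines(file.path(d2, f)),
                       label = paste(sc, f))
    unlink(c(d1, d2), recursive = TRUE)
  }
})

test_that("run_simulate rejects unknown scenarios", {
  expect_error(run_simulate("nope", 1, tempdir()), "unknown scenario")
})
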