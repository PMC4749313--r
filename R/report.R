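# Pipeline drivers: each run_* function wires the loaders, an analysis
# and the writers together, emits CSV/JSON reports into an output
# directory and returns the analysis objects invisibly. A manifest with
# the inputs, parameters and seed is written alongside every run.

write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

write_manifest <- function(out_dir, run, params) {
  write_json_report(
    list(run = run, params = params,
         r_version = as.character(getRversion()),
         package_version = as.character(utils::packageVersion("cnvdiet")),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    file.path(out_dir, paste0(run, "_manifest.json")))
}

comparison_report <- function(cmp) {
  list(gene = cmp$gene, nutrient = cmp$nutrient,
       group_high = cmp$group_high, group_low = cmp$group_low,
       n_high = cmp$n_high, n_low = cmp$n_low,
       mean_high = cmp$mean_high, sd_high = cmp$sd_high,
       mean_low = cmp$mean_low, sd_low = cmp$sd_low,
       rro = as_report(cmp$rro), fk = as_report(cmp$fk),
       threshold = cmp$threshold,
       proportion_high = cmp$proportion_high,
       proportion_low = cmp$proportion_low)
}

#' Run the diet-group copy-number comparisons
#'
#' @param cnv_path CNV-call table (CSV/TSV), or a \code{cnv_calls}
#'   data.frame.
#' @param breed_path breed metadata table, or a \code{breed_info}
#'   data.frame.
#' @param out_dir output directory (created if needed).
#' @param analyses named list mapping gene -> list(nutrient, grouping,
#'   threshold); the default runs the three study genes with their
#'   nutrient pairings (starch with a 10-copy threshold, sugar
#'   moderate-vs-low, phytanic acid high-vs-low).
#' @return invisibly, the list of \code{diet_comparison} objects.
#' @export
run_diet <- function(cnv_path, breed_path, out_dir,
                     analyses = list(
                       AMY2B = list(nutrient = "starch",
                                    grouping = list(high = "high", low = "low"),
                                    threshold = 10L),
                       GCKR = list(nutrient = "sugar",
                                   grouping = list(high = "moderate", low = "low"),
                                   threshold = NULL),
                       PHYH = list(nutrient = "phytanic_acid",
                                   grouping = list(high = "high", low = "low"),
                                   threshold = NULL))) {
  calls <- if (is.character(cnv_path)) load_cnv_calls(cnv_path) else
    as_cnv_calls(as.data.frame(cnv_path))
  breeds <- if (is.character(breed_path)) load_breed_info(breed_path) else
    as_breed_info(as.data.frame(breed_path))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  results <- list()
  for (gene in names(analyses)) {
    a <- analyses[[gene]]
    if (!any(calls$gene == gene)) next
    cmp <- compare_by_diet(calls, breeds, gene, a$nutrient,
                           grouping = a$grouping %||% list(high = "high",
                                                           low = "low"),
                           threshold = a$threshold)
    results[[gene]] <- cmp
    write_json_report(comparison_report(cmp),
                      file.path(out_dir, paste0("diet_", gene, ".json")))
    write_delim_auto(breed_summary(calls, gene),
                     file.path(out_dir, paste0("breed_summary_", gene, ".csv")))
  }
  if (!length(results)) stop("no configured gene present in the call table")
  write_manifest(out_dir, "diet",
                 list(genes = names(results),
                      n_calls = nrow(calls)))
  invisible(results)
}

#' Run the latitude starch-proxy analysis
#'
#' @inheritParams run_diet
#' @param split_degrees absolute-latitude split (default 40).
#' @param gene gene to analyse (default "AMY2B").
#' @return invisibly, the \code{latitude_analysis} object.
#' @export
run_latitude <- function(cnv_path, breed_path, out_dir,
                         split_degrees = 40, gene = "AMY2B") {
  calls <- if (is.character(cnv_path)) load_cnv_calls(cnv_path) else
    as_cnv_calls(as.data.frame(cnv_path))
  breeds <- if (is.character(breed_path)) load_breed_info(breed_path) else
    as_breed_info(as.data.frame(breed_path))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  la <- latitude_analysis(calls, breeds, split_degrees, gene)
  write_json_report(
    list(gene = la$gene, split_degrees = la$split_degrees,
         r_squared = la$fit$r_squared, p_slope = la$fit$p_slope,
         n_below = la$n_below, n_above = la$n_above,
         mean_below = la$mean_below, sd_below = la$sd_below,
         mean_above = la$mean_above, sd_above = la$sd_above,
         fk = as_report(la$fk)),
    file.path(out_dir, "latitude.json"))
  write_manifest(out_dir, "latitude",
                 list(split_degrees = split_degrees, gene = gene))
  invisible(la)
}

#' Run the aCGH focal-outlier analysis in both orientations
#'
#' Vertical residuals depend on which breed sits on the y axis, so the
#' report carries both orientations.
#'
#' @param acgh_path long-format aCGH table (CSV/TSV) or data.frame.
#' @param out_dir output directory.
#' @param breed_x,breed_y the two focal breeds.
#' @param focal_x,focal_y focal mean log2 ratios (on breed_x and breed_y
#'   respectively); alternatively derive them with [cnv_to_log2()] from
#'   mean diploid copy numbers and a reference copy count.
#' @param focal_label focal locus label (default "AMY2B").
#' @return invisibly, list with elements \code{xy} (y on x) and
#'   \code{yx} (x on y), both \code{acgh_outlier} objects.
#' @export
run_acgh <- function(acgh_path, out_dir,
                     breed_x = "Alaskan Malamute", breed_y = "Shar Pei",
                     focal_x, focal_y, focal_label = "AMY2B") {
  acgh <- if (is.character(acgh_path)) read_delim_auto(acgh_path) else
    as.data.frame(acgh_path)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sites <- site_means(acgh, breed_x, breed_y)
  xy <- outlier_z(sites, focal_x, focal_y, focal_label)
  flipped <- sites
  names(flipped)[match(c("mean_x", "mean_y", "n_x", "n_y"), names(flipped))] <-
    c("mean_y", "mean_x", "n_y", "n_x")
  yx <- outlier_z(flipped, focal_y, focal_x, focal_label)
  null_df <- as.data.frame(sites)[as.data.frame(sites)$null_eligible, ]
  null_df$residual <- xy$fit$residuals
  write_delim_auto(null_df, file.path(out_dir, "acgh_null_sites.csv"))
  write_json_report(
    list(focal_label = focal_label,
         orientation_y_on_x = list(x_breed = breed_x, y_breed = breed_y,
                                   z_score = xy$z_score,
                                   residual = xy$residual,
                                   n_null_sites = xy$n_null_sites),
         orientation_x_on_y = list(x_breed = breed_y, y_breed = breed_x,
                                   z_score = yx$z_score,
                                   residual = yx$residual,
                                   n_null_sites = yx$n_null_sites)),
    file.path(out_dir, "acgh_outlier.json"))
  write_manifest(out_dir, "acgh",
                 list(breed_x = breed_x, breed_y = breed_y,
                      focal_x = focal_x, focal_y = focal_y))
  invisible(list(xy = xy, yx = yx))
}

#' Run the introgression scan
#'
#' @param geno list with \code{loci}, \code{dosage} and \code{samples}
#'   (from [read_genotypes_vcf()] / [read_genotypes_dosage()]), or a path
#'   to a dosage table.
#' @param pop_map named character vector sample -> population, or a path
#'   for [read_population_map()]. Populations named in
#'   \code{wolf_population} are wolves; all others are dog breeds, pooled
#'   for the genome-wide scan.
#' @param regions list of \code{gene_region} objects (or a BED path).
#' @param out_dir output directory.
#' @param wolf_population population label of the wolves (default
#'   "wolves").
#' @param multiplier aiSNP SD multiplier (default 2).
#' @param chrom_control optional chromosome label for the genome-vs-
#'   chromosome Welch control.
#' @return invisibly, list with the scan, per-region aiSNPs, breed
#'   rankings and the control test.
#' @export
run_introgression <- function(geno, pop_map, regions, out_dir,
                              wolf_population = "wolves", multiplier = 2,
                              chrom_control = NULL) {
  if (is.character(geno)) geno <- read_genotypes_dosage(geno)
  if (is.character(pop_map)) pop_map <- read_population_map(pop_map)
  if (is.character(regions)) regions <- read_regions_bed(regions)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  by_pop <- split_by_population(geno, pop_map)
  if (!wolf_population %in% names(by_pop))
    stop("wolf population '", wolf_population, "' absent from panel")
  wolves <- by_pop[[wolf_population]]
  dogs_by_breed <- by_pop[setdiff(names(by_pop), wolf_population)]
  dogs_pooled <- do.call(cbind, dogs_by_breed)

  daf_dogs <- derived_allele_freq(dogs_pooled)
  daf_wolves <- derived_allele_freq(wolves)
  scan <- delta_daf_scan(geno$loci, daf_dogs, daf_wolves, multiplier)
  write_daf_scan(scan, file.path(out_dir, "daf_scan.tsv"))

  region_results <- lapply(regions, function(r) {
    hits <- aisnps_in_region(scan, r)
    res <- list(gene = r$gene, chrom = r$chrom,
                window_start = r$window_start, window_end = r$window_end,
                n_aisnps = nrow(hits), aisnps = hits)
    if (nrow(hits)) {
      idx <- match(paste(hits$chrom, hits$pos),
                   paste(scan$loci$chrom, scan$loci$pos))
      wf <- wolf_allele_freq_by_breed(dogs_by_breed, daf_wolves, idx)
      res$ranking <- wf$ranking
      res$freqs <- wf$freqs
    }
    res
  })
  names(region_results) <- vapply(regions, function(r) r$gene, "")

  control <- NULL
  if (!is.null(chrom_control))
    control <- chromosome_control(scan, chrom_control)

  write_json_report(
    list(genome_mean = scan$genome_mean, genome_sd = scan$genome_sd,
         upper_threshold = scan$upper_threshold,
         lower_threshold = scan$lower_threshold,
         n_loci = scan$n_loci, n_aisnps = sum(scan$loci$aisnp),
         regions = lapply(region_results, function(r)
           list(gene = r$gene, n_aisnps = r$n_aisnps,
                ranking = if (!is.null(r$ranking))
                  list(breed = r$ranking$breed,
                       mean_wolf_allele_freq = r$ranking$mean_wolf_allele_freq)
                else NULL)),
         chromosome_control = if (!is.null(control)) as_report(control)
         else NULL),
    file.path(out_dir, "introgression.json"))
  write_manifest(out_dir, "introgression",
                 list(multiplier = multiplier,
                      wolf_population = wolf_population,
                      chrom_control = chrom_control))
  invisible(list(scan = scan, regions = region_results, control = control))
}

#' Generate a named synthetic-data scenario bundle
#'
#' Scenarios: \code{"study-scale"} (the five-breed ddPCR panel, ~80
#' calls), \code{"acgh-outlier"} (156 null sites with a planted focal
#' deviation), \code{"introgression"} (four dog breeds plus wolves, one
#' breed half-introgressed, three planted ancestry-informative loci in a
#' gene region) and \code{"latitude"} (latitude-structured calls).
#' The datasets are written in the same dialects the loaders read, with
#' a JSON ground-truth sidecar.
#'
#' @param scenario scenario name.
#' @param seed integer RNG seed.
#' @param out_dir output directory.
#' @return invisibly, the generated bundle.
#' @export
run_simulate <- function(scenario, seed, out_dir) {
  scenarios <- c("study-scale", "acgh-outlier", "introgression", "latitude")
  if (!scenario %in% scenarios)
    stop("unknown scenario '", scenario, "'; available: ",
         paste(scenarios, collapse = ", "))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (scenario == "study-scale") {
    sim <- simulate_breed_cnv(seed = seed)
    write_cnv_calls(sim$calls, file.path(out_dir, "cnv_calls.csv"))
    write_delim_auto(as.data.frame(sim$breeds),
                     file.path(out_dir, "breeds.csv"))
    truth <- sim$truth
  } else if (scenario == "acgh-outlier") {
    sim <- simulate_acgh(seed = seed)
    write_delim_auto(sim$acgh, file.path(out_dir, "acgh.csv"))
    truth <- c(sim$truth, focal = sim$focal)
  } else if (scenario == "introgression") {
    region <- gene_region("AMY2B", "chr6", 2000000L, 3000000L)
    sim <- simulate_genotypes(introgressed_breed = "BreedD",
                              introgression_fraction = 0.5,
                              n_planted_aisnps = 3L,
                              planted_region = region, seed = seed)
    dos <- do.call(cbind, sim$dosage_by_pop)
    write_delim_auto(cbind(sim$loci, as.data.frame(dos)),
                     file.path(out_dir, "dosage.tsv"), sep = "\t")
    pops <- rep(names(sim$dosage_by_pop),
                vapply(sim$dosage_by_pop, ncol, 0L))
    write_delim_auto(data.frame(sample_id = colnames(dos), population = pops),
                     file.path(out_dir, "populations.csv"))
    write_regions_bed(list(region), file.path(out_dir, "regions.bed"))
    truth <- sim$truth[setdiff(names(sim$truth), c("p_dog", "p_wolf"))]
  } else {
    sim <- simulate_latitude_dataset(seed = seed)
    write_cnv_calls(sim$calls, file.path(out_dir, "cnv_calls.csv"))
    write_delim_auto(as.data.frame(sim$breeds),
                     file.path(out_dir, "breeds.csv"))
    truth <- sim$truth[c("mean_cn", "latitudes", "seed")]
  }
  write_json_report(truth, file.path(out_dir, "ground_truth.json"))
  write_manifest(out_dir, "simulate", list(scenario = scenario, seed = seed))
  invisible(sim)
}
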