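# dDAF computation, aiSNP thresholding, gene-region windows, per-breed
# wolf-allele frequencies and the chromosome-level control.

#' Validate a locus table
#'
#' Loci are biallelic with an explicit ancestral designation. Positions are
#' 1-based at the interface (VCF convention) and converted to 0-based
#' half-open coordinates only when intersected with regions.
#'
#' @param loci data.frame with columns chrom, pos, ancestral_allele,
#'   derived_allele.
#' @return the validated data.frame.
#' @export
as_loci <- function(loci) {
  need <- c("chrom", "pos", "ancestral_allele", "derived_allele")
  missing_cols <- setdiff(need, names(loci))
  if (length(missing_cols))
    stop("locus table lacks column(s): ", paste(missing_cols, collapse = ", "))
  loci$pos <- as.integer(loci$pos)
  if (any(loci$pos < 1L)) stop("positions are 1-based; found pos < 1")
  same <- which(loci$ancestral_allele == loci$derived_allele)
  if (length(same))
    stop("ancestral and derived allele identical at row(s): ",
         paste(same, collapse = ", "))
  loci
}

#' Derived allele frequency per locus
#'
#' Frequencies are derived-allele counts over non-missing chromosomes:
#' each individual contributes its dosage (0, 1 or 2 copies of the derived
#' allele) and 2 chromosomes; missing genotypes (NA) are dropped per locus,
#' never imputed.
#'
#' @param dosage numeric matrix, rows = loci, columns = individuals,
#'   entries in \{0, 1, 2, NA\}.
#' @param samples optional column subset (names or indices) restricting the
#'   computation to one population.
#' @return data.frame with daf, n_chrom and a missing flag per locus.
#' @export
derived_allele_freq <- function(dosage, samples = NULL) {
  if (!is.matrix(dosage)) dosage <- as.matrix(dosage)
  if (!is.null(samples)) dosage <- dosage[, samples, drop = FALSE]
  ok <- dosage %in% c(0, 1, 2) | is.na(dosage)
  if (!all(ok)) stop("dosages must be 0, 1, 2 or NA")
  n_chrom <- 2L * rowSums(!is.na(dosage))
  counts <- rowSums(dosage, na.rm = TRUE)
  daf <- ifelse(n_chrom > 0L, counts / n_chrom, NA_real_)
  data.frame(daf = daf, n_chrom = as.integer(n_chrom),
             missing = n_chrom == 0L)
}

#' aiSNP thresholds from genome-wide dDAF moments
#'
#' @param genome_mean,genome_sd genome-wide mean and SD of dDAF.
#' @param multiplier number of SDs defining an ancestry-informative SNP
#'   (default 2).
#' @return list with upper and lower thresholds (mean +/- multiplier * SD).
#' @export
aisnp_thresholds <- function(genome_mean, genome_sd, multiplier = 2) {
  stopifnot(multiplier > 0, genome_sd >= 0)
  list(upper = genome_mean + multiplier * genome_sd,
       lower = genome_mean - multiplier * genome_sd)
}

#' Invert aiSNP thresholds back to genome-wide moments
#'
#' The exact inverse of [aisnp_thresholds()]:
#' mean = (upper + lower) / 2 and SD = (upper - lower) / (2 * multiplier).
#'
#' @param upper,lower the two thresholds.
#' @param multiplier the SD multiplier used to build them (default 2).
#' @return list with genome_mean and genome_sd.
#' @export
invert_thresholds <- function(upper, lower, multiplier = 2) {
  stopifnot(multiplier > 0, upper >= lower)
  list(genome_mean = (upper + lower) / 2,
       genome_sd = (upper - lower) / (2 * multiplier))
}

#' Genome-wide dDAF scan and aiSNP flags
#'
#' Computes per-locus dDAF = DAF_dogs - DAF_wolves, the genome-wide mean
#' and SD (n - 1 denominator) over loci with non-missing dDAF, thresholds
#' at mean +/- multiplier * SD, and flags loci falling outside them.
#'
#' @param loci locus table (see [as_loci()]); rows align with the
#'   frequency vectors.
#' @param daf_dogs,daf_wolves per-locus derived allele frequencies for the
#'   pooled dog panel and the wolf panel (data.frames from
#'   [derived_allele_freq()] or plain numeric vectors).
#' @param multiplier SD multiplier for the aiSNP rule (default 2).
#' @return object of class \code{daf_scan}: a per-locus data.frame
#'   (chrom, pos, daf_dogs, daf_wolves, delta_daf, aisnp) plus genome
#'   moments, thresholds and a degeneracy flag (zero SD).
#' @export
delta_daf_scan <- function(loci, daf_dogs, daf_wolves, multiplier = 2) {
  loci <- as_loci(loci)
  fd <- if (is.data.frame(daf_dogs)) daf_dogs$daf else as.numeric(daf_dogs)
  fw <- if (is.data.frame(daf_wolves)) daf_wolves$daf else as.numeric(daf_wolves)
  if (length(fd) != nrow(loci) || length(fw) != nrow(loci))
    stop("frequency vectors must align with the locus table")
  delta <- fd - fw
  usable <- !is.na(delta)
  if (sum(usable) < 2L) stop("need at least two loci with non-missing dDAF")
  gm <- mean(delta[usable])
  gs <- sd(delta[usable])
  thr <- aisnp_thresholds(gm, gs, multiplier)
  degenerate <- gs == 0
  flags <- usable & (delta > thr$upper | delta < thr$lower)
  structure(
    list(loci = data.frame(loci,
                           daf_dogs = fd, daf_wolves = fw,
                           delta_daf = delta, aisnp = flags,
                           stringsAsFactors = FALSE),
         genome_mean = gm, genome_sd = gs,
         upper_threshold = thr$upper, lower_threshold = thr$lower,
         multiplier = multiplier, n_loci = sum(usable),
         degenerate = degenerate),
    class = "daf_scan")
}

#' @export
print.daf_scan <- function(x, ...) {
  cat(sprintf("dDAF scan over %d loci: mean %.4g, sd %.4g\n",
              x$n_loci, x$genome_mean, x$genome_sd))
  cat(sprintf("  aiSNP thresholds: > %.4g or < %.4g (%g SD); %d flagged\n",
              x$upper_threshold, x$lower_threshold, x$multiplier,
              sum(x$loci$aisnp)))
  if (x$degenerate) cat("  degenerate: genome-wide SD is zero\n")
  invisible(x)
}

#' Chromosome-level dDAF control
#'
#' Welch two-sample t test between one chromosome's dDAF values and the
#' genome-wide set, the sanity check that no single chromosome drives the
#' scan.
#'
#' @param scan a \code{daf_scan} object.
#' @param chrom chromosome label.
#' @return a \code{cnv_test} result (method \code{"welch_t"}).
#' @export
chromosome_control <- function(scan, chrom) {
  stopifnot(inherits(scan, "daf_scan"))
  df <- scan$loci[!is.na(scan$loci$delta_daf), , drop = FALSE]
  sel <- df$chrom == chrom
  if (!any(sel)) stop("unknown chromosome: ", chrom)
  if (sum(sel) < 2L) stop("chromosome ", chrom, " has fewer than two loci")
  welch_t_test(df$delta_daf[sel], df$delta_daf)
}

#' Gene-region window from flanking-gene transcription start sites
#'
#' The searched region spans the interval between the transcription start
#' sites of the flanking genes, expanded by \code{pad} bases on either
#' side (default 500 kb, the typical length of wolf-introgressed
#' haplotypes in dogs), clamped at zero. Coordinates are 0-based
#' half-open.
#'
#' @param gene gene symbol labelling the region.
#' @param chrom chromosome.
#' @param tss_upstream,tss_downstream 0-based coordinates of the two
#'   flanking transcription start sites (upstream < downstream).
#' @param pad flank expansion in bases (default 500000).
#' @return list of class \code{gene_region}: gene, chrom, window_start,
#'   window_end.
#' @export
gene_region <- function(gene, chrom, tss_upstream, tss_downstream,
                        pad = 500000L) {
  if (tss_upstream >= tss_downstream)
    stop("tss_upstream must be strictly below tss_downstream")
  stopifnot(pad >= 0)
  structure(
    list(gene = gene, chrom = chrom,
         window_start = max(0, tss_upstream - pad),
         window_end = tss_downstream + pad),
    class = "gene_region")
}

#' Flagged aiSNPs inside a gene region
#'
#' Locus positions are 1-based; a locus at position p lies inside the
#' 0-based half-open window \[start, end) iff start <= p - 1 < end.
#'
#' @param scan a \code{daf_scan} object.
#' @param region a \code{gene_region}.
#' @return the flagged rows of the scan's locus table falling inside the
#'   region (possibly zero rows).
#' @export
aisnps_in_region <- function(scan, region) {
  stopifnot(inherits(scan, "daf_scan"), inherits(region, "gene_region"))
  df <- scan$loci
  inside <- df$aisnp & df$chrom == region$chrom &
    (df$pos - 1L) >= region$window_start &
    (df$pos - 1L) < region$window_end
  out <- df[inside, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Wolf-allele frequency per breed at aiSNP loci
#'
#' The "wolf allele" at a locus is the allele at higher frequency in
#' wolves: the derived allele when the wolf DAF exceeds 0.5, the ancestral
#' allele when below, and -- deterministically -- the derived allele with a
#' tie flag at exactly 0.5. Each breed's frequency of that allele is
#' computed over its non-missing chromosomes, and breeds are ranked by
#' mean wolf-allele frequency across the supplied loci.
#'
#' @param breed_dosage named list of dosage matrices (rows = all scan
#'   loci, columns = individuals), one per breed.
#' @param daf_wolves per-locus wolf derived allele frequencies (vector or
#'   [derived_allele_freq()] frame) aligned with the scan's locus table.
#' @param loci_idx integer indices of the loci (rows) to evaluate,
#'   typically the aiSNPs inside a gene region.
#' @return list with \code{freqs} (long data.frame: breed, locus_idx,
#'   wolf_allele, wolf_allele_freq, tie_flag) and \code{ranking}
#'   (data.frame breed, mean_wolf_allele_freq, sorted decreasing).
#' @export
wolf_allele_freq_by_breed <- function(breed_dosage, daf_wolves, loci_idx) {
  stopifnot(is.list(breed_dosage), length(breed_dosage) >= 1L,
            !is.null(names(breed_dosage)))
  fw <- if (is.data.frame(daf_wolves)) daf_wolves$daf else as.numeric(daf_wolves)
  loci_idx <- as.integer(loci_idx)
  if (!length(loci_idx)) stop("no loci supplied")
  if (any(is.na(fw[loci_idx])))
    stop("wolf frequency missing at supplied locus indices")
  wolf_is_derived <- fw[loci_idx] >= 0.5
  tie <- fw[loci_idx] == 0.5
  if (any(tie))
    warning("wolf allele frequencies tied at 0.5 for ", sum(tie),
            " locus/loci; derived allele used")
  rows <- lapply(names(breed_dosage), function(br) {
    daf_b <- derived_allele_freq(breed_dosage[[br]])$daf[loci_idx]
    freq <- ifelse(wolf_is_derived, daf_b, 1 - daf_b)
    data.frame(breed = br, locus_idx = loci_idx,
               wolf_allele = ifelse(wolf_is_derived, "derived", "ancestral"),
               wolf_allele_freq = freq, tie_flag = tie,
               stringsAsFactors = FALSE)
  })
  freqs <- do.call(rbind, rows)
  ranking <- aggregate(wolf_allele_freq ~ breed, data = freqs, FUN = mean)
  names(ranking)[2] <- "mean_wolf_allele_freq"
  ranking <- ranking[order(-ranking$mean_wolf_allele_freq), , drop = FALSE]
  rownames(ranking) <- NULL
  list(freqs = freqs, ranking = ranking)
}

#' Write gene regions as BED
#'
#' @param regions list of \code{gene_region} objects.
#' @param path destination BED file (0-based half-open, 4 columns).
#' @return invisibly, the path.
#' @export
write_regions_bed <- function(regions, path) {
  df <- do.call(rbind, lapply(regions, function(r)
    data.frame(chrom = r$chrom, start = r$window_start, end = r$window_end,
               name = r$gene, stringsAsFactors = FALSE)))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene regions from a BED file
#'
#' @param path BED file with at least 3 columns (chrom, start, end,
#'   optional name), 0-based half-open.
#' @return list of \code{gene_region} objects.
#' @export
read_regions_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("BED file needs at least 3 columns")
  lapply(seq_len(nrow(df)), function(i) {
    structure(list(gene = if (ncol(df) >= 4L) df[[4]][i] else
      paste0("region", i),
      chrom = df[[1]][i],
      window_start = df[[2]][i], window_end = df[[3]][i]),
      class = "gene_region")
  })
}
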