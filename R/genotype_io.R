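# Genotype input: biallelic VCF with an ancestral-allele INFO field, or a
# flat dosage table; both converted to the internal derived-allele dosage
# matrix at the boundary.

#' Read a genotype panel from a VCF file
#'
#' Biallelic records only. The ancestral allele is read from the INFO
#' field named by \code{aa_field}; the derived allele is whichever of
#' REF/ALT differs from it. Genotypes are converted to derived-allele
#' dosages (0/1/2, NA for missing). Records whose ancestral allele is
#' missing or matches neither REF nor ALT are excluded, with a warning
#' reporting how many.
#'
#' @param path VCF file (plain text or bgzipped).
#' @param aa_field INFO key carrying the ancestral allele (default "AA").
#' @return list with \code{loci} (chrom, pos, ancestral_allele,
#'   derived_allele), \code{dosage} (loci x samples matrix) and
#'   \code{samples}.
#' @export
read_genotypes_vcf <- function(path, aa_field = "AA") {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  multi <- grepl(",", alt, fixed = TRUE)
  if (any(multi))
    stop("multiallelic record(s) at ",
         paste(paste0(fix[multi, "CHROM"], ":", fix[multi, "POS"]),
               collapse = ", "))
  aa <- vcfR::extract.info(vcf, element = aa_field)
  aa <- toupper(aa)
  usable <- !is.na(aa) & (aa == toupper(ref) | aa == toupper(alt))
  n_drop <- sum(!usable)
  if (n_drop)
    warning(n_drop, " record(s) without a usable ancestral designation excluded")
  if (!any(usable)) stop("no usable biallelic records with ancestral allele")

  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1,
                                     dimnames = list(NULL, names(gt)))
  gt <- gt[usable, , drop = FALSE]
  ref <- ref[usable]; alt <- alt[usable]; aa <- aa[usable]
  fix <- fix[usable, , drop = FALSE]

  alt_dosage <- function(g) {
    if (is.na(g)) return(NA_real_)
    alleles <- strsplit(g, "[/|]")[[1]]
    if (any(alleles == ".")) return(NA_real_)
    sum(alleles == "1")
  }
  dos <- apply(gt, c(1, 2), alt_dosage)
  # flip to derived dosage where the ancestral allele is ALT
  anc_is_alt <- aa == toupper(alt)
  dos[anc_is_alt, ] <- 2 - dos[anc_is_alt, , drop = FALSE]
  derived <- ifelse(anc_is_alt, ref, alt)

  loci <- data.frame(chrom = fix[, "CHROM"],
                     pos = as.integer(fix[, "POS"]),
                     ancestral_allele = aa,
                     derived_allele = toupper(derived),
                     stringsAsFactors = FALSE)
  rownames(dos) <- NULL
  list(loci = as_loci(loci), dosage = dos, samples = colnames(dos))
}

#' Read a derived-allele dosage table
#'
#' Tab- or comma-separated, one row per locus with leading columns chrom,
#' pos, ancestral_allele, derived_allele followed by one column per
#' sample holding dosages 0/1/2 (empty or NA for missing).
#'
#' @param path file path.
#' @return list with \code{loci}, \code{dosage} and \code{samples} as in
#'   [read_genotypes_vcf()].
#' @export
read_genotypes_dosage <- function(path) {
  df <- read_delim_auto(path)
  meta <- c("chrom", "pos", "ancestral_allele", "derived_allele")
  missing_cols <- setdiff(meta, names(df))
  if (length(missing_cols))
    stop("dosage table lacks column(s): ", paste(missing_cols, collapse = ", "))
  loci <- as_loci(df[meta])
  dos <- as.matrix(df[setdiff(names(df), meta)])
  storage.mode(dos) <- "double"
  list(loci = loci, dosage = dos, samples = colnames(dos))
}

#' Read a sample-to-population map
#'
#' @param path two-column delimited file with header
#'   \code{sample_id,population}.
#' @return named character vector mapping sample to population.
#' @export
read_population_map <- function(path) {
  df <- read_delim_auto(path)
  if (!all(c("sample_id", "population") %in% names(df)))
    stop("population map needs columns sample_id and population")
  stats::setNames(as.character(df$population), as.character(df$sample_id))
}

#' Split a dosage matrix by population
#'
#' @param geno list with \code{dosage} and \code{samples} (from a
#'   genotype reader).
#' @param pop_map named character vector sample -> population.
#' @return named list of dosage matrices, one per population.
#' @export
split_by_population <- function(geno, pop_map) {
  unknown <- setdiff(geno$samples, names(pop_map))
  if (length(unknown))
    stop("sample(s) missing from population map: ",
         paste(unknown, collapse = ", "))
  pops <- pop_map[geno$samples]
  lapply(split(seq_along(pops), pops),
         function(idx) geno$dosage[, idx, drop = FALSE])
}

#' Write a dDAF scan as TSV
#'
#' @param scan a \code{daf_scan} object.
#' @param path destination file.
#' @return invisibly, the path.
#' @export
write_daf_scan <- function(scan, path) {
  stopifnot(inherits(scan, "daf_scan"))
  write_delim_auto(scan$loci, path, sep = "\t")
  invisible(path)
}
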