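# Seeded synthetic-data generators emulating every input the analyses
# consume, with ground truth returned alongside for recovery testing.
# Each generator is a pure function of its arguments including the seed:
# the caller's RNG state is restored on exit.

# Truncated-normal draw (lower bound 0) by rejection; the truncation mass
# is tiny for all realistic copy-number configurations.
rtnorm0 <- function(n, mean, sd) {
  if (sd == 0) return(rep(max(mean, 0), n))
  out <- rnorm(n, mean, sd)
  bad <- which(out < 0)
  while (length(bad)) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < 0]
  }
  out
}

#' Default study-scale breed configuration for the copy-number generator
#'
#' Mirrors the analysed six-breed panel (Akita and Shiba Inu pooled as
#' "Japanese Dogs"): two high-starch breeds under stabilizing selection
#' around a high copy-number optimum with tight spread, three low-starch
#' breeds drifting around a lower mean with wide spread, with per-breed
#' sample sizes, means and SDs at the scale of the study's ddPCR panel.
#'
#' @return data.frame with columns name, regime, mean, sd, n, latitude,
#'   starch, sugar, phytanic_acid.
#' @export
default_breed_config <- function() {
  data.frame(
    name = c("Shar Pei", "Pekingese", "Japanese Dogs",
             "Siberian Husky", "Alaskan Malamute"),
    regime = c("selection", "selection", "drift", "drift", "drift"),
    mean = c(11.1, 10.7, 8.3, 7.8, 6.1),
    sd = c(2.7, 1.7, 3.4, 3.9, 5.0),
    n = c(16L, 18L, 14L, 17L, 15L),
    latitude = c(23.1, 39.9, 36.2, 63.0, 64.8),
    starch = c("high", "high", "low", "low", "low"),
    sugar = c("moderate", "moderate", "moderate", "low", "low"),
    phytanic_acid = c("low", "low", "high", "high", "high"),
    stringsAsFactors = FALSE)
}

#' Simulate per-breed diploid copy-number calls
#'
#' Each breed's true copy number is drawn from a normal law truncated at
#' zero -- under "selection" around an adaptive optimum with small SD,
#' under "drift" around a lower mean with large SD. The observed raw call
#' adds ddPCR measurement noise, is truncated at zero and rounded half
#' away from zero into the integer diploid call.
#'
#' @param breeds data.frame as in [default_breed_config()] (columns name,
#'   regime, mean, sd, n at minimum; latitude and diet columns are carried
#'   into the returned breed table when present).
#' @param gene gene label for the calls (default "AMY2B").
#' @param measurement_sd SD of the ddPCR measurement noise in diploid
#'   copies (default 0.3, the scale of reported technical errors).
#' @param seed integer RNG seed.
#' @return list with \code{calls} (a \code{cnv_calls} data.frame),
#'   \code{breeds} (a \code{breed_info} table when latitude/diet columns
#'   are available) and \code{truth} (the generating configuration).
#' @export
simulate_breed_cnv <- function(breeds = default_breed_config(),
                               gene = "AMY2B", measurement_sd = 0.3,
                               seed = 1L) {
  stopifnot(is.data.frame(breeds),
            all(c("name", "regime", "mean", "sd", "n") %in% names(breeds)),
            all(breeds$sd >= 0), all(breeds$n >= 1), measurement_sd >= 0)
  bad <- setdiff(breeds$regime, c("selection", "drift"))
  if (length(bad)) stop("unknown regime(s): ", paste(bad, collapse = ", "))
  with_seed(seed, {
    rows <- lapply(seq_len(nrow(breeds)), function(i) {
      b <- breeds[i, ]
      true_cn <- rtnorm0(b$n, b$mean, b$sd)
      raw <- pmax(0, true_cn + rnorm(b$n, 0, measurement_sd))
      data.frame(
        sample_id = sprintf("%s_%02d", gsub("\\s+", "", b$name), seq_len(b$n)),
        breed = b$name, gene = gene,
        raw_copy_number = raw,
        technical_error = abs(rnorm(b$n, measurement_sd, measurement_sd / 4)),
        source = "collected", stringsAsFactors = FALSE)
    })
    calls <- as_cnv_calls(do.call(rbind, rows))
    info <- NULL
    if ("latitude" %in% names(breeds)) {
      info <- breeds[, intersect(c("name", "latitude", "starch", "sugar",
                                   "phytanic_acid"), names(breeds))]
      names(info)[1] <- "breed"
      info <- as_breed_info(info)
    }
    list(calls = calls, breeds = info,
         truth = list(config = breeds, gene = gene,
                      measurement_sd = measurement_sd, seed = seed))
  })
}

#' Simulate an aCGH site table with a planted focal outlier
#'
#' Null-site breed-x means are drawn uniformly on \code{x_range}; breed-y
#' means follow the line slope * x + intercept plus vertical noise. The
#' focal point sits exactly at slope * focal_x + intercept + focal_offset
#' (its deviation is the planted ground truth, carrying no extra noise).
#' Per-sample log2 ratios are jittered around each site mean with the
#' jitter centered within site, so site means are preserved exactly.
#'
#' @param n_null_sites number of null sites (default 156, the study
#'   scale).
#' @param slope,intercept the generating line (defaults 1, 0).
#' @param noise_sd vertical noise SD of null-site y means (default 0.15).
#' @param focal_offset planted vertical deviation of the focal point
#'   (default 0.9).
#' @param samples_per_site per-breed samples at each site (default 4).
#' @param focal_x focal x coordinate (default 0.5).
#' @param x_range range of the uniform x means (default c(-1.5, 1.5)).
#' @param jitter_sd per-sample jitter SD (default 0.1).
#' @param breed_x,breed_y breed labels.
#' @param seed integer RNG seed.
#' @return list with \code{acgh} (long table for [site_means()]),
#'   \code{focal} (list x, y), and \code{truth}.
#' @export
simulate_acgh <- function(n_null_sites = 156L, slope = 1, intercept = 0,
                          noise_sd = 0.15, focal_offset = 0.9,
                          samples_per_site = 4L, focal_x = 0.5,
                          x_range = c(-1.5, 1.5), jitter_sd = 0.1,
                          breed_x = "Alaskan Malamute",
                          breed_y = "Shar Pei", seed = 1L) {
  stopifnot(n_null_sites >= 3L, noise_sd >= 0, samples_per_site >= 1L,
            jitter_sd >= 0)
  with_seed(seed, {
    mx <- runif(n_null_sites, x_range[1], x_range[2])
    my <- slope * mx + intercept + rnorm(n_null_sites, 0, noise_sd)
    centered_jitter <- function(k) {
      if (k == 1L || jitter_sd == 0) return(rep(0, k))
      j <- rnorm(k, 0, jitter_sd)
      j - mean(j)
    }
    long <- lapply(seq_len(n_null_sites), function(i) {
      jx <- centered_jitter(samples_per_site)
      jy <- centered_jitter(samples_per_site)
      data.frame(
        site_id = sprintf("site%03d", i), chrom = "chr1",
        start = (i - 1L) * 10000L, end = (i - 1L) * 10000L + 1000L,
        breed = rep(c(breed_x, breed_y), each = samples_per_site),
        sample_id = sprintf("%s_%d", rep(c("x", "y"), each = samples_per_site),
                            seq_len(samples_per_site)),
        log2 = c(mx[i] + jx, my[i] + jy),
        stringsAsFactors = FALSE)
    })
    list(acgh = do.call(rbind, long),
         focal = list(x = focal_x,
                      y = slope * focal_x + intercept + focal_offset),
         truth = list(slope = slope, intercept = intercept,
                      noise_sd = noise_sd, focal_offset = focal_offset,
                      expected_z = if (noise_sd > 0) focal_offset / noise_sd
                      else Inf,
                      n_null_sites = n_null_sites, seed = seed))
  })
}

#' Simulate dog and wolf genotype panels with optional introgression
#'
#' Per locus, the wolf derived-allele frequency is drawn from a beta law;
#' the shared dog base frequency equals the wolf frequency plus normal
#' divergence noise (clamped to [0, 1]). Dog breeds sample dosages
#' binomially from the base frequency; wolves from the wolf frequency.
#' In the introgressed breed each haplotype comes from the wolf frequency
#' with probability \code{introgression_fraction}, so its allele frequency
#' is the corresponding mixture. Planted ancestry-informative loci get
#' dog/wolf frequencies 0.5 +/- effect/2 and, when a region is supplied,
#' coordinates inside (and optionally outside) that region.
#'
#' @param n_loci number of loci (default 1000).
#' @param breeds named integer vector of per-breed individual counts
#'   (default four breeds of 20).
#' @param n_wolves wolf individuals (default 20).
#' @param wolf_beta shape parameters of the beta law for wolf frequencies
#'   (default c(1, 1)).
#' @param divergence_sd SD of dog-wolf frequency divergence before
#'   clamping to [0, 1] (default 0.35, giving a genome-wide dDAF SD of
#'   roughly 0.29 on the default panel, the spread real dog/wolf scans
#'   show).
#' @param introgressed_breed optional breed name receiving wolf
#'   haplotypes.
#' @param introgression_fraction probability a haplotype of that breed is
#'   wolf-derived (default 0).
#' @param n_planted_aisnps planted high-dDAF loci (default 0).
#' @param planted_effect dog-minus-wolf frequency difference at planted
#'   loci (default 0.8).
#' @param planted_region optional \code{gene_region}; planted loci are
#'   placed inside its window, on its chromosome.
#' @param n_planted_outside additional planted loci outside the region on
#'   the same chromosome (default 0).
#' @param n_chromosomes chromosomes the null loci are spread over
#'   (default 10, labelled chr1..chrN).
#' @param seed integer RNG seed.
#' @return list with \code{loci}, \code{dosage_by_pop} (named list, dogs
#'   by breed plus \code{"wolves"}), and \code{truth} (planted locus
#'   indices inside/outside the region, generating frequencies, config).
#' @export
simulate_genotypes <- function(n_loci = 1000L,
                               breeds = c(BreedA = 20L, BreedB = 20L,
                                          BreedC = 20L, BreedD = 20L),
                               n_wolves = 20L, wolf_beta = c(1, 1),
                               divergence_sd = 0.35,
                               introgressed_breed = NULL,
                               introgression_fraction = 0,
                               n_planted_aisnps = 0L, planted_effect = 0.8,
                               planted_region = NULL,
                               n_planted_outside = 0L,
                               n_chromosomes = 10L, seed = 1L) {
  stopifnot(n_loci >= 2L, length(breeds) >= 1L, !is.null(names(breeds)),
            introgression_fraction >= 0, introgression_fraction <= 1,
            n_planted_aisnps + n_planted_outside <= n_loci,
            planted_effect >= 0, planted_effect <= 1)
  if (!is.null(introgressed_breed) && !introgressed_breed %in% names(breeds))
    stop("introgressed_breed not among breeds: ", introgressed_breed)
  with_seed(seed, {
    p_wolf <- rbeta(n_loci, wolf_beta[1], wolf_beta[2])
    p_dog <- pmin(1, pmax(0, p_wolf + rnorm(n_loci, 0, divergence_sd)))

    # coordinates: null loci spread over chromosomes, 10 kb apart
    chrom <- paste0("chr", rep_len(seq_len(n_chromosomes), n_loci))
    pos <- integer(n_loci)
    for (cc in unique(chrom)) {
      idx <- which(chrom == cc)
      pos[idx] <- seq_along(idx) * 10000L
    }

    planted_in <- integer(0); planted_out <- integer(0)
    n_planted <- n_planted_aisnps + n_planted_outside
    if (n_planted > 0L) {
      take <- seq_len(n_planted)
      planted_in <- take[seq_len(n_planted_aisnps)]
      planted_out <- setdiff(take, planted_in)
      p_dog[take] <- 0.5 + planted_effect / 2
      p_wolf[take] <- 0.5 - planted_effect / 2
      if (!is.null(planted_region)) {
        stopifnot(inherits(planted_region, "gene_region"))
        w0 <- planted_region$window_start; w1 <- planted_region$window_end
        if (w1 - w0 < n_planted_aisnps)
          stop("planted region too narrow on the simulated chromosome")
        chrom[take] <- planted_region$chrom
        # inside: 1-based positions within the half-open window
        pos[planted_in] <- as.integer(round(
          w0 + (w1 - w0) * (seq_len(n_planted_aisnps) /
                              (n_planted_aisnps + 1)))) + 1L
        # outside: beyond the window end on the same chromosome
        pos[planted_out] <- as.integer(w1 + 50000L * seq_along(planted_out)) + 1L
      }
    }

    draw <- function(freqs, n_ind) {
      matrix(rbinom(length(freqs) * n_ind, 2L, rep(freqs, n_ind)),
             nrow = length(freqs), ncol = n_ind)
    }
    dosage_by_pop <- lapply(names(breeds), function(br) {
      f <- if (!is.null(introgressed_breed) && br == introgressed_breed) {
        (1 - introgression_fraction) * p_dog + introgression_fraction * p_wolf
      } else p_dog
      m <- draw(f, breeds[[br]])
      colnames(m) <- sprintf("%s_%02d", br, seq_len(breeds[[br]]))
      m
    })
    names(dosage_by_pop) <- names(breeds)
    wm <- draw(p_wolf, n_wolves)
    colnames(wm) <- sprintf("wolf_%02d", seq_len(n_wolves))
    dosage_by_pop$wolves <- wm

    loci <- as_loci(data.frame(chrom = chrom, pos = pos,
                               ancestral_allele = "A", derived_allele = "G",
                               stringsAsFactors = FALSE))
    list(loci = loci, dosage_by_pop = dosage_by_pop,
         truth = list(p_dog = p_dog, p_wolf = p_wolf,
                      planted_in_region = planted_in,
                      planted_outside_region = planted_out,
                      introgressed_breed = introgressed_breed,
                      introgression_fraction = introgression_fraction,
                      seed = seed))
  })
}

#' Simulate a latitude-structured copy-number dataset
#'
#' Breed latitudes are drawn (or supplied); every call shares the same
#' mean copy number regardless of latitude, while the SD follows
#' \code{variance_model(|latitude|)} -- emulating the species-wide pattern
#' of latitude-independent means with latitude-dependent spread.
#'
#' @param n_breeds number of breeds (default 24; ignored when
#'   \code{latitudes} is supplied).
#' @param n_per_breed calls per breed, scalar or per-breed vector
#'   (default 10, giving ~240 calls, the scale of the species-wide
#'   regression panel).
#' @param latitude_range uniform sampling range of breed latitudes
#'   (default c(5, 65)).
#' @param variance_model function mapping absolute latitude to the copy
#'   number SD; the default steps from 4.4 below 40 degrees to 5.3 at or
#'   above it, the spreads observed on either side of the study's split.
#' @param mean_cn shared mean diploid copy number (default 11.5).
#' @param latitudes optional explicit per-breed latitudes.
#' @param gene gene label (default "AMY2B").
#' @param seed integer RNG seed.
#' @return list with \code{calls}, \code{breeds} and \code{truth}.
#' @export
simulate_latitude_dataset <- function(n_breeds = 24L, n_per_breed = 10L,
                                      latitude_range = c(5, 65),
                                      variance_model = function(alat)
                                        ifelse(alat >= 40, 5.3, 4.4),
                                      mean_cn = 11.5, latitudes = NULL,
                                      gene = "AMY2B", seed = 1L) {
  with_seed(seed, {
    if (is.null(latitudes))
      latitudes <- runif(n_breeds, latitude_range[1], latitude_range[2])
    n_breeds <- length(latitudes)
    n_per_breed <- rep_len(n_per_breed, n_breeds)
    rows <- lapply(seq_len(n_breeds), function(i) {
      sd_i <- variance_model(abs(latitudes[i]))
      cn <- rtnorm0(n_per_breed[i], mean_cn, sd_i)
      data.frame(
        sample_id = sprintf("B%02d_%02d", i, seq_len(n_per_breed[i])),
        breed = sprintf("Breed%02d", i), gene = gene,
        raw_copy_number = cn, technical_error = 0.3,
        source = "collected", stringsAsFactors = FALSE)
    })
    breeds <- as_breed_info(data.frame(
      breed = sprintf("Breed%02d", seq_len(n_breeds)),
      latitude = latitudes,
      starch = ifelse(abs(latitudes) >= 40, "low", "high"),
      stringsAsFactors = FALSE))
    list(calls = as_cnv_calls(do.call(rbind, rows)), breeds = breeds,
         truth = list(mean_cn = mean_cn, latitudes = latitudes,
                      variance_model = variance_model, seed = seed))
  })
}
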