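# Diet-group and per-breed CNV comparisons, the latitude proxy analysis
# and the cladogram overlay.

# Look up the diet category of each call's breed for one nutrient,
# erroring on breeds without a label.
call_categories <- function(calls, breeds, nutrient) {
  if (!nutrient %in% names(breeds))
    stop("breed table has no '", nutrient, "' column")
  idx <- match(breed_key(calls$breed), breed_key(breeds$breed))
  missing <- unique(calls$breed[is.na(idx)])
  if (length(missing))
    stop("breed(s) absent from breed table: ", paste(missing, collapse = ", "))
  cat_ <- breeds[[nutrient]][idx]
  unlabeled <- unique(calls$breed[is.na(cat_)])
  if (length(unlabeled))
    stop("breed(s) without a ", nutrient, " category: ",
         paste(unlabeled, collapse = ", "))
  cat_
}

#' Compare copy number between two diet groups
#'
#' Splits the calls for one gene into two groups of breeds according to
#' their diet category for a nutrient, then reports group means and SDs
#' (n - 1 denominator), the Fligner-Policello robust rank order test of
#' medians, the Fligner-Killeen test of variance homogeneity, and
#' optionally the per-group proportion of calls at or above a copy-number
#' threshold.
#'
#' @param calls a \code{cnv_calls} data.frame.
#' @param breeds a \code{breed_info} data.frame.
#' @param gene gene symbol to analyse (e.g. \code{"AMY2B"}).
#' @param nutrient breed-table column giving the diet category
#'   (\code{"starch"}, \code{"sugar"} or \code{"phytanic_acid"}).
#' @param grouping list with elements \code{high} and \code{low}, each a
#'   character vector of diet categories assigned to that comparison group.
#'   Categories in neither vector are excluded from the comparison.
#' @param threshold optional integer; when given, the fraction of calls
#'   with \code{copy_number >= threshold} is reported per group.
#' @return object of class \code{diet_comparison}.
#' @export
compare_by_diet <- function(calls, breeds, gene, nutrient,
                            grouping = list(high = "high", low = "low"),
                            threshold = NULL) {
  stopifnot(is.list(grouping), all(c("high", "low") %in% names(grouping)))
  calls <- calls[calls$gene == gene, , drop = FALSE]
  if (!nrow(calls)) stop("no calls for gene ", gene)
  cat_ <- call_categories(calls, breeds, nutrient)
  in_high <- cat_ %in% grouping$high
  in_low <- cat_ %in% grouping$low
  hi <- calls$copy_number[in_high]
  lo <- calls$copy_number[in_low]
  if (!length(hi) || !length(lo))
    stop("empty comparison group for ", gene, " / ", nutrient)

  res <- structure(
    list(gene = gene, nutrient = nutrient,
         group_high = sort(unique(calls$breed[in_high])),
         group_low = sort(unique(calls$breed[in_low])),
         n_high = length(hi), n_low = length(lo),
         mean_high = mean(hi), sd_high = sd(hi),
         mean_low = mean(lo), sd_low = sd(lo),
         # orientation: positive z means the high-diet group tends larger
         rro = fligner_policello_test(lo, hi),
         fk = fligner_killeen_test(list(hi, lo)),
         threshold = threshold,
         proportion_high = NULL, proportion_low = NULL),
    class = "diet_comparison")
  if (!is.null(threshold)) {
    stopifnot(threshold >= 0)
    res$proportion_high <- mean(hi >= threshold)
    res$proportion_low <- mean(lo >= threshold)
  }
  res
}

#' @export
print.diet_comparison <- function(x, ...) {
  cat(sprintf("%s by %s intake\n", x$gene, x$nutrient))
  cat(sprintf("  high group (n = %d): mean %.1f +/- %.1f  [%s]\n",
              x$n_high, x$mean_high, x$sd_high,
              paste(x$group_high, collapse = ", ")))
  cat(sprintf("  low group  (n = %d): mean %.1f +/- %.1f  [%s]\n",
              x$n_low, x$mean_low, x$sd_low,
              paste(x$group_low, collapse = ", ")))
  cat(sprintf("  robust rank order: z = %.3g, p = %.3g\n",
              x$rro$statistic, x$rro$p_value))
  cat(sprintf("  Fligner-Killeen:  X2 = %.3g, p = %.3g\n",
              x$fk$statistic, x$fk$p_value))
  if (!is.null(x$proportion_high))
    cat(sprintf("  >= %d copies: %.0f%% vs %.0f%%\n", x$threshold,
                100 * x$proportion_high, 100 * x$proportion_low))
  invisible(x)
}

#' Per-breed copy-number summary
#'
#' One row per breed with sample count, mean and SD of the diploid copy
#' number (SD is NA for single-call breeds), sorted by decreasing mean.
#'
#' @inheritParams compare_by_diet
#' @return data.frame with columns breed, n, mean, sd.
#' @export
breed_summary <- function(calls, gene) {
  calls <- calls[calls$gene == gene, , drop = FALSE]
  if (!nrow(calls)) stop("no calls for gene ", gene)
  sp <- split(calls$copy_number, calls$breed)
  out <- data.frame(
    breed = names(sp),
    n = lengths(sp),
    mean = vapply(sp, mean, 0),
    sd = vapply(sp, function(v) if (length(v) > 1L) sd(v) else NA_real_, 0),
    row.names = NULL, stringsAsFactors = FALSE)
  out[order(-out$mean), , drop = FALSE]
}

#' Proportion of calls at or above a copy-number threshold, per group
#'
#' @param calls a \code{cnv_calls} data.frame (already filtered to a gene
#'   if desired).
#' @param threshold non-negative integer copy-number cutoff.
#' @param groups named list mapping a group label to the character vector
#'   of breed names it contains (case-insensitive).
#' @return named numeric vector of exact fractions, one per group.
#' @export
proportion_at_least <- function(calls, threshold, groups) {
  stopifnot(threshold >= 0, is.list(groups), length(groups) >= 1L)
  vapply(groups, function(members) {
    sel <- breed_key(calls$breed) %in% breed_key(members)
    if (!any(sel)) return(NA_real_)
    mean(calls$copy_number[sel] >= threshold)
  }, 0)
}

#' Latitude as a starch-intake proxy
#'
#' Regresses diploid copy number on absolute latitude of breed origin, and
#' splits the calls at \code{split_degrees} of absolute latitude (the
#' boundary value itself falls in the "above" group) to compare
#' variances between low- and high-latitude dogs with the Fligner-Killeen
#' test.
#'
#' @inheritParams compare_by_diet
#' @param split_degrees absolute-latitude split point (default 40).
#' @param gene gene to analyse (default \code{"AMY2B"}).
#' @return object of class \code{latitude_analysis}.
#' @export
latitude_analysis <- function(calls, breeds, split_degrees = 40,
                              gene = "AMY2B") {
  calls <- calls[calls$gene == gene, , drop = FALSE]
  if (!nrow(calls)) stop("no calls for gene ", gene)
  idx <- match(breed_key(calls$breed), breed_key(breeds$breed))
  missing <- unique(calls$breed[is.na(idx)])
  if (length(missing))
    stop("breed(s) without latitude: ", paste(missing, collapse = ", "))
  alat <- abs(breeds$latitude[idx])
  cn <- calls$copy_number
  below <- alat < split_degrees
  if (!any(below) || all(below))
    stop("latitude split at ", split_degrees,
         " degrees leaves one side empty")
  structure(
    list(gene = gene,
         fit = ols_fit(alat, cn),
         split_degrees = split_degrees,
         n_below = sum(below), n_above = sum(!below),
         mean_below = mean(cn[below]), sd_below = sd(cn[below]),
         mean_above = mean(cn[!below]), sd_above = sd(cn[!below]),
         fk = fligner_killeen_test(list(cn[below], cn[!below]))),
    class = "latitude_analysis")
}

#' @export
print.latitude_analysis <- function(x, ...) {
  cat(sprintf("%s copy number vs absolute latitude (split at %g deg)\n",
              x$gene, x$split_degrees))
  cat(sprintf("  regression: R^2 = %.3g, p = %.3g\n",
              x$fit$r_squared, x$fit$p_slope))
  cat(sprintf("  below: n = %d, mean %.1f +/- %.1f; above: n = %d, mean %.1f +/- %.1f\n",
              x$n_below, x$mean_below, x$sd_below,
              x$n_above, x$mean_above, x$sd_above))
  cat(sprintf("  Fligner-Killeen: X2 = %.3g, p = %.3g\n",
              x$fk$statistic, x$fk$p_value))
  invisible(x)
}

#' Overlay per-breed mean copy number on a cladogram
#'
#' Purely descriptive: lists breeds in the tree's leaf order with their
#' mean copy number attached. Breeds absent from the tree are appended at
#' the end with a warning.
#'
#' @param tree a \code{phylo} object (see [load_cladogram()]).
#' @param summary a [breed_summary()] table.
#' @return data.frame (breed, tip_order, n, mean, sd, in_tree) ordered by
#'   leaf position.
#' @export
cladogram_overlay <- function(tree, summary) {
  if (!nrow(summary))
    return(data.frame(breed = character(0), tip_order = integer(0),
                      n = integer(0), mean = numeric(0), sd = numeric(0),
                      in_tree = logical(0)))
  pos <- match(breed_key(summary$breed), breed_key(tree$tip.label))
  absent <- summary$breed[is.na(pos)]
  if (length(absent))
    warning("breed(s) absent from cladogram, appended at end: ",
            paste(absent, collapse = ", "))
  out <- data.frame(breed = summary$breed, tip_order = pos,
                    n = summary$n, mean = summary$mean, sd = summary$sd,
                    in_tree = !is.na(pos), stringsAsFactors = FALSE)
  out <- out[order(is.na(out$tip_order), out$tip_order), , drop = FALSE]
  rownames(out) <- NULL
  out
}
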