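# Cross-breed aCGH null distribution and the focal-gene
# regression-residual outlier statistic.

#' Per-site mean log2 ratios for two focal breeds
#'
#' Collapses a long-format aCGH table (one row per site x breed x sample
#' log2 ratio) to per-site means for two focal breeds. A site is eligible
#' for the null distribution only if it carries at least one sample value
#' in each focal breed.
#'
#' @param acgh data.frame with columns site_id, chrom, start, end, breed,
#'   sample_id, log2 (start/end are 0-based half-open).
#' @param breed_x,breed_y the two focal breeds.
#' @return data.frame of class \code{acgh_sites} with one row per site:
#'   site_id, chrom, start, end, n_x, n_y, mean_x, mean_y, null_eligible.
#' @export
site_means <- function(acgh, breed_x, breed_y) {
  need <- c("site_id", "chrom", "start", "end", "breed", "sample_id", "log2")
  missing_cols <- setdiff(need, names(acgh))
  if (length(missing_cols))
    stop("aCGH table lacks column(s): ", paste(missing_cols, collapse = ", "))
  lv <- suppressWarnings(as.numeric(acgh$log2))
  bad <- which(is.na(lv) & !is.na(acgh$log2))
  if (length(bad))
    stop("non-numeric log2 ratio at row(s): ", paste(bad, collapse = ", "))
  if (anyNA(lv)) stop("missing log2 ratio at row(s): ",
                      paste(which(is.na(lv)), collapse = ", "))
  acgh$log2 <- lv

  sites <- unique(acgh[c("site_id", "chrom", "start", "end")])
  if (anyDuplicated(sites$site_id))
    stop("site_id maps to more than one coordinate set")
  bx <- breed_key(acgh$breed) == breed_key(breed_x)
  by <- breed_key(acgh$breed) == breed_key(breed_y)
  mean_of <- function(sel) {
    v <- tapply(acgh$log2[sel], acgh$site_id[sel], mean)
    v[match(sites$site_id, names(v))]
  }
  n_of <- function(sel) {
    v <- tapply(acgh$log2[sel], acgh$site_id[sel], length)
    n <- v[match(sites$site_id, names(v))]
    ifelse(is.na(n), 0L, n)
  }
  out <- data.frame(sites,
                    n_x = as.integer(n_of(bx)), n_y = as.integer(n_of(by)),
                    mean_x = as.numeric(mean_of(bx)),
                    mean_y = as.numeric(mean_of(by)),
                    stringsAsFactors = FALSE)
  out$null_eligible <- out$n_x >= 1L & out$n_y >= 1L
  attr(out, "breed_x") <- breed_x
  attr(out, "breed_y") <- breed_y
  class(out) <- c("acgh_sites", "data.frame")
  out
}

#' Convert a mean diploid copy number to an aCGH-style log2 ratio
#'
#' @param mean_diploid_cn positive mean diploid copy number (e.g. from
#'   ddPCR).
#' @param reference_diploid_cn positive diploid copy number of the
#'   reference genome at the locus. There is no default: the reference
#'   copy count must be supplied explicitly.
#' @return log2(mean_diploid_cn / reference_diploid_cn).
#' @export
cnv_to_log2 <- function(mean_diploid_cn, reference_diploid_cn) {
  if (any(mean_diploid_cn <= 0) || any(reference_diploid_cn <= 0))
    stop("copy numbers must be positive")
  log2(mean_diploid_cn / reference_diploid_cn)
}

#' Focal-gene outlier z score against the cross-breed null regression
#'
#' Fits an ordinary least-squares line of breed-y mean log2 ratios on
#' breed-x means over the null-eligible sites only (the focal point is
#' never part of the fit), then standardizes the focal point's vertical
#' residual by the null residuals' mean and SD:
#' z = (residual - residual_mean) / residual_sd.
#'
#' @param null_sites an \code{acgh_sites} table (only rows with
#'   \code{null_eligible} are used) or a data.frame with mean_x, mean_y.
#' @param focal_x,focal_y focal mean log2 ratios on the x and y breeds.
#' @param focal_label label for the focal locus (default "focal").
#' @return object of class \code{acgh_outlier}: focal coordinates, the
#'   null fit, the focal residual, the z score and the null-site count.
#' @export
outlier_z <- function(null_sites, focal_x, focal_y, focal_label = "focal") {
  df <- as.data.frame(null_sites)
  if ("null_eligible" %in% names(df)) df <- df[df$null_eligible, , drop = FALSE]
  if (nrow(df) < 3L) stop("need at least three null sites")
  fit <- ols_fit(df$mean_x, df$mean_y)
  residual <- focal_y - (fit$intercept + fit$slope * focal_x)
  degenerate <- fit$residual_sd == 0
  z <- if (degenerate) {
    if (residual == fit$residual_mean) 0 else sign(residual) * Inf
  } else {
    (residual - fit$residual_mean) / fit$residual_sd
  }
  structure(
    list(focal_label = focal_label, x_value = focal_x, y_value = focal_y,
         fit = fit, residual = residual, z_score = z,
         n_null_sites = nrow(df), degenerate = degenerate),
    class = "acgh_outlier")
}

#' @export
print.acgh_outlier <- function(x, ...) {
  cat(sprintf("aCGH outlier '%s' at (%.3g, %.3g): residual %.3g, z = %.3g\n",
              x$focal_label, x$x_value, x$y_value, x$residual, x$z_score))
  cat(sprintf("  null fit over %d sites: slope %.3g, intercept %.3g, residual sd %.3g\n",
              x$n_null_sites, x$fit$slope, x$fit$intercept, x$fit$residual_sd))
  invisible(x)
}
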