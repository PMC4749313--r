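#' Construct and validate a table of diploid copy-number calls
#'
#' A CNV-call table has one row per (sample, gene) measurement:
#' \code{sample_id}, \code{breed}, \code{gene}, \code{raw_copy_number}
#' (diploid copies as reported by the instrument; may be NA for calls
#' aggregated from the literature), \code{copy_number} (non-negative
#' integer, the raw value rounded half away from zero), \code{technical_error}
#' (>= 0, NA when unavailable -- never imputed to zero), \code{source}
#' (\code{"collected"} or \code{"aggregated"}) and optional
#' \code{dna_concentration} (ng/uL).
#'
#' @param df data.frame with at least sample_id, breed, gene and one of
#'   raw_copy_number / copy_number.
#' @return validated data.frame of class \code{cnv_calls}.
#' @export
as_cnv_calls <- function(df) {
  stopifnot(is.data.frame(df))
  required <- c("sample_id", "breed", "gene")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  if (!any(c("raw_copy_number", "copy_number") %in% names(df)))
    stop("missing required column(s): raw_copy_number or copy_number")

  out <- data.frame(
    sample_id = as.character(df$sample_id),
    breed = as.character(df$breed),
    gene = as.character(df$gene),
    raw_copy_number = if ("raw_copy_number" %in% names(df))
      as.numeric(df$raw_copy_number) else NA_real_,
    copy_number = if ("copy_number" %in% names(df))
      as.numeric(df$copy_number) else NA_real_,
    technical_error = if ("technical_error" %in% names(df))
      as.numeric(df$technical_error) else NA_real_,
    source = if ("source" %in% names(df))
      as.character(df$source) else "collected",
    dna_concentration = if ("dna_concentration" %in% names(df))
      as.numeric(df$dna_concentration) else NA_real_,
    stringsAsFactors = FALSE)

  # rounding rule: copy_number is raw rounded half away from zero
  has_raw <- !is.na(out$raw_copy_number)
  out$copy_number[has_raw] <- round_half_away(out$raw_copy_number[has_raw])

  bad_raw <- which(has_raw & out$raw_copy_number < 0)
  if (length(bad_raw))
    stop("negative raw copy number at row(s): ",
         paste(bad_raw, collapse = ", "))
  bad_cn <- which(!is.na(out$copy_number) &
                    (out$copy_number < 0 | out$copy_number != floor(out$copy_number)))
  if (length(bad_cn))
    stop("copy_number must be a non-negative integer at row(s): ",
         paste(bad_cn, collapse = ", "))
  no_cn <- which(is.na(out$copy_number))
  if (length(no_cn))
    stop("rows lacking both raw_copy_number and copy_number: ",
         paste(no_cn, collapse = ", "))
  bad_err <- which(!is.na(out$technical_error) & out$technical_error < 0)
  if (length(bad_err))
    stop("negative technical error at row(s): ", paste(bad_err, collapse = ", "))
  bad_src <- which(!out$source %in% c("collected", "aggregated"))
  if (length(bad_src))
    stop("source must be 'collected' or 'aggregated' at row(s): ",
         paste(bad_src, collapse = ", "))

  key <- paste(out$sample_id, out$gene, sep = "\r")
  dup <- key[duplicated(key)]
  if (length(dup))
    stop("duplicate sample_id+gene pair(s): ",
         paste(unique(gsub("\r", "/", dup)), collapse = ", "))

  class(out) <- c("cnv_calls", "data.frame")
  out
}

#' Load diploid copy-number calls from a delimited table
#'
#' Accepts comma- or tab-separated UTF-8 files (auto-detected from the
#' header). Column names can be remapped through \code{schema}, a named
#' character vector \code{c(internal_name = "file column name")}.
#'
#' @param path file path.
#' @param schema optional named character vector remapping file columns
#'   onto the canonical names (see [as_cnv_calls()]).
#' @return a \code{cnv_calls} data.frame.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("sample_id,breed,gene,raw_copy_number,technical_error,source",
#'              "s1,Shar Pei,AMY2B,10.6,0.4,collected"), f)
#' load_cnv_calls(f)$copy_number  # 11
#' @export
load_cnv_calls <- function(path, schema = NULL) {
  df <- read_delim_auto(path)
  if (!is.null(schema)) {
    for (internal in names(schema)) {
      src <- schema[[internal]]
      if (!src %in% names(df))
        stop("schema column not found in file: ", src)
      names(df)[names(df) == src] <- internal
    }
  }
  as_cnv_calls(df)
}

#' Write a CNV-call table
#'
#' Emits the canonical column set so that a written table reloads
#' identically through [load_cnv_calls()].
#'
#' @param calls a \code{cnv_calls} data.frame.
#' @param path destination file; extension ".tsv" selects tab separation.
#' @return invisibly, the path.
#' @export
write_cnv_calls <- function(calls, path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  write_delim_auto(as.data.frame(calls), path, sep = sep)
  invisible(path)
}

#' Combine collected and aggregated copy-number calls
#'
#' Unions the two call sets, preserving source tags, after checking that no
#' sample_id+gene key appears in both.
#'
#' @param collected,aggregated \code{cnv_calls} data.frames (either may be
#'   empty / NULL).
#' @return a \code{cnv_calls} data.frame; the attribute
#'   \code{"source_counts"} carries calls per source.
#' @export
assemble_dataset <- function(collected, aggregated = NULL) {
  if (is.null(aggregated) || nrow(aggregated) == 0L) {
    out <- as_cnv_calls(as.data.frame(collected))
  } else {
    a <- as.data.frame(collected); b <- as.data.frame(aggregated)
    key_a <- paste(a$sample_id, a$gene, sep = "\r")
    key_b <- paste(b$sample_id, b$gene, sep = "\r")
    clash <- intersect(key_a, key_b)
    if (length(clash))
      stop("sample_id+gene collision(s) across collected and aggregated: ",
           paste(gsub("\r", "/", clash), collapse = ", "))
    out <- as_cnv_calls(rbind(a, b))
  }
  attr(out, "source_counts") <- table(out$source)
  out
}

#' Construct and validate a breed metadata table
#'
#' One row per breed: \code{breed}, \code{latitude} (degrees of the breed's
#' location of origin, in [-90, 90]), one column per nutrient
#' (\code{starch}, \code{sugar}, \code{phytanic_acid}) holding a diet
#' category (\code{high}, \code{moderate}, \code{low}, or NA), and optional
#' \code{clade}.
#'
#' @param df data.frame.
#' @return validated data.frame of class \code{breed_info}.
#' @export
as_breed_info <- function(df) {
  stopifnot(is.data.frame(df))
  if (!all(c("breed", "latitude") %in% names(df)))
    stop("missing required column(s): breed and/or latitude")
  nutrients <- intersect(c("starch", "sugar", "phytanic_acid"), names(df))
  if (!length(nutrients))
    stop("need at least one nutrient column among starch, sugar, phytanic_acid")
  out <- df
  out$breed <- as.character(out$breed)
  out$latitude <- as.numeric(out$latitude)
  if (anyDuplicated(breed_key(out$breed)))
    stop("duplicate breed rows: ",
         paste(out$breed[duplicated(breed_key(out$breed))], collapse = ", "))
  bad_lat <- which(is.na(out$latitude) | abs(out$latitude) > 90)
  if (length(bad_lat))
    stop("latitude outside [-90, 90] (or missing) for breed(s): ",
         paste(out$breed[bad_lat], collapse = ", "))
  for (nut in nutrients) {
    out[[nut]] <- as.character(out[[nut]])
    bad <- which(!is.na(out[[nut]]) & !out[[nut]] %in% c("high", "moderate", "low"))
    if (length(bad))
      stop("unknown ", nut, " category '", out[[nut]][bad[1]],
           "' for breed ", out$breed[bad[1]],
           " (allowed: high, moderate, low)")
  }
  if (!"clade" %in% names(out)) out$clade <- NA_character_
  class(out) <- c("breed_info", "data.frame")
  out
}

#' Load breed metadata from a delimited table
#'
#' @param path CSV/TSV with header
#'   \code{breed,latitude,starch,sugar,phytanic_acid,clade}.
#' @return a \code{breed_info} data.frame.
#' @export
load_breed_info <- function(path) {
  as_breed_info(read_delim_auto(path))
}

#' Load a breed cladogram from a newick file
#'
#' Thin wrapper over [ape::read.tree()] that also reports which of the
#' analysed breeds are missing from the tree's leaf set.
#'
#' @param path newick file.
#' @param breeds optional character vector of breed names expected among
#'   the leaves; missing ones trigger a warning and are recorded in the
#'   \code{"missing_breeds"} attribute.
#' @return an [ape::read.tree()] \code{phylo} object.
#' @export
load_cladogram <- function(path, breeds = NULL) {
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stop("newick parse failure in ", path,
                                            ": ", conditionMessage(e)))
  if (is.null(tree)) stop("newick parse failure in ", path)
  missing <- character(0)
  if (!is.null(breeds)) {
    missing <- breeds[!breed_key(breeds) %in% breed_key(tree$tip.label)]
    if (length(missing))
      warning("breeds absent from cladogram: ", paste(missing, collapse = ", "))
  }
  attr(tree, "missing_breeds") <- missing
  tree
}

#' Collapse breed aliases onto a pooled label
#'
#' The study pools the Akita and Shiba Inu as "Japanese Dogs"; this helper
#' applies such alias maps uniformly (case-insensitive matching on the
#' alias keys).
#'
#' @param calls a \code{cnv_calls} data.frame.
#' @param aliases named character vector \code{c(original = "pooled label")}.
#' @return the calls with breed labels rewritten.
#' @export
apply_breed_aliases <- function(calls, aliases) {
  idx <- match(breed_key(calls$breed), breed_key(names(aliases)))
  hit <- !is.na(idx)
  calls$breed[hit] <- unname(aliases[idx[hit]])
  calls
}
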