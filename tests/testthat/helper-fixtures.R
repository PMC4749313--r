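# Small in-code fixtures shared across test files.

toy_calls <- function() {
  as_cnv_calls(data.frame(
    sample_id = c("s1", "s2", "s3", "s4", "s5", "s6"),
    breed = c("Shar Pei", "Shar Pei", "Pekingese",
              "Siberian Husky", "Siberian Husky", "Alaskan Malamute"),
    gene = "AMY2B",
    raw_copy_number = c(11.2, 10.4, 10.9, 6.1, 8.8, 4.2),
    technical_error = 0.3,
    source = "collected",
    stringsAsFactors = FALSE))
}

toy_breeds <- function() {
  as_breed_info(data.frame(
    breed = c("Shar Pei", "Pekingese", "Siberian Husky", "Alaskan Malamute"),
    latitude = c(23.1, 39.9, 63.0, 64.8),
    starch = c("high", "high", "low", "low"),
    sugar = c("moderate", "moderate", "low", "low"),
    phytanic_acid = c("low", "low", "high", "high"),
    stringsAsFactors = FALSE))
}

write_tmp_lines <- function(lines, ext = ".csv") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
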