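#' Read and write pipeline tables
#'
#' Plain-text interchange formats: summary statistics as tab-delimited with
#' the header `rsid chr pos effect_allele other_allele beta raf pval info`;
#' genotype dosages as (optionally gzipped) tab-delimited with a one-line
#' variant header; cohorts as CSV; incidence and age-weight tables as CSV
#' with columns `age, sex, value`.
#'
#' @param stats,geno,cohort,table Objects to write.
#' @param path File path; `.gz` suffixes are handled transparently.
#' @return Readers return data.frames (or a matrix for genotypes); writers
#'   return `path` invisibly.
#' @name mced_io
NULL

#' @rdname mced_io
#' @export
write_summary_stats <- function(stats, path) {
  utils::write.table(stats, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname mced_io
#' @export
read_summary_stats <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("rsid", "chr", "pos", "effect_allele", "other_allele", "beta",
            "raf", "pval", "info")
  assert_that(all(need %in% names(df)),
              paste("summary-statistics file missing columns:",
                    paste(setdiff(need, names(df)), collapse = ", ")))
  df
}

#' @rdname mced_io
#' @export
write_genotypes <- function(geno, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(paste(colnames(geno), collapse = "\t"), con)
  utils::write.table(geno, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname mced_io
#' @export
read_genotypes <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df)
  assert_that(all(m >= 0 & m <= 2, na.rm = TRUE),
              "dosages must lie in [0, 2]")
  attr(m, "observed_freq") <- colMeans(m, na.rm = TRUE) / 2
  m
}

#' @rdname mced_io
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname mced_io
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("smoking" %in% names(df)) {
    df$smoking <- factor(df$smoking, levels = c("never", "former", "current"))
  }
  df
}

#' @rdname mced_io
#' @export
write_rate_table <- function(table, path) {
  value_col <- intersect(c("rate", "weight"), names(table))[1]
  out <- data.frame(age = table$age, sex = table$sex,
                    value = table[[value_col]])
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname mced_io
#' @param value_name Column name to give the `value` column on read
#'   (`"rate"` for incidence tables, `"weight"` for age weights).
#' @export
read_rate_table <- function(path, value_name = "rate") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  assert_that(all(c("age", "sex", "value") %in% names(df)),
              "rate table must have columns age, sex, value")
  names(df)[names(df) == "value"] <- value_name
  df
}
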