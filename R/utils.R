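# Internal helpers shared across modules.

#' Order chromosome labels naturally
#'
#' Numeric-like labels ("1".."31") sort numerically and come first; anything
#' else ("X", "Un", "0") follows in alphabetical order. Labels are compared as
#' strings everywhere else in the package.
#'
#' @param chrom character vector of chromosome labels
#' @return integer ordering permutation
#' @keywords internal
chrom_order <- function(chrom) {
  num <- suppressWarnings(as.numeric(chrom))
  is_num <- !is.na(num)
  key1 <- ifelse(is_num, 0L, 1L)
  key2 <- ifelse(is_num, num, NA_real_)
  order(key1, key2, chrom)
}

#' Write a data frame as a deterministic TSV
#'
#' Fixed formatting (no scientific notation, "." decimal mark, NA as "NA",
#' Unix newlines) so that identical inputs produce byte-identical files.
#'
#' @param x data frame
#' @param path output path
#' @keywords internal
write_tsv_file <- function(x, path) {
  old <- options(scipen = 15, OutDec = ".")
  on.exit(options(old), add = TRUE)
  con <- file(path, open = "wb")
  on.exit(close(con), add = TRUE)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, na = "NA", eol = "\n")
  invisible(path)
}

#' Read a headered TSV written by this package
#' @param path input path
#' @return data frame with character columns left unconverted to factors
#' @keywords internal
read_tsv_file <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                    stringsAsFactors = FALSE, colClasses = NA,
                    check.names = FALSE, comment.char = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_data <- function(...) stop(errorCondition(paste0(...), class = c("rohqc_data_error", "error")))
stop_config <- function(...) stop(errorCondition(paste0(...), class = c("rohqc_config_error", "error")))
stop_parse <- function(...) stop(errorCondition(paste0(...), class = c("rohqc_parse_error", "error")))
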