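#' Derive a child seed from a master seed and a stage tag
#'
#' All randomness in the package is funnelled through one master seed; each
#' stage (generation, permutation, ordination, ...) draws a deterministic
#' child seed so stages can be regenerated independently of one another.
#' The derivation is a 31-bit polynomial string hash folded into the master.
#'
#' @param master integer master seed.
#' @param tag character stage label, e.g. `"indicators:upper_10_100"`.
#' @return an integer in `[1, 2^31 - 2]`, deterministic in `(master, tag)`.
#' @export
childSeed <- function(master, tag) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(tag))
  m <- 2147483647  # 2^31 - 1, keeps every derived seed a valid 32-bit integer
  h <- as.double(master) %% m
  for (code in utf8ToInt(tag)) h <- (h * 31 + code) %% m
  as.integer(h %% (m - 1) + 1)
}

# Run log: pipeline stages append one entry per dropped sample/OTU/edge.
# When the "blobind.logfile" option points at a path the entry is appended
# there; entries also surface as messages when "blobind.verbose" is TRUE.
blobLog <- function(...) {
  txt <- paste0(...)
  lf <- getOption("blobind.logfile", NULL)
  if (!is.null(lf)) cat(txt, "\n", sep = "", file = lf, append = TRUE)
  if (isTRUE(getOption("blobind.verbose", FALSE))) message(txt)
  invisible(txt)
}

# Stable TSV writer: fixed column order, no quoting, full precision.
writeTsv <- function(df, path, rowNames = FALSE) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = rowNames, col.names = TRUE)
  invisible(path)
}

readTsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}
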