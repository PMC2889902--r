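# Minimal reader for GEO series-matrix files, sufficient to load
# real platform data (expression values plus sample annotation) into an
# analysis-ready matrix.

#' Read a GEO series-matrix file
#'
#' Parses the `!Sample_*` header lines into a sample-annotation table and
#' the block between `!series_matrix_table_begin` and
#' `!series_matrix_table_end` into a numeric matrix (probes x samples).
#' Handles plain or gzip-compressed files.
#'
#' @param file path to a series-matrix TXT file.
#' @return list: `matrix` (numeric, rownames = probe ids, colnames = GSM
#'   accessions) and `sampleInfo` (data.frame, one row per sample, one
#'   column per `!Sample_` field; repeated fields are suffixed).
#' @export
readSeriesMatrix <- function(file) {
  con <- if (grepl("\\.gz$", file)) gzfile(file, "rt") else
    file(file, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  hdr <- grep("^!Sample_", lines, value = TRUE)
  meta <- list()
  for (l in hdr) {
    parts <- strsplit(sub("^!", "", l), "\t")[[1]]
    key <- parts[1]
    vals <- gsub('^"|"$', "", parts[-1])
    nm <- key
    k <- 1L
    while (nm %in% names(meta)) { k <- k + 1L; nm <- paste0(key, ".", k) }
    meta[[nm]] <- vals
  }
  b <- grep("^!series_matrix_table_begin", lines)
  e <- grep("^!series_matrix_table_end", lines)
  if (!length(b) || !length(e))
    stop("no series-matrix table found in ", file)
  tab <- utils::read.table(text = lines[(b + 1L):(e - 1L)], sep = "\t",
                           header = TRUE, row.names = 1,
                           check.names = FALSE, quote = '"',
                           na.strings = c("", "NA", "null"))
  m <- as.matrix(tab)
  mode(m) <- "numeric"
  si <- as.data.frame(meta, stringsAsFactors = FALSE,
                      check.names = FALSE)
  if (nrow(si)) rownames(si) <- si[["Sample_geo_accession"]]
  list(matrix = m, sampleInfo = si)
}
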