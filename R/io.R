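# Reading and writing small-RNA read sets. FASTQ quality is ignored;
# collapsed FASTA encodes multiplicity in the header (default dialect
# "id_x123", regex-configurable).

#' Read small-RNA reads from FASTQ or (collapsed) FASTA
#'
#' @param path input file.
#' @param format `"auto"` (by extension), `"fasta"`, `"fastq"` or
#'   `"collapsed"` (FASTA with header-encoded counts).
#' @param count_regex regex with one capture group extracting the count
#'   from a collapsed header (default matches `..._x123` or `...x123`).
#' @return tibble with `id`, `seq` (RNA alphabet), `count`.
#' @export
read_small_rna <- function(path, format = c("auto", "fasta", "fastq",
                                            "collapsed"),
                           count_regex = "[_x]x?(\\d+)$") {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path,
                        ignore.case = TRUE)) "fastq" else "fasta"
  }
  ss <- Biostrings::readBStringSet(path,
                                   format = if (format == "fastq") "fastq"
                                   else "fasta")
  ids <- sub("\\s.*$", "", names(ss))
  counts <- rep(1, length(ss))
  if (format == "collapsed") {
    m <- regmatches(ids, regexec(count_regex, ids))
    got <- lengths(m) == 2
    if (!all(got)) {
      stop("collapsed header(s) without a count: ",
           paste(utils::head(ids[!got], 3), collapse = ", "), call. = FALSE)
    }
    counts <- as.numeric(vapply(m, `[`, character(1), 2))
  }
  tibble::tibble(id = ids,
                 seq = unname(normalize_rna(as.character(ss), ids = ids)),
                 count = unname(counts))
}

#' Write reads as collapsed FASTA
#'
#' Headers are `id_x<count>`.
#'
#' @param reads tibble with `id`, `seq`, `count`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_collapsed_fasta <- function(reads, path) {
  hdr <- sprintf(">%s_x%s", reads$id,
                 format(reads$count, trim = TRUE, scientific = FALSE))
  writeLines(as.vector(rbind(hdr, reads$seq)), path)
  invisible(path)
}

#' Write reads as FASTQ with constant quality
#'
#' One record per row (counts are not expanded); quality is a constant
#' run of `"I"`.
#'
#' @inheritParams write_collapsed_fasta
#' @return invisibly, `path`.
#' @export
write_fastq <- function(reads, path) {
  qual <- strrep("I", nchar(reads$seq))
  writeLines(as.vector(rbind(paste0("@", reads$id), reads$seq, "+", qual)),
             path)
  invisible(path)
}
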