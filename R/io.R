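#' Read and write BED / bedGraph tables
#'
#' Minimal tibble-based readers/writers for the interval formats the
#' pipeline exchanges: BED3/BED6 (`chrom`, `start`, `end`, optionally
#' `name`, `score`, `strand`) and 4-column bedGraph (`chrom`, `start`,
#' `end`, `value`).  Coordinates are 0-based half-open, as in the formats
#' themselves.
#'
#' @param path File path.
#' @param x Tibble to write.
#' @return Readers return a tibble; writers return `path` invisibly.
#' @name bed_io
NULL

#' @rdname bed_io
#' @export
read_bed <- function(path) {
  first <- readr::read_tsv(path, comment = "#", col_names = FALSE,
                           n_max = 1, col_types = readr::cols(.default = "c"),
                           progress = FALSE)
  nc <- ncol(first)
  nms <- c("chrom", "start", "end", "name", "score", "strand")[seq_len(min(nc, 6))]
  types <- substr("ciicdc", 1, min(nc, 6))
  readr::read_tsv(path, comment = "#", col_names = nms, col_types = types,
                  progress = FALSE)
}

#' @rdname bed_io
#' @export
write_bed <- function(x, path) {
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(x))
  readr::write_tsv(x[, cols], path, col_names = FALSE)
  invisible(path)
}

#' @rdname bed_io
#' @export
read_bedgraph <- function(path) {
  readr::read_tsv(path, comment = "#",
                  col_names = c("chrom", "start", "end", "value"),
                  col_types = "ciid", progress = FALSE)
}

#' @rdname bed_io
#' @export
write_bedgraph <- function(x, path) {
  readr::write_tsv(x[, c("chrom", "start", "end", "value")], path,
                   col_names = FALSE)
  invisible(path)
}

#' Write a genome as FASTA
#'
#' @param genome A `DNAStringSet` or named character vector.
#' @param path Output FASTA path.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(load_genome(genome), path)
  invisible(path)
}
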