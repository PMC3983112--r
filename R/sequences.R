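# Sequence and alignment I/O, delegated to seqinr.

#' Read protein sequences from a FASTA file
#'
#' @param path FASTA file.
#' @return Named character vector of upper-case one-letter sequences.
#' @export
read_fasta_sequences <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  s <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                          set.attributes = FALSE)
  out <- toupper(unlist(s))
  names(out) <- names(s)
  out
}

#' Read a multiple sequence alignment
#'
#' Accepts aligned FASTA or Clustal bodies (detected from the first line
#' unless `format` is given). All rows must have equal gapped length.
#'
#' @param path alignment file.
#' @param format `"auto"`, `"fasta"` or `"clustal"`.
#' @return An object of class `msa`: list with `ids` (character) and
#'   `seqs` (upper-case gapped sequences, equal length).
#' @export
read_alignment <- function(path, format = c("auto", "fasta", "clustal")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    first <- readLines(path, n = 1, warn = FALSE)
    format <- if (grepl("^CLUSTAL", first, ignore.case = TRUE))
      "clustal" else "fasta"
  }
  a <- seqinr::read.alignment(path, format = format)
  seqs <- toupper(unlist(a$seq))
  ids <- a$nam
  if (length(seqs) == 0) stop("no sequences in '", path, "'")
  len <- nchar(seqs)
  if (length(unique(len)) != 1)
    stop("ragged alignment: row lengths ", paste(unique(len), collapse = ", "))
  structure(list(ids = ids, seqs = unname(seqs)), class = "msa")
}

#' Write an alignment as aligned FASTA
#'
#' Round-trips with [read_alignment()]: identifiers and columns are
#' preserved.
#'
#' @param aln an `msa` object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  seqinr::write.fasta(as.list(aln$seqs), names = aln$ids, file.out = path,
                      nbchar = 60)
  invisible(path)
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("msa: %d sequences x %d columns\n", length(x$ids),
              nchar(x$seqs[1])))
  invisible(x)
}
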