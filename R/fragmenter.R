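# Segmentation of an unstructured tail into overlapping peptide
# fragments for fragment-based binding scans.

#' Segment a sequence into overlapping fragments
#'
#' Tiles a 1-letter sequence with fragments of `nominal_len` residues and
#' an overlap of `overlap` residues between neighbours (stride
#' `nominal_len - overlap`), so that no potential binding region is cut
#' without also appearing intact in a neighbouring fragment. A fragment
#' end is extended (up to `max_len`) while a structurally constrained
#' residue (`avoid_residue`, proline by default) lies within `end_window`
#' residues of the fragment end or of the next fragment's start; if the
#' window cannot be cleaned within `max_len` the nominal end is kept and
#' a warning is issued. The final fragment is anchored to the sequence
#' end and back-extended to at least `nominal_len`. Every residue is
#' covered by at least one fragment and adjacent fragments share at least
#' `overlap` residues.
#'
#' @param sequence 1-letter amino-acid string.
#' @param start_number author residue number of the first sequence
#'   position; fragment coordinates are reported in this numbering.
#' @param nominal_len nominal fragment length (default 30).
#' @param max_len maximum length an end may be extended to (default 44).
#' @param overlap minimum residues shared by consecutive fragments
#'   (default 10).
#' @param avoid_residue 1-letter code to keep away from fragment ends
#'   (default `"P"`; set `NA` to disable).
#' @param end_window how close to an end counts as "near" (default 3
#'   residues).
#' @return Object of class `fragment_set`: data.frame with columns
#'   `index`, `start`, `end`, `length`, `sequence`.
#' @export
segment_chain <- function(sequence, start_number = 1, nominal_len = 30,
                          max_len = 44, overlap = 10,
                          avoid_residue = "P", end_window = 3) {
  sequence <- toupper(gsub("\\s", "", sequence))
  n <- nchar(sequence)
  if (overlap <= 0 || overlap >= nominal_len || nominal_len > max_len)
    stop("need 0 < overlap < nominal_len <= max_len")
  chars <- strsplit(sequence, "")[[1]]
  avoid_pos <- if (is.na(avoid_residue)) integer(0)
               else which(chars == toupper(avoid_residue))
  frag_rows <- function(starts, ends) {
    data.frame(index = seq_along(starts),
               start = start_number + starts - 1,
               end = start_number + ends - 1,
               length = ends - starts + 1,
               sequence = substring(sequence, starts, ends),
               stringsAsFactors = FALSE)
  }
  done <- function(starts, ends)
    structure(frag_rows(starts, ends),
              class = c("fragment_set", "data.frame"),
              overlap = overlap, nominal_len = nominal_len)
  if (n < nominal_len) {
    warning("sequence shorter than nominal fragment length; ",
            "returning a single fragment")
    return(done(1L, n))
  }
  # an end position is clean when no avoided residue sits within
  # end_window of it or of the next fragment's start
  end_clean <- function(e) {
    w <- c(seq(max(1, e - end_window + 1), min(n, e + end_window)),
           seq(e - overlap + 1, min(n, e - overlap + end_window)))
    !any(avoid_pos %in% w)
  }
  starts <- integer(0); ends <- integer(0)
  s <- 1L
  repeat {
    e <- s + nominal_len - 1L
    if (e >= n) {
      s <- min(s, n - nominal_len + 1L)
      starts <- c(starts, s); ends <- c(ends, n)
      break
    }
    e0 <- e
    while (!end_clean(e) && (e - s + 1L) < max_len && e < n) e <- e + 1L
    if (!end_clean(e) && (e - s + 1L) >= max_len) {
      warning("cannot keep '", avoid_residue, "' out of the end window ",
              "of fragment starting at ", start_number + s - 1,
              " within max_len; keeping nominal end")
      e <- e0
    }
    if (e >= n) {
      s <- min(s, n - nominal_len + 1L)
      starts <- c(starts, s); ends <- c(ends, n)
      break
    }
    starts <- c(starts, s); ends <- c(ends, e)
    s <- e - overlap + 1L
  }
  done(starts, ends)
}

#' Write a fragment set as TSV
#'
#' Columns: `index  start  end  length  sequence`.
#'
#' @param x a `fragment_set`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fragments_tsv <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
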