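# Alignment-column conservation classification and its projection onto
# binding sites. A substitution within one physicochemical group (acidic,
# basic, polar uncharged, nonpolar) counts as conserved.

#' Default amino-acid conservation groups
#'
#' Partition of the 20 standard residues by charge and polarity: acidic
#' `{D, E}`, basic `{K, R, H}`, polar uncharged
#' `{S, T, N, Q, C, Y, G}`, nonpolar `{A, V, L, I, M, F, W, P}`. The
#' membership is a documented convention, overridable wherever a groups
#' argument is accepted.
#'
#' @return Named list of character vectors.
#' @export
default_aa_groups <- function() {
  list(acidic = c("D", "E"),
       basic = c("K", "R", "H"),
       polar = c("S", "T", "N", "Q", "C", "Y", "G"),
       nonpolar = c("A", "V", "L", "I", "M", "F", "W", "P"))
}

GAP_CHARS <- c("-", ".", "~")

CONS_CLASSES <- c("fully_conserved", "group_conserved", "not_conserved",
                  "gap_majority")

#' Classify alignment columns by conservation
#'
#' For every alignment column holding a non-gap residue of the reference
#' sequence, the column is `fully_conserved` when all non-gap symbols are
#' identical, `group_conserved` when they all fall in one
#' charge/polarity group, `gap_majority` when more than half the rows are
#' gaps, and `not_conserved` otherwise (tested in that order). The
#' profile is indexed by reference residue number.
#'
#' @param aln an `msa` from [read_alignment()].
#' @param reference_id identifier of the reference row.
#' @param groups amino-acid partition, see [default_aa_groups()].
#' @param ref_start author residue number of the reference sequence's
#'   first residue.
#' @return Object of class `conservation_profile`: data.frame with
#'   columns `resseq`, `ref_aa`, `class`, plus attributes `reference` and
#'   `groups`.
#' @export
classify_columns <- function(aln, reference_id,
                             groups = default_aa_groups(),
                             ref_start = 1) {
  ri <- match(reference_id, aln$ids)
  if (is.na(ri))
    stop("reference '", reference_id, "' not found in alignment")
  rows <- do.call(rbind, strsplit(toupper(aln$seqs), ""))
  group_of <- character(0)
  for (g in names(groups)) group_of[groups[[g]]] <- g
  ref <- rows[ri, ]
  ref_nogap <- !(ref %in% GAP_CHARS)
  cols <- which(ref_nogap)
  cls <- character(length(cols))
  for (k in seq_along(cols)) {
    col <- rows[, cols[k]]
    gap <- col %in% GAP_CHARS
    sym <- col[!gap]
    cls[k] <- if (length(unique(sym)) == 1) "fully_conserved"
      else if (length(unique(stats::na.omit(group_of[sym]))) == 1 &&
                 !anyNA(group_of[sym])) "group_conserved"
      else if (mean(gap) > 0.5) "gap_majority"
      else "not_conserved"
  }
  out <- data.frame(resseq = ref_start + seq_along(cols) - 1,
                    ref_aa = ref[cols],
                    class = factor(cls, levels = CONS_CLASSES),
                    stringsAsFactors = FALSE)
  structure(out, class = c("conservation_profile", "data.frame"),
            reference = reference_id, groups = groups)
}

#' Conservation classes of a binding site's residues
#'
#' Looks up each site residue in a conservation profile and summarizes
#' the class counts; the counts always sum to the site's residue count.
#'
#' @param profile a `conservation_profile` from [classify_columns()].
#' @param site a [site_definition()].
#' @return List with `per_residue` (data.frame `resseq`, `class`) and
#'   `summary` (named integer vector over the four classes).
#' @export
site_conservation <- function(profile, site) {
  idx <- match(site$residues$resseq, profile$resseq)
  if (anyNA(idx))
    stop("site residue(s) outside conservation profile: ",
         paste(site$residues$resseq[is.na(idx)], collapse = ", "))
  per <- data.frame(resseq = site$residues$resseq,
                    class = profile$class[idx])
  list(per_residue = per, summary = table(per$class))
}
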