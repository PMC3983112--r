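# Nonbonded parameter assignment. The bundled table is a reduced,
# documented set: per-element vdW radii (C 1.7, N 1.55, O 1.52, S 1.8,
# H 1.2 A), side-chain formal charges localized on the terminal polar
# atoms (Asp/Glu carboxylate oxygens -0.5 each, Lys NZ +1, Arg NH1/NH2
# +0.5 each) and generic per-element Lennard-Jones parameters. It is a
# plain TSV config so users can substitute full force-field values.

#' Read a nonbonded parameter table
#'
#' The table is tab-separated with header
#' `residue  atom  radius  charge  epsilon  rmin_half`. Rows with
#' `residue = "*"` are element-level fallbacks keyed on the `atom` column
#' holding an element symbol. `radius` is the van der Waals radius
#' (Angstrom), `charge` the partial charge (e), `epsilon` the
#' Lennard-Jones well depth (kcal/mol, >= 0) and `rmin_half` half the LJ
#' minimum-energy distance (Angstrom, > 0).
#'
#' @param path path to the TSV; defaults to the bundled reduced table.
#' @return data.frame of parameter rows.
#' @export
read_param_table <- function(path = default_param_path()) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("residue", "atom", "radius", "charge", "epsilon", "rmin_half")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0)
    stop("parameter table missing columns: ", paste(miss, collapse = ", "))
  if (any(tab$radius <= 0) || any(tab$rmin_half <= 0) ||
      any(tab$epsilon < 0))
    stop("parameter table has non-positive radius/rmin_half or negative epsilon")
  tab
}

#' @rdname read_param_table
#' @export
default_param_path <- function() {
  system.file("extdata", "nonbonded_params.tsv", package = "peptscan",
              mustWork = TRUE)
}

#' Assign nonbonded parameters to every atom
#'
#' Atoms are matched by (residue name, atom name) first; unmatched atoms
#' fall back to their element's generic row when `element_fallback` is
#' enabled. After success no atom has a missing radius, charge or LJ
#' parameter. Fallback usage is recorded per atom in the
#' `"param_fallback"` attribute and summarized in a message.
#'
#' @param sys a `molsys`.
#' @param table parameter table from [read_param_table()].
#' @param element_fallback allow element-level fallback rows?
#' @param quiet suppress the fallback summary message.
#' @return The `molsys` with parameter columns filled.
#' @export
assign_parameters <- function(sys, table = read_param_table(),
                              element_fallback = TRUE, quiet = FALSE) {
  a <- sys$atom
  spec <- table[table$residue != "*", , drop = FALSE]
  fall <- table[table$residue == "*", , drop = FALSE]
  i_spec <- match(paste(a$resname, a$name), paste(spec$residue, spec$atom))
  i_fall <- match(toupper(a$elem), toupper(fall$atom))
  use_fall <- is.na(i_spec) & !is.na(i_fall) & element_fallback
  unmatched <- is.na(i_spec) & !use_fall
  if (any(unmatched)) {
    who <- with(a[unmatched, , drop = FALSE],
                paste0(resname, resseq, ":", name))
    stop("no parameters for atoms: ",
         paste(utils::head(unique(who), 10), collapse = ", "),
         if (sum(unmatched) > 10) " ..." else "")
  }
  src <- rbind(spec, fall)
  row <- ifelse(use_fall, nrow(spec) + i_fall, i_spec)
  for (p in c("radius", "charge", "epsilon", "rmin_half"))
    sys$atom[[p]] <- src[[p]][row]
  attr(sys, "param_fallback") <- which(use_fall)
  if (!quiet && any(use_fall))
    message(sum(use_fall), " atom(s) parameterized by element fallback")
  sys
}

# error unless every atom involved has parameters
check_parameterized <- function(sys, idx = seq_len(n_atoms(sys))) {
  if (anyNA(sys$atom$radius[idx]) || anyNA(sys$atom$charge[idx]) ||
      anyNA(sys$atom$epsilon[idx]) || anyNA(sys$atom$rmin_half[idx]))
    stop("atoms without assigned nonbonded parameters; ",
         "run assign_parameters() first")
  invisible(TRUE)
}
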