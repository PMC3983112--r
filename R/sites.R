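# Binding-site definitions and the packaged CRM1/Snurportin reference
# site list.

#' Define a binding site
#'
#' A site is a non-empty set of receptor residues on one chain, in author
#' numbering, with optional per-residue annotation flags:
#' `predicted_interfacial` (externally predicted interfacial residue,
#' e.g. by a structure-based predictor), `salt_bridge` (residue observed
#' to form a salt bridge with the ligand), `fully_conserved` (invariant
#' column in a reference alignment) and `snurportin` (residue belongs to
#' the cargo rather than the exportin). Flags may be `NA` when unknown.
#'
#' @param site_id integer site identifier.
#' @param chain chain identifier the residues live on.
#' @param resseq integer vector of author residue numbers (unique).
#' @param resname 3-letter residue names, recycled if length 1.
#' @param predicted_interfacial,salt_bridge,fully_conserved,snurportin
#'   logical per-residue flags.
#' @param position_note free-text description of the site's location.
#' @return An object of class `site_def`.
#' @export
site_definition <- function(site_id, chain, resseq, resname = "UNK",
                            predicted_interfacial = FALSE,
                            salt_bridge = FALSE,
                            fully_conserved = NA,
                            snurportin = FALSE,
                            position_note = "") {
  n <- length(resseq)
  if (n == 0) stop("a site needs at least one residue")
  if (anyDuplicated(resseq)) stop("duplicate residue numbers in site")
  residues <- data.frame(
    resseq = as.integer(resseq),
    resname = rep_len(resname, n),
    predicted_interfacial = rep_len(predicted_interfacial, n),
    salt_bridge = rep_len(salt_bridge, n),
    fully_conserved = rep_len(fully_conserved, n),
    snurportin = rep_len(snurportin, n),
    stringsAsFactors = FALSE)
  structure(list(site_id = as.integer(site_id), chain = chain,
                 residues = residues, position_note = position_note),
            class = "site_def")
}

#' @export
print.site_def <- function(x, ...) {
  cat(sprintf("site %d (chain %s): %s\n", x$site_id, x$chain,
              paste0(aa_three_to_one(x$residues$resname), x$residues$resseq,
                     collapse = " ")))
  if (nzchar(x$position_note)) cat("  ", x$position_note, "\n")
  invisible(x)
}

AA_THREE <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
              Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
              L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
              S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

#' Convert between one- and three-letter amino-acid codes
#' @param x character vector of codes.
#' @return Converted codes (`"UNK"`/`"X"` for unknowns).
#' @export
aa_one_to_three <- function(x) {
  out <- AA_THREE[toupper(x)]
  out[is.na(out)] <- "UNK"
  unname(out)
}

#' @rdname aa_one_to_three
#' @export
aa_three_to_one <- function(x) {
  m <- names(AA_THREE)[match(toupper(x), AA_THREE)]
  m[is.na(m)] <- "X"
  m
}

# Packaged reference site list. Each residue token is the one-letter code
# plus author number, with suffix markers: "i" = predicted interfacial,
# "b" = salt bridge, "s" = cargo (Snurportin) residue.
REFERENCE_SITES <- list(
  list(1, "A", "K112.b T113 S115.i T118.i E121.ib K122.i",
       "Far side away from the Snurportin, on convex side"),
  list(2, "A", "Y240 E243.b",
       "Far side away from the Snurportin, on convex side"),
  list(3, "A", "K253.ib N256.i T285 L289 M292 Q293",
       "Far side away from the Snurportin, on convex side"),
  list(4, "A", "K446.ib D447.i K455.b",
       "Next to the RanGTP, concave side"),
  list(5, "A", "T477.i Q481.i N485 R515.i K522.i D523.i",
       "Next to the Snurportin-NES binding site, on convex side"),
  list(6, "A", "R556.b Q593 K594 R596.b R597.b",
       "Near Snurportin, on the concave side"),
  list(7, "A", "N675 V676.i D677.b K680 D681 P682 E726.b",
       "Immediately next to Snurportin on convex side"),
  list(8, "A", "E954.ib E955.ib K995.i E1047.ib",
       "Far side away from Snurportin"),
  list(9, "A", "D1007.b K1012 E1013",
       paste("Next to RanGTP, concave side, away from Snurportin;",
             "blocked by helix H20B in absence of RanGTP")),
  list(10, "S", "R55.ibs K92.bs",
       "Side of Snurportin near convex side"),
  list(11, "S", "E42.ibs R46.is D110.bs V111.s P112.s S113.s",
       "Far edge of Snurportin"))

#' Reference binding-site fixture
#'
#' The packaged list of 11 reference binding sites for the
#' exportin--cargo complex: sites 1--9 on the exportin (42 residues in
#' total) and sites 10--11 on the Snurportin cargo (8 residues), with
#' per-residue annotation flags for externally predicted interfacial
#' residues (21 across all sites) and salt-bridge formation (19, at a
#' 3.2 Angstrom cutoff). Full-conservation flags are not populated in
#' this fixture (`NA`); conservation is recomputed from an alignment via
#' [classify_columns()] instead.
#'
#' @return List of 11 [site_definition()] objects.
#' @export
reference_sites <- function() {
  lapply(REFERENCE_SITES, function(s) {
    tok <- strsplit(s[[3]], " ", fixed = TRUE)[[1]]
    body <- sub("\\..*$", "", tok)
    mark <- ifelse(grepl(".", tok, fixed = TRUE), sub("^.*\\.", "", tok), "")
    aa <- substr(body, 1, 1)
    num <- as.integer(substring(body, 2))
    site_definition(
      site_id = s[[1]], chain = s[[2]], resseq = num,
      resname = aa_one_to_three(aa),
      predicted_interfacial = grepl("i", mark),
      salt_bridge = grepl("b", mark),
      fully_conserved = NA,
      snurportin = grepl("s", mark),
      position_note = s[[4]])
  })
}

# site residues as "chain:resseq" keys
site_res_keys <- function(site) res_key(site$chain, site$residues$resseq)
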