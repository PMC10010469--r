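# Packaged encodings of the reference summary tables: the 6x6
# substitution-pattern matrix, the functional-site substitution instances
# (NPA motifs and Ar/R selectivity filter) and the channel-facing
# substitutions, plus helpers to expand them back into variant records.

#' Reference substitution-pattern counts
#'
#' The 6x6 matrix of missense substitution counts across the six amino-acid
#' groups over all 13 human AQP homologs (rows = from-group, columns =
#' to-group). Marginals are derived from the cells, not stored.
#'
#' @return A `substitution_matrix` with grand total 2978.
#' @export
aqp_substitution_counts <- function() {
  m <- matrix(c(
    427, 268, 242,  26,  73,  50,
    188, 457,  55,  18,  79,  60,
    116,  30, 182, 120,  62,  28,
     38,  10,  70,   0,   0,  15,
     78,  70,  32,   8,   8,   0,
     80,  57,  27,   4,   0,   0
  ), nrow = 6, byrow = TRUE,
  dimnames = list(from = AA_GROUPS, to = AA_GROUPS))
  storage.mode(m) <- "integer"
  class(m) <- c("substitution_matrix", class(m))
  m
}

site_row <- function(site, gn, ref_aa, alt_aa, homologs) {
  data.frame(site = site, gn = gn, ref_aa = ref_aa, alt_aa = alt_aa,
             homolog = homologs, stringsAsFactors = FALSE)
}

#' Published substitutions in the functionally important sites
#'
#' One row per (generic position, reference amino acid, alternate amino
#' acid, homolog) instance of a missense substitution in the LB-NPA motif,
#' the LE-NPA motif or the aromatic/arginine selectivity filter. The
#' wild-type residue letters follow the reference listing, including homolog
#' wild types deviating from Asn-Pro-Ala; site membership is positional.
#'
#' @return Data frame with columns `site` (`NPA_LB`, `NPA_LE`, `ARR_SF`),
#'   `gn`, `ref_aa`, `alt_aa`, `homolog`. 33 LB-NPA, 23 LE-NPA and 54 Ar/R
#'   instances.
#' @export
aqp_functional_site_table <- function() {
  L <- list(
    # LB-NPA motif
    site_row("NPA_LB", "LB.50", "N", "T", c("AQP2", "AQP5", "AQP6", "AQP11")),
    site_row("NPA_LB", "LB.50", "N", "S", c("AQP2", "AQP8", "AQP9", "AQP11")),
    site_row("NPA_LB", "LB.50", "N", "D", "AQP9"),
    site_row("NPA_LB", "LB.50", "N", "I", c("AQP9", "AQP11")),
    site_row("NPA_LB", "LB.50", "N", "K", "AQP10"),
    site_row("NPA_LB", "LB.51", "P", "T", c("AQP0", "AQP12")),
    site_row("NPA_LB", "LB.51", "P", "Q", c("AQP1", "AQP11")),
    site_row("NPA_LB", "LB.51", "P", "L", c("AQP1", "AQP10", "AQP11")),
    site_row("NPA_LB", "LB.51", "P", "A", "AQP1"),
    site_row("NPA_LB", "LB.51", "P", "S", c("AQP1", "AQP3")),
    site_row("NPA_LB", "LB.51", "P", "H", "AQP5"),
    site_row("NPA_LB", "LB.51", "P", "R", "AQP12"),
    site_row("NPA_LB", "LB.50", "A", "T", "AQP7"),
    site_row("NPA_LB", "LB.52", "A", "V", c("AQP3", "AQP8", "AQP10")),
    site_row("NPA_LB", "LB.52", "A", "S", "AQP5"),
    site_row("NPA_LB", "LB.52", "A", "T", "AQP6"),
    site_row("NPA_LB", "LB.52", "A", "D", "AQP6"),
    site_row("NPA_LB", "LB.52", "A", "G", "AQP7"),
    site_row("NPA_LB", "LB.52", "T", "A", "AQP12"),
    # LE-NPA motif
    site_row("NPA_LE", "LE.50", "N", "T", c("AQP0", "AQP7")),
    site_row("NPA_LE", "LE.50", "N", "K", c("AQP1", "AQP9")),
    site_row("NPA_LE", "LE.50", "N", "S", c("AQP2", "AQP7", "AQP10")),
    site_row("NPA_LE", "LE.51", "P", "S", c("AQP0", "AQP4")),
    site_row("NPA_LE", "LE.51", "P", "A", c("AQP2", "AQP5", "AQP10")),
    site_row("NPA_LE", "LE.51", "P", "R", c("AQP5", "AQP9")),
    site_row("NPA_LE", "LE.51", "P", "L", c("AQP5", "AQP7")),
    site_row("NPA_LE", "LE.52", "A", "T", c("AQP4", "AQP8", "AQP9")),
    site_row("NPA_LE", "LE.52", "A", "V", c("AQP5", "AQP10")),
    site_row("NPA_LE", "LE.52", "A", "D", "AQP8"),
    site_row("NPA_LE", "LE.52", "S", "F", "AQP7"),
    # Ar/R selectivity filter
    site_row("ARR_SF", "2.49", "F", "C", "AQP0"),
    site_row("ARR_SF", "2.49", "F", "L", "AQP1"),
    site_row("ARR_SF", "2.49", "F", "I", "AQP2"),
    site_row("ARR_SF", "2.49", "H", "Q", "AQP8"),
    site_row("ARR_SF", "2.49", "H", "Y", "AQP8"),
    site_row("ARR_SF", "2.49", "Y", "C", "AQP11"),
    site_row("ARR_SF", "LE.47", "A", "T", c("AQP0", "AQP4")),
    site_row("ARR_SF", "LE.47", "C", "F", "AQP1"),
    site_row("ARR_SF", "LE.47", "C", "W", c("AQP2", "AQP5", "AQP6", "AQP9")),
    site_row("ARR_SF", "LE.47", "C", "Y", "AQP2"),
    site_row("ARR_SF", "LE.47", "Y", "C", "AQP3"),
    site_row("ARR_SF", "LE.47", "I", "T", "AQP10"),
    site_row("ARR_SF", "LE.53", "R", "L", c("AQP0", "AQP4", "AQP7")),
    site_row("ARR_SF", "LE.53", "R", "H",
             c("AQP0", "AQP2", "AQP5", "AQP6", "AQP8")),
    site_row("ARR_SF", "LE.53", "R", "C",
             c("AQP0", "AQP2", "AQP5", "AQP6", "AQP8")),
    site_row("ARR_SF", "LE.53", "R", "G", "AQP1"),
    site_row("ARR_SF", "LE.53", "R", "W", c("AQP1", "AQP3", "AQP7", "AQP10")),
    site_row("ARR_SF", "LE.53", "R", "Q",
             c("AQP1", "AQP3", "AQP4", "AQP7", "AQP9", "AQP10")),
    site_row("ARR_SF", "LE.53", "R", "S", "AQP6"),
    site_row("ARR_SF", "LE.53", "R", "P", c("AQP8", "AQP9")),
    site_row("ARR_SF", "5.57", "H", "Q", "AQP2"),
    site_row("ARR_SF", "5.57", "H", "R", c("AQP4", "AQP5")),
    site_row("ARR_SF", "5.57", "H", "Y", "AQP4"),
    site_row("ARR_SF", "5.57", "G", "R", c("AQP7", "AQP10")),
    site_row("ARR_SF", "5.57", "G", "A", "AQP7"),
    site_row("ARR_SF", "5.57", "I", "M", "AQP8"),
    site_row("ARR_SF", "5.57", "A", "V", "AQP9"),
    site_row("ARR_SF", "5.57", "A", "T", "AQP12"),
    site_row("ARR_SF", "5.57", "V", "I", "AQP11")
  )
  out <- do.call(rbind, L)
  rownames(out) <- NULL
  out
}

#' Published substitutions of channel-facing residues
#'
#' One row per (segment, generic position, reference amino acid, alternate
#' amino acid, homolog) instance of the listed non-conservative missense
#' substitutions at channel-facing positions.
#'
#' @return Data frame with columns `segment`, `gn`, `ref_aa`, `alt_aa`,
#'   `homolog`.
#' @export
aqp_channel_facing_table <- function() {
  row_ <- function(segment, gn, ref, alt, homologs) {
    data.frame(segment = segment, gn = gn, ref_aa = ref, alt_aa = alt,
               homolog = homologs, stringsAsFactors = FALSE)
  }
  L <- list(
    row_("TM1", "1.53", "R", "W", "AQP12"),
    row_("TM1", "1.57", "F", "S", "AQP5"),
    row_("TM1", "1.57", "L", "S", "AQP9"),
    row_("TM1", "1.57", "L", "P", "AQP10"),
    row_("TM1", "1.61", "G", "R", c("AQP2", "AQP8")),
    row_("TM1", "1.61", "G", "V", c("AQP7", "AQP9")),
    row_("TM1", "1.61", "G", "E", "AQP9"),
    row_("TM1", "1.61", "T", "I", "AQP11"),
    row_("TM1", "1.65", "A", "D", "AQP1"),
    row_("TM1", "1.65", "V", "G", "AQP9"),
    row_("TM1", "1.65", "Q", "R", "AQP11"),
    row_("TM1", "1.65", "Y", "N", "AQP12"),
    row_("TM1", "1.65", "Y", "H", "AQP12"),
    row_("TM1", "1.68", "M", "T", "AQP7"),
    row_("TM1", "1.68", "M", "K", "AQP7"),
    row_("TM1", "1.69", "K", "E", "AQP1"),
    row_("TM1", "1.69", "I", "T", "AQP9"),
    row_("TM2", "2.45", "I", "T", c("AQP2", "AQP6")),
    row_("TM2", "2.45", "I", "S", "AQP5"),
    row_("TM2", "2.45", "P", "L", "AQP8"),
    row_("TM2", "2.49", "Y", "C", "AQP11"),
    row_("TM2", "2.53", "L", "P", c("AQP0", "AQP11")),
    row_("TM2", "2.53", "I", "T", c("AQP1", "AQP4")),
    row_("TM2", "2.53", "I", "S", c("AQP4", "AQP5")),
    row_("TM2", "2.53", "T", "I", "AQP6"),
    row_("TM2", "2.57", "V", "G", "AQP7"),
    row_("TM2", "2.57", "I", "S", "AQP9"),
    row_("TM2", "2.57", "I", "N", "AQP10"),
    row_("TM2", "2.61", "W", "R", "AQP6"),
    row_("TM2", "2.61", "G", "V", "AQP7"),
    row_("TM2", "2.61", "G", "D", "AQP7"),
    row_("TM2", "2.61", "G", "R", "AQP8"),
    row_("TM2", "2.64", "S", "R", "AQP2"),
    row_("TM2", "2.65", "G", "R", "AQP2"),
    row_("LB", "LB.53", "V", "D", "AQP0"),
    row_("LB", "LB.57", "C", "Y", "AQP2"),
    row_("LB", "LB.57", "M", "T", "AQP10"),
    row_("TM3", "3.42", "R", "C", c("AQP0", "AQP6")),
    row_("TM3", "3.42", "R", "G", "AQP0"),
    row_("TM3", "3.42", "R", "W", "AQP5"),
    row_("TM3", "3.42", "K", "N", c("AQP3", "AQP4")),
    row_("TM3", "3.42", "K", "T", "AQP9"),
    row_("TM3", "3.42", "T", "M", "AQP11"),
    row_("TM4", "4.57", "L", "P", "AQP6"),
    row_("TM4", "4.61", "V", "D", "AQP9"),
    row_("TM4", "4.61", "L", "P", "AQP12"),
    row_("TM4", "4.65", "T", "I", "AQP2"),
    row_("TM4", "4.65", "T", "M", "AQP7"),
    row_("TM4", "4.65", "R", "W", "AQP12"),
    row_("TM4", "4.65", "R", "Q", "AQP12"),
    row_("TM4", "4.66", "D", "G", "AQP6"),
    row_("TM5", "5.45", "I", "T", "AQP4"),
    row_("TM5", "5.45", "I", "K", "AQP4"),
    row_("TM5", "5.49", "I", "T", c("AQP2", "AQP4", "AQP6", "AQP7", "AQP9")),
    row_("TM5", "5.49", "I", "N", "AQP9"),
    row_("TM5", "5.49", "I", "S", "AQP9"),
    row_("TM5", "5.53", "V", "D", c("AQP8", "AQP12")),
    row_("TM5", "5.57", "G", "R", "AQP10"),
    row_("TM5", "5.61", "M", "T", "AQP0"),
    row_("TM5", "5.61", "I", "T", "AQP1"),
    row_("TM5", "5.61", "G", "V", c("AQP7", "AQP11")),
    row_("TM5", "5.61", "G", "R", "AQP12"),
    row_("TM5", "5.65", "G", "R", "AQP2"),
    row_("TM5", "5.65", "G", "D", "AQP4"),
    row_("TM5", "5.65", "G", "V", "AQP5"),
    row_("TM6", "6.62", "F", "S", "AQP5"),
    row_("TM6", "6.62", "R", "S", "AQP8")
  )
  out <- do.call(rbind, L)
  rownames(out) <- NULL
  out
}

#' Synthetic per-homolog segment maps for fixture expansion
#'
#' Instance counting at functional sites depends only on generic positions,
#' so any internally consistent segment map per homolog suffices to expand
#' the reference site listings into variant records. This returns a named
#' list of synthetic maps, one per homolog, each a copy of the packaged AQP4
#' map with the homolog name swapped in; they are stand-ins, not real
#' per-homolog anchor assignments.
#'
#' @param homologs Homolog names.
#' @return Named list of `segment_map` objects.
#' @export
synthetic_segment_maps <- function(homologs = AQP_HOMOLOGS) {
  base <- aqp4_segment_map()
  out <- lapply(homologs, function(h) {
    m <- base
    m$homolog <- h
    m
  })
  stats::setNames(out, homologs)
}

#' Expand a site-listing fixture into variant records
#'
#' Turns rows of a reference site listing (generic position, reference and
#' alternate amino acid, homolog) into raw variant records: the residue
#' index is recovered through each homolog's segment map, a synthetic rsID
#' is attached and a consistent single-nucleotide codon pair is chosen where
#' one exists (otherwise codons are left blank).
#'
#' @param listing Data frame with columns `gn`, `ref_aa`, `alt_aa`,
#'   `homolog` (e.g. [aqp_functional_site_table()]).
#' @param maps Named list of `segment_map`s covering every homolog in
#'   `listing` (default [synthetic_segment_maps()]).
#' @return Raw-record data frame acceptable to [apply_snp_filters()].
#' @export
expand_site_listing <- function(listing, maps = synthetic_segment_maps()) {
  pairs <- single_nt_codon_pairs()
  n <- nrow(listing)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    r <- listing[i, ]
    idx <- residue_of(maps[[r$homolog]], r$gn)
    cand <- pairs[pairs$key == paste0(r$ref_aa, ">", r$alt_aa), , drop = FALSE]
    if (nrow(cand) > 0) {
      ref_codon <- cand$ref_codon[1]; alt_codon <- cand$alt_codon[1]
      pos <- cand$pos[1]
    } else {
      ref_codon <- NA_character_; alt_codon <- NA_character_; pos <- 1L
    }
    rows[[i]] <- data.frame(
      rsid = paste0("rs", 500000L + i), gene = r$homolog,
      ref_codon = ref_codon, alt_codon = alt_codon,
      codon_change_pos = as.integer(pos), residue_index = idx,
      ref_aa = r$ref_aa, alt_aa = r$alt_aa, deprecated = FALSE,
      disease = "", stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
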