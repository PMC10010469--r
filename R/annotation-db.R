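# The annotated variant database: joining variants with generic numbering
# and structural regions, CSV serialisation, summary statistics and
# conjunctive queries.

ANNOTATED_COLUMNS <- c("db_id", "rsid", "homolog", "residue_index", "ref_aa",
                       "alt_aa", "ref_codon", "alt_codon", "codon_change_pos",
                       "generic_number", "segment_or_loop", "functional_site",
                       "region", "ref_group", "alt_group", "conservative",
                       "codon_unverified", "disease")

#' Annotate validated variants with numbering, sites and regions
#'
#' Joins each validated variant with its generic number (or positional tag
#' `LOOP`/`NTERM`/`CTERM`), its segment or loop label, its functional-site
#' flag, its amino-acid groups and, when a region assignment is available
#' for the homolog, its structural region. Positions without a resolved
#' residue in the structure (or homologs without an assignment) are labelled
#' `UNMAPPED`, never dropped.
#'
#' @param variants Validated variant data frame from
#'   [apply_snp_filters()]`$variants`.
#' @param segment_maps Named list of `segment_map`s; every homolog present
#'   in `variants` must have one.
#' @param region_assignments Optional named list of `region_assignment`s by
#'   homolog (from [classify_regions()]); region labels are taken from the
#'   assignment's first chain.
#' @return Data frame of annotated entries with the documented column set
#'   (see [write_aqpsnp_csv()]).
#' @export
annotate_variants <- function(variants, segment_maps,
                              region_assignments = NULL) {
  missing <- setdiff(unique(variants$gene), names(segment_maps))
  if (length(missing) > 0) {
    stop("no segment map for homolog(s): ", paste(missing, collapse = ", "))
  }
  n <- nrow(variants)
  if (n == 0) {
    out <- data.frame(matrix(nrow = 0, ncol = length(ANNOTATED_COLUMNS)))
    names(out) <- ANNOTATED_COLUMNS
    return(out)
  }
  generic <- rep(NA_character_, n)
  seg_or_loop <- rep(NA_character_, n)
  for (h in unique(variants$gene)) {
    sel <- which(variants$gene == h)
    gnd <- generic_number(segment_maps[[h]], variants$residue_index[sel])
    generic[sel] <- ifelse(gnd$kind == "TM", gnd$gn, gnd$kind)
    seg_or_loop[sel] <- ifelse(gnd$kind == "TM", gnd$segment,
                               ifelse(gnd$kind == "LOOP", gnd$segment,
                                      gnd$kind))
  }
  site <- functional_site(ifelse(generic %in% c("LOOP", "NTERM", "CTERM"),
                                 NA_character_, generic))
  region <- rep("UNMAPPED", n)
  if (!is.null(region_assignments)) {
    for (h in intersect(unique(variants$gene), names(region_assignments))) {
      ra <- region_assignments[[h]]
      ra <- ra[ra$chain == ra$chain[1], , drop = FALSE]
      sel <- which(variants$gene == h)
      hit <- match(variants$residue_index[sel], ra$resno)
      region[sel[!is.na(hit)]] <- ra$region[hit[!is.na(hit)]]
    }
  }
  cu <- if (!is.null(variants$codon_unverified)) variants$codon_unverified else {
    is.na(variants$ref_codon) | is.na(variants$alt_codon)
  }
  out <- data.frame(
    db_id = variants$db_id, rsid = variants$rsid, homolog = variants$gene,
    residue_index = as.integer(variants$residue_index),
    ref_aa = variants$ref_aa, alt_aa = variants$alt_aa,
    ref_codon = variants$ref_codon, alt_codon = variants$alt_codon,
    codon_change_pos = as.integer(variants$codon_change_pos),
    generic_number = generic, segment_or_loop = seg_or_loop,
    functional_site = site, region = region,
    ref_group = as.character(aa_group(variants$ref_aa)),
    alt_group = as.character(aa_group(variants$alt_aa)),
    conservative = is_group_conservative(variants$ref_aa, variants$alt_aa),
    codon_unverified = cu, disease = variants$disease,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Write annotated entries to CSV
#'
#' RFC-4180 CSV (comma-separated, double-quote quoting, UTF-8) with the
#' fixed header `db_id, rsid, homolog, residue_index, ref_aa, alt_aa,
#' ref_codon, alt_codon, codon_change_pos, generic_number, segment_or_loop,
#' functional_site, region, ref_group, alt_group, conservative,
#' codon_unverified, disease`. Blank codon fields encode records whose
#' codons were absent from the source dump.
#'
#' @param entries Annotated entries from [annotate_variants()].
#' @param path Output file.
#' @export
write_aqpsnp_csv <- function(entries, path) {
  stopifnot(identical(names(entries), ANNOTATED_COLUMNS))
  out <- entries
  out$ref_codon[is.na(out$ref_codon)] <- ""
  out$alt_codon[is.na(out$alt_codon)] <- ""
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' Read annotated entries from CSV
#'
#' Inverse of [write_aqpsnp_csv()]; `read_aqpsnp_csv(write_aqpsnp_csv(x))`
#' is the identity. The header must match the documented column set exactly
#' and every row is validated (labels, amino acids, integer fields); a bad
#' row fails with its row number.
#'
#' @param path CSV file.
#' @return Annotated entry data frame.
#' @export
read_aqpsnp_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  if (!identical(names(df), ANNOTATED_COLUMNS)) {
    stop("unexpected header in ", path, ": expected columns ",
         paste(ANNOTATED_COLUMNS, collapse = ", "))
  }
  df$residue_index <- suppressWarnings(as.integer(df$residue_index))
  df$codon_change_pos <- suppressWarnings(as.integer(df$codon_change_pos))
  df$ref_codon[df$ref_codon == ""] <- NA_character_
  df$alt_codon[df$alt_codon == ""] <- NA_character_
  df$conservative <- df$conservative == "TRUE"
  df$codon_unverified <- df$codon_unverified == "TRUE"

  std_aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  tags <- c("LOOP", "NTERM", "CTERM")
  for (i in seq_len(nrow(df))) {
    r <- df[i, ]
    problem <- if (!r$region %in% c(REGION_LABELS, "UNMAPPED")) {
      paste0("invalid region label '", r$region, "'")
    } else if (!r$functional_site %in% c(names(FUNCTIONAL_SITES), "NONE")) {
      paste0("invalid functional_site '", r$functional_site, "'")
    } else if (!r$ref_group %in% AA_GROUPS || !r$alt_group %in% AA_GROUPS) {
      "invalid amino-acid group"
    } else if (!r$ref_aa %in% std_aa || !r$alt_aa %in% std_aa) {
      "invalid amino acid"
    } else if (is.na(r$residue_index) || r$residue_index < 1) {
      "invalid residue_index"
    } else if (!(r$generic_number %in% tags ||
                 grepl("^(1|2|3|4|5|6|LB|LE)\\.[0-9]+$", r$generic_number))) {
      paste0("invalid generic_number '", r$generic_number, "'")
    } else NULL
    if (!is.null(problem)) stop("row ", i, ": ", problem)
  }
  rownames(df) <- NULL
  df
}

#' Summary statistics of an annotated database
#'
#' Computes the aggregations shown on a statistics page: entry counts per
#' homolog, per-homolog counts in each structural region (entries without a
#' mapped structural position are tallied separately as `n_unmapped`), the
#' global 6x6 substitution-pattern matrix, functional-site instance counts
#' and the split of positions over TM segments, loops and termini.
#'
#' @param entries Annotated entries.
#' @return List of class `aqpsnp_statistics` with components `per_homolog`,
#'   `per_homolog_region`, `n_unmapped`, `substitution_matrix`,
#'   `functional_sites` and `position_classes`.
#' @export
aqpsnp_statistics <- function(entries) {
  homolog <- factor(entries$homolog,
                    levels = sort(unique(c(AQP_HOMOLOGS, entries$homolog))))
  mapped <- entries$region != "UNMAPPED"
  per_region <- table(homolog = homolog[mapped],
                      region = factor(entries$region[mapped],
                                      levels = REGION_LABELS))
  kind <- ifelse(entries$generic_number %in% c("LOOP", "NTERM", "CTERM"),
                 entries$generic_number, "TM")
  m <- if (nrow(entries) > 0) {
    build_substitution_matrix(entries$ref_aa, entries$alt_aa)
  } else {
    build_substitution_matrix(character(0), character(0))
  }
  structure(list(
    per_homolog = table(homolog),
    per_homolog_region = per_region,
    n_unmapped = sum(!mapped),
    substitution_matrix = m,
    functional_sites = table(factor(entries$functional_site,
                                    levels = c(names(FUNCTIONAL_SITES), "NONE"))),
    position_classes = table(factor(kind, levels = c("TM", "LOOP", "NTERM",
                                                     "CTERM")))
  ), class = "aqpsnp_statistics")
}

#' @export
print.aqpsnp_statistics <- function(x, ...) {
  cat("dbAQP-SNP statistics\n\nEntries per homolog:\n")
  print(x$per_homolog)
  cat("\nMapped entries per structural region (", x$n_unmapped,
      " not mapped):\n", sep = "")
  print(x$per_homolog_region)
  cat("\nFunctional-site instances:\n")
  print(x$functional_sites)
  cat("\nPosition classes:\n")
  print(x$position_classes)
  cat("\n")
  print(x$substitution_matrix)
  invisible(x)
}

#' Query an annotated database with conjunctive filters
#'
#' All supplied filters are combined with AND, mirroring an advanced-search
#' form: e.g. all entries of one homolog that lie at the helix-helix
#' interface and replace a charged residue with an aromatic one. Input
#' order is preserved.
#'
#' @param entries Annotated entries.
#' @param homolog,region,functional_site,ref_group,alt_group,rsid,db_id
#'   Optional exact-match filters; values are validated against their label
#'   sets and unknown values raise an error.
#' @param disease_contains Optional case-insensitive substring match on the
#'   disease text.
#' @return The matching subset of `entries`.
#' @export
query_aqpsnp <- function(entries, homolog = NULL, region = NULL,
                         functional_site = NULL, ref_group = NULL,
                         alt_group = NULL, rsid = NULL, db_id = NULL,
                         disease_contains = NULL) {
  check_value <- function(value, allowed, what) {
    if (!is.null(value) && !all(value %in% allowed)) {
      stop("unknown ", what, ": ", paste(setdiff(value, allowed), collapse = ", "))
    }
  }
  check_value(homolog, AQP_HOMOLOGS, "homolog")
  check_value(region, c(REGION_LABELS, "UNMAPPED"), "region")
  check_value(functional_site, c(names(FUNCTIONAL_SITES), "NONE"),
              "functional site")
  check_value(ref_group, AA_GROUPS, "amino-acid group")
  check_value(alt_group, AA_GROUPS, "amino-acid group")

  keep <- rep(TRUE, nrow(entries))
  if (!is.null(homolog)) keep <- keep & entries$homolog %in% homolog
  if (!is.null(region)) keep <- keep & entries$region %in% region
  if (!is.null(functional_site)) {
    keep <- keep & entries$functional_site %in% functional_site
  }
  if (!is.null(ref_group)) keep <- keep & entries$ref_group %in% ref_group
  if (!is.null(alt_group)) keep <- keep & entries$alt_group %in% alt_group
  if (!is.null(rsid)) keep <- keep & entries$rsid %in% rsid
  if (!is.null(db_id)) keep <- keep & entries$db_id %in% db_id
  if (!is.null(disease_contains)) {
    keep <- keep & grepl(tolower(disease_contains), tolower(entries$disease),
                         fixed = TRUE)
  }
  out <- entries[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
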