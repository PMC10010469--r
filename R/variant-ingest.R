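# Ingestion and filtering of dbSNP-style missense variant dumps.

RAW_SNP_FIELDS <- c("rsid", "gene", "ref_codon", "alt_codon",
                    "codon_change_pos", "residue_index",
                    "ref_aa", "alt_aa", "deprecated", "disease")

AQP_HOMOLOGS <- paste0("AQP", 0:12)

#' Translate a codon with the standard genetic code
#'
#' Thin, vectorised wrapper around the standard genetic code
#' ([Biostrings::GENETIC_CODE]) used to validate that the reference and
#' alternate codons of a variant record actually encode the reported
#' reference and alternate amino acids.
#'
#' @param codon Character vector of 3-letter codons over `{A, C, G, T}`
#'   (case-insensitive).
#' @return Character vector of 1-letter amino-acid codes, `"*"` for the
#'   three stop codons.
#' @examples
#' translate_codon("AAT")            # "N"
#' translate_codon(c("TGA", "ATG"))  # "*" "M"
#' @export
translate_codon <- function(codon) {
  codon <- toupper(as.character(codon))
  bad <- is.na(codon) | nchar(codon) != 3L | grepl("[^ACGT]", codon)
  if (any(bad)) {
    stop("invalid codon(s): ", paste(unique(codon[bad]), collapse = ", "),
         " (must be 3 characters over A/C/G/T)")
  }
  unname(Biostrings::GENETIC_CODE[codon])
}

#' Parse a dbSNP-style variant dump
#'
#' Reads a missense-variant dump in either JSON-lines form (one object per
#' line, field names as in the returned data frame) or CSV form (header row,
#' comma-separated). Malformed rows are not fatal: they are collected with
#' their line numbers and returned alongside the well-formed records.
#'
#' @param path Path to the dump file, or a character vector of lines when
#'   `text = TRUE`.
#' @param format `"jsonl"` or `"csv"`.
#' @param text If `TRUE`, `path` is taken to be the content itself.
#' @return A list with components
#'   \describe{
#'     \item{records}{data frame of raw SNP records, one row per well-formed
#'       input row, input order preserved, with columns `rsid`, `gene`,
#'       `ref_codon`, `alt_codon`, `codon_change_pos`, `residue_index`,
#'       `ref_aa`, `alt_aa`, `deprecated`, `disease`.}
#'     \item{errors}{data frame with columns `line` and `message`, one row
#'       per malformed input row.}
#'   }
#' @export
parse_snp_dump <- function(path, format = c("jsonl", "csv"), text = FALSE) {
  format <- match.arg(format)
  lines <- if (text) as.character(path) else {
    if (!file.exists(path)) stop("cannot read variant dump: ", path)
    readLines(path, warn = FALSE)
  }
  if (format == "jsonl") parse_dump_jsonl(lines) else parse_dump_csv(lines)
}

empty_raw_records <- function() {
  data.frame(rsid = character(), gene = character(),
             ref_codon = character(), alt_codon = character(),
             codon_change_pos = integer(), residue_index = integer(),
             ref_aa = character(), alt_aa = character(),
             deprecated = logical(), disease = character(),
             stringsAsFactors = FALSE)
}

parse_error_df <- function(line = integer(), message = character()) {
  data.frame(line = as.integer(line), message = as.character(message),
             stringsAsFactors = FALSE)
}

# Coerce one parsed row (named list) into the RawSnpRecord column types.
# Returns the coerced list or a character error message.
coerce_raw_row <- function(x) {
  required <- setdiff(RAW_SNP_FIELDS, c("ref_codon", "alt_codon", "disease"))
  missing <- setdiff(required, names(x))
  if (length(missing) > 0) {
    return(paste("missing field(s):", paste(missing, collapse = ", ")))
  }
  out <- list(
    rsid = as.character(x$rsid),
    gene = as.character(x$gene),
    ref_codon = if (is_blank(x$ref_codon)) NA_character_ else toupper(as.character(x$ref_codon)),
    alt_codon = if (is_blank(x$alt_codon)) NA_character_ else toupper(as.character(x$alt_codon)),
    codon_change_pos = suppressWarnings(as.integer(x$codon_change_pos)),
    residue_index = suppressWarnings(as.integer(x$residue_index)),
    ref_aa = toupper(as.character(x$ref_aa)),
    alt_aa = toupper(as.character(x$alt_aa)),
    deprecated = parse_flag(x$deprecated),
    disease = if (is_blank(x$disease)) "" else as.character(x$disease)
  )
  if (is.na(out$rsid) || !grepl("^rs[0-9]+$", out$rsid)) {
    return(paste0("bad rsid: '", out$rsid, "'"))
  }
  if (is.na(out$gene) || !nzchar(out$gene)) return("missing gene")
  if (is.na(out$codon_change_pos) || !out$codon_change_pos %in% 1:3) {
    return("codon_change_pos must be 1, 2 or 3")
  }
  if (is.na(out$residue_index) || out$residue_index < 1L) {
    return("residue_index must be a positive integer")
  }
  if (!nzchar(out$ref_aa) || nchar(out$ref_aa) != 1L) return("bad ref_aa")
  if (!nzchar(out$alt_aa) || nchar(out$alt_aa) != 1L) return("bad alt_aa")
  if (is.na(out$deprecated)) return("deprecated flag must be true/false")
  for (cf in c("ref_codon", "alt_codon")) {
    cod <- out[[cf]]
    if (!is.na(cod) && (nchar(cod) != 3L || grepl("[^ACGT]", cod))) {
      return(paste0("bad ", cf, ": '", cod, "'"))
    }
  }
  if (!is.na(out$ref_codon) && !is.na(out$alt_codon) &&
      out$ref_codon == out$alt_codon) {
    return("ref_codon and alt_codon are identical")
  }
  out
}

is_blank <- function(x) {
  is.null(x) || length(x) == 0 || is.na(x[1]) || !nzchar(as.character(x[1]))
}

parse_flag <- function(x) {
  if (is.null(x) || length(x) == 0) return(NA)
  if (is.logical(x)) return(x[1])
  v <- tolower(as.character(x[1]))
  if (v %in% c("true", "t", "1", "yes")) return(TRUE)
  if (v %in% c("false", "f", "0", "no")) return(FALSE)
  NA
}

parse_dump_jsonl <- function(lines) {
  keep <- nzchar(trimws(lines))
  rows <- vector("list", length(lines))
  errors <- parse_error_df()
  for (i in seq_along(lines)) {
    if (!keep[i]) next
    obj <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = TRUE),
                    error = function(e) conditionMessage(e))
    if (is.character(obj) && !is.list(obj)) {
      errors <- rbind(errors, parse_error_df(i, paste("bad JSON:", obj)))
      next
    }
    res <- coerce_raw_row(as.list(obj))
    if (is.character(res)) {
      errors <- rbind(errors, parse_error_df(i, res))
    } else {
      rows[[i]] <- res
    }
  }
  list(records = bind_raw_rows(rows), errors = errors)
}

parse_dump_csv <- function(lines) {
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(list(records = empty_raw_records(), errors = parse_error_df()))
  }
  header <- utils::read.csv(text = lines[1], header = FALSE,
                            stringsAsFactors = FALSE)
  header <- trimws(as.character(unlist(header)))
  rows <- vector("list", length(lines))
  errors <- parse_error_df()
  for (i in seq_along(lines)[-1]) {
    vals <- tryCatch(
      utils::read.csv(text = lines[i], header = FALSE,
                      colClasses = "character", stringsAsFactors = FALSE),
      error = function(e) conditionMessage(e))
    if (is.character(vals)) {
      errors <- rbind(errors, parse_error_df(i, paste("bad CSV row:", vals)))
      next
    }
    vals <- as.character(unlist(vals))
    if (length(vals) != length(header)) {
      errors <- rbind(errors, parse_error_df(
        i, sprintf("expected %d fields, found %d", length(header), length(vals))))
      next
    }
    res <- coerce_raw_row(stats::setNames(as.list(vals), header))
    if (is.character(res)) {
      errors <- rbind(errors, parse_error_df(i, res))
    } else {
      rows[[i]] <- res
    }
  }
  list(records = bind_raw_rows(rows), errors = errors)
}

bind_raw_rows <- function(rows) {
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) return(empty_raw_records())
  out <- do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}

#' Validate raw SNP records as missense variants
#'
#' Applies the missense-only validation rules to each raw record: deprecated
#' entries, synonymous changes (reference and alternate amino acid
#' identical), nonsense changes (stop gain), codon/amino-acid inconsistencies
#' and multi-nucleotide codon changes are all rejected with a categorised
#' reason. Records whose codon fields are absent are accepted with codon
#' validation skipped and flagged `codon_unverified`.
#'
#' @param records Data frame of raw records as returned by
#'   [parse_snp_dump()]`$records`.
#' @return The input data frame with two added columns: `rejection`
#'   (`NA` for accepted records, otherwise one of `"deprecated"`,
#'   `"synonymous"`, `"nonsense"`, `"codon-mismatch"`, `"multi-nucleotide"`,
#'   `"invalid"`) and `codon_unverified` (logical).
#' @export
validate_snps <- function(records) {
  n <- nrow(records)
  rejection <- rep(NA_character_, n)
  codon_unverified <- rep(FALSE, n)
  std_aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (i in seq_len(n)) {
    r <- records[i, ]
    if (!(r$ref_aa %in% std_aa) || !(r$alt_aa %in% c(std_aa, "*")) ||
        is.na(r$residue_index) || r$residue_index < 1L) {
      rejection[i] <- "invalid"
      next
    }
    if (isTRUE(r$deprecated)) { rejection[i] <- "deprecated"; next }
    if (r$alt_aa == "*")      { rejection[i] <- "nonsense";   next }
    if (r$ref_aa == r$alt_aa) { rejection[i] <- "synonymous"; next }
    if (is.na(r$ref_codon) || is.na(r$alt_codon)) {
      codon_unverified[i] <- TRUE
      next
    }
    diff_pos <- which(strsplit(r$ref_codon, "")[[1]] != strsplit(r$alt_codon, "")[[1]])
    if (length(diff_pos) != 1L) { rejection[i] <- "multi-nucleotide"; next }
    if (diff_pos != r$codon_change_pos ||
        translate_codon(r$ref_codon) != r$ref_aa ||
        translate_codon(r$alt_codon) != r$alt_aa) {
      rejection[i] <- "codon-mismatch"
      next
    }
  }
  records$rejection <- rejection
  records$codon_unverified <- codon_unverified
  records
}

#' Filter a raw variant dump down to validated missense records
#'
#' Reproduces the dump-curation protocol: duplicates (same rsID, gene,
#' residue index and alternate amino acid) are collapsed to their first
#' occurrence, then deprecated, synonymous, nonsense and otherwise invalid
#' entries are removed. Every kept record is assigned a unique database
#' identifier of the form `dbAQPSNP-<GENE>-<5-digit serial>` in kept order
#' (serial per gene).
#'
#' @param records Data frame of raw records ([parse_snp_dump()]`$records`).
#' @return A list with components
#'   \describe{
#'     \item{variants}{data frame of kept, validated records with an added
#'       `db_id` column (and `codon_unverified` flag); the `deprecated`
#'       column is dropped.}
#'     \item{report}{one-row data frame (class `filter_report`) with counts
#'       `n_input`, `n_duplicates_removed`, `n_deprecated_removed`,
#'       `n_synonymous_removed`, `n_nonsense_removed`, `n_invalid_removed`,
#'       `n_kept`. The counts always balance: kept plus removals equals
#'       input.}
#'   }
#' @export
apply_snp_filters <- function(records) {
  n_input <- nrow(records)
  key <- paste(records$rsid, records$gene, records$residue_index,
               records$alt_aa, sep = "\r")
  dup <- duplicated(key)
  n_dup <- sum(dup)
  records <- records[!dup, , drop = FALSE]

  records <- validate_snps(records)
  rej <- records$rejection
  n_deprecated <- sum(rej == "deprecated", na.rm = TRUE)
  n_synonymous <- sum(rej == "synonymous", na.rm = TRUE)
  n_nonsense <- sum(rej == "nonsense", na.rm = TRUE)
  n_invalid <- sum(rej %in% c("invalid", "codon-mismatch", "multi-nucleotide"))

  kept <- records[is.na(rej), , drop = FALSE]
  kept$rejection <- NULL
  kept$deprecated <- NULL
  if (nrow(kept) > 0) {
    serial <- stats::ave(seq_len(nrow(kept)), kept$gene, FUN = seq_along)
    kept$db_id <- sprintf("dbAQPSNP-%s-%05d", kept$gene, serial)
  } else {
    kept$db_id <- character(0)
  }
  rownames(kept) <- NULL

  report <- data.frame(
    n_input = n_input,
    n_duplicates_removed = n_dup,
    n_deprecated_removed = n_deprecated,
    n_synonymous_removed = n_synonymous,
    n_nonsense_removed = n_nonsense,
    n_invalid_removed = n_invalid,
    n_kept = nrow(kept)
  )
  class(report) <- c("filter_report", class(report))
  stopifnot(report$n_kept + n_dup + n_deprecated + n_synonymous +
              n_nonsense + n_invalid == n_input)
  list(variants = kept, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Missense variant filter report\n")
  cat(sprintf("  input records        %6d\n", x$n_input))
  cat(sprintf("  duplicates removed   %6d\n", x$n_duplicates_removed))
  cat(sprintf("  deprecated removed   %6d\n", x$n_deprecated_removed))
  cat(sprintf("  synonymous removed   %6d\n", x$n_synonymous_removed))
  cat(sprintf("  nonsense removed     %6d\n", x$n_nonsense_removed))
  cat(sprintf("  invalid removed      %6d\n", x$n_invalid_removed))
  cat(sprintf("  kept                 %6d\n", x$n_kept))
  invisible(x)
}
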