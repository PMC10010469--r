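# Six-group amino-acid classification and the substitution-pattern matrix.

#' @name aa_groups
#' @title The six amino-acid groups
#' @description
#' The 20 standard amino acids partition into six physicochemical groups used
#' throughout the package:
#' \describe{
#'   \item{SWP}{small and weakly polar — Gly, Ala, Cys, Ser, Thr. Highly
#'     group-conserved at helix-helix interfaces of membrane proteins.}
#'   \item{AH}{aliphatic hydrophobic — Leu, Ile, Val, Met.}
#'   \item{CHARGED}{basic and acidic — Asp, Glu, Lys, Arg, His.}
#'   \item{NP}{neutral polar — Asn, Gln.}
#'   \item{AROMATIC}{Phe, Trp, Tyr.}
#'   \item{PRO}{proline alone, a helix breaker kept separate.}
#' }
NULL

AA_GROUPS <- c("SWP", "AH", "CHARGED", "NP", "AROMATIC", "PRO")

AA_GROUP_MEMBERS <- list(
  SWP = c("G", "A", "C", "S", "T"),
  AH = c("L", "I", "V", "M"),
  CHARGED = c("D", "E", "K", "R", "H"),
  NP = c("N", "Q"),
  AROMATIC = c("F", "W", "Y"),
  PRO = "P"
)

.AA_TO_GROUP <- local({
  m <- unlist(AA_GROUP_MEMBERS)
  stats::setNames(rep(names(AA_GROUP_MEMBERS), lengths(AA_GROUP_MEMBERS)), m)
})

#' Classify amino acids into the six groups
#'
#' @param aa Character vector of 1-letter amino-acid codes (the 20 standard
#'   residues; selenocysteine `U` and pyrrolysine `O` are rejected).
#' @return Factor with levels `SWP`, `AH`, `CHARGED`, `NP`, `AROMATIC`,
#'   `PRO`.
#' @seealso [aa_groups] for group membership.
#' @examples
#' aa_group(c("G", "N", "P"))  # SWP NP PRO
#' @export
aa_group <- function(aa) {
  aa <- toupper(as.character(aa))
  g <- .AA_TO_GROUP[aa]
  if (anyNA(g)) {
    stop("unknown amino acid(s): ", paste(unique(aa[is.na(g)]), collapse = ", "))
  }
  factor(unname(g), levels = AA_GROUPS)
}

#' Is a substitution group-conservative?
#'
#' A substitution is conservative in the six-group sense when the reference
#' and alternate amino acids fall in the same group (e.g. Asp to Lys, both
#' CHARGED, is conservative; Glu to Gly is not).
#'
#' @param ref_aa,alt_aa 1-letter amino-acid codes (vectorised).
#' @return Logical vector.
#' @export
is_group_conservative <- function(ref_aa, alt_aa) {
  as.character(aa_group(ref_aa)) == as.character(aa_group(alt_aa))
}

#' Build the 6x6 substitution-pattern matrix
#'
#' Tallies amino-acid substitutions by group: cell `(i, j)` counts the
#' variants whose reference amino acid is in group `i` and alternate amino
#' acid in group `j`. The matrix is directional (rows = from, columns = to)
#' and is not symmetrised.
#'
#' @param ref_aa,alt_aa 1-letter amino-acid vectors of equal length, or a
#'   data frame with `ref_aa`/`alt_aa` columns passed as the first argument.
#' @return An integer matrix of class `substitution_matrix` with the six
#'   groups as dimnames.
#' @export
build_substitution_matrix <- function(ref_aa, alt_aa = NULL) {
  if (is.data.frame(ref_aa)) {
    alt_aa <- ref_aa$alt_aa
    ref_aa <- ref_aa$ref_aa
  }
  stopifnot(length(ref_aa) == length(alt_aa))
  if (length(ref_aa) > 0 && any(toupper(ref_aa) == toupper(alt_aa))) {
    stop("substitutions must change the amino acid (ref_aa == alt_aa found)")
  }
  tab <- table(from = aa_group(ref_aa), to = aa_group(alt_aa))
  m <- matrix(as.integer(tab), nrow = length(AA_GROUPS),
              dimnames = list(from = AA_GROUPS, to = AA_GROUPS))
  class(m) <- c("substitution_matrix", class(m))
  m
}

#' Marginal totals of a substitution matrix
#'
#' @param m A `substitution_matrix` (or any 6x6 count matrix with group
#'   dimnames).
#' @return List with `row_totals`, `col_totals` and `grand_total`.
#' @export
substitution_marginals <- function(m) {
  list(row_totals = rowSums(unclass(m)),
       col_totals = colSums(unclass(m)),
       grand_total = sum(m))
}

#' Lay out a substitution matrix as a bordered table
#'
#' Returns the matrix as a data frame in the layout of the reference
#' substitution-pattern table: one row per from-group, one column per
#' to-group, plus a `Total` row and column.
#'
#' @param m A `substitution_matrix`.
#' @return Data frame with a `Group` column, the six group columns and
#'   `Total` margins.
#' @export
substitution_table <- function(m) {
  mm <- unclass(m)
  marg <- substitution_marginals(m)
  body <- cbind(mm, Total = marg$row_totals)
  body <- rbind(body, Total = c(marg$col_totals, marg$grand_total))
  data.frame(Group = rownames(body), body, row.names = NULL,
             check.names = FALSE)
}

#' Write a substitution matrix to CSV
#'
#' @param m A `substitution_matrix`.
#' @param path Output file.
#' @export
write_substitution_matrix <- function(m, path) {
  utils::write.csv(substitution_table(m), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read a substitution matrix from the bordered CSV layout
#'
#' Inverse of [write_substitution_matrix()]: reads the 7x7 bordered table
#' and checks that the stored margins match the recomputed ones.
#'
#' @param path CSV file written by [write_substitution_matrix()].
#' @return A `substitution_matrix`.
#' @export
read_substitution_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  stopifnot(identical(df$Group, c(AA_GROUPS, "Total")))
  m <- as.matrix(df[seq_along(AA_GROUPS), AA_GROUPS])
  storage.mode(m) <- "integer"
  dimnames(m) <- list(from = AA_GROUPS, to = AA_GROUPS)
  class(m) <- c("substitution_matrix", class(m))
  marg <- substitution_marginals(m)
  if (!all(df$Total[seq_along(AA_GROUPS)] == marg$row_totals) ||
      !all(unlist(df[nrow(df), AA_GROUPS]) == marg$col_totals) ||
      df$Total[nrow(df)] != marg$grand_total) {
    stop("stored margins do not match recomputed margins in ", path)
  }
  m
}

#' @export
print.substitution_matrix <- function(x, ...) {
  cat("Substitution-pattern matrix (rows = from-group, columns = to-group)\n")
  print(substitution_table(x), row.names = FALSE)
  invisible(x)
}
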