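# Structure-based generic residue numbering for the aquaporin hour-glass
# fold, and flagging of the NPA-motif and Ar/R selectivity-filter positions.
#
# Each of the six transmembrane helices (TM1-TM6) and two half-helices
# (LB, LE) has a most-conserved anchor residue numbered 50; every other
# position in the segment is numbered relative to it, e.g. 3.47 is three
# residues before the TM3 anchor, LB.52 two after the LB anchor.

SEGMENT_ORDER <- c("TM1", "TM2", "LB", "TM3", "TM4", "TM5", "LE", "TM6")
SEGMENT_PREFIX <- c(TM1 = "1", TM2 = "2", TM3 = "3", TM4 = "4", TM5 = "5",
                    TM6 = "6", LB = "LB", LE = "LE")

FUNCTIONAL_SITES <- list(
  NPA_LB = c("LB.50", "LB.51", "LB.52"),
  NPA_LE = c("LE.50", "LE.51", "LE.52"),
  ARR_SF = c("2.49", "5.57", "LE.47", "LE.53")
)

#' Define a per-homolog segment map
#'
#' A segment map records, for one aquaporin homolog, the residue span and the
#' conserved anchor residue (generic position 50) of each of the eight
#' segments of the hour-glass fold, in primary-isoform 1-based numbering.
#' Segments must appear in the order TM1, TM2, LB, TM3, TM4, TM5, LE, TM6
#' along the sequence and must not overlap.
#'
#' @param homolog Homolog name, e.g. `"AQP4"`.
#' @param segments Data frame with columns `segment` (the eight labels),
#'   `start`, `end`, `anchor` (1-based residue indices, `start <= anchor <=
#'   end`).
#' @param sequence_length Length of the primary-isoform protein sequence.
#' @return Object of class `segment_map`.
#' @export
segment_map <- function(homolog, segments, sequence_length) {
  stopifnot(is.data.frame(segments),
            all(c("segment", "start", "end", "anchor") %in% names(segments)))
  segments <- segments[match(SEGMENT_ORDER, segments$segment), ]
  if (anyNA(segments$segment)) {
    stop("segment map must define all eight segments: ",
         paste(SEGMENT_ORDER, collapse = ", "))
  }
  for (col in c("start", "end", "anchor")) {
    segments[[col]] <- as.integer(segments[[col]])
  }
  sequence_length <- as.integer(sequence_length)
  with(segments, {
    if (any(start > anchor | anchor > end)) {
      stop("each segment needs start <= anchor <= end")
    }
    if (any(start < 1L) || any(end > sequence_length)) {
      stop("segment spans must lie within 1..sequence_length")
    }
    if (any(utils::head(end, -1) >= utils::tail(start, -1))) {
      stop("segments must be non-overlapping and ordered ",
           paste(SEGMENT_ORDER, collapse = ", "), " along the sequence")
    }
  })
  rownames(segments) <- segments$segment
  structure(list(homolog = as.character(homolog), segments = segments,
                 sequence_length = sequence_length),
            class = "segment_map")
}

#' Load a segment map from a YAML or JSON config file
#'
#' The config holds `homolog`, `sequence_length` and a `segments` mapping of
#' segment label to `[start, end, anchor]` (or an object with those keys).
#'
#' @param path Config file; format chosen by extension (`.yaml`/`.yml` or
#'   `.json`).
#' @return A validated `segment_map`.
#' @export
load_segment_map <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!all(c("homolog", "sequence_length", "segments") %in% names(cfg))) {
    stop("segment-map config needs fields homolog, sequence_length, segments")
  }
  seg <- cfg$segments
  rows <- lapply(names(seg), function(s) {
    v <- seg[[s]]
    if (is.list(v) && !is.null(v$start)) v <- c(v$start, v$end, v$anchor)
    v <- as.integer(unlist(v))
    if (length(v) != 3) stop("segment ", s, " needs [start, end, anchor]")
    data.frame(segment = s, start = v[1], end = v[2], anchor = v[3])
  })
  segment_map(cfg$homolog, do.call(rbind, rows), cfg$sequence_length)
}

#' Write a segment map to YAML
#'
#' @param map A `segment_map`.
#' @param path Output file.
#' @export
write_segment_map <- function(map, path) {
  seg <- lapply(seq_len(nrow(map$segments)), function(i) {
    as.list(map$segments[i, c("start", "end", "anchor")])
  })
  names(seg) <- map$segments$segment
  yaml::write_yaml(list(homolog = map$homolog,
                        sequence_length = map$sequence_length,
                        segments = seg), path)
  invisible(path)
}

#' @export
print.segment_map <- function(x, ...) {
  cat(sprintf("Segment map for %s (sequence length %d)\n",
              x$homolog, x$sequence_length))
  print(x$segments, row.names = FALSE)
  invisible(x)
}

#' The packaged AQP4 segment map
#'
#' Anchors follow the reference human AQP4 assignment (PDB 3GD8 numbering):
#' E44 (1.50), G78 (2.50), N97 (LB.50), Q122 (3.50), E163 (4.50),
#' G194 (5.50), N213 (LE.50) and P237 (6.50). The span boundaries are a
#' package fixture chosen to bracket the anchors with typical helix lengths;
#' they are not an authoritative secondary-structure assignment.
#'
#' @return A `segment_map` for AQP4.
#' @export
aqp4_segment_map <- function() {
  segment_map("AQP4", data.frame(
    segment = c("TM1", "TM2", "LB", "TM3", "TM4", "TM5", "LE", "TM6"),
    start   = c(34, 65, 94, 110, 150, 182, 209, 226),
    end     = c(58, 88, 104, 135, 173, 206, 220, 250),
    anchor  = c(44, 78, 97, 122, 163, 194, 213, 237)
  ), sequence_length = 323)
}

#' Generic number of residue positions
#'
#' Maps 1-based residue indices to generic numbers. Indices inside a segment
#' span get `"<prefix>.<offset>"` with offset `50 + (index - anchor)`;
#' indices before TM1 are tagged `NTERM`, after TM6 `CTERM`, and indices
#' between segments `LOOP` with the flanking segments recorded.
#'
#' @param map A `segment_map`.
#' @param residue_index Integer vector of residue indices in
#'   `1..sequence_length`.
#' @return Data frame with columns `residue_index`, `kind` (`"TM"`, `"LOOP"`,
#'   `"NTERM"`, `"CTERM"`), `segment` (segment label or, for loops,
#'   `"between(A,B)"`; `NA` for termini), `offset` and `gn` (the rendered
#'   generic number, `NA` off-segment).
#' @examples
#' generic_number(aqp4_segment_map(), c(97, 237))  # LB.50, 6.50
#' @export
generic_number <- function(map, residue_index) {
  stopifnot(inherits(map, "segment_map"))
  residue_index <- as.integer(residue_index)
  if (any(is.na(residue_index)) || any(residue_index < 1L) ||
      any(residue_index > map$sequence_length)) {
    stop("residue_index out of range 1..", map$sequence_length)
  }
  seg <- map$segments
  n <- length(residue_index)
  kind <- character(n); segment <- rep(NA_character_, n)
  offset <- rep(NA_integer_, n); gn <- rep(NA_character_, n)
  for (k in seq_len(n)) {
    i <- residue_index[k]
    hit <- which(seg$start <= i & i <= seg$end)
    if (length(hit) == 1) {
      s <- seg$segment[hit]
      kind[k] <- "TM"
      segment[k] <- s
      offset[k] <- 50L + (i - seg$anchor[hit])
      gn[k] <- paste0(SEGMENT_PREFIX[[s]], ".", offset[k])
    } else if (i < seg$start[1]) {
      kind[k] <- "NTERM"
    } else if (i > seg$end[nrow(seg)]) {
      kind[k] <- "CTERM"
    } else {
      kind[k] <- "LOOP"
      before <- max(which(seg$end < i))
      segment[k] <- sprintf("between(%s,%s)", seg$segment[before],
                            seg$segment[before + 1])
    }
  }
  data.frame(residue_index = residue_index, kind = kind, segment = segment,
             offset = offset, gn = gn, stringsAsFactors = FALSE)
}

parse_generic_number <- function(gn) {
  parts <- strsplit(as.character(gn), ".", fixed = TRUE)
  lapply(parts, function(p) {
    if (length(p) != 2) stop("malformed generic number: ", paste(p, collapse = "."))
    seg <- names(SEGMENT_PREFIX)[match(p[1], SEGMENT_PREFIX)]
    if (is.na(seg)) stop("unknown segment prefix in generic number: ", p[1])
    off <- suppressWarnings(as.integer(p[2]))
    if (is.na(off)) stop("malformed generic-number offset: ", p[2])
    list(segment = seg, offset = off)
  })
}

#' Residue index of a generic number
#'
#' Inverse of [generic_number()]: `residue_of(map, generic_number(map, i)$gn)
#' == i` for every in-segment index `i`.
#'
#' @param map A `segment_map`.
#' @param gn Character vector of generic numbers such as `"1.50"` or
#'   `"LB.52"`.
#' @return Integer vector of residue indices.
#' @export
residue_of <- function(map, gn) {
  stopifnot(inherits(map, "segment_map"))
  parsed <- parse_generic_number(gn)
  vapply(parsed, function(p) {
    row <- map$segments[p$segment, ]
    idx <- row$anchor + (p$offset - 50L)
    if (idx < row$start || idx > row$end) {
      stop("generic number ", SEGMENT_PREFIX[[p$segment]], ".", p$offset,
           " falls outside the ", p$segment, " span ",
           row$start, "-", row$end, " of ", map$homolog)
    }
    as.integer(idx)
  }, integer(1))
}

#' Functional site of a generic position
#'
#' Flags the two NPA motifs (generic positions 50-52 of the LB and LE
#' half-helices) and the four aromatic/arginine selectivity-filter positions
#' (2.49, 5.57, LE.47, LE.53). The flag depends only on the generic
#' position, never on the wild-type residue, so homologs whose wild type
#' deviates from Asn-Pro-Ala are handled positionally.
#'
#' @param gn Character vector of generic numbers (`NA` allowed: positions
#'   without a generic number are never functional sites).
#' @return Character vector over `"NPA_LB"`, `"NPA_LE"`, `"ARR_SF"`,
#'   `"NONE"`.
#' @export
functional_site <- function(gn) {
  out <- rep("NONE", length(gn))
  for (site in names(FUNCTIONAL_SITES)) {
    out[!is.na(gn) & gn %in% FUNCTIONAL_SITES[[site]]] <- site
  }
  out
}

#' Count variant instances per functional site
#'
#' Maps each variant to its generic position via the homolog's segment map,
#' flags the NPA and Ar/R selectivity-filter positions and tallies instances
#' (one per variant record) per site. The listing groups instances by
#' (generic position, reference amino acid, alternate amino acid) with the
#' homologs in which each substitution occurs.
#'
#' @param variants Data frame of validated variants with columns `gene`,
#'   `residue_index`, `ref_aa`, `alt_aa`.
#' @param maps Named list of `segment_map` objects, one per homolog present
#'   in `variants`.
#' @return List with
#'   \describe{
#'     \item{counts}{named integer vector over `NPA_LB`, `NPA_LE`, `ARR_SF`,
#'       `NONE`.}
#'     \item{listing}{data frame (`site`, `gn`, `ref_aa`, `alt_aa`, `n`,
#'       `homologs`) for the functional-site instances.}
#'   }
#' @export
functional_site_report <- function(variants, maps) {
  missing <- setdiff(unique(variants$gene), names(maps))
  if (length(missing) > 0) {
    stop("no segment map for homolog(s): ", paste(missing, collapse = ", "))
  }
  counts <- stats::setNames(integer(4), c(names(FUNCTIONAL_SITES), "NONE"))
  if (nrow(variants) == 0) {
    return(list(counts = counts,
                listing = data.frame(site = character(), gn = character(),
                                     ref_aa = character(), alt_aa = character(),
                                     n = integer(), homologs = character())))
  }
  gn <- character(nrow(variants))
  for (h in unique(variants$gene)) {
    sel <- variants$gene == h
    gn[sel] <- generic_number(maps[[h]], variants$residue_index[sel])$gn
  }
  site <- functional_site(gn)
  tab <- table(factor(site, levels = names(counts)))
  counts[] <- as.integer(tab)

  hit <- site != "NONE"
  listing <- if (any(hit)) {
    d <- data.frame(site = site[hit], gn = gn[hit],
                    ref_aa = variants$ref_aa[hit],
                    alt_aa = variants$alt_aa[hit],
                    gene = variants$gene[hit], stringsAsFactors = FALSE)
    agg <- stats::aggregate(gene ~ site + gn + ref_aa + alt_aa, data = d,
                            FUN = function(g) paste(sort(unique(g)), collapse = ","))
    n <- stats::aggregate(gene ~ site + gn + ref_aa + alt_aa, data = d, FUN = length)
    agg$n <- n$gene
    names(agg)[names(agg) == "gene"] <- "homologs"
    agg[order(agg$site, agg$gn, agg$ref_aa, agg$alt_aa),
        c("site", "gn", "ref_aa", "alt_aa", "n", "homologs")]
  } else {
    data.frame(site = character(), gn = character(), ref_aa = character(),
               alt_aa = character(), n = integer(), homologs = character())
  }
  rownames(listing) <- NULL
  list(counts = counts, listing = listing)
}
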