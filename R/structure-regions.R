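# Geometric classification of resolved residues of a tetrameric channel
# structure into six structural regions:
#   CHANNEL_FACING, HELIX_INTERFACE, MONOMER_INTERFACE, LIPID_FACING,
#   CYTOPLASMIC, EXTRACELLULAR.
#
# Distance rules (4 A, heavy atoms, strict <= with no tolerance):
#   helix-helix interface : a backbone atom of a helix residue within 4 A of
#                           any atom of a residue in a *different* helix of
#                           the same chain;
#   monomer interface     : any atom of a residue within 4 A of any atom of
#                           a different chain.

BACKBONE_ATOMS <- c("N", "CA", "C", "O")

REGION_LABELS <- c("CHANNEL_FACING", "HELIX_INTERFACE", "MONOMER_INTERFACE",
                   "LIPID_FACING", "CYTOPLASMIC", "EXTRACELLULAR")

#' Construct a structure model from an atom table
#'
#' The package's structure container is a plain atom data frame (one row per
#' protein heavy atom) wrapped in class `structure_model`. Most users will
#' obtain one from [read_structure()] or the synthetic generators.
#'
#' @param atoms Data frame with columns `chain`, `resno`, `resid` (3-letter
#'   residue name), `elety` (atom name), `x`, `y`, `z` (Angstrom).
#' @return A `structure_model`: the atom data frame with an added logical
#'   `backbone` column (atom name in N, CA, C, O).
#' @export
structure_model <- function(atoms) {
  need <- c("chain", "resno", "resid", "elety", "x", "y", "z")
  stopifnot(is.data.frame(atoms), all(need %in% names(atoms)))
  if (nrow(atoms) == 0) stop("empty structure: no atoms")
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    stop("non-finite coordinates in structure")
  }
  atoms$resno <- as.integer(atoms$resno)
  atoms$backbone <- atoms$elety %in% BACKBONE_ATOMS
  rownames(atoms) <- NULL
  class(atoms) <- c("structure_model", "data.frame")
  atoms
}

#' Read a protein structure from a PDB file
#'
#' Wraps [bio3d::read.pdb()] and applies the model rules used throughout the
#' package: only `ATOM` records are kept (waters and other heteroatoms are
#' dropped), hydrogens are removed, and alternate locations are resolved to
#' the highest-occupancy conformer (ties broken in favour of altloc `"A"`,
#' then file order).
#'
#' @param path Path to a PDB file.
#' @return A `structure_model`.
#' @export
read_structure <- function(path) {
  pdb <- bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0) stop("no ATOM records in ", path)
  elem <- at$elesy
  noel <- is.na(elem) | !nzchar(trimws(elem))
  elem[noel] <- substr(gsub("[0-9]", "", at$elety[noel]), 1, 1)
  at <- at[toupper(trimws(elem)) != "H", , drop = FALSE]

  # altloc: keep the highest-occupancy conformer per atom site
  alt <- at$alt
  alt[is.na(alt)] <- ""
  occ <- at$o
  occ[is.na(occ)] <- 1
  key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "\r")
  pref <- order(key, -occ, alt != "A", seq_len(nrow(at)))
  at <- at[pref, , drop = FALSE]
  at <- at[!duplicated(paste(at$chain, at$resno, at$insert, at$elety,
                             sep = "\r")), , drop = FALSE]
  at <- at[order(match(at$chain, unique(at$chain)), at$resno,
                 match(at$elety, c(BACKBONE_ATOMS, sort(unique(at$elety))))), ,
           drop = FALSE]

  structure_model(data.frame(chain = at$chain, resno = at$resno,
                             resid = at$resid, elety = at$elety,
                             x = at$x, y = at$y, z = at$z,
                             stringsAsFactors = FALSE))
}

#' Write a structure model to a PDB file
#'
#' @param model A `structure_model`.
#' @param path Output file.
#' @export
write_structure <- function(model, path) {
  n <- nrow(model)
  bio3d::write.pdb(file = path, xyz = as.numeric(t(as.matrix(model[, c("x", "y", "z")]))),
                   type = rep("ATOM", n), resno = model$resno,
                   resid = model$resid, chain = model$chain,
                   elety = model$elety, eleno = seq_len(n))
  invisible(path)
}

# Pairs within cutoff between two coordinate matrices (n x 3, m x 3).
# Per-coordinate outer differences keep the arithmetic identical to the
# naive per-pair scan: (dx^2 + dy^2) + dz^2 <= cutoff^2, strict <=.
cross_within <- function(A, B, cutoff) {
  dx <- outer(A[, 1], B[, 1], "-")
  dy <- outer(A[, 2], B[, 2], "-")
  dz <- outer(A[, 3], B[, 3], "-")
  dx * dx + dy * dy + dz * dz <= cutoff * cutoff
}

as_span_df <- function(helix_spans) {
  stopifnot(is.data.frame(helix_spans),
            all(c("start", "end") %in% names(helix_spans)))
  if (is.null(helix_spans$helix)) helix_spans$helix <- seq_len(nrow(helix_spans))
  helix_spans
}

chain_spans <- function(helix_spans, chains) {
  # spans without a chain column apply to every chain
  if (!"chain" %in% names(helix_spans)) {
    helix_spans <- do.call(rbind, lapply(chains, function(ch) {
      cbind(chain = ch, helix_spans)
    }))
  }
  helix_spans
}

xyz_matrix <- function(model, sel = TRUE) {
  as.matrix(model[sel, c("x", "y", "z"), drop = FALSE])
}

#' Helix-helix interface residues
#'
#' A residue is at the helix-helix interface when a backbone heavy atom of
#' that residue (it must itself belong to a helix span) lies within 4.0
#' Angstrom of any heavy atom of a residue belonging to a different helix
#' span of the same chain.
#'
#' @param model A `structure_model`.
#' @param helix_spans Data frame of helix residue ranges with columns
#'   `start`, `end`, optionally `helix` (identifier) and `chain`; spans
#'   without a `chain` column are applied to every chain.
#' @param cutoff Distance cutoff in Angstrom (default 4.0, compared with
#'   strict `<=`).
#' @return Data frame (`chain`, `resno`) of interface residues, sorted.
#' @export
helix_interface_residues <- function(model, helix_spans, cutoff = 4.0) {
  helix_spans <- chain_spans(as_span_df(helix_spans), unique(model$chain))
  out <- list()
  for (ch in unique(helix_spans$chain)) {
    sp <- helix_spans[helix_spans$chain == ch, , drop = FALSE]
    sub <- model[model$chain == ch, , drop = FALSE]
    if (nrow(sub) == 0) stop("helix span refers to absent chain ", ch)
    helix_of <- rep(NA_character_, nrow(sub))
    for (i in seq_len(nrow(sp))) {
      inside <- sub$resno >= sp$start[i] & sub$resno <= sp$end[i]
      if (!any(inside)) stop("helix span ", sp$helix[i], " (", sp$start[i],
                             "-", sp$end[i], ") has no residues in chain ", ch)
      helix_of[inside] <- as.character(sp$helix[i])
    }
    inhx <- !is.na(helix_of)
    if (!any(inhx)) next
    q <- sub[inhx & sub$backbone, , drop = FALSE]
    qh <- helix_of[inhx & sub$backbone]
    t_ <- sub[inhx, , drop = FALSE]
    th <- helix_of[inhx]
    hit <- cross_within(xyz_matrix(q), xyz_matrix(t_), cutoff)
    hit <- hit & outer(qh, th, "!=")
    sel <- rowSums(hit) > 0
    if (any(sel)) {
      out[[ch]] <- unique(data.frame(chain = ch, resno = q$resno[sel],
                                     stringsAsFactors = FALSE))
    }
  }
  collect_residue_set(out)
}

#' Monomer-monomer interface residues
#'
#' A residue is at the monomer-monomer interface when any of its heavy atoms
#' lies within 4.0 Angstrom of any heavy atom of a different chain.
#'
#' @inheritParams helix_interface_residues
#' @return Data frame (`chain`, `resno`) of interface residues, sorted.
#'   A single-chain model yields an empty set with a warning.
#' @export
monomer_interface_residues <- function(model, cutoff = 4.0) {
  chains <- unique(model$chain)
  if (length(chains) < 2) {
    warning("single-chain model: monomer interface is empty")
    return(collect_residue_set(list()))
  }
  out <- list()
  for (i in seq_along(chains)) {
    for (j in seq_along(chains)) {
      if (i == j) next
      A <- model[model$chain == chains[i], , drop = FALSE]
      B <- model[model$chain == chains[j], , drop = FALSE]
      hit <- rowSums(cross_within(xyz_matrix(A), xyz_matrix(B), cutoff)) > 0
      if (any(hit)) {
        out[[paste(i, j)]] <- data.frame(chain = chains[i],
                                         resno = A$resno[hit],
                                         stringsAsFactors = FALSE)
      }
    }
  }
  collect_residue_set(out)
}

collect_residue_set <- function(lst) {
  if (length(lst) == 0) {
    return(data.frame(chain = character(), resno = integer(),
                      stringsAsFactors = FALSE))
  }
  df <- unique(do.call(rbind, lst))
  df <- df[order(df$chain, df$resno), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Pore axis of one monomer
#'
#' Least-squares line through the CA atoms of all helix-span residues of one
#' chain. For the pseudo-symmetric hour-glass bundle this is the central
#' channel axis. The direction is a unit vector oriented toward +z.
#'
#' @inheritParams helix_interface_residues
#' @param chain_id Chain to use.
#' @return List with `point` (centroid, length-3) and `direction` (unit
#'   vector, length 3).
#' @export
pore_axis <- function(model, chain_id, helix_spans) {
  helix_spans <- chain_spans(as_span_df(helix_spans), unique(model$chain))
  sp <- helix_spans[helix_spans$chain == chain_id, , drop = FALSE]
  sub <- model[model$chain == chain_id & model$elety == "CA", , drop = FALSE]
  keep <- rep(FALSE, nrow(sub))
  for (i in seq_len(nrow(sp))) {
    keep <- keep | (sub$resno >= sp$start[i] & sub$resno <= sp$end[i])
  }
  ca <- xyz_matrix(sub, keep)
  if (nrow(ca) < 3) stop("need at least 3 CA atoms to fit a pore axis")
  ctr <- colMeans(ca)
  centered <- sweep(ca, 2, ctr)
  sv <- svd(centered, nu = 0, nv = 1)
  if (sv$d[1] < 1e-8 || nrow(unique(round(centered, 6))) < 3) {
    stop("degenerate geometry: CA atoms do not define a line")
  }
  v <- sv$v[, 1]
  if (v[3] < 0 || (v[3] == 0 && sum(v) < 0)) v <- -v
  list(point = ctr, direction = v / sqrt(sum(v^2)))
}

point_axis_distance <- function(P, axis) {
  rel <- sweep(P, 2, axis$point)
  t_ <- rel %*% axis$direction
  perp <- rel - t_ %*% t(axis$direction)
  sqrt(rowSums(perp^2))
}

#' Define a membrane slab
#'
#' The membrane slab is the region between the two lipid head-group boundary
#' planes along the membrane normal. Models are assumed pre-oriented with
#' the normal along z.
#'
#' @param z_lo,z_hi Slab boundaries in Angstrom, `z_lo < z_hi`.
#' @param extracellular_side `"+z"` or `"-z"`: which side of the slab faces
#'   the extracellular environment.
#' @return Object of class `membrane_slab`.
#' @export
membrane_slab <- function(z_lo, z_hi, extracellular_side = c("+z", "-z")) {
  extracellular_side <- match.arg(extracellular_side)
  stopifnot(is.numeric(z_lo), is.numeric(z_hi), z_lo < z_hi)
  structure(list(z_lo = z_lo, z_hi = z_hi,
                 extracellular_side = extracellular_side),
            class = "membrane_slab")
}

#' Channel-facing residues of one monomer
#'
#' A residue is channel-facing when (a) its CA lies inside the membrane
#' slab, (b) the minimum distance from its side-chain heavy atoms to the
#' monomer's pore axis is at most `r_pore`, and (c) its side-chain centroid
#' is not farther from the axis than its CA, i.e. the side chain points
#' inward. Glycine, having no side chain, uses its CA as the side-chain
#' surrogate.
#'
#' @inheritParams pore_axis
#' @param slab A `membrane_slab`.
#' @param r_pore Pore radius in Angstrom within which a side chain counts as
#'   lining the channel (default 6.0).
#' @return Data frame (`chain`, `resno`), sorted.
#' @export
channel_facing_residues <- function(model, chain_id, helix_spans, slab,
                                    r_pore = 6.0) {
  stopifnot(inherits(slab, "membrane_slab"))
  axis <- pore_axis(model, chain_id, helix_spans)
  sub <- model[model$chain == chain_id, , drop = FALSE]
  out <- list()
  for (rn in unique(sub$resno)) {
    res <- sub[sub$resno == rn, , drop = FALSE]
    ca <- res[res$elety == "CA", , drop = FALSE]
    if (nrow(ca) == 0) next
    if (ca$z[1] < slab$z_lo || ca$z[1] > slab$z_hi) next
    sc <- res[!res$backbone, , drop = FALSE]
    if (nrow(sc) == 0) sc <- ca  # glycine: CA as side-chain surrogate
    dsc <- point_axis_distance(xyz_matrix(sc), axis)
    if (min(dsc) > r_pore) next
    dca <- point_axis_distance(xyz_matrix(ca), axis)
    centroid <- matrix(colMeans(xyz_matrix(sc)), nrow = 1)
    if (point_axis_distance(centroid, axis) > dca) next
    out[[as.character(rn)]] <- data.frame(chain = chain_id, resno = rn,
                                          stringsAsFactors = FALSE)
  }
  collect_residue_set(out)
}

#' Classify all resolved residues into structural regions
#'
#' Assigns exactly one region label to every resolved residue, applying the
#' criteria in precedence order: (1) CA outside the membrane slab gives
#' `EXTRACELLULAR` or `CYTOPLASMIC` according to the side; then, inside the
#' slab, (2) `CHANNEL_FACING`, (3) `HELIX_INTERFACE`, (4)
#' `MONOMER_INTERFACE` and (5) `LIPID_FACING` as the residual class.
#'
#' @inheritParams helix_interface_residues
#' @param slab A `membrane_slab`.
#' @param r_pore Pore radius for the channel-facing rule (Angstrom).
#' @param cutoff Interface distance cutoff (Angstrom).
#' @return A `region_assignment`: data frame with one row per resolved
#'   residue (`chain`, `resno`, `resid`, `region`) plus the per-residue
#'   evidence (`ca_z`, `in_slab`, `sc_axis_dist`, `helix_contact`,
#'   `monomer_contact`).
#' @export
classify_regions <- function(model, helix_spans, slab, r_pore = 6.0,
                             cutoff = 4.0) {
  stopifnot(inherits(slab, "membrane_slab"))
  spans <- chain_spans(as_span_df(helix_spans), unique(model$chain))

  hx <- helix_interface_residues(model, spans, cutoff = cutoff)
  mono <- if (length(unique(model$chain)) >= 2) {
    monomer_interface_residues(model, cutoff = cutoff)
  } else {
    data.frame(chain = character(), resno = integer())
  }

  rows <- list()
  for (ch in unique(model$chain)) {
    sub <- model[model$chain == ch, , drop = FALSE]
    axis <- pore_axis(model, ch, spans)
    chan <- channel_facing_residues(model, ch, spans, slab, r_pore = r_pore)
    for (rn in unique(sub$resno)) {
      res <- sub[sub$resno == rn, , drop = FALSE]
      ca <- res[res$elety == "CA", , drop = FALSE]
      ca_z <- if (nrow(ca) > 0) ca$z[1] else NA_real_
      in_slab <- !is.na(ca_z) && ca_z >= slab$z_lo && ca_z <= slab$z_hi
      sc <- res[!res$backbone, , drop = FALSE]
      if (nrow(sc) == 0) sc <- ca
      sc_axis <- if (nrow(sc) > 0) {
        min(point_axis_distance(xyz_matrix(sc), axis))
      } else NA_real_
      helix_contact <- any(hx$chain == ch & hx$resno == rn)
      monomer_contact <- any(mono$chain == ch & mono$resno == rn)
      region <- if (!in_slab) {
        above <- !is.na(ca_z) && ca_z > slab$z_hi
        if ((above && slab$extracellular_side == "+z") ||
            (!above && slab$extracellular_side == "-z")) {
          "EXTRACELLULAR"
        } else "CYTOPLASMIC"
      } else if (any(chan$resno == rn)) {
        "CHANNEL_FACING"
      } else if (helix_contact) {
        "HELIX_INTERFACE"
      } else if (monomer_contact) {
        "MONOMER_INTERFACE"
      } else {
        "LIPID_FACING"
      }
      rows[[paste(ch, rn)]] <- data.frame(
        chain = ch, resno = rn, resid = res$resid[1], region = region,
        ca_z = ca_z, in_slab = in_slab, sc_axis_dist = sc_axis,
        helix_contact = helix_contact, monomer_contact = monomer_contact,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$chain, out$resno), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("region_assignment", "data.frame")
  out
}

#' Tabulate a region assignment
#'
#' @param assignment A `region_assignment`.
#' @return Named integer vector of residue counts over the six region
#'   labels; counts always sum to the number of resolved residues.
#' @export
region_counts <- function(assignment) {
  tab <- table(factor(assignment$region, levels = REGION_LABELS))
  stats::setNames(as.integer(tab), REGION_LABELS)
}
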