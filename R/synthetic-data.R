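# Synthetic structures and variant tables with known ground truth.
#
# The structure generator builds ideal alpha-helix bundles arranged like the
# hour-glass fold (eight helices on a ring) and C4 tetramers of them, with
# channel-facing and interface labels known by construction, so the geometric
# classifiers can be validated end to end without any downloaded structure.

#' Specification of a synthetic helix bundle
#'
#' @param n_helices Number of helices in the bundle (default 8: six full and
#'   two half-helix stand-ins).
#' @param residues_per_helix Residues per helix (default 24; the bundle then
#'   pokes out of a 30 Angstrom membrane slab on both sides).
#' @param ring_radius Distance from the bundle axis to each helix axis in
#'   Angstrom (default 11.75, giving adjacent helix-axis separations of
#'   about 9 Angstrom, close enough for 4 Angstrom backbone contacts).
#' @param tilt_deg Tilt of each helix axis toward the bundle axis, degrees.
#' @param spacing Distance from the tetramer (global z) axis to each
#'   monomer's bundle axis in Angstrom; the default 23 puts neighbouring
#'   monomers in 4 Angstrom contact (contacts vanish above roughly 25).
#' @param seed Integer seed; generation is deterministic per seed.
#' @return Object of class `bundle_spec`.
#' @export
bundle_spec <- function(n_helices = 8, residues_per_helix = 24,
                        ring_radius = 11.75, tilt_deg = 0, spacing = 23,
                        seed = 1) {
  stopifnot(n_helices >= 2, residues_per_helix >= 4, ring_radius > 0,
            spacing > 0)
  structure(list(n_helices = as.integer(n_helices),
                 residues_per_helix = as.integer(residues_per_helix),
                 ring_radius = ring_radius, tilt_deg = tilt_deg,
                 spacing = spacing, seed = as.integer(seed)),
            class = "bundle_spec")
}

# Rotation matrix taking +z onto the unit vector `dir`.
rotation_to <- function(dir) {
  dir <- dir / sqrt(sum(dir^2))
  z <- c(0, 0, 1)
  v <- c(z[2] * dir[3] - z[3] * dir[2],
         z[3] * dir[1] - z[1] * dir[3],
         z[1] * dir[2] - z[2] * dir[1])
  c_ <- sum(z * dir)
  if (sqrt(sum(v^2)) < 1e-12) {
    return(if (c_ > 0) diag(3) else diag(c(1, -1, -1)))
  }
  vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + vx + vx %*% vx / (1 + c_)
}

#' Generate an ideal alpha helix
#'
#' Canonical helix geometry: CA rise 1.5 Angstrom per residue, 3.6 residues
#' per turn (100 degrees twist), CA helix radius 2.3 Angstrom. Each residue
#' carries N, CA, C, O backbone atoms plus a CB placed radially outward from
#' the helix axis (omitted for glycine). Consecutive CA-CA distances come
#' out at 3.8 Angstrom.
#'
#' @param n_residues Number of residues (at least 4).
#' @param origin Point on the helix axis where residue 1 sits (length-3).
#' @param direction Helix axis direction (length-3, need not be unit).
#' @param phase Phase angle of residue 1 around the axis, degrees.
#' @param chain Chain identifier.
#' @param start_resno Residue number of the first residue.
#' @param resid 3-letter residue name used for every residue (`"GLY"` builds
#'   no CB).
#' @return A `structure_model` with one chain.
#' @export
ideal_helix <- function(n_residues, origin = c(0, 0, 0),
                        direction = c(0, 0, 1), phase = 0, chain = "A",
                        start_resno = 1, resid = "ALA") {
  if (n_residues < 4) stop("need at least 4 residues for a helix")
  rot <- rotation_to(direction)
  twist <- 100 * pi / 180
  rise <- 1.5
  th0 <- phase * pi / 180

  place <- function(i, r, dth, dz) {
    th <- th0 + (i - 1) * twist + dth
    c(r * cos(th), r * sin(th), (i - 1) * rise + dz)
  }
  rows <- vector("list", n_residues)
  for (i in seq_len(n_residues)) {
    atoms <- list(
      N = place(i, 1.6, -28 * pi / 180, -0.9),
      CA = place(i, 2.3, 0, 0),
      C = place(i, 1.7, 26 * pi / 180, 0.65),
      O = place(i, 2.9, 26 * pi / 180, 0.75)
    )
    if (toupper(resid) != "GLY") atoms$CB <- place(i, 3.83, 0, 0)
    xyz <- t(vapply(atoms, identity, numeric(3)))
    xyz <- xyz %*% t(rot)
    xyz <- sweep(xyz, 2, origin, "+")
    rows[[i]] <- data.frame(chain = chain, resno = start_resno + i - 1L,
                            resid = toupper(resid), elety = names(atoms),
                            x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                            stringsAsFactors = FALSE)
  }
  structure_model(do.call(rbind, rows))
}

#' Build a synthetic hour-glass-like monomer with known truth
#'
#' Places `n_helices` ideal helices on a ring about the z axis (the bundle's
#' channel axis), centred on z = 0. Residues whose outward CB direction is
#' aligned (within 40 degrees) with the direction toward the bundle axis are
#' turned into channel-lining probes: their CB is re-placed on the segment
#' from the CA toward the axis at an axis distance of exactly 4 Angstrom.
#' These probe residues are the planted channel-facing truth. Helix-helix
#' interface truth is derived internally with the 4 Angstrom backbone scan,
#' and the generator asserts that the planted channel set is exactly
#' recovered by [channel_facing_residues()] before returning.
#'
#' @param spec A [bundle_spec()].
#' @param chain Chain identifier.
#' @return List with components
#'   \describe{
#'     \item{model}{the `structure_model` (one chain).}
#'     \item{spans}{helix spans (`helix`, `start`, `end`); with 8 helices the
#'       helix labels follow the fold order TM1, TM2, LB, TM3, TM4, TM5, LE,
#'       TM6.}
#'     \item{truth}{list with `channel_facing` (planted residue set inside
#'       the default slab), `helix_interface` (4 Angstrom scan), `slab` (the
#'       default +/- 15 Angstrom slab used for the self-check), `axis`
#'       (bundle axis point and direction).}
#'   }
#' @export
build_monomer <- function(spec = bundle_spec(), chain = "A") {
  stopifnot(inherits(spec, "bundle_spec"))
  rng <- local_rng(spec$seed)
  on.exit(rng())
  n <- spec$n_helices
  rph <- spec$residues_per_helix
  z0 <- -(rph - 1) * 1.5 / 2
  phases <- stats::runif(n, 0, 360)

  helices <- vector("list", n)
  spans <- data.frame(helix = character(n), start = integer(n),
                      end = integer(n), stringsAsFactors = FALSE)
  labels <- if (n == 8) SEGMENT_ORDER else paste0("H", seq_len(n))
  for (h in seq_len(n)) {
    ang <- 2 * pi * (h - 1) / n
    base <- c(spec$ring_radius * cos(ang), spec$ring_radius * sin(ang), z0)
    dir <- c(0, 0, 1)
    if (spec$tilt_deg != 0) {
      # tilt the axis toward the bundle axis in the radial plane
      t_ <- spec$tilt_deg * pi / 180
      radial <- c(cos(ang), sin(ang), 0)
      dir <- cos(t_) * c(0, 0, 1) - sin(t_) * radial
    }
    start <- (h - 1L) * rph + 1L
    helices[[h]] <- ideal_helix(rph, origin = base, direction = dir,
                                phase = phases[h], chain = chain,
                                start_resno = start)
    spans$helix[h] <- labels[h]
    spans$start[h] <- start
    spans$end[h] <- start + rph - 1L
  }
  atoms <- do.call(rbind, helices)

  # plant channel-facing probes: CB re-placed at axis distance 4 A
  planted <- integer(0)
  for (rn in unique(atoms$resno)) {
    sel <- atoms$resno == rn
    ca <- atoms[sel & atoms$elety == "CA", c("x", "y", "z")]
    cb_i <- which(sel & atoms$elety == "CB")
    if (length(cb_i) != 1) next
    cb <- atoms[cb_i, c("x", "y", "z")]
    ca_r <- sqrt(ca$x^2 + ca$y^2)
    if (ca_r <= 4.5) next
    inward <- c(-ca$x, -ca$y, 0) / ca_r
    cbdir <- c(cb$x - ca$x, cb$y - ca$y, cb$z - ca$z)
    cbdir <- cbdir / sqrt(sum(cbdir^2))
    if (sum(inward * cbdir) > cos(40 * pi / 180)) {
      atoms[cb_i, c("x", "y")] <- ca[c("x", "y")] * (4.0 / ca_r)
      planted <- c(planted, rn)
    }
  }
  model <- structure_model(atoms)

  ca <- model[model$elety == "CA", , drop = FALSE]
  dmat <- as.matrix(stats::dist(ca[, c("x", "y", "z")]))
  diag(dmat) <- Inf
  if (min(dmat) < 2) stop("steric collapse: CA-CA distance below 2 Angstrom")

  slab <- membrane_slab(-15, 15, "+z")
  in_slab <- vapply(planted, function(rn) {
    z <- model$z[model$resno == rn & model$elety == "CA"]
    z >= slab$z_lo && z <= slab$z_hi
  }, logical(1))
  truth_channel <- data.frame(chain = chain, resno = sort(planted[in_slab]),
                              stringsAsFactors = FALSE)

  got <- channel_facing_residues(model, chain, spans, slab, r_pore = 6.0)
  if (!identical(got$resno, truth_channel$resno)) {
    stop("generator self-check failed: channel-facing truth not recovered")
  }
  hx <- helix_interface_residues(model, spans)

  list(model = model, spans = spans,
       truth = list(channel_facing = truth_channel, helix_interface = hx,
                    slab = slab,
                    axis = list(point = c(0, 0, 0), direction = c(0, 0, 1))))
}

#' Assemble a C4 tetramer from a monomer
#'
#' Translates the monomer's bundle axis to `(spacing, 0)` and generates
#' chains A-D as exact 90-degree rotated copies about the global z axis.
#' Inter-chain 4 Angstrom contacts exist when `spacing` is below roughly 25
#' Angstrom for the default bundle, and vanish for larger spacings.
#'
#' @param monomer A single-chain `structure_model` (bundle axis on z).
#' @param spacing Distance from the global z axis to each monomer's bundle
#'   axis, Angstrom.
#' @return A `structure_model` with chains `A`, `B`, `C`, `D`.
#' @export
build_tetramer <- function(monomer, spacing = 23) {
  stopifnot(inherits(monomer, "structure_model"))
  chains <- c("A", "B", "C", "D")
  out <- vector("list", 4)
  xyz <- as.matrix(monomer[, c("x", "y", "z")])
  xyz[, 1] <- xyz[, 1] + spacing
  for (k in 0:3) {
    th <- k * pi / 2
    rot <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
    rxyz <- xyz %*% t(rot)
    m <- monomer
    m$chain <- chains[k + 1]
    m$x <- rxyz[, 1]; m$y <- rxyz[, 2]; m$z <- rxyz[, 3]
    out[[k + 1]] <- as.data.frame(m)
  }
  structure_model(do.call(rbind, out))
}

# Save/restore the global RNG around seeded generation.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
}

# Codon pairs differing at exactly one position, indexed by "ref>alt"
# amino-acid pair (stops excluded).
single_nt_codon_pairs <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    bases <- c("A", "C", "G", "T")
    codons <- apply(expand.grid(bases, bases, bases), 1, paste, collapse = "")
    rows <- list()
    for (cod in codons) {
      aa1 <- translate_codon(cod)
      if (aa1 == "*") next
      for (p in 1:3) {
        for (b in setdiff(bases, substr(cod, p, p))) {
          alt <- cod
          substr(alt, p, p) <- b
          aa2 <- translate_codon(alt)
          if (aa2 == "*" || aa2 == aa1) next
          rows[[length(rows) + 1]] <- data.frame(
            key = paste0(aa1, ">", aa2), ref_codon = cod, alt_codon = alt,
            pos = p, stringsAsFactors = FALSE)
        }
      }
    }
    cache <<- do.call(rbind, rows)
    cache
  }
})

#' Sample a synthetic variant table with exact group-pair counts
#'
#' For each cell `(i, j)` of a 6x6 intended-count matrix, emits exactly that
#' many variant records whose reference amino acid is drawn uniformly from
#' group `i` and alternate from group `j` (reference and alternate always
#' differ). Each record gets a synthetic rsID and, where the amino-acid pair
#' is reachable by a single nucleotide change, a consistent codon pair;
#' otherwise the codons are left blank and the record carries the
#' codon-unverified convention. Aggregating the output with
#' [build_substitution_matrix()] recovers `cell_counts` exactly.
#'
#' @param cell_counts 6x6 non-negative integer matrix in group order SWP,
#'   AH, CHARGED, NP, AROMATIC, PRO (rows = from, columns = to). A positive
#'   PRO-to-PRO cell is rejected: proline is a single-member group, so a
#'   within-group missense change is impossible.
#' @param seed Integer seed.
#' @param homologs Homolog names to draw genes from.
#' @return List with `variants` (raw-record data frame acceptable to
#'   [apply_snp_filters()]) and `truth` (the intended count matrix).
#' @export
sample_variants <- function(cell_counts, seed = 1,
                            homologs = AQP_HOMOLOGS) {
  cell_counts <- as.matrix(cell_counts)
  stopifnot(all(dim(cell_counts) == c(6, 6)), all(cell_counts >= 0),
            sum(cell_counts) > 0)
  dimnames(cell_counts) <- list(from = AA_GROUPS, to = AA_GROUPS)
  if (cell_counts["PRO", "PRO"] > 0) {
    stop("PRO -> PRO substitutions are impossible: proline is the only group member")
  }
  rng <- local_rng(seed)
  on.exit(rng())
  pairs <- single_nt_codon_pairs()

  rows <- list()
  serial <- 0L
  for (i in AA_GROUPS) {
    for (j in AA_GROUPS) {
      cnt <- cell_counts[i, j]
      if (cnt == 0) next
      members_i <- AA_GROUP_MEMBERS[[i]]
      members_j <- AA_GROUP_MEMBERS[[j]]
      for (k in seq_len(cnt)) {
        repeat {
          ref <- sample(members_i, 1)
          alt <- sample(members_j, 1)
          if (ref != alt) break
        }
        serial <- serial + 1L
        cand <- pairs[pairs$key == paste0(ref, ">", alt), , drop = FALSE]
        if (nrow(cand) > 0) {
          pick <- cand[sample.int(nrow(cand), 1), ]
          ref_codon <- pick$ref_codon; alt_codon <- pick$alt_codon
          pos <- pick$pos
        } else {
          ref_codon <- NA_character_; alt_codon <- NA_character_; pos <- 1L
        }
        rows[[serial]] <- data.frame(
          rsid = paste0("rs", 900000L + serial),
          gene = sample(homologs, 1),
          ref_codon = ref_codon, alt_codon = alt_codon,
          codon_change_pos = as.integer(pos),
          residue_index = sample.int(300L, 1),
          ref_aa = ref, alt_aa = alt, deprecated = FALSE, disease = "",
          stringsAsFactors = FALSE)
      }
    }
  }
  variants <- do.call(rbind, rows)
  rownames(variants) <- NULL
  list(variants = variants, truth = cell_counts)
}
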