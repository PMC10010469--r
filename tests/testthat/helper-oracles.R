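# Independent brute-force oracles used to validate the package's
# implementations. These deliberately take a different computational route
# (full stats::dist matrices, per-pair loops, per-entry predicate scans).

# All-pairs distance matrix over atoms, via stats::dist.
oracle_dist <- function(model) {
  as.matrix(stats::dist(as.matrix(model[, c("x", "y", "z")])))
}

# Monomer-monomer interface: any heavy atom within cutoff of another chain.
oracle_monomer_interface <- function(model, cutoff = 4.0) {
  d <- oracle_dist(model)
  cross <- outer(model$chain, model$chain, "!=")
  hit <- rowSums(d <= cutoff & cross) > 0
  df <- unique(data.frame(chain = model$chain[hit], resno = model$resno[hit],
                          stringsAsFactors = FALSE))
  df <- df[order(df$chain, df$resno), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# Helix-helix interface: a backbone atom of a helix residue within cutoff of
# any atom of a different helix of the same chain.
oracle_helix_interface <- function(model, spans, cutoff = 4.0) {
  if (!"chain" %in% names(spans)) {
    spans <- do.call(rbind, lapply(unique(model$chain), function(ch) {
      cbind(chain = ch, spans)
    }))
  }
  helix_of <- rep(NA_character_, nrow(model))
  for (i in seq_len(nrow(spans))) {
    sel <- model$chain == spans$chain[i] & model$resno >= spans$start[i] &
      model$resno <= spans$end[i]
    helix_of[sel] <- paste(spans$chain[i], spans$helix[i])
  }
  d <- oracle_dist(model)
  same_chain <- outer(model$chain, model$chain, "==")
  diff_helix <- outer(helix_of, helix_of, "!=")
  in_helix <- !is.na(helix_of)
  valid <- same_chain & diff_helix & outer(in_helix, in_helix, "&")
  query <- model$elety %in% c("N", "CA", "C", "O")
  hit <- rowSums(d <= cutoff & valid) > 0 & query & in_helix
  df <- unique(data.frame(chain = model$chain[hit], resno = model$resno[hit],
                          stringsAsFactors = FALSE))
  df <- df[order(df$chain, df$resno), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# Independent per-pair group tally (own group lookup, no aa_group()).
oracle_substitution_tally <- function(ref_aa, alt_aa) {
  members <- list(SWP = c("G", "A", "C", "S", "T"), AH = c("L", "I", "V", "M"),
                  CHARGED = c("D", "E", "K", "R", "H"), NP = c("N", "Q"),
                  AROMATIC = c("F", "W", "Y"), PRO = "P")
  lookup <- function(a) names(which(vapply(members, function(m) a %in% m,
                                           logical(1))))
  groups <- names(members)
  m <- matrix(0L, 6, 6, dimnames = list(from = groups, to = groups))
  for (k in seq_along(ref_aa)) {
    i <- lookup(ref_aa[k]); j <- lookup(alt_aa[k])
    m[i, j] <- m[i, j] + 1L
  }
  m
}

# Random amino-acid substitution pairs (ref != alt) for property tests.
random_aa_pairs <- function(n, seed = 1) {
  std <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  set.seed(seed)
  ref <- sample(std, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(std, r), 1), character(1))
  data.frame(ref_aa = ref, alt_aa = unname(alt), stringsAsFactors = FALSE)
}

# Rigid transform of a structure model: rotation (3x3) then translation.
transform_model <- function(model, rot = diag(3), shift = c(0, 0, 0)) {
  xyz <- as.matrix(model[, c("x", "y", "z")]) %*% t(rot)
  xyz <- sweep(xyz, 2, shift, "+")
  model$x <- xyz[, 1]; model$y <- xyz[, 2]; model$z <- xyz[, 3]
  model
}

rotation_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
}

# A small raw variant record, with overridable fields.
raw_record <- function(...) {
  base <- list(rsid = "rs1", gene = "AQP4", ref_codon = "AAT",
               alt_codon = "ACT", codon_change_pos = 2L, residue_index = 97L,
               ref_aa = "N", alt_aa = "T", deprecated = FALSE, disease = "")
  override <- list(...)
  base[names(override)] <- override
  as.data.frame(base, stringsAsFactors = FALSE)
}
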