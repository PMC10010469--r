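two_parallel_helices <- function(sep = 9, n = 20) {
  h1 <- ideal_helix(n, origin = c(0, 0, 0), phase = 0, start_resno = 1)
  h2 <- ideal_helix(n, origin = c(sep, 0, 0), phase = 180, start_resno = 101)
  model <- structure_model(rbind(as.data.frame(h1), as.data.frame(h2)))
  spans <- data.frame(helix = c("H1", "H2"), start = c(1, 101),
                      end = c(n, 100 + n))
  list(model = model, spans = spans)
}

test_that("PDB files round-trip and follow the altloc/HETATM/hydrogen rules", {
  h <- two_parallel_helices()
  pdb <- withr::local_tempfile(fileext = ".pdb")
  write_structure(h$model, pdb)
  back <- read_structure(pdb)
  expect_equal(nrow(back), nrow(h$model))
  expect_equal(unique(back$chain), "A")
  expect_equal(sort(unique(back$resno)), sort(unique(h$model$resno)))
  expect_equal(as.matrix(back[order(back$resno, back$elety),
                              c("x", "y", "z")]),
               as.matrix(h$model[order(h$model$resno, h$model$elety),
                                 c("x", "y", "z")]),
               tolerance = 1e-3, ignore_attr = TRUE)

  # waters and hydrogens dropped; altloc resolved to highest occupancy
  atom_line <- function(serial, name, alt, res, chain, resno, x, occ,
                        type = "ATOM  ", elem = substr(name, 1, 1)) {
    sprintf("%-6s%5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            type, serial, name, alt, res, chain, resno, x, 0, 0, occ, 0, elem)
  }
  lines <- c(
    atom_line(1, "N", " ", "ALA", "A", 1, 0.0, 1.0),
    atom_line(2, "CA", "A", "ALA", "A", 1, 1.5, 0.4),
    atom_line(3, "CA", "B", "ALA", "A", 1, 9.9, 0.6),
    atom_line(4, "CB", " ", "ALA", "A", 1, 2.0, 1.0),
    atom_line(5, "HB1", " ", "ALA", "A", 1, 2.5, 1.0, elem = "H"),
    atom_line(6, "O", " ", "HOH", "A", 90, 8.0, 1.0, type = "HETATM"),
    "END")
  pdb2 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, pdb2)
  m <- read_structure(pdb2)
  expect_equal(nrow(m), 3)                        # N, CA, CB only
  expect_false(any(m$resid == "HOH"))
  expect_equal(m$x[m$elety == "CA"], 9.9)         # occupancy 0.6 wins
})

test_that("helix-interface residues match the brute-force distance oracle", {
  h <- two_parallel_helices(sep = 9)
  got <- helix_interface_residues(h$model, h$spans)
  expect_gt(nrow(got), 0)
  expect_equal(got, oracle_helix_interface(h$model, h$spans))

  # monotone in the cutoff
  wider <- helix_interface_residues(h$model, h$spans, cutoff = 5)
  expect_true(all(paste(got$chain, got$resno) %in%
                    paste(wider$chain, wider$resno)))

  far <- two_parallel_helices(sep = 40)
  expect_equal(nrow(helix_interface_residues(far$model, far$spans)), 0)

  solo <- ideal_helix(20)
  expect_equal(nrow(helix_interface_residues(
    solo, data.frame(helix = "H1", start = 1, end = 20))), 0)
})

test_that("monomer-interface residues match the brute-force oracle on a tetramer", {
  mon <- build_monomer(bundle_spec(seed = 3))
  tet <- build_tetramer(mon$model, spacing = 23)
  got <- monomer_interface_residues(tet)
  expect_gt(nrow(got), 0)
  expect_equal(got, oracle_monomer_interface(tet))

  # C4 symmetry: identical residue sets on all four chains
  per_chain <- split(got$resno, got$chain)
  expect_length(per_chain, 4)
  expect_true(all(vapply(per_chain, identical, logical(1), per_chain[[1]])))

  wider <- monomer_interface_residues(tet, cutoff = 5)
  expect_true(all(paste(got$chain, got$resno) %in%
                    paste(wider$chain, wider$resno)))

  far <- build_tetramer(mon$model, spacing = 100)
  expect_equal(nrow(monomer_interface_residues(far)), 0)
  expect_warning(single <- monomer_interface_residues(mon$model),
                 "single-chain")
  expect_equal(nrow(single), 0)

  # symmetric criterion: a clashing residue pair flags both residues
  a <- ideal_helix(5, chain = "A")
  b <- ideal_helix(5, origin = c(3, 0, 0), chain = "B")
  both <- monomer_interface_residues(
    structure_model(rbind(as.data.frame(a), as.data.frame(b))))
  expect_setequal(unique(both$chain), c("A", "B"))
})

test_that("the pore axis recovers the generator axis and is rotation-equivariant", {
  mon <- build_monomer(bundle_spec(seed = 11))
  ax <- pore_axis(mon$model, "A", mon$spans)
  expect_lt(sqrt(sum(ax$point[1:2]^2)), 0.5)
  expect_lt(acos(min(1, abs(sum(ax$direction * c(0, 0, 1))))) * 180 / pi, 5)

  rot <- rotation_z(30) %*% matrix(c(1, 0, 0, 0, 0, -1, 0, 1, 0), 3, 3)
  moved <- transform_model(mon$model, rot, shift = c(10, -4, 2))
  ax2 <- pore_axis(structure_model(as.data.frame(moved)), "A", mon$spans)
  expected_dir <- as.vector(rot %*% ax$direction)
  if (expected_dir[3] < 0) expected_dir <- -expected_dir
  expect_equal(abs(sum(ax2$direction * expected_dir)), 1, tolerance = 1e-6)

  line <- ideal_helix(4)
  line <- line[line$elety == "CA", ][1:2, ]
  expect_error(pore_axis(structure_model(line),
                         "A", data.frame(helix = 1, start = 1, end = 2)),
               "at least 3 CA")
})

test_that("channel-facing detection honours the slab gate and pore radius", {
  mon <- build_monomer(bundle_spec(seed = 5))
  slab <- mon$truth$slab
  got <- channel_facing_residues(mon$model, "A", mon$spans, slab)
  expect_equal(got$resno, mon$truth$channel_facing$resno)
  expect_gt(nrow(got), 0)

  # residues with CA above the slab are excluded regardless of geometry
  low <- membrane_slab(-15, 5, "+z")
  gated <- channel_facing_residues(mon$model, "A", mon$spans, low)
  ca_z <- vapply(gated$resno, function(rn) {
    mon$model$z[mon$model$resno == rn & mon$model$elety == "CA"]
  }, numeric(1))
  expect_true(all(ca_z <= 5))
  expect_true(all(gated$resno %in% got$resno))

  none <- channel_facing_residues(mon$model, "A", mon$spans, slab, r_pore = 0)
  expect_equal(nrow(none), 0)
})

test_that("region labels form a partition matching generator truth", {
  mon <- build_monomer(bundle_spec(seed = 9))
  tet <- build_tetramer(mon$model, spacing = 23)
  slab <- mon$truth$slab
  ra <- classify_regions(tet, mon$spans, slab)

  # partition and conservation
  expect_equal(nrow(ra), length(unique(paste(tet$chain, tet$resno))))
  expect_true(all(ra$region %in% REGION_LABELS))
  expect_equal(sum(region_counts(ra)), nrow(ra))

  # extracellular / cytoplasmic assignment by slab side
  expect_true(all(ra$region[ra$ca_z > slab$z_hi] == "EXTRACELLULAR"))
  expect_true(all(ra$region[ra$ca_z < slab$z_lo] == "CYTOPLASMIC"))

  # planted channel truth respected on chain A (in-slab probes)
  chan <- ra[ra$chain == "A" & ra$region == "CHANNEL_FACING", ]
  expect_setequal(chan$resno, mon$truth$channel_facing$resno)

  # unambiguous in-slab residues match the single criterion they satisfy
  hx <- mon$truth$helix_interface
  mono <- monomer_interface_residues(tet)
  amb <- ra$chain == "A" & ra$in_slab
  only_helix <- amb & ra$resno %in% hx$resno &
    !(ra$resno %in% mon$truth$channel_facing$resno) &
    !(paste(ra$chain, ra$resno) %in% paste(mono$chain, mono$resno))
  expect_true(all(ra$region[only_helix] == "HELIX_INTERFACE"))
  residual <- amb & !(ra$resno %in% hx$resno) &
    !(ra$resno %in% mon$truth$channel_facing$resno) &
    !(paste(ra$chain, ra$resno) %in% paste(mono$chain, mono$resno))
  expect_true(all(ra$region[residual] == "LIPID_FACING"))
})

test_that("region labels are invariant under a joint rigid transform", {
  mon <- build_monomer(bundle_spec(seed = 13))
  tet <- build_tetramer(mon$model, spacing = 23)
  slab <- membrane_slab(-15, 15, "+z")
  ra <- classify_regions(tet, mon$spans, slab)

  # rotate about the membrane normal and translate; shift the slab with z
  moved <- transform_model(tet, rotation_z(47), shift = c(12.5, -8, 6))
  moved <- structure_model(as.data.frame(moved))
  ra2 <- classify_regions(moved, mon$spans, membrane_slab(-15 + 6, 15 + 6, "+z"))
  expect_equal(ra2$region, ra$region)
})
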