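make_entries <- function(n = 50, seed = 7, with_regions = TRUE) {
  counts <- matrix(0L, 6, 6)
  counts[1, 2] <- n %/% 2
  counts[3, 5] <- n - n %/% 2
  sv <- sample_variants(counts, seed = seed)
  kept <- apply_snp_filters(sv$variants)$variants
  maps <- synthetic_segment_maps()
  regions <- NULL
  if (with_regions) {
    mon <- build_monomer(bundle_spec(seed = seed))
    ra <- classify_regions(mon$model, mon$spans, mon$truth$slab)
    regions <- stats::setNames(rep(list(ra), length(maps)), names(maps))
  }
  annotate_variants(kept, maps, regions)
}

test_that("annotation joins numbering, sites, groups and regions", {
  maps <- synthetic_segment_maps()
  kept <- apply_snp_filters(raw_record(rsid = "rs10", gene = "AQP4",
                                       residue_index = 97))$variants
  ann <- annotate_variants(kept, maps)
  expect_equal(ann$generic_number, "LB.50")
  expect_equal(ann$segment_or_loop, "LB")
  expect_equal(ann$functional_site, "NPA_LB")
  expect_equal(ann$ref_group, "NP")
  expect_equal(ann$alt_group, "SWP")
  expect_false(ann$conservative)
  expect_equal(ann$region, "UNMAPPED")   # no region assignment supplied

  nterm <- apply_snp_filters(raw_record(rsid = "rs11", gene = "AQP4",
                                        residue_index = 1))$variants
  ann2 <- annotate_variants(nterm, maps)
  expect_equal(ann2$generic_number, "NTERM")
  expect_equal(ann2$region, "UNMAPPED")

  empty <- annotate_variants(kept[0, ], maps)
  expect_equal(nrow(empty), 0)
  expect_error(annotate_variants(transform(kept, gene = "AQP99"), maps),
               "no segment map")
})

test_that("entries round-trip through CSV field-for-field", {
  entries <- make_entries(50)
  entries$disease[1] <- "nephrogenic diabetes insipidus, autosomal"
  entries$disease[2] <- 'quoted "text" with, commas'
  path <- withr::local_tempfile(fileext = ".csv")
  write_aqpsnp_csv(entries, path)
  back <- read_aqpsnp_csv(path)
  expect_equal(back, entries)

  # hand-edited invalid region label is rejected with its row number
  bad <- entries
  bad$region[3] <- "INSIDE_OUT"
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_aqpsnp_csv(bad, path2)
  expect_error(read_aqpsnp_csv(path2), "row 3.*invalid region")

  wrong_header <- withr::local_tempfile(fileext = ".csv")
  writeLines("a,b,c", wrong_header)
  expect_error(read_aqpsnp_csv(wrong_header), "unexpected header")
})

test_that("statistics are consistent, cross-checked and permutation-invariant", {
  entries <- make_entries(60, seed = 21)
  st <- aqpsnp_statistics(entries)
  expect_equal(sum(st$per_homolog), nrow(entries))
  expect_equal(sum(st$per_homolog_region) + st$n_unmapped, nrow(entries))
  expect_equal(sum(st$position_classes), nrow(entries))
  expect_equal(unclass(st$substitution_matrix),
               unclass(build_substitution_matrix(entries$ref_aa,
                                                 entries$alt_aa)))
  st2 <- aqpsnp_statistics(entries[sample.int(nrow(entries)), ])
  expect_equal(st2$per_homolog, st$per_homolog)
  expect_equal(st2$per_homolog_region, st$per_homolog_region)
  expect_equal(unclass(st2$substitution_matrix),
               unclass(st$substitution_matrix))

  # the reference functional-site fixture flows through statistics
  fx <- apply_snp_filters(expand_site_listing(aqp_functional_site_table()))
  ann <- annotate_variants(fx$variants, synthetic_segment_maps())
  stf <- aqpsnp_statistics(ann)
  expect_equal(as.vector(stf$functional_sites[c("NPA_LB", "NPA_LE", "ARR_SF")]),
               c(33L, 23L, 54L))
})

test_that("conjunctive queries match a brute-force predicate scan", {
  entries <- make_entries(80, seed = 33)
  q <- list(homolog = "AQP0", region = "HELIX_INTERFACE",
            ref_group = "CHARGED", alt_group = "AROMATIC")
  got <- query_aqpsnp(entries, homolog = q$homolog, region = q$region,
                      ref_group = q$ref_group, alt_group = q$alt_group)
  scan <- entries[vapply(seq_len(nrow(entries)), function(i) {
    e <- entries[i, ]
    e$homolog == q$homolog && e$region == q$region &&
      e$ref_group == q$ref_group && e$alt_group == q$alt_group
  }, logical(1)), ]
  rownames(scan) <- NULL
  expect_equal(got, scan)

  # several single filters, scanned the same way
  for (filter in list(list(region = "CHANNEL_FACING"),
                      list(ref_group = "CHARGED"),
                      list(homolog = "AQP7"))) {
    got_i <- do.call(query_aqpsnp, c(list(entries), filter))
    col <- c(region = "region", ref_group = "ref_group",
             homolog = "homolog")[names(filter)]
    scan_i <- entries[entries[[col]] == filter[[1]], ]
    rownames(scan_i) <- NULL
    expect_equal(got_i, scan_i)
  }

  expect_equal(query_aqpsnp(entries), entries)              # empty query
  expect_equal(nrow(query_aqpsnp(entries, rsid = "rs1")), 0)
  expect_error(query_aqpsnp(entries, region = "OUTSIDE"), "unknown region")
  expect_error(query_aqpsnp(entries, homolog = "AQP99"), "unknown homolog")

  planted <- entries
  planted$disease[c(2, 5)] <- "Cataract, congenital"
  hits <- query_aqpsnp(planted, disease_contains = "cataract")
  expect_equal(hits$db_id, planted$db_id[c(2, 5)])
})
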