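test_that("codon translation follows the standard genetic code", {
  expect_equal(translate_codon("AAT"), "N")
  expect_equal(translate_codon("TGA"), "*")
  expect_equal(translate_codon(c("ATG", "tgg")), c("M", "W"))
  expect_error(translate_codon("AXT"), "invalid codon")
  expect_error(translate_codon("AA"), "invalid codon")

  bases <- c("A", "C", "G", "T")
  codons <- apply(expand.grid(bases, bases, bases), 1, paste, collapse = "")
  aa <- translate_codon(codons)
  expect_length(aa, 64)
  expect_equal(sum(aa == "*"), 3)
  expect_equal(sort(unique(aa[aa != "*"])),
               sort(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]))

  skip_if_not_installed("seqinr")
  indep <- vapply(codons, function(cod) {
    seqinr::translate(seqinr::s2c(cod))
  }, character(1))
  expect_equal(aa, unname(indep))
})

test_that("JSON-lines dumps parse with per-row error collection", {
  rec <- function(rsid, residue_index = 97) {
    jsonlite::toJSON(list(rsid = rsid, gene = "AQP4", ref_codon = "AAT",
                          alt_codon = "ACT", codon_change_pos = 2,
                          residue_index = residue_index, ref_aa = "N",
                          alt_aa = "T", deprecated = FALSE, disease = ""),
                     auto_unbox = TRUE)
  }
  good <- vapply(1:8, function(i) rec(paste0("rs", i)), character(1))
  lines <- c(good[1:4], "{not json", good[5:8], rec("not-an-rsid"))
  parsed <- parse_snp_dump(lines, format = "jsonl", text = TRUE)
  expect_equal(nrow(parsed$records), 8)
  expect_equal(parsed$records$rsid, paste0("rs", 1:8))
  expect_equal(nrow(parsed$errors), 2)
  expect_equal(parsed$errors$line, c(5L, 10L))

  empty <- parse_snp_dump(character(0), format = "jsonl", text = TRUE)
  expect_equal(nrow(empty$records), 0)
  expect_equal(nrow(empty$errors), 0)
})

test_that("CSV dumps parse with the documented field order", {
  lines <- c(
    "rsid,gene,ref_codon,alt_codon,codon_change_pos,residue_index,ref_aa,alt_aa,deprecated,disease",
    "rs123,AQP4,AAT,ACT,2,97,N,T,false,",
    "rs124,AQP1,GAA,AAA,1,12,E,K,false,\"cataract, congenital\"",
    "rs125,AQP1,GAA,AAA,1,12,E"
  )
  parsed <- parse_snp_dump(lines, format = "csv", text = TRUE)
  expect_equal(nrow(parsed$records), 2)
  expect_equal(parsed$records$disease[2], "cataract, congenital")
  expect_equal(parsed$errors$line, 4L)
})

test_that("validation categorises rejections and flags missing codons", {
  v <- validate_snps(raw_record())
  expect_true(is.na(v$rejection))
  expect_false(v$codon_unverified)

  syn <- validate_snps(raw_record(alt_codon = "AAC", alt_aa = "N"))
  expect_equal(syn$rejection, "synonymous")
  non <- validate_snps(raw_record(ref_codon = "TAT", alt_codon = "TAA",
                                  codon_change_pos = 3, ref_aa = "Y",
                                  alt_aa = "*"))
  expect_equal(non$rejection, "nonsense")
  dep <- validate_snps(raw_record(deprecated = TRUE))
  expect_equal(dep$rejection, "deprecated")
  mnv <- validate_snps(raw_record(alt_codon = "CCT", alt_aa = "P"))
  expect_equal(mnv$rejection, "multi-nucleotide")
  mis <- validate_snps(raw_record(alt_codon = "GAT", codon_change_pos = 1,
                                  alt_aa = "T"))
  expect_equal(mis$rejection, "codon-mismatch")
  wrongpos <- validate_snps(raw_record(codon_change_pos = 1))
  expect_equal(wrongpos$rejection, "codon-mismatch")

  nocodon <- validate_snps(raw_record(ref_codon = NA, alt_codon = NA))
  expect_true(is.na(nocodon$rejection))
  expect_true(nocodon$codon_unverified)
})

test_that("filtering removes duplicates and invalid records with balanced counts", {
  raws <- rbind(
    raw_record(rsid = "rs1"), raw_record(rsid = "rs1"),            # 1 dup
    raw_record(rsid = "rs2"), raw_record(rsid = "rs2"),            # 1 dup
    raw_record(rsid = "rs2"),                                      # 1 dup
    raw_record(rsid = "rs3", deprecated = TRUE),
    raw_record(rsid = "rs4", deprecated = TRUE),
    raw_record(rsid = "rs5", alt_codon = "AAC", alt_aa = "N"),     # synonymous
    raw_record(rsid = "rs6", alt_codon = "AAC", alt_aa = "N"),     # synonymous
    raw_record(rsid = "rs7", ref_codon = "TAT", alt_codon = "TAA",
               codon_change_pos = 3, ref_aa = "Y", alt_aa = "*"),  # nonsense
    do.call(rbind, lapply(8:17, function(i) {
      raw_record(rsid = paste0("rs", i), gene = sample(c("AQP1", "AQP4"), 1),
                 residue_index = i)
    }))
  )
  res <- apply_snp_filters(raws)
  expect_equal(res$report$n_input, 20)
  expect_equal(res$report$n_duplicates_removed, 3)
  expect_equal(res$report$n_deprecated_removed, 2)
  expect_equal(res$report$n_synonymous_removed, 2)
  expect_equal(res$report$n_nonsense_removed, 1)
  expect_equal(res$report$n_kept, 12)
  with(res$report, expect_equal(
    n_kept + n_duplicates_removed + n_deprecated_removed +
      n_synonymous_removed + n_nonsense_removed + n_invalid_removed,
    n_input))

  # kept records satisfy the genetic-code invariants
  expect_true(all(translate_codon(res$variants$ref_codon) ==
                    res$variants$ref_aa))
  expect_true(all(translate_codon(res$variants$alt_codon) ==
                    res$variants$alt_aa))
  expect_true(all(grepl("^dbAQPSNP-AQP[0-9]+-[0-9]{5}$", res$variants$db_id)))

  # idempotence: refiltering the kept set keeps everything
  again <- apply_snp_filters(res$variants[, RAW_SNP_FIELDS[RAW_SNP_FIELDS != "deprecated"]] |>
                               transform(deprecated = FALSE))
  expect_equal(again$report$n_kept, res$report$n_kept)
  expect_equal(again$variants$rsid, res$variants$rsid)

  empty <- apply_snp_filters(raws[0, ])
  expect_equal(empty$report$n_input, 0)
  expect_equal(empty$report$n_kept, 0)
  expect_equal(nrow(empty$variants), 0)
})
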