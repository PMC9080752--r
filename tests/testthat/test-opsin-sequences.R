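test_that("translation follows the standard genetic code", {
  expect_equal(translate_cds("ATG"), "M")
  expect_equal(translate_cds("ATGAAATAA"), "MK")  # trailing stop trimmed
  # against an independent codon lookup, many random CDSs
  set.seed(42)
  for (i in 1:10) {
    codons <- sample(names(codon_table()), 20, replace = TRUE)
    cds <- paste(codons, collapse = "")
    oracle <- translate_oracle(cds)
    if (grepl("\\*", substr(oracle, 1, 19))) {
      expect_error(translate_cds(cds), "internal stop")
    } else {
      expected <- sub("\\*$", "", oracle)
      expect_equal(translate_cds(cds), expected)
    }
  }
})

test_that("translation rejects malformed input and handles N", {
  expect_error(translate_cds("ATGTA"), "multiple of 3")
  expect_error(translate_cds("ATGTAAAAA"), "codon index 2")
  expect_equal(translate_cds("ATGANT"), "MX")
})

test_that("pairwise alignment is a maximal-score global alignment", {
  # identity
  aln <- align_pair("MKV", "MKV")
  expect_equal(nrow(aln), 3)
  expect_false(any(aln$query_res == "-" | aln$ref_res == "-"))
  # one gap opposite K (exhaustive enumeration oracle)
  aln2 <- align_pair("MKV", "MV")
  expect_equal(attr(aln2, "score"), brute_force_align_score("MKV", "MV"))
  expect_equal(alignment_score(aln2), attr(aln2, "score"))
  expect_equal(aln2$query_res, c("M", "K", "V"))
  expect_equal(aln2$ref_res, c("M", "-", "V"))
  # gap opposite E, maximal BLOSUM62 score (brute force over monotone
  # alignments)
  aln3 <- align_pair("ACDEFG", "ACDFG")
  expect_equal(attr(aln3, "score"),
               brute_force_align_score("ACDEFG", "ACDFG"))
  expect_equal(aln3$ref_res[aln3$query_res == "E"], "-")
  # random short pairs achieve the brute-force optimum
  for (i in 1:5) {
    a <- random_aa(4, seed = i); b <- random_aa(3, seed = 100 + i)
    expect_equal(attr(align_pair(a, b), "score"),
                 brute_force_align_score(a, b))
  }
  expect_error(align_pair("MKB", "MKV"), "non-standard")
})

test_that("self-alignment has no gaps and full identity", {
  for (i in 1:5) {
    a <- random_aa(30, seed = i)
    aln <- align_pair(a, a)
    expect_false(any(aln$query_res == "-"))
    expect_equal(percent_identity(a, a), 1.0)
  }
})

test_that("bovine numbering labels reference residues 1..348", {
  bov <- bovine_rhodopsin()
  aln <- assign_bovine_numbering(bov)
  expect_equal(aln$bovine_site, 1:348)
  expect_equal(aln$query_res[aln$bovine_site == 296], "K")
  expect_false(attr(aln, "low_coverage"))
  # repeated runs give identical site maps (determinism)
  expect_identical(bovine_site_map(bov), bovine_site_map(bov))
})

test_that("a deletion before site 100 shifts the query index by one", {
  bov <- bovine_rhodopsin()
  del <- paste0(substr(bov, 1, 49), substr(bov, 51, 348))  # drop residue 50
  map <- bovine_site_map(del)
  expect_equal(map[100], 99)
  expect_true(is.na(map[50]))
  expect_equal(map[348], 347)
})

test_that("low bovine coverage is flagged for non-opsin queries", {
  q <- random_aa(30, seed = 9)
  expect_warning(aln <- assign_bovine_numbering(q), "covers only")
  expect_true(attr(aln, "low_coverage"))
})

test_that("substitution detection recovers planted differences exactly", {
  ref <- opsin_sequence("ref", "RH1", amino_acids = bovine_rhodopsin())
  expect_equal(nrow(detect_substitutions(ref, ref)), 0)
  v <- make_opsin_variant(ref, data.frame(bovine_site = c(299, 164),
                                          to = c("S", "S")))
  subs <- detect_substitutions(v$sequence, ref)
  expect_equal(subs$bovine_site, c(164, 299))  # sorted
  expect_equal(subs, data.frame(bovine_site = c(164L, 299L),
                                from = c("A", "A"), to = c("S", "S")))
  # matches the generator's ledger
  led <- v$ledger$truth$planted
  expect_setequal(paste(subs$bovine_site, subs$to),
                  paste(led$bovine_site, led$to))
  # mirror symmetry
  rev_subs <- detect_substitutions(ref, v$sequence)
  expect_equal(rev_subs$bovine_site, subs$bovine_site)
  expect_equal(rev_subs$from, subs$to)
  expect_equal(rev_subs$to, subs$from)
})

test_that("percent identity counts only comparable columns", {
  expect_equal(percent_identity("MKVW", "MKVW"), 1.0)
  expect_equal(percent_identity("WWWW", "GGGG"), 0.0)
  # 348-residue pair differing at 6 sites: 342/348
  ref <- opsin_sequence("ref", "RH2", amino_acids = bovine_rhodopsin())
  v <- make_opsin_variant(ref, data.frame(
    bovine_site = c(88, 97, 112, 151, 185, 266),
    to = c("C", "A", "V", "S", "T", "V")))
  expect_equal(percent_identity(v$sequence, ref), 342 / 348)
  expect_equal(round(100 * percent_identity(v$sequence, ref), 1), 98.3)
  # X is excluded from numerator and denominator
  expect_equal(percent_identity("MKXV", "MKWV"), 1.0)
})

test_that("transmembrane predicate matches the configured ranges", {
  expect_true(in_transmembrane(296))
  expect_false(in_transmembrane(1))
  tm <- bovine_tm_ranges()
  expect_equal(sum(in_transmembrane(1:348)), sum(tm$end - tm$start + 1))
  expect_error(in_transmembrane(349), "1..348")
  expect_error(in_transmembrane(0), "1..348")
})

test_that("FASTA round-trip preserves sequences and class annotation", {
  tmp <- tempfile(fileext = ".fasta")
  seqs <- list(
    opsin_sequence("q1", "RH2", amino_acids = random_aa(75, seed = 1)),
    opsin_sequence("q2", "LWS", amino_acids = random_aa(61, seed = 2)))
  write_opsin_fasta(seqs, tmp)
  back <- read_opsin_fasta(tmp)
  expect_equal(length(back), 2)
  expect_equal(back[[1]]$id, "q1")
  expect_equal(back[[1]]$opsin_class, "RH2")
  expect_equal(back[[2]]$amino_acids, seqs[[2]]$amino_acids)
})

test_that("opsin_sequence validates its invariants", {
  expect_error(opsin_sequence("x", "RH1", amino_acids = ""), "non-empty")
  expect_error(opsin_sequence("x", "RH1", amino_acids = "MK-V"), "gap")
  s <- opsin_sequence("x", "RH1", nucleotide_cds = "ATGAAAGTT")
  expect_equal(s$amino_acids, "MKV")
  expect_error(opsin_sequence("x", "RH1", amino_acids = "MKW",
                              nucleotide_cds = "ATGAAAGTT"),
               "does not equal")
})
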