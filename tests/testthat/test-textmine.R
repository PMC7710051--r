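test_that("token filter implements the all-caps-with-letter rule", {
  expect_equal(filter_tokens("The IGF1 and CAST genes impact pigs."),
               c("IGF1", "CAST"))
  expect_equal(filter_tokens(""), character(0))
  ## hyphen splits; a pure number and a single letter are rejected
  expect_equal(filter_tokens("A 2020 DNA-SEQ run"), c("DNA", "SEQ"))
  ## mixed case never matches
  expect_equal(filter_tokens("Cast CAst caST"), character(0))
  ## repeats kept in document order
  expect_equal(filter_tokens("SCD then CAST then SCD"),
               c("SCD", "CAST", "SCD"))
})

test_that("mine_genes counts lexicon hits, maps aliases, records provenance", {
  lex <- toy_lexicon()
  corpus <- abstract_corpus(
    c("d1", "d2"),
    c("SCD expression in muscle", "no symbols here"),
    c("SCD and CAST and SCD. TIAB token and GDF8 ignored? GDF8 maps.",
      "CAST only. impact pigs."))
  mined <- mine_genes(corpus, lex)
  expect_equal(mined$freq[["SCD"]], 3L) # 1 title + 2 abstract occurrences
  expect_equal(mined$freq[["CAST"]], 2L)
  expect_equal(mined$freq[["MSTN"]], 2L) # via the GDF8 alias
  expect_false("TIAB" %in% names(mined$freq))
  expect_setequal(mined$provenance$CAST, c("d1", "d2"))
  ## article mode counts distinct documents
  byart <- mine_genes(corpus, lex, count_mode = "articles")
  expect_equal(byart$freq[["SCD"]], 1L)
  expect_equal(byart$freq[["CAST"]], 2L)
  ## empty corpus is fine
  empty <- abstract_corpus(character(0), character(0), character(0))
  expect_length(mine_genes(empty, lex)$freq, 0)
})

test_that("mined frequencies equal planted frequencies on random corpora", {
  lex <- toy_lexicon()
  for (s in 1:10) {
    set.seed(s)
    syms <- sample(lex$symbols, sample(2:5, 1))
    planted <- setNames(sample(1:12, length(syms), replace = TRUE), syms)
    res <- simulate_corpus(lex, planted, n_docs = sample(5:25, 1), seed = s)
    mined <- mine_genes(res$corpus, lex)
    expected <- setNames(as.integer(planted), names(planted))
    nm <- sort(names(planted))
    expect_identical(mined$freq[nm], expected[nm])
    expect_false(any(c("IMPACT", "PIGS") %in% names(mined$freq)))
  }
})

test_that("adding a document never decreases any frequency", {
  lex <- toy_lexicon()
  res <- simulate_corpus(lex, c(SCD = 4, LEP = 2), n_docs = 8, seed = 5)
  base <- mine_genes(res$corpus, lex)$freq
  bigger <- rbind(res$corpus,
                  abstract_corpus("extra", "SCD again", "with CAPN1 twice CAPN1"))
  grown <- mine_genes(bigger, lex)$freq
  for (sym in names(base)) expect_gte(grown[[sym]], base[[sym]])
})

test_that("top_frequency_table ranks by frequency with alphabetical ties", {
  mined <- structure(list(freq = c(B = 3L, A = 3L, C = 1L),
                          provenance = list(), trait = NA, count_mode = "occurrences"),
                     class = "mined_gene_set")
  top <- top_frequency_table(mined, 2)
  expect_equal(top$symbol, c("A", "B"))
  expect_equal(top$freq, c(3L, 3L))
  expect_equal(nrow(top_frequency_table(mined, 99)), 3)
})

test_that("select_snps maps gene and intergenic intervals to the tm set", {
  ## 14 SNPs at positions 100..1400; gene A spans 500..1000 (SNPs 5..10),
  ## gene B starts at 1500 (off the SNP grid), so intergenic A-B covers
  ## positions 1001..1499 (SNPs 11..14)
  panel <- toy_panel(matrix(rep(c(0L, 1L, 2L), length.out = 3 * 14), 3, 14))
  ann <- gene_annotation(c("GENEA", "GENEB"), "chr1", c(500, 1500),
                         c(1000, 1600))
  part_on <- select_snps("GENEA", ann, panel, include_intergenic = TRUE)
  expect_identical(part_on$tm, 5:14)
  part_off <- select_snps("GENEA", ann, panel, include_intergenic = FALSE)
  expect_identical(part_off$tm, 5:10)
  ## mining gene B pulls the same intergenic stretch from the other side
  part_b <- select_snps("GENEB", ann, panel, include_intergenic = TRUE)
  expect_identical(part_b$tm, 11:14)
  ## flank cap restricts the intergenic reach (0.2 kb from gene A's end)
  capped <- select_snps("GENEA", ann, panel, include_intergenic = TRUE,
                        flank_cap_kb = 0.2)
  expect_identical(capped$tm, 5:12)
  ## empty mined set: everything is exp
  none <- select_snps(character(0), ann, panel)
  expect_identical(none$tm, integer(0))
  expect_identical(none$exp, 1:14)
  ## a mined gene missing from the annotation warns and is skipped
  expect_warning(select_snps(c("GENEA", "GHOST1"), ann, panel), "absent")
})

test_that("partitions are exact complements for arbitrary inputs", {
  sim <- simulate_genotypes(20, 60, n_chrom = 2, seed = 8)
  for (s in 1:5) {
    set.seed(s)
    tm <- sample(60, sample(0:60, 1))
    part <- snp_partition(sim$panel$map$id, tm = tm)
    expect_identical(sort(c(part$tm, part$exp)), 1:60)
    expect_length(intersect(part$tm, part$exp), 0)
  }
})
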