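test_that("codons are read in frame, remnants dropped, stops excluded", {
  tab <- count_codons(seqs = c(g = "ATGAAATAA"))
  expect_equal(tab$count[tab$codon == "ATG"], 1L)
  expect_equal(tab$count[tab$codon == "AAA"], 1L)
  expect_equal(tab$count[tab$codon == "TAA"], 0L) # stop excluded
  expect_equal(attr(tab, "total_codons"), 2L)
  # trailing 2-nt remnant dropped
  tab2 <- count_codons(seqs = c(g = "ATGAAATA"))
  expect_equal(attr(tab2, "total_codons"), 2L)
})

test_that("the vertebrate mitochondrial code drives translation classes", {
  code <- count_codons(seqs = c(g = "ATGAAA"))
  expect_equal(code$aa[code$codon == "AGA"], "*")
  expect_equal(code$aa[code$codon == "AGG"], "*")
  expect_equal(code$aa[code$codon == "ATA"], "M")
  expect_equal(code$aa[code$codon == "TGA"], "W")
})

test_that("RSCU follows the family formula exactly", {
  # family of four with counts (4, 2, 1, 1) -> RSCU (2.0, 1.0, 0.5, 0.5)
  s <- paste0(strrep("GCA", 4), strrep("GCC", 2), "GCG", "GCT")
  tab <- count_codons(seqs = c(g = paste0("ATG", s)))
  ala <- tab[tab$aa == "A", ]
  expect_equal(
    setNames(ala$rscu, ala$codon)[c("GCA", "GCC", "GCG", "GCT")],
    c(GCA = 2, GCC = 1, GCG = 0.5, GCT = 0.5)
  )
  # equal counts within a family -> all 1
  eq <- count_codons(seqs = c(g = paste0("ATG", "GGA", "GGC", "GGG", "GGT")))
  expect_equal(eq$rscu[eq$aa == "G"], rep(1, 4))
})

test_that("report mode pins Met-ATG and Trp-TGG at RSCU 1; code mode does not", {
  s <- c(g = paste0("ATG", "ATG", "ATA", "TGG", "TGA", "TGA"))
  rep_mode <- count_codons(seqs = s, family_mode = "report")
  expect_equal(rep_mode$rscu[rep_mode$codon == "ATG"], 1)
  expect_equal(rep_mode$rscu[rep_mode$codon == "TGG"], 1)
  expect_equal(rep_mode$rscu[rep_mode$codon == "ATA"], 1)
  code_mode <- count_codons(seqs = s, family_mode = "code")
  # {ATA, ATG} family with counts (1, 2): RSCU 2/3 and 4/3
  expect_equal(code_mode$rscu[code_mode$codon == "ATG"], 4 / 3)
  expect_equal(code_mode$rscu[code_mode$codon == "ATA"], 2 / 3)
  expect_equal(code_mode$rscu[code_mode$codon == "TGG"], 2 / 3)
})

test_that("RSCU sums to family size and is scale invariant", {
  anc <- ancestor_fixture()
  tab <- count_codons(anc$sequence, anc$annotation)
  sums <- dplyr::count(
    dplyr::filter(tab, .data$aa != "*", !is.na(.data$rscu)),
    .data$family,
    wt = .data$rscu, name = "rscu_sum"
  )
  fam_sizes <- dplyr::count(dplyr::filter(tab, .data$aa != "*"),
                            .data$family)
  m <- dplyr::left_join(sums, fam_sizes, by = "family")
  expect_equal(m$rscu_sum, as.numeric(m$n))
  # duplicating every gene leaves RSCU unchanged
  seqs <- extract_gene_seq(anc$sequence,
                           dplyr::filter(tibble::as_tibble(anc$annotation),
                                         .data$cls == "PCG"))
  tab2 <- count_codons(seqs = c(seqs, seqs))
  expect_equal(tab2$rscu, tab$rscu)
})

test_that("uniform codon usage yields RSCU near 1 everywhere", {
  set.seed(11)
  sense <- setdiff(
    names(Biostrings::getGeneticCode("SGC1")),
    c("TAA", "TAG", "AGA", "AGG")
  )
  s <- paste(sample(sense, 10000, replace = TRUE), collapse = "")
  tab <- count_codons(seqs = c(g = s), family_mode = "code")
  vals <- tab$rscu[!is.na(tab$rscu)]
  expect_true(all(abs(vals - 1) < 0.25)) # sampling error at n = 10,000
  expect_lt(mean(abs(vals - 1)), 0.08)
})

test_that("amino-acid percentages sum to 100 and merge Leu/Ser families", {
  tab <- count_codons(seqs = c(g = "ATGAAA"))
  prof <- amino_acid_profile(tab)
  expect_equal(sum(prof$pct), 100)
  expect_setequal(prof$aa3, c("Met", "Lys"))
  expect_equal(prof$pct, c(50, 50))
  # CTA (Leu, CUN family) and TTA (Leu, UUR family) pool into one Leu row
  tab2 <- count_codons(seqs = c(g = paste0("ATG", "CTA", "TTA", "TCA")))
  prof2 <- amino_acid_profile(tab2)
  expect_equal(prof2$pct[prof2$aa3 == "Leu"], 50)
  anc <- ancestor_fixture()
  prof3 <- amino_acid_profile(count_codons(anc$sequence, anc$annotation))
  expect_equal(sum(prof3$pct), 100)
})

test_that("generator codon frequencies are recovered from counts", {
  # genes drawn from a known codon distribution: recovered percentages track
  # the sampling distribution closely
  set.seed(21)
  probs <- c(GCC = 0.5, AAA = 0.3, TTC = 0.2)
  s <- paste(sample(names(probs), 6000, replace = TRUE, prob = probs),
             collapse = "")
  tab <- count_codons(seqs = c(g = s))
  got <- tab$count[match(names(probs), tab$codon)] / sum(tab$count)
  expect_true(all(abs(got - probs) < 0.02))
})

test_that("pooled and mean combinations of codon tables both normalize", {
  anc <- ancestor_fixture()
  evo <- evolve_genomes(anc, sim_config(seed = 101L,
                                        branch_lengths = c(a = 0.02,
                                                           b = 0.05)))
  tabs <- lapply(evo$genomes, function(g) count_codons(g, evo$annotation))
  pooled <- combine_codon_tables(tabs, "pooled")
  avg <- combine_codon_tables(tabs, "mean")
  expect_equal(sum(pooled$count), sum(vapply(tabs, function(t) sum(t$count),
                                             numeric(1))))
  expect_equal(pooled$rscu[pooled$codon == "ATG"], 1)
  expect_equal(avg$rscu[avg$codon == "ATG"], 1)
})
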