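test_that("the default ancestor realizes the full gene architecture", {
  anc <- ancestor_fixture()
  a <- anc$annotation
  expect_equal(anc$sequence$length, 16571L)
  expect_equal(nrow(a), 38L)
  expect_equal(sum(a$cls != "CR"), 37L)
  # architecture conservation invariant holds on generated data
  led <- build_ledger(a)
  expect_equal(sum(a$size) + sum(led$intergenic), genome_length(a))
  expect_equal(led$intergenic[led$upstream == "ATP8"], -7L)
  expect_equal(led$intergenic[led$upstream == "ND4L"], -7L)
})

test_that("every generated PCG is a clean reading frame", {
  anc <- ancestor_fixture()
  pcg <- dplyr::filter(tibble::as_tibble(anc$annotation), cls == "PCG")
  seqs <- extract_gene_seq(anc$sequence, pcg)
  stops <- c("TAA", "TAG", "AGA", "AGG")
  code <- Biostrings::getGeneticCode("SGC1")
  for (g in names(seqs)) {
    s <- seqs[[g]]
    expect_true(substr(s, 1, 3) %in% c("ATG", "GTG"), label = g)
    ncod <- nchar(s) %/% 3
    cods <- substring(s, 3 * seq_len(ncod) - 2, 3 * seq_len(ncod))
    internal <- cods[seq_len(ncod - 1)]
    expect_false(any(internal %in% stops), label = g)
    if (nchar(s) %% 3 == 0) {
      expect_true(cods[ncod] %in% stops, label = g)
    }
  }
  expect_equal(substr(seqs[["COI"]], 1, 3), "GTG")
})

test_that("composition lands within a percentage point of the targets", {
  anc <- ancestor_fixture()
  comp <- summarize_partitions(anc$sequence, anc$annotation)
  whole <- comp[comp$partition == "mitogenome", ]
  expect_lt(abs(whole$at_content - 57.7), 1)
  expect_lt(whole$gc_skew, 0) # negative GC-skew, AT-rich genome
  cr <- comp[comp$partition == "CR", ]
  expect_lt(abs(cr$at_content - 68.74), 3.5) # CSB implants perturb the CR
})

test_that("generation is byte-identical under a fixed seed", {
  a1 <- make_ancestor(sim_config(seed = 77L))
  a2 <- make_ancestor(sim_config(seed = 77L))
  expect_identical(a1$sequence$residues, a2$sequence$residues)
  expect_identical(
    tibble::as_tibble(a1$annotation),
    tibble::as_tibble(a2$annotation)
  )
  a3 <- make_ancestor(sim_config(seed = 78L))
  expect_false(identical(a1$sequence$residues, a3$sequence$residues))
})

test_that("implanted control-region features are recorded as truth and detectable", {
  cfg <- sim_config(seed = 91L,
                    cr_repeat = list(motif = "ACGTTGCAACGTTGCAA"[[1]],
                                     copies = 2.2))
  cfg$cr_repeat$motif <- substr("ACGTTGCAACGTTGCAA", 1, 17)
  anc <- make_ancestor(cfg)
  expect_equal(nrow(anc$truth$csb), 4L)
  cr_row <- dplyr::filter(tibble::as_tibble(anc$annotation), cls == "CR")
  cr_seq <- extract_gene_seq(anc$sequence, cr_row)[[1]]
  hits <- scan_csb(cr_seq, csb_seed_motifs(), max_mismatch = 0)
  expect_true(all(hits$found))
  expect_equal(hits$start, anc$truth$csb$start)
  rep_truth <- anc$truth$cr_repeat
  expect_equal(rep_truth$period, 17L)
  found <- find_tandem_repeats(cr_seq)
  hit <- found[found$period == 17L, ]
  expect_equal(nrow(hit), 1L)
  expect_lte(abs(hit$copies - 2.2), 0.1)
  expect_equal(hit$start, rep_truth$start)
})

test_that("evolution respects branch lengths, omega and determinism", {
  anc <- ancestor_fixture()
  cfg0 <- sim_config(seed = 101L, branch_lengths = c(z = 0))
  evo0 <- evolve_genomes(anc, cfg0)
  expect_identical(evo0$genomes$z$residues, anc$sequence$residues)

  cfg <- sim_config(seed = 101L, branch_lengths = c(a = 0.03, b = 0.06))
  evo1 <- evolve_genomes(anc, cfg)
  evo2 <- evolve_genomes(anc, cfg)
  expect_identical(evo1$genomes$a$residues, evo2$genomes$a$residues)
  # more proposals accumulate more divergence
  p_a <- pair_diffs(anc$sequence$residues, evo1$genomes$a$residues)
  p_b <- pair_diffs(anc$sequence$residues, evo1$genomes$b$residues)
  expect_gt(p_b$p_distance, p_a$p_distance)
  expect_gt(p_a$p_distance, 0)
  # evolved PCGs still translate cleanly
  cc <- call_codons(evo1$genomes$b, evo1$annotation)
  expect_true(all(nchar(cc$start_codon) == 3L))
  pcg <- dplyr::filter(tibble::as_tibble(evo1$annotation), cls == "PCG")
  seqs <- extract_gene_seq(evo1$genomes$b, pcg)
  stops <- c("TAA", "TAG", "AGA", "AGG")
  for (g in names(seqs)) {
    ncod <- nchar(seqs[[g]]) %/% 3
    cods <- substring(seqs[[g]], 3 * seq_len(ncod) - 2, 3 * seq_len(ncod))
    expect_false(any(cods[seq_len(ncod - 1)] %in% stops), label = g)
  }
  expect_true(all(evo1$truth$accepted <= evo1$truth$proposed))
})

test_that("neutral branch divergence is recovered by K2P within 3 SE", {
  # rRNA partition evolves without coding constraints: compare realized
  # divergence there against the K2P estimate
  est <- vapply(1:10, function(s) {
    pr <- simulate_k80_pair(10000, 0.06, kappa = 4, seed = 300L + s)
    k2p_distance(pair_diffs(pr[["x"]], pr[["y"]]))
  }, numeric(1))
  se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - 0.06), 3 * se + 1e-8)
})
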