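test_that("block consensus is majority rule with per-row mismatch counts", {
  base <- "ACGTACGTACGTACGTAC" # 18 bp window
  rows <- c(r1 = base, r2 = base, r3 = base, r4 = base)
  cons <- build_csb_consensus(rows, list("CSB-D" = c(1, 18)))
  expect_equal(cons$consensus, base)
  expect_equal(unname(cons$mismatches[[1]]), rep(0L, 4))
  # one row carrying two substitutions is flagged as the variant
  ch <- strsplit(base, "")[[1]]
  ch[c(3, 10)] <- c("T", "A")
  rows["r2"] <- paste(ch, collapse = "")
  cons2 <- build_csb_consensus(rows, list("CSB-D" = c(1, 18)))
  expect_equal(cons2$consensus, base) # majority unaffected
  mm <- cons2$mismatches[[1]]
  expect_equal(unname(mm["r2"]), 2L)
  expect_equal(unname(mm[c("r1", "r3", "r4")]), rep(0L, 3))
  expect_error(build_csb_consensus(rows, list(b = c(1, 99))),
               "outside alignment")
  expect_error(build_csb_consensus(rows[1:2], list(b = c(1, 5))),
               "at least three")
})

test_that("consensus blocks are recovered from a noisy 24-row alignment", {
  set.seed(17)
  truth <- random_dna(400)
  windows <- list("CSB-D" = c(50, 67), "CSB-1" = c(120, 140),
                  "CSB-2" = c(200, 217), "CSB-3" = c(300, 319))
  rows <- vapply(1:24, function(i) {
    ch <- strsplit(truth, "")[[1]]
    pos <- sample(400, 1) # at most one substitution per row
    ch[pos] <- sample(setdiff(c("A", "C", "G", "T"), ch[pos]), 1)
    paste(ch, collapse = "")
  }, character(1))
  names(rows) <- paste0("sp", 1:24)
  cons <- build_csb_consensus(rows, windows)
  for (i in seq_len(nrow(cons))) {
    expect_equal(cons$consensus[i],
                 substr(truth, cons$start[i], cons$end[i]))
  }
})

test_that("CSB scanning finds exact and mismatched copies and reports absences", {
  set.seed(23)
  motifs <- csb_seed_motifs()
  cr <- paste0(
    random_dna(80), motifs[["CSB-D"]],
    random_dna(60), motifs[["CSB-1"]],
    random_dna(60), motifs[["CSB-2"]],
    random_dna(60), motifs[["CSB-3"]],
    random_dna(40)
  )
  hits <- scan_csb(cr, motifs, max_mismatch = 2)
  expect_true(all(hits$found))
  expect_equal(hits$mismatches, rep(0L, 4))
  expect_equal(hits$block, c("CSB-D", "CSB-1", "CSB-2", "CSB-3"))
  expect_true(all(diff(hits$start) > 0)) # D < 1 < 2 < 3 along the CR
  expect_equal(hits$start[1], 81L)

  # two substitutions within the allowance are reported with their count
  ch <- strsplit(cr, "")[[1]]
  ch[81:82] <- c("G", "G") # CSB-D starts TA...
  hits2 <- scan_csb(paste(ch, collapse = ""), motifs, max_mismatch = 4)
  expect_true(hits2$found[hits2$block == "CSB-D"])
  expect_equal(hits2$mismatches[hits2$block == "CSB-D"], 2L)

  # deleting a block produces an explicit absence record
  no_d <- paste0(substr(cr, 1, 80), substr(cr, 99, nchar(cr)))
  hits3 <- scan_csb(no_d, motifs, max_mismatch = 2)
  expect_false(hits3$found[hits3$block == "CSB-D"])
  expect_true(is.na(hits3$start[hits3$block == "CSB-D"]))
})

test_that("CSB hit positions shift exactly with flanking padding", {
  set.seed(29)
  motifs <- csb_seed_motifs()[1:2]
  core <- paste0(random_dna(50), motifs[[1]], random_dna(50), motifs[[2]],
                 random_dna(30))
  pad <- random_dna(37)
  h0 <- scan_csb(core, motifs, max_mismatch = 1)
  h1 <- scan_csb(paste0(pad, core), motifs, max_mismatch = 1)
  expect_equal(h1$start, h0$start + 37L)
  expect_equal(h1$end, h0$end + 37L)
})

test_that("pure tandem arrays are read off exactly", {
  out <- find_tandem_repeats("ATATATATAT", min_score = 10)
  expect_equal(out$period, 2L)
  expect_equal(out$copies, 5.0)
  expect_equal(out$consensus, "AT")
  expect_equal(out$pct_match, 100)
})

test_that("an implanted 17-bp repeat at 2.2 copies is detected", {
  set.seed(37)
  motif <- random_dna(17)
  span <- round(17 * 2.2)
  unit <- strrep(motif, 3)
  cr <- paste0(random_dna(300), substr(unit, 1, span), random_dna(563))
  out <- find_tandem_repeats(cr)
  expect_equal(nrow(out), 1L)
  expect_equal(out$period, 17L)
  expect_lte(abs(out$copies - 2.2), 0.1)
  expect_equal(out$consensus, motif)
  # span/period/copies consistency
  expect_lte(abs((out$end - out$start + 1) - out$period * out$copies),
             out$period)
})

test_that("repeat calls mirror under reverse complement", {
  set.seed(41)
  motif <- random_dna(11)
  cr <- paste0(random_dna(100), strrep(motif, 3), random_dna(100))
  fwd <- find_tandem_repeats(cr)
  rc <- find_tandem_repeats(
    extract_gene_seq(cr, tibble::tibble(gene = "x", start = 1L,
                                        end = nchar(cr), strand = "L"))
  )
  expect_equal(nrow(fwd), 1L)
  expect_equal(rc$period, fwd$period)
  expect_equal(rc$copies, fwd$copies)
  expect_equal(rc$start, nchar(cr) - fwd$end + 1L)
  expect_equal(rc$end, nchar(cr) - fwd$start + 1L)
})

test_that("random sequence rarely triggers long-period repeat calls", {
  hits <- vapply(1:100, function(s) {
    set.seed(s)
    out <- find_tandem_repeats(random_dna(900))
    any(out$period >= 10 & out$copies >= 1.9)
  }, logical(1))
  expect_lte(mean(hits), 0.05)
})
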