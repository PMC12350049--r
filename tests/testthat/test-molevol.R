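test_that("pairwise transition/transversion tallies are exact", {
  pd <- pair_diffs("AAAA", "AAAA")
  expect_equal(c(pd$sites, pd$s, pd$v), c(4L, 0L, 0L))
  pd <- pair_diffs("AG", "GG")
  expect_equal(c(pd$s, pd$v), c(1L, 0L))
  pd <- pair_diffs("AC", "AA")
  expect_equal(c(pd$s, pd$v), c(0L, 1L))
  # gaps and ambiguities excluded pairwise
  pd <- pair_diffs("A-CN", "AACC")
  expect_equal(pd$sites, 2L)
  expect_error(pair_diffs("--", "AA"), "zero comparable sites")
  # exact recovery of implanted counts on a 1,000-site pair
  set.seed(3)
  x <- strsplit(random_dna(1000), "")[[1]]
  y <- x
  ts <- c(A = "G", G = "A", C = "T", T = "C")
  tv <- c(A = "C", G = "T", C = "G", T = "A")
  is_pos <- sample(1000, 60)
  y[is_pos[1:40]] <- ts[y[is_pos[1:40]]]
  y[is_pos[41:60]] <- tv[y[is_pos[41:60]]]
  pd <- pair_diffs(paste(x, collapse = ""), paste(y, collapse = ""))
  expect_equal(c(pd$s, pd$v), c(40L, 20L))
})

test_that("K2P matches the closed form and an independent implementation", {
  expect_equal(k2p_distance(0, 0), 0)
  # direct numeric evaluation of the formula
  P <- 0.1
  Q <- 0.05
  expect_equal(k2p_distance(P, Q),
               -0.5 * log((1 - 2 * P - Q) * sqrt(1 - 2 * Q)))
  # against ape::dist.dna on simulated pairs
  for (seed in 1:3) {
    pr <- simulate_k80_pair(4000, 0.12, kappa = 4, seed = seed)
    pd <- pair_diffs(pr[["x"]], pr[["y"]])
    bin <- ape::as.DNAbin(rbind(
      x = strsplit(tolower(pr[["x"]]), "")[[1]],
      y = strsplit(tolower(pr[["y"]]), "")[[1]]
    ))
    expect_equal(k2p_distance(pd), as.numeric(ape::dist.dna(bin, "K80")),
                 tolerance = 1e-12)
  }
  # saturation -> NA with warning
  expect_warning(d <- k2p_distance(0.5, 0.3), "saturated")
  expect_true(is.na(d))
})

test_that("F84 matches ape and collapses toward K2P at equal frequencies", {
  for (seed in 4:6) {
    pr <- simulate_k80_pair(4000, 0.15, kappa = 4, seed = seed)
    pd <- pair_diffs(pr[["x"]], pr[["y"]])
    m <- rbind(strsplit(pr[["x"]], "")[[1]], strsplit(pr[["y"]], "")[[1]])
    bf <- vapply(c("A", "C", "G", "T"), function(b) mean(m == b), numeric(1))
    bin <- ape::as.DNAbin(rbind(x = tolower(m[1, ]), y = tolower(m[2, ])))
    expect_equal(f84_distance(pd, base_freq = bf),
                 as.numeric(ape::dist.dna(bin, "F84")), tolerance = 1e-12)
  }
  # identical sequences -> 0; equal frequencies -> agrees with K2P closed form
  expect_equal(f84_distance(0, 0), 0)
  P <- 0.08
  Q <- 0.04
  expect_equal(f84_distance(P, Q, base_freq = rep(0.25, 4)),
               k2p_distance(P, Q), tolerance = 1e-9)
})

test_that("K2P dominates the p-distance with equality only at zero", {
  set.seed(8)
  for (d in c(0.02, 0.1, 0.25)) {
    pr <- simulate_k80_pair(3000, d, kappa = 4, seed = round(1000 * d))
    pd <- pair_diffs(pr[["x"]], pr[["y"]])
    expect_gt(k2p_distance(pd), pd$p_distance)
  }
  pd0 <- pair_diffs("ACGT", "ACGT")
  expect_equal(k2p_distance(pd0), pd0$p_distance)
})

test_that("simulated K2P distances are recovered within 3 standard errors", {
  d_true <- 0.08
  reps <- 20L
  L <- 10000L
  est <- vapply(seq_len(reps), function(s) {
    pr <- simulate_k80_pair(L, d_true, kappa = 4, seed = 500L + s)
    k2p_distance(pair_diffs(pr[["x"]], pr[["y"]]))
  }, numeric(1))
  se <- sd(est) / sqrt(reps)
  expect_lt(abs(mean(est) - d_true), 3 * se + 1e-8)
})

test_that("sliding pi is exact on hand-counted windows and flags truncation", {
  a <- strrep("A", 200)
  b <- paste0(strrep("A", 190), strrep("C", 10))
  prof <- sliding_pi(c(x = a, y = b), window = 200, step = 25)
  expect_equal(nrow(prof), 1L)
  expect_equal(prof$pi, 10 / 200)
  # all-identical rows -> 0 everywhere
  prof0 <- sliding_pi(c(x = strrep("ACGT", 100), y = strrep("ACGT", 100)))
  expect_true(all(prof0$pi == 0))
  # window longer than alignment -> single truncated window
  proft <- sliding_pi(c(x = "ACGTACGT", y = "ACGTACGA"), window = 200)
  expect_equal(nrow(proft), 1L)
  expect_true(proft$truncated)
  expect_equal(proft$pi, 1 / 8)
  expect_error(sliding_pi(c(x = "ACGT")), "at least two")
})

test_that("window partition of pi reconstructs the whole-alignment value", {
  anc <- ancestor_fixture()
  evo <- evolve_genomes(anc, sim_config(
    seed = 101L,
    branch_lengths = c(a = 0.02, b = 0.05, c = 0.08)
  ))
  aln <- vapply(evo$genomes, function(g) g$residues, character(1))
  aln <- vapply(aln, substr, character(1), start = 1L, stop = 4000L)
  prof <- sliding_pi(aln, window = 200, step = 200) # disjoint partition
  whole <- nucleotide_diversity(aln)
  expect_equal(sum(prof$pi * prof$sites) / sum(prof$sites), whole,
               tolerance = 1e-12)
  # the n/(n-1) flag scales pi exactly
  expect_equal(nucleotide_diversity(aln, corrected = TRUE),
               whole * 3 / 2)
})

test_that("a hypervariable insert is localized by the pi profile", {
  set.seed(31)
  core <- random_dna(1000)
  rows <- c(a = core, b = core, c = core, d = core)
  mut <- function(s, from, to) {
    ch <- strsplit(s, "")[[1]]
    idx <- seq(from, to)
    flip <- idx[runif(length(idx)) < 0.4]
    ch[flip] <- vapply(ch[flip], function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1)
    }, character(1))
    paste(ch, collapse = "")
  }
  rows[2:4] <- vapply(rows[2:4], mut, character(1), from = 401, to = 600)
  prof <- sliding_pi(rows, window = 200, step = 25)
  peak <- prof[which.max(prof$pi), ]
  expect_true(peak$start <= 600 && peak$end >= 401)
})

test_that("distance matrices are symmetric with group means equal to brute force", {
  aln <- c(
    a1 = "ACGTACGTACGTACGTACGT",
    a2 = "ACGTACGTACGTACGTACGA",
    b1 = "ACGTTCGTACGAACGTACGT",
    b2 = "ACGTTCGTACGAACGTACGA"
  )
  D <- distance_matrix(aln, model = "p")
  expect_true(isSymmetric(unclass(D)))
  expect_equal(diag(unclass(D)), setNames(rep(0, 4), names(aln)))
  groups <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B")
  gm <- group_distance_means(D, groups)
  brute_within_A <- D["a1", "a2"]
  brute_between <- mean(c(D["a1", "b1"], D["a1", "b2"],
                          D["a2", "b1"], D["a2", "b2"]))
  expect_equal(gm$mean_distance[gm$group_i == "A" & gm$group_j == "A"],
               brute_within_A)
  expect_equal(gm$mean_distance[gm$group_i == "A" & gm$group_j == "B"],
               brute_between)
  ov <- overall_distance_mean(D)
  expect_equal(ov$mean_distance, mean(D[lower.tri(D)]))
  # identical rows -> zero matrix
  D0 <- distance_matrix(c(x = "ACGT", y = "ACGT"))
  expect_true(all(D0 == 0))
})

test_that("saturation profiles rise with divergence", {
  aln <- c(
    s1 = simulate_k80_pair(3000, 0.01, seed = 71)[["y"]],
    s2 = simulate_k80_pair(3000, 0.01, seed = 71)[["x"]],
    s3 = simulate_k80_pair(3000, 0.01, seed = 72)[["x"]]
  )
  sat <- saturation_profile(aln)
  expect_equal(nrow(sat), 3L)
  expect_true(all(sat$f84 >= 0, na.rm = TRUE))
  # mean F84 never decreases as simulated divergence scales up
  mean_f84 <- vapply(c(0.02, 0.08, 0.2), function(d) {
    pr <- simulate_k80_pair(3000, d, kappa = 4, seed = round(100 * d))
    mean(saturation_profile(pr)$f84)
  }, numeric(1))
  expect_true(all(diff(mean_f84) > 0))
})
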