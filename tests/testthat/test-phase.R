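test_that("depth filtering trims outside the empirical 10th-90th percentiles", {
  s10 <- data.frame(ref = "r", pos = 1:10, depth = 1:10)
  kept <- depth_filter(s10)
  expect_equal(kept$depth, 2:9)

  flat <- data.frame(ref = "r", pos = 1:10, depth = rep(7, 10))
  expect_equal(nrow(depth_filter(flat)), 10L)

  set.seed(31)
  s1000 <- data.frame(ref = "r", pos = 1:1000,
                      depth = runif(1000, 0, 100))
  q <- unname(stats::quantile(s1000$depth, c(0.1, 0.9), type = 7))
  expect_equal(nrow(depth_filter(s1000)),
               sum(s1000$depth >= q[1] & s1000$depth <= q[2]))
})

test_that("truth-table polarization recovers construction truth exactly", {
  f1 <- simulate_f1(sim_config(seed = 8, genome_length = 2e5, theta = 0.05))
  truth <- f1$truth
  # VCF-style sites with alleles in arbitrary order
  set.seed(9)
  swap <- runif(nrow(truth)) < 0.5
  sites <- data.frame(
    ref = truth$ref, pos = truth$pos,
    allele1 = ifelse(swap, truth$alleleB, truth$alleleA),
    allele2 = ifelse(swap, truth$alleleA, truth$alleleB),
    depth = 30, stringsAsFactors = FALSE)
  pol <- polarize(sites, truth = truth)
  expect_true(all(pol$status == "polarized"))
  expect_equal(pol$alleleA, truth$alleleA)
  expect_equal(pol$alleleB, truth$alleleB)

  # a site whose alleles contradict the truth table is flagged
  sites$allele1[1] <- setdiff(c("A", "C", "G", "T"),
                              c(truth$alleleA[1], truth$alleleB[1]))[1]
  pol2 <- polarize(sites, truth = truth)
  expect_equal(pol2$status[1], "inconsistent")
  expect_equal(unname(attr(pol2, "diagnostics")["inconsistent"]), 1L)
})

test_that("PAF polarization resolves sites from cs tags", {
  # parent A aligned to assembly 'asm'; a substitution at 10 (*ag: assembly
  # base a, parent base g), a 2-bp query deletion at [40, 42), match elsewhere
  paf <- paste("parentA", 100, 0, 60, "+", "asm", 100, 0, 60, 58, 60, 60,
               "cs:Z::10*ag:29-cc:18", sep = "\t")
  sites <- data.frame(ref = "asm", pos = c(10, 45, 41, 80),
                      allele1 = c("A", "T", "A", "C"),
                      allele2 = c("G", "C", "G", "T"),
                      depth = 30, stringsAsFactors = FALSE)
  pol <- polarize(sites, paf = paf)
  expect_equal(pol$status, c("polarized", "polarized", "unpolarized",
                             "unpolarized"))
  # substitution: parent base G -> allele2 is parent A's
  expect_equal(pol$alleleA[1], "G")
  # match run: assembly allele (allele1) is parent A's
  expect_equal(pol$alleleA[2], "T")

  # a site covered by two alignments stays unpolarized
  paf2 <- c(paf, paste("parentA", 100, 0, 60, "+", "asm", 100, 5, 35, 30,
                       30, 60, "cs:Z::30", sep = "\t"))
  pol2 <- polarize(sites, paf = paf2)
  expect_equal(pol2$status[1], "unpolarized")
})

test_that("switch/mismatch decomposition matches the stated definitions", {
  perfect <- eval_one_pattern(rep(TRUE, 8))
  expect_equal(perfect$n_switch + perfect$n_mismatch, 0L)

  # 5-site block with only site 3 flipped: one mismatch
  flip3 <- eval_one_pattern(c(TRUE, TRUE, FALSE, TRUE, TRUE))
  expect_equal(flip3$n_mismatch, 1L)
  expect_equal(flip3$n_switch, 0L)

  # agree on 1-3, disagree on 4-6: one switch
  tail3 <- eval_one_pattern(c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(tail3$n_switch, 1L)
  expect_equal(tail3$n_mismatch, 0L)

  # interior >= 2 run is bounded by two phase changes
  mid <- eval_one_pattern(c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE))
  expect_equal(mid$n_switch, 2L)
  expect_equal(mid$n_mismatch, 0L)
})

test_that("orientation symmetry: flipping a whole block changes nothing", {
  set.seed(17)
  for (i in 1:20) {
    pat <- runif(12) < 0.75
    a <- eval_one_pattern(pat)
    b <- eval_one_pattern(!pat)
    expect_equal(a$n_switch, b$n_switch)
    expect_equal(a$n_mismatch, b$n_mismatch)
  }
})

test_that("evaluate_phase equals the brute-force oracle on short blocks", {
  for (n in 2:8) {
    for (bits in 0:(2^n - 1)) {
      agree <- as.logical(bitwAnd(bits, 2^(0:(n - 1))))
      got <- eval_one_pattern(agree)
      want <- oracle_block_errors(agree)
      expect_equal(got$n_switch, want$sw,
                   info = paste("n", n, "pattern", bits))
      expect_equal(got$n_mismatch, want$mm,
                   info = paste("n", n, "pattern", bits))
    }
  }
})

test_that("planted switch and mismatch rates are recovered across seeds", {
  for (seed in 1:5) {
    tr <- simulate_truth_sites(20000, seed = seed)
    sim <- simulate_phased_blocks(tr, sim_config(
      seed = seed + 100, block_length = 200,
      switch_rate = 0.0126, mismatch_rate = 0))
    rep <- evaluate_phase(sim$blocks, tr)
    se <- sqrt(0.0126 * (1 - 0.0126) / 20000)
    expect_lt(abs(rep$switch_rate - 0.0126), 3 * se)
    # combined rate identity holds exactly
    expect_equal(rep$combined_rate * rep$n_sites,
                 rep$n_switch + rep$n_mismatch)
  }
  for (seed in 1:5) {
    tr <- simulate_truth_sites(50000, seed = seed)
    sim <- simulate_phased_blocks(tr, sim_config(
      seed = seed + 200, block_length = 14,
      switch_rate = 0, mismatch_rate = 0.00147))
    rep <- evaluate_phase(sim$blocks, tr)
    se <- sqrt(0.00147 * (1 - 0.00147) / 50000)
    expect_lt(abs(rep$combined_rate - 0.00147), 3 * se)
  }
})

test_that("sites absent from truth are excluded and tallied", {
  tr <- simulate_truth_sites(200, seed = 2)
  sim <- simulate_phased_blocks(tr, sim_config(seed = 3, block_length = 20,
                                               switch_rate = 0,
                                               mismatch_rate = 0))
  rep_full <- evaluate_phase(sim$blocks, tr)
  expect_equal(rep_full$n_excluded, 0L)
  rep_part <- evaluate_phase(sim$blocks, tr[-(1:10), ])
  expect_equal(rep_part$n_excluded, 10L)
  expect_equal(rep_part$n_sites, 190L)
})

test_that("block statistics summarize size, span and dominance", {
  one <- data.frame(block = "b1", ref = "r", pos = c(10, 20, 30, 40, 50))
  s1 <- block_stats(one)
  expect_equal(s1$mean_variants, 5)
  expect_equal(s1$largest_block_fraction, 1)
  expect_equal(s1$mean_span, 40)

  two <- data.frame(block = rep(c("b1", "b2"), c(4, 6)),
                    ref = "r", pos = c(1:4, 11:16))
  s2 <- block_stats(two)
  expect_equal(s2$mean_variants, 5)
  expect_equal(s2$largest_block_fraction, 0.6)
  expect_equal(unname(s2$largest_block_fraction_by_ref["r"]), 0.6)
})

test_that("the block-join switch fraction multiplies rate by block length", {
  expect_equal(join_switch_fraction(0.0126, 14), 0.1764)
  expect_equal(trunc(100 * join_switch_fraction(0.0126, 14)), 17)
  expect_equal(join_switch_fraction(0, 1000), 0)
  expect_equal(join_switch_fraction(0.05, 10), 0.5)
  expect_error(join_switch_fraction(-0.1, 10), ">= 0")
})

test_that("phased VCF round-trips preserve blocks and haplotypes", {
  tr <- simulate_truth_sites(500, seed = 4)
  sim <- simulate_phased_blocks(tr, sim_config(seed = 5, block_length = 25,
                                               switch_rate = 0.05,
                                               mismatch_rate = 0.01))
  f <- tempfile(fileext = ".vcf")
  on.exit(unlink(f))
  write_phased_vcf(sim$blocks, c(ref1 = 5000), file = f)
  back <- read_phased_vcf(f)
  expect_equal(nrow(back), nrow(sim$blocks))
  expect_equal(back$pos, sim$blocks$pos)
  expect_equal(back$hap, sim$blocks$hap)
  r1 <- evaluate_phase(sim$blocks, tr)
  r2 <- evaluate_phase(back, tr)
  expect_equal(r2$n_switch, r1$n_switch)
  expect_equal(r2$n_mismatch, r1$n_mismatch)
})
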