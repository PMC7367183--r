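refs2 <- c(chrA = 1000, chrB = 500)

test_that(".pairs records read with canonical upper-triangle ordering", {
  lines <- c("## pairs format v1.0",
             "#columns: readID chr1 pos1 chr2 pos2 strand1 strand2",
             "r1\tchrA\t11\tchrA\t101\t+\t-",
             "r2\tchrB\t6\tchrA\t11\t-\t+")
  cs <- read_pairs(lines, refs2)
  expect_equal(nrow(cs), 2L)
  # 1-based on disk -> 0-based internally
  expect_equal(cs$pos1[1], 10)
  expect_equal(cs$pos2[1], 100)
  # record 2 flipped into canonical order, strands travel with coordinates
  expect_equal(cs$ref1[2], "chrA")
  expect_equal(cs$pos1[2], 10)
  expect_equal(cs$strand1[2], "+")
  expect_equal(cs$ref2[2], "chrB")
  expect_equal(cs$pos2[2], 5)
  expect_equal(cs$strand2[2], "-")
})

test_that(".pairs parse errors carry line numbers", {
  hdr <- "#columns: readID chr1 pos1 chr2 pos2 strand1 strand2"
  expect_error(read_pairs(c(hdr, "r1\tchrA\t10\tchrA"), refs2),
               "line 2.*truncated")
  expect_error(read_pairs(c(hdr, "r1\tchrA\tx\tchrA\t5\t+\t+"), refs2),
               "line 2.*non-numeric")
  expect_error(read_pairs(c(hdr, "r1\tchrC\t10\tchrA\t5\t+\t+"), refs2),
               "line 2.*unknown reference")
  expect_error(read_pairs(c(hdr, "r1\tchrA\t10\tchrB\t501\t+\t+"), refs2),
               "line 2.*outside reference")
})

test_that("pairs round-trip through the .pairs writer, refs from header", {
  set.seed(42)
  df <- data.frame(ref1 = sample(names(refs2), 50, TRUE),
                   pos1 = sample(0:499, 50, TRUE), strand1 = "+",
                   ref2 = sample(names(refs2), 50, TRUE),
                   pos2 = sample(0:499, 50, TRUE), strand2 = "-",
                   stringsAsFactors = FALSE)
  cs <- contact_set(df, refs2)
  back <- read_pairs(write_pairs(cs))
  expect_identical(as.data.frame(back), as.data.frame(cs))
  expect_identical(attr(back, "refs"), refs2)
})

test_that("deduplication counts exact positional copies", {
  df <- data.frame(ref1 = "chrA", pos1 = 10 * (1:10), strand1 = "+",
                   ref2 = "chrA", pos2 = 10 * (1:10) + 5, strand2 = "-",
                   stringsAsFactors = FALSE)
  dd <- deduplicate(contact_set(df, refs2))
  expect_equal(dd$stats$duplication_rate, 0)
  expect_equal(dd$stats$n_unique, 10L)

  # 8 distinct + 2 exact copies of one of them: 10 records, rate 0.2
  df2 <- rbind(df[1:8, ], df[1, ], df[1, ])
  dd2 <- deduplicate(contact_set(df2, refs2))
  expect_equal(dd2$stats$duplication_rate, 0.2)
  expect_equal(dd2$stats$n_unique, 8L)

  # idempotent
  dd3 <- deduplicate(dd2$contacts)
  expect_equal(dd3$stats$duplication_rate, 0)
  expect_identical(as.data.frame(dd3$contacts), as.data.frame(dd2$contacts))

  # empty set: rate defined as 0
  dd4 <- deduplicate(contact_set(df[0, ], refs2))
  expect_equal(dd4$stats$duplication_rate, 0)
})

test_that("deduplication recovers a planted duplicate rate", {
  cfg <- sim_config(seed = 11, n_contacts = 5e4, dup_rate = 0.12,
                    trans_rate = 0.05)
  sim <- simulate_contacts(c(chr1 = 3e6, chr2 = 2e6), cfg)
  dd <- deduplicate(sim$contacts)
  se <- sqrt(0.12 * 0.88 / 5e4)
  expect_lt(abs(dd$stats$duplication_rate - 0.12), 3 * se)
})

test_that("contact binning is symmetric and conserves pair counts", {
  df <- data.frame(ref1 = c("chrA", "chrA", "chrA"),
                   pos1 = c(5, 0, 120), strand1 = "+",
                   ref2 = c("chrA", "chrA", "chrB"),
                   pos2 = c(7, 100, 30), strand2 = "+",
                   stringsAsFactors = FALSE)
  m <- bin_contacts(contact_set(df, refs2), 100)
  expect_true(isSymmetric(unname(m)))
  # intra-bin pair -> single diagonal increment
  expect_equal(m["chrA:0", "chrA:0"], 1)
  # pair at positions (0, binsize) -> entries (0,1) and (1,0)
  expect_equal(m["chrA:0", "chrA:100"], 1)
  expect_equal(m["chrA:100", "chrA:0"], 1)
  expect_equal((sum(m) - sum(diag(m))) / 2 + sum(diag(m)), nrow(df))
})

test_that("depth statistics are base-weighted population moments", {
  t1 <- depth_track(data.frame(ref = "r", start = 0, end = 1000, depth = 5))
  s1 <- depth_stats(t1)
  expect_equal(s1$depth_mean, 5)
  expect_equal(s1$depth_variance, 0)

  t2 <- depth_track(data.frame(ref = "r", start = c(0, 500),
                               end = c(500, 1000), depth = c(0, 10)))
  s2 <- depth_stats(t2)
  expect_equal(s2$depth_mean, 5)
  expect_equal(s2$depth_variance, 25)
  expect_equal(s2$dispersion_index, 5)

  # invariant to splitting runs
  t3 <- depth_track(data.frame(ref = "r", start = c(0, 200, 500, 900),
                               end = c(200, 500, 900, 1000),
                               depth = c(0, 0, 10, 10)))
  expect_equal(depth_stats(t3), s2)

  expect_error(depth_stats(t1[0, ]), "zero-length|missing columns")
})

test_that("simulated depth recovers its moments; Poisson dispersion is ~1", {
  nb <- simulate_depth(c(r = 1e6), sim_config(seed = 3, depth_mean = 40,
                                              depth_var = 1000))
  s <- depth_stats(nb)
  expect_lt(abs(s$depth_mean - 40) / 40, 0.05)
  expect_lt(abs(s$depth_variance - 1000) / 1000, 0.05)

  po <- simulate_depth(c(r = 1e6), sim_config(seed = 4, depth_mean = 30,
                                              depth_var = 30))
  expect_lt(abs(depth_stats(po)$dispersion_index - 1), 0.1)
})

test_that("BEDGRAPH round-trips and validates tiling", {
  tr <- simulate_depth(c(a = 5000, b = 3000),
                       sim_config(seed = 9, depth_mean = 5, depth_var = 20))
  back <- read_bedgraph(write_bedgraph(tr))
  expect_identical(as.data.frame(back), as.data.frame(tr))
  expect_error(depth_track(data.frame(ref = "r", start = c(0, 600),
                                      end = c(500, 1000), depth = 1)),
               "holes")
})

test_that("predicted coverage follows the base-count identity", {
  # long-read library: ~2.05M single reads of 3.5 kb median on a 120 Mb genome
  expect_equal(round(predicted_coverage(2046685, 3541, 120e6)), 60)
  expect_equal(predicted_coverage(0, 151, 1e6), 0)
  expect_equal(predicted_coverage(1000, 151, 302000, paired = TRUE), 1)
  expect_error(predicted_coverage(10, 100, 0), "positive")
})
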