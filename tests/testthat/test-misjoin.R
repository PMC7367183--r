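mk_contacts <- function(df, refs) {
  df$strand1 <- rep("+", nrow(df))
  df$strand2 <- rep("+", nrow(df))
  contact_set(df, refs)
}

test_that("spanning counts follow the half-open window convention", {
  refs <- c(s = 10000)
  empty <- mk_contacts(data.frame(ref1 = character(), pos1 = numeric(),
                                  ref2 = character(), pos2 = numeric()),
                       refs)
  expect_equal(spanning_count(empty, "s", 5000, 1000), 0)

  one <- mk_contacts(data.frame(ref1 = "s", pos1 = 4990,
                                ref2 = "s", pos2 = 5010), refs)
  expect_equal(spanning_count(one, "s", 5000, 1000), 1)

  # far end exactly at position + W is excluded
  edge <- mk_contacts(data.frame(ref1 = "s", pos1 = 4990,
                                 ref2 = "s", pos2 = 6000), refs)
  expect_equal(spanning_count(edge, "s", 5000, 1000), 0)
  expect_equal(spanning_count(edge, "s", 5000, 1011), 1)
})

test_that("spanning_count is monotone in W and matches the naive scan", {
  refs <- c(s1 = 50000, s2 = 30000)
  set.seed(7)
  df <- data.frame(ref1 = sample(names(refs), 400, TRUE),
                   pos1 = sample(0:29999, 400, TRUE),
                   ref2 = sample(names(refs), 400, TRUE),
                   pos2 = sample(0:29999, 400, TRUE))
  cs <- mk_contacts(df, refs)
  for (pos in c(1000, 15000, 29000)) {
    prev <- -1
    for (W in c(500, 2000, 8000, 40000)) {
      got <- spanning_count(cs, "s1", pos, W)
      expect_equal(got, naive_spanning_count(cs, "s1", pos, W))
      expect_gte(got, prev)
      prev <- got
    }
  }
})

test_that("scan_joins scores one point per contig-contig junction", {
  toy <- toy_layout()
  refs <- toy$scaffold_lengths
  cs <- mk_contacts(data.frame(ref1 = "s1", pos1 = 100,
                               ref2 = "s1", pos2 = 1300), refs)
  res <- scan_joins(cs, toy, misjoin_params(window = 1000))
  # s1 and s3 have 2 contigs each; s2, s4, s5 have none
  expect_equal(nrow(res), 2L)
  expect_setequal(res$scaffold, c("s1", "s3"))
  expect_equal(res$score[res$scaffold == "s1"], 1)
  expect_true(all(res$truncated))

  singles <- parse_agp(c("a\t1\t100\t1\tW\tx\t1\t100\t+",
                         "b\t1\t100\t1\tW\ty\t1\t100\t+"))
  expect_equal(nrow(scan_joins(mk_contacts(
    data.frame(ref1 = "a", pos1 = 1, ref2 = "b", pos2 = 2),
    singles$scaffold_lengths), singles)), 0L)
})

test_that("false-join null sampling is seeded, sized and zero without trans contacts", {
  toy <- toy_layout()
  refs <- toy$scaffold_lengths
  cis_only <- mk_contacts(data.frame(ref1 = rep("s1", 20),
                                     pos1 = seq(0, 950, 50),
                                     ref2 = rep("s1", 20),
                                     pos2 = seq(10, 960, 50)), refs)
  p <- misjoin_params(window = 500, n_null = 100, seed = 5)
  null0 <- false_join_null(cis_only, toy, p)
  expect_length(null0, 100)
  expect_true(all(null0 == 0))

  trans <- mk_contacts(data.frame(ref1 = c("s1", "s2", "s4"),
                                  pos1 = c(900, 700, 1900),
                                  ref2 = c("s2", "s4", "s5"),
                                  pos2 = c(10, 5, 10)), refs)
  n1 <- false_join_null(trans, toy, p)
  n2 <- false_join_null(trans, toy, p)
  expect_identical(n1, n2)
  expect_true(any(n1 > 0))

  one_scaffold <- parse_agp(c("a\t1\t100\t1\tW\tx\t1\t100\t+",
                              "a\t101\t200\t2\tW\ty\t1\t100\t+"))
  expect_error(false_join_null(mk_contacts(
    data.frame(ref1 = "a", pos1 = 1, ref2 = "a", pos2 = 150),
    one_scaffold$scaffold_lengths), one_scaffold, p), "unlinked")
})

test_that("the flag rule compares scores to the empirical null quantile", {
  null <- c(rep(0, 50), rep(2, 30), rep(5, 15), rep(50, 5))
  res <- data.frame(scaffold = c("s1", "s2", "s3"),
                    position = c(10, 20, 30),
                    score = c(100, stats::median(null), 0),
                    stringsAsFactors = FALSE)
  out <- call_misjoins(res, null, misjoin_params(flag_quantile = 0.95))
  # strictly above max(null) -> never flagged
  expect_false(out$results$flagged[1])
  # at the null median -> flagged for any q >= 0.5
  expect_true(out$results$flagged[2])
  expect_true(out$results$flagged[3])
  # breakpoints sorted by ascending score
  expect_equal(out$breakpoints$score, sort(out$breakpoints$score))
  expect_error(call_misjoins(res, numeric(0), misjoin_params()), "empty null")
})

test_that("a planted misjoin is flagged and a true join is not (reduced scale)", {
  for (seed in 1:3) {
    b <- misjoin_benchmark(seed, n_contacts = 2e5)
    out <- detect_misjoins(b$contacts, b$layout,
                           misjoin_params(seed = seed + 1000))
    res <- out$results
    planted <- res$scaffold == b$junction$scaffold &
      res$position == b$junction$position
    expect_true(res$flagged[planted])
    expect_false(any(res$flagged[!planted]))
    expect_equal(out$breakpoints$scaffold, b$junction$scaffold)
  }
})

test_that("flagged misjoins break the assembly where planted", {
  b <- misjoin_benchmark(4, n_contacts = 2e5)
  out <- detect_misjoins(b$contacts, b$layout, misjoin_params(seed = 99))
  broken <- apply_breaks(b$layout, out$breakpoints)
  expect_equal(span_bases(broken), span_bases(b$layout))
  expect_equal(length(broken$scaffold_lengths),
               length(b$layout$scaffold_lengths) + 1L)
  # the fused scaffold separates back into its two source contigs
  pieces <- broken$components[grepl("fused", broken$components$scaffold), ]
  expect_setequal(pieces$contig, c("cA", "cB"))
})
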