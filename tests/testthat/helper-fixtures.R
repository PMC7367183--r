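# Fixtures built in code: a small normalized AGP layout, a brute-force
# insulation counter, a brute-force phase-error oracle, and the planted
# misjoin benchmark assembly.

toy_agp_lines <- function() {
  c("s1\t1\t1000\t1\tW\tc1\t1\t1000\t+",
    "s1\t1001\t1100\t2\tN\t100\tscaffold\tyes\tna",
    "s1\t1101\t1600\t3\tW\tc2\t1\t500\t-",
    "s2\t1\t800\t1\tW\tc3\t1\t800\t+",
    "s3\t1\t300\t1\tW\tc4\t1\t300\t-",
    "s3\t301\t350\t2\tU\t50\tcontig\tno\tna",
    "s3\t351\t950\t3\tW\tc5\t1\t600\t+",
    "s4\t1\t2000\t1\tW\tc6\t1\t2000\t+",
    "s5\t1\t120\t1\tW\tc7\t1\t120\t+")
}

toy_layout <- function() parse_agp(toy_agp_lines())

# O(n) reference implementation of the spanning-contact count
naive_spanning_count <- function(contacts, scaffold, position, window) {
  L <- attr(contacts, "refs")[[scaffold]]
  lo <- max(0, position - window)
  hi <- min(L, position + window)
  n <- 0L
  for (i in seq_len(nrow(contacts))) {
    r1 <- contacts$ref1[i]; p1 <- contacts$pos1[i]
    r2 <- contacts$ref2[i]; p2 <- contacts$pos2[i]
    if (r1 != scaffold || r2 != scaffold) next
    a <- min(p1, p2); b <- max(p1, p2)
    if (a >= lo && a < position && b >= position && b < hi) n <- n + 1L
  }
  n
}

# Brute-force switch/mismatch oracle: enumerate both block orientations,
# count errors by direct positional scan, take the minimum (ties toward
# the orientation agreeing at the first site).
oracle_block_errors <- function(agree) {
  scan_one <- function(d) {
    n <- length(d); sw <- 0L; mm <- 0L; i <- 1L
    while (i <= n) {
      if (d[i]) { i <- i + 1L; next }
      j <- i
      while (j < n && !d[j + 1L]) j <- j + 1L
      if (j == i) {
        mm <- mm + 1L
      } else {
        if (i > 1L) sw <- sw + 1L
        if (j < n) sw <- sw + 1L
      }
      i <- j + 1L
    }
    list(sw = sw, mm = mm, tot = sw + mm, first = d[1])
  }
  e0 <- scan_one(agree)
  e1 <- scan_one(!agree)
  if (e0$tot < e1$tot) e0
  else if (e1$tot < e0$tot) e1
  else if (e0$first) e0 else e1
}

# Single-pattern wrapper around evaluate_phase
eval_one_pattern <- function(agree) {
  n <- length(agree)
  blocks <- data.frame(block = "b1", ref = "r", pos = seq_len(n),
                       a0 = "A", a1 = "C",
                       hap = ifelse(agree, 0L, 1L),
                       stringsAsFactors = FALSE)
  truth <- data.frame(ref = "r", pos = seq_len(n),
                      alleleA = "A", alleleB = "C",
                      stringsAsFactors = FALSE)
  evaluate_phase(blocks, truth)
}

# Planted-misjoin benchmark: two unlinked 3-Mb contigs fused into one
# scaffold, a truly linked 6-Mb control scaffold laid out as two 3-Mb
# contigs, and two 1.5-Mb singleton contigs completing the unlinked pool
# for the false-join null.  Contacts: distance-decay cis pairs at uniform
# per-base density (~200k per 3 Mb at the default n) plus 1% trans.
misjoin_benchmark <- function(seed, n_contacts = 1e6) {
  comp <- data.frame(
    scaffold = c("sA", "sB", "ctrl", "ctrl", "sD", "sE"),
    type = "W",
    start = c(0, 0, 0, 3e6, 0, 0),
    end = c(3e6, 3e6, 3e6, 6e6, 1.5e6, 1.5e6),
    contig = c("cA", "cB", "cC1", "cC2", "cD", "cE"),
    cstart = 0,
    cend = c(3e6, 3e6, 3e6, 3e6, 1.5e6, 1.5e6),
    orientation = "+", gap_type = NA_character_,
    linkage = NA_character_, evidence = NA_character_,
    stringsAsFactors = FALSE)
  true_layout <- scaffold_layout(comp)
  cfg <- sim_config(seed = seed, n_contacts = n_contacts,
                    trans_rate = 0.01, dup_rate = 0)
  sim <- simulate_contacts(true_layout, cfg)
  pm <- plant_misjoin(true_layout, "cA", "cB", contacts = sim$contacts)
  list(layout = pm$layout, contacts = pm$contacts, junction = pm$junction,
       control = data.frame(scaffold = "ctrl", position = 3e6))
}
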