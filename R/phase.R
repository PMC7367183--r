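# Diploid phasing evaluation for an F1 individual: depth filtering of
# heterozygous sites, parental polarization (truth table or PAF alignment),
# switch/mismatch error decomposition against truth, block statistics, and
# the block-join switch-fraction estimator.

#' Filter heterozygous sites by observed sequencing depth
#'
#' Removes sites whose depth falls strictly below the empirical 10th
#' percentile or strictly above the 90th percentile of the call set,
#' trimming the depth extremes where variant calls are least reliable
#' (collapsed repeats at the top, dropout at the bottom).  Percentiles use
#' linear interpolation (`stats::quantile` type 7).
#'
#' @param sites data.frame with a `depth` column
#' @param lower,upper percentile bounds (defaults 0.10 and 0.90)
#' @return the retained subset of `sites`
#' @export
depth_filter <- function(sites, lower = 0.10, upper = 0.90) {
  if (nrow(sites) == 0L) return(sites)
  q <- stats::quantile(sites$depth, c(lower, upper), type = 7, names = FALSE)
  out <- sites[sites$depth >= q[1] & sites$depth <= q[2], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read phased genotypes from a VCF
#'
#' Diploid phased genotypes (`GT` with the `|` separator) are read via
#' `vcfR`; the `PS` FORMAT tag defines phase blocks (records without `PS`
#' fall into one block per reference).  Unphased and non-biallelic records
#' are ignored.
#'
#' @param path VCF file (plain text or bgzipped)
#' @return data.frame with columns `block`, `ref`, `pos` (0-based), `a0`
#'   (REF allele), `a1` (ALT allele), `hap` (allele index, 0 or 1, assigned
#'   to the first haplotype)
#' @export
read_phased_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")[, 1]
  ps <- tryCatch(vcfR::extract.gt(v, element = "PS")[, 1],
                 error = function(e) rep(NA_character_, length(gt)))
  fix <- vcfR::getFIX(v)
  phased <- grepl("^[01]\\|[01]$", gt)
  biall <- !grepl(",", fix[, "ALT"]) & !is.na(fix[, "ALT"])
  keep <- phased & biall
  ref <- as.character(fix[keep, "CHROM"])
  blk <- ifelse(is.na(ps[keep]), paste0("ref:", ref),
                paste0(ref, ":", ps[keep]))
  out <- data.frame(
    block = blk,
    ref = ref,
    pos = as.numeric(fix[keep, "POS"]) - 1,
    a0 = as.character(fix[keep, "REF"]),
    a1 = as.character(fix[keep, "ALT"]),
    hap = as.integer(substr(gt[keep], 1, 1)),
    stringsAsFactors = FALSE)
  out <- out[order(out$ref, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write phased genotypes as a minimal VCF
#'
#' @param blocks data.frame as returned by [read_phased_vcf()] (columns
#'   `block`, `ref`, `pos`, `a0`, `a1`, `hap`); `block` is written to the
#'   `PS` tag as the 1-based position of the first site in the block when
#'   numeric, else hashed to an integer.
#' @param refs named reference-length vector for the `##contig` headers
#' @param file optional path
#' @return the VCF lines, invisibly when written
#' @export
write_phased_vcf <- function(blocks, refs, file = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           paste0("##contig=<ID=", names(refs), ",length=",
                  format(refs, scientific = FALSE, trim = TRUE), ">"),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=PS,Number=1,Type=Integer,Description=\"Phase set\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tsample")
  # numeric PS: first site position (1-based) of each block
  first_pos <- stats::ave(blocks$pos, blocks$block, FUN = min) + 1
  gt <- ifelse(blocks$hap == 0L, "0|1", "1|0")
  body <- paste(blocks$ref,
                format(blocks$pos + 1, scientific = FALSE, trim = TRUE),
                ".", blocks$a0, blocks$a1, ".", "PASS", ".", "GT:PS",
                paste0(gt, ":", format(first_pos, scientific = FALSE,
                                       trim = TRUE)),
                sep = "\t")
  out <- c(hdr, body)
  if (!is.null(file)) { writeLines(out, file); return(invisible(out)) }
  out
}

#' Read alignments from PAF with cs tags
#'
#' @param x path, connection or character lines
#' @return data.frame of the 12 mandatory PAF columns plus `cs`
#' @export
read_paf <- function(x) {
  lines <- as_lines(x)
  lines <- lines[nzchar(trimws(lines))]
  f <- strsplit(lines, "\t")
  bad <- which(lengths(f) < 12L)
  if (length(bad) > 0L)
    stop("PAF parse error at line ", bad[1], ": fewer than 12 columns")
  get <- function(k) vapply(f, `[`, "", k)
  cs <- vapply(f, function(v) {
    tag <- grep("^cs:Z:", v, value = TRUE)
    if (length(tag) == 0L) NA_character_ else sub("^cs:Z:", "", tag[1])
  }, "")
  data.frame(qname = get(1), qlen = as.numeric(get(2)),
             qstart = as.numeric(get(3)), qend = as.numeric(get(4)),
             strand = get(5), tname = get(6), tlen = as.numeric(get(7)),
             tstart = as.numeric(get(8)), tend = as.numeric(get(9)),
             nmatch = as.numeric(get(10)), alnlen = as.numeric(get(11)),
             mapq = as.numeric(get(12)), cs = cs, stringsAsFactors = FALSE)
}

# Walk one cs string along the target, returning substituted target
# positions with their query base and target intervals deleted from the
# query.  Positions are 0-based on the target (the assembly).
walk_cs <- function(cs, tstart) {
  ops <- regmatches(cs, gregexpr(
    ":[0-9]+|\\*[A-Za-z][A-Za-z]|\\+[A-Za-z]+|-[A-Za-z]+|=[A-Za-z]+", cs))[[1]]
  if (sum(nchar(ops)) != nchar(cs))
    stop("unparseable cs tag: ", substr(cs, 1, 40))
  tpos <- tstart
  sub_pos <- numeric(0); sub_base <- character(0)
  del_start <- numeric(0); del_end <- numeric(0)
  for (op in ops) {
    code <- substr(op, 1, 1)
    if (code == ":") {
      tpos <- tpos + as.numeric(substr(op, 2, nchar(op)))
    } else if (code == "=") {
      tpos <- tpos + nchar(op) - 1L
    } else if (code == "*") {
      sub_pos <- c(sub_pos, tpos)
      sub_base <- c(sub_base, toupper(substr(op, 3, 3)))
      tpos <- tpos + 1
    } else if (code == "-") {           # deletion from the query
      del_start <- c(del_start, tpos)
      del_end <- c(del_end, tpos + nchar(op) - 1L)
      tpos <- tpos + nchar(op) - 1L
    }                                    # "+": query insertion, no t advance
  }
  list(tend = tpos,
       subs = data.frame(pos = sub_pos, base = sub_base,
                         stringsAsFactors = FALSE),
       dels = data.frame(start = del_start, end = del_end))
}

#' Polarize heterozygous sites against a parental genome
#'
#' For an F1 individual whose assembly is a mosaic of two parental
#' haplotypes, assigns each allele of each heterozygous site to its parent
#' of origin.  Two input routes:
#'
#' * `truth`: a table (`ref`, `pos`, `alleleA`, `alleleB`) stating parent
#'   A's and parent B's allele directly (the synthetic-data route).
#' * `paf`: a parent-A-to-assembly alignment in PAF format with cs tags
#'   (query = parent A, target = assembly).  The aligned parent base at a
#'   site determines which allele is labeled A: a match run implies the
#'   assembly (REF) allele, a substitution supplies the parent base
#'   explicitly.  Sites in unaligned, multiply-aligned or query-deleted
#'   regions are left unpolarized; indel sites are not base-resolvable from
#'   cs substitutions and are likewise left unpolarized on this route.
#'
#' @param sites data.frame with columns `ref`, `pos`, `allele1` (the
#'   assembly/REF allele), `allele2`, and optionally `class`
#' @param truth optional truth table (data.frame or TSV path with header)
#' @param paf optional PAF input for [read_paf()]
#' @return `sites` with `alleleA`, `alleleB` and `status` columns appended
#'   (`status` one of `polarized`, `unpolarized`, `inconsistent`); the
#'   count of each status is attached as attribute `diagnostics`
#' @export
polarize <- function(sites, truth = NULL, paf = NULL) {
  if (is.null(truth) == is.null(paf))
    stop("supply exactly one of `truth` or `paf`")
  sites$alleleA <- NA_character_
  sites$alleleB <- NA_character_
  sites$status <- "unpolarized"

  if (!is.null(truth)) {
    if (is.character(truth))
      truth <- utils::read.delim(truth, stringsAsFactors = FALSE)
    key <- paste(sites$ref, sites$pos)
    tkey <- paste(truth$ref, truth$pos)
    m <- match(key, tkey)
    hit <- !is.na(m)
    tA <- truth$alleleA[m[hit]]; tB <- truth$alleleB[m[hit]]
    ok1 <- sites$allele1[hit] == tA & sites$allele2[hit] == tB
    ok2 <- sites$allele1[hit] == tB & sites$allele2[hit] == tA
    sites$alleleA[hit][ok1 | ok2] <- tA[ok1 | ok2]
    sites$alleleB[hit][ok1 | ok2] <- tB[ok1 | ok2]
    sites$status[hit][ok1 | ok2] <- "polarized"
    sites$status[hit][!(ok1 | ok2)] <- "inconsistent"
  } else {
    aln <- if (is.data.frame(paf)) paf else read_paf(paf)
    if (anyNA(aln$cs))
      stop("PAF records lack cs tags; rerun the aligner with --cs")
    parent_base <- vector("list", nrow(sites))
    ncov <- integer(nrow(sites))
    deleted <- logical(nrow(sites))
    for (j in seq_len(nrow(aln))) {
      w <- walk_cs(aln$cs[j], aln$tstart[j])
      on_t <- which(sites$ref == aln$tname[j] &
                      sites$pos >= aln$tstart[j] & sites$pos < aln$tend[j])
      if (length(on_t) == 0L) next
      ncov[on_t] <- ncov[on_t] + 1L
      sm <- match(sites$pos[on_t], w$subs$pos)
      for (k in seq_along(on_t)) {
        i <- on_t[k]
        if (nrow(w$dels) > 0L &&
            any(sites$pos[i] >= w$dels$start & sites$pos[i] < w$dels$end)) {
          deleted[i] <- TRUE
        } else if (!is.na(sm[k])) {
          parent_base[[i]] <- c(parent_base[[i]], w$subs$base[sm[k]])
        } else {
          parent_base[[i]] <- c(parent_base[[i]], sites$allele1[i])
        }
      }
    }
    is_snp <- nchar(sites$allele1) == 1L & nchar(sites$allele2) == 1L
    for (i in seq_len(nrow(sites))) {
      if (ncov[i] != 1L || deleted[i] || !is_snp[i]) next
      b <- parent_base[[i]]
      if (length(b) != 1L) next
      if (b == sites$allele1[i]) {
        sites$alleleA[i] <- sites$allele1[i]
        sites$alleleB[i] <- sites$allele2[i]
        sites$status[i] <- "polarized"
      } else if (b == sites$allele2[i]) {
        sites$alleleA[i] <- sites$allele2[i]
        sites$alleleB[i] <- sites$allele1[i]
        sites$status[i] <- "polarized"
      } else {
        sites$status[i] <- "inconsistent"
      }
    }
  }
  attr(sites, "diagnostics") <- table(sites$status)
  sites
}

# Switch/mismatch counts of one agreement vector.  An isolated single-site
# disagreement (flanked by agreement or a block edge) is 1 mismatch.  A
# maximal run of >= 2 contiguous disagreeing sites contributes one switch
# per phase change bounding it: 2 for an interior run, 1 when the run
# reaches a block edge (0 further changes if it covers the whole block,
# but the orientation minimization resolves that case to 0 errors anyway).
count_runs <- function(agree) {
  n <- length(agree)
  r <- rle(!agree)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  bad <- which(r$values)
  len <- r$lengths[bad]
  changes <- 2L - (starts[bad] == 1L) - (ends[bad] == n)
  c(switch = sum(changes[len >= 2L]), mismatch = sum(len == 1L))
}

#' Evaluate phased blocks against truth haplotypes
#'
#' Per block, the assigned haplotype sequence is compared with the truth
#' polarization under the better of the two global block orientations
#' (minimum switch + mismatch count; ties broken toward the orientation
#' agreeing at the first site).  An isolated single-site disagreement
#' counts as one mismatch; a maximal run of two or more contiguous
#' disagreeing sites counts one switch per phase change bounding it (two
#' for an interior run, one when the run reaches a block edge), so that
#' every change after which at least two subsequent variants are phased
#' incorrectly is a switch error.  Rates divide by the total
#' number of truth-labeled phased sites; sites without a truth label are
#' excluded and tallied.
#'
#' @param blocks data.frame as from [read_phased_vcf()]: columns `block`,
#'   `ref`, `pos`, `a0`, `a1`, `hap`
#' @param truth truth table with columns `ref`, `pos`, `alleleA`,
#'   `alleleB` (data.frame or TSV path with header)
#' @return list of class `phase_error_report`
#' @export
evaluate_phase <- function(blocks, truth) {
  if (is.character(truth))
    truth <- utils::read.delim(truth, stringsAsFactors = FALSE)
  key <- paste(blocks$ref, blocks$pos)
  m <- match(key, paste(truth$ref, truth$pos))
  tA <- truth$alleleA[m]
  # truth haplotype index: which VCF allele is parent A's
  t_idx <- ifelse(!is.na(m) & blocks$a0 == tA, 0L,
                  ifelse(!is.na(m) & blocks$a1 == tA, 1L, NA_integer_))
  excluded <- sum(is.na(t_idx))
  keep <- !is.na(t_idx)
  ev <- blocks[keep, , drop = FALSE]
  ti <- t_idx[keep]
  if (nrow(ev) == 0L) stop("no evaluable sites: truth table matches nothing")
  o <- order(ev$block, ev$ref, ev$pos)
  ev <- ev[o, , drop = FALSE]
  ti <- ti[o]

  agree <- ev$hap == ti
  sp <- split(seq_len(nrow(ev)), ev$block)
  n_switch <- 0L; n_mismatch <- 0L
  for (ix in sp) {
    if (length(ix) < 2L) next
    d <- agree[ix]
    e0 <- count_runs(d)
    e1 <- count_runs(!d)
    tot0 <- sum(e0); tot1 <- sum(e1)
    best <- if (tot0 < tot1) e0 else if (tot1 < tot0) e1 else
      if (d[1]) e0 else e1
    n_switch <- n_switch + best[["switch"]]
    n_mismatch <- n_mismatch + best[["mismatch"]]
  }
  n <- nrow(ev)
  bs <- block_stats(ev)
  structure(list(
    n_sites = n,
    n_switch = n_switch,
    n_mismatch = n_mismatch,
    switch_rate = n_switch / n,
    mismatch_rate = n_mismatch / n,
    combined_rate = (n_switch + n_mismatch) / n,
    n_excluded = excluded,
    block_stats = bs), class = "phase_error_report")
}

#' @export
print.phase_error_report <- function(x, ...) {
  cat("<phase_error_report>\n",
      "  sites evaluated : ", x$n_sites, "\n",
      "  switch errors   : ", x$n_switch,
      "  (", signif(x$switch_rate, 4), "/site)\n",
      "  mismatch errors : ", x$n_mismatch,
      "  (", signif(x$mismatch_rate, 4), "/site)\n",
      "  combined rate   : ", signif(x$combined_rate, 4), " errors/site\n",
      "  excluded sites  : ", x$n_excluded, "\n",
      "  blocks          : ", x$block_stats$n_blocks,
      " (mean ", signif(x$block_stats$mean_variants, 4), " variants, ",
      signif(x$block_stats$mean_span, 4), " bp span)\n", sep = "")
  invisible(x)
}

#' Phase-block statistics
#'
#' @param blocks data.frame with columns `block`, `ref`, `pos`
#' @return list: `n_blocks`, `mean_variants` (mean sites per block),
#'   `mean_span` (mean of last-minus-first site position per block),
#'   `largest_block_fraction` (share of all phased sites in the largest
#'   block), and `largest_block_fraction_by_ref` (the same computed within
#'   each reference)
#' @export
block_stats <- function(blocks) {
  if (nrow(blocks) == 0L) stop("no blocks supplied")
  sizes <- table(blocks$block)
  spans <- tapply(blocks$pos, blocks$block, function(p) max(p) - min(p))
  by_ref <- vapply(split(blocks, blocks$ref), function(g)
    max(table(g$block)) / nrow(g), 0)
  list(n_blocks = length(sizes),
       mean_variants = mean(sizes),
       mean_span = mean(spans),
       largest_block_fraction = max(sizes) / nrow(blocks),
       largest_block_fraction_by_ref = by_ref)
}

#' Fraction of block joins that introduce a switch error
#'
#' When short-read phase blocks are joined into chromosome-scale blocks by
#' Hi-C, each original block contributes about one join, so joins per site
#' is roughly 1 / mean block length.  The fraction of joins introducing a
#' switch is then the per-site switch-rate increase multiplied by the mean
#' block length in variants.
#'
#' @param rate_increase per-site switch-error rate increase attributable
#'   to the joining data
#' @param mean_block_length mean block length in variants (>= 1)
#' @return estimated fraction of joined blocks with a switch error
#' @export
join_switch_fraction <- function(rate_increase, mean_block_length) {
  if (rate_increase < 0) stop("rate_increase must be >= 0")
  if (mean_block_length < 1) stop("mean_block_length must be >= 1")
  rate_increase * mean_block_length
}
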