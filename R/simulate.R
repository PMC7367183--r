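# Seeded synthetic-data generators with known ground truth: F1 diploid
# genomes, distance-decay Hi-C contacts with planted misjoins and PCR
# duplicates, overdispersed depth tracks, annotated toy genomes and phased
# blocks with planted switch/mismatch events.  Every generator is
# deterministic under a fixed seed and emits data that round-trips through
# the corresponding reader.

#' Simulation configuration
#'
#' Defaults emulate a low-input single-individual F1 sequencing regime:
#' parental divergence of 5 SNPs/kb (typical for distinct inbred
#' *Drosophila* strains), a power-law contact distance decay with exponent
#' 1 above a 1 kb minimum separation, a 1% trans-contact background, a 12%
#' PCR duplicate rate, negative-binomial depth with mean 39.7 and variance
#' 1038 (an amplified long-read library), 14-variant phase blocks, a
#' 0.0126/site switch rate and a 0.00147/site mismatch rate.
#'
#' @param seed RNG seed (all generators restore the caller's RNG state)
#' @param genome_length reference length in bases
#' @param n_contigs number of contigs for layout-producing generators
#' @param theta per-base heterozygosity of the F1 (probability a base
#'   differs between the parents)
#' @param n_contacts number of Hi-C pair records to emit (duplicates
#'   included)
#' @param alpha distance-decay exponent: contact separation density
#'   proportional to s^-alpha
#' @param min_sep minimum cis separation in bases
#' @param trans_rate probability a pair is trans (uniform across distinct
#'   references)
#' @param dup_rate fraction of emitted records that are exact copies of
#'   earlier records
#' @param depth_mean,depth_var per-base depth moments; negative binomial
#'   when `depth_var > depth_mean`, Poisson when equal
#' @param block_length phase-block length in variants
#' @param block_dist `"fixed"` (consecutive blocks of `block_length`) or
#'   `"geometric"` (lengths geometric with that mean)
#' @param switch_rate per-adjacency probability of a planted switch event
#' @param mismatch_rate per-site probability of a planted mismatch event
#' @return list of class `sim_config`
#' @export
sim_config <- function(seed = 1L,
                       genome_length = 1e6,
                       n_contigs = 5L,
                       theta = 0.005,
                       n_contacts = 1e5,
                       alpha = 1,
                       min_sep = 1000,
                       trans_rate = 0.01,
                       dup_rate = 0.12,
                       depth_mean = 39.7,
                       depth_var = 1038,
                       block_length = 14L,
                       block_dist = c("fixed", "geometric"),
                       switch_rate = 0.0126,
                       mismatch_rate = 0.00147) {
  block_dist <- match.arg(block_dist)
  stopifnot(theta > 0, theta < 1, alpha > 0, min_sep >= 1,
            trans_rate >= 0, trans_rate <= 1,
            dup_rate >= 0, dup_rate < 1,
            switch_rate >= 0, switch_rate <= 1,
            mismatch_rate >= 0, mismatch_rate <= 1)
  if (depth_var < depth_mean)
    stop("depth_var must be >= depth_mean (no underdispersion model)")
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate an F1 heterozygote's parental genomes
#'
#' Parent A is random DNA; parent B differs by SNP substitutions placed by
#' a seeded Bernoulli(theta) process (coordinates identical between the
#' parents, so the truth table is exact).
#'
#' @param config a [sim_config()]; uses `seed`, `genome_length`, `theta`
#' @param ref_name reference name used in the truth table and FASTA
#' @return list with `parentA`, `parentB` (Biostrings `DNAStringSet`) and
#'   `truth` (data.frame `ref`, `pos`, `alleleA`, `alleleB`)
#' @export
simulate_f1 <- function(config = sim_config(), ref_name = "ref1") {
  L <- as.integer(config$genome_length)
  bases <- c("A", "C", "G", "T")
  with_seed(config$seed, {
    a <- sample(bases, L, replace = TRUE)
    is_site <- stats::runif(L) < config$theta
    pos <- which(is_site)
    b <- a
    # substitute to a uniformly chosen different base
    b[pos] <- vapply(a[pos], function(x)
      sample(setdiff(bases, x), 1L), "")
    truth <- data.frame(ref = ref_name, pos = pos - 1L,
                        alleleA = a[pos], alleleB = b[pos],
                        stringsAsFactors = FALSE)
    list(parentA = Biostrings::DNAStringSet(
           stats::setNames(paste(a, collapse = ""), ref_name)),
         parentB = Biostrings::DNAStringSet(
           stats::setNames(paste(b, collapse = ""), ref_name)),
         truth = truth)
  })
}

#' Simulate a heterozygous-site truth table directly
#'
#' Shortcut for phasing simulations that need many sites without the cost
#' of materializing parental sequences: site positions are a sorted uniform
#' draw and alleles are distinct random bases.
#'
#' @param n_sites number of heterozygous sites
#' @param ref_length reference length in bases (must allow `n_sites`
#'   distinct positions)
#' @param seed RNG seed
#' @param ref_name reference name
#' @return data.frame `ref`, `pos`, `alleleA`, `alleleB`
#' @export
simulate_truth_sites <- function(n_sites, ref_length = 10 * n_sites,
                                 seed = 1L, ref_name = "ref1") {
  if (ref_length < n_sites) stop("ref_length too small for n_sites")
  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    pos <- sort(sample.int(ref_length, n_sites)) - 1L
    aA <- sample(bases, n_sites, replace = TRUE)
    aB <- vapply(aA, function(x) sample(setdiff(bases, x), 1L), "")
    data.frame(ref = ref_name, pos = pos, alleleA = aA, alleleB = unname(aB),
               stringsAsFactors = FALSE)
  })
}

# Inverse-CDF draw from the truncated power law density ~ s^-alpha on
# [lo, hi].
rpowerlaw <- function(n, alpha, lo, hi) {
  u <- stats::runif(n)
  if (abs(alpha - 1) < 1e-12) {
    lo * (hi / lo)^u
  } else {
    a1 <- 1 - alpha
    (lo^a1 + u * (hi^a1 - lo^a1))^(1 / a1)
  }
}

#' Simulate distance-decay Hi-C contacts
#'
#' Cis pairs (probability `1 - trans_rate`) live on a reference chosen
#' proportional to length, with separation drawn from the truncated
#' density proportional to s^-alpha on `[min_sep, L - 1]` and the left end
#' uniform given the separation.  Trans pairs pick an unordered pair of
#' distinct references uniformly, with uniform positions.  PCR duplicates
#' are planted by re-emitting already-emitted records until a fraction
#' `dup_rate` of all records are copies.
#'
#' @param refs named reference-length vector, or a `scaff_layout` (its
#'   scaffolds become the references)
#' @param config a [sim_config()]; uses `seed`, `n_contacts`, `alpha`,
#'   `min_sep`, `trans_rate`, `dup_rate`
#' @return list with `contacts` (a [contact_set()], records in emission
#'   order) and `truth` (list with `is_duplicate` flags and the planted
#'   `trans` flags, aligned to the emitted records)
#' @export
simulate_contacts <- function(refs, config = sim_config()) {
  if (inherits(refs, "scaff_layout")) refs <- refs$scaffold_lengths
  if (is.null(names(refs))) stop("refs must be named")
  if (any(refs <= config$min_sep))
    stop("all references must be longer than min_sep")
  n <- as.integer(config$n_contacts)
  n_dup <- round(config$dup_rate * n)
  n_orig <- n - n_dup
  if (config$trans_rate > 0 && length(refs) < 2L)
    stop("trans contacts need at least 2 references")

  with_seed(config$seed, {
    is_trans <- stats::runif(n_orig) < config$trans_rate
    nt <- sum(is_trans); nc <- n_orig - nt

    # cis pairs
    ref_c <- sample(names(refs), nc, replace = TRUE, prob = refs)
    L <- refs[ref_c]
    s <- rpowerlaw(nc, config$alpha, config$min_sep, L - 1)
    s <- pmin(floor(s), L - 1)
    p1 <- floor(stats::runif(nc) * (L - s))
    cis <- data.frame(ref1 = ref_c, pos1 = p1, ref2 = ref_c, pos2 = p1 + s,
                      stringsAsFactors = FALSE)

    # trans pairs: unordered reference pair uniform, positions uniform
    if (nt > 0L) {
      i <- sample.int(length(refs), nt, replace = TRUE)
      j <- sample.int(length(refs) - 1L, nt, replace = TRUE)
      j <- ifelse(j >= i, j + 1L, j)
      ra <- names(refs)[i]; rb <- names(refs)[j]
      trans <- data.frame(ref1 = ra,
                          pos1 = floor(stats::runif(nt) * refs[ra]),
                          ref2 = rb,
                          pos2 = floor(stats::runif(nt) * refs[rb]),
                          stringsAsFactors = FALSE)
    } else trans <- cis[0, ]

    df <- rbind(cis, trans)
    perm <- sample.int(n_orig)
    df <- df[perm, , drop = FALSE]
    trans_flag <- c(rep(FALSE, nc), rep(TRUE, nt))[perm]
    df$strand1 <- sample(c("+", "-"), n_orig, replace = TRUE)
    df$strand2 <- sample(c("+", "-"), n_orig, replace = TRUE)

    if (n_dup > 0L) {
      src <- sample.int(n_orig, n_dup, replace = TRUE)
      df <- rbind(df, df[src, , drop = FALSE])
      trans_flag <- c(trans_flag, trans_flag[src])
      is_dup <- c(rep(FALSE, n_orig), rep(TRUE, n_dup))
      perm2 <- sample.int(n)
      df <- df[perm2, , drop = FALSE]
      trans_flag <- trans_flag[perm2]
      is_dup <- is_dup[perm2]
    } else is_dup <- rep(FALSE, n_orig)

    list(contacts = contact_set(df, refs),
         truth = list(is_duplicate = is_dup, is_trans = trans_flag))
  })
}

#' Plant a misjoin by concatenating two unlinked contigs
#'
#' Takes two contigs living in different single-contig scaffolds and fuses
#' them into one scaffold, recording the junction.  Base content is
#' conserved; only the layout changes, so contacts simulated per true
#' contig remain internally consistent.
#'
#' @param layout a `scaff_layout`
#' @param contig_a,contig_b contig names (defaults: the two largest
#'   contigs in distinct scaffolds)
#' @param new_name name of the fused scaffold
#' @param contacts optional [contact_set()] in scaffold coordinates of
#'   `layout`; endpoints on the two merged scaffolds are re-expressed in
#'   the fused scaffold's coordinates
#' @return list with `layout` (the shuffled layout), `junction`
#'   (data.frame `scaffold`, `position`) and, when supplied, the remapped
#'   `contacts`
#' @export
plant_misjoin <- function(layout, contig_a = NULL, contig_b = NULL,
                          new_name = NULL, contacts = NULL) {
  comp <- layout$components
  w <- comp[comp$type == "W", , drop = FALSE]
  singles <- names(which(table(comp$scaffold) == 1))
  singles <- w$contig[w$scaffold %in% singles]
  if (is.null(contig_a) || is.null(contig_b)) {
    if (length(singles) < 2L) stop("need >= 2 single-contig scaffolds")
    ord <- singles[order(-layout$contig_lengths[singles])]
    contig_a <- ord[1]; contig_b <- ord[2]
  }
  ra <- w[w$contig == contig_a, , drop = FALSE]
  rb <- w[w$contig == contig_b, , drop = FALSE]
  if (nrow(ra) != 1L || nrow(rb) != 1L ||
      ra$scaffold == rb$scaffold ||
      nrow(comp[comp$scaffold %in% c(ra$scaffold, rb$scaffold), ]) != 2L)
    stop("contigs must each occupy their own single-contig scaffold")
  if (is.null(new_name)) new_name <- paste0(contig_a, "_", contig_b, "_fused")
  la <- ra$end - ra$start
  lb <- rb$end - rb$start
  fused <- rbind(ra, rb)
  fused$scaffold <- new_name
  fused$start <- c(0, la)
  fused$end <- c(la, la + lb)
  if (ra$orientation != "+" || rb$orientation != "+")
    stop("only forward-oriented source scaffolds are supported")
  rest <- comp[!comp$scaffold %in% c(ra$scaffold, rb$scaffold), , drop = FALSE]
  out <- rbind(fused, rest)
  rownames(out) <- NULL
  new_layout <- scaffold_layout(out, layout$contig_lengths)
  res <- list(layout = new_layout,
              junction = data.frame(scaffold = new_name, position = la,
                                    stringsAsFactors = FALSE))
  if (!is.null(contacts)) {
    df <- as.data.frame(contacts)
    remap <- function(ref, pos) {
      sel_a <- ref == ra$scaffold
      sel_b <- ref == rb$scaffold
      pos[sel_b] <- pos[sel_b] + la
      ref[sel_a | sel_b] <- new_name
      list(ref = ref, pos = pos)
    }
    m1 <- remap(df$ref1, df$pos1)
    m2 <- remap(df$ref2, df$pos2)
    df$ref1 <- m1$ref; df$pos1 <- m1$pos
    df$ref2 <- m2$ref; df$pos2 <- m2$pos
    res$contacts <- contact_set(df, new_layout$scaffold_lengths)
  }
  res
}

#' Map contig-coordinate contacts onto a layout's scaffolds
#'
#' Re-expresses a contact set whose references are contigs in the scaffold
#' coordinates of `layout`.  Every contig must be placed as a single span
#' covering its full length.
#'
#' @param contacts a [contact_set()] with contig references
#' @param layout a `scaff_layout` placing those contigs
#' @return a [contact_set()] with scaffold references
#' @export
map_contacts_to_layout <- function(contacts, layout) {
  comp <- layout$components
  w <- comp[comp$type == "W", , drop = FALSE]
  if (anyDuplicated(w$contig))
    stop("contigs split across multiple spans are not supported here")
  full <- w$cstart == 0 & w$cend == layout$contig_lengths[w$contig]
  if (!all(full)) stop("all contigs must be placed in full")
  idx1 <- match(contacts$ref1, w$contig)
  idx2 <- match(contacts$ref2, w$contig)
  if (anyNA(idx1) || anyNA(idx2))
    stop("contact references missing from the layout's contigs")
  mapped_pos <- function(idx, pos)
    ifelse(w$orientation[idx] == "+",
           w$start[idx] + pos,
           w$start[idx] + (w$cend[idx] - 1 - pos))
  df <- data.frame(ref1 = w$scaffold[idx1],
                   pos1 = mapped_pos(idx1, contacts$pos1),
                   strand1 = contacts$strand1,
                   ref2 = w$scaffold[idx2],
                   pos2 = mapped_pos(idx2, contacts$pos2),
                   strand2 = contacts$strand2,
                   stringsAsFactors = FALSE)
  contact_set(df, layout$scaffold_lengths)
}

#' Simulate an overdispersed per-base depth track
#'
#' Per-base depths are i.i.d. negative binomial with the configured mean
#' and variance (Poisson when they are equal), then run-length encoded.
#'
#' @param refs named reference-length vector (or `scaff_layout`)
#' @param config a [sim_config()]; uses `seed`, `depth_mean`, `depth_var`
#' @return a [depth_track()]
#' @export
simulate_depth <- function(refs, config = sim_config()) {
  if (inherits(refs, "scaff_layout")) refs <- refs$scaffold_lengths
  if (is.null(names(refs)) || any(refs < 1))
    stop("refs must be a named vector of positive lengths")
  mu <- config$depth_mean; v <- config$depth_var
  if (mu <= 0) stop("depth_mean must be positive")
  with_seed(config$seed, {
    runs <- lapply(names(refs), function(r) {
      L <- as.integer(refs[[r]])
      d <- if (v > mu)
        stats::rnbinom(L, mu = mu, size = mu^2 / (v - mu))
      else
        stats::rpois(L, mu)
      rl <- rle(d)
      ends <- cumsum(rl$lengths)
      data.frame(ref = r, start = c(0, ends[-length(ends)]), end = ends,
                 depth = rl$values, stringsAsFactors = FALSE)
    })
    depth_track(do.call(rbind, runs))
  })
}

#' Simulate phased blocks with planted switch and mismatch errors
#'
#' Sites of the truth table are partitioned into blocks by the configured
#' length distribution.  Within each block, haplotype assignments start
#' from truth; independent per-adjacency switch events (probability
#' `switch_rate`) toggle the running orientation, and independent per-site
#' mismatch events (probability `mismatch_rate`) flip single sites.  The
#' VCF REF/ALT order is randomized per site so that allele matching in the
#' evaluator is exercised.
#'
#' @param truth truth table (`ref`, `pos`, `alleleA`, `alleleB`)
#' @param config a [sim_config()]; uses `seed`, `block_length`,
#'   `block_dist`, `switch_rate`, `mismatch_rate`
#' @return list with `blocks` (data.frame for [evaluate_phase()]) and
#'   `truth_events` (list of planted `switch` adjacency indices and
#'   `mismatch` site indices, in the row order of `blocks`)
#' @export
simulate_phased_blocks <- function(truth, config = sim_config()) {
  if (nrow(truth) == 0L) stop("empty truth table")
  truth <- truth[order(truth$ref, truth$pos), , drop = FALSE]
  n <- nrow(truth)
  with_seed(config$seed, {
    # partition sites into blocks per reference
    block_id <- character(n)
    for (r in unique(truth$ref)) {
      ix <- which(truth$ref == r)
      m <- length(ix)
      if (config$block_dist == "fixed") {
        sizes <- rep(config$block_length, ceiling(m / config$block_length))
      } else {
        sizes <- integer(0)
        while (sum(sizes) < m)
          sizes <- c(sizes, 1L + stats::rgeom(1L,
                       1 / max(1, config$block_length)))
      }
      lab <- rep(seq_along(sizes), sizes)[seq_len(m)]
      block_id[ix] <- sprintf("%s_b%05d", r, lab)
    }

    # random REF/ALT order per site
    swap <- stats::runif(n) < 0.5
    a0 <- ifelse(swap, truth$alleleB, truth$alleleA)
    a1 <- ifelse(swap, truth$alleleA, truth$alleleB)
    idxA <- ifelse(swap, 1L, 0L)     # allele index of parent A in (a0, a1)

    # plant switch (per adjacency) and mismatch (per site) events
    new_block <- c(TRUE, block_id[-1] != block_id[-n])
    sw_event <- stats::runif(n) < config$switch_rate & !new_block
    orient <- as.integer(stats::ave(as.integer(sw_event), block_id,
                                    FUN = cumsum) %% 2L)
    mm_event <- stats::runif(n) < config$mismatch_rate
    flip <- (orient + mm_event) %% 2L
    hap <- ifelse(flip == 1L, 1L - idxA, idxA)

    blocks <- data.frame(block = block_id, ref = truth$ref, pos = truth$pos,
                         a0 = a0, a1 = a1, hap = hap,
                         stringsAsFactors = FALSE)
    list(blocks = blocks,
         truth_events = list(switch = which(sw_event),
                             mismatch = which(mm_event)))
  })
}

#' Simulate a toy annotation as GFF3
#'
#' Places non-overlapping features uniformly at random by stick-breaking
#' the free space of each reference, cycling through the requested types.
#'
#' @param refs named reference-length vector (or `scaff_layout`)
#' @param n_features number of features per reference
#' @param types character vector of feature type labels, recycled
#' @param feature_length feature length in bases (scalar or per-type)
#' @param seed RNG seed
#' @return list with `features` (data.frame as from [read_gff3()]) and
#'   `gff3` (character lines)
#' @export
simulate_annotation <- function(refs, n_features = 50L,
                                types = c("gene", "exon", "transposable_element"),
                                feature_length = 500L, seed = 1L) {
  if (inherits(refs, "scaff_layout")) refs <- refs$scaffold_lengths
  with_seed(seed, {
    feats <- lapply(names(refs), function(r) {
      if (n_features == 0L) return(NULL)
      L <- refs[[r]]
      ty <- rep_len(types, n_features)
      fl <- rep_len(feature_length, length(types))[match(ty, types)]
      free <- L - sum(fl)
      if (free < 0) stop("features do not fit in reference ", r)
      gaps <- diff(c(0, sort(stats::runif(n_features)), 1)) * free
      starts <- cumsum(gaps[-length(gaps)]) + cumsum(c(0, fl[-n_features]))
      starts <- floor(starts)
      data.frame(ref = r, start = starts, end = starts + fl, strand = "+",
                 type = ty,
                 id = sprintf("%s_f%04d", r, seq_len(n_features)),
                 stringsAsFactors = FALSE)
    })
    feats <- do.call(rbind, feats)
    gff <- c("##gff-version 3")
    if (!is.null(feats) && nrow(feats) > 0L)
      gff <- c(gff, paste(feats$ref, "scaffcheck_sim", feats$type,
                          format(feats$start + 1, scientific = FALSE,
                                 trim = TRUE),
                          format(feats$end, scientific = FALSE, trim = TRUE),
                          ".", feats$strand, ".",
                          paste0("ID=", feats$id), sep = "\t"))
    list(features = if (is.null(feats))
      data.frame(ref = character(), start = numeric(), end = numeric(),
                 strand = character(), type = character(), id = character())
      else feats,
      gff3 = gff)
  })
}
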