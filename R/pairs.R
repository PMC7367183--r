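# Hi-C contact pairs: I/O, deduplication, binning, library QC statistics.

#' Construct a contact set
#'
#' A contact set stores mapped Hi-C pair endpoints against a reference
#' name -> length map (a contig set or the scaffolds of a layout).  Pairs
#' are kept in canonical upper-triangle order: `(ref1, pos1) <= (ref2,
#' pos2)` under (reference name, position) lexicographic order; strand
#' assignments travel with their coordinates when a record is flipped.
#'
#' @param pairs data.frame with columns `ref1`, `pos1`, `strand1`, `ref2`,
#'   `pos2`, `strand2`; positions 0-based leftmost mapped base.
#' @param refs named numeric vector of reference lengths.
#' @return data.frame of class `contact_set` with a `refs` attribute.
#' @export
contact_set <- function(pairs, refs) {
  need <- c("ref1", "pos1", "strand1", "ref2", "pos2", "strand2")
  miss <- setdiff(need, names(pairs))
  if (length(miss) > 0L)
    stop("contact pairs missing columns: ", paste(miss, collapse = ", "))
  pairs <- pairs[need]
  pairs$ref1 <- as.character(pairs$ref1)
  pairs$ref2 <- as.character(pairs$ref2)
  pairs$pos1 <- as.numeric(pairs$pos1)
  pairs$pos2 <- as.numeric(pairs$pos2)
  pairs$strand1 <- as.character(pairs$strand1)
  pairs$strand2 <- as.character(pairs$strand2)
  if (is.null(names(refs))) stop("refs must be a named length vector")

  unknown <- setdiff(unique(c(pairs$ref1, pairs$ref2)), names(refs))
  if (length(unknown) > 0L)
    stop("unknown reference(s): ", paste(unknown, collapse = ", "))
  if (any(pairs$pos1 < 0) || any(pairs$pos2 < 0))
    stop("negative contact position")
  if (any(pairs$pos1 >= refs[pairs$ref1]) || any(pairs$pos2 >= refs[pairs$ref2]))
    stop("contact position beyond reference length")
  if (!all(c(pairs$strand1, pairs$strand2) %in% c("+", "-")))
    stop("strands must be '+' or '-'")

  flip <- pairs$ref2 < pairs$ref1 |
    (pairs$ref1 == pairs$ref2 & pairs$pos2 < pairs$pos1)
  if (any(flip)) {
    tmp <- pairs[flip, ]
    pairs[flip, c("ref1", "pos1", "strand1")] <-
      tmp[, c("ref2", "pos2", "strand2")]
    pairs[flip, c("ref2", "pos2", "strand2")] <-
      tmp[, c("ref1", "pos1", "strand1")]
  }
  rownames(pairs) <- NULL
  structure(pairs, refs = refs, class = c("contact_set", "data.frame"))
}

#' @export
print.contact_set <- function(x, ...) {
  cat("<contact_set> ", nrow(x), " pair(s) on ",
      length(attr(x, "refs")), " reference(s)\n", sep = "")
  invisible(x)
}

pairs_error <- function(line_no, msg) {
  stop(".pairs parse error at line ", line_no, ": ", msg, call. = FALSE)
}

#' Read Hi-C contact pairs
#'
#' Reads the 4DN `.pairs` text dialect (header lines starting with `#`,
#' columns `readID chr1 pos1 chr2 pos2 strand1 strand2`, positions 1-based)
#' or a headerless 6-column TSV (`ref1 pos1 ref2 pos2 strand1 strand2`,
#' positions 0-based, mirroring the internal convention).
#'
#' @param x path, connection or character lines
#' @param refs named reference-length vector; when `NULL`, taken from
#'   `#chromsize:` header lines (error if absent).
#' @return a [contact_set()]
#' @export
read_pairs <- function(x, refs = NULL) {
  lines <- as_lines(x)
  hdr <- grepl("^#", lines)
  has_header <- any(hdr)
  if (is.null(refs)) {
    cs <- grep("^#chromsize:", lines[hdr], value = TRUE)
    if (length(cs) == 0L)
      stop("no reference map supplied and no #chromsize header present")
    f <- strsplit(sub("^#chromsize:\\s*", "", cs), "[ \t]+")
    refs <- stats::setNames(as.numeric(vapply(f, `[`, "", 2L)),
                            vapply(f, `[`, "", 1L))
  }
  body <- which(!hdr & nzchar(trimws(lines)))
  if (length(body) == 0L)
    return(contact_set(data.frame(ref1 = character(), pos1 = numeric(),
                                  strand1 = character(), ref2 = character(),
                                  pos2 = numeric(), strand2 = character()),
                       refs))
  fields <- strsplit(lines[body], "[ \t]+")
  ncol <- lengths(fields)
  if (has_header) {
    bad <- which(ncol < 7L)
    if (length(bad) > 0L) pairs_error(body[bad[1]], "truncated record (< 7 columns)")
    get <- function(k) vapply(fields, `[`, "", k)
    df <- data.frame(ref1 = get(2), pos1 = suppressWarnings(as.numeric(get(3))) - 1,
                     ref2 = get(4), pos2 = suppressWarnings(as.numeric(get(5))) - 1,
                     strand1 = get(6), strand2 = get(7), stringsAsFactors = FALSE)
  } else {
    bad <- which(ncol < 6L)
    if (length(bad) > 0L) pairs_error(body[bad[1]], "truncated record (< 6 columns)")
    get <- function(k) vapply(fields, `[`, "", k)
    df <- data.frame(ref1 = get(1), pos1 = suppressWarnings(as.numeric(get(2))),
                     ref2 = get(3), pos2 = suppressWarnings(as.numeric(get(4))),
                     strand1 = get(5), strand2 = get(6), stringsAsFactors = FALSE)
  }
  bad <- which(is.na(df$pos1) | is.na(df$pos2))
  if (length(bad) > 0L) pairs_error(body[bad[1]], "non-numeric position")
  bad <- which(!(df$ref1 %in% names(refs)) | !(df$ref2 %in% names(refs)))
  if (length(bad) > 0L)
    pairs_error(body[bad[1]],
                paste0("unknown reference '",
                       setdiff(c(df$ref1[bad[1]], df$ref2[bad[1]]), names(refs))[1],
                       "'"))
  bad <- which(df$pos1 < 0 | df$pos2 < 0 |
                 df$pos1 >= refs[df$ref1] | df$pos2 >= refs[df$ref2])
  if (length(bad) > 0L) pairs_error(body[bad[1]], "position outside reference")
  contact_set(df, refs)
}

#' Write a contact set in 4DN `.pairs` text format
#'
#' @param contacts a [contact_set()]
#' @param file optional path or connection
#' @return the lines, invisibly when written to `file`
#' @export
write_pairs <- function(contacts, file = NULL) {
  refs <- attr(contacts, "refs")
  hdr <- c("## pairs format v1.0",
           paste0("#chromsize: ", names(refs), " ",
                  format(refs, scientific = FALSE, trim = TRUE)),
           "#columns: readID chr1 pos1 chr2 pos2 strand1 strand2")
  n <- nrow(contacts)
  body <- if (n == 0L) character() else
    paste(paste0("p", seq_len(n)), contacts$ref1,
          format(contacts$pos1 + 1, scientific = FALSE, trim = TRUE),
          contacts$ref2,
          format(contacts$pos2 + 1, scientific = FALSE, trim = TRUE),
          contacts$strand1, contacts$strand2, sep = "\t")
  out <- c(hdr, body)
  if (!is.null(file)) { writeLines(out, file); return(invisible(out)) }
  out
}

#' Remove PCR duplicate pairs
#'
#' Collapses records identical on both endpoints and strands
#' (`ref1,pos1,strand1,ref2,pos2,strand2`) to one representative, the
#' standard positional definition of a PCR duplicate for proximity-ligation
#' libraries.  The duplication rate is the fraction of records removed.
#'
#' @param contacts a [contact_set()]
#' @return list with `contacts` (the unique set) and `stats`, a
#'   `library_stats` list with `n_pairs`, `n_unique`, `duplication_rate`.
#' @export
deduplicate <- function(contacts) {
  n <- nrow(contacts)
  key <- paste(contacts$ref1, contacts$pos1, contacts$strand1,
               contacts$ref2, contacts$pos2, contacts$strand2, sep = "\r")
  keep <- !duplicated(key)
  uniq <- contact_set(as.data.frame(contacts)[keep, , drop = FALSE],
                      attr(contacts, "refs"))
  stats <- structure(
    list(n_pairs = n, n_unique = sum(keep),
         duplication_rate = if (n == 0L) 0 else 1 - sum(keep) / n),
    class = "library_stats")
  list(contacts = uniq, stats = stats)
}

#' @export
print.library_stats <- function(x, ...) {
  cat("<library_stats>\n")
  for (f in names(x))
    if (!is.null(x[[f]]))
      cat("  ", f, ": ", format(x[[f]], digits = 6), "\n", sep = "")
  invisible(x)
}

#' Bin contacts into a symmetric count matrix
#'
#' Bins are laid out per reference in the order of the reference map, each
#' reference contributing `ceiling(length / binsize)` bins.  Every pair
#' increments `(i, j)` and `(j, i)` when the bins differ and the diagonal
#' once when they coincide, so `sum(off-diagonal)/2 + sum(diagonal)` equals
#' the number of pairs.
#'
#' @param contacts a [contact_set()]
#' @param binsize bin width in bases (>= 1)
#' @return symmetric numeric matrix with `ref:start` dimnames
#' @export
bin_contacts <- function(contacts, binsize) {
  if (binsize < 1) stop("binsize must be >= 1")
  refs <- attr(contacts, "refs")
  nb <- pmax(1L, as.integer(ceiling(refs / binsize)))
  offset <- stats::setNames(cumsum(c(0L, nb[-length(nb)])), names(refs))
  K <- sum(nb)
  i <- offset[contacts$ref1] + contacts$pos1 %/% binsize
  j <- offset[contacts$ref2] + contacts$pos2 %/% binsize
  counts <- tabulate(i * K + j + 1L, nbins = K * K)
  m <- matrix(counts, K, K, byrow = TRUE)  # index k = i*K + j is row-major
  m <- m + t(m) - diag(diag(m))
  labs <- unlist(lapply(seq_along(refs), function(k)
    paste0(names(refs)[k], ":", (seq_len(nb[k]) - 1L) * binsize)),
    use.names = FALSE)
  dimnames(m) <- list(labs, labs)
  m
}

#' Construct a per-base depth track
#'
#' Run-length encoded sequencing depth: intervals tile each reference
#' exactly once (the BEDGRAPH `-bga` convention, zero-depth runs included).
#'
#' @param runs data.frame with columns `ref`, `start`, `end` (0-based
#'   half-open) and `depth` (non-negative)
#' @return data.frame of class `depth_track`
#' @export
depth_track <- function(runs) {
  need <- c("ref", "start", "end", "depth")
  miss <- setdiff(need, names(runs))
  if (length(miss) > 0L)
    stop("depth runs missing columns: ", paste(miss, collapse = ", "))
  runs <- runs[need]
  runs$ref <- as.character(runs$ref)
  runs$start <- as.numeric(runs$start)
  runs$end <- as.numeric(runs$end)
  runs$depth <- as.numeric(runs$depth)
  runs <- runs[order(runs$ref, runs$start), , drop = FALSE]
  if (any(runs$end <= runs$start)) stop("empty or inverted depth run")
  if (any(runs$depth < 0)) stop("negative depth")
  for (r in unique(runs$ref)) {
    v <- runs[runs$ref == r, , drop = FALSE]
    if (v$start[1] != 0)
      stop("depth runs of ", r, " do not start at 0")
    if (nrow(v) > 1L && any(v$start[-1] != v$end[-nrow(v)]))
      stop("depth runs of ", r, " leave holes or overlap")
  }
  rownames(runs) <- NULL
  structure(runs, class = c("depth_track", "data.frame"))
}

#' Read a BEDGRAPH depth track
#'
#' Expects the `bedtools genomecov -bga` dialect: 4 tab-separated columns
#' (`ref start end depth`, 0-based half-open) with explicit zero-coverage
#' runs so that intervals tile every reference.
#'
#' @param x path, connection or character lines
#' @return a [depth_track()]
#' @export
read_bedgraph <- function(x) {
  lines <- as_lines(x)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty BEDGRAPH input")
  f <- strsplit(lines, "[ \t]+")
  bad <- which(lengths(f) < 4L)
  if (length(bad) > 0L)
    stop("BEDGRAPH parse error at record ", bad[1], ": fewer than 4 columns")
  df <- data.frame(ref = vapply(f, `[`, "", 1L),
                   start = suppressWarnings(as.numeric(vapply(f, `[`, "", 2L))),
                   end = suppressWarnings(as.numeric(vapply(f, `[`, "", 3L))),
                   depth = suppressWarnings(as.numeric(vapply(f, `[`, "", 4L))),
                   stringsAsFactors = FALSE)
  bad <- which(is.na(df$start) | is.na(df$end) | is.na(df$depth))
  if (length(bad) > 0L)
    stop("BEDGRAPH parse error at record ", bad[1], ": non-numeric field")
  depth_track(df)
}

#' Write a depth track as BEDGRAPH (`-bga` dialect)
#' @param track a [depth_track()]
#' @param file optional path or connection
#' @return the lines, invisibly when written
#' @export
write_bedgraph <- function(track, file = NULL) {
  out <- paste(track$ref,
               format(track$start, scientific = FALSE, trim = TRUE),
               format(track$end, scientific = FALSE, trim = TRUE),
               format(track$depth, scientific = FALSE, trim = TRUE),
               sep = "\t")
  if (!is.null(file)) { writeLines(out, file); return(invisible(out)) }
  out
}

#' Depth summary statistics
#'
#' Base-weighted mean and population variance of per-base depth, plus the
#' dispersion index (variance/mean), which is 1 in expectation for depth
#' sampled uniformly at random (Poisson); amplified low-input libraries
#' typically show substantial overdispersion.
#'
#' @param track a [depth_track()]
#' @return `library_stats` list with `depth_mean`, `depth_variance`,
#'   `dispersion_index`, `n_bases`
#' @export
depth_stats <- function(track) {
  len <- track$end - track$start
  L <- sum(len)
  if (L == 0) stop("zero-length depth track")
  m <- sum(track$depth * len) / L
  v <- sum(track$depth^2 * len) / L - m^2
  structure(list(depth_mean = m, depth_variance = v,
                 dispersion_index = if (m > 0) v / m else NA_real_,
                 n_bases = L),
            class = "library_stats")
}

#' Predicted fold coverage of a sequencing library
#'
#' `n_reads * read_length * (2 if paired) / genome_size`, reported as an
#' unrounded float (display rounding is left to callers).
#'
#' @param n_reads number of reads (read pairs count once with
#'   `paired = TRUE`, which doubles the base count)
#' @param read_length read (or median read) length in bases
#' @param genome_size haploid genome size in bases
#' @param paired whether reads are paired-end
#' @return fold coverage
#' @export
predicted_coverage <- function(n_reads, read_length, genome_size,
                               paired = FALSE) {
  if (genome_size <= 0) stop("genome_size must be positive")
  if (n_reads < 0 || read_length < 0) stop("negative read count or length")
  n_reads * read_length * (if (paired) 2 else 1) / genome_size
}
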