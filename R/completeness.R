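# Assembly completeness by annotation class: per-feature base-by-base
# coverage from an alignment-derived depth track, and the percent of
# elements of each annotation type with at least a threshold fraction of
# their sequence captured.

#' Read features from a GFF3 annotation
#'
#' Thin wrapper over `ape::read.gff()` with a validation pass that reports
#' malformed records by line number.  GFF3 coordinates (1-based inclusive)
#' are converted to the internal 0-based half-open convention; the feature
#' type is column 3 and the identifier is the `ID` attribute, falling back
#' to the positional index.
#'
#' @param x path, connection or character lines
#' @return data.frame with columns `ref`, `start`, `end`, `strand`, `type`,
#'   `id`
#' @export
read_gff3 <- function(x) {
  lines <- as_lines(x)
  body <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
  for (i in body) {
    f <- strsplit(lines[i], "\t")[[1]]
    if (length(f) != 9L)
      stop("GFF3 parse error at line ", i, ": expected 9 columns, got ",
           length(f), call. = FALSE)
    s <- suppressWarnings(as.numeric(f[4]))
    e <- suppressWarnings(as.numeric(f[5]))
    if (is.na(s) || is.na(e))
      stop("GFF3 parse error at line ", i, ": non-numeric coordinates",
           call. = FALSE)
    if (s < 1)
      stop("GFF3 parse error at line ", i, ": start < 1", call. = FALSE)
    if (e < s)
      stop("GFF3 parse error at line ", i, ": end < start", call. = FALSE)
    if (!nzchar(f[3]))
      stop("GFF3 parse error at line ", i, ": empty feature type",
           call. = FALSE)
  }
  if (length(body) == 0L)
    return(data.frame(ref = character(), start = numeric(), end = numeric(),
                      strand = character(), type = character(),
                      id = character(), stringsAsFactors = FALSE))
  tf <- tempfile(fileext = ".gff3")
  on.exit(unlink(tf))
  writeLines(lines, tf)
  g <- ape::read.gff(tf, GFF3 = TRUE)
  ids <- sub(";.*$", "", sub("^.*?ID=", "", g$attributes))
  ids[!grepl("ID=", g$attributes)] <- NA
  ids[is.na(ids)] <- as.character(which(is.na(ids)))
  data.frame(ref = as.character(g$seqid), start = g$start - 1, end = g$end,
             strand = as.character(g$strand), type = as.character(g$type),
             id = ids, stringsAsFactors = FALSE)
}

#' Per-feature coverage from a depth track
#'
#' Assigns depth to every annotated span base by base: the covered fraction
#' is the share of bases with depth >= 1 and the mean depth is the
#' per-base average over the span.  Depth is strandless, so feature strand
#' is ignored.
#'
#' @param track a [depth_track()]
#' @param features data.frame as returned by [read_gff3()]
#' @return `features` with `covered_fraction` and `mean_depth` columns
#'   appended
#' @export
feature_coverage <- function(track, features) {
  missing_refs <- setdiff(unique(features$ref), unique(track$ref))
  if (length(missing_refs) > 0L) {
    off <- features$id[features$ref %in% missing_refs]
    stop("feature(s) on reference(s) absent from the depth track: ",
         paste(utils::head(off, 5), collapse = ", "),
         if (length(off) > 5) " ...")
  }
  features$covered_fraction <- NA_real_
  features$mean_depth <- NA_real_
  for (r in unique(features$ref)) {
    tr <- track[track$ref == r, , drop = FALSE]
    s <- tr$start; e <- tr$end; d <- tr$depth
    reflen <- e[length(e)]
    Pcov <- c(0, cumsum((d > 0) * (e - s)))
    Pdep <- c(0, cumsum(d * (e - s)))
    fi <- which(features$ref == r)
    a <- features$start[fi]; b <- features$end[fi]
    if (any(a < 0) || any(b > reflen))
      stop("feature outside reference ", r, " bounds")
    ia <- findInterval(a, s)
    ib <- findInterval(b - 1, s)
    cov <- (Pcov[ib + 1] - Pcov[ia]) -
      (d[ia] > 0) * (a - s[ia]) - (d[ib] > 0) * (e[ib] - b)
    dep <- (Pdep[ib + 1] - Pdep[ia]) -
      d[ia] * (a - s[ia]) - d[ib] * (e[ib] - b)
    features$covered_fraction[fi] <- cov / (b - a)
    features$mean_depth[fi] <- dep / (b - a)
  }
  features
}

#' Completeness report by annotation type
#'
#' Groups per-feature coverages by type label and reports, per type, the
#' element count, the percent of elements with `covered_fraction >= tau`
#' ("captured"), and the mean and median of per-element mean depths.
#'
#' @param coverages output of [feature_coverage()]
#' @param tau capture threshold on the covered fraction, in (0, 1];
#'   0.90 scores an element as captured when at least 90% of its sequence
#'   is present.
#' @return data.frame of class `completeness_report`: `type`, `n`,
#'   `pct_captured`, `mean_mean_depth`, `median_mean_depth`, with `tau`
#'   as an attribute
#' @export
completeness_report <- function(coverages, tau = 0.90) {
  if (tau <= 0 || tau > 1) stop("tau must be in (0, 1]")
  if (nrow(coverages) == 0L) {
    out <- data.frame(type = character(), n = integer(),
                      pct_captured = numeric(), mean_mean_depth = numeric(),
                      median_mean_depth = numeric())
    return(structure(out, tau = tau,
                     class = c("completeness_report", "data.frame")))
  }
  sp <- split(coverages, coverages$type)
  out <- data.frame(
    type = names(sp),
    n = vapply(sp, nrow, 0L),
    pct_captured = vapply(sp, function(g)
      100 * sum(g$covered_fraction >= tau) / nrow(g), 0),
    mean_mean_depth = vapply(sp, function(g) mean(g$mean_depth), 0),
    median_mean_depth = vapply(sp, function(g)
      stats::median(g$mean_depth), 0),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, tau = tau, class = c("completeness_report", "data.frame"))
}

#' Bimodality of the per-element coverage distribution
#'
#' Assemblies from short reads tend to either capture an annotated element
#' essentially whole or miss it entirely, so the covered-fraction
#' distribution is bimodal.  Reports a 10-bin histogram of covered
#' fractions and the fraction of elements at the extremes
#' (`covered_fraction <= 0.1` or `>= 0.9`).
#'
#' @param coverages output of [feature_coverage()]
#' @return list with `breaks`, `counts` (10 bins) and `extreme_fraction`
#' @export
coverage_bimodality <- function(coverages) {
  if (nrow(coverages) == 0L) stop("no feature coverages supplied")
  x <- coverages$covered_fraction
  # right = FALSE gives [a, b) bins; include.lowest keeps 1.0 in the last
  h <- graphics::hist(x, breaks = seq(0, 1, by = 0.1), plot = FALSE,
                      include.lowest = TRUE, right = FALSE)
  list(breaks = h$breaks, counts = h$counts,
       extreme_fraction = mean(x <= 0.1 | x >= 0.9))
}
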