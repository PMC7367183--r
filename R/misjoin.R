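# Insulation-score misjoin detection: score candidate points by the number
# of Hi-C pairs spanning them, compare against an empirical null built from
# artificial false-joins between unlinked contigs, and emit breakpoints.

#' Misjoin-detection parameters
#'
#' @param window flanking window on either side of a test point, in bases.
#'   1 Mb spans the typical range of strong proximity-ligation signal.
#' @param n_null number of artificial false-joins sampled for the
#'   empirical null.
#' @param flag_quantile a junction is flagged when its score is at or below
#'   this empirical quantile of the null sample, i.e. indistinguishable
#'   from a false join at the chosen stringency.
#' @param seed RNG seed for the null sampling.
#' @return list of class `misjoin_params`
#' @export
misjoin_params <- function(window = 1e6, n_null = 1000,
                           flag_quantile = 0.95, seed = 1L) {
  stopifnot(window >= 1, n_null >= 1,
            flag_quantile > 0, flag_quantile < 1)
  structure(list(window = window, n_null = n_null,
                 flag_quantile = flag_quantile, seed = seed),
            class = "misjoin_params")
}

#' Count Hi-C pairs spanning a focal point
#'
#' The insulation score of a test point: the number of pairs with one end
#' in `[max(0, position - W), position)` and the other in
#' `[position, min(L, position + W))`, both on the same scaffold.  Windows
#' are truncated at scaffold ends.
#'
#' @param contacts a [contact_set()] in scaffold coordinates
#' @param scaffold scaffold name
#' @param position 0-based focal position
#' @param window flank size W in bases
#' @return integer count
#' @export
spanning_count <- function(contacts, scaffold, position, window) {
  refs <- attr(contacts, "refs")
  L <- refs[[scaffold]]
  if (is.null(L) || is.na(L)) stop("unknown scaffold '", scaffold, "'")
  lo <- max(0, position - window)
  hi <- min(L, position + window)
  cis <- contacts$ref1 == scaffold & contacts$ref2 == scaffold
  # canonical order guarantees pos1 <= pos2 on cis pairs
  sum(cis &
        contacts$pos1 >= lo & contacts$pos1 < position &
        contacts$pos2 >= position & contacts$pos2 < hi)
}

# Junction positions of a layout: one per boundary between consecutive
# contig spans in a scaffold.  The test point is the first base of the
# right-hand contig span (for gapped joins, the base after the gap).
layout_junctions <- function(layout) {
  comp <- layout$components
  res <- list()
  for (sc in unique(comp$scaffold)) {
    rows <- comp[comp$scaffold == sc, , drop = FALSE]
    w <- which(rows$type == "W")
    if (length(w) < 2L) next
    res[[sc]] <- data.frame(
      scaffold = sc,
      position = rows$start[w[-1]],
      left_contig = rows$contig[w[-length(w)]],
      right_contig = rows$contig[w[-1]],
      stringsAsFactors = FALSE)
  }
  if (length(res) == 0L)
    return(data.frame(scaffold = character(), position = numeric(),
                      left_contig = character(), right_contig = character()))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Score contig-contig junctions across a layout
#'
#' Computes the insulation score at every junction between consecutive
#' contig spans of every scaffold, and optionally at fixed-stride positions
#' genome wide.
#'
#' @param contacts a [contact_set()] in scaffold coordinates of `layout`
#' @param layout a `scaff_layout`
#' @param params a [misjoin_params()]
#' @param stride optional stride in bases for an additional genome-wide
#'   scan (`NULL` scans junctions only)
#' @return data.frame of class `insulation_result`: `scaffold`, `position`,
#'   `score`, `left_contig`, `right_contig` (`NA` for strided points) and
#'   `truncated` (window clipped by a scaffold end).
#' @export
scan_joins <- function(contacts, layout, params = misjoin_params(),
                       stride = NULL) {
  refs <- attr(contacts, "refs")
  unknown <- setdiff(names(layout$scaffold_lengths), names(refs))
  if (length(unknown) > 0L)
    stop("layout scaffolds absent from the contact set reference map: ",
         paste(unknown, collapse = ", "))
  pts <- layout_junctions(layout)
  if (!is.null(stride)) {
    extra <- do.call(rbind, lapply(names(layout$scaffold_lengths), function(sc) {
      L <- layout$scaffold_lengths[[sc]]
      p <- seq(stride, L - 1, by = stride)
      if (length(p) == 0L) return(NULL)
      data.frame(scaffold = sc, position = p,
                 left_contig = NA_character_, right_contig = NA_character_,
                 stringsAsFactors = FALSE)
    }))
    pts <- rbind(pts, extra)
  }
  if (nrow(pts) == 0L)
    return(structure(cbind(pts, score = numeric(0), truncated = logical(0)),
                     class = c("insulation_result", "data.frame")))
  W <- params$window
  pts$score <- vapply(seq_len(nrow(pts)), function(i)
    spanning_count(contacts, pts$scaffold[i], pts$position[i], W), 0)
  lens <- layout$scaffold_lengths[pts$scaffold]
  pts$truncated <- pts$position - W < 0 | pts$position + W > lens
  rownames(pts) <- NULL
  structure(pts, class = c("insulation_result", "data.frame"))
}

#' Empirical false-join null of insulation scores
#'
#' Samples `n_null` artificial false-joins: each draw picks an ordered
#' random pair of distinct unlinked contigs (contigs placed in different
#' scaffolds), forms a virtual junction joining the right end of the first
#' to the left end of the second, and counts pairs with one end within `W`
#' of the first contig's right end and the other within `W` of the second
#' contig's left end.  Only inter-contig contacts can contribute, so the
#' sample estimates the score distribution a genuine misjoin would show.
#'
#' @inheritParams scan_joins
#' @return numeric vector of `n_null` null scores
#' @export
false_join_null <- function(contacts, layout, params = misjoin_params()) {
  comp <- layout$components
  w <- comp[comp$type == "W", , drop = FALSE]
  contigs <- unique(w$contig)
  home <- vapply(contigs, function(cg)
    unique(w$scaffold[w$contig == cg])[1], "")
  if (length(contigs) < 2L || length(unique(home)) < 2L)
    stop("need at least 2 unlinked contigs (in different scaffolds)")
  W <- params$window
  clens <- layout$contig_lengths[contigs]

  # scaffold-coordinate windows at each contig's left and right end
  left_win <- lapply(contigs, function(cg)
    contig_interval_to_scaffold(layout, cg, 0, min(W, clens[[cg]])))
  right_win <- lapply(contigs, function(cg)
    contig_interval_to_scaffold(layout, cg, max(0, clens[[cg]] - W), clens[[cg]]))
  names(left_win) <- names(right_win) <- contigs

  # only pairs bridging two scaffolds can fall in windows of unlinked contigs
  trans <- contacts[contacts$ref1 != contacts$ref2, , drop = FALSE]
  in_win <- function(ref, pos, win) {
    out <- rep(FALSE, length(ref))
    for (k in seq_len(nrow(win)))
      out <- out | (ref == win$scaffold[k] &
                      pos >= win$start[k] & pos < win$end[k])
    out
  }

  # precompute membership per contig end to make the draw loop cheap
  r1 <- trans$ref1; p1 <- trans$pos1; r2 <- trans$ref2; p2 <- trans$pos2
  mem_left1 <- lapply(left_win, function(wn) in_win(r1, p1, wn))
  mem_left2 <- lapply(left_win, function(wn) in_win(r2, p2, wn))
  mem_right1 <- lapply(right_win, function(wn) in_win(r1, p1, wn))
  mem_right2 <- lapply(right_win, function(wn) in_win(r2, p2, wn))

  with_seed(params$seed, {
    scores <- numeric(params$n_null)
    for (k in seq_len(params$n_null)) {
      repeat {
        ab <- sample(contigs, 2L)
        if (home[[ab[1]]] != home[[ab[2]]]) break
      }
      a <- ab[1]; b <- ab[2]
      scores[k] <- sum((mem_right1[[a]] & mem_left2[[b]]) |
                         (mem_right2[[a]] & mem_left1[[b]]))
    }
    scores
  })
}

#' Call misjoin breakpoints from scored junctions
#'
#' A junction is flagged when its score is less than or equal to the
#' empirical `flag_quantile` quantile of the null sample (inverse-ECDF
#' order statistic): its Hi-C support is indistinguishable from that of an
#' artificial false join.  Flagged junctions are returned as breakpoints
#' sorted by ascending score.
#'
#' @param results an `insulation_result` data.frame from [scan_joins()]
#' @param null_scores numeric null sample from [false_join_null()]
#' @param params a [misjoin_params()]
#' @return list with `results` (input plus `null_quantile` and `flagged`
#'   columns), `threshold`, and `breakpoints` (data.frame `scaffold`,
#'   `position`, `score`), ready for [apply_breaks()]
#' @export
call_misjoins <- function(results, null_scores, params = misjoin_params()) {
  if (length(null_scores) == 0L) stop("empty null sample")
  thr <- stats::quantile(null_scores, params$flag_quantile,
                         type = 1, names = FALSE)
  results$null_quantile <- stats::ecdf(null_scores)(results$score)
  results$flagged <- results$score <= thr
  bp <- results[results$flagged, c("scaffold", "position", "score")]
  bp <- bp[order(bp$score), , drop = FALSE]
  rownames(bp) <- NULL
  list(results = results, threshold = thr, breakpoints = bp)
}

#' Insulation-score misjoin detection, end to end
#'
#' Convenience wrapper: scores all junctions, builds the false-join null
#' and calls breakpoints.
#'
#' @inheritParams scan_joins
#' @return as [call_misjoins()], plus `null_scores`
#' @export
detect_misjoins <- function(contacts, layout, params = misjoin_params()) {
  res <- scan_joins(contacts, layout, params)
  null_scores <- false_join_null(contacts, layout, params)
  out <- call_misjoins(res, null_scores, params)
  out$null_scores <- null_scores
  out
}
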