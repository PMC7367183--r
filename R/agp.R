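# Internal coordinate convention: 0-based, half-open everywhere.  AGP's
# 1-based inclusive coordinates are converted at the I/O boundary only.

#' Construct a scaffold layout
#'
#' A scaffold layout describes an assembly as ordered, oriented contig spans
#' and gaps (AGP semantics).  It is the coordinate backbone used by the
#' misjoin scanner, the contact simulator and the break applicator.
#'
#' @param components data.frame with one row per component, columns
#'   `scaffold`, `type` (`"W"` for a contig span, `"N"`/`"U"` for a gap),
#'   `start`, `end` (0-based half-open scaffold coordinates), `contig`,
#'   `cstart`, `cend`, `orientation` (`"+"`/`"-"`; `NA` for gaps),
#'   `gap_type`, `linkage`, `evidence` (`NA` for contig spans).
#' @param contig_lengths optional named vector of contig lengths; inferred
#'   as the maximum used coordinate per contig when omitted.
#'
#' @return An object of class `scaff_layout` with elements `components`,
#'   `scaffold_lengths` and `contig_lengths`.
#' @export
scaffold_layout <- function(components, contig_lengths = NULL) {
  need <- c("scaffold", "type", "start", "end", "contig", "cstart", "cend",
            "orientation", "gap_type", "linkage", "evidence")
  miss <- setdiff(need, names(components))
  if (length(miss) > 0L)
    stop("layout components missing columns: ", paste(miss, collapse = ", "))
  components <- components[need]
  components$scaffold <- as.character(components$scaffold)
  components$contig <- as.character(components$contig)

  used <- components$type == "W"
  if (is.null(contig_lengths)) {
    contig_lengths <- tapply(components$cend[used], components$contig[used], max)
    contig_lengths <- stats::setNames(as.numeric(contig_lengths), names(contig_lengths))
  }
  obj <- structure(
    list(components = components,
         scaffold_lengths = vapply(split(components$end, components$scaffold), max, 0),
         contig_lengths = contig_lengths),
    class = "scaff_layout")
  validate_layout(obj)
  obj
}

validate_layout <- function(layout) {
  comp <- layout$components
  for (sc in unique(comp$scaffold)) {
    rows <- comp[comp$scaffold == sc, , drop = FALSE]
    if (rows$start[1] != 0)
      stop("scaffold ", sc, ": first component does not start at 0")
    if (any(rows$end <= rows$start))
      stop("scaffold ", sc, ": empty or inverted component interval")
    if (nrow(rows) > 1L && any(rows$start[-1] != rows$end[-nrow(rows)]))
      stop("scaffold ", sc, ": components do not tile the scaffold")
    gap <- rows$type != "W"
    if (any(gap[-1] & gap[-length(gap)]))
      stop("scaffold ", sc, ": two adjacent gap components")
  }
  w <- comp[comp$type == "W", , drop = FALSE]
  if (any(w$cstart < 0) || any(w$cend <= w$cstart))
    stop("invalid contig interval in layout")
  bad <- w$cend > layout$contig_lengths[w$contig]
  if (any(bad))
    stop("contig interval beyond contig length for: ",
         paste(unique(w$contig[bad]), collapse = ", "))
  # a contig's spans must not overlap each other anywhere in the layout
  for (cg in unique(w$contig)) {
    iv <- w[w$contig == cg, c("cstart", "cend"), drop = FALSE]
    if (nrow(iv) > 1L) {
      iv <- iv[order(iv$cstart), , drop = FALSE]
      if (any(iv$cstart[-1] < iv$cend[-nrow(iv)]))
        stop("overlapping spans of contig ", cg)
    }
  }
  invisible(layout)
}

#' @export
print.scaff_layout <- function(x, ...) {
  cat("<scaff_layout> ", length(x$scaffold_lengths), " scaffold(s), ",
      length(x$contig_lengths), " contig(s), ",
      format(sum(x$scaffold_lengths), big.mark = ","), " bp total\n", sep = "")
  invisible(x)
}

#' Total non-gap (contig span) bases of a layout
#' @param layout a `scaff_layout`
#' @return numeric base count
#' @export
span_bases <- function(layout) {
  w <- layout$components[layout$components$type == "W", , drop = FALSE]
  sum(w$end - w$start)
}

agp_error <- function(line_no, msg) {
  stop("AGP parse error at line ", line_no, ": ", msg, call. = FALSE)
}

#' Read an AGP v2.1 assembly layout
#'
#' @param x file path, connection, or character vector of AGP lines.
#'   Coordinates are 1-based inclusive on disk and converted to the internal
#'   0-based half-open convention.
#' @return a [scaffold_layout()] object.
#' @export
parse_agp <- function(x) {
  lines <- if (is.character(x) && length(x) == 1L && file.exists(x))
    readLines(x) else if (inherits(x, "connection")) readLines(x) else x
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0L) stop("AGP input contains no records")
  fields <- strsplit(lines[idx], "[ \t]+")

  n <- length(idx)
  comp <- data.frame(
    scaffold = character(n), type = character(n),
    start = numeric(n), end = numeric(n),
    contig = NA_character_, cstart = NA_real_, cend = NA_real_,
    orientation = NA_character_, gap_type = NA_character_,
    linkage = NA_character_, evidence = NA_character_,
    stringsAsFactors = FALSE)
  part_no <- integer(n)

  for (i in seq_len(n)) {
    f <- fields[[i]]
    ln <- idx[i]
    if (length(f) < 6L) agp_error(ln, "fewer than 6 columns")
    beg <- suppressWarnings(as.numeric(f[2]))
    end <- suppressWarnings(as.numeric(f[3]))
    prt <- suppressWarnings(as.integer(f[4]))
    if (anyNA(c(beg, end, prt))) agp_error(ln, "non-numeric coordinates")
    if (beg < 1 || end < beg) agp_error(ln, "invalid object coordinates")
    type <- f[5]
    comp$scaffold[i] <- f[1]
    comp$start[i] <- beg - 1
    comp$end[i] <- end
    part_no[i] <- prt
    if (type == "W") {
      if (length(f) < 9L) agp_error(ln, "W record needs 9 columns")
      cb <- suppressWarnings(as.numeric(f[7]))
      ce <- suppressWarnings(as.numeric(f[8]))
      if (anyNA(c(cb, ce)) || cb < 1 || ce < cb)
        agp_error(ln, "invalid component coordinates")
      if (ce - cb != end - beg)
        agp_error(ln, "component span length differs from object span")
      if (!f[9] %in% c("+", "-"))
        agp_error(ln, paste0("unsupported orientation '", f[9], "'"))
      comp$type[i] <- "W"
      comp$contig[i] <- f[6]
      comp$cstart[i] <- cb - 1
      comp$cend[i] <- ce
      comp$orientation[i] <- f[9]
    } else if (type %in% c("N", "U")) {
      glen <- suppressWarnings(as.numeric(f[6]))
      if (is.na(glen) || glen < 1) agp_error(ln, "invalid gap length")
      if (glen != end - beg + 1) agp_error(ln, "gap length differs from object span")
      comp$type[i] <- type
      comp$gap_type[i] <- if (length(f) >= 7L) f[7] else "scaffold"
      comp$linkage[i] <- if (length(f) >= 8L) f[8] else "yes"
      comp$evidence[i] <- if (length(f) >= 9L) f[9] else "na"
    } else {
      agp_error(ln, paste0("unknown component type '", type, "'"))
    }
  }

  # records must be sorted by object, parts consecutive from 1 and contiguous
  for (sc in unique(comp$scaffold)) {
    w <- which(comp$scaffold == sc)
    if (any(diff(w) != 1L))
      agp_error(idx[w[which(diff(w) != 1L)[1] + 1L]],
                paste0("records of object ", sc, " are not consecutive"))
    if (!identical(part_no[w], seq_along(w)))
      agp_error(idx[w[1]], paste0("part numbers of ", sc, " not consecutive from 1"))
    if (comp$start[w[1]] != 0)
      agp_error(idx[w[1]], "object does not start at base 1")
    if (length(w) > 1L && any(comp$start[w][-1] != comp$end[w][-length(w)]))
      agp_error(idx[w[1]], paste0("parts of ", sc, " overlap or leave holes"))
  }
  scaffold_layout(comp)
}

#' Write a layout as AGP v2.1
#'
#' @param layout a `scaff_layout`
#' @param file optional path or connection; when `NULL` the AGP lines are
#'   returned as a character vector.
#' @return character vector of AGP lines, invisibly when written to `file`.
#' @export
write_agp <- function(layout, file = NULL) {
  comp <- layout$components
  out <- character(nrow(comp))
  part <- stats::ave(seq_len(nrow(comp)), comp$scaffold, FUN = seq_along)
  for (i in seq_len(nrow(comp))) {
    if (comp$type[i] == "W") {
      out[i] <- paste(comp$scaffold[i], comp$start[i] + 1, comp$end[i], part[i],
                      "W", comp$contig[i], comp$cstart[i] + 1, comp$cend[i],
                      comp$orientation[i], sep = "\t")
    } else {
      out[i] <- paste(comp$scaffold[i], comp$start[i] + 1, comp$end[i], part[i],
                      comp$type[i], comp$end[i] - comp$start[i],
                      comp$gap_type[i], comp$linkage[i], comp$evidence[i],
                      sep = "\t")
    }
  }
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  out
}

#' Lift scaffold coordinates to contig coordinates
#'
#' Inverse of contig placement.  For a `-` span, scaffold offset `k` within
#' the span maps to contig coordinate `cend - 1 - k`.
#'
#' @param layout a `scaff_layout`
#' @param scaffold scaffold name (recycled)
#' @param position 0-based scaffold position(s)
#' @return data.frame with columns `contig`, `position`, `orientation` and
#'   `is_gap`; positions falling in gaps have `is_gap = TRUE` and `NA`
#'   contig coordinates rather than an error.
#' @export
lift_scaffold_to_contig <- function(layout, scaffold, position) {
  n <- max(length(scaffold), length(position))
  scaffold <- rep_len(as.character(scaffold), n)
  position <- rep_len(position, n)
  comp <- layout$components
  out <- data.frame(contig = NA_character_, position = NA_real_,
                    orientation = NA_character_, is_gap = FALSE,
                    stringsAsFactors = FALSE)[rep(1L, n), , drop = FALSE]
  rownames(out) <- NULL
  for (i in seq_len(n)) {
    len <- layout$scaffold_lengths[scaffold[i]]
    if (is.na(len)) stop("unknown scaffold '", scaffold[i], "'")
    if (position[i] < 0 || position[i] >= len)
      stop("position ", position[i], " outside scaffold ", scaffold[i])
    rows <- which(comp$scaffold == scaffold[i] &
                    comp$start <= position[i] & position[i] < comp$end)
    r <- rows[1]
    if (comp$type[r] != "W") {
      out$is_gap[i] <- TRUE
      next
    }
    k <- position[i] - comp$start[r]
    out$contig[i] <- comp$contig[r]
    out$orientation[i] <- comp$orientation[r]
    out$position[i] <- if (comp$orientation[r] == "+")
      comp$cstart[r] + k else comp$cend[r] - 1 - k
  }
  out
}

#' Lift contig coordinates to scaffold coordinates
#'
#' @param layout a `scaff_layout`
#' @param contig contig name (recycled)
#' @param position 0-based contig position(s); must fall inside a placed span
#' @return data.frame with columns `scaffold`, `position`, `orientation`.
#' @export
lift_contig_to_scaffold <- function(layout, contig, position) {
  n <- max(length(contig), length(position))
  contig <- rep_len(as.character(contig), n)
  position <- rep_len(position, n)
  comp <- layout$components
  out <- data.frame(scaffold = NA_character_, position = NA_real_,
                    orientation = NA_character_, stringsAsFactors = FALSE)
  out <- out[rep(1L, n), , drop = FALSE]
  rownames(out) <- NULL
  for (i in seq_len(n)) {
    r <- which(comp$type == "W" & comp$contig == contig[i] &
                 comp$cstart <= position[i] & position[i] < comp$cend)
    if (length(r) == 0L)
      stop("contig position ", contig[i], ":", position[i],
           " is not placed in the layout")
    r <- r[1]
    out$scaffold[i] <- comp$scaffold[r]
    out$orientation[i] <- comp$orientation[r]
    out$position[i] <- if (comp$orientation[r] == "+")
      comp$start[r] + (position[i] - comp$cstart[r])
    else
      comp$start[r] + (comp$cend[r] - 1 - position[i])
  }
  out
}

# Map a contig-coordinate interval [cstart, cend) to the scaffold interval(s)
# covering it.  Returns data.frame(scaffold, start, end); multiple rows when
# the contig is split across several spans.
contig_interval_to_scaffold <- function(layout, contig, cstart, cend) {
  comp <- layout$components
  r <- which(comp$type == "W" & comp$contig == contig &
               comp$cstart < cend & comp$cend > cstart)
  if (length(r) == 0L)
    return(data.frame(scaffold = character(), start = numeric(), end = numeric()))
  res <- lapply(r, function(j) {
    a <- max(cstart, comp$cstart[j])
    b <- min(cend, comp$cend[j])
    if (comp$orientation[j] == "+") {
      data.frame(scaffold = comp$scaffold[j],
                 start = comp$start[j] + (a - comp$cstart[j]),
                 end = comp$start[j] + (b - comp$cstart[j]),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(scaffold = comp$scaffold[j],
                 start = comp$start[j] + (comp$cend[j] - b),
                 end = comp$start[j] + (comp$cend[j] - a),
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, res)
}

#' Break scaffolds at misjoin positions
#'
#' Splits each named scaffold at the given 0-based positions (the offset of
#' the first base of the right-hand product).  Breaks falling inside a gap
#' remove the gap and split there, matching a scaffolder severing an
#' unsupported join; breaks inside a contig span split the span and the
#' underlying contig into deterministically named pieces (`<name>.1`,
#' `<name>.2`).  Leading/trailing gaps of the products are dropped.
#' Non-gap bases are conserved.
#'
#' @param layout a `scaff_layout`
#' @param breakpoints data.frame with columns `scaffold` and `position`
#'   (0-based scaffold coordinate); an empty data.frame is a no-op.
#' @return the broken `scaff_layout`
#' @export
apply_breaks <- function(layout, breakpoints) {
  if (is.null(breakpoints) || nrow(breakpoints) == 0L) return(layout)
  comp <- layout$components
  clens <- layout$contig_lengths
  bp <- breakpoints
  bp$scaffold <- as.character(bp$scaffold)
  for (i in seq_len(nrow(bp))) {
    len <- layout$scaffold_lengths[bp$scaffold[i]]
    if (is.na(len)) stop("breakpoint names unknown scaffold '", bp$scaffold[i], "'")
    if (bp$position[i] <= 0 || bp$position[i] >= len)
      stop("breakpoint at ", bp$position[i], " on ", bp$scaffold[i],
           " is a no-op split (must satisfy 0 < position < length)")
  }

  pieces <- list()
  for (sc in unique(comp$scaffold)) {
    rows <- comp[comp$scaffold == sc, , drop = FALSE]
    pos <- sort(unique(bp$position[bp$scaffold == sc]))
    if (length(pos) == 0L) {
      pieces[[length(pieces) + 1L]] <- rows
      next
    }
    cuts <- c(0, pos, layout$scaffold_lengths[[sc]])
    for (k in seq_len(length(cuts) - 1L)) {
      a <- cuts[k]; b <- cuts[k + 1L]
      sel <- rows[rows$end > a & rows$start < b, , drop = FALSE]
      # trim components straddling the cut points
      for (j in seq_len(nrow(sel))) {
        s0 <- sel$start[j]; e0 <- sel$end[j]
        na <- max(s0, a); nb <- min(e0, b)
        if (na == s0 && nb == e0) next
        if (sel$type[j] != "W") {   # gap split: gap is removed at the cut
          sel$start[j] <- na; sel$end[j] <- nb
          next
        }
        # split contig span: determine contig split coordinate(s)
        if (sel$orientation[j] == "+") {
          sel$cstart[j] <- sel$cstart[j] + (na - s0)
          sel$cend[j] <- sel$cend[j] - (e0 - nb)
        } else {
          sel$cstart[j] <- sel$cstart[j] + (e0 - nb)
          sel$cend[j] <- sel$cend[j] - (na - s0)
        }
        sel$start[j] <- na; sel$end[j] <- nb
        sel$contig[j] <- paste0(sel$contig[j], "@split")  # renamed below
      }
      # drop leading/trailing gaps
      while (nrow(sel) > 0L && sel$type[1] != "W") sel <- sel[-1, , drop = FALSE]
      while (nrow(sel) > 0L && sel$type[nrow(sel)] != "W")
        sel <- sel[-nrow(sel), , drop = FALSE]
      if (nrow(sel) == 0L) next
      sel$scaffold <- if (length(cuts) > 2L) paste0(sc, ".", k) else
        paste0(sc, ".", k)
      off <- sel$start[1]
      sel$start <- sel$start - off
      sel$end <- sel$end - off
      pieces[[length(pieces) + 1L]] <- sel
    }
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL

  # rename split contigs: each original contig cut at contig coordinates
  # yields pieces <name>.1, <name>.2, ... ordered by contig coordinate
  marked <- grepl("@split$", out$contig)
  if (any(marked)) {
    out$contig <- sub("@split$", "", out$contig)
    for (cg in unique(out$contig[marked])) {
      rows <- which(out$contig == cg)
      cutpts <- sort(unique(c(out$cstart[rows], out$cend[rows],
                              0, clens[[cg]])))
      # pieces delimited by the cut points actually used by spans
      used <- sort(unique(c(out$cstart[rows], out$cend[rows])))
      cutpts <- sort(unique(c(0, used, clens[[cg]])))
      starts <- cutpts[-length(cutpts)]
      ends <- cutpts[-1]
      for (j in rows) {
        p <- which(starts <= out$cstart[j] & out$cend[j] <= ends)
        if (length(p) != 1L)
          stop("break splits contig ", cg,
               " inconsistently with another span of the same contig")
        newname <- paste0(cg, ".", p)
        clens[[newname]] <- ends[p] - starts[p]
        out$cstart[j] <- out$cstart[j] - starts[p]
        out$cend[j] <- out$cend[j] - starts[p]
        out$contig[j] <- newname
      }
      clens <- clens[names(clens) != cg]
    }
  }
  scaffold_layout(out, contig_lengths = unlist(clens))
}

#' Read a breakpoint list from BED
#'
#' BED is 0-based half-open; each record's `start` is taken as the
#' breakpoint position (first base of the right-hand product).
#'
#' @param x path, connection or character lines
#' @return data.frame with columns `scaffold`, `position`
#' @export
read_breaks_bed <- function(x) {
  lines <- if (is.character(x) && length(x) == 1L && file.exists(x))
    readLines(x) else if (inherits(x, "connection")) readLines(x) else x
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L)
    return(data.frame(scaffold = character(), position = numeric()))
  f <- strsplit(lines, "[ \t]+")
  data.frame(scaffold = vapply(f, `[`, "", 1L),
             position = as.numeric(vapply(f, `[`, "", 2L)),
             stringsAsFactors = FALSE)
}

#' Write breakpoints as BED
#' @param breakpoints data.frame with `scaffold`, `position`
#' @param file optional path; lines returned when `NULL`
#' @return BED lines, invisibly when written
#' @export
write_breaks_bed <- function(breakpoints, file = NULL) {
  out <- sprintf("%s\t%d\t%d", breakpoints$scaffold,
                 as.integer(breakpoints$position),
                 as.integer(breakpoints$position) + 1L)
  if (!is.null(file)) { writeLines(out, file); return(invisible(out)) }
  out
}
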