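#' Per-base depth from read placements
#'
#' Direct interval accumulation: `depth[i]` is the number of placements
#' covering base i, so the depth sum equals the summed aligned lengths of
#' the placements supplied. Which placements to count (unique only, or every
#' best location of multi-mapped reads) is the caller's choice; translocation
#' calling feeds all best placements so duplicated donor content stays
#' visible.
#'
#' @param placements data.frame with `chrom`, `tstart`, `tend` (0-based
#'   half-open; [map_fragments()] output) and optionally `id` for error
#'   reporting.
#' @param genome named character vector (defines chromosome lengths).
#' @return named list of integer depth vectors, one per chromosome.
#' @export
compute_depth <- function(placements, genome) {
  lens <- nchar(genome)
  bad <- placements$tstart < 0 | placements$tend > lens[placements$chrom]
  if (any(bad)) {
    nm <- if (!is.null(placements$id)) placements$id[which(bad)[1]]
          else paste0("row ", which(bad)[1])
    sg_error("sg_validation_error", "out-of-bounds placement: ", nm)
  }
  out <- lapply(names(genome), function(cn) {
    L <- lens[[cn]]
    sel <- placements$chrom == cn
    if (!any(sel)) return(integer(L))
    s <- placements$tstart[sel]
    e <- placements$tend[sel]
    cumsum(tabulate(s + 1L, nbins = L) -
           c(0L, tabulate(e, nbins = L))[seq_len(L)])
  })
  names(out) <- names(genome)
  out
}

# delta trick check: read [0,100): +1 at base 1, -1 after base 100

#' Sliding-window median depth
#'
#' Windows start at 0, step, 2*step, ... while the start lies inside the
#' chromosome; the terminal window is truncated and flagged. Medians follow
#' the even-count rule (mean of the central pair).
#'
#' @param profile named list of per-base depth vectors ([compute_depth()]).
#' @param window_size window length in bp.
#' @param window_step step between window starts in bp.
#' @return data.frame: chrom, start, end, median_depth, truncated.
#' @export
window_medians <- function(profile, window_size, window_step) {
  out <- lapply(names(profile), function(cn) {
    d <- profile[[cn]]
    L <- length(d)
    starts <- seq(0, max(0, L - 1), by = window_step)
    starts <- starts[starts < L]
    ends <- pmin(starts + window_size, L)
    med <- vapply(seq_along(starts), function(i)
      median(d[(starts[i] + 1):ends[i]]), numeric(1))
    data.frame(chrom = cn, start = starts, end = ends,
               median_depth = med,
               truncated = (ends - starts) < window_size,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Call donor-present translocation segments from window medians
#'
#' The donor's baseline is the median of window medians on its home
#' chromosomes (assignment == donor). A window on a non-home chromosome
#' qualifies as donor-present when its median depth is at least
#' `high_frac * baseline`; consecutive qualifying windows (allowing
#' `max_gap_windows` non-qualifying windows between them) merge into one
#' segment. When `placements` carrying read-origin columns (`chrom.orig`)
#' are supplied, the donor chromosome of each segment is taken as the modal
#' origin of the reads placed inside it, and the segment is classed
#' homoeologous iff donor and host chromosomes share the same group index;
#' otherwise the class is NA.
#'
#' @param windows data.frame from [window_medians()] over the host genome.
#' @param assignment named character vector chrom -> A/C/D.
#' @param donor subgenome label of the read source.
#' @param high_frac qualification threshold as a fraction of baseline.
#' @param max_gap_windows tolerated gap windows inside a segment.
#' @param placements optional placements with origin columns `chrom.orig`
#'   (see [simulate_reads()] naming) used for donor-chromosome inference.
#' @return data.frame of segments: chrom, start, end, donor_subgenome,
#'   host_subgenome, mean_window_median, donor_chrom, class.
#' @export
call_segments <- function(windows, assignment, donor, high_frac = 0.5,
                          max_gap_windows = 1, placements = NULL) {
  home <- names(assignment)[assignment == donor]
  if (length(home) == 0)
    sg_error("sg_validation_error",
             "no home chromosomes for donor ", donor, "; baseline undefined")
  baseline <- median(windows$median_depth[windows$chrom %in% home])
  if (!is.finite(baseline) || baseline <= 0)
    sg_error("sg_validation_error", "undefined or zero donor baseline")
  segs <- list()
  for (cn in setdiff(unique(windows$chrom), home)) {
    w <- windows[windows$chrom == cn, , drop = FALSE]
    w <- w[order(w$start), , drop = FALSE]
    q <- which(w$median_depth >= high_frac * baseline)
    if (length(q) == 0) next
    grp <- cumsum(c(1L, diff(q) > max_gap_windows + 1L))
    for (g in unique(grp)) {
      idx <- q[grp == g]
      segs[[length(segs) + 1L]] <- data.frame(
        chrom = cn,
        start = min(w$start[idx]),
        end = max(w$end[idx]),
        donor_subgenome = donor,
        host_subgenome = unname(assignment[cn]),
        mean_window_median = mean(w$median_depth[idx]),
        stringsAsFactors = FALSE)
    }
  }
  if (length(segs) == 0)
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), donor_subgenome = character(0),
                      host_subgenome = character(0),
                      mean_window_median = numeric(0),
                      donor_chrom = character(0), class = character(0),
                      stringsAsFactors = FALSE))
  segs <- do.call(rbind, segs)
  segs$donor_chrom <- NA_character_
  if (nrow(segs) > 0 && !is.null(placements) &&
      "chrom.orig" %in% colnames(placements)) {
    for (i in seq_len(nrow(segs))) {
      sel <- placements$chrom == segs$chrom[i] &
        placements$tstart < segs$end[i] & placements$tend > segs$start[i]
      if (any(sel)) {
        tab <- sort(table(placements$chrom.orig[sel]), decreasing = TRUE)
        segs$donor_chrom[i] <- names(tab)[1]
      }
    }
  }
  segs$class <- ifelse(is.na(segs$donor_chrom), NA_character_,
                       ifelse(chrom_group(segs$donor_chrom) ==
                                chrom_group(segs$chrom),
                              "homoeologous", "non-homoeologous"))
  segs
}

#' Percentage share of translocated sequence
#'
#' @param part_len translocated length in the category of interest.
#' @param total_len total translocated length.
#' @return 100 * part / total (percent, unrounded).
#' @export
translocation_share <- function(part_len, total_len) {
  if (any(total_len <= 0))
    sg_error("sg_validation_error", "total length must be positive")
  if (any(part_len < 0) || any(part_len > total_len))
    sg_error("sg_validation_error", "part must lie in [0, total]")
  100 * part_len / total_len
}

#' Summarize translocated sequence by subgenome pair and class
#'
#' Totals partition the summed segment length exactly; shares are computed
#' with [translocation_share()].
#'
#' @param segments data.frame from [call_segments()] (or a truth table with
#'   the same columns).
#' @return list with `pairs` (donor, host, total_len, share_pct), `classes`
#'   (class, total_len, share_pct) and `total_len`.
#' @export
summarize_pairs <- function(segments) {
  if (nrow(segments) == 0)
    return(list(pairs = data.frame(donor = character(0), host = character(0),
                                   total_len = numeric(0),
                                   share_pct = numeric(0)),
                classes = data.frame(class = character(0),
                                     total_len = numeric(0),
                                     share_pct = numeric(0)),
                total_len = 0))
  len <- segments$end - segments$start
  total <- sum(len)
  key <- paste(segments$donor_subgenome, segments$host_subgenome, sep = "->")
  ptot <- tapply(len, key, sum)
  pairs <- data.frame(donor = sub("->.*", "", names(ptot)),
                      host = sub(".*->", "", names(ptot)),
                      total_len = as.numeric(ptot),
                      share_pct = translocation_share(as.numeric(ptot), total),
                      stringsAsFactors = FALSE)
  cl <- ifelse(is.na(segments$class), "unknown", segments$class)
  ctot <- tapply(len, cl, sum)
  classes <- data.frame(class = names(ctot), total_len = as.numeric(ctot),
                        share_pct = translocation_share(as.numeric(ctot),
                                                        total),
                        stringsAsFactors = FALSE)
  rownames(pairs) <- rownames(classes) <- NULL
  list(pairs = pairs, classes = classes, total_len = total)
}
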