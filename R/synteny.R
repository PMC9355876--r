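#' Call syntenic blocks from unique fragment placements
#'
#' A block is a maximal run of uniquely placed fragments from one source
#' chromosome onto one target chromosome, consistent in orientation and
#' monotone in target coordinate, tolerating up to `max_gap_fragments`
#' missing or interrupting fragments between consecutive members. Runs with
#' fewer than `min_block_fragments` members are discarded.
#'
#' @param placements data.frame from [map_fragments()] on fragments carrying
#'   `source_chrom` and `index`; only unique placements are considered.
#' @param min_block_fragments minimum members per block.
#' @param max_gap_fragments tolerated missing/interrupting fragments.
#' @return list with `blocks` (data.frame: source_chrom, target_chrom,
#'   orientation, fragment_count, source/target span columns) and `members`
#'   (list of integer row indices into `placements` per block).
#' @export
call_syntenic_blocks <- function(placements, min_block_fragments = 5,
                                 max_gap_fragments = 1) {
  pl <- placements[placements$unique, , drop = FALSE]
  pl$.row <- match(rownames(pl), rownames(placements))
  if (nrow(pl) == 0)
    return(list(blocks = empty_blocks(), members = list()))
  blocks <- list(); members <- list()
  for (sc in unique(pl$source_chrom)) {
    sub0 <- pl[pl$source_chrom == sc, , drop = FALSE]
    for (tc in unique(sub0$chrom)) for (st in c("+", "-")) {
      sub <- sub0[sub0$chrom == tc & sub0$strand == st, , drop = FALSE]
      if (nrow(sub) == 0) next
      sub <- sub[order(sub$index), , drop = FALSE]
      run <- 1L
      for (i in seq_len(nrow(sub))) {
        if (i == 1) next
        gap <- sub$index[i] - sub$index[i - 1] - 1L
        mono <- if (st == "+") sub$tstart[i] > sub$tstart[i - 1]
                else sub$tstart[i] < sub$tstart[i - 1]
        run[i] <- if (gap <= max_gap_fragments && mono)
          run[i - 1] else run[i - 1] + 1L
      }
      for (r in unique(run)) {
        m <- sub[run == r, , drop = FALSE]
        if (nrow(m) < min_block_fragments) next
        blocks[[length(blocks) + 1L]] <- data.frame(
          source_chrom = sc, target_chrom = tc, orientation = st,
          fragment_count = nrow(m),
          source_start = min(m$start), source_end = max(m$end),
          target_start = min(m$tstart), target_end = max(m$tend),
          stringsAsFactors = FALSE)
        members[[length(members) + 1L]] <- m$.row
      }
    }
  }
  blocks <- if (length(blocks)) do.call(rbind, blocks) else empty_blocks()
  list(blocks = blocks, members = members)
}

empty_blocks <- function() {
  data.frame(source_chrom = character(0), target_chrom = character(0),
             orientation = character(0), fragment_count = integer(0),
             source_start = numeric(0), source_end = numeric(0),
             target_start = numeric(0), target_end = numeric(0),
             stringsAsFactors = FALSE)
}

#' Assign polyploid chromosomes to ancestral subgenomes by similarity rank
#'
#' For every target chromosome, the similarity score is
#' `covered_bp * mean fragment identity / chromosome length`, where
#' `covered_bp` sums the lengths of retained (uniquely placed) fragments;
#' when a [call_syntenic_blocks()] result is supplied, only block-member
#' fragments count. Chromosomes are rank-sorted: the top third (highest
#' similarity to the A-like reference) is labeled A, the bottom third C and
#' the middle third D. Ties break by covered bp, then chromosome name.
#'
#' @param placements data.frame from [map_fragments()].
#' @param target named character vector (the polyploid genome).
#' @param blocks optional result of [call_syntenic_blocks()] on the same
#'   placements, restricting the score to block members.
#' @return list with `report` (per-chromosome data.frame) and `assignment`
#'   (named character vector chrom -> A/C/D).
#' @export
assign_subgenomes <- function(placements, target, blocks = NULL) {
  n <- length(target)
  if (n %% 3 != 0)
    warning("chromosome count not divisible by 3; labels assigned by tercile")
  mem <- if (!is.null(blocks))
    placements[unlist(blocks$members), , drop = FALSE]
  else placements[placements$unique, , drop = FALSE]
  flen <- if (nrow(mem) > 0) mem$tend - mem$tstart else numeric(0)
  report <- data.frame(target_chrom = names(target),
                       chrom_length = unname(nchar(target)),
                       covered_bp = 0, fragment_identity_mean = 0,
                       similarity_score = 0, stringsAsFactors = FALSE)
  if (nrow(mem) > 0) {
    cov <- tapply(flen, mem$chrom, sum)
    ident <- tapply(1 - mem$mismatches / flen, mem$chrom, mean)
    i <- match(names(cov), report$target_chrom)
    report$covered_bp[i] <- as.numeric(cov)
    report$fragment_identity_mean[i] <- as.numeric(ident)
  }
  report$similarity_score <- report$covered_bp *
    report$fragment_identity_mean / report$chrom_length
  if (all(report$similarity_score == 0))
    sg_error("sg_assignment_error",
             "all similarity scores are zero; refusing assignment ",
             "(no retained block fragments)")
  ord <- order(-report$similarity_score, -report$covered_bp,
               report$target_chrom)
  report <- report[ord, , drop = FALSE]
  kA <- ceiling(n / 3)
  kC <- ceiling((n - kA) / 2)
  lab <- rep("D", n)
  lab[seq_len(kA)] <- "A"
  lab[seq(n - kC + 1L, n)] <- "C"
  report$assignment <- lab
  rownames(report) <- NULL
  list(report = report,
       assignment = setNames(report$assignment, report$target_chrom))
}

#' Validate a subgenome assignment by ancestor read depth
#'
#' Groups per-chromosome mean depth of one ancestor's reads by assigned
#' label and flags the assignment consistent when the expected ancestor's
#' chromosomes have strictly the highest mean depth.
#'
#' @param mean_depth named numeric vector: mean read depth per chromosome.
#' @param assignment named character vector chrom -> A/C/D.
#' @param ancestor the subgenome label the reads come from.
#' @return data.frame (chrom, assignment, mean_depth) with attribute
#'   `consistent` (logical).
#' @export
validate_by_depth <- function(mean_depth, assignment, ancestor) {
  tab <- data.frame(chrom = names(assignment),
                    assignment = unname(assignment),
                    mean_depth = unname(mean_depth[names(assignment)]),
                    stringsAsFactors = FALSE)
  tab$mean_depth[is.na(tab$mean_depth)] <- 0
  grp <- tapply(tab$mean_depth, tab$assignment, mean)
  consistent <- FALSE
  if (all(tab$mean_depth == 0) || !(ancestor %in% names(grp))) {
    warning("no depth signal; consistency flag unset")
  } else {
    others <- grp[setdiff(names(grp), ancestor)]
    consistent <- length(others) > 0 && all(grp[[ancestor]] > others)
    if (!consistent) warning("depth ordering does not match the expected ",
                             "ancestor affinity (tie or inversion)")
  }
  attr(tab, "consistent") <- consistent
  tab
}
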