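#' @useDynLib subgenomics, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats median cor hclust as.dist pchisq phyper wilcox.test
#'   p.adjust rbinom rpois rnbinom runif rnorm setNames complete.cases isoreg
#' @importFrom utils read.table write.table
NULL

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

sg_log <- function(..., level = "INFO") {
  message(sprintf("[%s] %s", level, paste0(...)))
}

sg_error <- function(class, ...) {
  stop(structure(class = c(class, "subgenomics_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

#' Genomic interval constructor (0-based, half-open)
#'
#' All internal coordinates in the package are 0-based half-open; conversion
#' to/from the 1-based conventions of VCF/GFF3 happens only at I/O edges.
#'
#' @param chrom character chromosome names.
#' @param start integer start, `>= 0`.
#' @param end integer end, `> start`.
#' @return data.frame with columns chrom, start, end.
#' @export
interval <- function(chrom, start, end) {
  start <- as.numeric(start); end <- as.numeric(end)
  if (any(start < 0)) sg_error("sg_interval_error", "interval start must be >= 0")
  if (any(end <= start)) sg_error("sg_interval_error", "interval end must exceed start")
  data.frame(chrom = as.character(chrom), start = start, end = end,
             stringsAsFactors = FALSE)
}

interval_length <- function(iv) iv$end - iv$start

# Reverse complement of an uppercase DNA string (N self-complementary).
revcomp <- function(x) {
  chartr("ACGTN", "TGCAN", vapply(x, function(s)
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""), ""))
}

# Homoeologous group index from a chromosome name such as "1A" or "chr2D".
chrom_group <- function(chrom) {
  g <- regmatches(chrom, regexpr("[0-9]+", chrom))
  out <- rep(NA_character_, length(chrom))
  out[lengths(regmatches(chrom, gregexpr("[0-9]+", chrom))) > 0] <- unlist(g)
  out
}

# Subgenome letter from a chromosome name ("1A" -> "A").
chrom_subgenome <- function(chrom) {
  m <- regmatches(chrom, regexpr("[ACD]$", chrom))
  out <- rep(NA_character_, length(chrom))
  out[grepl("[ACD]$", chrom)] <- m
  out
}
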