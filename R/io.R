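#' Read a FASTA file into a named vector of uppercase DNA sequences
#'
#' Sequences are normalized to uppercase over the closed alphabet
#' \{A,C,G,T,N\}; IUPAC ambiguity codes other than N are mapped to N with a
#' logged count, so downstream mismatch counting sees a closed alphabet.
#'
#' @param path FASTA file.
#' @return named character vector (name = record id, value = sequence).
#'   Empty file returns an empty vector with a warning.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) sg_error("sg_io_error", "no such file: ", path)
  if (file.size(path) == 0) {
    warning("empty FASTA file: ", path)
    return(setNames(character(0), character(0)))
  }
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e)
                    sg_error("sg_format_error", "malformed FASTA '", path,
                             "': ", conditionMessage(e)))
  seqs <- toupper(as.character(set))
  nm <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(nm)) || any(!nzchar(seqs))) {
    bad <- which(!nzchar(nm) | !nzchar(seqs))[1]
    sg_error("sg_format_error", "empty FASTA record at position ", bad,
             " in ", path)
  }
  n_amb <- sum(vapply(seqs, function(s)
    nchar(gsub("[ACGTN]", "", s)), numeric(1)))
  if (n_amb > 0) {
    sg_log(n_amb, " ambiguous bases mapped to N in ", path)
    seqs <- vapply(seqs, function(s) gsub("[^ACGTN]", "N", s), "")
  }
  if (anyDuplicated(nm))
    sg_error("sg_format_error", "duplicated record name: ",
             nm[duplicated(nm)][1])
  setNames(unname(seqs), nm)
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output file.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  set <- Biostrings::BStringSet(seqs)
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Write reads to FASTQ
#'
#' @param reads data.frame with columns `id`, `seq` (and optionally `qual`;
#'   a constant high quality is emitted when absent).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  qual <- if (!is.null(reads$qual)) reads$qual else
    vapply(nchar(reads$seq), function(n) strrep("I", n), "")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", reads$id, "\n", reads$seq, "\n+\n", qual), con)
  invisible(path)
}

#' Read a FASTQ file
#'
#' @param path FASTQ file.
#' @return data.frame with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) %% 4 != 0)
    sg_error("sg_format_error", "FASTQ record count not a multiple of 4: ", path)
  ids <- lines[seq(1, length(lines), by = 4)]
  if (!all(startsWith(ids, "@")))
    sg_error("sg_format_error", "malformed FASTQ header in ", path)
  data.frame(id = sub("^@", "", ids),
             seq = toupper(lines[seq(2, length(lines), by = 4)]),
             qual = lines[seq(4, length(lines), by = 4)],
             stringsAsFactors = FALSE)
}

#' Read a labeled numeric TSV matrix
#'
#' First row and first column are labels. Missing cells ("" or "NA") become
#' `NA`, never silently zero.
#'
#' @param path TSV file.
#' @return numeric matrix with dimnames.
#' @export
read_tsv_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) sg_error("sg_format_error", "empty table: ", path)
  cells <- strsplit(lines, "\t", fixed = TRUE)
  ncol_expected <- length(cells[[1]])
  ragged <- which(lengths(cells) != ncol_expected)
  if (length(ragged) > 0)
    sg_error("sg_format_error", "ragged row ", ragged[1], " in ", path)
  header <- cells[[1]][-1]
  body <- cells[-1]
  rn <- vapply(body, `[`, "", 1)
  vals <- t(vapply(body, function(r) {
    v <- r[-1]
    v[v %in% c("", "NA")] <- NA
    suppressWarnings(as.numeric(v))
  }, numeric(ncol_expected - 1)))
  if (length(body) == 1) vals <- matrix(vals, nrow = 1)
  dimnames(vals) <- list(rn, header)
  vals
}

#' Write a labeled numeric matrix as TSV
#'
#' @param mat matrix with dimnames.
#' @param path output file.
#' @param corner label for the top-left header cell.
#' @return `path`, invisibly.
#' @export
write_tsv_matrix <- function(mat, path, corner = "id") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c(corner, colnames(mat))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a VCF subset into variant records
#'
#' Parses CHROM/POS/REF/ALT/QUAL, the INFO keys QD, FS and MQ (NA when
#' absent) and per-sample GT (plus DP when present). Positions stay 1-based
#' as in the VCF.
#'
#' @param path VCF 4.x file.
#' @return list with `variants` (data.frame: chrom, pos, ref, alt, qual, qd,
#'   fs, mq, allele_count, is_indel, is_het_any), `gt` (character matrix,
#'   variants x samples, NA for missing) and `dp` (numeric matrix or NULL).
#' @export
read_vcf_lite <- function(path) {
  if (!file.exists(path)) sg_error("sg_io_error", "no such file: ", path)
  head_lines <- readLines(path, n = 500L, warn = FALSE)
  if (!any(startsWith(head_lines, "#CHROM")))
    sg_error("sg_format_error", "missing #CHROM header line in ", path)
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e)
                  sg_error("sg_format_error", "malformed VCF '", path, "': ",
                           conditionMessage(e)))
  fx <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  info_num <- function(key) {
    x <- vcfR::extract.info(v, element = key, as.numeric = TRUE)
    if (is.null(x)) rep(NA_real_, nrow(fx)) else as.numeric(x)
  }
  gt <- NULL; dp <- NULL
  if (ncol(v@gt) > 1) {
    gt <- vcfR::extract.gt(v, element = "GT")
    fmt <- strsplit(v@gt[1, "FORMAT"], ":", fixed = TRUE)[[1]]
    if ("DP" %in% fmt)
      dp <- suppressWarnings(vcfR::extract.gt(v, element = "DP",
                                              as.numeric = TRUE))
  }
  alt <- fx$ALT
  n_alt <- ifelse(is.na(alt) | alt == ".", 0L,
                  lengths(strsplit(alt, ",", fixed = TRUE)))
  is_indel <- mapply(function(r, a) {
    if (is.na(a) || a == ".") return(FALSE)
    any(nchar(strsplit(a, ",", fixed = TRUE)[[1]]) != nchar(r))
  }, fx$REF, alt, USE.NAMES = FALSE)
  het_any <- if (is.null(gt)) rep(NA, nrow(fx)) else
    apply(gt, 1, function(g) any(is_het_gt(g), na.rm = TRUE))
  variants <- data.frame(
    chrom = fx$CHROM,
    pos = as.integer(fx$POS),
    ref = fx$REF,
    alt = alt,
    qual = suppressWarnings(as.numeric(fx$QUAL)),
    qd = info_num("QD"),
    fs = info_num("FS"),
    mq = info_num("MQ"),
    allele_count = n_alt + 1L,
    is_indel = is_indel,
    is_het_any = het_any,
    stringsAsFactors = FALSE)
  list(variants = variants, gt = gt, dp = dp)
}

is_missing_gt <- function(g) is.na(g) | g %in% c(".", "./.", ".|.")

is_het_gt <- function(g) {
  a <- strsplit(ifelse(is_missing_gt(g), "0/0", g), "[/|]")
  het <- vapply(a, function(x) length(unique(x)) > 1, logical(1))
  het[is_missing_gt(g)] <- NA
  het
}

# allele dosage of the first ALT allele; NA for missing genotypes
gt_dosage <- function(g) {
  d <- vapply(strsplit(ifelse(is_missing_gt(g), "0/0", g), "[/|]"),
              function(x) sum(x == "1"), numeric(1))
  d[is_missing_gt(g)] <- NA_real_
  d
}

#' Write variant records as a plain-text VCF
#'
#' @param variants data.frame as returned in `read_vcf_lite()$variants`.
#' @param path output file.
#' @param gt optional character genotype matrix (variants x samples).
#' @param dp optional numeric depth matrix matching `gt`.
#' @return `path`, invisibly.
#' @export
write_vcf_lite <- function(variants, path, gt = NULL, dp = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Qual by depth\">",
               "##INFO=<ID=FS,Number=1,Type=Float,Description=\"Fisher strand\">",
               "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"Mapping quality\">",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">"),
             con)
  samples <- if (!is.null(gt)) colnames(gt) else character(0)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", if (length(samples)) c("FORMAT", samples)),
                   collapse = "\t"), con)
  info <- apply(cbind(QD = variants$qd, FS = variants$fs, MQ = variants$mq),
                1, function(r) {
                  keep <- !is.na(r)
                  if (!any(keep)) "." else
                    paste(paste0(names(r)[keep], "=", r[keep]), collapse = ";")
                })
  fixed <- paste(variants$chrom, variants$pos, ".", variants$ref,
                 variants$alt,
                 ifelse(is.na(variants$qual), ".", variants$qual),
                 ".", info, sep = "\t")
  if (length(samples)) {
    fmt <- if (!is.null(dp)) "GT:DP" else "GT"
    cells <- gt
    cells[is.na(cells)] <- "./."
    if (!is.null(dp)) {
      dpc <- dp
      dpc[is.na(dpc)] <- "."
      cells <- matrix(paste(cells, dpc, sep = ":"), nrow = nrow(gt),
                      dimnames = dimnames(gt))
    }
    fixed <- paste(fixed, fmt,
                   apply(cells, 1, paste, collapse = "\t"), sep = "\t")
  }
  writeLines(fixed, con)
  invisible(path)
}

#' Write intervals to BED (0-based half-open, as stored internally)
#'
#' @param segments data.frame with chrom, start, end and optional extra
#'   columns appended after the coordinate triple.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(segments, path) {
  core <- segments[, c("chrom", "start", "end"), drop = FALSE]
  extra <- segments[, setdiff(colnames(segments), colnames(core)), drop = FALSE]
  write.table(cbind(core, extra), path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a GFF3 subset (gene/mRNA/CDS features)
#'
#' Coordinates convert from GFF3's 1-based closed convention to the
#' package's 0-based half-open intervals at this boundary.
#'
#' @param path GFF3 file.
#' @return data.frame: chrom, start, end (0-based half-open), strand, type,
#'   id, parent.
#' @export
read_gff3_lite <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e)
                   sg_error("sg_format_error", "malformed GFF3 '", path,
                            "': ", conditionMessage(e)))
  df <- as.data.frame(gr)
  df <- df[df$type %in% c("gene", "mRNA", "CDS"), , drop = FALSE]
  parent <- if ("Parent" %in% colnames(df))
    vapply(df$Parent, function(p) if (length(p)) as.character(p[1])
           else NA_character_, "")
  else rep(NA_character_, nrow(df))
  out <- data.frame(chrom = as.character(df$seqnames),
                    start = df$start - 1L, end = df$end,
                    strand = as.character(df$strand),
                    type = as.character(df$type),
                    id = if ("ID" %in% colnames(df)) as.character(df$ID)
                         else NA_character_,
                    parent = parent, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Write gene/mRNA/CDS features as GFF3
#'
#' @param features data.frame as returned by [read_gff3_lite()] (0-based
#'   half-open coordinates; converted to 1-based closed on output).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gff3_lite <- function(features, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  attrs <- ifelse(is.na(features$parent),
                  paste0("ID=", features$id),
                  paste0("ID=", features$id, ";Parent=", features$parent))
  writeLines(paste(features$chrom, "subgenomics", features$type,
                   features$start + 1L, features$end, ".",
                   features$strand, ".", attrs, sep = "\t"), con)
  invisible(path)
}
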