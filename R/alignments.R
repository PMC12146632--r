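#' Read alignment records from SAM/BAM
#'
#' Loads primary and supplementary alignment records into a plain
#' `data.frame`, the internal exchange format of the profiler and the
#' validation/masking operations. Text SAM is converted on the fly with
#' [Rsamtools::asBam]; CRAM is accepted when `Rsamtools` can open it.
#' Unmapped and secondary records are kept out unless requested: the
#' split-read machinery uses primary + supplementary records (and the
#' `SA` tag dialect), while depth-style consumers may ask for secondary
#' records too.
#'
#' @param path Path to a `.sam`, `.bam` or `.cram` file.
#' @param includeSecondary Keep secondary (0x100) records (default
#'   `FALSE`).
#' @return `data.frame` with columns `qname`, `flag`, `rname`, `pos`,
#'   `mapq`, `cigar`, `seq`, `sa` (the `SA` tag or `NA`).
#' @export
readAlignments <- function(path, includeSecondary = FALSE) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "sam") {
    dest <- tempfile(fileext = "")
    bam <- suppressMessages(asBam(path, dest, overwrite = TRUE,
                                  indexDestination = FALSE))
  } else {
    bam <- path
  }
  flag <- scanBamFlag(isUnmappedQuery = FALSE,
                      isSecondaryAlignment = if (includeSecondary) NA else FALSE)
  param <- ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq"),
    tag = "SA", flag = flag)
  res <- scanBam(BamFile(bam), param = param)[[1]]
  sa <- res$tag$SA
  if (is.null(sa)) sa <- rep(NA_character_, length(res$qname))
  data.frame(
    qname = res$qname,
    flag = res$flag,
    rname = as.character(res$rname),
    pos = res$pos,
    mapq = res$mapq,
    cigar = res$cigar,
    seq = as.character(res$seq),
    sa = sa,
    stringsAsFactors = FALSE
  )
}

## --- CIGAR helpers shared by profiler, validation and masking ---------

.cigarParts <- function(cigar) {
  list(ops = explodeCigarOps(cigar)[[1]],
       lens = explodeCigarOpLengths(cigar)[[1]])
}

.leadingClip <- function(ops, lens) {
  n <- 0L
  for (i in seq_along(ops)) {
    if (ops[i] %in% c("S", "H")) n <- n + lens[i] else break
  }
  n
}

.trailingClip <- function(ops, lens) {
  .leadingClip(rev(ops), rev(lens))
}

.alignedQueryWidth <- function(ops, lens) {
  sum(lens[ops %in% c("M", "I", "=", "X")])
}

.refWidth <- function(ops, lens) {
  sum(lens[ops %in% c("M", "D", "N", "=", "X")])
}

## Reference positions covered by one record (ref-consuming ops);
## deletions count as covered when `spanDeletions` (mirrors depth -J).
.coveredRefRanges <- function(pos, cigar, spanDeletions = TRUE) {
  p <- .cigarParts(cigar)
  keep <- if (spanDeletions) c("M", "D", "N", "=", "X") else c("M", "=", "X")
  at <- pos
  st <- integer(0); en <- integer(0)
  for (i in seq_along(p$ops)) {
    op <- p$ops[i]; len <- p$lens[i]
    if (op %in% c("M", "D", "N", "=", "X")) {
      if (op %in% keep) {
        st <- c(st, at); en <- c(en, at + len - 1L)
      }
      at <- at + len
    }
  }
  IRanges::reduce(IRanges(st, en))
}
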