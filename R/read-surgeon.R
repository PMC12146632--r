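## Read surgery: splitting reads at somatic V(D)J breakends and
## enriching germline J-D coverage before reassembly.

#' J-D enrichment region of a reference
#'
#' The interval targeted for coverage enrichment: the J--D span of the
#' locus extended by `flank` on both sides (clipped to position 1).
#'
#' @param locusMap A [LocusMap].
#' @param flank Extension in bp (default 5000).
#' @return [IRanges::IRanges] of length 1.
#' @export
enrichmentRegion <- function(locusMap, flank = 5000) {
  jd <- jdInterval(locusMap)
  stopifnot(length(jd) == 1)
  IRanges(max(1L, start(jd) - flank), end(jd) + flank)
}

#' Plan read surgery from profiler evidence
#'
#' One cut per somatic junction, at the junction's read offset (the
#' midpoint when split alignments overlap). Junctions connecting two V
#' genes are not somatic V(D)J recombination and yield no cut;
#' unrecombined reads are absent from the plan.
#'
#' @param evidences List of [ReadEvidence].
#' @return Named list: `readId -> ` sorted integer cut offsets (a read
#'   cut at offset k yields fragments `1..k` and `k+1..length`).
#' @export
planSurgery <- function(evidences) {
  plan <- list()
  for (ev in evidences) {
    if (eventClass(ev) == "unrecombined") next
    jx <- readJunctions(ev)
    vv <- !is.na(jx$leftClass) & !is.na(jx$rightClass) &
      jx$leftClass == "V" & jx$rightClass == "V"
    cuts <- sort(unique(as.integer(jx$readOffset[!vv])))
    if (length(cuts)) plan[[readId(ev)]] <- cuts
  }
  plan
}

#' Cut reads according to a surgery plan
#'
#' Splits each planned read at its cut offsets; fragments are named
#' `readid/1`, `readid/2`, ... in read order and their concatenation
#' equals the original sequence. Fragments shorter than `minFragment`
#' are dropped and logged. Reads absent from the plan pass through
#' unchanged. Quality strings, when present, are sliced alongside.
#'
#' @param reads Named [Biostrings::DNAStringSet].
#' @param plan Surgery plan from [planSurgery].
#' @param minFragment Minimum emitted fragment length (default 500).
#' @param quality Optional named [Biostrings::BStringSet] of per-base
#'   qualities matching `reads`.
#' @return List with `reads` (fragments + untouched reads), `quality`
#'   (`NULL` if none supplied) and `dropped` (`data.frame` of dropped
#'   fragments: `readId`, `fragment`, `length`).
#' @export
applySurgery <- function(reads, plan, minFragment = 500, quality = NULL) {
  stopifnot(!is.null(names(reads)))
  unknown <- setdiff(names(plan), names(reads))
  if (length(unknown))
    stop("plan refers to unknown read(s): ", paste(unknown, collapse = ", "))
  outSeq <- list(); outQual <- list()
  dropped <- data.frame(readId = character(0), fragment = character(0),
                        length = integer(0), stringsAsFactors = FALSE)
  for (nm in names(reads)) {
    cuts <- plan[[nm]]
    if (is.null(cuts)) {
      outSeq[[nm]] <- reads[[nm]]
      if (!is.null(quality)) outQual[[nm]] <- quality[[nm]]
      next
    }
    len <- length(reads[[nm]])
    if (any(cuts <= 0 | cuts >= len))
      stop("cut offset out of range for read '", nm, "'")
    bounds <- c(0L, cuts, len)
    for (k in seq_len(length(bounds) - 1)) {
      st <- bounds[k] + 1L; en <- bounds[k + 1]
      fid <- sprintf("%s/%d", nm, k)
      if (en - st + 1L < minFragment) {
        dropped <- rbind(dropped, data.frame(
          readId = nm, fragment = fid, length = en - st + 1L,
          stringsAsFactors = FALSE))
        next
      }
      outSeq[[fid]] <- subseq(reads[[nm]], st, en)
      if (!is.null(quality)) outQual[[fid]] <- subseq(quality[[nm]], st, en)
    }
  }
  res <- list(reads = do.call(DNAStringSet, list(outSeq)),
              quality = if (is.null(quality)) NULL
                        else do.call(BStringSet, list(outQual)),
              dropped = dropped)
  res
}

#' Enrich J-D coverage by read duplication
#'
#' Emits every read or fragment whose alignment overlaps the enrichment
#' region `factor` times (extra copies suffixed `" dup"`, `" dup2"`,
#' ...), and every other read once, doubling (by default) the read
#' depth over the J--D region. The enriched set is intended exclusively
#' for de novo assembly.
#'
#' @param reads Named [Biostrings::DNAStringSet] of processed
#'   reads/fragments.
#' @param alignments SAM/BAM path or [readAlignments] `data.frame` of
#'   these reads on the reference carrying `locusMap`.
#' @param locusMap [LocusMap] of that reference.
#' @param flank Region flank, see [enrichmentRegion].
#' @param factor Total copies for overlapping reads (default 2).
#' @return Named [Biostrings::DNAStringSet].
#' @export
enrichReads <- function(reads, alignments, locusMap, flank = 5000,
                        factor = 2) {
  stopifnot(factor >= 1)
  if (is.character(alignments)) alignments <- readAlignments(alignments)
  region <- enrichmentRegion(locusMap, flank)
  aln <- alignments[alignments$rname == referenceName(locusMap), ,
                    drop = FALSE]
  overlaps <- character(0)
  for (i in seq_len(nrow(aln))) {
    rr <- .coveredRefRanges(aln$pos[i], aln$cigar[i])
    if (any(start(rr) <= end(region) & end(rr) >= start(region)))
      overlaps <- c(overlaps, aln$qname[i])
  }
  overlaps <- unique(overlaps)
  outSeq <- list()
  for (nm in names(reads)) {
    outSeq[[nm]] <- reads[[nm]]
    if (nm %in% overlaps && factor > 1) {
      for (k in seq_len(factor - 1)) {
        suffix <- if (k == 1) " dup" else sprintf(" dup%d", k)
        outSeq[[paste0(nm, suffix)]] <- reads[[nm]]
      }
    }
  }
  do.call(DNAStringSet, list(outSeq))
}

#' Write reads as FASTA
#'
#' @param reads Named [Biostrings::DNAStringSet].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeReadsFasta <- function(reads, path) {
  writeXStringSet(reads, path)
  invisible(path)
}
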