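#' Extract aligned segments of one read
#'
#' Normalises the primary + supplementary alignment records of a single
#' read into segments in original-read orientation, sorted by read
#' offset. Hard clips are reconciled with the soft-clip convention (both
#' count toward read coordinates), and the `SA`-tag dialect is used to
#' recover segments whose supplementary records are absent.
#'
#' @param records `data.frame` of alignment records for one read (layout
#'   of [readAlignments]).
#' @return `data.frame` with columns `readId`, `readStart`, `readEnd`,
#'   `reference`, `refStart`, `refEnd`, `orientation`, `cigar`,
#'   `samFlag`, sorted by `readStart`.
#' @export
extractSegments <- function(records) {
  stopifnot(length(unique(records$qname)) == 1)
  ## SA-tag dialect: materialise segments listed in SA but not present
  ## as records
  extra <- list()
  for (i in seq_len(nrow(records))) {
    sa <- records$sa[i]
    if (is.na(sa) || !nzchar(sa)) next
    for (ent in strsplit(sa, ";", fixed = TRUE)[[1]]) {
      if (!nzchar(ent)) next
      f <- strsplit(ent, ",", fixed = TRUE)[[1]]
      pos <- as.integer(f[2])
      known <- any(records$pos == pos & records$rname == f[1] &
                     records$cigar == f[4])
      if (!known)
        extra[[length(extra) + 1]] <- data.frame(
          qname = records$qname[i],
          flag = if (f[3] == "-") 2064L else 2048L,
          rname = f[1], pos = pos, mapq = as.integer(f[5]),
          cigar = f[4], seq = NA_character_, sa = NA_character_,
          stringsAsFactors = FALSE)
    }
  }
  if (length(extra)) records <- rbind(records, do.call(rbind, extra))
  segs <- lapply(seq_len(nrow(records)), function(i) {
    p <- .cigarParts(records$cigar[i])
    lead <- .leadingClip(p$ops, p$lens)
    trail <- .trailingClip(p$ops, p$lens)
    alq <- .alignedQueryWidth(p$ops, p$lens)
    readLen <- lead + alq + trail
    minus <- bitwAnd(records$flag[i], 16L) > 0
    if (minus) {
      rs <- trail + 1L; re <- readLen - lead
    } else {
      rs <- lead + 1L; re <- readLen - trail
    }
    data.frame(
      readId = records$qname[i], readStart = rs, readEnd = re,
      reference = records$rname[i], refStart = records$pos[i],
      refEnd = records$pos[i] + .refWidth(p$ops, p$lens) - 1L,
      orientation = if (minus) "-" else "+",
      cigar = records$cigar[i], samFlag = records$flag[i],
      readLen = readLen, stringsAsFactors = FALSE)
  })
  segs <- do.call(rbind, segs)
  if (length(unique(segs$readLen)) > 1)
    stop("inconsistent read lengths across records of read ",
         records$qname[1])
  ## drop duplicates (record + its SA echo)
  segs <- segs[!duplicated(segs[c("refStart", "cigar", "orientation")]), ,
               drop = FALSE]
  segs[order(segs$readStart, segs$refStart), , drop = FALSE]
}

.emptyJunctions <- function() {
  data.frame(readId = character(0), readOffset = integer(0),
             leftRef = numeric(0), rightRef = numeric(0),
             origin = character(0), flip = logical(0),
             leftGene = character(0), leftSide = character(0),
             leftClass = character(0), leftDist = numeric(0),
             leftSegStart = numeric(0), leftSegEnd = numeric(0),
             rightGene = character(0), rightSide = character(0),
             rightClass = character(0), rightDist = numeric(0),
             rightSegStart = numeric(0), rightSegEnd = numeric(0),
             meaningful = logical(0), confident = logical(0),
             stringsAsFactors = FALSE)
}

.junctionRow <- function(readId, readOffset, leftRef, rightRef, origin,
                         flip, leftRss, rightRss, leftSeg, rightSeg,
                         confidentOverride = NA) {
  f <- function(r, what) if (is.null(r)) switch(what, gene = NA_character_,
                                                side = NA_character_,
                                                class = NA_character_,
                                                dist = NA_real_)
    else r[[what]][1]
  meaningful <- !is.null(leftRss) || !is.null(rightRss)
  confident <- if (!is.na(confidentOverride)) confidentOverride
    else (!is.null(leftRss) && !is.null(rightRss))
  data.frame(
    readId = readId, readOffset = readOffset,
    leftRef = leftRef, rightRef = rightRef, origin = origin, flip = flip,
    leftGene = f(leftRss, "gene"), leftSide = f(leftRss, "side"),
    leftClass = f(leftRss, "class"), leftDist = f(leftRss, "dist"),
    leftSegStart = leftSeg[1], leftSegEnd = leftSeg[2],
    rightGene = f(rightRss, "gene"), rightSide = f(rightRss, "side"),
    rightClass = f(rightRss, "class"), rightDist = f(rightRss, "dist"),
    rightSegStart = rightSeg[1], rightSegEnd = rightSeg[2],
    meaningful = meaningful, confident = confident,
    stringsAsFactors = FALSE)
}

.rssLookup <- function(locusMap, position, maxDist,
                       anchors = rssAnchors(locusMap)) {
  hit <- nearestRss(locusMap, position, maxDist, anchors = anchors)
  if (is.null(hit)) return(NULL)
  list(gene = hit$gene, side = hit$side, class = hit$class,
       dist = hit$distance)
}

#' Junctions between adjacent split-alignment segments
#'
#' Forms one junction per adjacent segment pair (ordered by read
#' offset). Unaligned gaps up to `maxGap` bases between adjacent
#' segments (non-templated junction nucleotides) are tolerated; larger
#' gaps break adjacency and yield no junction. When adjacent segments
#' overlap on the read by a few bases (aligner double-counting), the
#' junction point is placed at the midpoint of the overlap. Each
#' breakend is matched to its nearest RSS anchor within `maxDist`; a
#' junction with at least one matched breakend is "meaningful", one with
#' both matched is "confident".
#'
#' @param segments Segment table from [extractSegments] (one read).
#' @param locusMap The [LocusMap] of the reference the segments are on.
#' @param maxDist RSS window in bp (default 50, inclusive).
#' @param maxGap Maximum tolerated unaligned gap between adjacent
#'   segments (default 30).
#' @param maxOverlap Maximum tolerated read-interval overlap (default
#'   30).
#' @param anchors Precomputed [rssAnchors] table for `locusMap`; pass it
#'   when calling repeatedly to avoid recomputation.
#' @return Junction `data.frame` (possibly empty), columns as in the
#'   internal junction layout.
#' @export
junctionsFromSegments <- function(segments, locusMap, maxDist = 50,
                                  maxGap = 30, maxOverlap = 30,
                                  anchors = rssAnchors(locusMap)) {
  out <- .emptyJunctions()
  if (nrow(segments) < 2) return(out)
  segments <- segments[order(segments$readStart), , drop = FALSE]
  for (i in seq_len(nrow(segments) - 1)) {
    a <- segments[i, ]; b <- segments[i + 1, ]
    gap <- b$readStart - a$readEnd - 1L
    if (gap > maxGap) next
    if (-gap > maxOverlap) next
    offset <- if (gap >= 0) a$readEnd + (gap + 1L) %/% 2L
      else a$readEnd + gap %/% 2L   # midpoint of the overlap
    leftRef <- if (a$orientation == "+") a$refEnd else a$refStart
    rightRef <- if (b$orientation == "+") b$refStart else b$refEnd
    out <- rbind(out, .junctionRow(
      a$readId, offset, leftRef, rightRef, "split_alignment",
      a$orientation != b$orientation,
      .rssLookup(locusMap, leftRef, maxDist, anchors),
      .rssLookup(locusMap, rightRef, maxDist, anchors),
      c(a$refStart, a$refEnd), c(b$refStart, b$refEnd)))
  }
  out
}

#' Recombination junctions from in-CIGAR deletions
#'
#' Long CIGAR deletions between two D genes are the aligner's
#' representation of short D-D recombination events. A deletion of
#' length L located between the 5' RSS anchor of one D gene and the 3'
#' RSS anchor of another (anchor distance d) yields a confident junction
#' when `|L - d| <= slack`, regardless of exact RSS proximity, because
#' the repetitive D locus lets the aligner slide the deletion.
#' Deletions shorter than `minLen` are ignored.
#'
#' @param segment One row of the [extractSegments] table.
#' @param locusMap The reference [LocusMap].
#' @param slack Tolerance on `|L - d|` in bp (default 50, inclusive).
#' @param minLen Minimum deletion length scanned (default 100).
#' @param anchors Precomputed [rssAnchors] table for `locusMap`; pass it
#'   when calling repeatedly to avoid recomputation.
#' @return Junction `data.frame` (possibly empty).
#' @export
detectCigarDeletions <- function(segment, locusMap, slack = 50,
                                 minLen = 100,
                                 anchors = rssAnchors(locusMap)) {
  out <- .emptyJunctions()
  p <- .cigarParts(segment$cigar)
  dUp <- anchors[anchors$class == "D" & anchors$side == "upstream", ]
  dDown <- anchors[anchors$class == "D" & anchors$side == "downstream", ]
  if (nrow(dUp) == 0 || nrow(dDown) == 0) return(out)
  refAt <- segment$refStart
  samOffset <- 0L   # consumed read bases in SAM orientation
  lead <- .leadingClip(p$ops, p$lens)
  for (i in seq_along(p$ops)) {
    op <- p$ops[i]; len <- p$lens[i]
    if (op == "D" && len >= minLen) {
      delStart <- refAt; delEnd <- refAt + len - 1L
      best <- NULL
      for (u in seq_len(nrow(dUp))) for (v in seq_len(nrow(dDown))) {
        x <- dUp$position[u]; y <- dDown$position[v]
        if (x >= y || dUp$gene[u] == dDown$gene[v]) next
        d <- y - x
        err <- abs(len - d)
        if (err > slack) next
        if (delEnd < x - slack || delStart > y + slack) next
        ## the evenly spaced D locus makes several pairs share the same
        ## anchor distance; break ties by positional consistency of the
        ## deletion with the pair's anchors
        posErr <- abs(delStart - 1 - x) + abs(delEnd + 1 - y)
        if (is.null(best) || err < best$err ||
            (err == best$err && posErr < best$posErr))
          best <- list(u = u, v = v, err = err, posErr = posErr)
      }
      if (!is.null(best)) {
        lrss <- list(gene = dUp$gene[best$u], side = "upstream",
                     class = "D", dist = abs(delStart - 1 - dUp$position[best$u]))
        rrss <- list(gene = dDown$gene[best$v], side = "downstream",
                     class = "D", dist = abs(delEnd + 1 - dDown$position[best$v]))
        samOff <- lead + samOffset
        readOffset <- if (segment$orientation == "-")
          segment$readLen - samOff else samOff
        out <- rbind(out, .junctionRow(
          segment$readId, readOffset, delStart - 1L, delEnd + 1L,
          "cigar_deletion", FALSE, lrss, rrss,
          c(segment$refStart, delStart - 1L),
          c(delEnd + 1L, segment$refEnd), confidentOverride = TRUE))
      }
    }
    if (op %in% c("M", "=", "X")) { refAt <- refAt + len; samOffset <- samOffset + len }
    else if (op %in% c("D", "N")) refAt <- refAt + len
    else if (op == "I") samOffset <- samOffset + len
  }
  out
}

#' Classify one read's junctions into an event class
#'
#' Applies the event grammar to the confident junctions of one read:
#' no junctions is unrecombined; a single J-V junction is a complete
#' V(D)J event (the D portion is too short to split on); J-D is a
#' D-J-only partial event; a lone D-V junction is V-D-only when the D
#' side flank extends in germline form at least `intergenicFlank` bases
#' into the J-D intergenic region, otherwise evidence of a multiple-D
#' event; two or more junctions using two or more distinct D genes is a
#' multiple-D (RSS skipping) event; any orientation-flipped junction is
#' an inversion, typed by the matched anchor classes; anything else with
#' a meaningful junction is complex.
#'
#' @param junctions Junction table of one read.
#' @param locusMap The reference [LocusMap].
#' @param intergenicFlank Germline flank requirement in bp (default
#'   200).
#' @param anchors Precomputed [rssAnchors] table for `locusMap`; pass it
#'   when calling repeatedly to avoid recomputation.
#' @return List with `class` and `genes` (`data.frame` of `gene`,
#'   `side`, `class` in locus order).
#' @export
classifyRead <- function(junctions, locusMap, intergenicFlank = 200,
                         anchors = rssAnchors(locusMap)) {
  geneTable <- function(rows) {
    keep <- rbind(
      data.frame(gene = rows$leftGene, side = rows$leftSide,
                 class = rows$leftClass, stringsAsFactors = FALSE),
      data.frame(gene = rows$rightGene, side = rows$rightSide,
                 class = rows$rightClass, stringsAsFactors = FALSE))
    keep <- unique(keep[!is.na(keep$gene), , drop = FALSE])
    rk <- anchors$locusRank[match(keep$gene, anchors$gene)]
    keep <- keep[order(rk), , drop = FALSE]
    rownames(keep) <- NULL
    keep
  }
  empty <- data.frame(gene = character(0), side = character(0),
                      class = character(0))
  if (nrow(junctions) == 0)
    return(list(class = "unrecombined", genes = empty))
  cj <- junctions[junctions$confident, , drop = FALSE]
  if (nrow(cj) == 0)
    return(list(class = "complex", genes = geneTable(junctions)))
  if (any(cj$flip)) {
    fl <- cj[cj$flip, , drop = FALSE]
    pairs <- unique(vapply(seq_len(nrow(fl)), function(i)
      paste(sort(c(fl$leftClass[i], fl$rightClass[i])), collapse = ""),
      character(1)))
    cls <- if (length(pairs) == 1)
      switch(pairs, DJ = "inversion_DJ", DD = "inversion_DD",
             DV = "inversion_VD", "complex")
    else "complex"
    return(list(class = cls, genes = geneTable(fl)))
  }
  dGenes <- unique(c(cj$leftGene[cj$leftClass %in% "D"],
                     cj$rightGene[cj$rightClass %in% "D"]))
  if (nrow(cj) == 1) {
    pair <- paste(sort(c(cj$leftClass, cj$rightClass)), collapse = "")
    if (pair == "JV")
      return(list(class = "complete_VDJ", genes = geneTable(cj)))
    if (pair == "DJ")
      return(list(class = "DJ_only", genes = geneTable(cj)))
    if (pair == "DD" && length(dGenes) >= 2)
      return(list(class = "multiple_D", genes = geneTable(cj)))
    if (pair == "DV") {
      ## flank of the D-side segment into the J-D intergenic region
      dLeft <- cj$leftClass %in% "D"
      seg <- if (dLeft) c(cj$leftSegStart, cj$leftSegEnd)
        else c(cj$rightSegStart, cj$rightSegEnd)
      g <- locusGenes(locusMap)
      jfirst <- locusOrientation(locusMap) == "jfirst"
      jBound <- if (jfirst) max(end(g)[mcols(g)$class == "J"])
        else min(start(g)[mcols(g)$class == "J"])
      dBound <- if (jfirst) min(start(g)[mcols(g)$class == "D"])
        else max(end(g)[mcols(g)$class == "D"])
      inter <- if (jfirst) c(jBound + 1, dBound - 1)
        else c(dBound + 1, jBound - 1)
      reach <- max(0, min(seg[2], inter[2]) - max(seg[1], inter[1]) + 1)
      cls <- if (reach >= intergenicFlank) "VD_only" else "multiple_D"
      return(list(class = cls, genes = geneTable(cj)))
    }
    return(list(class = "complex", genes = geneTable(cj)))
  }
  if (length(dGenes) >= 2)
    return(list(class = "multiple_D", genes = geneTable(cj)))
  list(class = "complex", genes = geneTable(cj))
}

.evidenceForRead <- function(records, locusMap, reference, config,
                             anchors = rssAnchors(locusMap)) {
  segs <- extractSegments(records)
  jx <- junctionsFromSegments(segs, locusMap,
                              maxDist = config$rssWindow,
                              maxGap = config$maxGap,
                              maxOverlap = config$maxOverlap,
                              anchors = anchors)
  for (i in seq_len(nrow(segs)))
    jx <- rbind(jx, detectCigarDeletions(segs[i, ], locusMap,
                                         slack = config$delSlack,
                                         minLen = config$minDelLen,
                                         anchors = anchors))
  cl <- classifyRead(jx, locusMap,
                     intergenicFlank = config$intergenicFlank,
                     anchors = anchors)
  confident <- nrow(jx) > 0 && all(jx$confident)
  new("ReadEvidence", readId = segs$readId[1], reference = reference,
      segments = segs, junctions = jx, eventClass = cl$class,
      genesUsed = cl$genes, confident = confident)
}

#' Default profiler configuration
#'
#' @param rssWindow RSS proximity window in bp (inclusive; default 50).
#' @param maxGap Maximum unaligned gap between adjacent segments
#'   (default 30).
#' @param maxOverlap Maximum tolerated segment overlap on the read
#'   (default 30).
#' @param minDelLen Minimum CIGAR deletion length scanned (default 100).
#' @param delSlack Tolerance for the D-D deletion-length rule (default
#'   50).
#' @param intergenicFlank Germline flank for the V-D-only call (default
#'   200).
#' @return Named list of configuration values.
#' @export
profilerConfig <- function(rssWindow = 50, maxGap = 30, maxOverlap = 30,
                           minDelLen = 100, delSlack = 50,
                           intergenicFlank = 200) {
  list(rssWindow = rssWindow, maxGap = maxGap, maxOverlap = maxOverlap,
       minDelLen = minDelLen, delSlack = delSlack,
       intergenicFlank = intergenicFlank)
}

#' Choose the best-supported reference for a read
#'
#' Ranks the per-reference evidence of one read: (1) evidence whose
#' breakends are all RSS-confident wins; (2) more RSS-confident
#' breakends win; (3) fewer complex/non-meaningful junctions win; (4)
#' remaining ties fall back to the fixed priority order of the
#' [ReferenceSet]. Deterministic: equal inputs always return the same
#' choice.
#'
#' @param perReference Named list of [ReadEvidence], one per reference
#'   with an alignment.
#' @param referenceSet The [ReferenceSet].
#' @return The chosen [ReadEvidence].
#' @export
chooseReference <- function(perReference, referenceSet) {
  if (length(perReference) == 0)
    stop("no reference has an alignment for this read")
  score <- function(ev) {
    jx <- readJunctions(ev)
    nBreakends <- sum(!is.na(jx$leftGene)) + sum(!is.na(jx$rightGene))
    allConf <- nrow(jx) == 0 || all(jx$confident)
    bad <- sum(!jx$meaningful) +
      as.integer(eventClass(ev) == "complex")
    c(allConf = as.integer(allConf), nConf = nBreakends, bad = -bad)
  }
  sc <- t(vapply(perReference, score, numeric(3)))
  prio <- match(names(perReference), referencePriority(referenceSet))
  ord <- order(-sc[, "allConf"], -sc[, "nConf"], -sc[, "bad"], prio)
  perReference[[ord[1]]]
}

#' Profile a sample's reads for V(D)J recombination
#'
#' Runs the whole read pipeline: restricts to reads mapped fully or
#' partially within the J-D span of at least one reference, assembles
#' split segments, forms junctions (split and in-CIGAR), classifies each
#' read, and picks the best-supported reference per read. Reads whose
#' only junctions join two V genes are dropped as potential germline SV
#' evidence. Reads are processed in lexicographic read-id order so
#' output is stable.
#'
#' @param alignments Named list (by reference) of alignment inputs:
#'   either a SAM/BAM path or a records `data.frame` (layout of
#'   [readAlignments]).
#' @param referenceSet [ReferenceSet] whose maps cover the references.
#' @param config See [profilerConfig].
#' @return List of [ReadEvidence] sorted by read id, with attribute
#'   `droppedVV` giving the ids of V-V-only reads that were excluded.
#' @export
profileSample <- function(alignments, referenceSet,
                          config = profilerConfig()) {
  maps <- locusMaps(referenceSet)
  refs <- intersect(names(alignments), names(maps))
  if (length(refs) == 0)
    stop("no reference with a usable LocusMap")
  perRef <- lapply(refs, function(r) {
    recs <- alignments[[r]]
    if (is.character(recs)) recs <- readAlignments(recs)
    recs
  })
  names(perRef) <- refs
  ## qualifying reads: any record overlapping the J-D span somewhere
  qualify <- character(0)
  for (r in refs) {
    recs <- perRef[[r]]
    if (nrow(recs) == 0) next
    jd <- jdInterval(maps[[r]])
    p <- vapply(seq_len(nrow(recs)), function(i) {
      parts <- .cigarParts(recs$cigar[i])
      e <- recs$pos[i] + .refWidth(parts$ops, parts$lens) - 1L
      recs$pos[i] <= end(jd) && e >= start(jd)
    }, logical(1))
    qualify <- union(qualify, recs$qname[p])
  }
  qualify <- sort(qualify)
  anchorsByRef <- lapply(refs, function(r) rssAnchors(maps[[r]]))
  names(anchorsByRef) <- refs
  byRead <- lapply(perRef, function(recs)
    split(recs, factor(recs$qname, levels = sort(unique(recs$qname)))))
  dropped <- character(0)
  out <- list()
  for (q in qualify) {
    evs <- list()
    for (r in refs) {
      recs <- byRead[[r]][[q]]
      if (is.null(recs) || nrow(recs) == 0) next
      evs[[r]] <- .evidenceForRead(recs, maps[[r]], r, config,
                                   anchors = anchorsByRef[[r]])
    }
    if (length(evs) == 0) next
    best <- chooseReference(evs, referenceSet)
    jx <- readJunctions(best)
    mj <- jx[jx$meaningful, , drop = FALSE]
    if (nrow(mj) > 0 &&
        all(mj$leftClass %in% "V" | is.na(mj$leftGene)) &&
        all(mj$rightClass %in% "V" | is.na(mj$rightGene)) &&
        any(mj$leftClass %in% "V") && any(mj$rightClass %in% "V")) {
      dropped <- c(dropped, q)
      next
    }
    out[[q]] <- best
  }
  structure(out, droppedVV = dropped)
}

#' Tabulate read evidence
#'
#' Flattens a list of [ReadEvidence] into one row per read, including an
#' encoded junction column that [readEvidenceTsv] can reverse.
#'
#' @param evidences List of [ReadEvidence].
#' @return `data.frame` with columns `readId`, `reference`,
#'   `eventClass`, `confident`, `nJunctions`, `genesUsed`, `junctions`.
#' @export
evidenceTable <- function(evidences) {
  rows <- lapply(evidences, function(ev) {
    jx <- readJunctions(ev)
    enc <- if (nrow(jx) == 0) "" else paste(vapply(seq_len(nrow(jx)),
      function(i) paste(jx$leftGene[i], jx$leftSide[i], jx$leftClass[i],
                        jx$leftRef[i], jx$rightGene[i], jx$rightSide[i],
                        jx$rightClass[i], jx$rightRef[i], jx$flip[i],
                        jx$origin[i], jx$readOffset[i], jx$meaningful[i],
                        jx$confident[i], sep = "|"),
      character(1)), collapse = ";")
    gu <- genesUsed(ev)
    data.frame(
      readId = readId(ev), reference = referenceName(ev),
      eventClass = eventClass(ev), confident = isConfident(ev),
      nJunctions = nrow(jx),
      genesUsed = paste(sprintf("%s[%s]", gu$gene, gu$side),
                        collapse = ";"),
      junctions = enc, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Write read evidence as TSV
#'
#' @param evidences List of [ReadEvidence].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeEvidenceTsv <- function(evidences, path) {
  write.table(evidenceTable(evidences), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read evidence back from TSV
#'
#' Reconstructs a minimal [ReadEvidence] list (junction table and
#' classification; segment detail is not round-tripped) from the output
#' of [writeEvidenceTsv], enough for clonality aggregation and surgery
#' planning.
#'
#' @param path TSV path written by [writeEvidenceTsv].
#' @return List of [ReadEvidence].
#' @export
readEvidenceTsv <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(tab)), function(i) {
    jx <- .emptyJunctions()
    if (nzchar(tab$junctions[i]) && !is.na(tab$junctions[i])) {
      for (ent in strsplit(tab$junctions[i], ";", fixed = TRUE)[[1]]) {
        f <- strsplit(ent, "|", fixed = TRUE)[[1]]
        asNa <- function(x) ifelse(x == "NA", NA, x)
        jx <- rbind(jx, data.frame(
          readId = tab$readId[i], readOffset = as.integer(f[11]),
          leftRef = as.numeric(f[4]), rightRef = as.numeric(f[8]),
          origin = f[10], flip = as.logical(f[9]),
          leftGene = asNa(f[1]), leftSide = asNa(f[2]),
          leftClass = asNa(f[3]), leftDist = NA_real_,
          leftSegStart = NA_real_, leftSegEnd = NA_real_,
          rightGene = asNa(f[5]), rightSide = asNa(f[6]),
          rightClass = asNa(f[7]), rightDist = NA_real_,
          rightSegStart = NA_real_, rightSegEnd = NA_real_,
          meaningful = as.logical(f[12]), confident = as.logical(f[13]),
          stringsAsFactors = FALSE))
      }
    }
    gu <- if (nzchar(tab$genesUsed[i]) && !is.na(tab$genesUsed[i])) {
      parts <- strsplit(tab$genesUsed[i], ";", fixed = TRUE)[[1]]
      m <- regmatches(parts, regexec("^(.*)\\[(.*)\\]$", parts))
      data.frame(gene = vapply(m, `[`, character(1), 2),
                 side = vapply(m, `[`, character(1), 3),
                 class = NA_character_, stringsAsFactors = FALSE)
    } else data.frame(gene = character(0), side = character(0),
                      class = character(0))
    new("ReadEvidence", readId = tab$readId[i],
        reference = tab$reference[i],
        segments = data.frame(), junctions = jx,
        eventClass = tab$eventClass[i], genesUsed = gu,
        confident = tab$confident[i])
  })
}
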