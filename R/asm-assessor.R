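## Assembly assessment: gene annotation on contigs, orphon filtering,
## duplicate naming, junction/breakpoint calling, and short-read
## validation of assembled genes.

.readFastaOrSet <- function(x) {
  if (is(x, "DNAStringSet")) return(x)
  if (is.character(x) && length(x) == 1 && file.exists(x))
    return(readDNAStringSet(x))
  stop("expected a DNAStringSet or a FASTA path")
}

## Parse the allele DB header dialect `gene*allele|class|functionality`.
.parseAlleleHeaders <- function(nm) {
  parts <- strsplit(nm, "|", fixed = TRUE)
  bad <- which(lengths(parts) != 3)
  if (length(bad))
    stop("malformed allele header(s): ", paste(nm[bad], collapse = ", "))
  id <- vapply(parts, `[`, character(1), 1)
  gene <- sub("\\*.*$", "", id)
  data.frame(allele = id, gene = gene,
             class = vapply(parts, `[`, character(1), 2),
             functionality = vapply(parts, `[`, character(1), 3),
             stringsAsFactors = FALSE)
}

## Unit-cost edit distance between an allele and a contig region, via
## global alignment scored 0/-1/-1 so that edits = -score.
.editDistance <- local({
  mat <- NULL
  function(a, b) {
    if (length(a) == 0 || length(b) == 0)
      return(max(length(a), length(b)))
    if (is.null(mat))
      mat <<- nucleotideSubstitutionMatrix(match = 0, mismatch = -1,
                                           baseOnly = FALSE)
    sc <- pairwiseAlignment(a, b, type = "global",
                            substitutionMatrix = mat,
                            gapOpening = 0, gapExtension = 1,
                            scoreOnly = TRUE)
    as.integer(round(-sc))
  }
})

## Alleles at least this long are searched via exact seed pieces; the
## budget formula then guarantees piece width >= 7.
.seedMinLen <- 100L

## Disjoint fixed-width seed pieces of every long allele on both
## strands, grouped by piece width into PDicts so a single matchPDict
## call scans a contig for every piece of that width at once.
## Pigeonhole: a placement within `budget` edits leaves at least one of
## its budget+1 disjoint pieces intact, so exact piece hits (padded by
## the budget) enumerate all candidate windows.
.seedTable <- local({
  lastKey <- NULL
  lastResult <- NULL
  function(pats, budgets, key) {
    ## the seed table and its PDicts depend only on the allele DB and
    ## budgets; reuse them across calls on the same DB
    if (identical(key, lastKey)) return(lastResult)
    info <- list()
    for (ai in seq_along(pats)) {
      plen <- length(pats[[ai]][["+"]])
      if (budgets[ai] == 0L || plen < .seedMinLen) next
      w <- plen %/% (budgets[ai] + 1L)
      o <- (seq_len(budgets[ai] + 1L) - 1L) * w + 1L
      for (strand in c("+", "-"))
        info[[length(info) + 1L]] <- data.frame(
          ai = ai, strand = strand, offset = o, width = w,
          seq = vapply(o, function(p) as.character(
            subseq(pats[[ai]][[strand]], p, p + w - 1L)), character(1)),
          stringsAsFactors = FALSE)
    }
    if (!length(info)) {
      lastKey <<- key
      lastResult <<- NULL
      return(NULL)
    }
    info <- do.call(rbind, info)
    groups <- split(info, info$width)
    dicts <- lapply(groups, function(g)
      tryCatch(PDict(DNAStringSet(g$seq)), error = function(e) NULL))
    ok <- !vapply(dicts, is.null, logical(1))
    res <- if (!any(ok)) NULL
      else list(groups = groups[ok], dicts = dicts[ok],
                seeded = sort(unique(unlist(
                  lapply(groups[ok], `[[`, "ai")))))
    lastKey <<- key
    lastResult <<- res
    res
  }
})

## Candidate windows per allele/strand for one contig, as an environment
## keyed by paste0(ai, strand).
.seedWindows <- function(seedTab, cseq, plens, budgets) {
  slen <- length(cseq)
  allKey <- character(0)
  allS <- allE <- integer(0)
  for (gi in seq_along(seedTab$dicts)) {
    g <- seedTab$groups[[gi]]
    starts <- startIndex(matchPDict(seedTab$dicts[[gi]], cseq))
    n <- lengths(starts)
    if (sum(n) == 0) next
    idx <- rep.int(seq_len(nrow(g)), n)
    ai <- g$ai[idx]
    anchor <- unlist(starts, use.names = FALSE) - (g$offset[idx] - 1L)
    allKey <- c(allKey, paste0(ai, g$strand[idx]))
    allS <- c(allS, pmax(1L, anchor - budgets[ai]))
    allE <- c(allE, pmin(slen, anchor + plens[ai] - 1L + budgets[ai]))
  }
  out <- new.env(parent = emptyenv())
  if (length(allKey)) {
    ks <- split(seq_along(allKey), allKey)
    for (key in names(ks))
      assign(key, IRanges(allS[ks[[key]]], allE[ks[[key]]]), envir = out)
  }
  out
}

## All matches of `pat` in `cseq` within `budget` edits, as an IRanges.
## Equivalent to matchPattern(..., max.mismatch = budget,
## with.indels = TRUE); `windows` restricts the budgeted search to the
## seeded candidate windows ("direct" = scan the whole contig, NULL =
## seeded allele with no seed hit anywhere).
.alleleMatches <- function(pat, cseq, budget, windows) {
  if (identical(windows, "direct"))
    return(as(matchPattern(pat, cseq, max.mismatch = budget,
                           with.indels = TRUE), "IRanges"))
  if (is.null(windows)) return(IRanges())
  wnd <- IRanges::reduce(windows)
  hits <- IRanges()
  for (k in seq_along(wnd)) {
    ws <- start(wnd)[k]
    mm <- matchPattern(pat, subseq(cseq, ws, end(wnd)[k]),
                       max.mismatch = budget, with.indels = TRUE)
    if (length(mm))
      hits <- c(hits, IRanges::shift(as(mm, "IRanges"), ws - 1L))
  }
  hits
}

.hitsForAllele <- function(pats, contigSeq, budget, windows) {
  out <- list()
  for (strand in c("+", "-")) {
    pat <- pats[[strand]]
    m <- .alleleMatches(pat, contigSeq, budget, windows[[strand]])
    if (length(m) == 0) next
    rg <- IRanges::reduce(m, min.gapwidth = length(pat))
    for (i in seq_along(rg)) {
      ## refine: re-extract a padded window and take the matched span's
      ## exact edit distance to the allele
      st <- start(rg)[i]; en <- end(rg)[i]
      ed <- if (en - st + 1L == length(pat)) {
        ## same width: Hamming <= 1 equals the edit distance (gaps cost
        ## at least 2 on equal-length strings), so skip the alignment
        h <- neditAt(pat, contigSeq, at = st)
        if (h <= 1L) h else .editDistance(pat, subseq(contigSeq, st, en))
      } else .editDistance(pat, subseq(contigSeq, st, en))
      out[[length(out) + 1L]] <-
        data.frame(start = st, end = en, strand = strand,
                   mismatches = ed, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) return(NULL)
  do.call(rbind, out)
}

#' Annotate IGH genes on assembly contigs
#'
#' Searches every database allele against every contig on both strands
#' (seeded by exact allele-piece matches, verified by budgeted
#' approximate matching and refined by unit-cost edit distance) and
#' reports, for each distinct placement of each gene, the
#' best-matching allele and its edit distance. The per-allele search
#' budget is `min(maxEdit + 5, allele length %/% 8)` edits, so short D
#' genes cannot produce spurious matches.
#'
#' @param contigs Assembly as a named [Biostrings::DNAStringSet] or
#'   FASTA path.
#' @param alleleDb Allele database ([Biostrings::DNAStringSet] or FASTA
#'   path) with headers `gene*allele|class|functionality`.
#' @param maxEdit Edit budget anchor (default 15, the orphon cut-off).
#' @return `data.frame` of gene hits: `contig`, `gene`, `allele`,
#'   `class`, `functionality`, `start`, `end`, `strand`, `mismatches`,
#'   sorted by contig then coordinate.
#' @export
annotateContigs <- function(contigs, alleleDb, maxEdit = 15) {
  contigs <- .readFastaOrSet(contigs)
  alleleDb <- .readFastaOrSet(alleleDb)
  if (length(alleleDb) == 0) stop("allele database is empty")
  meta <- .parseAlleleHeaders(names(alleleDb))
  plens <- vapply(seq_along(alleleDb), function(ai)
    length(alleleDb[[ai]]), integer(1))
  budgets <- pmin(maxEdit + 5L, pmax(2L, plens %/% 8L))
  pats <- lapply(seq_along(alleleDb), function(ai)
    list("+" = alleleDb[[ai]],
         "-" = reverseComplement(alleleDb[[ai]])))
  seedTab <- .seedTable(pats, budgets,
                        key = list(names(alleleDb),
                                   as.character(alleleDb), budgets))
  rows <- list()
  for (ci in seq_along(contigs)) {
    cname <- names(contigs)[ci]
    cseq <- contigs[[ci]]
    wndEnv <- if (is.null(seedTab)) NULL
      else .seedWindows(seedTab, cseq, plens, budgets)
    for (ai in seq_along(alleleDb)) {
      windows <- if (is.null(seedTab) || !(ai %in% seedTab$seeded))
        list("+" = "direct", "-" = "direct")
      else
        list("+" = get0(paste0(ai, "+"), envir = wndEnv,
                        ifnotfound = NULL),
             "-" = get0(paste0(ai, "-"), envir = wndEnv,
                        ifnotfound = NULL))
      h <- .hitsForAllele(pats[[ai]], cseq, budgets[ai], windows)
      if (is.null(h)) next
      h$contig <- cname
      h$gene <- meta$gene[ai]
      h$allele <- meta$allele[ai]
      h$class <- meta$class[ai]
      h$functionality <- meta$functionality[ai]
      rows[[length(rows) + 1L]] <- h
    }
  }
  empty <- data.frame(contig = character(0), gene = character(0),
                      allele = character(0), class = character(0),
                      functionality = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      mismatches = integer(0), stringsAsFactors = FALSE)
  if (length(rows) == 0) return(empty)
  hits <- do.call(rbind, rows)
  ## one hit per (gene, placement): cluster overlapping same-gene hits
  ## and keep the best allele (fewest edits, then allele name)
  keep <- list()
  for (key in unique(paste(hits$contig, hits$gene))) {
    grp <- hits[paste(hits$contig, hits$gene) == key, , drop = FALSE]
    rg <- IRanges(grp$start, grp$end)
    cl <- subjectHits(findOverlaps(rg, IRanges::reduce(rg)))
    for (c0 in unique(cl)) {
      sub <- grp[cl == c0, , drop = FALSE]
      sub <- sub[order(sub$mismatches, sub$allele), , drop = FALSE]
      keep[[length(keep) + 1L]] <- sub[1, , drop = FALSE]
    }
  }
  hits <- do.call(rbind, keep)
  hits <- hits[, colnames(empty), drop = FALSE]
  hits <- hits[order(hits$contig, hits$start, hits$gene), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Filter orphons and empty contigs
#'
#' Drops gene hits with more than `maxMismatch` edits (orphons:
#' paralogues outside the locus that match only loosely), then removes
#' from the analysis any contig left without hits.
#'
#' @param hits Gene hit table from [annotateContigs].
#' @param maxMismatch Edit cut-off (default 15; a hit with exactly 15 is
#'   kept, 16 is dropped).
#' @return List with `hits` (kept rows, `kept = TRUE` column added),
#'   `dropped` (removed rows) and `contigs` (retained contig names).
#' @export
filterOrphons <- function(hits, maxMismatch = 15) {
  ok <- hits$mismatches <= maxMismatch
  kept <- hits[ok, , drop = FALSE]
  if (nrow(kept)) kept$kept <- TRUE
  dropped <- hits[!ok, , drop = FALSE]
  list(hits = kept, dropped = dropped,
       contigs = unique(kept$contig))
}

.locusGeneOrder <- function(locusMap) {
  g <- locusGenes(locusMap)
  nm <- mcols(g)$gene
  if (locusOrientation(locusMap) == "vfirst") nm <- rev(nm)
  nm
}

#' Profile contigs by their gene content
#'
#' Builds one [ContigProfile] per retained contig: hits sorted by contig
#' coordinate and decorated with the locus rank of each gene (position
#' in J -> D -> V order), the majority hit strand as the contig
#' orientation, and the locus-rank range covered.
#'
#' @param hits Kept gene hits ([filterOrphons]).
#' @param locusMap [LocusMap] providing the locus gene order.
#' @return Named list of [ContigProfile] objects.
#' @export
contigProfiles <- function(hits, locusMap) {
  order0 <- .locusGeneOrder(locusMap)
  out <- list()
  for (cname in unique(hits$contig)) {
    h <- hits[hits$contig == cname, , drop = FALSE]
    h <- h[order(h$start), , drop = FALSE]
    h$locusRank <- match(h$gene, order0)
    na <- is.na(h$locusRank)
    h$locusRank[na] <- match(sub("D$", "", h$gene[na]), order0)
    rownames(h) <- NULL
    strands <- table(h$strand)
    orient <- names(strands)[which.max(strands)]
    rr <- range(h$locusRank, na.rm = TRUE)
    out[[cname]] <- new("ContigProfile", contig = cname, hits = h,
                        orientation = orient, locusRankRange = rr)
  }
  out
}

#' Resolve duplicate gene names on a contig
#'
#' Sequence identity cannot distinguish the duplicated gene pairs of the
#' IGH locus (for example IGHV3-23 vs IGHV3-23D), so the annotator names
#' all copies after the base gene. When two or more instances of a
#' duplicate-pair base name occur on one contig, the instance sitting at
#' the reference layout position of the `"D"`-suffixed copy is renamed;
#' single instances keep the base name. Third and further copies keep
#' the base name and are flagged in an `extraCopy` column rather than
#' given invented names.
#'
#' @param profile A [ContigProfile].
#' @param locusMap [LocusMap]; if it annotates the `"D"`-suffixed gene,
#'   its position relative to the base gene decides which instance is
#'   renamed, otherwise the J-proximal instance is.
#' @param duplicateBases Base names of the known duplicated pairs
#'   (default `c("IGHV3-23", "IGHV1-69", "IGHV2-70")`).
#' @return The updated [ContigProfile].
#' @export
assignDuplicateNames <- function(profile, locusMap,
                                 duplicateBases = c("IGHV3-23", "IGHV1-69",
                                                    "IGHV2-70")) {
  h <- contigHits(profile)
  if (!"extraCopy" %in% colnames(h))
    h$extraCopy <- rep(FALSE, nrow(h))
  order0 <- .locusGeneOrder(locusMap)
  for (base in duplicateBases) {
    idx <- which(h$gene == base)
    if (length(idx) < 2) next
    ## order the instances along the locus direction (J-proximal first)
    jfirstOnContig <- contigOrientation(profile) == "+"
    ord <- order(h$start[idx], decreasing = !jfirstOnContig)
    idx <- idx[ord]
    dupName <- paste0(base, "D")
    rBase <- match(base, order0)
    rDup <- match(dupName, order0)
    dupIsJProximal <- if (!is.na(rBase) && !is.na(rDup)) rDup < rBase else TRUE
    dupAt <- if (dupIsJProximal) 1L else 2L
    h$gene[idx[dupAt]] <- dupName
    if (length(idx) > 2)
      h$extraCopy[idx[-c(1L, 2L)]] <- TRUE
  }
  initialize(profile, hits = h)
}

#' @rdname accessors
#' @export
setGeneric("contigOrientation", function(x) standardGeneric("contigOrientation"))
#' @rdname accessors
#' @export
setMethod("contigOrientation", "ContigProfile", function(x) x@orientation)

#' Detect V(D)J junctions on a contig
#'
#' Scans coordinate-adjacent gene hits: a pair of genes from different
#' segment classes (among V, D, J; C genes are ignored) lying within
#' `window` bp of each other is called a V(D)J junction — germline
#' spacing between classes is far larger, so proximity implies a
#' recombination survived into the assembly. The one D gene that lies
#' naturally within the window of the J genes (`exemptD`) never pairs
#' with a J.
#'
#' @param profile A [ContigProfile].
#' @param window Maximum gap in bp (default 10000).
#' @param exemptD Gene name of the J-proximal D gene exempted from D-J
#'   calls (default `"IGHD7-27"`).
#' @return `data.frame`: `contig`, `leftGene`, `rightGene`, `leftClass`,
#'   `rightClass`, `gap`, `type` (`"VJ"`, `"DJ"`, `"VD"`).
#' @export
detectVdjJunctions <- function(profile, window = 10000,
                               exemptD = "IGHD7-27") {
  h <- contigHits(profile)
  h <- h[h$class %in% c("V", "D", "J"), , drop = FALSE]
  h <- h[order(h$start), , drop = FALSE]
  out <- list()
  if (nrow(h) >= 2) for (i in seq_len(nrow(h) - 1)) {
    a <- h[i, ]; b <- h[i + 1, ]
    if (a$class == b$class) next
    gap <- max(0L, b$start - a$end - 1L)
    if (gap > window) next
    cls <- sort(c(a$class, b$class))
    if (identical(cls, c("D", "J")) &&
        (if (a$class == "D") a$gene else b$gene) == exemptD)
      next
    type <- if (identical(cls, c("J", "V"))) "VJ"
            else if (identical(cls, c("D", "J"))) "DJ"
            else "VD"
    out[[length(out) + 1L]] <-
      data.frame(contig = contigName(profile),
                 leftGene = a$gene, rightGene = b$gene,
                 leftClass = a$class, rightClass = b$class,
                 gap = gap, type = type, stringsAsFactors = FALSE)
  }
  if (length(out) == 0)
    return(data.frame(contig = character(0), leftGene = character(0),
                      rightGene = character(0), leftClass = character(0),
                      rightClass = character(0), gap = integer(0),
                      type = character(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

.profileRanks <- function(profile) {
  r <- contigHits(profile)$locusRank
  r[!is.na(r)]
}

#' Classify breakpoints between contigs of a haplotype
#'
#' Sorts contigs by the median locus rank of their gene hits (robust to
#' a single stray hit), then compares each coordinate-adjacent pair:
#' `duplication` when one contig's gene set is contained in the other's,
#' `overlap` when their locus-rank spans intersect, `disjoint`
#' otherwise. Only disjoint pairs can imply missing genes, which are
#' listed from the locus gene order.
#'
#' @param profiles List of [ContigProfile] for one haplotype (length >=
#'   2).
#' @param locusMap [LocusMap] for the gene order.
#' @return `data.frame`: `contigA`, `contigB`, `relation`, `boundaryA`,
#'   `boundaryB` (nearest genes at the facing ends), `missingGenes`
#'   (`;`-separated), `nMissing`.
#' @export
classifyBreakpoints <- function(profiles, locusMap) {
  stopifnot(length(profiles) >= 2)
  order0 <- .locusGeneOrder(locusMap)
  med <- vapply(profiles, function(p) median(.profileRanks(p)), numeric(1))
  profiles <- profiles[order(med)]
  out <- list()
  for (i in seq_len(length(profiles) - 1)) {
    a <- profiles[[i]]; b <- profiles[[i + 1]]
    ra <- .profileRanks(a); rb <- .profileRanks(b)
    ga <- unique(contigHits(a)$gene); gb <- unique(contigHits(b)$gene)
    if (all(gb %in% ga) || all(ga %in% gb)) {
      rel <- "duplication"; missing <- character(0)
    } else if (max(ra) >= min(rb)) {
      rel <- "overlap"; missing <- character(0)
    } else {
      rel <- "disjoint"
      between <- order0[seq_along(order0) > max(ra) &
                          seq_along(order0) < min(rb)]
      missing <- setdiff(between, c(ga, gb))
    }
    bndA <- contigHits(a)$gene[which.max(contigHits(a)$locusRank)]
    bndB <- contigHits(b)$gene[which.min(contigHits(b)$locusRank)]
    out[[length(out) + 1L]] <-
      data.frame(contigA = contigName(a), contigB = contigName(b),
                 relation = rel, boundaryA = bndA, boundaryB = bndB,
                 missingGenes = paste(missing, collapse = ";"),
                 nMissing = length(missing), stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Summarize an assembly into a report
#'
#' Counts contigs, builds the deduplicated gene presence set per
#' haplotype (genes on duplicated sequence count once), attaches V(D)J
#' junction and breakpoint calls, and reports V/D/J gene counts with
#' pseudogenes excluded from the V headline number.
#'
#' @param profiles Named list (by haplotype) of lists of
#'   [ContigProfile].
#' @param locusMap [LocusMap].
#' @param window,exemptD Passed to [detectVdjJunctions].
#' @return An [AssemblyReport].
#' @export
summarizeAssembly <- function(profiles, locusMap, window = 10000,
                              exemptD = "IGHD7-27") {
  g <- locusGenes(locusMap)
  lookup <- function(gene, what) {
    i <- match(gene, mcols(g)$gene)
    i[is.na(i)] <- match(sub("D$", "", gene[is.na(i)]), mcols(g)$gene)
    mcols(g)[[what]][i]
  }
  sm <- list(); pres <- list(); jx <- list(); bp <- list()
  for (hap in names(profiles)) {
    pf <- profiles[[hap]]
    genes <- unique(unlist(lapply(pf, function(p) contigHits(p)$gene)))
    cls <- lookup(genes, "class")
    fun <- lookup(genes, "functionality")
    sm[[hap]] <- data.frame(
      haplotype = hap, nContigs = length(pf),
      nV = sum(cls == "V" & fun != "pseudogene", na.rm = TRUE),
      nD = sum(cls == "D", na.rm = TRUE),
      nJ = sum(cls == "J", na.rm = TRUE),
      stringsAsFactors = FALSE)
    pres[[hap]] <- sort(genes)
    j <- do.call(rbind, lapply(pf, detectVdjJunctions, window = window,
                               exemptD = exemptD))
    if (!is.null(j) && nrow(j)) { j$haplotype <- hap; jx[[hap]] <- j }
    if (length(pf) >= 2) {
      b <- classifyBreakpoints(pf, locusMap)
      if (nrow(b)) { b$haplotype <- hap; bp[[hap]] <- b }
    }
  }
  emptyJ <- cbind(detectVdjJunctions(
    new("ContigProfile", contig = "", hits = data.frame(
      class = character(0), gene = character(0), start = integer(0),
      end = integer(0)), orientation = "+",
    locusRankRange = numeric(0))),
    data.frame(haplotype = character(0)))
  emptyB <- data.frame(contigA = character(0), contigB = character(0),
                       relation = character(0), boundaryA = character(0),
                       boundaryB = character(0),
                       missingGenes = character(0), nMissing = integer(0),
                       haplotype = character(0), stringsAsFactors = FALSE)
  new("AssemblyReport",
      summary = do.call(rbind, c(sm, list(make.row.names = FALSE))),
      presence = pres,
      junctions = if (length(jx)) do.call(rbind, c(jx, list(make.row.names = FALSE))) else emptyJ,
      breakpoints = if (length(bp)) do.call(rbind, c(bp, list(make.row.names = FALSE))) else emptyB)
}

## Per-read supported/covered reference positions against the assembly.
.readSupport <- function(pos, cigar, readSeq, contigSeq) {
  p <- .cigarParts(cigar)
  refAt <- pos; qryAt <- 1L
  covered <- integer(0); supported <- integer(0)
  lastMEnd <- NA_integer_
  for (i in seq_along(p$ops)) {
    op <- p$ops[i]; len <- p$lens[i]
    if (op %in% c("M", "=", "X")) {
      refIdx <- refAt:(refAt + len - 1L)
      covered <- c(covered, refIdx)
      if (op != "X") {
        rb <- strsplit(substr(readSeq, qryAt, qryAt + len - 1L), "")[[1]]
        ab <- strsplit(as.character(subseq(contigSeq, refAt,
                                           refAt + len - 1L)), "")[[1]]
        supported <- c(supported, refIdx[rb == ab])
      }
      refAt <- refAt + len; qryAt <- qryAt + len
      lastMEnd <- refAt - 1L
    } else if (op %in% c("D", "N")) {
      covered <- c(covered, refAt:(refAt + len - 1L))
      refAt <- refAt + len
      lastMEnd <- NA_integer_
    } else if (op == "I") {
      ## an insertion disputes the assembly base to its left
      if (!is.na(lastMEnd)) supported <- setdiff(supported, lastMEnd)
      qryAt <- qryAt + len
    } else if (op %in% c("S")) {
      qryAt <- qryAt + len
    }
  }
  list(covered = unique(covered), supported = unique(supported))
}

#' Validate assembled genes with short reads
#'
#' For each gene hit, checks against an independent short-read alignment
#' to the assembly: the gene is fully covered when every base is covered
#' by at least one passing read (mapping quality at least `mapqMin`;
#' deletions span coverage), and its edit distance is the number of
#' covered bases supported by no read (a base is supported when some
#' passing read carries the identical base there, not immediately left
#' of an insertion). A gene is confident when fully covered with edit
#' distance at most 1.
#'
#' @param assembly Named [Biostrings::DNAStringSet] (or FASTA path) that
#'   the reads were aligned to.
#' @param alignments SAM/BAM path or the `data.frame` of
#'   [readAlignments].
#' @param hits Gene hit table ([annotateContigs]/[filterOrphons]).
#' @param mapqMin Minimum mapping quality (default 10).
#' @return `hits` with columns `fullyCovered`, `editDistance`,
#'   `confident` appended.
#' @export
validateGenes <- function(assembly, alignments, hits, mapqMin = 10) {
  assembly <- .readFastaOrSet(assembly)
  if (is.character(alignments)) alignments <- readAlignments(alignments)
  aln <- alignments[alignments$mapq >= mapqMin, , drop = FALSE]
  if (nrow(aln) && !any(aln$rname %in% names(assembly)))
    stop("alignments reference sequences absent from the assembly")
  out <- hits
  out$fullyCovered <- logical(nrow(hits))
  out$editDistance <- integer(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    cname <- hits$contig[i]
    span <- hits$start[i]:hits$end[i]
    sub <- aln[aln$rname == cname, , drop = FALSE]
    covered <- integer(0); supported <- integer(0)
    for (r in seq_len(nrow(sub))) {
      s <- .readSupport(sub$pos[r], sub$cigar[r], sub$seq[r],
                        assembly[[cname]])
      covered <- union(covered, intersect(s$covered, span))
      supported <- union(supported, intersect(s$supported, span))
    }
    out$fullyCovered[i] <- all(span %in% covered)
    out$editDistance[i] <- length(setdiff(covered, supported))
  }
  out$confident <- out$fullyCovered & out$editDistance <= 1
  out
}
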