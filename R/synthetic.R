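#' Generate a toy IGH locus
#'
#' Lays out an artificial IGH-like locus in J -> D -> V order along
#' increasing coordinates (`"jfirst"` orientation): a block of J genes,
#' a J-D intergenic gap, a block of short D genes, a D-V gap, and a block
#' of V genes. Recombining gene boundaries carry a planted RSS heptamer
#' (`CACAGTG`) immediately outside the gene body. The emitted annotation,
#' reference sequence and allele database are mutually consistent, and
#' the whole construction is deterministic under `seed`.
#'
#' Default gene sizes follow the real locus: J bodies ~60 bp, D bodies
#' well under the 40 bp bound of human D genes, V bodies ~300 bp. The
#' default geometry also mirrors two load-bearing distances of the real
#' locus: the D block sits within 10 kbp of the J block (so the
#' J-proximal D gene, `toyD1`, plays the role the exempted D gene plays
#' in assembly junction calling), while the D-V gap exceeds 10 kbp.
#'
#' @param nJ,nD,nV Gene counts per class.
#' @param jLen,dLen,vLen Gene body lengths (bp).
#' @param jSpace,dSpace,vSpace Intergenic spacing within each block (bp).
#' @param jdGap,dvGap Gaps between the J/D and D/V blocks (bp).
#' @param pad Flanking padding at both locus ends (bp).
#' @param vPseudo Integer indices of V genes annotated as pseudogenes.
#' @param reference Reference sequence name.
#' @param seed Integer seed (`NULL` = use current RNG state).
#' @return A list with elements `locusMap` ([LocusMap]), `sequence`
#'   (named [Biostrings::DNAStringSet] of length 1), `alleleDb`
#'   (DNAStringSet, names `gene*01|class|functionality`), and
#'   `annotation` (the annotation `data.frame`).
#' @export
makeToyLocus <- function(nJ = 4, nD = 6, nV = 18,
                         jLen = 60, dLen = 24, vLen = 300,
                         jSpace = 600, dSpace = 600, vSpace = 1000,
                         jdGap = 3000, dvGap = 12000, pad = 800,
                         vPseudo = integer(0),
                         reference = "toyIGH", seed = 1) {
  stopifnot(nJ >= 1, nD >= 1, nV >= 1, dLen <= 40)
  if (!is.null(seed)) set.seed(seed)
  genes <- list()
  at <- pad + 1L
  addBlock <- function(n, len, space, prefix, class, at, pseudo = integer(0)) {
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      rows[[i]] <- data.frame(
        gene = paste0(prefix, i), class = class,
        functionality = if (i %in% pseudo) "pseudogene" else "functional",
        start = at, end = at + len - 1L, stringsAsFactors = FALSE)
      at <- at + len + space
    }
    list(rows = do.call(rbind, rows), at = at - space)
  }
  jb <- addBlock(nJ, jLen, jSpace, "toyJ", "J", at)
  db <- addBlock(nD, dLen, dSpace, "toyD", "D", jb$at + jdGap)
  vb <- addBlock(nV, vLen, vSpace, "toyV", "V", db$at + dvGap,
                 pseudo = vPseudo)
  ann <- rbind(jb$rows, db$rows, vb$rows)
  ann$reference <- reference
  ann$strand <- "-"   # real IGH genes lie on the minus strand of chr14
  ann$rssSides <- ifelse(ann$class == "D", "upstream,downstream",
                         ifelse(ann$class == "J", "upstream", "downstream"))
  total <- vb$at + pad
  seqChars <- sample(c("A", "C", "G", "T"), total, replace = TRUE)
  ## distinct gene bodies are already guaranteed w.h.p. by randomness;
  ## plant RSS heptamers just outside each recombining boundary
  heptamer <- strsplit("CACAGTG", "")[[1]]
  for (i in seq_len(nrow(ann))) {
    sides <- strsplit(ann$rssSides[i], ",")[[1]]
    for (s in sides) {
      if (s == "upstream") {          # jfirst: 5' side at high coordinates
        p <- ann$end[i] + 1L
        if (p + 6L <= total) seqChars[p:(p + 6L)] <- heptamer
      } else {
        p <- ann$start[i] - 7L
        if (p >= 1L) seqChars[p:(p + 6L)] <- heptamer
      }
    }
  }
  refSeq <- DNAStringSet(paste(seqChars, collapse = ""))
  names(refSeq) <- reference
  lm <- makeLocusMap(ann, reference, orientation = "jfirst")
  g <- locusGenes(lm)
  db <- DNAStringSet(vapply(seq_along(g), function(i)
    as.character(subseq(refSeq[[1]], start(g)[i], end(g)[i])), character(1)))
  names(db) <- sprintf("%s*01|%s|%s", mcols(g)$gene, mcols(g)$class,
                       mcols(g)$functionality)
  list(locusMap = lm, sequence = refSeq, alleleDb = db, annotation = ann)
}

#' Write toy locus fixtures to disk
#'
#' @param toy Result of [makeToyLocus].
#' @param dir Output directory (created if absent).
#' @return Named character vector of paths (`reference`, `annotation`,
#'   `alleles`).
#' @export
writeToyLocus <- function(toy, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ref <- file.path(dir, "reference.fa")
  ann <- file.path(dir, "annotation.tsv")
  alle <- file.path(dir, "alleles.fa")
  writeXStringSet(toy$sequence, ref)
  writeLocusMap(toy$locusMap, ann)
  writeXStringSet(toy$alleleDb, alle)
  c(reference = ref, annotation = ann, alleles = alle)
}

.anchorPos <- function(anchors, gene, side) {
  i <- which(anchors$gene == gene & anchors$side == side)
  if (length(i) != 1)
    stop("no unique RSS anchor for ", gene, " [", side, "]")
  anchors[i, , drop = FALSE]
}

#' Describe a recombination event to simulate
#'
#' @param class Event class: `"complete_VDJ"`, `"DJ_only"`, `"VD_only"`,
#'   `"multiple_D"`, `"inversion_DJ"`, `"inversion_DD"`,
#'   `"inversion_VD"`.
#' @param jGene,vGene Gene symbols (as required by the class).
#' @param dGenes Character vector of D genes, ordered J-proximal first
#'   (`multiple_D` needs at least 2; inversions between two D genes need
#'   exactly 2).
#' @param maxInsert Maximum non-templated insertion length per junction
#'   (bases drawn uniformly in `0:maxInsert`; default 3).
#' @param style `multiple_D` only. `"skip"` (the default): RSS
#'   skipping — the span from the J-proximal D gene through the
#'   V-proximal D gene is retained intact between the D-J and V-D
#'   junctions. `"join"`: a bare D-D recombination joining the upstream
#'   RSS of one D gene to the downstream RSS of the next, deleting the
#'   inter-D sequence (J and V uninvolved).
#' @return A list of class `simEventSpec`.
#' @export
simEventSpec <- function(class, jGene = NULL, dGenes = NULL, vGene = NULL,
                         maxInsert = 3, style = c("skip", "join")) {
  style <- match.arg(style)
  need <- switch(class,
    complete_VDJ = c(j = TRUE, d = 1, v = TRUE),
    DJ_only = c(j = TRUE, d = 1, v = FALSE),
    VD_only = c(j = FALSE, d = 1, v = TRUE),
    multiple_D = if (style == "join") c(j = FALSE, d = 2, v = FALSE)
                 else c(j = TRUE, d = 2, v = TRUE),
    inversion_DJ = c(j = TRUE, d = 1, v = FALSE),
    inversion_DD = c(j = FALSE, d = 2, v = FALSE),
    inversion_VD = c(j = FALSE, d = 1, v = TRUE),
    stop("unsupported event class: ", class))
  if (isTRUE(as.logical(need["j"])) && is.null(jGene))
    stop(class, " requires jGene")
  if (isTRUE(as.logical(need["v"])) && is.null(vGene))
    stop(class, " requires vGene")
  if (length(dGenes) < need["d"])
    stop(class, " requires at least ", need["d"], " D gene(s)")
  structure(list(class = class, jGene = jGene, dGenes = dGenes,
                 vGene = vGene, maxInsert = maxInsert, style = style),
            class = "simEventSpec")
}

.randomBases <- function(n) {
  if (n <= 0) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Apply a recombination event to a germline haplotype
#'
#' Executes the event grammar on the germline sequence: deletions remove
#' the open interval between the two joined RSS anchors (optionally with
#' non-templated junction insertions); inversions reverse-complement the
#' span delimited by the two initiating RSS anchors. The returned truth
#' records every junction with its anchors and its position on the
#' recombined haplotype.
#'
#' @param toy Result of [makeToyLocus] (germline reference + map).
#' @param spec A [simEventSpec].
#' @param seed Optional integer seed for junction insertions.
#' @return List: `sequence` (DNAString), `blocks` (`data.frame` tiling
#'   the haplotype: `type`, `refStart`, `refEnd`, `strand`, `seq`,
#'   `hapStart`, `hapEnd`), `junctions` (truth junction table),
#'   `eventClass`, `genesUsed`.
#' @export
simulateRecombination <- function(toy, spec, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lm <- toy$locusMap
  anchors <- rssAnchors(lm)
  a <- function(g, s) .anchorPos(anchors, g, s)
  ops <- list()
  del <- function(left, right) {
    list(kind = "del", left = left, right = right,
         ins = .randomBases(sample(0:spec$maxInsert, 1)))
  }
  inv <- function(left, right, invStart, invEnd) {
    list(kind = "inv", left = left, right = right,
         invStart = invStart, invEnd = invEnd)
  }
  cls <- spec$class
  if (cls == "complete_VDJ") {
    d <- spec$dGenes[1]
    ops <- list(del(a(spec$jGene, "upstream"), a(d, "downstream")),
                del(a(d, "upstream"), a(spec$vGene, "downstream")))
  } else if (cls == "DJ_only") {
    ops <- list(del(a(spec$jGene, "upstream"),
                    a(spec$dGenes[1], "downstream")))
  } else if (cls == "VD_only") {
    ops <- list(del(a(spec$dGenes[1], "upstream"),
                    a(spec$vGene, "downstream")))
  } else if (cls == "multiple_D") {
    ds <- spec$dGenes
    if (spec$style == "join") {
      ## bare D-D joins: delete the sequence between consecutive D genes
      ops <- lapply(seq_len(length(ds) - 1), function(i)
        del(a(ds[i], "upstream"), a(ds[i + 1], "downstream")))
    } else {
      ## RSS skipping: D-J junction at the J-proximal D, V-D junction at
      ## the V-proximal D; the span between the two D genes is retained
      ops <- list(del(a(spec$jGene, "upstream"), a(ds[1], "downstream")),
                  del(a(ds[length(ds)], "upstream"),
                      a(spec$vGene, "downstream")))
    }
  } else if (cls == "inversion_DJ") {
    lj <- a(spec$jGene, "upstream"); rj <- a(spec$dGenes[1], "upstream")
    ops <- list(inv(lj, rj, lj$position + 1L, rj$position))
  } else if (cls == "inversion_DD") {
    lj <- a(spec$dGenes[1], "downstream")
    rj <- a(spec$dGenes[2], "downstream")
    ops <- list(inv(lj, rj, lj$position, rj$position - 1L))
  } else if (cls == "inversion_VD") {
    lj <- a(spec$dGenes[1], "downstream")
    rj <- a(spec$vGene, "downstream")
    ops <- list(inv(lj, rj, lj$position, rj$position - 1L))
  }
  refSeq <- toy$sequence[[1]]
  L <- length(refSeq)
  ## walk the germline, emitting ref/ins blocks and truth junctions
  blocks <- list(); junctions <- list(); cursor <- 1L
  pushRef <- function(s, e, strand) {
    blocks[[length(blocks) + 1]] <<- data.frame(
      type = "ref", refStart = s, refEnd = e, strand = strand,
      seq = NA_character_, stringsAsFactors = FALSE)
  }
  pushIns <- function(seqc) {
    if (nchar(seqc) > 0)
      blocks[[length(blocks) + 1]] <<- data.frame(
        type = "ins", refStart = NA, refEnd = NA, strand = "+",
        seq = seqc, stringsAsFactors = FALSE)
  }
  pushJunction <- function(left, right, flip, insLen) {
    junctions[[length(junctions) + 1]] <<- data.frame(
      leftGene = left$gene, leftSide = left$side, leftClass = left$class,
      leftPos = left$position,
      rightGene = right$gene, rightSide = right$side,
      rightClass = right$class, rightPos = right$position,
      flip = flip, insLen = insLen, stringsAsFactors = FALSE)
  }
  for (op in ops) {
    if (op$kind == "del") {
      pushRef(cursor, op$left$position, "+")
      pushIns(op$ins)
      pushJunction(op$left, op$right, FALSE, nchar(op$ins))
      cursor <- op$right$position
    } else {
      pushRef(cursor, op$invStart - 1L, "+")
      pushRef(op$invStart, op$invEnd, "-")
      pushJunction(op$left, op$right, TRUE, 0L)
      pushJunction(op$left, op$right, TRUE, 0L)
      cursor <- op$invEnd + 1L
    }
  }
  pushRef(cursor, L, "+")
  blocks <- do.call(rbind, blocks)
  wid <- ifelse(blocks$type == "ins", nchar(blocks$seq),
                blocks$refEnd - blocks$refStart + 1L)
  blocks$hapStart <- cumsum(c(1L, head(wid, -1)))[seq_len(nrow(blocks))]
  blocks$hapEnd <- blocks$hapStart + wid - 1L
  pieces <- lapply(seq_len(nrow(blocks)), function(i) {
    if (blocks$type[i] == "ins") DNAString(blocks$seq[i])
    else if (blocks$strand[i] == "+")
      subseq(refSeq, blocks$refStart[i], blocks$refEnd[i])
    else reverseComplement(subseq(refSeq, blocks$refStart[i],
                                  blocks$refEnd[i]))
  })
  hap <- do.call(Biostrings::xscat, pieces)
  junctions <- if (length(junctions)) do.call(rbind, junctions) else
    data.frame()
  ## haplotype coordinates of junctions: between consecutive ref blocks
  refIdx <- which(blocks$type == "ref")
  if (nrow(junctions)) {
    junctions$hapLeftEnd <- blocks$hapEnd[refIdx[seq_len(nrow(junctions))]]
    junctions$hapRightStart <-
      blocks$hapStart[refIdx[seq_len(nrow(junctions)) + 1L]]
  }
  genes <- if (nrow(junctions)) {
    u <- unique(rbind(
      data.frame(gene = junctions$leftGene, side = junctions$leftSide,
                 class = junctions$leftClass, stringsAsFactors = FALSE),
      data.frame(gene = junctions$rightGene, side = junctions$rightSide,
                 class = junctions$rightClass, stringsAsFactors = FALSE)))
    rk <- anchors$locusRank[match(u$gene, anchors$gene)]
    u[order(rk), , drop = FALSE]
  } else data.frame(gene = character(0), side = character(0),
                    class = character(0))
  list(sequence = hap, blocks = blocks, junctions = junctions,
       eventClass = cls, genesUsed = genes)
}

#' A germline (unrecombined) haplotype in block form
#'
#' @param toy Result of [makeToyLocus].
#' @return Same structure as [simulateRecombination] with no junctions.
#' @export
germlineHaplotype <- function(toy) {
  L <- length(toy$sequence[[1]])
  list(sequence = toy$sequence[[1]],
       blocks = data.frame(type = "ref", refStart = 1L, refEnd = L,
                           strand = "+", seq = NA_character_,
                           hapStart = 1L, hapEnd = L,
                           stringsAsFactors = FALSE),
       junctions = data.frame(), eventClass = "unrecombined",
       genesUsed = data.frame(gene = character(0), side = character(0),
                              class = character(0)))
}

## Effective junctions of one read: what an aligner faithful to the
## truth can expose. Segments shorter than `minAnchor` are unalignable
## and become part of the unaligned gap; a junction exists between
## consecutive alignable segments when that gap is at most `maxGap`.
## Gene anchors come from the haplotype's truth junction table: the
## left anchor of the first and the right anchor of the last truth
## junction collapsed into the gap (a complete V(D)J event therefore
## shows one effective J-V junction, its D body being unalignable).
.effectiveJunctions <- function(sg, hapJx, minAnchor, maxGap) {
  empty <- data.frame(leftGene = character(0), leftSide = character(0),
                      leftClass = character(0), rightGene = character(0),
                      rightSide = character(0), rightClass = character(0),
                      flip = logical(0), leftSegStart = numeric(0),
                      leftSegEnd = numeric(0), rightSegStart = numeric(0),
                      rightSegEnd = numeric(0), stringsAsFactors = FALSE)
  keep <- sg[sg$he - sg$hs + 1L >= minAnchor, , drop = FALSE]
  if (nrow(keep) < 2 || nrow(hapJx) == 0) return(empty)
  out <- empty
  for (i in seq_len(nrow(keep) - 1)) {
    a <- keep[i, ]; b <- keep[i + 1, ]
    if (b$hs - a$he - 1L > maxGap) next
    between <- hapJx[hapJx$hapLeftEnd >= a$he & hapJx$hapRightStart <= b$hs,
                     , drop = FALSE]
    if (nrow(between) == 0) next
    first <- between[which.min(between$hapLeftEnd), ]
    last <- between[which.max(between$hapRightStart), ]
    out <- rbind(out, data.frame(
      leftGene = first$leftGene, leftSide = first$leftSide,
      leftClass = first$leftClass, rightGene = last$rightGene,
      rightSide = last$rightSide, rightClass = last$rightClass,
      flip = a$orientation != b$orientation,
      leftSegStart = a$refStart, leftSegEnd = a$refEnd,
      rightSegStart = b$refStart, rightSegEnd = b$refEnd,
      stringsAsFactors = FALSE))
  }
  out
}

## Declarative truth classification of one read from its effective
## junctions; mirrors the documented event grammar independently of the
## profiler implementation.
.truthClassify <- function(eff, locusMap, intergenicFlank = 200) {
  anchors <- rssAnchors(locusMap)
  pairGenes <- function(rows) {
    u <- unique(rbind(
      data.frame(gene = rows$leftGene, side = rows$leftSide,
                 class = rows$leftClass, stringsAsFactors = FALSE),
      data.frame(gene = rows$rightGene, side = rows$rightSide,
                 class = rows$rightClass, stringsAsFactors = FALSE)))
    rk <- anchors$locusRank[match(u$gene, anchors$gene)]
    u <- u[order(rk), , drop = FALSE]
    rownames(u) <- NULL
    u
  }
  if (nrow(eff) == 0)
    return(list(class = "unrecombined",
                genes = data.frame(gene = character(0), side = character(0),
                                   class = character(0))))
  if (any(eff$flip)) {
    fl <- eff[eff$flip, , drop = FALSE]
    p <- unique(vapply(seq_len(nrow(fl)), function(i)
      paste(sort(c(fl$leftClass[i], fl$rightClass[i])), collapse = ""),
      character(1)))
    cls <- if (length(p) == 1)
      switch(p, DJ = "inversion_DJ", DD = "inversion_DD",
             DV = "inversion_VD", "complex")
    else "complex"
    return(list(class = cls, genes = pairGenes(fl)))
  }
  dGenes <- unique(c(eff$leftGene[eff$leftClass == "D"],
                     eff$rightGene[eff$rightClass == "D"]))
  if (nrow(eff) == 1) {
    p <- paste(sort(c(eff$leftClass, eff$rightClass)), collapse = "")
    cls <- switch(p,
      JV = "complete_VDJ", DJ = "DJ_only",
      DD = if (length(dGenes) >= 2) "multiple_D" else "complex",
      DV = {
        ## identifiable as V-D-only iff the D-side germline segment
        ## reaches at least `intergenicFlank` bases into the J-D
        ## intergenic region
        g <- locusGenes(locusMap)
        jEnd <- max(end(g)[mcols(g)$class == "J"])
        dStart <- min(start(g)[mcols(g)$class == "D"])
        reach <- max(0, min(eff$leftSegEnd, dStart - 1) -
                       max(eff$leftSegStart, jEnd + 1) + 1)
        if (reach >= intergenicFlank) "VD_only" else "multiple_D"
      },
      "complex")
    return(list(class = cls, genes = pairGenes(eff)))
  }
  if (length(dGenes) >= 2)
    return(list(class = "multiple_D", genes = pairGenes(eff)))
  list(class = "complex", genes = pairGenes(eff))
}

#' Simulate long reads from a clone mixture
#'
#' Draws reads uniformly along each clone haplotype at clone-proportional
#' rates (Poisson read counts, expected coverage `depth * fraction`),
#' optionally injects substitution errors, and emits per-read truth:
#' the alignment segments on the germline reference and the event
#' classification identifiable from that read alone (junctions counted
#' as visible when the read anchors them with at least `minAnchor`
#' bases on both sides).
#'
#' @param toy Result of [makeToyLocus].
#' @param clones List of clones, each a list with `name`, `hap` (result
#'   of [simulateRecombination] or [germlineHaplotype]) and `fraction`;
#'   fractions must sum to 1.
#' @param depth Total expected coverage of the mixture.
#' @param readLen Read length (bp).
#' @param errorRate Per-base substitution error rate.
#' @param seed Integer seed.
#' @param minAnchor Minimum segment length (bp) for a truth segment to
#'   count as alignable; junctions are visible only between alignable
#'   segments. Must match the `minAnchor` used when emitting alignment
#'   records ([truthRecords]). Default 50.
#' @param maxGap Maximum unaligned read gap (bp) across which two
#'   alignable segments still expose their junction (default 30; the
#'   profiler's adjacency tolerance).
#' @param intergenicFlank Germline flank (bp) into the J-D intergenic
#'   region required to label a lone D-V junction `VD_only` rather than
#'   `multiple_D` (default 200).
#' @param bothStrands Sample reads from both strands (default `TRUE`).
#' @return List: `reads` (named DNAStringSet), `segments` (truth
#'   alignment segments per read, original-read orientation), `truth`
#'   (per-read `data.frame`: `readId`, `clone`, `class`, `genes`,
#'   `nVisible`).
#' @export
simulateReads <- function(toy, clones, depth = 30, readLen = 5000,
                          errorRate = 0, seed = 1, minAnchor = 50,
                          maxGap = 30, intergenicFlank = 200,
                          bothStrands = TRUE) {
  stopifnot(abs(sum(vapply(clones, `[[`, numeric(1), "fraction")) - 1) < 1e-8)
  set.seed(seed)
  reads <- list(); segs <- list(); truth <- list()
  for (cl in clones) {
    hap <- cl$hap
    hapLen <- length(hap$sequence)
    rl <- as.integer(min(readLen, hapLen))
    nReads <- rpois(1, depth * cl$fraction * hapLen / rl)
    for (i in seq_len(nReads)) {
      rs <- if (hapLen > rl) sample.int(hapLen - rl + 1L, 1) else 1L
      re <- rs + rl - 1L
      readSeq <- subseq(hap$sequence, rs, re)
      minus <- bothStrands && sample(c(TRUE, FALSE), 1)
      rid <- sprintf("%s_r%05d", cl$name, i)
      ## truth segments in forward slice coordinates (hs/he: haplotype)
      b <- hap$blocks[hap$blocks$type == "ref", , drop = FALSE]
      b <- b[b$hapEnd >= rs & b$hapStart <= re, , drop = FALSE]
      sg <- do.call(rbind, lapply(seq_len(nrow(b)), function(k) {
        hs <- max(b$hapStart[k], rs); he <- min(b$hapEnd[k], re)
        if (b$strand[k] == "+") {
          rfs <- b$refStart[k] + (hs - b$hapStart[k])
          rfe <- b$refStart[k] + (he - b$hapStart[k])
        } else {
          rfe <- b$refEnd[k] - (hs - b$hapStart[k])
          rfs <- b$refEnd[k] - (he - b$hapStart[k])
        }
        data.frame(readId = rid, readStart = hs - rs + 1L,
                   readEnd = he - rs + 1L, refStart = rfs, refEnd = rfe,
                   orientation = b$strand[k], hs = hs, he = he,
                   stringsAsFactors = FALSE)
      }))
      eff <- .effectiveJunctions(sg, hap$junctions, minAnchor, maxGap)
      tc <- .truthClassify(eff, toy$locusMap, intergenicFlank)
      sg$hs <- NULL; sg$he <- NULL
      if (errorRate > 0) {
        n <- length(readSeq)
        hit <- which(runif(n) < errorRate)
        if (length(hit)) {
          ch <- strsplit(as.character(readSeq), "")[[1]]
          for (p in hit)
            ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
          readSeq <- DNAString(paste(ch, collapse = ""))
        }
      }
      if (minus) {
        readSeq <- reverseComplement(readSeq)
        n <- rl
        sg2 <- sg
        sg2$readStart <- n - sg$readEnd + 1L
        sg2$readEnd <- n - sg$readStart + 1L
        sg2$orientation <- ifelse(sg$orientation == "+", "-", "+")
        sg <- sg2[order(sg2$readStart), , drop = FALSE]
      }
      reads[[rid]] <- readSeq
      segs[[rid]] <- sg
      truth[[rid]] <- data.frame(
        readId = rid, clone = cl$name, class = tc$class,
        genes = paste(sprintf("%s[%s]", tc$genes$gene, tc$genes$side),
                      collapse = ";"),
        nVisible = nrow(eff), stringsAsFactors = FALSE)
    }
  }
  ord <- order(names(reads))
  reads <- reads[ord]
  list(reads = DNAStringSet(reads),
       segments = do.call(rbind, c(segs[ord], list(make.row.names = FALSE))),
       truth = do.call(rbind, c(truth[ord], list(make.row.names = FALSE))))
}

## build SAM-style records (data.frame) from truth segments of one read
.recordsForRead <- function(rid, sg, readSeq, refName,
                            mergeDeletionsUpTo = 0, minAnchor = 50) {
  n <- nchar(readSeq)
  ## segments shorter than the alignability threshold are not reported
  sg <- sg[sg$readEnd - sg$readStart + 1L >= minAnchor, , drop = FALSE]
  if (nrow(sg) == 0) return(NULL)
  sg <- sg[order(sg$readStart), , drop = FALSE]
  ## chain consecutive colinear segments into single records with D/I ops
  chains <- list(); cur <- sg[1, , drop = FALSE]
  curOps <- sprintf("%dM", cur$readEnd - cur$readStart + 1L)
  flush <- function() {
    chains[[length(chains) + 1]] <<- list(row = cur, ops = curOps)
  }
  if (nrow(sg) > 1) for (i in 2:nrow(sg)) {
    nx <- sg[i, , drop = FALSE]
    readGap <- nx$readStart - cur$readEnd - 1L
    colinear <- nx$orientation == cur$orientation &&
      ((cur$orientation == "+" && nx$refStart > cur$refEnd) ||
       (cur$orientation == "-" && nx$refEnd < cur$refStart))
    refGap <- if (cur$orientation == "+") nx$refStart - cur$refEnd - 1L
              else cur$refStart - nx$refEnd - 1L
    if (colinear && readGap >= 0 && refGap >= 1 &&
        refGap <= mergeDeletionsUpTo) {
      gapOps <- c(if (readGap > 0) sprintf("%dI", readGap),
                  sprintf("%dD", refGap),
                  sprintf("%dM", nx$readEnd - nx$readStart + 1L))
      curOps <- c(curOps, gapOps)
      cur$readEnd <- nx$readEnd
      if (cur$orientation == "+") cur$refEnd <- nx$refEnd
      else cur$refStart <- nx$refStart
    } else {
      flush(); cur <- nx
      curOps <- sprintf("%dM", cur$readEnd - cur$readStart + 1L)
    }
  }
  flush()
  recs <- lapply(chains, function(ch) {
    r <- ch$row
    body <- ch$ops
    if (r$orientation == "-") {
      ## mirror the op order into SAM (reference) orientation
      body <- rev(body)
      lead <- n - r$readEnd; trail <- r$readStart - 1L
      seqOut <- as.character(reverseComplement(DNAString(readSeq)))
      flagStrand <- 16L
    } else {
      lead <- r$readStart - 1L; trail <- n - r$readEnd
      seqOut <- readSeq
      flagStrand <- 0L
    }
    cigar <- paste0(if (lead > 0) sprintf("%dS", lead) else "",
                    paste(body, collapse = ""),
                    if (trail > 0) sprintf("%dS", trail) else "")
    list(pos = r$refStart, cigar = cigar, seq = seqOut,
         strand = if (flagStrand == 16L) "-" else "+",
         flagStrand = flagStrand,
         alignedLen = r$readEnd - r$readStart + 1L)
  })
  primary <- which.max(vapply(recs, `[[`, numeric(1), "alignedLen"))
  saOf <- function(k) sprintf("%s,%d,%s,%s,60,0;", refName, recs[[k]]$pos,
                              recs[[k]]$strand, recs[[k]]$cigar)
  do.call(rbind, lapply(seq_along(recs), function(k) {
    others <- setdiff(seq_along(recs), k)
    data.frame(
      qname = rid,
      flag = recs[[k]]$flagStrand + if (k == primary) 0L else 2048L,
      rname = refName, pos = recs[[k]]$pos, mapq = 60L,
      cigar = recs[[k]]$cigar, seq = recs[[k]]$seq,
      sa = if (length(others))
        paste(vapply(others, saOf, character(1)), collapse = "")
      else NA_character_,
      stringsAsFactors = FALSE)
  }))
}

#' Alignment records implied by simulated truth
#'
#' Converts the truth segments of [simulateReads] into primary +
#' supplementary alignment records with `SA` tags, exactly as an aligner
#' faithful to the truth would report them against the germline
#' reference. Adjacent reference-colinear segments whose reference gap is
#' at most `mergeDeletionsUpTo` are merged into a single record with a
#' CIGAR deletion (and insertion for any unaligned read bases), which is
#' how aligners represent short D-D recombination events.
#'
#' @param sim Result of [simulateReads].
#' @param toy Result of [makeToyLocus].
#' @param mergeDeletionsUpTo Merge threshold in bp (default 0 = never).
#' @param minAnchor Alignability threshold in bp; segments shorter than
#'   this are left unaligned (default 50, matching [simulateReads]).
#' @return `data.frame` in the [readAlignments] record layout.
#' @export
truthRecords <- function(sim, toy, mergeDeletionsUpTo = 0,
                         minAnchor = 50) {
  refName <- referenceName(toy$locusMap)
  out <- lapply(names(sim$reads), function(rid) {
    sg <- sim$segments[sim$segments$readId == rid, , drop = FALSE]
    .recordsForRead(rid, sg, as.character(sim$reads[[rid]]), refName,
                    mergeDeletionsUpTo, minAnchor)
  })
  recs <- do.call(rbind, out)
  recs$mapq <- as.integer(recs$mapq)
  recs
}

#' Write truth alignments as SAM
#'
#' @param sim Result of [simulateReads].
#' @param toy Result of [makeToyLocus].
#' @param path Output `.sam` path.
#' @param mergeDeletionsUpTo,minAnchor See [truthRecords].
#' @return `path`, invisibly.
#' @export
writeTruthSam <- function(sim, toy, path, mergeDeletionsUpTo = 0,
                          minAnchor = 50) {
  recs <- truthRecords(sim, toy, mergeDeletionsUpTo, minAnchor)
  refName <- referenceName(toy$locusMap)
  refLen <- length(toy$sequence[[1]])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:unknown",
               sprintf("@SQ\tSN:%s\tLN:%d", refName, refLen)), con)
  lines <- vapply(seq_len(nrow(recs)), function(i) {
    fields <- c(recs$qname[i], recs$flag[i], recs$rname[i], recs$pos[i],
                recs$mapq[i], recs$cigar[i], "*", "0", "0",
                recs$seq[i], "*")
    if (!is.na(recs$sa[i]))
      fields <- c(fields, paste0("SA:Z:", recs$sa[i]))
    paste(fields, collapse = "\t")
  }, character(1))
  writeLines(lines, con)
  invisible(path)
}

## midpoints used by the SV fixtures; mirror of the stitching junctions
.svSpans <- function(sv, locusMap) {
  g <- locusGenes(locusMap)
  iv <- function(nm) {
    i <- match(nm, mcols(g)$gene)
    c(start(g)[i], end(g)[i])
  }
  rg <- .svRegion(sv, locusMap)
  fl <- iv(rg$flanks[1]); fr <- iv(rg$flanks[2])
  ol <- iv(rg$outer[1]); or <- iv(rg$outer[2])
  insideIv <- range(unlist(lapply(rg$inside, iv)))
  list(bbStart = (ol[2] + fl[1]) %/% 2 + 1L,
       bbEnd = (fr[2] + or[1]) %/% 2,
       delStart = (fl[2] + insideIv[1]) %/% 2 + 1L,
       delEnd = (insideIv[2] + fr[1]) %/% 2,
       inside = rg$inside, flanks = rg$flanks)
}

#' Toy seven-SV fixture: locus, catalogue, registry and novel genes
#'
#' Builds a toy locus (22 V genes) carrying a catalogue of seven
#' structural variants with the same topology as the real one: six
#' deletions (of D and V genes) and one complex variant whose
#' alternative haplotype swaps two backbone V genes (`toyV5`, `toyV6`)
#' for two novel genes (`toyVB1`, `toyVB2`) absent from the backbone.
#' SV regions are spaced so that every combination of alternative
#' alleles can be stitched simultaneously. Also produces the matching
#' segment registry (backbone + one alternative segment per SV) and an
#' allele database extended with the novel genes.
#'
#' @param seed Integer seed.
#' @return List: `toy` ([makeToyLocus] result), `svCatalog` (list of
#'   [svDefinition]), `registry` (in-memory [readSegmentRegistry]
#'   layout), `alleleDb` (extended DNAStringSet), `spans` (per-SV
#'   coordinate spans on the backbone), `novelBlock` (the complex
#'   alternative insert), `novelGenes` (their offsets inside the block).
#' @export
makeToySvSetup <- function(seed = 1) {
  toy <- makeToyLocus(nV = 22, seed = seed)
  svCatalog <- list(
    svDefinition(1, "deletion", "toyD2", "toyD3",
                 sourceDefault = "backbone", sourceAlternative = "altSV1"),
    svDefinition(2, "deletion", "toyV2",
                 sourceDefault = "backbone", sourceAlternative = "altSV2"),
    svDefinition(3, "complex", "toyV5", "toyV6",
                 hapAGenes = c("toyV5", "toyV6"),
                 hapBGenes = c("toyVB1", "toyVB2"),
                 sourceDefault = "backbone", sourceAlternative = "altSV3"),
    svDefinition(4, "deletion", "toyV9",
                 sourceDefault = "backbone", sourceAlternative = "altSV4"),
    svDefinition(5, "deletion", "toyV12", "toyV13",
                 sourceDefault = "backbone", sourceAlternative = "altSV5"),
    svDefinition(6, "deletion", "toyV16",
                 sourceDefault = "backbone", sourceAlternative = "altSV6"),
    svDefinition(7, "deletion", "toyV19", "toyV20",
                 sourceDefault = "backbone", sourceAlternative = "altSV7")
  )
  backbone <- toy$sequence[[1]]
  spans <- lapply(svCatalog, .svSpans, locusMap = toy$locusMap)
  names(spans) <- as.character(vapply(svCatalog, `[[`, integer(1), "svId"))
  ## novel block for the complex alternative: two V-like genes with
  ## planted downstream RSS heptamers
  set.seed(seed + 1000L)
  vLen <- 300L; spacer <- function(n) .randomBases(n)
  b1 <- .randomBases(vLen); b2 <- .randomBases(vLen)
  pre <- spacer(300); mid <- spacer(600); post <- spacer(300)
  novelBlock <- DNAString(paste0(pre, "CACAGTG", b1, mid, "CACAGTG", b2,
                                 post))
  off1 <- nchar(pre) + 7L + 1L
  off2 <- nchar(pre) + 7L + vLen + nchar(mid) + 7L + 1L
  novelGenes <- data.frame(
    gene = c("toyVB1", "toyVB2"),
    start = c(off1, off2), end = c(off1 + vLen - 1L, off2 + vLen - 1L),
    stringsAsFactors = FALSE)
  segs <- list()
  for (sv in svCatalog) {
    sp <- spans[[as.character(sv$svId)]]
    left <- subseq(backbone, sp$bbStart, sp$delStart - 1L)
    right <- subseq(backbone, sp$delEnd + 1L, sp$bbEnd)
    segs[[paste0("altSV", sv$svId)]] <-
      if (sv$kind == "complex") xscat(left, novelBlock, right)
      else xscat(left, right)
  }
  regSeqs <- do.call(DNAStringSet, list(c(list(backbone = backbone), segs)))
  registry <- list(
    sequences = regSeqs, backbone = "backbone",
    segments = data.frame(sv = vapply(svCatalog, `[[`, integer(1), "svId"),
                          allele = "alternative",
                          record = paste0("altSV",
                                          vapply(svCatalog, `[[`,
                                                 integer(1), "svId")),
                          stringsAsFactors = FALSE))
  alleleDb <- c(toy$alleleDb,
                setNames(DNAStringSet(c(b1, b2)),
                         c("toyVB1*01|V|functional",
                           "toyVB2*01|V|functional")))
  list(toy = toy, svCatalog = svCatalog, registry = registry,
       alleleDb = alleleDb, spans = spans, novelBlock = novelBlock,
       novelGenes = novelGenes)
}

#' Construct a haplotype with a chosen SV genotype
#'
#' Builds the haplotype sequence directly from the backbone — deleting
#' the span between the junction midpoints for each `"alternative"`
#' deletion and substituting the novel block for the complex
#' alternative — independently of the reference-stitching code path, so
#' the two constructions can check each other. Also reports the gene
#' set the haplotype is expected to carry.
#'
#' @param setup Result of [makeToySvSetup].
#' @param genotype Named character vector (names `"1"`..`"7"`), values
#'   `"default"` or `"alternative"`.
#' @return List: `sequence` (DNAString), `genes` (expected gene symbols
#'   present).
#' @export
makeSvHaplotype <- function(setup, genotype) {
  stopifnot(all(names(genotype) %in% names(setup$spans)),
            all(genotype %in% c("default", "alternative")))
  backbone <- setup$registry$sequences[["backbone"]]
  alt <- names(genotype)[genotype == "alternative"]
  edits <- lapply(alt, function(id) {
    sp <- setup$spans[[id]]
    sv <- setup$svCatalog[[as.integer(id)]]
    list(start = sp$delStart, end = sp$delEnd,
         insert = if (sv$kind == "complex") setup$novelBlock else NULL)
  })
  if (length(edits) > 1)
    edits <- edits[order(vapply(edits, `[[`, numeric(1), "start"))]
  pieces <- list(); at <- 1L
  for (e in edits) {
    pieces[[length(pieces) + 1L]] <- subseq(backbone, at, e$start - 1L)
    if (!is.null(e$insert)) pieces[[length(pieces) + 1L]] <- e$insert
    at <- e$end + 1L
  }
  pieces[[length(pieces) + 1L]] <- subseq(backbone, at, length(backbone))
  seqOut <- if (length(pieces) == 1) pieces[[1]] else do.call(xscat, pieces)
  g <- locusGenes(setup$toy$locusMap)
  genes <- mcols(g)$gene
  for (id in alt) {
    sv <- setup$svCatalog[[as.integer(id)]]
    if (sv$kind == "complex") {
      genes <- setdiff(genes, sv$hapAGenes)
      genes <- c(genes, sv$hapBGenes)
    } else {
      genes <- setdiff(genes, setup$spans[[id]]$inside)
    }
  }
  list(sequence = seqOut, genes = sort(genes))
}

#' Write simulated reads as FASTQ
#'
#' @param reads Named [Biostrings::DNAStringSet].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeReadsFastq <- function(reads, path) {
  qual <- BStringSet(vapply(width(reads),
                            function(w) paste(rep("I", w), collapse = ""),
                            character(1)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(reads)) {
    writeLines(c(paste0("@", names(reads)[i]), as.character(reads[[i]]),
                 "+", as.character(qual[[i]])), con)
  }
  invisible(path)
}
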