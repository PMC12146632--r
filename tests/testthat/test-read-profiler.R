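test_that("extractSegments normalises split records, SA entries and strands", {
  ## original-read bases 501..1000 align reverse: they occupy positions
  ## 1..500 of the reverse-complemented read, so the SAM CIGAR of the
  ## minus-strand record is 500M500S
  recs <- rbind(
    alnRecord("r1", "ref", 1001L, "400M600S",
              sa = "ref,5001,-,500M500S,60,0;"),
    alnRecord("r1", "ref", 5001L, "500M500S", flag = 2064L))
  segs <- extractSegments(recs)
  expect_identical(nrow(segs), 2L)
  expect_identical(segs$readStart, c(1L, 501L))
  expect_identical(segs$readEnd, c(400L, 1000L))
  expect_identical(segs$refStart, c(1001L, 5001L))
  expect_identical(segs$refEnd, c(1400L, 5500L))
  expect_identical(segs$orientation, c("+", "-"))
  ## the minus-strand record alone, via its SA echo, gives the same span
  segs2 <- extractSegments(alnRecord(
    "r1", "ref", 5001L, "500M500S", flag = 2064L,
    sa = "ref,1001,+,400M600S,60,0;"))
  expect_identical(segs2$readStart, segs$readStart)
  expect_identical(segs2$refStart, segs$refStart)
})

test_that("extractSegments rejects inconsistent record sets", {
  recs <- rbind(alnRecord("r1", "ref", 1L, "100M"),
                alnRecord("r1", "ref", 500L, "200M"))
  expect_error(extractSegments(recs), "inconsistent read length")
  expect_error(extractSegments(rbind(alnRecord("a", "ref", 1L, "100M"),
                                     alnRecord("b", "ref", 1L, "100M"))))
})

test_that("junctionsFromSegments places offsets at gap and overlap midpoints", {
  toy <- toyFixture()
  a <- rssAnchors(toy$locusMap)
  jPos <- a$position[a$gene == "toyJ2" & a$side == "upstream"]
  vPos <- a$position[a$gene == "toyV4" & a$side == "downstream"]
  seg <- function(rs, re, fs, fe) data.frame(
    readId = "r1", readStart = rs, readEnd = re, reference = "toyIGH",
    refStart = fs, refEnd = fe, orientation = "+", stringsAsFactors = FALSE)
  ## 2-base unaligned gap: junction at midpoint of the gap
  segs <- rbind(seg(1L, 200L, jPos - 199L, jPos),
                seg(203L, 400L, vPos, vPos + 197L))
  jx <- junctionsFromSegments(segs, toy$locusMap)
  expect_identical(nrow(jx), 1L)
  expect_identical(jx$readOffset, 201L)
  expect_identical(jx$leftGene, "toyJ2")
  expect_identical(jx$rightGene, "toyV4")
  expect_true(jx$confident)
  expect_false(jx$flip)
  ## 10-base overlap: junction at the overlap midpoint
  segs2 <- rbind(seg(1L, 200L, jPos - 199L, jPos),
                 seg(191L, 400L, vPos, vPos + 209L))
  jx2 <- junctionsFromSegments(segs2, toy$locusMap)
  expect_identical(jx2$readOffset, 195L)
  ## gap beyond maxGap: no junction
  segs3 <- rbind(seg(1L, 200L, jPos - 199L, jPos),
                 seg(232L, 400L, vPos, vPos + 168L))
  expect_identical(nrow(junctionsFromSegments(segs3, toy$locusMap)), 0L)
})

test_that("detectCigarDeletions applies the minLen and |L - d| rules", {
  toy <- toyFixture()
  a <- rssAnchors(toy$locusMap)
  up <- a$position[a$gene == "toyD2" & a$side == "upstream"]
  down <- a$position[a$gene == "toyD3" & a$side == "downstream"]
  d <- down - up                      # anchor distance
  seg <- function(cigar, refStart) data.frame(
    readId = "r1", readStart = 1L, cigar = cigar, refStart = refStart,
    refEnd = refStart + IGHvdj:::.refWidth(IGHvdj:::.cigarParts(cigar)$ops,
                                           IGHvdj:::.cigarParts(cigar)$lens) - 1L,
    orientation = "+", readLen = 400L, readEnd = 400L,
    stringsAsFactors = FALSE)
  ## deletion of exactly the anchor distance at the anchor: confident D-D
  jx <- detectCigarDeletions(seg(sprintf("200M%dD200M", d), up - 199L),
                             toy$locusMap)
  expect_identical(nrow(jx), 1L)
  expect_identical(jx$leftGene, "toyD2")
  expect_identical(jx$rightGene, "toyD3")
  expect_identical(jx$origin, "cigar_deletion")
  expect_true(jx$confident)
  ## |L - d| just inside / outside the 50 bp slack
  expect_identical(nrow(detectCigarDeletions(
    seg(sprintf("200M%dD200M", d - 50L), up - 199L), toy$locusMap)), 1L)
  expect_identical(nrow(detectCigarDeletions(
    seg(sprintf("200M%dD200M", d - 51L), up - 199L), toy$locusMap)), 0L)
  ## deletions shorter than minLen are never scanned
  expect_identical(nrow(detectCigarDeletions(
    seg("200M99D200M", up - 199L), toy$locusMap, minLen = 100)), 0L)
})

test_that("classifyRead implements the event grammar", {
  toy <- toyFixture()
  a <- rssAnchors(toy$locusMap)
  pos <- function(g, s) a$position[a$gene == g & a$side == s]
  jxRow <- function(lg, ls, rg, rs, flip = FALSE,
                    leftSeg = NULL, rightSeg = NULL) {
    lp <- pos(lg, ls); rp <- pos(rg, rs)
    IGHvdj:::.junctionRow(
      "r1", 100L, lp, rp, "split_alignment", flip,
      IGHvdj:::.rssLookup(toy$locusMap, lp, 50),
      IGHvdj:::.rssLookup(toy$locusMap, rp, 50),
      if (is.null(leftSeg)) c(lp - 400, lp) else leftSeg,
      if (is.null(rightSeg)) c(rp, rp + 400) else rightSeg)
  }
  cls <- function(jx) classifyRead(jx, toy$locusMap)$class
  expect_identical(cls(IGHvdj:::.emptyJunctions()), "unrecombined")
  expect_identical(cls(jxRow("toyJ2", "upstream", "toyV4", "downstream")),
                   "complete_VDJ")
  expect_identical(cls(jxRow("toyJ1", "upstream", "toyD4", "downstream")),
                   "DJ_only")
  expect_identical(cls(jxRow("toyJ2", "upstream", "toyD4", "upstream",
                             flip = TRUE)), "inversion_DJ")
  expect_identical(cls(jxRow("toyD2", "downstream", "toyD5", "downstream",
                             flip = TRUE)), "inversion_DD")
  expect_identical(cls(jxRow("toyD3", "downstream", "toyV5", "downstream",
                             flip = TRUE)), "inversion_VD")
  expect_identical(cls(rbind(
    jxRow("toyJ3", "upstream", "toyD2", "downstream"),
    jxRow("toyD5", "upstream", "toyV3", "downstream"))), "multiple_D")
})

test_that("lone D-V junction needs the intergenic flank to be VD_only", {
  toy <- toyFixture()
  g <- locusGenes(toy$locusMap)
  m <- S4Vectors::mcols(g)
  jEnd <- max(IRanges::end(g)[m$class == "J"])
  a <- rssAnchors(toy$locusMap)
  dUp <- a$position[a$gene == "toyD2" & a$side == "upstream"]
  vDown <- a$position[a$gene == "toyV7" & a$side == "downstream"]
  mk <- function(leftSegStart) IGHvdj:::.junctionRow(
    "r1", 100L, dUp, vDown, "split_alignment", FALSE,
    IGHvdj:::.rssLookup(toy$locusMap, dUp, 50),
    IGHvdj:::.rssLookup(toy$locusMap, vDown, 50),
    c(leftSegStart, dUp), c(vDown, vDown + 400))
  ## D-side segment reaching 200 bp into the J-D intergenic region
  expect_identical(classifyRead(mk(jEnd + 1), toy$locusMap)$class, "VD_only")
  ## segment confined near the D block: evidence of a multiple-D event
  expect_identical(classifyRead(mk(dUp - 100), toy$locusMap)$class,
                   "multiple_D")
})

test_that("profileSample qualifies by J-D overlap and drops V-V-only reads", {
  toy <- toyFixture()
  ref <- referenceName(toy$locusMap)
  rs <- makeReferenceSet(setNames(list(toy$locusMap), ref))
  a <- rssAnchors(toy$locusMap)
  jd <- jdInterval(toy$locusMap)
  v2 <- a$position[a$gene == "toyV2"]
  v9 <- a$position[a$gene == "toyV9"]
  ## read with a lone germline J-block segment plus a V2-V9 split: its
  ## only junction joins two V genes => excluded as germline SV evidence
  recs <- rbind(
    alnRecord("vv1", ref, IRanges::start(jd), "100M600S"),
    alnRecord("vv1", ref, v2 - 199L, "300S200M200S", flag = 2048L),
    alnRecord("vv1", ref, v9, "500S200M", flag = 2048L))
  prof <- profileSample(setNames(list(recs), ref), rs)
  expect_identical(length(prof), 0L)
  expect_identical(attr(prof, "droppedVV"), "vv1")
  ## a read aligned entirely outside the J-D span never qualifies
  recs2 <- alnRecord("far1", ref, v9, "200M")
  prof2 <- profileSample(setNames(list(recs2), ref), rs)
  expect_identical(length(prof2), 0L)
  expect_identical(attr(prof2, "droppedVV"), character(0))
})

test_that("chooseReference prefers all-confident evidence, then priority", {
  mix <- mixtureFixture()
  prof <- mix$prof
  ## pick one recombined evidence and a synthetic unrecombined rival
  ev <- prof[[which(vapply(prof, eventClass, character(1)) ==
                      "complete_VDJ")[1]]]
  rival <- new("ReadEvidence", readId = readId(ev), reference = "alt",
               segments = readSegments(ev),
               junctions = IGHvdj:::.emptyJunctions(),
               eventClass = "unrecombined",
               genesUsed = data.frame(gene = character(0),
                                      side = character(0),
                                      class = character(0)),
               confident = FALSE)
  rs2 <- makeReferenceSet(setNames(list(mix$toy$locusMap,
                                        mix$toy$locusMap),
                                   c("alt", referenceName(ev))))
  ## the recombined evidence has more confident breakends and wins even
  ## though "alt" has priority
  pick <- chooseReference(setNames(list(rival, ev),
                                   c("alt", referenceName(ev))), rs2)
  expect_identical(referenceName(pick), referenceName(ev))
  ## with two equally scored candidates, ReferenceSet priority decides
  altTwin <- initialize(ev, reference = "alt")
  pick2 <- chooseReference(setNames(list(ev, altTwin),
                                    c(referenceName(ev), "alt")), rs2)
  expect_identical(referenceName(pick2), "alt")
  expect_error(chooseReference(list(), rs2), "no reference")
})

test_that("evidence TSV round-trips classification and junctions", {
  mix <- mixtureFixture()
  prof <- mix$prof
  path <- tempfile(fileext = ".tsv")
  writeEvidenceTsv(prof, path)
  back <- readEvidenceTsv(path)
  t1 <- evidenceTable(prof)
  t2 <- evidenceTable(back)
  rownames(t1) <- rownames(t2) <- NULL
  expect_equal(t2$readId, t1$readId)
  expect_equal(t2$eventClass, t1$eventClass)
  expect_equal(t2$genesUsed, t1$genesUsed)
  expect_equal(t2$nJunctions, t1$nJunctions)
  expect_equal(t2$confident, t1$confident)
  unlink(path)
})
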