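test_that("annotateContigs recovers every toy gene exactly on germline", {
  toy <- toyFixture()
  hits <- annotateContigs(toy$sequence, toy$alleleDb, maxEdit = 2)
  g <- locusGenes(toy$locusMap)
  m <- S4Vectors::mcols(g)
  expect_identical(nrow(hits), length(g))
  expect_setequal(hits$gene, m$gene)
  i <- match(hits$gene, m$gene)
  expect_identical(hits$start, IRanges::start(g)[i])
  expect_identical(hits$end, IRanges::end(g)[i])
  expect_true(all(hits$mismatches == 0L))
  expect_true(all(hits$strand == "+"))
  expect_true(all(hits$allele == paste0(hits$gene, "*01")))
})

test_that("annotateContigs accepts FASTA paths and finds reversed contigs", {
  toy <- toyFixture()
  dir <- tempfile()
  paths <- writeToyLocus(toy, dir)
  hits <- annotateContigs(paths["reference"], paths["alleles"],
                          maxEdit = 2)
  direct <- annotateContigs(toy$sequence, toy$alleleDb, maxEdit = 2)
  expect_identical(hits$gene, direct$gene)
  expect_identical(hits$start, direct$start)
  ## a reverse-complemented contig yields the same genes on "-"
  rc <- Biostrings::reverseComplement(toy$sequence)
  names(rc) <- "rev"
  hitsRc <- annotateContigs(rc, toy$alleleDb, maxEdit = 2)
  expect_setequal(hitsRc$gene, direct$gene)
  expect_true(all(hitsRc$strand == "-"))
  unlink(dir, recursive = TRUE)
})

test_that("filterOrphons drops loose hits and empty contigs", {
  toy <- toyFixture()
  hits <- annotateContigs(toy$sequence, toy$alleleDb, maxEdit = 2)
  hits$mismatches[1] <- 16L
  extra <- hits[2, ]
  extra$contig <- "orphonOnly"
  extra$mismatches <- 20L
  flt <- filterOrphons(rbind(hits, extra))
  expect_identical(nrow(flt$dropped), 2L)
  expect_false("orphonOnly" %in% flt$contigs)
  expect_true(all(flt$hits$kept))
})

test_that("contigProfiles ranks genes along the locus and votes orientation", {
  toy <- toyFixture()
  hits <- filterOrphons(annotateContigs(toy$sequence, toy$alleleDb,
                                        maxEdit = 2))$hits
  pf <- contigProfiles(hits, toy$locusMap)[[1]]
  h <- contigHits(pf)
  expect_identical(h$locusRank, seq_len(nrow(h)))
  expect_identical(contigOrientation(pf), "+")
  expect_identical(contigName(pf), referenceName(toy$locusMap))
  rc <- Biostrings::reverseComplement(toy$sequence)
  names(rc) <- "rev"
  pfRc <- contigProfiles(filterOrphons(
    annotateContigs(rc, toy$alleleDb, maxEdit = 2))$hits,
    toy$locusMap)[[1]]
  expect_identical(contigOrientation(pfRc), "-")
})

test_that("assignDuplicateNames resolves duplicated gene pairs", {
  toy <- toyFixture()
  g <- locusGenes(toy$locusMap)
  refSeq <- toy$sequence[[1]]
  v3 <- match("toyV3", S4Vectors::mcols(g)$gene)
  body <- Biostrings::subseq(refSeq, IRanges::start(g)[v3] - 50,
                             IRanges::end(g)[v3] + 50)
  cut <- IRanges::end(g)[v3] + 500
  dup <- Biostrings::DNAStringSet(c(dup = paste0(
    as.character(Biostrings::subseq(refSeq, 1, cut)),
    as.character(body),
    as.character(Biostrings::subseq(refSeq, cut + 1, length(refSeq))))))
  pf <- contigProfiles(filterOrphons(
    annotateContigs(dup, toy$alleleDb, maxEdit = 2))$hits, toy$locusMap)[[1]]
  expect_identical(sum(contigHits(pf)$gene == "toyV3"), 2L)
  pf2 <- assignDuplicateNames(pf, toy$locusMap, duplicateBases = "toyV3")
  h <- contigHits(pf2)
  expect_identical(sum(h$gene == "toyV3"), 1L)
  expect_identical(sum(h$gene == "toyV3D"), 1L)
  ## the toy map has no toyV3D entry, so the J-proximal copy is renamed
  expect_lt(h$start[h$gene == "toyV3D"], h$start[h$gene == "toyV3"])
  expect_false(any(h$extraCopy))
  ## a single instance keeps its base name untouched
  pf3 <- assignDuplicateNames(pf, toy$locusMap, duplicateBases = "toyV5")
  expect_identical(contigHits(pf3)$gene, contigHits(pf)$gene)
})

test_that("summarizeAssembly reports per-haplotype gene content", {
  toy2 <- fixture("toyPseudo", function()
    makeToyLocus(seed = 3, vPseudo = c(2L, 5L)))
  hits <- filterOrphons(annotateContigs(toy2$sequence, toy2$alleleDb,
                                        maxEdit = 2))$hits
  profs <- contigProfiles(hits, toy2$locusMap)
  rpt <- summarizeAssembly(list(hap1 = profs), toy2$locusMap,
                           exemptD = "toyD1")
  sm <- assemblySummary(rpt)
  expect_identical(sm$nV, 16L)    # pseudogenes excluded from the V count
  expect_identical(sm$nD, 6L)
  expect_identical(sm$nJ, 4L)
  expect_identical(sm$nContigs, 1L)
  expect_setequal(genePresence(rpt)$hap1, contigHits(profs[[1]])$gene)
  ## an intact germline assembly carries no V(D)J junction calls
  expect_identical(nrow(assemblyJunctions(rpt)), 0L)
  expect_identical(nrow(assemblyBreakpoints(rpt)), 0L)
  out <- capture.output(show(rpt))
  expect_true(any(grepl("hap1", out)))
})

test_that("classifyBreakpoints types contig adjacency", {
  toy <- toyFixture()
  refSeq <- toy$sequence[[1]]
  g <- locusGenes(toy$locusMap)
  dEnd <- max(IRanges::end(g)[S4Vectors::mcols(g)$class == "D"])
  vStart <- min(IRanges::start(g)[S4Vectors::mcols(g)$class == "V"])
  mkProfiles <- function(cutA, startB) {
    ctgs <- Biostrings::DNAStringSet(c(
      cA = as.character(Biostrings::subseq(refSeq, 1, cutA)),
      cB = as.character(Biostrings::subseq(refSeq, startB,
                                           length(refSeq)))))
    contigProfiles(filterOrphons(
      annotateContigs(ctgs, toy$alleleDb, maxEdit = 2))$hits,
      toy$locusMap)
  }
  ## disjoint split inside the D-V gap: V1..V3 fall in neither contig
  v3 <- match("toyV3", S4Vectors::mcols(g)$gene)
  profs <- mkProfiles(dEnd + 100, IRanges::end(g)[v3] + 500)
  bp <- classifyBreakpoints(profs, toy$locusMap)
  expect_identical(bp$relation, "disjoint")
  expect_setequal(strsplit(bp$missingGenes, ";")[[1]],
                  c("toyV1", "toyV2", "toyV3"))
  ## overlapping contigs share genes
  profs2 <- mkProfiles(vStart + 1000, dEnd - 100)
  bp2 <- classifyBreakpoints(profs2, toy$locusMap)
  expect_identical(bp2$relation, "overlap")
  ## containment is a duplication
  ctgs3 <- Biostrings::DNAStringSet(c(
    whole = as.character(refSeq),
    part = as.character(Biostrings::subseq(refSeq, 1, dEnd + 100))))
  profs3 <- contigProfiles(filterOrphons(
    annotateContigs(ctgs3, toy$alleleDb, maxEdit = 2))$hits,
    toy$locusMap)
  bp3 <- classifyBreakpoints(profs3, toy$locusMap)
  expect_identical(bp3$relation, "duplication")
})

test_that("validateGenes enforces coverage, mapq and the edit rule", {
  set.seed(99)
  contig <- paste(sample(c("A", "C", "G", "T"), 600, replace = TRUE),
                  collapse = "")
  asm <- Biostrings::DNAStringSet(c(c1 = contig))
  hits <- data.frame(contig = "c1", gene = "g1", start = 101L, end = 400L,
                     stringsAsFactors = FALSE)
  mut <- function(s, at) {
    ch <- strsplit(s, "")[[1]]
    for (p in at) ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
    paste(ch, collapse = "")
  }
  perfect <- alnRecord("p", "c1", 1L, "600M", seq = contig)
  one <- alnRecord("m1", "c1", 1L, "600M", seq = mut(contig, 200))
  two <- alnRecord("m2", "c1", 1L, "600M", seq = mut(contig, c(200, 300)))
  v0 <- validateGenes(asm, perfect, hits)
  expect_true(v0$fullyCovered && v0$editDistance == 0L && v0$confident)
  v1 <- validateGenes(asm, one, hits)
  expect_identical(v1$editDistance, 1L)
  expect_true(v1$confident)
  v2 <- validateGenes(asm, two, hits)
  expect_identical(v2$editDistance, 2L)
  expect_false(v2$confident)
  ## low-mapq reads are ignored entirely
  low <- alnRecord("lo", "c1", 1L, "600M", seq = contig, mapq = 5L)
  vLow <- validateGenes(asm, low, hits)
  expect_false(vLow$fullyCovered)
  ## alignments naming an unknown record are rejected
  stray <- alnRecord("s", "elsewhere", 1L, "600M", seq = contig)
  expect_error(validateGenes(asm, stray, hits), "absent")
})
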