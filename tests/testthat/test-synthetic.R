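test_that("makeToyLocus is deterministic and plants RSS heptamers", {
  t1 <- makeToyLocus(seed = 7)
  t2 <- makeToyLocus(seed = 7)
  expect_identical(as.character(t1$sequence), as.character(t2$sequence))
  a <- rssAnchors(t1$locusMap)
  seqc <- as.character(t1$sequence[[1]])
  for (i in seq_len(nrow(a))) {
    if (a$side[i] == "upstream") {
      got <- substr(seqc, a$position[i] + 1, a$position[i] + 7)
    } else {
      got <- substr(seqc, a$position[i] - 7, a$position[i] - 1)
    }
    expect_identical(got, "CACAGTG")
  }
  ## the allele database holds the exact gene bodies
  g <- locusGenes(t1$locusMap)
  i <- match("toyD3*01|D|functional", names(t1$alleleDb))
  k <- match("toyD3", S4Vectors::mcols(g)$gene)
  expect_identical(as.character(t1$alleleDb[[i]]),
                   as.character(Biostrings::subseq(
                     t1$sequence[[1]], IRanges::start(g)[k],
                     IRanges::end(g)[k])))
})

test_that("simEventSpec enforces per-class gene requirements", {
  expect_error(simEventSpec("complete_VDJ", dGenes = "toyD1",
                            vGene = "toyV1"), "requires jGene")
  expect_error(simEventSpec("multiple_D", jGene = "toyJ1", dGenes = "toyD1",
                            vGene = "toyV1"), "at least 2")
  sJoin <- simEventSpec("multiple_D", dGenes = c("toyD1", "toyD2"),
                        style = "join")
  expect_identical(sJoin$style, "join")
  expect_error(simEventSpec("no_such_class"), "unsupported")
})

test_that("simulated deletions and inversions rewrite the haplotype correctly", {
  toy <- toyFixture()
  L <- length(toy$sequence[[1]])
  a <- rssAnchors(toy$locusMap)
  pos <- function(g, s) a$position[a$gene == g & a$side == s]
  ## DJ_only: one deletion of the open interval between the anchors
  hap <- simulateRecombination(
    toy, simEventSpec("DJ_only", jGene = "toyJ1", dGenes = "toyD4"),
    seed = 3)
  delLen <- pos("toyD4", "downstream") - pos("toyJ1", "upstream") - 1L
  insLen <- hap$junctions$insLen[1]
  expect_identical(length(hap$sequence), L - delLen + insLen)
  expect_identical(hap$eventClass, "DJ_only")
  ## blocks tile the haplotype contiguously
  expect_identical(hap$blocks$hapStart[1], 1L)
  expect_identical(max(hap$blocks$hapEnd), length(hap$sequence))
  expect_true(all(hap$blocks$hapStart[-1] ==
                    head(hap$blocks$hapEnd, -1) + 1))
  ## sequence check across the junction
  jxAt <- hap$junctions$hapLeftEnd[1]
  expect_identical(
    as.character(Biostrings::subseq(hap$sequence, 1, jxAt)),
    as.character(Biostrings::subseq(toy$sequence[[1]], 1,
                                    pos("toyJ1", "upstream"))))
  ## inversion preserves length and reverse-complements the span
  inv <- simulateRecombination(
    toy, simEventSpec("inversion_DD", dGenes = c("toyD2", "toyD5")),
    seed = 4)
  expect_identical(length(inv$sequence), L)
  s <- pos("toyD2", "downstream"); e <- pos("toyD5", "downstream") - 1
  expect_identical(
    as.character(Biostrings::subseq(inv$sequence, s, e)),
    as.character(Biostrings::reverseComplement(
      Biostrings::subseq(toy$sequence[[1]], s, e))))
  expect_true(all(inv$junctions$flip))
})

test_that("multiple_D styles retain or delete the inter-D span as documented", {
  toy <- toyFixture()
  a <- rssAnchors(toy$locusMap)
  pos <- function(g, s) a$position[a$gene == g & a$side == s]
  ## skip style: the toyD2..toyD5 span survives intact between junctions
  skip <- simulateRecombination(
    toy, simEventSpec("multiple_D", jGene = "toyJ3",
                      dGenes = c("toyD2", "toyD5"), vGene = "toyV3"),
    seed = 6)
  retained <- as.character(Biostrings::subseq(
    toy$sequence[[1]], pos("toyD2", "downstream"),
    pos("toyD5", "upstream")))
  expect_true(grepl(retained, as.character(skip$sequence), fixed = TRUE))
  expect_identical(nrow(skip$junctions), 2L)
  ## join style: the sequence between the two D genes is deleted
  join <- simulateRecombination(
    toy, simEventSpec("multiple_D", dGenes = c("toyD2", "toyD3"),
                      style = "join"), seed = 6)
  inter <- as.character(Biostrings::subseq(
    toy$sequence[[1]], pos("toyD2", "upstream") + 1,
    pos("toyD3", "downstream") - 1))
  expect_false(grepl(inter, as.character(join$sequence), fixed = TRUE))
})

test_that("simulated reads slice the haplotype faithfully on both strands", {
  mix <- mixtureFixture()
  sim <- mix$sim
  toy <- mix$toy
  refSeq <- toy$sequence[[1]]
  ## truth segments reproduce the reference subsequence of each read
  some <- head(names(sim$reads), 40)
  for (rid in some) {
    sg <- sim$segments[sim$segments$readId == rid, , drop = FALSE]
    for (k in seq_len(nrow(sg))) {
      got <- Biostrings::subseq(sim$reads[[rid]], sg$readStart[k],
                                sg$readEnd[k])
      want <- Biostrings::subseq(refSeq, sg$refStart[k], sg$refEnd[k])
      if (sg$orientation[k] == "-")
        want <- Biostrings::reverseComplement(want)
      expect_identical(as.character(got), as.character(want))
    }
  }
  ## both strands are sampled
  firstSeg <- sim$segments[!duplicated(sim$segments$readId), ]
  expect_setequal(unique(firstSeg$orientation), c("+", "-"))
})

test_that("truth records form a consistent SAM that round-trips", {
  mix <- mixtureFixture()
  recs <- mix$recs
  ## exactly one primary record per read, SA tags name the others
  byRead <- split(recs, recs$qname)
  for (rr in byRead[seq_len(min(30, length(byRead)))]) {
    expect_identical(sum(bitwAnd(rr$flag, 2048L) == 0L), 1L)
    if (nrow(rr) > 1) expect_true(all(!is.na(rr$sa)))
  }
  ## SAM written to disk parses back into the same records
  sam <- tempfile(fileext = ".sam")
  writeTruthSam(mix$sim, mix$toy, sam)
  back <- readAlignments(sam)
  ord <- order(recs$qname, recs$pos, recs$cigar)
  ordB <- order(back$qname, back$pos, back$cigar)
  expect_identical(back$qname[ordB], recs$qname[ord])
  expect_identical(back$pos[ordB], recs$pos[ord])
  expect_identical(back$cigar[ordB], recs$cigar[ord])
  expect_identical(back$flag[ordB], recs$flag[ord])
  unlink(sam)
  ## profiling the file and the records gives identical evidence
  ref <- referenceName(mix$toy$locusMap)
  profB <- profileSample(setNames(list(back), ref), mix$refset)
  expect_identical(evidenceTable(profB), evidenceTable(mix$prof))
})

test_that("the toy SV setup is internally consistent", {
  setup <- svFixture()
  lm <- setup$toy$locusMap
  expect_identical(length(setup$svCatalog), 7L)
  expect_identical(setup$registry$backbone %in%
                     names(setup$registry$sequences), TRUE)
  expect_true(all(sprintf("altSV%d", 1:7) %in%
                    names(setup$registry$sequences)))
  ## deletion spans are pairwise disjoint on the backbone
  spans <- do.call(rbind, lapply(names(setup$spans), function(id) {
    sp <- setup$spans[[id]]
    data.frame(id = id, start = sp$delStart, end = sp$delEnd)
  }))
  spans <- spans[order(spans$start), ]
  expect_true(all(spans$start[-1] > head(spans$end, -1)))
  ## the novel complex block carries the two novel V alleles
  expect_true(all(c("toyVB1*01|V|functional", "toyVB2*01|V|functional")
                  %in% names(setup$alleleDb)))
})

test_that("makeSvHaplotype removes exactly the selected genes", {
  setup <- svFixture()
  geno <- setNames(rep("default", 7), as.character(1:7))
  geno["5"] <- "alternative"
  hap <- makeSvHaplotype(setup, geno)
  germGenes <- S4Vectors::mcols(locusGenes(setup$toy$locusMap))$gene
  lost <- setdiff(germGenes, hap$genes)
  expect_identical(sort(lost), sort(setup$spans[["5"]]$inside))
  expect_lt(length(hap$sequence), length(setup$toy$sequence[[1]]))
})
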