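test_that("svDefinition validates its inputs", {
  expect_error(svDefinition(1L, "complex", "x", "x",
                            hapAGenes = character(0),
                            hapBGenes = "b",
                            sourceDefault = "d", sourceAlternative = "a"),
               "disjoint, non-empty")
  expect_error(svDefinition(1L, "complex", "x", "x",
                            hapAGenes = c("g1"), hapBGenes = c("g1"),
                            sourceDefault = "d", sourceAlternative = "a"),
               "disjoint, non-empty")
  sv <- svDefinition(2L, "deletion", "IGHV7-4-1",
                     sourceDefault = "CHM13", sourceAlternative = "GRCh37")
  expect_identical(sv$kind, "deletion")
  expect_identical(sv$insideFrom, sv$insideTo)
})

test_that("the built-in SV catalog matches the published seven events", {
  cat <- ighSvCatalog()
  expect_identical(length(cat), 7L)
  expect_identical(vapply(cat, `[[`, integer(1), "svId"), 1:7)
  kinds <- vapply(cat, `[[`, character(1), "kind")
  expect_identical(sum(kinds == "deletion"), 6L)
  expect_identical(which(kinds == "complex"), 3L)
  expect_setequal(cat[[3]]$hapAGenes, c("IGHV1-8", "IGHV3-9"))
  expect_setequal(cat[[3]]$hapBGenes, c("IGHV3-64D", "IGHV5-10-1"))
  expect_identical(cat[[1]]$insideFrom, "IGHD2-8")
  expect_identical(cat[[1]]$insideTo, "IGHD3-3")
  expect_identical(cat[[7]]$insideFrom, "IGHV2-70D")
  expect_identical(cat[[7]]$insideTo, "IGHV1-69D")
})

test_that("typeSvAlleles follows the presence rules, including one flank", {
  setup <- svFixture()
  lm <- setup$toy$locusMap
  sv2 <- setup$svCatalog[[2]]           # deletion of a single V gene
  rg <- IGHvdj:::.svRegion(sv2, lm)
  g <- locusGenes(lm)
  m <- S4Vectors::mcols(g)
  span <- function(genes) {
    i <- match(genes, m$gene)
    c(min(IRanges::start(g)[i]) - 50L, max(IRanges::end(g)[i]) + 50L)
  }
  mkProfile <- function(from, to) {
    ctg <- Biostrings::DNAStringSet(setNames(list(
      Biostrings::subseq(setup$toy$sequence[[1]], from, to)), "c"))
    contigProfiles(filterOrphons(
      annotateContigs(ctg, setup$alleleDb, maxEdit = 2))$hits, lm)[[1]]
  }
  ## germline contig over the whole SV region: inside gene present
  s <- span(c(rg$flanks, rg$inside))
  callFull <- typeSvAlleles(mkProfile(s[1], s[2]), setup$svCatalog, lm)
  expect_identical(callFull$call[callFull$svId == 2L], "default")
  ## contig covering only the J-proximal flank: unknown
  sLeft <- span(rg$flanks[1])
  callLeft <- typeSvAlleles(mkProfile(sLeft[1], sLeft[2]),
                            setup$svCatalog, lm)
  expect_identical(callLeft$call[callLeft$svId == 2L], "unknown")
})

test_that("consolidateCalls merges compatible calls and flags conflicts", {
  calls <- data.frame(
    contig = c("a", "b", "c", "a", "b"),
    svId = c(1L, 1L, 1L, 2L, 2L),
    call = c("alternative", "unknown", "alternative",
             "default", "alternative"),
    stringsAsFactors = FALSE)
  res <- consolidateCalls(calls)
  expect_identical(res$calls$call[res$calls$svId == 1L], "alternative")
  expect_false(res$calls$conflict[res$calls$svId == 1L])
  expect_true(res$calls$conflict[res$calls$svId == 2L])
  expect_true(res$conflict)
  allUnknown <- consolidateCalls(data.frame(
    contig = "a", svId = 3L, call = "unknown", stringsAsFactors = FALSE))
  expect_identical(allUnknown$calls$call, "unknown")
})

test_that("reconcileHaplotypes resolves conflicts by single-contig moves", {
  mk <- function(contig, svId, call)
    data.frame(contig = contig, svId = svId, call = call,
               stringsAsFactors = FALSE)
  ## consistent groups: nothing to do
  ok <- reconcileHaplotypes(rbind(mk("c1", 1L, "default"),
                                  mk("c2", 1L, "default")),
                            list(pat = c("c1", "c2"), mat = character(0)))
  expect_identical(ok$status, "ok")
  expect_identical(length(ok$moved), 0L)
  ## one conflicting contig moves to the other parent
  fix <- reconcileHaplotypes(rbind(mk("c1", 1L, "default"),
                                   mk("c2", 1L, "alternative"),
                                   mk("c3", 1L, "alternative")),
                             list(pat = c("c1", "c2"), mat = "c3"))
  expect_identical(fix$status, "reconciled")
  expect_identical(fix$moved, "c2")
  expect_true("c2" %in% fix$groups$mat)
  ## irresolvable cross-conflicts are surfaced for manual review
  bad <- reconcileHaplotypes(rbind(mk("c1", 1L, "default"),
                                   mk("c2", 1L, "alternative"),
                                   mk("c3", 2L, "default"),
                                   mk("c4", 2L, "alternative")),
                             list(pat = c("c1", "c2"),
                                  mat = c("c3", "c4")))
  expect_identical(bad$status, "manual_required")
})

test_that("segment registries load from JSON with relative FASTA paths", {
  setup <- svFixture()
  dir <- tempfile()
  dir.create(dir)
  fa <- file.path(dir, "segments.fa")
  seqs <- c(setup$registry$sequences["backbone"],
            setup$registry$sequences["altSV2"])
  Biostrings::writeXStringSet(seqs, fa)
  json <- file.path(dir, "registry.json")
  jsonlite::write_json(list(
    fasta = "segments.fa", backbone = "backbone",
    segments = list(list(sv = 2L, allele = "alternative",
                         record = "altSV2"))),
    json, auto_unbox = TRUE)
  reg <- readSegmentRegistry(json)
  expect_identical(as.character(reg$sequences[["backbone"]]),
                   as.character(setup$registry$sequences[["backbone"]]))
  seg <- IGHvdj:::.registrySegment(reg, 2L, "alternative")
  expect_identical(seg$name, "altSV2")
  expect_identical(as.character(seg$seq),
                   as.character(setup$registry$sequences[["altSV2"]]))
  unlink(dir, recursive = TRUE)
})

test_that("buildPersonalReference tiles provenance over the haplotype", {
  setup <- svFixture()
  lm <- setup$toy$locusMap
  calls <- data.frame(contig = "h", svId = 1:7,
                      call = c("alternative", "default", "alternative",
                               "default", "unknown", "default",
                               "alternative"),
                      stringsAsFactors = FALSE)
  pr <- buildPersonalReference(list(hap1 = calls), setup$registry,
                               setup$svCatalog, lm)
  seqs <- haplotypeSequences(pr)
  prov <- provenance(pr)
  expect_identical(names(seqs), "hap1")
  one <- prov[prov$haplotype == "hap1", , drop = FALSE]
  expect_identical(one$start[1], 1L)
  expect_identical(max(one$end), length(seqs[[1]]))
  expect_true(all(one$start[-1] == head(one$end, -1) + 1))
  expect_setequal(unique(one$source),
                  c("backbone", "altSV1", "altSV3", "altSV7"))
  expect_identical(sum(one$source != "backbone"), 3L)
  ## unknown calls keep the backbone
  expect_identical(svCalls(pr)$call, calls$call)
  ## an all-default set reproduces the backbone verbatim
  prDef <- buildPersonalReference(
    list(h = data.frame(contig = "h", svId = 1:7, call = "default")),
    setup$registry, setup$svCatalog, lm)
  expect_identical(
    as.character(haplotypeSequences(prDef)[["h"]]),
    as.character(setup$registry$sequences[["backbone"]]))
})

test_that("maskUnsupported drops records with no contig support", {
  asm <- Biostrings::DNAStringSet(c(
    good = paste(rep("A", 300), collapse = ""),
    ghost = paste(rep("C", 200), collapse = "")))
  contigAln <- alnRecord("ctg1", "good", 1L, "300M")
  readAln <- alnRecord("rd1", "ghost", 1L, "200M")
  m <- maskUnsupported(asm, readAln, contigAln)
  expect_identical(names(haplotypeSequences(m)), "good")
  log <- maskLog(m)
  expect_identical(log$reason[log$contig == "ghost"],
                   "dropped_no_contig_support")
})
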