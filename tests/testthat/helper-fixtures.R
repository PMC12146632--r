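## Shared fixtures, built lazily and cached for the whole test run.

.fx <- new.env(parent = emptyenv())

fixture <- function(name, make) {
  if (!exists(name, envir = .fx, inherits = FALSE))
    assign(name, make(), envir = .fx)
  get(name, envir = .fx)
}

toyFixture <- function() fixture("toy", function() makeToyLocus(seed = 1))

## One clone per event class plus a germline clone, equal fractions.
allClassClones <- function(toy) {
  sr <- function(spec, seed) simulateRecombination(toy, spec, seed = seed)
  f <- 1 / 8
  list(
    list(name = "vdj", fraction = f,
         hap = sr(simEventSpec("complete_VDJ", jGene = "toyJ2",
                               dGenes = "toyD3", vGene = "toyV4"), 11)),
    list(name = "dj", fraction = f,
         hap = sr(simEventSpec("DJ_only", jGene = "toyJ1",
                               dGenes = "toyD4"), 12)),
    list(name = "vd", fraction = f,
         hap = sr(simEventSpec("VD_only", dGenes = "toyD2",
                               vGene = "toyV7"), 13)),
    list(name = "multid", fraction = f,
         hap = sr(simEventSpec("multiple_D", jGene = "toyJ3",
                               dGenes = c("toyD2", "toyD5"),
                               vGene = "toyV3"), 14)),
    list(name = "invdj", fraction = f,
         hap = sr(simEventSpec("inversion_DJ", jGene = "toyJ2",
                               dGenes = "toyD4"), 15)),
    list(name = "invdd", fraction = f,
         hap = sr(simEventSpec("inversion_DD",
                               dGenes = c("toyD2", "toyD5")), 16)),
    list(name = "invvd", fraction = f,
         hap = sr(simEventSpec("inversion_VD", dGenes = "toyD3",
                               vGene = "toyV5"), 17)),
    list(name = "germ", fraction = f, hap = germlineHaplotype(toy)))
}

## Simulated all-class mixture, its truth alignments and the profiler's
## read evidence for it (the default simulator conditions: depth 40 so
## every class is covered by several reads).
mixtureFixture <- function() fixture("mixture", function() {
  toy <- toyFixture()
  ref <- referenceName(toy$locusMap)
  sim <- simulateReads(toy, allClassClones(toy), depth = 40,
                       readLen = 5000, seed = 42)
  recs <- truthRecords(sim, toy)
  rs <- makeReferenceSet(setNames(list(toy$locusMap), ref))
  prof <- profileSample(setNames(list(recs), ref), rs)
  list(toy = toy, sim = sim, recs = recs, refset = rs, prof = prof)
})

## Bare D-D join mixture whose truth alignments carry the recombination
## as an in-CIGAR deletion (exercises the CIGAR detection route).
cigarFixture <- function() fixture("cigarJoin", function() {
  toy <- toyFixture()
  ref <- referenceName(toy$locusMap)
  clones <- list(
    list(name = "ddjoin", fraction = 1,
         hap = simulateRecombination(
           toy, simEventSpec("multiple_D", dGenes = c("toyD2", "toyD3"),
                             style = "join"), seed = 5)),
    NULL)
  clones <- clones[!vapply(clones, is.null, logical(1))]
  sim <- simulateReads(toy, clones, depth = 20, readLen = 4000, seed = 7)
  recs <- truthRecords(sim, toy, mergeDeletionsUpTo = 700)
  rs <- makeReferenceSet(setNames(list(toy$locusMap), ref))
  prof <- profileSample(setNames(list(recs), ref), rs)
  list(toy = toy, sim = sim, recs = recs, prof = prof)
})

## Toy structural-variant setup (7-SV catalog, registry, allele db).
svFixture <- function() fixture("svSetup", function() makeToySvSetup(seed = 1))

## Split truth gene strings ("gene[side];...") into a character set.
geneSet <- function(s) {
  if (is.na(s) || !nzchar(s)) return(character(0))
  sort(unique(strsplit(s, ";", fixed = TRUE)[[1]]))
}

## Gene set of a ReadEvidence in the same encoding as simulation truth.
evidenceGeneSet <- function(ev) {
  gu <- genesUsed(ev)
  sort(unique(sprintf("%s[%s]", gu$gene, gu$side)))
}

## Minimal alignment record table in the readAlignments() layout.
alnRecord <- function(qname, rname, pos, cigar, seq = NA_character_,
                      flag = 0L, mapq = 60L, sa = NA_character_) {
  if (is.na(seq)) {
    p <- IGHvdj:::.cigarParts(cigar)
    qw <- sum(p$lens[p$ops %in% c("M", "I", "=", "X", "S")])
    seq <- paste(rep("A", qw), collapse = "")
  }
  data.frame(qname = qname, flag = flag, rname = rname, pos = pos,
             mapq = mapq, cigar = cigar, seq = seq, sa = sa,
             stringsAsFactors = FALSE)
}
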