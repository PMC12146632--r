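## Personal reference construction: typing the catalogued IGH SVs from
## contig gene content, reconciling parental contig groups, stitching a
## per-haplotype guide reference, and masking unsupported regions.

#' Define one catalogued IGH structural variant
#'
#' @param svId Integer identifier.
#' @param kind `"deletion"` or `"complex"`.
#' @param insideFrom,insideTo Gene symbols bounding (inclusively) the
#'   genes absent on the deletion allele; equal for single-gene
#'   deletions. For complex SVs these bound the region on the default
#'   haplotype.
#' @param hapAGenes,hapBGenes Complex SVs only: the genes unique to the
#'   default (A) and alternative (B) haplotype.
#' @param sourceDefault,sourceAlternative Names of the sequence sources
#'   providing the default and alternative segment.
#' @return A list of class `"svDefinition"`.
#' @export
svDefinition <- function(svId, kind = c("deletion", "complex"),
                         insideFrom, insideTo = insideFrom,
                         hapAGenes = character(0),
                         hapBGenes = character(0),
                         sourceDefault, sourceAlternative) {
  kind <- match.arg(kind)
  if (kind == "complex") {
    if (length(hapAGenes) == 0 || length(hapBGenes) == 0 ||
        length(intersect(hapAGenes, hapBGenes)))
      stop("complex SVs need disjoint, non-empty hapA/hapB gene sets")
  }
  structure(list(svId = as.integer(svId), kind = kind,
                 insideFrom = insideFrom, insideTo = insideTo,
                 hapAGenes = hapAGenes, hapBGenes = hapBGenes,
                 sourceDefault = sourceDefault,
                 sourceAlternative = sourceAlternative),
            class = "svDefinition")
}

#' The catalogue of 7 common IGH structural variants
#'
#' Six deletions and one complex variant, with the sequence sources used
#' when stitching a personalized reference (default = allele without
#' deletion): T2T-CHM13, GRCh37, GRCh38, a custom IGH reference, and the
#' assembled paternal haplotype of HG02148.
#'
#' @return List of [svDefinition] objects, indexed 1 to 7.
#' @export
ighSvCatalog <- function() {
  list(
    svDefinition(1, "deletion", "IGHD2-8", "IGHD3-3",
                 sourceDefault = "CHM13", sourceAlternative = "HG02148"),
    svDefinition(2, "deletion", "IGHV7-4-1",
                 sourceDefault = "CHM13", sourceAlternative = "GRCh37"),
    svDefinition(3, "complex", "IGHV1-8", "IGHV3-9",
                 hapAGenes = c("IGHV1-8", "IGHV3-9"),
                 hapBGenes = c("IGHV3-64D", "IGHV5-10-1"),
                 sourceDefault = "CHM13", sourceAlternative = "GRCh38"),
    svDefinition(4, "deletion", "IGHV3-23D",
                 sourceDefault = "Custom", sourceAlternative = "CHM13"),
    svDefinition(5, "deletion", "IGHV4-30-2", "IGHV3-33",
                 sourceDefault = "CHM13", sourceAlternative = "GRCh38"),
    svDefinition(6, "deletion", "IGHV4-38-2", "IGHV1-38-4",
                 sourceDefault = "Custom", sourceAlternative = "CHM13"),
    svDefinition(7, "deletion", "IGHV2-70D", "IGHV1-69D",
                 sourceDefault = "CHM13", sourceAlternative = "GRCh38")
  )
}

## Region of an SV on the locus: ranks of inside genes, flank genes
## (nearest annotated genes outside), and outer neighbors of the flanks.
.svRegion <- function(sv, locusMap) {
  order0 <- .locusGeneOrder(locusMap)
  from <- match(sv$insideFrom, order0)
  to <- match(sv$insideTo, order0)
  if (is.na(from) || is.na(to))
    stop(sprintf("SV %d genes not in the locus map", sv$svId))
  lo <- min(from, to); hi <- max(from, to)
  list(inside = order0[lo:hi],
       flanks = c(if (lo > 1) order0[lo - 1] else NA_character_,
                  if (hi < length(order0)) order0[hi + 1] else NA_character_),
       outer = c(if (lo > 2) order0[lo - 2] else NA_character_,
                 if (hi < length(order0) - 1) order0[hi + 2] else NA_character_))
}

#' Type SV alleles from a contig's gene content
#'
#' For deletion SVs: a contig supports the deletion (call
#' `"alternative"`) when it carries both genes flanking the deleted
#' region but none of the genes inside it; carrying any inside gene
#' makes the call `"default"`; anything else — including covering only
#' one flank — is `"unknown"`. For the complex SV the call follows
#' which haplotype's unique genes are present; none or both gives
#' `"unknown"`.
#'
#' @param profile A [ContigProfile] with duplicate names resolved.
#' @param svCatalog List of [svDefinition] (default [ighSvCatalog]).
#' @param locusMap [LocusMap] used to resolve inside/flank gene sets.
#' @return `data.frame`: `contig`, `svId`, `call`.
#' @export
typeSvAlleles <- function(profile, svCatalog = ighSvCatalog(), locusMap) {
  present <- unique(contigHits(profile)$gene)
  calls <- vapply(svCatalog, function(sv) {
    if (sv$kind == "complex") {
      a <- any(sv$hapAGenes %in% present)
      b <- any(sv$hapBGenes %in% present)
      if (a && !b) "default" else if (b && !a) "alternative" else "unknown"
    } else {
      rg <- .svRegion(sv, locusMap)
      insideHit <- any(rg$inside %in% present)
      flanksHit <- !anyNA(rg$flanks) && all(rg$flanks %in% present)
      if (insideHit) "default"
      else if (flanksHit) "alternative"
      else "unknown"
    }
  }, character(1))
  data.frame(contig = contigName(profile),
             svId = vapply(svCatalog, `[[`, integer(1), "svId"),
             call = calls, stringsAsFactors = FALSE)
}

#' Consolidate per-contig SV calls within a parental group
#'
#' `"unknown"` calls are compatible with anything; a `"default"` and an
#' `"alternative"` call on the same SV from two contigs of the same
#' group is a conflict.
#'
#' @param calls `data.frame` of [typeSvAlleles] rows for the group's
#'   contigs.
#' @return List with `calls` (`data.frame`: `svId`, `call`, `conflict`)
#'   and `conflict` (any SV conflicted).
#' @export
consolidateCalls <- function(calls) {
  if (nrow(calls) == 0)
    return(list(calls = data.frame(svId = integer(0),
                                   call = character(0),
                                   conflict = logical(0)),
                conflict = FALSE))
  out <- do.call(rbind, lapply(split(calls, calls$svId), function(grp) {
    known <- unique(grp$call[grp$call != "unknown"])
    if (length(known) == 0)
      data.frame(svId = grp$svId[1], call = "unknown", conflict = FALSE)
    else if (length(known) == 1)
      data.frame(svId = grp$svId[1], call = known, conflict = FALSE)
    else
      data.frame(svId = grp$svId[1], call = NA_character_, conflict = TRUE)
  }))
  out <- out[order(out$svId), , drop = FALSE]
  rownames(out) <- NULL
  list(calls = out, conflict = any(out$conflict))
}

#' Reconcile parental contig groups by moving conflicted contigs
#'
#' When a parental group carries internally conflicting SV calls
#' (usually a mis-binned contig), tries moving one contig at a time to
#' the other group — contigs tried in name order — and accepts the
#' first assignment in which neither group conflicts. If no single move
#' resolves the conflicts, manual reconciliation is requested.
#'
#' @param calls Combined [typeSvAlleles] table for all contigs.
#' @param groups Named list of two character vectors: contig names per
#'   parental group.
#' @return List with `groups` (possibly updated), `status` (`"ok"`,
#'   `"reconciled"`, `"manual_required"`), `moved` (contig moved, or
#'   `character(0)` if none), and `consolidated` (per-group [consolidateCalls] results).
#' @export
reconcileHaplotypes <- function(calls, groups) {
  stopifnot(length(groups) == 2, !is.null(names(groups)))
  consolidate <- function(gr) {
    lapply(gr, function(ctgs)
      consolidateCalls(calls[calls$contig %in% ctgs, , drop = FALSE]))
  }
  ok <- function(cons) !any(vapply(cons, `[[`, logical(1), "conflict"))
  cons <- consolidate(groups)
  if (ok(cons))
    return(list(groups = groups, status = "ok", moved = character(0),
                consolidated = cons))
  for (ctg in sort(unique(unlist(groups)))) {
    from <- names(groups)[vapply(groups, function(g) ctg %in% g, logical(1))]
    to <- setdiff(names(groups), from)
    trial <- groups
    trial[[from]] <- setdiff(trial[[from]], ctg)
    trial[[to]] <- sort(c(trial[[to]], ctg))
    consT <- consolidate(trial)
    if (ok(consT))
      return(list(groups = trial, status = "reconciled", moved = ctg,
                  consolidated = consT))
  }
  list(groups = groups, status = "manual_required", moved = character(0),
       consolidated = cons)
}

#' Read a segment registry
#'
#' The registry is a JSON file naming a FASTA of sequence segments, the
#' backbone record, and one record per (SV, allele) pair:
#' `{"fasta": "...", "backbone": "recordName", "segments":
#' [{"sv": 1, "allele": "alternative", "record": "..."}]}`. Relative
#' FASTA paths resolve against the registry file's directory.
#'
#' @param path Path to the registry JSON.
#' @return List with `sequences` ([Biostrings::DNAStringSet]),
#'   `backbone` (record name) and `segments` (`data.frame`: `sv`,
#'   `allele`, `record`).
#' @export
readSegmentRegistry <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  fa <- cfg$fasta
  if (!file.exists(fa)) fa <- file.path(dirname(path), cfg$fasta)
  seqs <- readDNAStringSet(fa)
  if (!cfg$backbone %in% names(seqs))
    stop("registry backbone record '", cfg$backbone, "' not in FASTA")
  seg <- as.data.frame(cfg$segments, stringsAsFactors = FALSE)
  miss <- setdiff(seg$record, names(seqs))
  if (length(miss))
    stop("registry record(s) missing from FASTA: ",
         paste(miss, collapse = ", "))
  list(sequences = seqs, backbone = cfg$backbone, segments = seg)
}

.registrySegment <- function(registry, svId, allele) {
  seg <- registry$segments
  i <- which(seg$sv == svId & seg$allele == allele)
  if (length(i) != 1)
    stop(sprintf("registry has no segment for SV %d allele '%s'",
                 svId, allele))
  list(name = seg$record[i], seq = registry$sequences[[seg$record[i]]])
}

#' Stitch a personalized guide reference
#'
#' Copies the backbone and, for every SV whose consolidated call is
#' `"alternative"`, replaces the SV span with the registered alternative
#' segment. The replaced span is extended to include the flanking genes:
#' each junction is placed at the midpoint between an SV flank gene and
#' its nearest neighbor outside the SV, for determinism. `"unknown"`
#' calls keep the default (backbone) source.
#'
#' @param callsPerHaplotype Named list (by haplotype) of consolidated
#'   call tables (`svId`, `call`).
#' @param registry Segment registry ([readSegmentRegistry] layout); the
#'   backbone record must be the reference the `locusMap` describes.
#' @param svCatalog List of [svDefinition].
#' @param locusMap [LocusMap] on the backbone.
#' @return A [PersonalReference].
#' @export
buildPersonalReference <- function(callsPerHaplotype, registry,
                                   svCatalog = ighSvCatalog(), locusMap) {
  backbone <- registry$sequences[[registry$backbone]]
  g <- locusGenes(locusMap)
  geneIv <- function(nm) {
    i <- match(nm, mcols(g)$gene)
    if (is.na(i)) stop("gene '", nm, "' not in the locus map")
    c(start(g)[i], end(g)[i])
  }
  bySv <- setNames(svCatalog,
                   vapply(svCatalog, `[[`, integer(1), "svId"))
  outSeq <- list(); prov <- list(); callRows <- list()
  for (hap in names(callsPerHaplotype)) {
    calls <- callsPerHaplotype[[hap]]
    repl <- list()
    for (i in seq_len(nrow(calls))) {
      if (is.na(calls$call[i]) || calls$call[i] != "alternative") next
      sv <- bySv[[as.character(calls$svId[i])]]
      rg <- .svRegion(sv, locusMap)
      if (anyNA(rg$flanks) || anyNA(rg$outer))
        stop(sprintf("SV %d lacks outer neighbors for junction placement",
                     sv$svId))
      ivs <- lapply(c(rg$outer[1], rg$flanks, rg$outer[2]), geneIv)
      lo <- sort(c(ivs[[1]], ivs[[2]]))   # outer-left, flank-left
      hi <- sort(c(ivs[[3]], ivs[[4]]))   # flank-right, outer-right
      bbStart <- (lo[2] + lo[3]) %/% 2 + 1L   # midpoint of the gap
      bbEnd <- (hi[2] + hi[3]) %/% 2
      seg <- .registrySegment(registry, sv$svId, "alternative")
      repl[[length(repl) + 1L]] <-
        list(start = bbStart, end = bbEnd, seq = seg$seq,
             source = sv$sourceAlternative, record = seg$name)
    }
    if (length(repl) > 1) {
      ord <- order(vapply(repl, `[[`, numeric(1), "start"))
      repl <- repl[ord]
      ends <- vapply(repl, `[[`, numeric(1), "end")
      starts <- vapply(repl, `[[`, numeric(1), "start")
      if (any(starts[-1] <= ends[-length(ends)]))
        stop("alternative SV spans overlap on the backbone")
    }
    pieces <- list(); rows <- list(); at <- 1L; outAt <- 0L
    emit <- function(seq, source) {
      if (length(seq) == 0) return(invisible())
      pieces[[length(pieces) + 1L]] <<- seq
      rows[[length(rows) + 1L]] <<- data.frame(
        haplotype = hap, start = outAt + 1L, end = outAt + length(seq),
        source = source, stringsAsFactors = FALSE)
      outAt <<- outAt + length(seq)
    }
    for (r in repl) {
      if (r$start > at)
        emit(subseq(backbone, at, r$start - 1L), registry$backbone)
      emit(r$seq, r$record)
      at <- r$end + 1L
    }
    if (at <= length(backbone))
      emit(subseq(backbone, at, length(backbone)), registry$backbone)
    outSeq[[hap]] <- do.call(xscat, pieces)
    prov[[hap]] <- do.call(rbind, rows)
    cr <- calls
    cr$haplotype <- hap
    callRows[[hap]] <- cr
  }
  seqs <- do.call(DNAStringSet, list(outSeq))
  new("PersonalReference", sequences = seqs,
      provenance = do.call(rbind, c(prov, list(make.row.names = FALSE))),
      calls = do.call(rbind, c(callRows, list(make.row.names = FALSE))))
}

#' @rdname accessors
#' @export
setGeneric("svCalls", function(x) standardGeneric("svCalls"))
#' @rdname accessors
#' @export
setMethod("svCalls", "PersonalReference", function(x) x@calls)

#' Mask assembly regions without read or contig support
#'
#' Positions covered by neither the read alignments nor the de novo
#' contig alignments are replaced by `N` (lengths preserved); assembly
#' records with no contig support at all are dropped entirely. Coverage
#' counts secondary alignments and spans in-read deletions. The
#' operation is idempotent.
#'
#' @param assembly Named [Biostrings::DNAStringSet] (or FASTA path).
#' @param readAlignments SAM/BAM path or [readAlignments] `data.frame`
#'   of reads on this assembly.
#' @param contigAlignments Same, for the de novo contigs.
#' @return A [MaskedAssembly].
#' @export
maskUnsupported <- function(assembly, readAlignments, contigAlignments) {
  assembly <- .readFastaOrSet(assembly)
  loadAln <- function(x) {
    if (is.character(x)) x <- readAlignments(x, includeSecondary = TRUE)
    x
  }
  rAln <- loadAln(readAlignments)
  cAln <- loadAln(contigAlignments)
  bad <- setdiff(unique(c(rAln$rname, cAln$rname)), names(assembly))
  if (length(bad))
    stop("alignments reference records absent from the assembly: ",
         paste(bad, collapse = ", "))
  covRanges <- function(aln, rec) {
    sub <- aln[aln$rname == rec, , drop = FALSE]
    if (nrow(sub) == 0) return(IRanges())
    IRanges::reduce(do.call(c, lapply(seq_len(nrow(sub)), function(i)
      .coveredRefRanges(sub$pos[i], sub$cigar[i]))))
  }
  outSeq <- list()
  log <- data.frame(contig = character(0), start = integer(0),
                    end = integer(0), reason = character(0),
                    stringsAsFactors = FALSE)
  for (rec in names(assembly)) {
    len <- length(assembly[[rec]])
    contigCov <- covRanges(cAln, rec)
    if (length(contigCov) == 0) {
      log <- rbind(log, data.frame(contig = rec, start = 1L, end = len,
                                   reason = "dropped_no_contig_support",
                                   stringsAsFactors = FALSE))
      next
    }
    readCov <- covRanges(rAln, rec)
    support <- IRanges::reduce(c(contigCov, readCov))
    support <- restrict(support, 1L, len)
    unsupported <- gaps(support, start = 1L, end = len)
    seq <- assembly[[rec]]
    for (i in seq_along(unsupported)) {
      st <- start(unsupported)[i]; en <- end(unsupported)[i]
      subseq(seq, st, en) <- DNAString(paste(rep("N", en - st + 1L),
                                             collapse = ""))
      log <- rbind(log, data.frame(contig = rec, start = st, end = en,
                                   reason = "masked_no_support",
                                   stringsAsFactors = FALSE))
    }
    outSeq[[rec]] <- seq
  }
  new("MaskedAssembly", sequences = do.call(DNAStringSet, list(outSeq)),
      maskLog = log)
}
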