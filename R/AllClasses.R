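#' Class "LocusMap": the IGH locus coordinate model
#'
#' A `LocusMap` holds the ordered gene annotation of one IGH locus on one
#' named reference sequence, together with the recombination signal
#' sequence (RSS) anchor model and the J--D span used to select reads for
#' recombination profiling.
#'
#' Genes are stored as a [GenomicRanges::GRanges] (1-based, closed
#' intervals) with metadata columns `gene` (symbol), `class` (one of
#' `"V"`, `"D"`, `"J"`, `"C"`), `functionality` (`"functional"`, `"ORF"`,
#' `"pseudogene"`) and `rssSides` (comma-separated subset of
#' `"upstream"`/`"downstream"`).
#'
#' Side vocabulary is gene-transcriptional: `"upstream"` is the 5' side of
#' a gene, `"downstream"` the 3' side. All IGH genes are transcribed in
#' the same direction, so with `orientation = "jfirst"` (J genes at low
#' coordinates, V genes at high coordinates, as in the built-in toy locus)
#' the upstream/5' anchor of a gene sits at its high-coordinate boundary
#' and the downstream/3' anchor at its low-coordinate boundary; with
#' `orientation = "vfirst"` the mapping is mirrored. Recombining sides
#' are: J genes upstream (facing the D locus), D genes both, V genes
#' downstream (facing the D locus).
#'
#' @slot reference Name of the reference sequence the map lives on.
#' @slot genes `GRanges` of gene bodies, sorted by coordinate.
#' @slot jdInterval `IRanges` spanning from the outermost J gene to the
#'   outermost D gene (closed span).
#' @slot orientation `"jfirst"` or `"vfirst"`: which coordinate direction
#'   corresponds to the J -> D -> V gene order.
#' @exportClass LocusMap
setClass("LocusMap",
  representation(
    reference = "character",
    genes = "GRanges",
    jdInterval = "IRanges",
    orientation = "character"
  )
)

setValidity("LocusMap", function(object) {
  msg <- character(0)
  g <- object@genes
  need <- c("gene", "class", "functionality", "rssSides")
  if (!all(need %in% colnames(mcols(g))))
    return(paste("genes must carry metadata columns:",
                 paste(need, collapse = ", ")))
  if (!object@orientation %in% c("jfirst", "vfirst"))
    msg <- c(msg, "orientation must be 'jfirst' or 'vfirst'")
  if (length(g)) {
    if (is.unsorted(start(g)))
      msg <- c(msg, "genes must be sorted by coordinate")
    if (!all(mcols(g)$class %in% c("V", "D", "J", "C")))
      msg <- c(msg, "gene class must be one of V, D, J, C")
    dlen <- width(g)[mcols(g)$class == "D"]
    if (any(dlen > 40))
      msg <- c(msg, "D gene bodies must not exceed 40 bp")
    recomb <- mcols(g)$class %in% c("V", "D", "J")
    if (length(object@jdInterval) == 1 && any(recomb)) {
      jd <- object@jdInterval
      vs <- g[mcols(g)$class == "V"]
      if (length(vs) && any(start(vs) <= end(jd) & end(vs) >= start(jd)))
        msg <- c(msg, "jdInterval must not contain V genes")
      jds <- g[mcols(g)$class %in% c("J", "D")]
      if (length(jds) &&
          !all(start(jds) >= start(jd) & end(jds) <= end(jd)))
        msg <- c(msg, "jdInterval must contain all J and D genes")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Class "ReferenceSet": registry of references with locus maps
#'
#' Bundles one or more (reference sequence, [LocusMap]) pairs with a fixed
#' priority order used as the final tie-break when choosing which
#' reference best explains a read.
#'
#' @slot maps Named list of [LocusMap] objects, one per reference.
#' @slot sequences Named [Biostrings::DNAStringSet] of reference
#'   sequences (may be empty when sequence access is not needed).
#' @slot priority Character permutation of `names(maps)`.
#' @exportClass ReferenceSet
setClass("ReferenceSet",
  representation(
    maps = "list",
    sequences = "DNAStringSet",
    priority = "character"
  )
)

setValidity("ReferenceSet", function(object) {
  nm <- names(object@maps)
  if (is.null(nm) || anyDuplicated(nm))
    return("maps must be uniquely named by reference")
  if (!all(vapply(object@maps, is, logical(1), "LocusMap")))
    return("maps must all be LocusMap objects")
  if (!setequal(object@priority, nm) || length(object@priority) != length(nm))
    return("priority must be a permutation of reference names")
  TRUE
})

#' Class "ReadEvidence": one read's recombination evidence
#'
#' The per-read result of the profiler on its chosen reference: aligned
#' segments in original-read orientation, junctions (breakend pairs with
#' RSS matches), the event classification, and the genes used.
#'
#' @slot readId Read identifier.
#' @slot reference Chosen reference name.
#' @slot segments `data.frame` of aligned segments (columns `readStart`,
#'   `readEnd`, `refStart`, `refEnd`, `orientation`, `cigar`).
#' @slot junctions `data.frame` of junctions (see [junctionsFromSegments]).
#' @slot eventClass One of `"unrecombined"`, `"complete_VDJ"`,
#'   `"DJ_only"`, `"VD_only"`, `"multiple_D"`, `"inversion_DJ"`,
#'   `"inversion_DD"`, `"inversion_VD"`, `"complex"`.
#' @slot genesUsed `data.frame` with columns `gene`, `side`, ordered by
#'   locus position.
#' @slot confident Logical: all junction breakends RSS-confident.
#' @exportClass ReadEvidence
setClass("ReadEvidence",
  representation(
    readId = "character",
    reference = "character",
    segments = "data.frame",
    junctions = "data.frame",
    eventClass = "character",
    genesUsed = "data.frame",
    confident = "logical"
  )
)

.eventClasses <- c("unrecombined", "complete_VDJ", "DJ_only", "VD_only",
                   "multiple_D", "inversion_DJ", "inversion_DD",
                   "inversion_VD", "complex")

setValidity("ReadEvidence", function(object) {
  if (!object@eventClass %in% .eventClasses)
    return(paste("eventClass must be one of:",
                 paste(.eventClasses, collapse = ", ")))
  if (object@eventClass == "unrecombined" && nrow(object@junctions) > 0)
    return("unrecombined evidence must have no junctions")
  TRUE
})

#' Class "ClonalityReport": Simpson's index summary of a sample
#'
#' @slot si Simpson's index of the distinct-event read counts, or `NA`
#'   when no recombination-bearing reads were observed.
#' @slot nTotal Total recombination-bearing reads (the N of the index).
#' @slot nDistinct Number of distinct events.
#' @slot label `"monoclonal"`, `"intermediate"`, `"polyclonal"` or `NA`.
#' @slot thresholds Named numeric: `mono` and `poly` cut-offs.
#' @exportClass ClonalityReport
setClass("ClonalityReport",
  representation(
    si = "numeric",
    nTotal = "integer",
    nDistinct = "integer",
    label = "character",
    thresholds = "numeric"
  )
)

setValidity("ClonalityReport", function(object) {
  if (!all(c("mono", "poly") %in% names(object@thresholds)))
    return("thresholds must be named 'mono' and 'poly'")
  if (!is.na(object@si) && (object@si <= 0 || object@si > 1))
    return("si must lie in (0, 1]")
  TRUE
})

#' Class "ContigProfile": annotated IGH gene content of one contig
#'
#' @slot contig Contig name.
#' @slot hits `data.frame` of kept gene hits, sorted by contig
#'   coordinate (columns `gene`, `allele`, `class`, `functionality`,
#'   `start`, `end`, `strand`, `mismatches`, `locusRank`).
#' @slot orientation `"+"` if the contig runs in locus orientation,
#'   `"-"` otherwise (majority strand of its hits).
#' @slot locusRankRange Range of locus ranks covered (median-projected).
#' @exportClass ContigProfile
setClass("ContigProfile",
  representation(
    contig = "character",
    hits = "data.frame",
    orientation = "character",
    locusRankRange = "numeric"
  )
)

#' Class "AssemblyReport": per-haplotype summary of an IGH assembly
#'
#' @slot summary `data.frame` with one row per haplotype: `haplotype`,
#'   `nContigs`, `nV` (functional/ORF V genes only), `nD`, `nJ`.
#' @slot presence Named list (by haplotype) of character vectors: the
#'   deduplicated gene presence set (each gene counted once per
#'   haplotype, including on duplicated sequence).
#' @slot junctions `data.frame` of V(D)J junction calls across all
#'   contigs, with a `haplotype` column.
#' @slot breakpoints `data.frame` of inter-contig breakpoint calls,
#'   with a `haplotype` column.
#' @exportClass AssemblyReport
setClass("AssemblyReport",
  representation(
    summary = "data.frame",
    presence = "list",
    junctions = "data.frame",
    breakpoints = "data.frame"
  )
)

setValidity("AssemblyReport", function(object) {
  if (!setequal(names(object@presence), object@summary$haplotype))
    return("presence must be named by the haplotypes in summary")
  if (any(vapply(object@presence, anyDuplicated, integer(1)) > 0))
    return("presence sets must be deduplicated")
  TRUE
})

#' Class "PersonalReference": stitched per-haplotype guide reference
#'
#' @slot sequences [Biostrings::DNAStringSet], one record per haplotype.
#' @slot provenance `data.frame` with columns `haplotype`, `start`,
#'   `end`, `source`: which source segment produced each span. Provenance
#'   tiles each haplotype sequence exactly.
#' @slot calls `data.frame` of the consolidated SV allele calls used.
#' @exportClass PersonalReference
setClass("PersonalReference",
  representation(
    sequences = "DNAStringSet",
    provenance = "data.frame",
    calls = "data.frame"
  )
)

setValidity("PersonalReference", function(object) {
  pv <- object@provenance
  for (h in names(object@sequences)) {
    p <- pv[pv$haplotype == h, , drop = FALSE]
    p <- p[order(p$start), , drop = FALSE]
    len <- length(object@sequences[[h]])
    if (nrow(p) == 0 || p$start[1] != 1 || p$end[nrow(p)] != len ||
        (nrow(p) > 1 && any(p$start[-1] != p$end[-nrow(p)] + 1)))
      return(sprintf("provenance does not tile haplotype '%s'", h))
  }
  TRUE
})

#' Class "MaskedAssembly": assembly with unsupported regions masked
#'
#' @slot sequences [Biostrings::DNAStringSet] with unsupported positions
#'   replaced by `N`; retained records keep their input length.
#' @slot maskLog `data.frame` with columns `contig`, `start`, `end`,
#'   `reason` for every masked interval and dropped contig.
#' @exportClass MaskedAssembly
setClass("MaskedAssembly",
  representation(
    sequences = "DNAStringSet",
    maskLog = "data.frame"
  )
)
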