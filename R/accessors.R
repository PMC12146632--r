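#' Accessors for IGHvdj classes
#'
#' Small accessor generics so downstream code never touches slots
#' directly.
#'
#' @param x An IGHvdj object.
#' @return The corresponding component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("locusGenes", function(x) standardGeneric("locusGenes"))
#' @rdname accessors
#' @export
setMethod("locusGenes", "LocusMap", function(x) x@genes)

#' @rdname accessors
#' @export
setGeneric("referenceName", function(x) standardGeneric("referenceName"))
#' @rdname accessors
#' @export
setMethod("referenceName", "LocusMap", function(x) x@reference)

#' @rdname accessors
#' @export
setGeneric("jdInterval", function(x) standardGeneric("jdInterval"))
#' @rdname accessors
#' @export
setMethod("jdInterval", "LocusMap", function(x) x@jdInterval)

#' @rdname accessors
#' @export
setGeneric("locusOrientation", function(x) standardGeneric("locusOrientation"))
#' @rdname accessors
#' @export
setMethod("locusOrientation", "LocusMap", function(x) x@orientation)

#' @rdname accessors
#' @export
setGeneric("locusMaps", function(x) standardGeneric("locusMaps"))
#' @rdname accessors
#' @export
setMethod("locusMaps", "ReferenceSet", function(x) x@maps)

#' @rdname accessors
#' @export
setGeneric("referencePriority", function(x) standardGeneric("referencePriority"))
#' @rdname accessors
#' @export
setMethod("referencePriority", "ReferenceSet", function(x) x@priority)

#' @rdname accessors
#' @export
setGeneric("referenceSequences", function(x) standardGeneric("referenceSequences"))
#' @rdname accessors
#' @export
setMethod("referenceSequences", "ReferenceSet", function(x) x@sequences)

#' @rdname accessors
#' @export
setGeneric("readId", function(x) standardGeneric("readId"))
#' @rdname accessors
#' @export
setMethod("readId", "ReadEvidence", function(x) x@readId)

#' @rdname accessors
#' @export
setGeneric("eventClass", function(x) standardGeneric("eventClass"))
#' @rdname accessors
#' @export
setMethod("eventClass", "ReadEvidence", function(x) x@eventClass)

#' @rdname accessors
#' @export
setGeneric("genesUsed", function(x) standardGeneric("genesUsed"))
#' @rdname accessors
#' @export
setMethod("genesUsed", "ReadEvidence", function(x) x@genesUsed)

#' @rdname accessors
#' @export
setGeneric("readSegments", function(x) standardGeneric("readSegments"))
#' @rdname accessors
#' @export
setMethod("readSegments", "ReadEvidence", function(x) x@segments)

#' @rdname accessors
#' @export
setGeneric("readJunctions", function(x) standardGeneric("readJunctions"))
#' @rdname accessors
#' @export
setMethod("readJunctions", "ReadEvidence", function(x) x@junctions)

#' @rdname accessors
#' @export
setGeneric("isConfident", function(x) standardGeneric("isConfident"))
#' @rdname accessors
#' @export
setMethod("isConfident", "ReadEvidence", function(x) x@confident)

#' @rdname accessors
#' @export
setMethod("referenceName", "ReadEvidence", function(x) x@reference)

#' @rdname accessors
#' @export
setGeneric("simpsonValue", function(x) standardGeneric("simpsonValue"))
#' @rdname accessors
#' @export
setMethod("simpsonValue", "ClonalityReport", function(x) x@si)

#' @rdname accessors
#' @export
setGeneric("clonalityLabel", function(x) standardGeneric("clonalityLabel"))
#' @rdname accessors
#' @export
setMethod("clonalityLabel", "ClonalityReport", function(x) x@label)

#' @rdname accessors
#' @export
setGeneric("contigHits", function(x) standardGeneric("contigHits"))
#' @rdname accessors
#' @export
setMethod("contigHits", "ContigProfile", function(x) x@hits)

#' @rdname accessors
#' @export
setGeneric("contigName", function(x) standardGeneric("contigName"))
#' @rdname accessors
#' @export
setMethod("contigName", "ContigProfile", function(x) x@contig)

#' @rdname accessors
#' @export
setGeneric("assemblySummary", function(x) standardGeneric("assemblySummary"))
#' @rdname accessors
#' @export
setMethod("assemblySummary", "AssemblyReport", function(x) x@summary)

#' @rdname accessors
#' @export
setGeneric("genePresence", function(x) standardGeneric("genePresence"))
#' @rdname accessors
#' @export
setMethod("genePresence", "AssemblyReport", function(x) x@presence)

#' @rdname accessors
#' @export
setGeneric("assemblyJunctions", function(x) standardGeneric("assemblyJunctions"))
#' @rdname accessors
#' @export
setMethod("assemblyJunctions", "AssemblyReport", function(x) x@junctions)

#' @rdname accessors
#' @export
setGeneric("assemblyBreakpoints", function(x) standardGeneric("assemblyBreakpoints"))
#' @rdname accessors
#' @export
setMethod("assemblyBreakpoints", "AssemblyReport", function(x) x@breakpoints)

#' @rdname accessors
#' @export
setGeneric("haplotypeSequences", function(x) standardGeneric("haplotypeSequences"))
#' @rdname accessors
#' @export
setMethod("haplotypeSequences", "PersonalReference", function(x) x@sequences)
#' @rdname accessors
#' @export
setMethod("haplotypeSequences", "MaskedAssembly", function(x) x@sequences)

#' @rdname accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))
#' @rdname accessors
#' @export
setMethod("provenance", "PersonalReference", function(x) x@provenance)

#' @rdname accessors
#' @export
setGeneric("maskLog", function(x) standardGeneric("maskLog"))
#' @rdname accessors
#' @export
setMethod("maskLog", "MaskedAssembly", function(x) x@maskLog)

setMethod("show", "LocusMap", function(object) {
  g <- object@genes
  tab <- table(factor(mcols(g)$class, levels = c("J", "D", "V", "C")))
  cat("LocusMap on '", object@reference, "' (", object@orientation,
      "): ", length(g), " genes (",
      paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
      ")\n", sep = "")
  if (length(object@jdInterval))
    cat("  J-D span: ", start(object@jdInterval), "-",
        end(object@jdInterval), "\n", sep = "")
})

setMethod("show", "ReferenceSet", function(object) {
  cat("ReferenceSet with", length(object@maps), "reference(s); priority:",
      paste(object@priority, collapse = " > "), "\n")
})

setMethod("show", "ReadEvidence", function(object) {
  cat("ReadEvidence '", object@readId, "' on '", object@reference,
      "': ", object@eventClass,
      if (isTRUE(object@confident)) " (confident)" else "",
      "\n", sep = "")
  if (nrow(object@genesUsed))
    cat("  genes used:",
        paste(sprintf("%s[%s]", object@genesUsed$gene, object@genesUsed$side),
              collapse = ", "), "\n")
  cat("  ", nrow(object@segments), " segment(s), ",
      nrow(object@junctions), " junction(s)\n", sep = "")
})

setMethod("show", "ClonalityReport", function(object) {
  cat("ClonalityReport: SI =",
      if (is.na(object@si)) "NA" else format(object@si, digits = 4),
      "->", object@label, "\n")
  cat("  N =", object@nTotal, "reads in", object@nDistinct,
      "distinct event(s); thresholds mono >",
      object@thresholds[["mono"]], ", poly <",
      object@thresholds[["poly"]], "\n")
})

setMethod("show", "ContigProfile", function(object) {
  cat("ContigProfile '", object@contig, "' (", object@orientation, "): ",
      nrow(object@hits), " gene hit(s)\n", sep = "")
})

setMethod("show", "AssemblyReport", function(object) {
  cat("AssemblyReport over", nrow(object@summary), "haplotype(s):\n")
  for (i in seq_len(nrow(object@summary))) {
    s <- object@summary[i, ]
    cat("  ", s$haplotype, ": ", s$nContigs, " contig(s); V=", s$nV,
        " D=", s$nD, " J=", s$nJ, "\n", sep = "")
  }
  cat("  ", nrow(object@junctions), " V(D)J junction call(s), ",
      nrow(object@breakpoints), " breakpoint call(s)\n", sep = "")
})

setMethod("show", "PersonalReference", function(object) {
  cat("PersonalReference with", length(object@sequences),
      "haplotype(s):\n")
  for (h in names(object@sequences))
    cat("  ", h, ": ", length(object@sequences[[h]]), " bp, ",
        sum(object@provenance$haplotype == h), " provenance span(s)\n",
        sep = "")
})

setMethod("show", "MaskedAssembly", function(object) {
  cat("MaskedAssembly with", length(object@sequences), "record(s),",
      nrow(object@maskLog), "mask log entr(ies)\n")
})
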