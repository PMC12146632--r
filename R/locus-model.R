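#' Build a LocusMap from a gene annotation table
#'
#' Constructs the locus coordinate model from a per-gene annotation.
#' Intervals are 1-based closed; use [loadLocusMap] for BED-like
#' (0-based half-open) files.
#'
#' @param genes `data.frame` with columns `reference`, `start`, `end`
#'   (1-based closed), `gene`, `class`, `functionality`, `strand`,
#'   `rssSides` (comma-separated subset of `upstream`,`downstream`).
#' @param reference Reference name; must match the `reference` column.
#' @param orientation `"jfirst"` (J genes at low coordinates) or
#'   `"vfirst"`.
#' @return A [LocusMap].
#' @export
makeLocusMap <- function(genes, reference, orientation = "jfirst") {
  need <- c("reference", "start", "end", "gene", "class", "functionality",
            "strand", "rssSides")
  miss <- setdiff(need, colnames(genes))
  if (length(miss))
    stop("annotation is missing required column(s): ",
         paste(miss, collapse = ", "))
  genes <- genes[genes$reference == reference, , drop = FALSE]
  if (nrow(genes) == 0)
    stop("no annotation rows for reference '", reference, "'")
  bad <- which(!(genes$start <= genes$end) | is.na(genes$start) |
                 is.na(genes$end))
  if (length(bad))
    stop("malformed interval at annotation row(s): ",
         paste(bad, collapse = ", "))
  dup <- genes$gene[duplicated(paste(genes$gene, genes$start))]
  o <- order(genes$start, genes$end)
  genes <- genes[o, , drop = FALSE]
  gr <- GRanges(reference, IRanges(genes$start, genes$end),
                strand = genes$strand)
  mcols(gr)$gene <- genes$gene
  mcols(gr)$class <- genes$class
  mcols(gr)$functionality <- genes$functionality
  mcols(gr)$rssSides <- genes$rssSides
  jd <- mcols(gr)$class %in% c("J", "D")
  jdIv <- if (any(jd)) {
    IRanges(min(start(gr)[jd]), max(end(gr)[jd]))
  } else IRanges()
  new("LocusMap", reference = reference, genes = gr,
      jdInterval = jdIv, orientation = orientation)
}

#' Read a locus annotation file
#'
#' Parses a BED-like tab-separated annotation (0-based half-open
#' intervals, header line required, `#` comment lines allowed) into a
#' [LocusMap]. Required columns: `reference`, `start`, `end`, `gene`,
#' `class`, `functionality`, `strand`, `rss_sides`.
#'
#' @param path Path to the TSV file.
#' @param reference Reference name to extract.
#' @param orientation Locus orientation, see [makeLocusMap].
#' @return A [LocusMap].
#' @export
loadLocusMap <- function(path, reference, orientation = "jfirst") {
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("reference", "start", "end", "gene", "class", "functionality",
            "strand", "rss_sides")
  miss <- setdiff(need, colnames(tab))
  if (length(miss))
    stop("annotation file is missing required column(s): ",
         paste(miss, collapse = ", "))
  bad <- which(!is.finite(tab$start) | !is.finite(tab$end) |
                 tab$start >= tab$end)
  if (length(bad))
    stop("malformed annotation row(s): ", paste(bad, collapse = ", "))
  tab$start <- tab$start + 1L  # BED-like -> 1-based closed
  tab$rssSides <- tab$rss_sides
  makeLocusMap(tab, reference, orientation)
}

#' Write a locus annotation file
#'
#' Inverse of [loadLocusMap]: writes the BED-like 0-based half-open TSV
#' dialect.
#'
#' @param locusMap A [LocusMap].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeLocusMap <- function(locusMap, path) {
  g <- locusGenes(locusMap)
  tab <- data.frame(
    reference = as.character(seqnames(g)),
    start = start(g) - 1L,
    end = end(g),
    gene = mcols(g)$gene,
    class = mcols(g)$class,
    functionality = mcols(g)$functionality,
    strand = as.character(BiocGenerics::strand(g)),
    rss_sides = mcols(g)$rssSides,
    stringsAsFactors = FALSE
  )
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' RSS anchor table of a locus
#'
#' Expands the per-gene `rssSides` annotation into one row per RSS
#' anchor. Anchor positions are single reference coordinates at the gene
#' boundary on the stated side: in a `"jfirst"` locus the upstream (5')
#' anchor of a gene is its `end` coordinate and the downstream (3')
#' anchor its `start`; mirrored for `"vfirst"`.
#'
#' @param locusMap A [LocusMap].
#' @return `data.frame` with columns `gene`, `class`, `side`,
#'   `position`, `locusRank` (rank of the gene along J -> D -> V order).
#' @export
rssAnchors <- function(locusMap) {
  g <- locusGenes(locusMap)
  jfirst <- locusOrientation(locusMap) == "jfirst"
  rank0 <- if (jfirst) seq_along(g) else rev(seq_along(g))
  m <- mcols(g)
  sidesList <- strsplit(as.character(m$rssSides), ",", fixed = TRUE)
  sidesList <- lapply(sidesList, function(s) s[nzchar(s)])
  nSides <- lengths(sidesList)
  i <- rep.int(seq_along(g), nSides)
  side <- unlist(sidesList, use.names = FALSE)
  if (!length(i))
    return(data.frame(gene = character(0), class = character(0),
                      side = character(0), position = integer(0),
                      locusRank = integer(0)))
  pos <- ifelse((side == "upstream") == jfirst,
                end(g)[i], start(g)[i])
  out <- data.frame(gene = as.character(m$gene)[i],
                    class = as.character(m$class)[i],
                    side = side, position = as.integer(pos),
                    locusRank = rank0[i],
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$locusRank, out$position), , drop = FALSE]
}

#' Nearest RSS anchor to a position
#'
#' Returns the RSS anchor minimising the absolute distance to `position`
#' if that minimum is at most `maxDist` (inclusive), otherwise `NULL`.
#' Ties are broken by locus order, J-proximal anchor first.
#'
#' @param locusMap A [LocusMap].
#' @param position Reference coordinate (1-based).
#' @param maxDist Maximum distance in bp (default 50, inclusive).
#' @param anchors Precomputed [rssAnchors] table for `locusMap`; pass it
#'   when calling repeatedly to avoid recomputation.
#' @return `NULL`, or a one-row `data.frame` with the anchor columns of
#'   [rssAnchors] plus `distance`.
#' @export
nearestRss <- function(locusMap, position, maxDist = 50,
                       anchors = rssAnchors(locusMap)) {
  stopifnot(maxDist >= 0)
  if (nrow(anchors) == 0) return(NULL)
  d <- abs(anchors$position - position)
  dmin <- min(d)
  if (dmin > maxDist) return(NULL)
  hit <- anchors[d == dmin, , drop = FALSE]
  hit <- hit[order(hit$locusRank, hit$position), , drop = FALSE][1, , drop = FALSE]
  hit$distance <- dmin
  rownames(hit) <- NULL
  hit
}

#' Genes overlapping an interval
#'
#' @param locusMap A [LocusMap].
#' @param interval An [IRanges::IRanges] of length 1 (1-based closed), or
#'   a numeric `c(start, end)` pair. A zero-width query returns no genes.
#' @return `GRanges` of overlapping genes in locus order.
#' @export
genesInInterval <- function(locusMap, interval) {
  if (is.numeric(interval) && length(interval) == 2)
    interval <- IRanges(interval[1], interval[2])
  g <- locusGenes(locusMap)
  hit <- g[start(g) <= end(interval) & end(g) >= start(interval)]
  if (locusOrientation(locusMap) == "vfirst") hit <- rev(hit)
  hit
}

#' Bundle references into a ReferenceSet
#'
#' @param maps Named list of [LocusMap] objects (names are reference
#'   names).
#' @param sequences Optional named [Biostrings::DNAStringSet] of the
#'   reference sequences.
#' @param priority Tie-break order; defaults to `names(maps)`.
#' @return A [ReferenceSet].
#' @export
makeReferenceSet <- function(maps, sequences = DNAStringSet(),
                             priority = names(maps)) {
  new("ReferenceSet", maps = maps, sequences = sequences,
      priority = priority)
}
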