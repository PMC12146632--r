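#' Aggregate read evidence into distinct recombination events
#'
#' Groups recombination-bearing reads (event class other than
#' unrecombined, with at least one meaningful junction) by a canonical
#' event key: the event class plus the ordered (gene, side) list from
#' the junction RSS matches. For complete V(D)J events the key carries
#' only the V and J anchors; the D gene cannot be resolved from a
#' single J-V split and never enters the key.
#'
#' @param evidences List of [ReadEvidence] from one sample.
#' @param confidentOnly Keep only evidence whose breakends are all
#'   RSS-confident (default `FALSE`: all recombination-bearing reads
#'   count).
#' @return `data.frame` of distinct events: `key`, `eventClass`,
#'   `genes`, `n` (supporting reads), `readIds` (`;`-separated), sorted
#'   by decreasing `n` then key.
#' @export
aggregateEvents <- function(evidences, confidentOnly = FALSE) {
  keep <- Filter(function(ev) {
    if (eventClass(ev) == "unrecombined") return(FALSE)
    jx <- readJunctions(ev)
    if (!any(jx$meaningful)) return(FALSE)
    if (confidentOnly && !isConfident(ev)) return(FALSE)
    TRUE
  }, evidences)
  if (length(keep) == 0)
    return(data.frame(key = character(0), eventClass = character(0),
                      genes = character(0), n = integer(0),
                      readIds = character(0), stringsAsFactors = FALSE))
  rows <- lapply(keep, function(ev) {
    gu <- genesUsed(ev)
    if (eventClass(ev) == "complete_VDJ")
      gu <- gu[is.na(gu$class) | gu$class %in% c("V", "J"), , drop = FALSE]
    genes <- paste(sprintf("%s[%s]", gu$gene, gu$side), collapse = ";")
    data.frame(readId = readId(ev), eventClass = eventClass(ev),
               genes = genes,
               key = paste(eventClass(ev), genes, sep = ":"),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  out <- do.call(rbind, lapply(split(tab, tab$key), function(grp) {
    data.frame(key = grp$key[1], eventClass = grp$eventClass[1],
               genes = grp$genes[1], n = nrow(grp),
               readIds = paste(sort(grp$readId), collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(-out$n, out$key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Simpson's index of clonality
#'
#' `SI = sum(n_i^2) / N^2`, where `n_i` is the number of reads
#' supporting distinct event i and `N = sum(n_i)` the total number of
#' recombination-bearing reads. Equivalently, the probability that two
#' reads drawn independently with replacement support the same event.
#' A sample dominated by one event per haplotype gives SI near 0.5; the
#' all-singleton floor is `1/N`.
#'
#' @param events Distinct-event table from [aggregateEvents], or a bare
#'   numeric vector of supporting-read counts.
#' @return The index in (0, 1], or `NA` when there are no events (the
#'   index is undefined, not zero).
#' @export
simpsonIndex <- function(events) {
  n <- if (is.numeric(events)) events else events$n
  n <- n[n > 0]
  if (length(n) == 0) return(NA_real_)
  sum(n^2) / sum(n)^2
}

#' Label a sample's clonality
#'
#' Samples with SI above `mono` are monoclonal (half of the 0.5 upper
#' limit expected for one dominant event per haplotype), below `poly`
#' polyclonal, and in between intermediate.
#'
#' @param si Simpson's index (may be `NA`).
#' @param mono Monoclonal threshold (default 0.25, exclusive).
#' @param poly Polyclonal threshold (default 0.125, exclusive).
#' @return `"monoclonal"`, `"intermediate"`, `"polyclonal"` or `NA`.
#' @export
classifyClonality <- function(si, mono = 0.25, poly = 0.125) {
  if (is.na(si)) return(NA_character_)
  stopifnot(si > 0, si <= 1)
  if (si > mono) "monoclonal"
  else if (si < poly) "polyclonal"
  else "intermediate"
}

#' Full clonality report for one sample
#'
#' @param evidences List of [ReadEvidence].
#' @param confidentOnly See [aggregateEvents].
#' @param mono,poly See [classifyClonality].
#' @return A [ClonalityReport].
#' @export
clonalityReport <- function(evidences, confidentOnly = FALSE,
                            mono = 0.25, poly = 0.125) {
  ev <- aggregateEvents(evidences, confidentOnly = confidentOnly)
  si <- simpsonIndex(ev)
  lab <- classifyClonality(si, mono, poly)
  new("ClonalityReport", si = si, nTotal = as.integer(sum(ev$n)),
      nDistinct = nrow(ev),
      label = if (is.na(lab)) NA_character_ else lab,
      thresholds = c(mono = mono, poly = poly))
}

.usagePair <- function(genes, classA, classB, anchors) {
  parts <- strsplit(genes, ";", fixed = TRUE)[[1]]
  gene <- sub("\\[.*$", "", parts)
  cls <- anchors$class[match(gene, anchors$gene)]
  a <- gene[cls == classA][1]
  b <- gene[cls == classB][1]
  if (is.na(a) || is.na(b)) return(NULL)
  c(a, b)
}

#' Gene usage tables from distinct events
#'
#' Builds the V-J usage table from confident complete V(D)J events and
#' the D-J table from confident D-J-only events; non-canonical classes
#' feed neither. `scope` controls the counting unit: each supporting
#' read, each distinct event once, or each sample once per pair.
#'
#' @param events One distinct-event table ([aggregateEvents]) or, for
#'   `scope = "individuals"`, a list of them (one per sample).
#' @param locusMap [LocusMap] used to type the gene symbols.
#' @param scope `"reads"`, `"events"` or `"individuals"`.
#' @return List of two `data.frame`s `vj` (`vGene`, `jGene`, `count`)
#'   and `dj` (`dGene`, `jGene`, `count`).
#' @export
geneUsage <- function(events, locusMap,
                      scope = c("events", "reads", "individuals")) {
  scope <- match.arg(scope)
  anchors <- rssAnchors(locusMap)
  samples <- if (scope == "individuals") {
    stopifnot(is.list(events) && !is.data.frame(events))
    events
  } else list(events)
  vj <- list(); dj <- list()
  for (s in seq_along(samples)) {
    ev <- samples[[s]]
    seenV <- character(0); seenD <- character(0)
    for (i in seq_len(nrow(ev))) {
      w <- if (scope == "reads") ev$n[i] else 1L
      if (ev$eventClass[i] == "complete_VDJ") {
        p <- .usagePair(ev$genes[i], "V", "J", anchors)
        if (is.null(p)) next
        key <- paste(p, collapse = "\t")
        if (scope == "individuals") {
          if (key %in% seenV) next
          seenV <- c(seenV, key)
          w <- 1L
        }
        vj[[key]] <- (if (is.null(vj[[key]])) 0L else vj[[key]]) + w
      } else if (ev$eventClass[i] == "DJ_only") {
        p <- .usagePair(ev$genes[i], "D", "J", anchors)
        if (is.null(p)) next
        key <- paste(p, collapse = "\t")
        if (scope == "individuals") {
          if (key %in% seenD) next
          seenD <- c(seenD, key)
          w <- 1L
        }
        dj[[key]] <- (if (is.null(dj[[key]])) 0L else dj[[key]]) + w
      }
    }
  }
  toDf <- function(x, a, b) {
    if (length(x) == 0)
      return(setNames(data.frame(character(0), character(0), integer(0),
                                 stringsAsFactors = FALSE),
                      c(a, b, "count")))
    parts <- strsplit(names(x), "\t", fixed = TRUE)
    out <- data.frame(vapply(parts, `[`, character(1), 1),
                      vapply(parts, `[`, character(1), 2),
                      unlist(x, use.names = FALSE),
                      stringsAsFactors = FALSE)
    names(out) <- c(a, b, "count")
    out[order(out[[1]], out[[2]]), , drop = FALSE]
  }
  list(vj = toDf(vj, "vGene", "jGene"), dj = toDf(dj, "dGene", "jGene"))
}
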