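#' @include AllClasses.R divergence.R parsimony.R
NULL

#' Extract potentially informative exon indels
#'
#' Scans per-gene exon alignments (which must include the outgroup) for
#' maximal gap runs with identical boundaries. Each distinct run present in
#' at least one and absent from at least one ingroup taxon becomes a
#' candidate indel event. Polarity is read off the outgroup, which is
#' assumed ancestral: outgroup ungapped means the gap is a deletion
#' (\code{-}) in the gapped taxa; outgroup gapped means the ungapped state
#' is an insertion (\code{+}) and the ungapped ingroup taxa are derived.
#' An outgroup run that only partially overlaps the event leaves the
#' polarity undetermined (\code{NA}).
#'
#' @param geneAlignments named list of exon alignments (one per gene)
#' @param outgroup outgroup taxon name (must be present in each alignment)
#' @return data.frame of events: \code{gene}, \code{position} (aligned
#'   start), \code{size}, \code{polarity}, \code{derived_taxa}
#'   (comma-separated), \code{gapped_taxa}
#' @export
extractExonIndels <- function(geneAlignments, outgroup) {
  if (is.null(names(geneAlignments))) stop("gene alignments must be named")
  out <- list()
  for (g in names(geneAlignments)) {
    m <- .as_aln_matrix(geneAlignments[[g]])
    if (!outgroup %in% rownames(m)) stop("outgroup absent from gene ", g)
    ingroup <- setdiff(rownames(m), outgroup)
    runs <- .gap_runs(m)
    og_runs <- names(runs)[vapply(runs, function(tx) outgroup %in% tx,
                                  logical(1))]
    for (key in names(runs)) {
      se <- as.integer(strsplit(key, "-", fixed = TRUE)[[1]])
      gapped <- intersect(runs[[key]], ingroup)
      ## "possibly informative": the gap state must vary among the ingroup
      if (!length(gapped) || length(gapped) == length(ingroup)) next
      og_gapped <- outgroup %in% runs[[key]]
      ## partial outgroup overlap without identical boundaries
      og_partial <- !og_gapped && any(vapply(og_runs, function(k2) {
        se2 <- as.integer(strsplit(k2, "-", fixed = TRUE)[[1]])
        se2[1] <= se[2] && se2[2] >= se[1]
      }, logical(1)))
      if (og_gapped) {
        polarity <- "+"
        derived <- setdiff(ingroup, gapped)
        if (!length(derived)) next      # invariant among ingroup
      } else {
        polarity <- if (og_partial) NA_character_ else "-"
        derived <- gapped
        if (length(derived) == length(ingroup)) next
      }
      out[[length(out) + 1L]] <- data.frame(
        gene = g, position = se[1], size = se[2] - se[1] + 1L,
        polarity = polarity,
        derived_taxa = paste(sort(derived), collapse = ","),
        gapped_taxa = paste(sort(gapped), collapse = ","))
    }
  }
  if (!length(out))
    return(data.frame(gene = character(), position = integer(),
                      size = integer(), polarity = character(),
                      derived_taxa = character(), gapped_taxa = character()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

## binary states of one event over a taxon set (derived = 1)
.event_states <- function(event, taxa_all) {
  derived <- strsplit(event$derived_taxa, ",", fixed = TRUE)[[1]]
  stats::setNames(ifelse(taxa_all %in% derived, "1", "0"), taxa_all)
}

#' Append coded indel events to a character matrix
#'
#' Simple indel coding: each event becomes one binary character (derived
#' state = 1), appended after the existing characters.
#'
#' @param events data.frame from \code{\link{extractExonIndels}}
#' @param M a \linkS4class{CharacterMatrix}
#' @return extended \linkS4class{CharacterMatrix} (type becomes "mixed"
#'   when DNA characters are present)
#' @export
codeAndAppend <- function(events, M) {
  mat <- characterStates(M)
  if (!nrow(events)) return(M)
  extra <- vapply(seq_len(nrow(events)), function(i)
    .event_states(events[i, ], rownames(mat)), character(nrow(mat)))
  if (nrow(mat) == 1L) extra <- matrix(extra, nrow = 1L)
  colnames(extra) <- paste0(events$gene, "@", events$position)
  characterMatrix(cbind(mat, extra))
}

#' Classify indel events on a reference tree
#'
#' Delegates to \code{\link{mapCharacter}}: an event with a single origin
#' on the tree is synapomorphic, otherwise homoplasious.
#'
#' @param events data.frame from \code{\link{extractExonIndels}}
#' @param tree reference topology
#' @param outgroup outgroup taxon
#' @return the events with \code{origins} and \code{classification} columns
#' @export
classifyEvents <- function(events, tree, outgroup) {
  if (!nrow(events)) {
    events$origins <- integer(); events$classification <- character()
    return(events)
  }
  res <- lapply(seq_len(nrow(events)), function(i)
    mapCharacter(tree, .event_states(events[i, ], tree$tip.label), outgroup))
  events$origins <- vapply(res, `[[`, numeric(1), "origins")
  events$classification <- vapply(res, `[[`, character(1), "classification")
  events
}

#' Detect small inversions flanked by palindromic repeats
#'
#' For each palindromic arm pair (found on the ungapped reference row, or
#' supplied), the enclosed segment of every other taxon is compared to the
#' reference segment directly and reverse-complemented. A taxon is called
#' inverted when the reverse-complement identity reaches
#' \code{minIdentity} while the direct identity stays below
#' \code{maxDirect}.
#'
#' @param aln alignment input
#' @param reference reference taxon (defaults to the first row)
#' @param repeats optional motif data.frame of palindromic repeats on the
#'   ungapped reference sequence; computed with \code{\link{findPalindromic}}
#'   when \code{NULL}
#' @param minIdentity minimum reverse-complement identity to call an
#'   inversion
#' @param maxDirect maximum direct identity for an inverted call
#' @param armIdentity identity used when locating the anchoring arms on the
#'   reference; exact by default so segment boundaries are precise
#' @param ... passed to \code{\link{findPalindromic}}
#' @return data.frame of events: reference coordinates of the arms and
#'   segment, \code{inverted_taxa} (comma separated; possibly empty rows
#'   are dropped)
#' @export
detectSmallInversions <- function(aln, reference = NULL, repeats = NULL,
                                  minIdentity = 0.9, maxDirect = 0.5,
                                  armIdentity = 1, ...) {
  m <- .as_aln_matrix(aln)
  if (is.null(reference)) reference <- rownames(m)[1]
  refrow <- m[reference, ]
  ref_cols <- which(!.is_gapchar(refrow))
  refseq <- .collapse_chars(refrow[ref_cols])
  if (is.null(repeats))
    repeats <- findPalindromic(refseq, minIdentity = armIdentity, ...)
  repeats <- repeats[repeats$type == "palindromic" & repeats$gap > 0, ,
                     drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(repeats))) {
    s <- repeats$end1[i] + 1L; e <- repeats$start2[i] - 1L
    if (e < s) next
    cols <- ref_cols[s:e]
    ref_seg <- m[reference, cols]
    inv <- character()
    for (tx in setdiff(rownames(m), reference)) {
      seg <- m[tx, cols]
      direct <- mean(.match_vec(seg, ref_seg))
      rcseg <- .revcomp_chars(seg)
      rc <- mean(.match_vec(rcseg, ref_seg))
      if (rc >= minIdentity && direct < maxDirect) inv <- c(inv, tx)
    }
    if (length(inv))
      out[[length(out) + 1L]] <- data.frame(
        arm1_start = repeats$start1[i], arm1_end = repeats$end1[i],
        arm2_start = repeats$start2[i], arm2_end = repeats$end2[i],
        segment_start = s, segment_end = e,
        segment_length = e - s + 1L,
        aln_start = cols[1], aln_end = cols[length(cols)],
        reference = reference,
        inverted_taxa = paste(sort(inv), collapse = ","))
  }
  if (!length(out))
    return(data.frame(arm1_start = integer(), arm1_end = integer(),
                      arm2_start = integer(), arm2_end = integer(),
                      segment_start = integer(), segment_end = integer(),
                      segment_length = integer(), aln_start = integer(),
                      aln_end = integer(), reference = character(),
                      inverted_taxa = character()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Neutralize small inversions in an alignment
#'
#' \code{mode = "exclude"} drops the inverted segment's columns from the
#' alignment; \code{mode = "reorient"} reverse-complements the segment in
#' the taxa carrying the minority orientation so all rows share one
#' orientation. Overlapping events are processed outermost first.
#' Reorientation is idempotent: a second pass finds nothing left to flip.
#'
#' @param aln alignment input
#' @param events data.frame from \code{\link{detectSmallInversions}}
#' @param mode "exclude" or "reorient"
#' @return the normalized alignment (character matrix)
#' @export
normalizeInversions <- function(aln, events, mode = c("exclude", "reorient")) {
  mode <- match.arg(mode)
  m <- .as_aln_matrix(aln)
  if (!nrow(events)) return(m)
  events <- events[order(events$aln_start,
                         -(events$aln_end - events$aln_start)), , drop = FALSE]
  if (mode == "exclude") {
    drop <- unlist(lapply(seq_len(nrow(events)), function(i)
      events$aln_start[i]:events$aln_end[i]))
    m[, -unique(drop), drop = FALSE]
  } else {
    for (i in seq_len(nrow(events))) {
      cols <- events$aln_start[i]:events$aln_end[i]
      for (tx in strsplit(events$inverted_taxa[i], ",", fixed = TRUE)[[1]])
        m[tx, cols] <- .revcomp_chars(m[tx, cols])
    }
    m
  }
}
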