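#' @include AllClasses.R repeatscan.R
NULL

## motif copy intervals as an IRanges (tandem: whole array as one interval)
.motif_copy_ranges <- function(m) {
  s <- c(m$start1, m$start2[!is.na(m$start2)])
  e <- c(m$end1, m$end2[!is.na(m$end2)])
  IRanges(s, e)
}

## feature context of one interval: overlapping gene names, else the
## flanking gene pair "left-right"
.interval_context <- function(s, e, per_gene) {
  if (!nrow(per_gene)) return("")
  hit <- per_gene$start <= e & per_gene$end >= s
  if (any(hit)) return(paste(sort(unique(per_gene$name[hit])), collapse = "+"))
  left <- per_gene[per_gene$end < s, , drop = FALSE]
  right <- per_gene[per_gene$start > e, , drop = FALSE]
  ln <- if (nrow(left)) left$name[which.max(left$end)] else "."
  rn <- if (nrow(right)) right$name[which.min(right$start)] else "."
  paste0(ln, "-", rn)
}

#' Merge, prioritize and classify repeat motifs of one genome
#'
#' Applies the resolution rules used for plastome repeat inventories:
#' overlapping same-type motifs are merged (contained motifs dropped), a
#' genomic region is assigned a single repeat type with tandem taking
#' priority over dispersed, motifs whose two copies overlap two distinct
#' tRNA genes or the members of a known paralogous gene pair are reclassified
#' as \code{similarity} repeats (sequence similarity from gene function, not
#' true repeats), and each motif is annotated with its location class
#' (coding/noncoding/both) and feature context.
#'
#' @param dispersed,tandem,palindromic motif data.frames from the finders
#' @param rec the annotated \linkS4class{GenomeRecord} the motifs came from
#' @param paralogPairs list of length-2 character vectors of paralogous gene
#'   pairs whose similarity should not count as a repeat
#' @return a \linkS4class{RepeatSet}
#' @export
resolveAndClassify <- function(dispersed, tandem, palindromic, rec,
                               paralogPairs = list(c("psaA", "psaB"))) {
  all_m <- rbind(dispersed, tandem, palindromic)
  if (!nrow(all_m)) {
    mm <- .empty_motifs()
    mm$location_class <- character(); mm$context <- character()
    return(new("RepeatSet", genomeId = rec@id, motifs = mm))
  }

  ## same-type merge: drop motifs whose copy intervals are all contained in
  ## the corresponding intervals of another motif of the same type
  contained_in <- function(m, i, j) {
    if (m$type[i] != m$type[j]) return(FALSE)
    ok1 <- m$start1[i] >= m$start1[j] & m$end1[i] <= m$end1[j]
    if (is.na(m$start2[i]) != is.na(m$start2[j])) return(FALSE)
    ok2 <- is.na(m$start2[i]) ||
      (m$start2[i] >= m$start2[j] & m$end2[i] <= m$end2[j])
    ok1 && ok2 && !(m$start1[i] == m$start1[j] && m$end1[i] == m$end1[j] &&
                      (is.na(m$start2[i]) ||
                         (m$start2[i] == m$start2[j] && m$end2[i] == m$end2[j])))
  }
  n <- nrow(all_m)
  drop <- logical(n)
  for (i in seq_len(n)) for (j in seq_len(n))
    if (i != j && !drop[j] && contained_in(all_m, i, j)) drop[i] <- TRUE
  all_m <- all_m[!drop, , drop = FALSE]

  ## priority: tandem over dispersed for the same region
  tand <- all_m[all_m$type == "tandem", , drop = FALSE]
  if (nrow(tand)) {
    tr <- IRanges(tand$start1, tand$end1)
    isd <- which(all_m$type == "dispersed")
    kill <- vapply(isd, function(i) {
      cr <- IRanges(c(all_m$start1[i], all_m$start2[i]),
                    c(all_m$end1[i], all_m$end2[i]))
      length(findOverlaps(cr, tr)) > 0
    }, logical(1))
    if (any(kill)) all_m <- all_m[-isd[kill], , drop = FALSE]
  }

  ## classification against the annotation
  genes <- .gene_table(rec)
  per_gene <- if (nrow(genes))
    do.call(rbind, lapply(split(genes, genes$feature_id), function(g)
      data.frame(name = g$name[1], start = min(g$start), end = max(g$end))))
  else data.frame(name = character(), start = integer(), end = integer())
  trna <- unique(rec@features$name[rec@features$kind == "tRNA"])
  coding <- reduce(.coding_ranges(rec))

  loc_class <- character(nrow(all_m))
  context <- character(nrow(all_m))
  type <- all_m$type
  for (i in seq_len(nrow(all_m))) {
    cr <- .motif_copy_ranges(all_m[i, , drop = FALSE])
    cov <- sum(width(IRanges::intersect(cr, coding)))
    tot <- sum(width(cr))
    loc_class[i] <- if (cov == 0) "noncoding" else if (cov == tot) "coding" else "both"
    ctxs <- vapply(seq_along(cr), function(k)
      .interval_context(start(cr)[k], end(cr)[k], per_gene), "")
    context[i] <- paste(sort(ctxs), collapse = "|")
    ## similarity: the two copies sit in two distinct tRNAs or in the two
    ## members of a paralogous pair
    if (type[i] %in% c("dispersed", "palindromic") && length(cr) == 2L) {
      g1 <- per_gene$name[per_gene$start <= end(cr)[1] & per_gene$end >= start(cr)[1]]
      g2 <- per_gene$name[per_gene$start <= end(cr)[2] & per_gene$end >= start(cr)[2]]
      two_trna <- length(intersect(g1, trna)) > 0 && length(intersect(g2, trna)) > 0 &&
        !identical(sort(intersect(g1, trna)), sort(intersect(g2, trna)))
      paralog <- any(vapply(paralogPairs, function(p)
        (p[1] %in% g1 && p[2] %in% g2) || (p[2] %in% g1 && p[1] %in% g2),
        logical(1)))
      if (two_trna || paralog) type[i] <- "similarity"
    }
  }
  all_m$type <- type
  all_m$location_class <- loc_class
  all_m$context <- context
  rownames(all_m) <- NULL
  new("RepeatSet", genomeId = rec@id, motifs = all_m)
}

#' One-call repeat scan of an annotated genome
#'
#' Runs the three finders and the resolution step. When a
#' \linkS4class{Quadripartite} is supplied (or detectable), one IR copy
#' (IRa) is masked before dispersed/palindromic scanning so the
#' genome-scale inverted repeat does not flood the repeat inventory; small
#' repeats inside the IR are still seen once, through the IRb copy.
#'
#' @param rec a \linkS4class{GenomeRecord}
#' @param quad optional \linkS4class{Quadripartite}; set
#'   \code{maskIR = FALSE} to scan the raw sequence
#' @param maskIR mask the IRa copy before scanning
#' @param ... passed to the finders (thresholds)
#' @return a \linkS4class{RepeatSet}
#' @export
scanRepeats <- function(rec, quad = NULL, maskIR = !is.null(quad), ...) {
  ch <- .seq_chars(as.character(rec@seq))
  if (maskIR) {
    if (is.null(quad)) stop("maskIR requires a Quadripartite")
    ira <- quad@ira
    ch[start(ira):end(ira)] <- "N"
  }
  s <- .collapse_chars(ch)
  dots <- list(...)
  pick <- function(f, allowed) do.call(f, c(list(s), dots[names(dots) %in% allowed]))
  disp <- pick(findDispersed, c("minLen", "minIdentity", "maxLen",
                                "exhaustiveLimit", "seedLen"))
  tand <- pick(findTandem, c("minUnit", "minIdentity", "maxUnit"))
  pali <- pick(findPalindromic, c("minArm", "maxGap", "minIdentity", "maxArm",
                                  "exhaustiveLimit", "seedLen"))
  resolveAndClassify(disp, tand, pali, rec)
}

## cross-genome repeat character key: same type, identical unit length,
## homologous region operationalized as identical feature context
.repeat_keys <- function(rs) {
  m <- rs@motifs
  m <- m[m$type != "similarity", , drop = FALSE]
  if (!nrow(m)) return(character())
  unique(paste(m$type, m$unit_length, m$context, sep = "//"))
}

#' Shared and unique repeats across genomes
#'
#' Two repeats in different genomes are treated as the same character iff
#' they have the same type, identical unit length and identical feature
#' context (homologous region). Similarity-class repeats are excluded.
#'
#' @param sets list of \linkS4class{RepeatSet}
#' @return list with \code{characters} (data.frame: key, presence per
#'   taxon), \code{shared_all} (count present in every genome),
#'   \code{unique_per_taxon} (named counts present in exactly one genome),
#'   and \code{subset_counts} (counts per presence signature)
#' @export
sharedRepeats <- function(sets) {
  if (length(sets) < 2L) stop("need at least two genomes")
  ids <- vapply(sets, genomeId, "")
  if (anyDuplicated(ids)) stop("duplicate genome ids")
  keysets <- lapply(sets, .repeat_keys)
  all_keys <- unique(unlist(keysets))
  pres <- vapply(keysets, function(k) all_keys %in% k,
                 logical(length(all_keys)))
  if (length(all_keys) == 1L) pres <- matrix(pres, nrow = 1L)
  colnames(pres) <- ids
  sig <- apply(pres, 1, function(z) paste(ids[z], collapse = ","))
  nshare <- rowSums(pres)
  list(characters = data.frame(key = all_keys, pres, check.names = FALSE),
       shared_all = sum(nshare == length(ids)),
       unique_per_taxon = vapply(ids, function(id)
         sum(pres[, id] & nshare == 1L), integer(1)),
       subset_counts = table(sig))
}

#' Repeat presence/absence character matrix
#'
#' One binary character per distinct repeat (similarity repeats excluded);
#' a genome scores 1 when it carries the repeat. Character provenance is
#' kept as column names.
#'
#' @param sets list of \linkS4class{RepeatSet}
#' @return a binary \linkS4class{CharacterMatrix}
#' @export
repeatBinaryMatrix <- function(sets) {
  sh <- sharedRepeats(sets)
  ids <- vapply(sets, genomeId, "")
  if (!nrow(sh$characters)) {
    mat <- matrix(character(), nrow = length(ids), ncol = 0,
                  dimnames = list(ids, NULL))
    return(characterMatrix(mat, "binary"))
  }
  pres <- as.matrix(sh$characters[, ids, drop = FALSE])
  mat <- matrix(ifelse(pres, "1", "0"), nrow(pres), ncol(pres))
  mat <- t(mat)
  rownames(mat) <- ids
  colnames(mat) <- sh$characters$key
  characterMatrix(mat, "binary")
}
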