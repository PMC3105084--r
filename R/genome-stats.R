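#' @include AllClasses.R
NULL

## exon-level coding intervals: CDS/tRNA/rRNA rows of the feature table
.coding_ranges <- function(rec) {
  f <- rec@features
  f <- f[f$kind %in% c("CDS", "tRNA", "rRNA") & !f$origin_spanning, , drop = FALSE]
  IRanges(start = f$start, end = f$end)
}

## gene-level extents (one range per gene feature)
.gene_table <- function(rec) {
  f <- rec@features
  f[f$kind == "gene" & !f$origin_spanning, , drop = FALSE]
}

#' Genome summary statistics
#'
#' Computes the headline descriptive statistics of an annotated plastome:
#' length, GC content, the percentage of the genome covered by coding exons
#' (CDS, tRNA and rRNA intervals, unioned so overlaps are not double
#' counted), and gene counts. A gene is counted as duplicated when it has
#' two copies lying wholly inside the two inverted-repeat arms; pass the
#' genome's \linkS4class{Quadripartite} to enable that classification.
#'
#' Ambiguity codes other than G/C/S count as non-GC. Percentages are
#' rounded to one decimal, the convention used in published plastome tables.
#'
#' @param rec a \linkS4class{GenomeRecord}
#' @param quad optional \linkS4class{Quadripartite} for duplicate-gene calls
#' @return named list: \code{length}, \code{gc_percent}, \code{coding_percent},
#'   \code{genes_total}, \code{genes_protein}, \code{genes_rna},
#'   \code{genes_unique}, \code{genes_duplicated}
#' @export
genomeStats <- function(rec, quad = NULL) {
  n <- length(rec@seq)
  if (n == 0L) stop("empty sequence")
  ch <- .seq_chars(as.character(rec@seq))
  gc <- sum(ch %in% c("G", "C", "S"))
  cod <- reduce(.coding_ranges(rec))
  coding_bp <- sum(width(cod))
  stopifnot(coding_bp <= n)

  f <- rec@features
  genes <- .gene_table(rec)
  gene_names <- unique(genes$name[!is.na(genes$name)])
  kinds_by_name <- function(kind)
    unique(f$name[f$kind == kind & !is.na(f$name)])
  protein <- intersect(gene_names, kinds_by_name("CDS"))
  rnas <- intersect(gene_names, union(kinds_by_name("tRNA"), kinds_by_name("rRNA")))

  dup <- character()
  if (!is.null(quad) && nrow(genes)) {
    ir1 <- quad@irb; ir2 <- quad@ira
    inside <- function(s, e, ir) any(s >= start(ir) & e <= end(ir))
    for (nm in gene_names) {
      g <- genes[genes$name %in% nm, , drop = FALSE]
      if (nrow(g) >= 2L) {
        in1 <- any(mapply(inside, g$start, g$end, MoreArgs = list(ir = ir1)))
        in2 <- any(mapply(inside, g$start, g$end, MoreArgs = list(ir = ir2)))
        if (in1 && in2) dup <- c(dup, nm)
      }
    }
  }
  list(length = n,
       gc_percent = round(100 * gc / n, 1),
       coding_percent = round(100 * coding_bp / n, 1),
       genes_total = length(gene_names),
       genes_protein = length(protein),
       genes_rna = length(rnas),
       genes_unique = length(gene_names) - length(dup),
       genes_duplicated = length(dup))
}

#' Partition a genome into coding and noncoding regions
#'
#' Emits every coding exon region and every noncoding region (intergenic
#' spacers, named by their flanking genes, and introns, named
#' \code{"<gene> intron"}) of length at least \code{minLen}. Spacers are the
#' gaps between consecutive gene extents; introns are the gaps between
#' consecutive exons of a multi-exon CDS/tRNA/rRNA feature.
#'
#' @param rec a \linkS4class{GenomeRecord}
#' @param minLen minimum region length in bp
#' @param singleCopyOnly drop regions overlapping the inverted repeats
#'   (requires \code{quad})
#' @param quad optional \linkS4class{Quadripartite}
#' @return data.frame: \code{name}, \code{class} (coding/noncoding),
#'   \code{start}, \code{end}, \code{length}, \code{genome}
#' @export
partitionRegions <- function(rec, minLen = 1, singleCopyOnly = FALSE,
                             quad = NULL) {
  f <- rec@features
  out <- list()
  ## coding exons
  cf <- f[f$kind %in% c("CDS", "tRNA", "rRNA") & !f$origin_spanning, , drop = FALSE]
  if (nrow(cf)) {
    for (fid in unique(cf$feature_id)) {
      rows <- cf[cf$feature_id == fid, , drop = FALSE]
      rows <- rows[order(rows$start), , drop = FALSE]
      nm <- if (is.na(rows$name[1])) paste0("feat", fid) else rows$name[1]
      for (i in seq_len(nrow(rows)))
        out[[length(out) + 1L]] <- data.frame(
          name = nm, class = "coding", start = rows$start[i], end = rows$end[i])
      if (nrow(rows) > 1L)        # introns between exons
        for (i in seq_len(nrow(rows) - 1L)) {
          s <- rows$end[i] + 1L; e <- rows$start[i + 1L] - 1L
          if (e >= s)
            out[[length(out) + 1L]] <- data.frame(
              name = paste(nm, "intron"), class = "noncoding", start = s, end = e)
        }
    }
  }
  ## intergenic spacers between consecutive gene extents
  genes <- .gene_table(rec)
  if (nrow(genes)) {
    per_gene <- do.call(rbind, lapply(split(genes, genes$feature_id), function(g)
      data.frame(name = g$name[1], start = min(g$start), end = max(g$end))))
    per_gene <- per_gene[order(per_gene$start, per_gene$end), , drop = FALSE]
    cover_end <- cummax(per_gene$end)
    for (i in seq_len(nrow(per_gene) - 1L)) {
      s <- cover_end[i] + 1L; e <- per_gene$start[i + 1L] - 1L
      if (e >= s) {
        left <- per_gene$name[which(per_gene$end == cover_end[i])[1]]
        out[[length(out) + 1L]] <- data.frame(
          name = paste0(left, "-", per_gene$name[i + 1L]), class = "noncoding",
          start = s, end = e)
      }
    }
  }
  if (!length(out))
    return(data.frame(name = character(), class = character(),
                      start = integer(), end = integer(), length = integer(),
                      genome = character()))
  regions <- do.call(rbind, out)
  regions$length <- regions$end - regions$start + 1L
  regions <- regions[regions$length >= minLen, , drop = FALSE]
  if (!nrow(regions))
    return(data.frame(name = character(), class = character(),
                      start = integer(), end = integer(), length = integer(),
                      genome = character()))
  if (singleCopyOnly) {
    if (is.null(quad)) stop("singleCopyOnly requires a Quadripartite")
    ir <- c(quad@irb, quad@ira)
    hits <- findOverlaps(IRanges(regions$start, regions$end), ir)
    drop <- unique(queryHits(hits))
    if (length(drop)) regions <- regions[-drop, , drop = FALSE]
  }
  regions$genome <- rec@id
  rownames(regions) <- NULL
  regions
}
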