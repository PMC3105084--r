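#' @include AllClasses.R
NULL

## maximal exact common runs between seq and revcomp(seq). Unique k-mers
## of both strings are matched (one vectorized match), hits grouped by
## diagonal, and one seed per diagonal is expanded outward by exact
## character comparison, which yields the true maximal run regardless of
## seed fragmentation.
.ir_seed_runs <- function(ch, k = 20L, maxDiagonals = 50L) {
  n <- length(ch)
  if (n < 2L * k) return(NULL)
  rcch <- .revcomp_chars(ch)
  s <- .collapse_chars(ch)
  rc <- .collapse_chars(rcch)
  pos <- seq_len(n - k + 1L)
  km_s <- substring(s, pos, pos + k - 1L)
  km_r <- substring(rc, pos, pos + k - 1L)
  uniq_s <- !(duplicated(km_s) | duplicated(km_s, fromLast = TRUE))
  uniq_r <- !(duplicated(km_r) | duplicated(km_r, fromLast = TRUE))
  j <- match(km_s, km_r)
  ok <- uniq_s & !is.na(j) & uniq_r[pmax(j, 1L)]
  if (!any(ok)) return(NULL)
  i <- pos[ok]; j <- j[ok]
  d <- j - i
  ## one seed per diagonal, diagonals ranked by number of supporting hits
  tab <- sort(table(d), decreasing = TRUE)
  diags <- as.integer(names(tab))[seq_len(min(length(tab), maxDiagonals))]
  runs <- matrix(0L, length(diags), 3,
                 dimnames = list(NULL, c("i", "j", "len")))
  for (r in seq_along(diags)) {
    dd <- diags[r]
    i0 <- i[d == dd][1]; j0 <- i0 + dd
    a <- i0; b <- i0 + k - 1L
    while (a > 1L && (j0 - (i0 - (a - 1L))) >= 1L &&
           ch[a - 1L] == rcch[j0 - (i0 - (a - 1L))]) a <- a - 1L
    while (b < n && (j0 + (b + 1L - i0)) <= n &&
           ch[b + 1L] == rcch[j0 + (b + 1L - i0)]) b <- b + 1L
    runs[r, ] <- c(a, j0 - (i0 - a), b - a + 1L)
  }
  unique(runs)
}

#' Detect the quadripartite LSC/IRb/SSC/IRa architecture
#'
#' Finds the maximal pair of disjoint segments of the genome where one is
#' the reverse complement of the other (exact seed match, maximal
#' extension), interprets the pair as the inverted repeat, and labels the
#' shorter inter-arm gap as SSC and the longer (possibly origin-wrapping)
#' gap as LSC. By default arm matching is exact; set \code{minIdentity}
#' below 1 to allow Hamming-mismatch extension for degraded genomes.
#'
#' @param x sequence (string, \code{DNAString} or \linkS4class{GenomeRecord})
#' @param minIR minimum IR arm length in bp; anything shorter raises a
#'   structured "no-IR" error
#' @param minIdentity required identity between the two arms (1 = exact)
#' @return a \linkS4class{Quadripartite}
#' @export
detectQuadripartite <- function(x, minIR = 10000, minIdentity = 1) {
  ch <- .seq_chars(x)
  n <- length(ch)
  if (n <= 2 * minIR) stop("sequence shorter than twice the minimum IR length")
  runs <- .ir_seed_runs(ch)
  err_noir <- function() stop(structure(
    class = c("noIRError", "error", "condition"),
    list(message = sprintf("no inverted repeat of >= %d bp found", minIR),
         call = sys.call(-1))))
  if (is.null(runs)) err_noir()

  ## translate rc coordinates back: rc[j .. j+len-1] is revcomp of
  ## seq[(n-j-len+2) .. (n-j+1)]; arm1 = run in seq, arm2 = its partner
  cand <- data.frame(a1 = runs[, "i"], b1 = runs[, "i"] + runs[, "len"] - 1L,
                     a2 = n - runs[, "j"] - runs[, "len"] + 2L,
                     b2 = n - runs[, "j"] + 1L, len = runs[, "len"])
  ## keep disjoint pairs, arm1 before arm2
  flip <- cand$a1 > cand$a2
  cand[flip, c("a1", "b1", "a2", "b2")] <- cand[flip, c("a2", "b2", "a1", "b1")]
  cand <- cand[cand$b1 < cand$a2, , drop = FALSE]
  cand <- unique(cand)
  if (!nrow(cand)) err_noir()

  if (minIdentity < 1) {
    ## greedy outward Hamming extension while running identity holds
    for (r in seq_len(nrow(cand))) {
      a1 <- cand$a1[r]; b1 <- cand$b1[r]; a2 <- cand$a2[r]; b2 <- cand$b2[r]
      mm <- 0L
      while (a1 > 1L && b2 < n && b1 + 1L < a2) {
        new_mm <- mm + (ch[a1 - 1L] != .complement_chars(ch[b2 + 1L]))
        len <- (b1 - a1 + 2L)
        if ((len - new_mm) / len < minIdentity) break
        a1 <- a1 - 1L; b2 <- b2 + 1L; mm <- new_mm
      }
      while (b1 + 1L < a2 && a2 - 1L > b1 + 1L) {
        new_mm <- mm + (ch[b1 + 1L] != .complement_chars(ch[a2 - 1L]))
        len <- (b1 - a1 + 2L)
        if ((len - new_mm) / len < minIdentity) break
        b1 <- b1 + 1L; a2 <- a2 - 1L; mm <- new_mm
      }
      cand[r, c("a1", "b1", "a2", "b2")] <- c(a1, b1, a2, b2)
      cand$len[r] <- b1 - a1 + 1L
    }
  }
  cand <- cand[cand$len >= minIR, , drop = FALSE]
  if (!nrow(cand)) err_noir()
  ## maximal IR, ties toward the lower coordinate
  cand <- cand[order(-cand$len, cand$a1), , drop = FALSE]
  a1 <- cand$a1[1]; b1 <- cand$b1[1]; a2 <- cand$a2[1]; b2 <- cand$b2[1]

  arm1 <- ch[a1:b1]
  arm2 <- .revcomp_chars(ch[a2:b2])
  ident <- mean(arm1 == arm2)

  gap_mid <- if (a2 > b1 + 1L) IRanges(b1 + 1L, a2 - 1L) else IRanges()
  wrap_s <- integer(); wrap_e <- integer()
  if (b2 < n) { wrap_s <- c(wrap_s, b2 + 1L); wrap_e <- c(wrap_e, n) }
  if (a1 > 1L) { wrap_s <- c(wrap_s, 1L); wrap_e <- c(wrap_e, a1 - 1L) }
  wrap <- IRanges(wrap_s, wrap_e)
  w_mid <- sum(width(gap_mid)); w_wrap <- sum(width(wrap))
  if (w_mid <= w_wrap) { ssc <- gap_mid; lsc <- wrap }
  else { ssc <- wrap; lsc <- gap_mid }

  new("Quadripartite",
      lsc = lsc, irb = IRanges(a1, b1), ssc = ssc, ira = IRanges(a2, b2),
      junctions = c(lsc_irb = a1, irb_ssc = b1, ssc_ira = a2, ira_lsc = b2),
      irIdentity = ident, genomeLength = as.integer(n))
}

#' Junction-gene geometry report
#'
#' For each of the four junctions, reports the annotated gene whose extent
#' crosses it together with the length of its extension into the inverted
#' repeat (0 when no gene crosses, in which case the nearest gene and its
#' distance to the junction are given). The classic diagnostic in grass
#' plastomes is \emph{ndhH} extending about 170-200 nt into the IR at the
#' SSC/IRa junction while \emph{ndhF} stays confined to the SSC.
#'
#' @param quad a \linkS4class{Quadripartite}
#' @param rec the matching annotated \linkS4class{GenomeRecord}
#' @return data.frame: \code{junction}, \code{coordinate}, \code{gene},
#'   \code{crosses}, \code{extension_into_ir}, \code{distance}
#' @export
junctionReport <- function(quad, rec) {
  genes <- .gene_table(rec)
  per_gene <- if (nrow(genes))
    do.call(rbind, lapply(split(genes, genes$feature_id), function(g)
      data.frame(name = g$name[1], start = min(g$start), end = max(g$end))))
  else data.frame(name = character(), start = integer(), end = integer())

  ir_ranges <- list(lsc_irb = quad@irb, irb_ssc = quad@irb,
                    ssc_ira = quad@ira, ira_lsc = quad@ira)
  out <- lapply(names(quad@junctions), function(jn) {
    jpos <- quad@junctions[[jn]]
    ## boundary between position jpos-1|jpos (start junctions) or jpos|jpos+1
    left_end <- if (jn %in% c("lsc_irb", "ssc_ira")) jpos - 0.5 else jpos + 0.5
    crossing <- per_gene[per_gene$start < left_end & per_gene$end > left_end, ,
                         drop = FALSE]
    ir <- ir_ranges[[jn]]
    if (nrow(crossing)) {
      g <- crossing[1, ]
      ext <- max(0L, min(g$end, end(ir)) - max(g$start, start(ir)) + 1L)
      data.frame(junction = jn, coordinate = jpos, gene = g$name,
                 crosses = TRUE, extension_into_ir = ext, distance = 0L)
    } else if (nrow(per_gene)) {
      dist <- pmin(abs(per_gene$start - left_end), abs(per_gene$end - left_end))
      g <- per_gene[which.min(dist), ]
      data.frame(junction = jn, coordinate = jpos, gene = g$name,
                 crosses = FALSE, extension_into_ir = 0L,
                 distance = as.integer(floor(min(dist))))
    } else {
      data.frame(junction = jn, coordinate = jpos, gene = NA_character_,
                 crosses = FALSE, extension_into_ir = 0L, distance = NA_integer_)
    }
  })
  do.call(rbind, out)
}
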