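#' @include AllClasses.R
NULL

## Match semantics used throughout the repeat finders: two positions match
## iff both bases are unambiguous (A/C/G/T) and equal (or complementary for
## palindromic comparisons). Identity is ungapped Hamming identity,
## matches/length; no indels inside a repeat copy.

.match_vec <- function(x1, x2) (x1 == x2) & .is_base(x1) & .is_base(x2)

## All maximal windows [a,b] on a logical match vector with length in
## [minLen, maxLen] and identity >= minIdentity. Maximal = not contained
## in another qualifying window.
##
## Completeness: every window meeting the identity cutoff contains an
## exact run of >= ceil((L - floor((1-id)L)) / (floor((1-id)L)+1)) >= 6
## matches for the thresholds used here, and extending a window across a
## run never drops its identity, so every MAXIMAL qualifying window
## contains at least one complete exact run of >= seedMin. Windows are
## therefore enumerated anchored on complete runs, pruned by the score
## bound m_l - id*(rs-a) + m_r - id*(b-re) >= -(1-id)*runlen.
.maximal_windows <- function(m, minLen, maxLen, minIdentity, seedMin = 6L) {
  L <- length(m)
  if (L < minLen) return(NULL)
  r <- rle(m)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ks <- which(r$values & r$lengths >= seedMin)
  if (!length(ks)) return(NULL)
  id <- minIdentity - 1e-12
  res <- list()
  for (k in ks) {
    rs <- starts[k]; re <- ends[k]; rl <- re - rs + 1L
    lo <- max(1L, re - maxLen + 1L); hi <- min(L, rs + maxLen - 1L)
    if (rs > lo) {
      ml <- cumsum(rev(m[lo:(rs - 1L)]))
      score_l <- c(0, ml - id * seq_along(ml))
      mlc <- c(0L, ml)
    } else { score_l <- 0; mlc <- 0L }
    a_pos <- rs:lo
    if (hi > re) {
      mr <- cumsum(m[(re + 1L):hi])
      score_r <- c(0, mr - id * seq_along(mr))
      mrc <- c(0L, mr)
    } else { score_r <- 0; mrc <- 0L }
    b_pos <- re:hi
    budget <- (1 - id) * rl
    aok <- which(score_l >= -budget - max(score_r))
    bok <- which(score_r >= -budget - max(score_l))
    for (ai in aok) {
      bs <- bok[score_r[bok] >= -budget - score_l[ai]]
      if (!length(bs)) next
      a <- a_pos[ai]; b <- b_pos[bs]
      len <- b - a + 1L
      keep <- len >= minLen & len <= maxLen
      if (!any(keep)) next
      b <- b[keep]; len <- len[keep]
      matches <- rl + mlc[ai] + mrc[bs[keep]]
      res[[length(res) + 1L]] <- data.frame(
        a = a, b = b, identity = matches / len)
    }
  }
  if (!length(res)) return(NULL)
  w <- unique(do.call(rbind, res))
  .drop_contained(w)
}

## merge overlapping windows (one diagonal): connected components by
## overlap; report the longest window per component, ties broken by higher
## identity then lower start -- emulates the manual redundancy filtering
## applied to raw repeat-finder output
.merge_overlapping <- function(w) {
  if (is.null(w) || nrow(w) < 2L) return(w)
  o <- order(w$a, w$b)
  w <- w[o, , drop = FALSE]
  comp <- integer(nrow(w))
  comp[1] <- 1L; hi <- w$b[1]
  for (i in seq_len(nrow(w))[-1]) {
    comp[i] <- if (w$a[i] <= hi) comp[i - 1L] else comp[i - 1L] + 1L
    hi <- max(hi, w$b[i])
  }
  picks <- vapply(split(seq_len(nrow(w)), comp), function(ix) {
    len <- w$b[ix] - w$a[ix]
    ix[order(-len, -w$identity[ix], w$a[ix])][1]
  }, integer(1))
  w[sort(picks), , drop = FALSE]
}

## remove windows contained in another (sort by a asc, b desc; sweep)
.drop_contained <- function(w) {
  o <- order(w$a, -w$b)
  w <- w[o, , drop = FALSE]
  maxb <- -Inf
  keep <- logical(nrow(w))
  for (i in seq_len(nrow(w))) {
    if (w$b[i] > maxb) { keep[i] <- TRUE; maxb <- w$b[i] }
  }
  w[keep, , drop = FALSE]
}

.empty_motifs <- function() data.frame(
  type = character(), start1 = integer(), end1 = integer(),
  start2 = integer(), end2 = integer(), unit_length = integer(),
  copies = integer(), identity = numeric(), gap = integer())

## candidate diagonals (dispersed) or anti-diagonals (palindromic) from
## exact k-mer seeding; used when the sequence is too long for the
## all-diagonal scan
.seed_diagonals <- function(ch, k, palindromic = FALSE, maxOcc = 25L) {
  n <- length(ch)
  s <- .collapse_chars(ch)
  pos <- seq_len(n - k + 1L)
  km <- substring(s, pos, pos + k - 1L)
  if (!palindromic) {
    dupval <- unique(km[duplicated(km)])
    if (!length(dupval)) return(NULL)
    hits <- list()
    for (w in dupval) {
      p <- pos[km == w]
      if (length(p) > maxOcc) next
      pr <- t(utils::combn(p, 2L))
      hits[[w]] <- cbind(d = pr[, 2] - pr[, 1], i = pr[, 1])
    }
    if (!length(hits)) return(NULL)
    do.call(rbind, hits)
  } else {
    rc <- .collapse_chars(.revcomp_chars(ch))
    kmr <- substring(rc, pos, pos + k - 1L)
    common <- intersect(km, kmr)
    if (!length(common)) return(NULL)
    hits <- list()
    ps <- split(pos[km %in% common], km[km %in% common])
    pr <- split(pos[kmr %in% common], kmr[kmr %in% common])
    for (w in common) {
      a <- ps[[w]]; b <- pr[[w]]
      if (length(a) * length(b) > maxOcc^2) next
      grid <- cbind(i = rep(a, each = length(b)), j = rep(b, length(a)))
      hits[[w]] <- cbind(d = n + 1L + grid[, "i"] - grid[, "j"], i = grid[, "i"])
    }
    if (!length(hits)) return(NULL)
    do.call(rbind, hits)
  }
}

#' Find dispersed (direct) repeats
#'
#' Reports all maximal pairs of same-strand, non-overlapping segments of
#' length at least \code{minLen} whose ungapped identity is at least
#' \code{minIdentity}; a pair is maximal when it is not contained in a
#' longer qualifying pair at the same copy spacing. Sequences up to
#' \code{exhaustiveLimit} are scanned over every diagonal; longer sequences
#' use exact k-mer seeding, which is complete for repeats whose longest
#' exact stretch reaches \code{seedLen}.
#'
#' @param x sequence input
#' @param minLen minimum copy length (bp)
#' @param minIdentity minimum identity between the two copies
#' @param maxLen longest copy considered
#' @param exhaustiveLimit sequence length up to which all diagonals are scanned
#' @param seedLen seed k-mer length for long sequences
#' @return motif data.frame (one row per repeat pair)
#' @export
findDispersed <- function(x, minLen = 30, minIdentity = 0.90, maxLen = 500,
                          exhaustiveLimit = 3000, seedLen = 12) {
  ch <- .seq_chars(x)
  n <- length(ch)
  if (n < 2 * minLen) return(.empty_motifs())
  res <- list()
  scan_diag <- function(d, lo = 1L, hi = n - d) {
    m <- .match_vec(ch[lo:(hi)], ch[(lo + d):(hi + d)])
    w <- .merge_overlapping(.maximal_windows(m, minLen, min(maxLen, d),
                                             minIdentity))
    if (is.null(w)) return(NULL)
    data.frame(type = "dispersed",
               start1 = lo + w$a - 1L, end1 = lo + w$b - 1L,
               start2 = lo + w$a - 1L + d, end2 = lo + w$b - 1L + d,
               unit_length = w$b - w$a + 1L, copies = 2L,
               identity = w$identity, gap = NA_integer_)
  }
  if (n <= exhaustiveLimit) {
    for (d in seq(minLen, n - minLen)) {
      r <- scan_diag(d)
      if (!is.null(r)) res[[length(res) + 1L]] <- r
    }
  } else {
    seeds <- .seed_diagonals(ch, seedLen)
    if (!is.null(seeds)) {
      seeds <- seeds[seeds[, "d"] >= minLen, , drop = FALSE]
      for (d in unique(seeds[, "d"])) {
        ii <- seeds[seeds[, "d"] == d, "i"]
        lo <- max(1L, min(ii) - maxLen); hi <- min(n - d, max(ii) + maxLen + seedLen)
        if (hi < lo) next
        r <- scan_diag(d, lo, hi)
        if (!is.null(r)) res[[length(res) + 1L]] <- r
      }
    }
  }
  if (!length(res)) return(.empty_motifs())
  out <- unique(do.call(rbind, res))
  rownames(out) <- NULL
  out
}

#' Find palindromic repeats (inverted pairs with a bounded gap)
#'
#' Reports maximal arm pairs where one arm matches the reverse complement
#' of the other at \code{minIdentity} or better, with arm length at least
#' \code{minArm} and the gap between arms between 0 and \code{maxGap}.
#' The genome-scale inverted repeat is excluded upstream by masking one IR
#' copy (see \code{\link{scanRepeats}}); the gap bound alone already keeps
#' the quadripartite IR out since the SSC is far longer than \code{maxGap}.
#'
#' @inheritParams findDispersed
#' @param minArm minimum arm length (bp)
#' @param maxGap maximum gap between the two arms (bp)
#' @param maxArm longest arm considered
#' @export
findPalindromic <- function(x, minArm = 20, maxGap = 3000, minIdentity = 0.90,
                            maxArm = 500, exhaustiveLimit = 3000,
                            seedLen = 12) {
  ch <- .seq_chars(x)
  n <- length(ch)
  if (n < 2 * minArm) return(.empty_motifs())
  comp <- .complement_chars(ch)
  res <- list()
  scan_anti <- function(cc, lo = NULL, hi = NULL) {
    ilo <- max(1L, cc - n); ihi <- (cc - 1L) %/% 2L
    if (!is.null(lo)) ilo <- max(ilo, lo)
    if (!is.null(hi)) ihi <- min(ihi, hi)
    if (ihi - ilo + 1L < minArm) return(NULL)
    i <- ilo:ihi
    m <- .match_vec(ch[i], comp[cc - i]) # comp of partner; partner base revcomp
    w <- .maximal_windows(m, minArm, min(maxArm, length(i)), minIdentity)
    if (is.null(w)) return(NULL)
    a1 <- ilo + w$a - 1L; b1 <- ilo + w$b - 1L
    gapw <- cc - 2L * b1 - 1L
    ok <- gapw >= 0L & gapw <= maxGap
    if (!any(ok)) return(NULL)
    w <- .merge_overlapping(.drop_contained(data.frame(
      a = a1[ok], b = b1[ok], identity = w$identity[ok])))
    data.frame(type = "palindromic", start1 = w$a, end1 = w$b,
               start2 = cc - w$b, end2 = cc - w$a,
               unit_length = w$b - w$a + 1L, copies = 2L,
               identity = w$identity, gap = cc - 2L * w$b - 1L)
  }
  if (n <= exhaustiveLimit) {
    for (cc in (2L * minArm):(2L * n - 1L)) {
      r <- scan_anti(cc)
      if (!is.null(r)) res[[length(res) + 1L]] <- r
    }
  } else {
    seeds <- .seed_diagonals(ch, seedLen, palindromic = TRUE)
    if (!is.null(seeds)) {
      for (cc in unique(seeds[, "d"])) {
        ii <- seeds[seeds[, "d"] == cc, "i"]
        r <- scan_anti(cc, lo = min(ii) - maxArm, hi = max(ii) + maxArm + seedLen)
        if (!is.null(r)) res[[length(res) + 1L]] <- r
      }
    }
  }
  if (!length(res)) return(.empty_motifs())
  out <- unique(do.call(rbind, res))
  rownames(out) <- NULL
  out
}

#' Find tandem repeats
#'
#' Detects arrays of two or more adjacent copies of a unit of at least
#' \code{minUnit} bp. An array is grown from positions where adjacent
#' copies match at \code{minIdentity} or better; for arrays of more than
#' two copies, the reported identity is the minimum identity of any copy
#' against the column-majority consensus unit, and the array is retained
#' only if that minimum meets the cutoff. Arrays whose span is contained
#' in the span of an array with a smaller unit are dropped (canonical
#' smallest period).
#'
#' @inheritParams findDispersed
#' @param minUnit minimum unit length (bp)
#' @param maxUnit longest unit considered
#' @export
findTandem <- function(x, minUnit = 15, minIdentity = 0.90, maxUnit = 200) {
  ch <- .seq_chars(x)
  n <- length(ch)
  if (n < 2 * minUnit) return(.empty_motifs())
  arrays <- list()
  isb <- .is_base(ch)
  for (p in minUnit:min(maxUnit, n %/% 2L)) {
    m <- ch[1:(n - p)] == ch[(1 + p):n] & isb[1:(n - p)] & isb[(1 + p):n]
    cs <- c(0L, cumsum(m))
    amax <- n - 2L * p + 1L
    if (amax < 1L) next
    a <- seq_len(amax)
    ident <- (cs[a + p] - cs[a]) / p         # copy at a vs copy at a+p
    cand <- a[ident >= minIdentity - 1e-12]
    if (!length(cand)) next
    ## maximal chains with step p within each residue class
    for (r0 in unique(cand %% p)) {
      cc <- sort(cand[cand %% p == r0])
      brk <- c(TRUE, diff(cc) != p)
      grp <- cumsum(brk)
      for (g in split(cc, grp)) {
        a0 <- g[1]; copies <- length(g) + 1L
        span_end <- a0 + copies * p - 1L
        cps <- matrix(ch[a0:span_end], nrow = p)
        if (copies > 2L) {
          cons <- apply(cps, 1, function(z) names(which.max(table(z))))
          idents <- colMeans(cps == cons & .is_base(cps))
        } else {
          idents <- rep(mean(.match_vec(cps[, 1], cps[, 2])), 2L)
        }
        if (min(idents) < minIdentity - 1e-12) {
          ## trim failing edge copies, keep the core if still >= 2 copies
          keep <- which(idents >= minIdentity - 1e-12)
          if (length(keep) < 2L || any(diff(keep) != 1L)) next
          a0 <- a0 + (keep[1] - 1L) * p
          copies <- length(keep)
          span_end <- a0 + copies * p - 1L
          idents <- idents[keep]
        }
        arrays[[length(arrays) + 1L]] <- data.frame(
          type = "tandem", start1 = a0, end1 = span_end,
          start2 = NA_integer_, end2 = NA_integer_,
          unit_length = p, copies = copies,
          identity = min(idents), gap = NA_integer_)
      }
    }
  }
  if (!length(arrays)) return(.empty_motifs())
  out <- unique(do.call(rbind, arrays))
  ## containment: drop arrays whose span lies within that of an array with a
  ## smaller (or equal, longer-span) unit
  o <- order(out$unit_length, out$start1, -out$end1)
  out <- out[o, , drop = FALSE]
  drop <- logical(nrow(out))
  for (i in seq_len(nrow(out))) {
    if (drop[i]) next
    within <- out$start1 >= out$start1[i] & out$end1 <= out$end1[i] &
      seq_len(nrow(out)) != i &
      (out$unit_length > out$unit_length[i] |
         (out$unit_length == out$unit_length[i] &
            (out$end1 - out$start1 < out$end1[i] - out$start1[i])))
    drop[within] <- TRUE
  }
  out <- out[!drop, , drop = FALSE]
  ## merge phase-shifted overlapping arrays of the same unit length: keep
  ## the one with most copies, then highest identity, then earliest start
  res <- list()
  for (p in unique(out$unit_length)) {
    sub <- out[out$unit_length == p, , drop = FALSE]
    sub <- sub[order(sub$start1), , drop = FALSE]
    comp <- integer(nrow(sub)); comp[1] <- 1L; hi <- sub$end1[1]
    for (i in seq_len(nrow(sub))[-1]) {
      comp[i] <- if (sub$start1[i] <= hi) comp[i - 1L] else comp[i - 1L] + 1L
      hi <- max(hi, sub$end1[i])
    }
    for (ix in split(seq_len(nrow(sub)), comp)) {
      best <- ix[order(-sub$copies[ix], -sub$identity[ix], sub$start1[ix])][1]
      res[[length(res) + 1L]] <- sub[best, , drop = FALSE]
    }
  }
  out <- do.call(rbind, res)
  out <- out[order(out$start1, out$unit_length), , drop = FALSE]
  rownames(out) <- NULL
  out
}
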