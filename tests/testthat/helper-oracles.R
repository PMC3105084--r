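# Independent brute-force oracles used to validate the production
# algorithms. These share only the mathematical definitions, not the code
# paths: window enumeration is exhaustive per (anti)diagonal, Fitch scores
# come from explicit enumeration of internal labelings, and topology sets
# come from recursive edge insertion.

.OC <- c(A = "T", C = "G", G = "C", T = "A")

o_revcomp <- function(ch) unname(rev(.OC[ch]))

rand_chars <- function(n, gc = 0.4) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

## containment + overlap-merge of qualifying windows on one diagonal
## (slow and simple: quadratic checks)
o_reduce_windows <- function(w) {
  if (is.null(w) || !nrow(w)) return(NULL)
  n <- nrow(w)
  contained <- vapply(seq_len(n), function(i) any(
    w$a <= w$a[i] & w$b >= w$b[i] & !(w$a == w$a[i] & w$b == w$b[i])),
    logical(1))
  w <- w[!contained, , drop = FALSE]
  w <- w[order(w$a, w$b), , drop = FALSE]
  groups <- list(); cur <- 1L; hi <- w$b[1]; gid <- rep(1L, nrow(w))
  if (nrow(w) > 1) for (i in 2:nrow(w)) {
    if (w$a[i] <= hi) gid[i] <- gid[i - 1L] else gid[i] <- gid[i - 1L] + 1L
    hi <- max(hi, w$b[i])
  }
  out <- lapply(split(seq_len(nrow(w)), gid), function(ix) {
    len <- w$b[ix] - w$a[ix]
    w[ix[order(-len, -w$identity[ix], w$a[ix])][1], , drop = FALSE]
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

oracle_dispersed <- function(ch, minLen = 30, minIdentity = 0.9,
                             maxLen = 500) {
  n <- length(ch)
  base_ok <- ch %in% c("A", "C", "G", "T")
  res <- list()
  for (d in seq_len(n - minLen)) {
    if (d < minLen) next
    L <- n - d
    m <- (ch[1:L] == ch[(1 + d):n]) & base_ok[1:L] & base_ok[(1 + d):n]
    cs <- c(0, cumsum(m))
    qual <- list()
    for (len in minLen:min(maxLen, d, L)) {
      a <- seq_len(L - len + 1L)
      ident <- (cs[a + len] - cs[a]) / len
      ok <- ident >= minIdentity - 1e-12
      if (any(ok))
        qual[[length(qual) + 1L]] <- data.frame(a = a[ok],
                                                b = a[ok] + len - 1L,
                                                identity = ident[ok])
    }
    if (!length(qual)) next
    w <- o_reduce_windows(unique(do.call(rbind, qual)))
    if (is.null(w)) next
    res[[length(res) + 1L]] <- data.frame(
      start1 = w$a, end1 = w$b, start2 = w$a + d, end2 = w$b + d,
      unit_length = w$b - w$a + 1L, identity = w$identity)
  }
  if (!length(res)) return(NULL)
  out <- do.call(rbind, res)
  out[order(out$start1, out$start2), , drop = FALSE]
}

oracle_palindromic <- function(ch, minArm = 20, maxGap = 3000,
                               minIdentity = 0.9, maxArm = 500) {
  n <- length(ch)
  comp <- unname(.OC[ch])
  base_ok <- ch %in% c("A", "C", "G", "T")
  res <- list()
  for (cc in (2 * minArm):(2 * n - 1)) {
    ilo <- max(1L, cc - n); ihi <- (cc - 1L) %/% 2L
    if (ihi - ilo + 1L < minArm) next
    i <- ilo:ihi
    m <- (ch[i] == comp[cc - i]) & base_ok[i] & base_ok[cc - i]
    cs <- c(0, cumsum(m))
    Lw <- length(i)
    qual <- list()
    for (len in minArm:min(maxArm, Lw)) {
      a <- seq_len(Lw - len + 1L)
      ident <- (cs[a + len] - cs[a]) / len
      a1 <- ilo + a - 1L; b1 <- a1 + len - 1L
      gap <- cc - 2L * b1 - 1L
      ok <- ident >= minIdentity - 1e-12 & gap >= 0L & gap <= maxGap
      if (any(ok))
        qual[[length(qual) + 1L]] <- data.frame(a = a1[ok], b = b1[ok],
                                                identity = ident[ok])
    }
    if (!length(qual)) next
    w <- o_reduce_windows(unique(do.call(rbind, qual)))
    if (is.null(w)) next
    res[[length(res) + 1L]] <- data.frame(
      start1 = w$a, end1 = w$b, start2 = cc - w$b, end2 = cc - w$a,
      unit_length = w$b - w$a + 1L, identity = w$identity,
      gap = cc - 2L * w$b - 1L)
  }
  if (!length(res)) return(NULL)
  out <- do.call(rbind, res)
  out[order(out$start1, out$start2), , drop = FALSE]
}

oracle_tandem <- function(ch, minUnit = 15, minIdentity = 0.9,
                          maxUnit = 200) {
  n <- length(ch)
  base_ok <- ch %in% c("A", "C", "G", "T")
  pair_ok <- function(a, p) {
    i <- a:(a + p - 1L); j <- i + p
    if (max(j) > n) return(FALSE)
    mean(ch[i] == ch[j] & base_ok[i] & base_ok[j]) >= minIdentity - 1e-12
  }
  arrays <- list()
  for (p in minUnit:min(maxUnit, n %/% 2L)) {
    a <- 1L
    for (a in seq_len(n - 2L * p + 1L)) {
      if (!pair_ok(a, p)) next
      if (a - p >= 1L && pair_ok(a - p, p)) next  # not left-maximal
      cpx <- 2L
      while (pair_ok(a + (cpx - 1L) * p, p)) cpx <- cpx + 1L
      ## consensus refinement as defined for >2 copies
      span_end <- a + cpx * p - 1L
      cps <- matrix(ch[a:span_end], nrow = p)
      if (cpx > 2L) {
        cons <- apply(cps, 1, function(z) names(which.max(table(z))))
        idents <- colMeans(cps == cons & matrix(cps %in% c("A","C","G","T"),
                                                nrow = p))
      } else idents <- rep(mean(ch[a:(a + p - 1L)] == ch[(a + p):(a + 2L * p - 1L)]), 2L)
      if (min(idents) < minIdentity - 1e-12) {
        keep <- which(idents >= minIdentity - 1e-12)
        if (length(keep) < 2L || any(diff(keep) != 1L)) next
        a2 <- a + (keep[1] - 1L) * p
        cpx <- length(keep)
        span_end <- a2 + cpx * p - 1L
        idents <- idents[keep]; a <- a2
      }
      arrays[[length(arrays) + 1L]] <- data.frame(
        start1 = a, end1 = span_end, unit_length = p, copies = cpx,
        identity = min(idents))
    }
  }
  if (!length(arrays)) return(NULL)
  out <- unique(do.call(rbind, arrays))
  ## canonical smallest period / longest span
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))) for (j in seq_len(nrow(out))) {
    if (i == j || !keep[i]) next
    if (out$start1[i] >= out$start1[j] && out$end1[i] <= out$end1[j] &&
        (out$unit_length[i] > out$unit_length[j] ||
         (out$unit_length[i] == out$unit_length[j] &&
          (out$end1[i] - out$start1[i]) < (out$end1[j] - out$start1[j]))))
      keep[i] <- FALSE
  }
  out <- out[keep, , drop = FALSE]
  ## merge overlapping same-unit arrays: most copies, identity, start
  res <- list()
  for (p in unique(out$unit_length)) {
    sub <- out[out$unit_length == p, , drop = FALSE]
    sub <- sub[order(sub$start1), , drop = FALSE]
    gid <- rep(1L, nrow(sub)); hi <- sub$end1[1]
    if (nrow(sub) > 1) for (i in 2:nrow(sub)) {
      gid[i] <- if (sub$start1[i] <= hi) gid[i - 1L] else gid[i - 1L] + 1L
      hi <- max(hi, sub$end1[i])
    }
    for (ix in split(seq_len(nrow(sub)), gid))
      res[[length(res) + 1L]] <-
        sub[ix[order(-sub$copies[ix], -sub$identity[ix], sub$start1[ix])][1], ,
            drop = FALSE]
  }
  out <- do.call(rbind, res)
  out <- out[order(out$start1, out$unit_length), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## Fitch length of one character by explicit enumeration of internal (and
## missing-tip) state assignments
oracle_fitch_char <- function(tree, states) {
  tree <- ape::unroot(tree)
  tl <- tree$tip.label
  st <- states[tl]
  alphabet <- unique(st[!st %in% c("?", "-", "N")])
  if (length(alphabet) <= 1L) return(0L)
  nt <- length(tl)
  free_tips <- which(st %in% c("?", "-", "N"))
  nodes <- (nt + 1L):(nt + tree$Nnode)
  vars <- c(free_tips, nodes)
  grid <- expand.grid(rep(list(alphabet), length(vars)),
                      stringsAsFactors = FALSE)
  assign_all <- character(nt + tree$Nnode)
  assign_all[seq_len(nt)] <- st
  best <- Inf
  for (r in seq_len(nrow(grid))) {
    assign_all[vars] <- unlist(grid[r, ], use.names = FALSE)
    changes <- sum(assign_all[tree$edge[, 1]] != assign_all[tree$edge[, 2]])
    if (changes < best) best <- changes
  }
  best
}

oracle_fitch <- function(tree, M) {
  mat <- characterStates(M)
  sum(vapply(seq_len(ncol(mat)), function(j)
    oracle_fitch_char(tree, stats::setNames(mat[, j], rownames(mat))),
    numeric(1)))
}

## all unrooted binary topologies by recursive edge insertion (independent
## of phangorn::allTrees)
oracle_all_topologies <- function(labels) {
  base <- ape::read.tree(text = sprintf("(%s,%s,%s);", labels[1], labels[2],
                                        labels[3]))
  trees <- list(base)
  one_tip <- structure(list(edge = matrix(c(2L, 1L), 1), tip.label = "x",
                            Nnode = 1L, edge.length = 1), class = "phylo")
  for (tip in labels[-(1:3)]) {
    one_tip$tip.label <- tip
    nxt <- list()
    for (tr in trees) {
      tr$edge.length <- rep(1, nrow(tr$edge))
      for (e in seq_len(nrow(tr$edge))) {
        t2 <- ape::bind.tree(tr, one_tip, where = tr$edge[e, 2],
                             position = 0.5)
        t2$edge.length <- NULL
        nxt[[length(nxt) + 1L]] <- t2
      }
    }
    trees <- nxt
  }
  trees
}

## toy alignment constructor
aln_mat <- function(...) {
  v <- c(...)
  do.call(rbind, stats::setNames(strsplit(toupper(v), ""), names(v)))
}

## normalized motif signature for set comparisons
motif_sig <- function(df, cols = c("start1", "end1", "start2", "end2",
                                   "unit_length")) {
  if (is.null(df) || !nrow(df)) return(character())
  unname(sort(apply(df[, intersect(cols, names(df)), drop = FALSE], 1, paste,
                    collapse = ":")))
}
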