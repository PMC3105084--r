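#' @include AllClasses.R
#' @importFrom ape read.tree write.tree root
NULL

## symbol -> bitmask encoding; '?', '-' and 'N' are wildcards (missing).
## DNA and binary characters can share a matrix (mixed indel-extended data).
.STATE_BITS <- c(A = 1L, C = 2L, G = 4L, T = 8L, "0" = 16L, "1" = 32L)
.WILDCARD <- 63L

.encode_states <- function(M) {
  mat <- characterStates(M)
  enc <- matrix(.WILDCARD, nrow(mat), ncol(mat),
                dimnames = list(rownames(mat), NULL))
  for (s in names(.STATE_BITS)) enc[mat == s] <- .STATE_BITS[[s]]
  enc
}

## Fitch bottom-up pass, vectorized over characters. Expects a binary
## (or trifurcating-root) tree; returns per-character change counts.
.fitch_counts <- function(tree, enc) {
  nt <- length(tree$tip.label)
  idx <- match(tree$tip.label, rownames(enc))
  if (anyNA(idx)) stop("tree taxa absent from the character matrix")
  tree <- stats::reorder(tree, "postorder")
  nnode <- tree$Nnode
  nchar_ <- ncol(enc)
  states <- matrix(0L, nt + nnode, nchar_)
  states[seq_len(nt), ] <- enc[idx, , drop = FALSE]
  filled <- c(rep(TRUE, nt), rep(FALSE, nnode))
  steps <- numeric(nchar_)
  e <- tree$edge
  for (k in seq_len(nrow(e))) {
    child <- e[k, 2]; parent <- e[k, 1]
    if (!filled[parent]) {
      states[parent, ] <- states[child, ]
      filled[parent] <- TRUE
    } else {
      inter <- bitwAnd(states[parent, ], states[child, ])
      empty <- inter == 0L
      steps[empty] <- steps[empty] + 1
      inter[empty] <- bitwOr(states[parent, empty], states[child, empty])
      states[parent, ] <- inter
    }
  }
  steps
}

#' Fitch parsimony tree length
#'
#' Minimum number of unordered state changes required by a character matrix
#' on a tree, summed over characters (Fitch bottom-up pass). \code{?},
#' \code{-} and \code{N} are wildcards. The length is invariant to rooting
#' and taxon order.
#'
#' @param tree an \code{ape} \code{phylo} (rooted or unrooted)
#' @param M a \linkS4class{CharacterMatrix}
#' @param perCharacter return the per-character change counts instead of
#'   the sum
#' @return tree length (or numeric vector of per-character steps)
#' @export
fitchLength <- function(tree, M, perCharacter = FALSE) {
  enc <- .encode_states(M)
  steps <- .fitch_counts(tree, enc)
  if (perCharacter) steps else sum(steps)
}

## per-character minimum (m) and maximum (g) conceivable steps on any tree
.char_bounds <- function(M) {
  mat <- characterStates(M)
  miss <- mat %in% c("?", "-", "N")
  dim(miss) <- dim(mat)
  m <- g <- numeric(ncol(mat))
  for (j in seq_len(ncol(mat))) {
    obs <- mat[!miss[, j], j]
    if (!length(obs)) { m[j] <- 0; g[j] <- 0; next }
    tab <- table(obs)
    m[j] <- length(tab) - 1L
    g[j] <- length(obs) - max(tab)
  }
  list(m = m, g = g)
}

#' Parsimony score with ensemble CI and RI
#'
#' Scores a tree and reports the ensemble consistency index CI = m/s and
#' retention index RI = (g-s)/(g-m), where m and g are the sums over
#' characters of the minimum and maximum conceivable steps. Following the
#' convention of the classic parsimony programs, parsimony-uninformative
#' characters are included in the sums.
#'
#' @inheritParams fitchLength
#' @return a \linkS4class{ParsimonyScore}
#' @export
scoreStats <- function(tree, M) {
  s <- fitchLength(tree, M)
  b <- .char_bounds(M)
  m <- sum(b$m); g <- sum(b$g)
  new("ParsimonyScore", steps = s, minSteps = m, maxSteps = g,
      ci = if (s > 0) m / s else NA_real_,
      ri = if (g > m) (g - s) / (g - m) else NA_real_)
}

#' Exhaustive maximum-parsimony tree search
#'
#' Enumerates every unrooted binary topology (via
#' \code{phangorn::allTrees}) and returns all minimum-length trees. Capped
#' at 9 taxa (135,135 topologies); larger matrices are directed to
#' \code{\link{heuristicSearch}}.
#'
#' @param M a \linkS4class{CharacterMatrix}
#' @return list: \code{trees} (multiPhylo of all optima), \code{score}
#'   (\linkS4class{ParsimonyScore} of the optimum), \code{lengths}
#'   (lengths of all enumerated topologies)
#' @export
exhaustiveSearch <- function(M) {
  tx <- taxa(M)
  n <- length(tx)
  if (n < 4L || n > 9L)
    stop("exhaustive search supports 4-9 taxa; use heuristicSearch() for more")
  enc <- .encode_states(M)
  all_t <- phangorn::allTrees(n, rooted = FALSE, tip.label = tx)
  lens <- vapply(all_t, function(t) sum(.fitch_counts(t, enc)), numeric(1))
  best <- which(lens == min(lens))
  opt <- all_t[best]
  class(opt) <- "multiPhylo"
  list(trees = opt, score = scoreStats(opt[[1]], M), lengths = lens)
}

#' Heuristic maximum-parsimony search (stepwise addition + NNI)
#'
#' For matrices beyond the exhaustive cap: taxa are added stepwise at the
#' best edge, then nearest-neighbour interchanges are applied until no
#' rearrangement shortens the tree.
#'
#' @param M a \linkS4class{CharacterMatrix}
#' @param seed optional seed controlling the randomized addition orders
#' @param restarts number of random addition orders (the first restart uses
#'   the matrix order)
#' @return list with \code{tree} and \code{score}
#' @export
heuristicSearch <- function(M, seed = NULL, restarts = 5) {
  tx <- taxa(M)
  if (length(tx) < 4L) stop("need at least 4 taxa")
  enc <- .encode_states(M)
  one_tip <- structure(list(edge = matrix(c(2L, 1L), 1),
                            tip.label = "zzz", Nnode = 1L,
                            edge.length = 1),
                       class = "phylo")
  one_round <- function(ord) {
    tree <- read.tree(text = sprintf("(%s,%s,%s);", ord[1], ord[2], ord[3]))
    for (tip in ord[-(1:3)]) {
      one_tip$tip.label <- tip
      tree$edge.length <- rep(1, nrow(tree$edge))
      cands <- lapply(seq_len(nrow(tree$edge)), function(e)
        ape::bind.tree(tree, one_tip, where = tree$edge[e, 2], position = 0.5))
      lens <- vapply(cands, function(t) sum(.fitch_counts(t, enc)), numeric(1))
      tree <- cands[[which.min(lens)]]
      tree$edge.length <- NULL
    }
    best_len <- sum(.fitch_counts(tree, enc))
    repeat {   # NNI hill climb
      nb <- phangorn::nni(tree)
      lens <- vapply(nb, function(t) sum(.fitch_counts(t, enc)), numeric(1))
      if (min(lens) >= best_len) break
      tree <- nb[[which.min(lens)]]
      best_len <- min(lens)
    }
    list(tree = tree, len = best_len)
  }
  .with_seed(seed, {
    best <- one_round(tx)
    for (r in seq_len(max(0, restarts - 1))) {
      cand <- one_round(sample(tx))
      if (cand$len < best$len) best <- cand
    }
    list(tree = best$tree, score = scoreStats(best$tree, M))
  })
}

## nontrivial bipartitions of an unrooted tree, canonicalized as the sorted
## taxon set on the side not containing the reference (first alphabetical)
## taxon, collapsed to a string
.bipartitions <- function(tree) {
  tx <- sort(tree$tip.label)
  ref <- tx[1]
  nt <- length(tree$tip.label)
  tree <- stats::reorder(tree, "postorder")
  desc <- vector("list", nt + tree$Nnode)
  for (i in seq_len(nt)) desc[[i]] <- tree$tip.label[i]
  for (k in seq_len(nrow(tree$edge))) {
    p <- tree$edge[k, 1]; c_ <- tree$edge[k, 2]
    desc[[p]] <- c(desc[[p]], desc[[c_]])
  }
  out <- character()
  for (k in seq_len(nrow(tree$edge))) {
    c_ <- tree$edge[k, 2]
    if (c_ <= nt) next
    side <- desc[[c_]]
    if (ref %in% side) side <- setdiff(tx, side)
    if (length(side) >= 2L && length(side) <= nt - 2L)
      out <- c(out, paste(sort(side), collapse = "|"))
  }
  unique(out)
}

#' Nonparametric bootstrap support for parsimony bipartitions
#'
#' Characters are resampled with replacement; each replicate matrix is
#' searched (exhaustively up to 9 taxa), and a bipartition scores a
#' replicate when it appears in the strict consensus of that replicate's
#' optimal trees. Support is the percentage of replicates.
#'
#' @param M a \linkS4class{CharacterMatrix}
#' @param reps number of bootstrap replicates
#' @param seed RNG seed (required, for reproducibility)
#' @return named numeric vector: support percentage per bipartition
#'   (names are \code{|}-separated taxon sets)
#' @export
bootstrapSupport <- function(M, reps = 1000, seed) {
  if (missing(seed)) stop("a seed is required for bootstrap resampling")
  mat <- characterStates(M)
  counts <- new.env(parent = emptyenv())
  .with_seed(seed, {
    for (r in seq_len(reps)) {
      cols <- sample.int(ncol(mat), replace = TRUE)
      Mr <- characterMatrix(mat[, cols, drop = FALSE], M@type)
      res <- if (length(taxa(M)) <= 9L) exhaustiveSearch(Mr)
      else list(trees = list(heuristicSearch(Mr)$tree))
      bip <- Reduce(intersect, lapply(res$trees, .bipartitions))
      for (b in bip)
        assign(b, (if (exists(b, counts)) get(b, counts) else 0) + 1, counts)
    }
  })
  out <- vapply(ls(counts), function(b) 100 * get(b, counts) / reps, numeric(1))
  sort(out, decreasing = TRUE)
}

#' Map a binary character onto a reference tree
#'
#' Counts the independent origins of the derived state by Fitch scoring the
#' single character on the tree, polarizes it against the outgroup (the
#' outgroup is assumed to carry the ancestral state), and classifies it as
#' synapomorphic (single origin) or homoplasious.
#'
#' @param tree reference topology (\code{phylo})
#' @param states named character vector of \code{0/1} (\code{?} missing)
#'   over the tree's taxa
#' @param outgroup outgroup taxon name
#' @return list: \code{origins}, \code{classification}, \code{derived_state},
#'   \code{derived_taxa}, \code{polarity} (\code{+} insertion / \code{-}
#'   deletion for gap characters where 1 encodes the gap; \code{NA} when the
#'   outgroup state is missing)
#' @export
mapCharacter <- function(tree, states, outgroup) {
  if (!outgroup %in% tree$tip.label) stop("outgroup not on the tree")
  if (is.null(names(states))) stop("states must be named by taxon")
  M <- characterMatrix(matrix(states, ncol = 1,
                              dimnames = list(names(states), NULL)), "binary")
  origins <- fitchLength(tree, M)
  og <- states[[outgroup]]
  if (og %in% c("?", "-", "N")) {
    derived <- NA_character_
    polarity <- NA_character_
    derived_taxa <- character()
  } else {
    derived <- if (og == "0") "1" else "0"
    derived_taxa <- setdiff(names(states)[states == derived], outgroup)
    ## convention for indel characters: state 1 = gap present; a derived
    ## gap is a deletion, a derived non-gap (outgroup gapped) an insertion
    polarity <- if (derived == "1") "-" else "+"
  }
  list(origins = origins,
       classification = if (is.na(origins)) NA_character_
         else if (origins == 1) "synapomorphic" else "homoplasious",
       derived_state = derived, derived_taxa = derived_taxa,
       polarity = polarity)
}

#' Strict consensus of a set of trees
#'
#' @param trees multiPhylo or list of phylo
#' @return a phylo containing only the bipartitions common to all trees
#' @export
strictConsensus <- function(trees) ape::consensus(trees, p = 1)

## ---- matrix I/O -------------------------------------------------------

#' Character matrix readers and writers (NEXUS / PHYLIP)
#'
#' Minimal, standards-conforming writers and readers for discrete
#' character matrices; reading NEXUS delegates to
#' \code{ape::read.nexus.data}.
#'
#' @param M a \linkS4class{CharacterMatrix}
#' @param path file path
#' @name matrixIO
NULL

#' @rdname matrixIO
#' @export
writeNexusMatrix <- function(M, path) {
  mat <- characterStates(M)
  dt <- if (M@type == "dna") "DNA" else "STANDARD"
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("#NEXUS", "BEGIN DATA;",
               sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", nrow(mat), ncol(mat)),
               sprintf("  FORMAT DATATYPE=%s MISSING=? GAP=-;", dt),
               "  MATRIX"), con)
  for (i in seq_len(nrow(mat)))
    writeLines(sprintf("  %-12s %s", rownames(mat)[i],
                       paste(mat[i, ], collapse = "")), con)
  writeLines(c("  ;", "END;"), con)
  invisible(path)
}

#' @rdname matrixIO
#' @export
readNexusMatrix <- function(path) {
  d <- ape::read.nexus.data(path)
  mat <- do.call(rbind, lapply(d, toupper))
  rownames(mat) <- names(d)
  characterMatrix(mat)
}

#' @rdname matrixIO
#' @export
writePhylipMatrix <- function(M, path) {
  mat <- characterStates(M)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("%d %d", nrow(mat), ncol(mat)), con)
  for (i in seq_len(nrow(mat)))
    writeLines(sprintf("%-12s%s", rownames(mat)[i],
                       paste(mat[i, ], collapse = "")), con)
  invisible(path)
}

#' @rdname matrixIO
#' @export
readPhylipMatrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
  rows <- lines[-1]
  nm <- trimws(substr(rows, 1, 12))
  states <- gsub("\\s", "", substring(rows, 13))
  mat <- do.call(rbind, strsplit(toupper(states), "", fixed = TRUE))
  rownames(mat) <- nm
  if (nrow(mat) != hdr[1] || ncol(mat) != hdr[2])
    stop("PHYLIP dimensions do not match the header")
  characterMatrix(mat)
}
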