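#' @include AllClasses.R
NULL

#' Read an aligned FASTA file
#'
#' @param path aligned FASTA
#' @return character matrix (taxa x columns) as used by the divergence
#'   functions
#' @export
readAlignedFasta <- function(path) {
  ss <- readDNAStringSet(path)
  .as_aln_matrix(ss)
}

#' Pairwise p-distances with group summaries
#'
#' Uncorrected p-distance per pair: the proportion of differing sites after
#' pairwise deletion of every column holding a gap or ambiguous base in
#' either sequence (the convention of the classic distance programs).
#' Group means are arithmetic means of the relevant pairwise values.
#'
#' @param aln alignment (character matrix, named character vector or
#'   \code{DNAStringSet})
#' @param groups optional named character vector assigning each taxon to a
#'   group
#' @return a \linkS4class{DistanceSummary}
#' @export
pDistance <- function(aln, groups = NULL) {
  m <- .as_aln_matrix(aln)
  if (nrow(m) < 2L) stop("need at least two sequences")
  nt <- nrow(m)
  valid <- matrix(.is_base(m), nrow = nt)
  d <- matrix(0, nt, nt, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(nt - 1L)) for (j in (i + 1L):nt) {
    comp <- valid[i, ] & valid[j, ]
    ncomp <- sum(comp)
    if (ncomp == 0L) {
      warning("no comparable sites between ", rownames(m)[i], " and ",
              rownames(m)[j])
      d[i, j] <- d[j, i] <- NA_real_
    } else {
      d[i, j] <- d[j, i] <- sum(m[i, comp] != m[j, comp]) / ncomp
    }
  }
  pairs <- d[upper.tri(d)]
  overall <- mean(pairs, na.rm = TRUE)
  within <- numeric(0); between <- NA_real_; grp <- character(0)
  if (!is.null(groups)) {
    grp <- groups[rownames(m)]
    if (anyNA(grp)) stop("groups must cover all taxa")
    gi <- matrix(grp[rep(seq_len(nt), nt)], nt)  # row index group
    same <- outer(grp, grp, "==")
    within <- vapply(unique(grp), function(g) {
      sel <- outer(grp == g, grp == g, "&") & upper.tri(d)
      if (!any(sel)) NA_real_ else mean(d[sel], na.rm = TRUE)
    }, numeric(1))
    bsel <- !same & upper.tri(d)
    between <- if (any(bsel)) mean(d[bsel], na.rm = TRUE) else NA_real_
  }
  new("DistanceSummary", dist = d, overall = overall, within = within,
      between = between, groups = if (length(grp)) grp else character(0))
}

#' Sliding-window identity profile against a reference
#'
#' Identity of every other taxon against a reference, in windows on
#' reference-anchored coordinates: columns gapped in the reference are
#' collapsed first, and a gap in the other taxon counts as a mismatch.
#' This is the plain-numbers equivalent of a VISTA identity plot.
#'
#' @param aln alignment input
#' @param reference reference taxon name
#' @param window window size (bp of the ungapped reference)
#' @param step step between window starts
#' @return data.frame: \code{taxon}, \code{start}, \code{end},
#'   \code{identity} (percent)
#' @export
identityProfile <- function(aln, reference, window = 100, step = 25) {
  m <- .as_aln_matrix(aln)
  if (!reference %in% rownames(m)) stop("reference not in alignment")
  keep <- !.is_gapchar(m[reference, ])
  m <- m[, keep, drop = FALSE]
  L <- ncol(m)
  if (window > L) window <- L
  starts <- seq(1L, max(1L, L - window + 1L), by = step)
  others <- setdiff(rownames(m), reference)
  eq <- m[others, , drop = FALSE] == matrix(m[reference, ], length(others),
                                            L, byrow = TRUE)
  out <- list()
  for (s in starts) {
    e <- min(L, s + window - 1L)
    ident <- 100 * rowSums(eq[, s:e, drop = FALSE]) / (e - s + 1L)
    out[[length(out) + 1L]] <- data.frame(taxon = others, start = s, end = e,
                                          identity = unname(ident))
  }
  do.call(rbind, out)
}

## maximal gap runs per row: distinct (start, end) pairs and which taxa
## carry each
.gap_runs <- function(m) {
  runs <- list()
  for (i in seq_len(nrow(m))) {
    r <- rle(m[i, ] == "-")
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    sel <- which(r$values)
    for (k in sel) {
      key <- paste(starts[k], ends[k], sep = "-")
      runs[[key]] <- c(runs[[key]], rownames(m)[i])
    }
  }
  runs
}

#' Per-region alignment variability statistics
#'
#' Computes, for one region alignment: the aligned length L, the number of
#' nucleotide substitutions NS (each variable column contributes its number
#' of distinct non-gap states minus one, the minimal-change count), the
#' number of indel events ID (distinct maximal gap runs; runs with
#' identical start and end shared by several taxa collapse to one event),
#' variable and parsimony-informative site counts, and the proportion of
#' mutation events, variation\% = 100 (NS + ID) / L. With
#' \code{countIndels = FALSE} (substitutions-only mode) ID is not counted.
#'
#' @param aln region alignment
#' @param countIndels score indel events as well as substitutions
#' @param name,class optional region name and class carried into the output
#' @return one-row data.frame: \code{name}, \code{class}, \code{L},
#'   \code{NS}, \code{ID}, \code{variable_sites}, \code{PI_sites},
#'   \code{variation_percent}, \code{PI_percent}
#' @export
regionVariability <- function(aln, countIndels = TRUE, name = "region",
                              class = NA_character_) {
  m <- .as_aln_matrix(aln)
  L <- ncol(m)
  if (L == 0L) stop("empty alignment")
  NS <- 0L; varsites <- 0L; pis <- 0L
  for (j in seq_len(L)) {
    col <- m[, j]
    col <- col[.is_base(col)]
    if (!length(col)) next
    tab <- table(col)
    if (length(tab) >= 2L) {
      varsites <- varsites + 1L
      NS <- NS + length(tab) - 1L
      if (sum(tab >= 2L) >= 2L) pis <- pis + 1L
    }
  }
  ID <- if (countIndels) length(.gap_runs(m)) else 0L
  data.frame(name = name, class = class, L = L, NS = NS, ID = ID,
             variable_sites = varsites, PI_sites = pis,
             variation_percent = 100 * (NS + ID) / L,
             PI_percent = 100 * pis / L)
}

#' Rank candidate markers by variability
#'
#' Sorts region statistics by variation\% (descending; ties broken by
#' PI\% then name) and returns the top \code{k} regions, with counts of
#' how many exceed the conventional marker thresholds (variation\% > 4,
#' PI\% > 3) attached as attributes.
#'
#' @param stats data.frame of rows from \code{\link{regionVariability}}
#' @param k number of markers to keep
#' @return ranked data.frame with a \code{rank} column; attributes
#'   \code{n_variation_gt4} and \code{n_pi_gt3}
#' @export
rankMarkers <- function(stats, k = 20) {
  o <- order(-stats$variation_percent, -stats$PI_percent, stats$name)
  ranked <- stats[o, , drop = FALSE]
  ranked$rank <- seq_len(nrow(ranked))
  out <- ranked[seq_len(min(k, nrow(ranked))), , drop = FALSE]
  attr(out, "n_variation_gt4") <- sum(stats$variation_percent > 4)
  attr(out, "n_pi_gt3") <- sum(stats$variation_percent > 4 & stats$PI_percent > 3)
  rownames(out) <- NULL
  out
}

#' Ordinary least-squares fit of PI\% against variable-site \%
#'
#' @param x predictor (e.g. percentage of variable sites)
#' @param y response (e.g. percentage of parsimony-informative sites)
#' @return list: \code{slope}, \code{intercept}, \code{r_squared},
#'   \code{p_value} (two-sided, for the slope)
#' @export
fitLinear <- function(x, y) {
  if (length(x) < 3L) stop("need at least three points")
  if (stats::var(x) == 0) stop("zero variance in x")
  fit <- stats::lm(y ~ x)
  sm <- suppressWarnings(summary(fit))  # silence the perfect-fit warning
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = sm$r.squared,
       p_value = unname(sm$coefficients[2, 4]))
}

#' Per-subfamily region variability table
#'
#' Substitutions-only variation\% per homologous region per group
#' (subfamily), for comparing how the same region evolves in different
#' lineages. Regions absent from a group yield \code{NA}.
#'
#' @param alignments nested list: \code{alignments[[group]][[region]]} is a
#'   region alignment
#' @param minLen regions shorter than this (aligned length) are skipped
#' @return data.frame region x group of variation percentages
#' @export
subfamilyProfiles <- function(alignments, minLen = 200) {
  groups <- names(alignments)
  regions <- unique(unlist(lapply(alignments, names)))
  out <- data.frame(region = regions)
  for (g in groups) {
    v <- vapply(regions, function(r) {
      a <- alignments[[g]][[r]]
      if (is.null(a)) return(NA_real_)
      m <- .as_aln_matrix(a)
      if (ncol(m) < minLen) return(NA_real_)
      regionVariability(m, countIndels = FALSE, name = r)$variation_percent
    }, numeric(1))
    out[[g]] <- v
  }
  out
}
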