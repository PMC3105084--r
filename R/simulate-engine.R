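#' @include simulate.R
NULL

.sample_bases <- function(n, gc) {
  sample(DNA_BASES, n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

## replacement base under the configured model, vectorized over hits
.draw_new_base <- function(old, cfg) {
  if (!length(old)) return(character())
  pi <- c(A = (1 - cfg$gc) / 2, C = cfg$gc / 2, G = cfg$gc / 2,
          T = (1 - cfg$gc) / 2)
  rates <- matrix(1, 4, 4, dimnames = list(DNA_BASES, DNA_BASES))
  if (cfg$model == "K2P") {
    rates["A", "G"] <- rates["G", "A"] <- cfg$kappa
    rates["C", "T"] <- rates["T", "C"] <- cfg$kappa
  } else if (cfg$model == "GTR") {
    r <- cfg$gtrRates
    rates["A", "C"] <- rates["C", "A"] <- r[["AC"]]
    rates["A", "G"] <- rates["G", "A"] <- r[["AG"]]
    rates["A", "T"] <- rates["T", "A"] <- r[["AT"]]
    rates["C", "G"] <- rates["G", "C"] <- r[["CG"]]
    rates["C", "T"] <- rates["T", "C"] <- r[["CT"]]
    rates["G", "T"] <- rates["T", "G"] <- r[["GT"]]
  }
  if (cfg$model != "JC") rates <- sweep(rates, 2, pi, "*")
  diag(rates) <- 0
  vapply(old, function(b) {
    if (!b %in% DNA_BASES) return(.sample_bases(1L, cfg$gc))
    sample(DNA_BASES, 1L, prob = rates[b, ])
  }, "", USE.NAMES = FALSE)
}

## ---- root construction ------------------------------------------------

.build_root <- function(cfg) {
  arch <- cfg$arch
  L <- arch$lengths[["total"]]
  base <- .sample_bases(L, cfg$gc)
  irb <- arch$irb; ira <- arch$ira
  base[ira[1]:ira[2]] <- .revcomp_chars(base[irb[1]:irb[2]])
  ## break mirror symmetry at the SSC boundaries so the detected IR cannot
  ## extend into the SSC by chance
  ssc <- arch$ssc
  if (base[ssc[1]] == .complement_chars(base[ssc[2]]))
    base[ssc[1]] <- setdiff(DNA_BASES,
                            .complement_chars(base[ssc[2]]))[1]

  regions <- .sim_regions(cfg)
  regions$id <- seq_len(nrow(regions))
  ov <- function(s, e, iv) pmin(e, iv[2]) >= pmax(s, iv[1])
  regions$in_ir <- ov(regions$start, regions$end, irb) |
    ov(regions$start, regions$end, ira)

  rid <- integer(L)
  for (i in seq_len(nrow(regions)))
    rid[regions$start[i]:regions$end[i]] <- regions$id[i]

  ## planted root repeats, written into spacers by overwriting (length
  ## preserved); one spacer is used per repeat
  spacers <- regions[regions$class == "noncoding" & !regions$in_ir &
                       regions$length >= 160 &
                       !grepl("intron", regions$name), , drop = FALSE]
  spacers <- spacers[order(-spacers$length), , drop = FALSE]
  root_repeats <- list()
  used <- integer()
  pick_spacer <- function(minlen) {
    ok <- setdiff(spacers$id[spacers$length >= minlen], used)
    if (!length(ok)) return(NA_integer_)
    if (length(ok) == 1L) ok else sample(ok, 1L)
  }
  if (cfg$rootRepeats > 0) {
    types <- rep(c("tandem", "dispersed", "palindromic"),
                 length.out = cfg$rootRepeats)
    for (ty in types) {
      if (ty == "tandem") {
        u <- sample(15:45, 1L)
        sid <- pick_spacer(2L * u + 20L)
        if (is.na(sid)) next
        r <- regions[regions$id == sid, ]
        p <- r$start + 5L
        base[(p + u):(p + 2L * u - 1L)] <- base[p:(p + u - 1L)]
        root_repeats[[length(root_repeats) + 1L]] <- data.frame(
          type = ty, unit = u, region = r$name, pos = p)
        used <- c(used, sid)
      } else if (ty == "dispersed") {
        u <- sample(30:70, 1L)
        sid <- pick_spacer(u + 20L)
        used <- c(used, sid)
        tid <- pick_spacer(u + 20L)
        if (is.na(sid) || is.na(tid)) next
        rs <- regions[regions$id == sid, ]; rt <- regions[regions$id == tid, ]
        p <- rs$start + 5L; q <- rt$start + 5L
        base[q:(q + u - 1L)] <- base[p:(p + u - 1L)]
        root_repeats[[length(root_repeats) + 1L]] <- data.frame(
          type = ty, unit = u, region = paste(rs$name, rt$name, sep = "~"),
          pos = p)
        used <- c(used, sid, tid)
      } else {
        a <- sample(20:25, 1L); gp <- sample(40:200, 1L)
        sid <- pick_spacer(2L * a + gp + 20L)
        if (is.na(sid)) next
        r <- regions[regions$id == sid, ]
        p <- r$start + 5L; q <- p + a + gp
        base[q:(q + a - 1L)] <- .revcomp_chars(base[p:(p + a - 1L)])
        root_repeats[[length(root_repeats) + 1L]] <- data.frame(
          type = ty, unit = a, region = r$name, pos = p)
        used <- c(used, sid)
      }
    }
  }

  ## planted inversion constructs: arm + segment + revcomp(arm), protected
  ## from indels via their own region entries
  inv_truth <- list()
  for (k in seq_along(cfg$inversions)) {
    iv <- cfg$inversions[[k]]
    r <- regions[regions$name == iv$spacer & regions$class == "noncoding", ]
    if (!nrow(r)) stop("inversion spacer not in architecture: ", iv$spacer)
    r <- r[1, ]
    need <- 2L * iv$armLength + iv$segmentLength + 10L
    if (r$length < need) stop("spacer too short for inversion construct")
    p <- r$start + (r$length - need) %/% 2L
    a <- iv$armLength; sg <- iv$segmentLength
    base[(p + a + sg):(p + 2L * a + sg - 1L)] <-
      .revcomp_chars(base[p:(p + a - 1L)])
    newid <- nrow(regions) + 1L
    regions <- rbind(regions, data.frame(
      name = paste0("inv:", iv$spacer), class = "noncoding",
      start = p, end = p + 2L * a + sg - 1L, length = need - 10L,
      genome = "root", id = newid, in_ir = FALSE))
    rid[p:(p + 2L * a + sg - 1L)] <- newid
    inv_truth[[k]] <- list(spacer = iv$spacer, arm = a, segment = sg,
                           seg_keys = c(p + a, p + a + sg - 1L),
                           arm1 = c(p, p + a - 1L),
                           arm2 = c(p + a + sg, p + 2L * a + sg - 1L),
                           branch = iv$branch)
  }

  ## per-region lookup tables (index rid + 1; slot 1 = background noncoding)
  nr <- nrow(regions)
  hot <- function(nm) {
    h <- cfg$hotRegions
    if (is.null(h)) return(rep(1, length(nm)))
    ifelse(nm %in% names(h), unname(h[nm]), 1)
  }
  ratef <- c(cfg$noncodingFactor,
             ifelse(regions$class == "coding", cfg$codingFactor,
                    cfg$noncodingFactor) * hot(regions$name))
  ## normalize the class factors (hot multipliers excluded) so the
  ## genome-wide mean substitution rate is 1 per unit branch length and
  ## branch lengths stay on the p-distance scale; IRb events count twice
  ## because mirroring changes both arms
  basef <- c(cfg$noncodingFactor,
             ifelse(regions$class == "coding", cfg$codingFactor,
                    cfg$noncodingFactor))[rid + 1L]
  basef[seq(ira[1], ira[2])] <- 0
  basef[seq(irb[1], irb[2])] <- basef[seq(irb[1], irb[2])] * cfg$irFactor
  rate_norm <- (sum(basef) + sum(basef[seq(irb[1], irb[2])])) / L
  if (rate_norm == 0) rate_norm <- 1   # zero-rate configs stay zero-rate
  protected <- grepl("^inv:", regions$name)
  iw <- c(1, ifelse(regions$in_ir | protected, 0,
                    ifelse(regions$class == "coding", 0.2, 1)) *
              hot(regions$name))
  iclass <- c(1L, ifelse(regions$in_ir | protected, 0L,
                         ifelse(regions$class == "coding", 2L, 1L)))
  list(node = list(key = as.numeric(seq_len(L)), base = base, rid = rid),
       regions = regions, ratef = ratef, rate_norm = rate_norm,
       iw = iw, iclass = iclass,
       root_repeats = if (length(root_repeats)) do.call(rbind, root_repeats)
         else NULL,
       inversions = inv_truth)
}

## ---- branch evolution -------------------------------------------------

.evolve_branch <- function(node, bl, edge_idx, env, cfg) {
  arch <- cfg$arch
  irb <- arch$irb; ira <- arch$ira
  key <- node$key; base <- node$base; rid <- node$rid
  ev <- list(substitutions = 0L, insertions = 0L, deletions = 0L,
             net_length = 0L, repeat_gains = NULL)

  ## substitutions (IRa silent; IRb events mirrored into IRa)
  f <- env$ratef[rid + 1L] / env$rate_norm
  in_ira <- key >= ira[1] & key <= ira[2]
  in_irb <- key >= irb[1] & key <= irb[2]
  f[in_ira] <- 0
  f[in_irb] <- f[in_irb] * cfg$irFactor
  nsub <- stats::rpois(1L, bl * sum(f))
  if (nsub > 0) {
    hits <- sample.int(length(key), nsub, replace = TRUE, prob = f)
    newb <- .draw_new_base(base[hits], cfg)
    base[hits] <- newb
    mir <- which(in_irb[hits])
    if (length(mir)) {
      pk <- ira[1] + (irb[2] - key[hits[mir]])
      pcol <- match(pk, key)
      base[pcol] <- .complement_chars(newb[mir])
    }
    ev$substitutions <- nsub
  }

  ## indels (single-copy only; exon indels keep frame)
  w <- env$iw[rid + 1L]
  w[in_ira | in_irb] <- 0          # the IR receives no indels
  ic <- env$iclass[rid + 1L]
  nind <- stats::rpois(1L, bl * cfg$indelRate * sum(w))
  p_geom <- 1 / cfg$indelMeanLen
  for (dummy in seq_len(nind)) {
    i <- sample.int(length(key), 1L, prob = w)
    exon <- ic[i] == 2L
    len <- if (exon) 3L * (1L + stats::rgeom(1L, 0.5))
           else 1L + stats::rgeom(1L, p_geom)
    if (stats::runif(1) < 0.5) {
      ## deletion clamped to the current region run
      jmax <- i
      while (jmax < length(key) && jmax - i + 1L < len &&
             rid[jmax + 1L] == rid[i]) jmax <- jmax + 1L
      del <- i:jmax
      key <- key[-del]; base <- base[-del]; rid <- rid[-del]
      w <- w[-del]; ic <- ic[-del]
      ev$deletions <- ev$deletions + 1L
      ev$net_length <- ev$net_length - length(del)
    } else {
      nb <- if (exon) .sample_bases(len, cfg$gc) else .sample_bases(len, cfg$gc)
      hi <- if (i < length(key)) key[i + 1L] else key[i] + 1
      nk <- key[i] + seq_len(len) * (hi - key[i]) / (len + 1)
      ins <- function(v, x) c(v[seq_len(i)], x, v[-seq_len(i)])
      key <- ins(key, nk); base <- ins(base, nb); rid <- ins(rid, rep(rid[i], len))
      w <- ins(w, rep(w[i], len)); ic <- ins(ic, rep(ic[i], len))
      ev$insertions <- ev$insertions + 1L
      ev$net_length <- ev$net_length + len
    }
  }

  ## repeat gains: insert a new duplication into a single-copy spacer
  ngain <- stats::rpois(1L, bl * cfg$repeatBirthRate)
  gains <- list()
  if (ngain > 0) {
    spacer_ids <- env$regions$id[env$regions$class == "noncoding" &
                                   !env$regions$in_ir &
                                   !grepl("^inv:", env$regions$name) &
                                   !grepl("intron", env$regions$name)]
    for (gidx in seq_len(ngain)) {
      ty <- sample(c("tandem", "dispersed", "palindromic"), 1L,
                   prob = c(0.40, 0.35, 0.25))
      ## current runs of spacer columns
      counts <- tabulate(rid + 1L, nbins = max(rid) + 1L)
      cand <- spacer_ids[counts[spacer_ids + 1L] >= 160L]
      if (!length(cand)) next
      tgt <- if (length(cand) == 1L) cand else sample(cand, 1L)
      cols <- which(rid == tgt)
      u <- switch(ty, tandem = sample(15:45, 1L),
                  dispersed = sample(30:70, 1L),
                  palindromic = sample(20:25, 1L))
      if (length(cols) < 2L * u + 80L) next
      ## random anchor inside the spacer, away from its edges
      io <- sample.int(length(cols) - 2L * u - 70L, 1L) + 4L
      p <- cols[io]
      src <- switch(ty, tandem = , palindromic = p, dispersed = {
        oth <- setdiff(spacer_ids[counts[spacer_ids + 1L] >= u + 20L], tgt)
        if (!length(oth)) next
        osp <- if (length(oth) == 1L) oth else sample(oth, 1L)
        which(rid == osp)[5L]
      })
      unit <- base[src:(src + u - 1L)]
      insert_at <- if (ty == "tandem") p + u - 1L
        else if (ty == "dispersed") p
        else {  # palindromic: revcomp copy a bounded gap downstream
          gp <- sample(40:max(41L, min(200L, length(cols) - io - 2L * u - 12L)), 1L)
          cols[min(io + u + gp, length(cols) - 1L)]
        }
      piece <- if (ty == "palindromic") .revcomp_chars(unit) else unit
      i <- insert_at
      hi <- if (i < length(key)) key[i + 1L] else key[i] + 1
      nk <- key[i] + seq_len(u) * (hi - key[i]) / (u + 1)
      ins <- function(v, x) c(v[seq_len(i)], x, v[-seq_len(i)])
      key <- ins(key, nk); base <- ins(base, piece)
      rid <- ins(rid, rep(rid[i], u))
      w <- ins(w, rep(w[i], u)); ic <- ins(ic, rep(ic[i], u))
      ev$net_length <- ev$net_length + u
      gains[[length(gains) + 1L]] <- data.frame(
        type = ty, unit = u, region = env$regions$name[env$regions$id == tgt],
        edge = edge_idx)
    }
  }
  if (length(gains)) ev$repeat_gains <- do.call(rbind, gains)

  ## planted inversion flips assigned to this edge
  for (k in seq_along(env$inversions)) {
    iv <- env$inversions[[k]]
    if (!is.na(iv$branch) && iv$branch == edge_idx) {
      sel <- which(key >= iv$seg_keys[1] & key <= iv$seg_keys[2])
      if (length(sel)) base[sel] <- .revcomp_chars(base[sel])
      ev$inversion_flipped <- c(ev$inversion_flipped, k)
    }
  }

  list(node = list(key = key, base = base, rid = rid), events = ev)
}

## ---- main entry -------------------------------------------------------

#' Simulate plastomes evolving on a known tree
#'
#' Builds a quadripartite root genome (IRa the exact reverse complement of
#' IRb), then evolves it along the configured tree: substitutions (with IR
#' events mirrored into both arms, modelling plastid IR homogenization),
#' indels in single-copy DNA (frame-preserving in exons), repeat-gain
#' duplications in spacers, and planted small inversions flipped on chosen
#' branches. The true alignment is maintained event-by-event; nothing is
#' ever re-aligned, so substitution/indel ground truth is exact.
#'
#' @param cfg a \code{\link{simulationConfig}}
#' @param seed integer seed; overrides \code{cfg$seed}; one of the two must
#'   be set
#' @return a \linkS4class{PlastomeSimulation}
#' @export
simulatePlastomes <- function(cfg, seed = cfg$seed) {
  if (is.null(seed)) stop("a seed is mandatory")
  .with_seed(seed, .simulate_impl(cfg))
}

.simulate_impl <- function(cfg) {
  tree <- stats::reorder(cfg$tree, "cladewise")
  nt <- length(tree$tip.label)
  env <- .build_root(cfg)
  ## assign unset inversion branches to random edges
  for (k in seq_along(env$inversions))
    if (is.na(env$inversions[[k]]$branch))
      env$inversions[[k]]$branch <- sample.int(nrow(tree$edge), 1L)

  states <- vector("list", nt + tree$Nnode)
  states[[nt + 1L]] <- env$node
  branch_events <- vector("list", nrow(tree$edge))
  for (e in seq_len(nrow(tree$edge))) {
    par <- tree$edge[e, 1]; chd <- tree$edge[e, 2]
    res <- .evolve_branch(states[[par]], tree$edge.length[e], e, env, cfg)
    states[[chd]] <- res$node
    branch_events[[e]] <- res$events
  }
  ## free internal states except tips
  leaves <- states[seq_len(nt)]
  names(leaves) <- tree$tip.label

  ## true alignment over all leaf columns
  all_keys <- sort(unique(unlist(lapply(leaves, `[[`, "key"))))
  aln <- matrix("-", nt, length(all_keys),
                dimnames = list(tree$tip.label, NULL))
  for (tx in tree$tip.label) {
    idx <- match(leaves[[tx]]$key, all_keys)
    aln[tx, idx] <- leaves[[tx]]$base
  }

  ## leaf GenomeRecords with features remapped through the column keys
  arch <- cfg$arch
  recs <- lapply(tree$tip.label, function(tx) {
    lv <- leaves[[tx]]
    f <- arch$features
    ls <- findInterval(f$start - 0.5, lv$key) + 1L
    le <- findInterval(f$end + 0.49, lv$key)
    ok <- le >= ls
    f <- f[ok, , drop = FALSE]
    f$start <- ls[ok]; f$end <- le[ok]
    genomeRecord(.collapse_chars(lv$base), id = tx, taxon = tx, features = f)
  })
  names(recs) <- tree$tip.label

  ## descendant leaves per edge (for repeat/inversion truth)
  desc <- vector("list", nt + tree$Nnode)
  for (i in seq_len(nt)) desc[[i]] <- tree$tip.label[i]
  post <- stats::reorder(tree, "postorder")
  for (e in seq_len(nrow(post$edge)))
    desc[[post$edge[e, 1]]] <- c(desc[[post$edge[e, 1]]],
                                 desc[[post$edge[e, 2]]])
  edge_leaves <- lapply(seq_len(nrow(tree$edge)), function(e)
    sort(desc[[tree$edge[e, 2]]]))

  gains <- do.call(rbind, lapply(branch_events, `[[`, "repeat_gains"))
  if (!is.null(gains))
    gains$leaves <- vapply(gains$edge, function(e)
      paste(edge_leaves[[e]], collapse = ","), "")

  inv_truth <- lapply(seq_along(env$inversions), function(k) {
    iv <- env$inversions[[k]]
    iv$inverted_leaves <- edge_leaves[[iv$branch]]
    iv
  })

  truth <- list(root = .collapse_chars(env$node$base),
                regions = env$regions,
                root_repeats = env$root_repeats,
                repeat_gains = gains,
                inversions = inv_truth,
                branch_events = lapply(branch_events, function(x)
                  x[c("substitutions", "insertions", "deletions",
                      "net_length")]),
                edge_leaves = edge_leaves,
                architecture = arch)
  new("PlastomeSimulation", records = recs, alignment = aln, truth = truth,
      config = unclass(cfg))
}

#' Simulate a repeat presence/absence history on a tree
#'
#' A lightweight companion to the full genome simulator: binary repeat
#' characters are gained on branches (chosen with probability proportional
#' to branch length) and inherited by all descendant leaves; with
#' probability \code{homoplasyProb} a character receives a second,
#' independent state flip on another branch, producing homoplasy at the
#' level seen in real plastome repeat matrices.
#'
#' @param tree phylo with branch lengths
#' @param nChar number of repeat characters
#' @param homoplasyProb probability a character gets a second flip
#' @param edgeWeights "length" samples gain branches proportionally to
#'   branch length (repeat turnover tied to overall divergence, the
#'   genome-simulator behaviour); "equal" treats every branch as an equally
#'   likely gain site, which yields many more parsimony-informative
#'   characters on trees with short internal branches and is the setting
#'   used for topology-recovery experiments
#' @param seed mandatory seed
#' @return list: \code{matrix} (binary \linkS4class{CharacterMatrix}),
#'   \code{gains} (data.frame edge per character), \code{tree}
#' @export
simulateRepeatHistory <- function(tree, nChar = 65, homoplasyProb = 0.03,
                                  edgeWeights = c("length", "equal"), seed) {
  if (missing(seed)) stop("a seed is mandatory")
  edgeWeights <- match.arg(edgeWeights)
  .with_seed(seed, {
    nt <- length(tree$tip.label)
    desc <- vector("list", nt + tree$Nnode)
    for (i in seq_len(nt)) desc[[i]] <- tree$tip.label[i]
    post <- stats::reorder(tree, "postorder")
    for (e in seq_len(nrow(post$edge)))
      desc[[post$edge[e, 1]]] <- c(desc[[post$edge[e, 1]]],
                                   desc[[post$edge[e, 2]]])
    ne <- nrow(tree$edge)
    mat <- matrix("0", nt, nChar, dimnames = list(tree$tip.label, NULL))
    gain_edge <- integer(nChar); extra_edge <- rep(NA_integer_, nChar)
    wts <- if (edgeWeights == "length") tree$edge.length else rep(1, ne)
    for (j in seq_len(nChar)) {
      e1 <- sample.int(ne, 1L, prob = wts)
      below <- desc[[tree$edge[e1, 2]]]
      st <- stats::setNames(rep("0", nt), tree$tip.label)
      st[below] <- "1"
      gain_edge[j] <- e1
      if (stats::runif(1) < homoplasyProb) {
        e2 <- sample(setdiff(seq_len(ne), e1), 1L)
        flip <- desc[[tree$edge[e2, 2]]]
        st[flip] <- ifelse(st[flip] == "1", "0", "1")
        extra_edge[j] <- e2
      }
      mat[, j] <- st[rownames(mat)]
    }
    list(matrix = characterMatrix(mat, "binary"),
         gains = data.frame(character = seq_len(nChar), edge = gain_edge,
                            extra_edge = extra_edge),
         tree = tree)
  })
}
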