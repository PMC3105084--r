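#' @include simulate-engine.R repeat-classify.R divergence.R indel-inversion.R
NULL

.write_tsv <- function(d, path)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)

.write_json <- function(x, path)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")

## map reference-sequence coordinates [s, e] to alignment column span
.ref_span <- function(refcols, s, e) refcols[s]:refcols[e]

#' Run the full comparative pipeline
#'
#' Orchestrates every stage over a set of genomes: summary statistics,
#' quadripartite structure and junctions, repeat scanning and the repeat
#' presence/absence tree, p-distances, marker ranking, exon-indel coding
#' and classification, and small-inversion detection. Each stage writes a
#' TSV (and JSON where the result is structured); a run manifest records
#' the package version, seed and effective configuration. Any stage
#' failure aborts with the stage named; outputs of completed stages are
#' retained.
#'
#' The input is either a \code{simulate} block (a
#' \code{\link{simulationConfig}} argument list) or \code{genbank} (paths
#' to annotated records) plus optionally \code{alignment} (aligned FASTA).
#' Alignment-dependent stages are skipped when no alignment is available.
#'
#' @param config named list (or path to a YAML file): \code{seed},
#'   \code{simulate} or \code{input}, \code{outgroup}, \code{groups},
#'   and per-stage parameter blocks \code{structure} (minIR),
#'   \code{repeats} (finder thresholds), \code{tree} (bootstrap reps),
#'   \code{markers} (minLen)
#' @param outDir output directory (created if needed)
#' @return invisibly, a list of per-stage results
#' @export
runPipeline <- function(config, outDir = "pipeline-out") {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  known <- c("seed", "simulate", "input", "outgroup", "groups", "structure",
             "repeats", "tree", "markers")
  unknown <- setdiff(names(config), known)
  if (length(unknown)) stop("unknown config key(s): ",
                            paste(unknown, collapse = ", "))
  if (is.null(config$seed)) stop("config must set a seed")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  results <- list()
  stage <- function(name, expr) {
    tryCatch(force(expr),
             error = function(e) stop("pipeline stage '", name, "' failed: ",
                                      conditionMessage(e), call. = FALSE))
  }

  ## -- inputs ----------------------------------------------------------
  aln <- NULL; sim <- NULL
  if (!is.null(config$simulate)) {
    cfg <- do.call(simulationConfig, config$simulate)
    sim <- simulatePlastomes(cfg, seed = config$seed)
    recs <- leafRecords(sim)
    aln <- trueAlignment(sim)
  } else if (!is.null(config$input$genbank)) {
    recs <- lapply(config$input$genbank, readGenBank)
    names(recs) <- vapply(recs, genomeId, "")
    if (!is.null(config$input$alignment))
      aln <- readAlignedFasta(config$input$alignment)
  } else stop("config must provide either 'simulate' or 'input$genbank'")

  minIR <- config$structure$minIR
  if (is.null(minIR)) minIR <- 10000

  ## -- stats -----------------------------------------------------------
  results$stats <- stage("stats", {
    quads <- lapply(recs, function(r)
      tryCatch(detectQuadripartite(r, minIR = minIR), error = function(e) NULL))
    st <- do.call(rbind, lapply(names(recs), function(id) {
      s <- genomeStats(recs[[id]], quad = quads[[id]])
      q <- quads[[id]]
      data.frame(genome = id, length = s$length, gc_percent = s$gc_percent,
                 coding_percent = s$coding_percent, genes = s$genes_total,
                 protein_genes = s$genes_protein, rna_genes = s$genes_rna,
                 lsc = if (is.null(q)) NA else regionLengths(q)[["lsc"]],
                 ssc = if (is.null(q)) NA else regionLengths(q)[["ssc"]],
                 ir = if (is.null(q)) NA else regionLengths(q)[["irb"]])
    }))
    .write_tsv(st, file.path(outDir, "stats.tsv"))
    list(table = st, quads = quads)
  })
  quads <- results$stats$quads

  ## -- structure / junctions -------------------------------------------
  results$structure <- stage("structure", {
    jr <- do.call(rbind, lapply(names(recs), function(id) {
      if (is.null(quads[[id]])) return(NULL)
      cbind(genome = id, junctionReport(quads[[id]], recs[[id]]))
    }))
    if (!is.null(jr)) .write_tsv(jr, file.path(outDir, "junctions.tsv"))
    jr
  })

  ## -- repeats ----------------------------------------------------------
  results$repeats <- stage("repeats", {
    rpar <- config$repeats
    sets <- lapply(names(recs), function(id)
      do.call(scanRepeats, c(list(recs[[id]], quad = quads[[id]]), rpar)))
    names(sets) <- names(recs)
    tab <- do.call(rbind, lapply(sets, function(s)
      if (nrow(motifs(s))) cbind(genome = genomeId(s), motifs(s)) else NULL))
    if (!is.null(tab)) .write_tsv(tab, file.path(outDir, "repeats.tsv"))
    sh <- sharedRepeats(sets)
    .write_json(list(shared_all = sh$shared_all,
                     unique_per_taxon = as.list(sh$unique_per_taxon),
                     subset_counts = as.list(sh$subset_counts)),
                file.path(outDir, "shared_repeats.json"))
    M <- repeatBinaryMatrix(sets)
    writeNexusMatrix(M, file.path(outDir, "repeat_matrix.nex"))
    list(sets = sets, shared = sh, matrix = M)
  })

  ## -- repeat tree -------------------------------------------------------
  results$repeat_tree <- stage("repeat-tree", {
    M <- results$repeats$matrix
    if (length(taxa(M)) < 4L || ncol(characterStates(M)) < 1L) return(NULL)
    res <- exhaustiveSearch(M)
    reps <- config$tree$bootstrap
    if (is.null(reps)) reps <- 100
    bs <- bootstrapSupport(M, reps = reps, seed = config$seed + 1L)
    write.tree(res$trees, file.path(outDir, "repeat_tree.nwk"))
    sc <- res$score
    .write_json(list(steps = sc@steps, ci = sc@ci, ri = sc@ri,
                     n_optimal = length(res$trees),
                     bootstrap = as.list(bs)),
                file.path(outDir, "repeat_tree.json"))
    list(search = res, bootstrap = bs)
  })

  if (is.null(aln)) {
    .write_json(.manifest(config), file.path(outDir, "manifest.json"))
    return(invisible(results))
  }
  ref <- rownames(aln)[1]
  outgroup <- config$outgroup
  if (is.null(outgroup)) outgroup <- ref
  refcols <- which(!.is_gapchar(aln[ref, ]))
  refrec <- recs[[ref]]

  ## -- distances ---------------------------------------------------------
  results$distance <- stage("distance", {
    groups <- if (!is.null(config$groups)) unlist(config$groups) else NULL
    ds <- pDistance(aln, groups = groups)
    .write_tsv(as.data.frame(distances(ds)), file.path(outDir, "distance.tsv"))
    .write_json(list(overall = ds@overall, within = as.list(ds@within),
                     between = ds@between), file.path(outDir, "distance.json"))
    ds
  })

  ## -- markers -----------------------------------------------------------
  results$markers <- stage("markers", {
    minLen <- config$markers$minLen
    if (is.null(minLen)) minLen <- 350
    regions <- partitionRegions(refrec, minLen = minLen,
                                singleCopyOnly = !is.null(quads[[ref]]),
                                quad = quads[[ref]])
    nc <- regions[regions$class == "noncoding", , drop = FALSE]
    st <- do.call(rbind, lapply(seq_len(nrow(nc)), function(i)
      regionVariability(aln[, .ref_span(refcols, nc$start[i], nc$end[i]),
                            drop = FALSE],
                        countIndels = TRUE, name = nc$name[i],
                        class = "noncoding")))
    rk <- if (!is.null(st)) rankMarkers(st) else NULL
    if (!is.null(rk)) .write_tsv(rk, file.path(outDir, "markers.tsv"))
    list(stats = st, ranked = rk)
  })

  ## -- exon indels -------------------------------------------------------
  results$indels <- stage("indels", {
    f <- genomeFeatures(refrec)
    cds <- f[f$kind == "CDS", , drop = FALSE]
    galn <- lapply(split(cds, cds$name), function(g) {
      cols <- unlist(lapply(seq_len(nrow(g)), function(i)
        .ref_span(refcols, g$start[i], g$end[i])))
      aln[, cols, drop = FALSE]
    })
    ev <- extractExonIndels(galn, outgroup)
    tr <- if (!is.null(results$repeat_tree)) results$repeat_tree$search$trees[[1]]
      else NULL
    if (!is.null(tr) && nrow(ev)) ev <- classifyEvents(ev, tr, outgroup)
    if (nrow(ev)) .write_tsv(ev, file.path(outDir, "indels.tsv"))
    ev
  })

  ## -- small inversions --------------------------------------------------
  results$inversions <- stage("inversions", {
    iv <- detectSmallInversions(aln, reference = ref)
    if (nrow(iv)) .write_tsv(iv, file.path(outDir, "inversions.tsv"))
    iv
  })

  .write_json(.manifest(config), file.path(outDir, "manifest.json"))
  invisible(results)
}

.manifest <- function(config) {
  cfgchr <- utils::capture.output(utils::str(config))
  list(package = "plastomeR",
       version = as.character(utils::packageVersion("plastomeR")),
       seed = config$seed,
       config_hash = sum(utf8ToInt(paste(cfgchr, collapse = ""))) %% 1e9,
       config = config)
}
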