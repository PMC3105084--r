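#' @import methods
#' @importFrom Biostrings DNAString DNAStringSet readDNAStringSet writeXStringSet
#' @importFrom IRanges IRanges reduce start end width findOverlaps
#' @importFrom S4Vectors queryHits subjectHits
NULL

#' Annotated plastome record
#'
#' Holds one plastid genome: its identifier, taxon label, nucleotide sequence
#' and annotated features. Features are stored as a data.frame with one row
#' per interval; multi-exon features (GenBank \code{join(...)} locations)
#' occupy several rows sharing a \code{feature_id}.
#'
#' @slot id accession or name
#' @slot taxon taxon label
#' @slot seq a \link[Biostrings]{DNAString}
#' @slot circular logical flag; genomes are analysed in their deposited
#'   rotation (treated as linear)
#' @slot features data.frame with columns \code{feature_id}, \code{kind}
#'   (gene/CDS/tRNA/rRNA/intron/spacer), \code{name}, \code{start},
#'   \code{end}, \code{strand}, \code{origin_spanning}
#' @exportClass GenomeRecord
setClass("GenomeRecord",
  slots = c(id = "character", taxon = "character", seq = "DNAString",
            circular = "logical", features = "data.frame"))

setValidity("GenomeRecord", function(object) {
  n <- length(object@seq)
  if (n < 1L) return("sequence must be non-empty")
  f <- object@features
  need <- c("feature_id", "kind", "name", "start", "end", "strand")
  if (!all(need %in% names(f)))
    return(paste("features must have columns:", paste(need, collapse = ", ")))
  if (nrow(f)) {
    if (any(f$start < 1L | f$end > n)) return("feature interval outside sequence")
    sp <- if ("origin_spanning" %in% names(f)) f$origin_spanning else FALSE
    if (any(f$start > f$end & !sp))
      return("start > end for a feature not flagged as origin-spanning")
    if (!all(f$strand %in% c("+", "-"))) return("strand must be '+' or '-'")
  }
  ok <- grepl("^[ACGTNRYSWKMBDHV]*$", as.character(object@seq))
  if (!ok) return("sequence contains non-IUPAC characters")
  TRUE
})

#' Quadripartite architecture of a plastome
#'
#' @slot lsc,irb,ssc,ira \link[IRanges]{IRanges} of the four regions
#'   (1-based inclusive, deposited rotation); \code{lsc} may contain two
#'   ranges when the large single-copy region wraps the origin
#' @slot junctions named numeric(4): first base of IRb (LSC/IRb), last base
#'   of IRb (IRb/SSC), first base of IRa (SSC/IRa), last base of IRa (IRa/LSC)
#' @slot irIdentity realized identity between the two IR arms
#' @slot genomeLength total genome length
#' @exportClass Quadripartite
setClass("Quadripartite",
  slots = c(lsc = "IRanges", irb = "IRanges", ssc = "IRanges", ira = "IRanges",
            junctions = "numeric", irIdentity = "numeric",
            genomeLength = "integer"))

setValidity("Quadripartite", function(object) {
  if (sum(width(object@irb)) != sum(width(object@ira)))
    return("|IRa| must equal |IRb|")
  tot <- sum(width(object@lsc)) + sum(width(object@ssc)) +
    sum(width(object@irb)) + sum(width(object@ira))
  if (tot != object@genomeLength)
    return("LSC+SSC+2*IR must tile the genome exactly")
  if (sum(width(object@lsc)) <= sum(width(object@ssc)))
    return("|LSC| must exceed |SSC|")
  if (length(object@junctions) != 4L) return("need 4 junction coordinates")
  TRUE
})

#' Classified repeat motifs of one genome
#'
#' @slot genomeId source genome identifier
#' @slot motifs data.frame, one row per motif: \code{type} (dispersed/tandem/
#'   palindromic/similarity), copy coordinates \code{start1,end1,start2,end2}
#'   (for tandem the whole array is \code{start1..end1} and
#'   \code{start2,end2} are \code{NA}), \code{unit_length}, \code{copies},
#'   \code{identity}, \code{location_class} (coding/noncoding/both),
#'   \code{context} (feature-context key used for cross-genome matching)
#' @exportClass RepeatSet
setClass("RepeatSet", slots = c(genomeId = "character", motifs = "data.frame"))

setValidity("RepeatSet", function(object) {
  m <- object@motifs
  need <- c("type", "start1", "end1", "start2", "end2", "unit_length",
            "copies", "identity", "location_class", "context")
  if (!all(need %in% names(m)))
    return(paste("motifs must have columns:", paste(need, collapse = ", ")))
  if (nrow(m)) {
    if (!all(m$type %in% c("dispersed", "tandem", "palindromic", "similarity")))
      return("unknown repeat type")
    if (any(m$identity < 0 | m$identity > 1)) return("identity outside [0,1]")
  }
  TRUE
})

#' Discrete character matrix for parsimony analysis
#'
#' @slot mat character matrix, taxa in rows; states are single characters
#'   (\code{0/1} for binary repeat or indel characters, \code{A,C,G,T} for
#'   sites); \code{?}, \code{-} and \code{N} are treated as missing
#' @slot type "binary", "dna" or "mixed"
#' @exportClass CharacterMatrix
setClass("CharacterMatrix", slots = c(mat = "matrix", type = "character"))

setValidity("CharacterMatrix", function(object) {
  if (!is.character(object@mat)) return("matrix must be of character states")
  if (is.null(rownames(object@mat))) return("taxa (rownames) required")
  if (anyDuplicated(rownames(object@mat))) return("duplicated taxa")
  TRUE
})

#' Parsimony tree score with ensemble consistency and retention indices
#'
#' @slot steps observed tree length s
#' @slot minSteps sum over characters of the minimum conceivable steps m
#' @slot maxSteps sum over characters of the maximum conceivable steps g
#' @slot ci ensemble consistency index m/s
#' @slot ri ensemble retention index (g-s)/(g-m); NA when g == m
#' @exportClass ParsimonyScore
setClass("ParsimonyScore",
  slots = c(steps = "numeric", minSteps = "numeric", maxSteps = "numeric",
            ci = "numeric", ri = "numeric"))

setValidity("ParsimonyScore", function(object) {
  if (object@minSteps > object@steps + 1e-9) return("m must be <= s")
  if (object@steps > object@maxSteps + 1e-9) return("s must be <= g")
  TRUE
})

#' Pairwise p-distance summary
#'
#' @slot dist symmetric p-distance matrix (proportion of differing sites,
#'   pairwise deletion of gap/ambiguous columns)
#' @slot overall mean over all pairs
#' @slot within named vector of within-group mean distances
#' @slot between mean over between-group pairs (NA without groups)
#' @slot groups named group assignment
#' @exportClass DistanceSummary
setClass("DistanceSummary",
  slots = c(dist = "matrix", overall = "numeric", within = "numeric",
            between = "numeric", groups = "character"))

#' Result bundle of a plastome simulation
#'
#' @slot records list of \linkS4class{GenomeRecord}, one per leaf
#' @slot alignment character matrix: the true alignment of the leaves,
#'   maintained event-by-event (never re-aligned)
#' @slot truth list of planted ground truth: per-branch substitution, indel,
#'   repeat-gain and inversion events, region table on root coordinates,
#'   and the root genome
#' @slot config the \code{simulationConfig()} used
#' @exportClass PlastomeSimulation
setClass("PlastomeSimulation",
  slots = c(records = "list", alignment = "matrix", truth = "list",
            config = "list"))

## ---- show methods -----------------------------------------------------

setMethod("show", "GenomeRecord", function(object) {
  cat("GenomeRecord:", object@id,
      if (nzchar(object@taxon)) paste0("(", object@taxon, ")"), "\n")
  cat("  length:", length(object@seq), "bp;",
      if (object@circular) "circular" else "linear", "\n")
  f <- object@features
  cat("  features:", nrow(f), "intervals,",
      length(unique(f$feature_id)), "features\n")
})

setMethod("show", "Quadripartite", function(object) {
  cat("Quadripartite structure (", object@genomeLength, " bp)\n", sep = "")
  cat(sprintf("  LSC %6d bp | IRb %6d bp | SSC %6d bp | IRa %6d bp\n",
              sum(width(object@lsc)), sum(width(object@irb)),
              sum(width(object@ssc)), sum(width(object@ira))))
  cat("  junctions:", paste(object@junctions, collapse = ", "),
      "\n  IR arm identity:", format(object@irIdentity, digits = 4), "\n")
})

setMethod("show", "RepeatSet", function(object) {
  tab <- table(factor(object@motifs$type,
                      c("dispersed", "tandem", "palindromic", "similarity")))
  cat("RepeatSet for", object@genomeId, "-", nrow(object@motifs), "motifs\n")
  cat(" ", paste(names(tab), tab, sep = ": ", collapse = "  "), "\n")
})

setMethod("show", "CharacterMatrix", function(object) {
  cat("CharacterMatrix:", nrow(object@mat), "taxa x", ncol(object@mat),
      "characters (", object@type, ")\n")
})

setMethod("show", "ParsimonyScore", function(object) {
  cat(sprintf("ParsimonyScore: length %g (m = %g, g = %g), CI = %.3f, RI = %s\n",
              object@steps, object@minSteps, object@maxSteps, object@ci,
              ifelse(is.na(object@ri), "NA", sprintf("%.3f", object@ri))))
})

setMethod("show", "DistanceSummary", function(object) {
  cat("DistanceSummary over", nrow(object@dist), "taxa; overall mean p =",
      format(object@overall, digits = 3), "\n")
  if (length(object@within))
    cat("  within-group means:",
        paste(names(object@within), format(object@within, digits = 3),
              sep = " = ", collapse = ", "),
        "; between =", format(object@between, digits = 3), "\n")
})

setMethod("show", "PlastomeSimulation", function(object) {
  cat("PlastomeSimulation:", length(object@records), "leaf genomes,",
      ncol(object@alignment), "true-alignment columns\n")
})
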