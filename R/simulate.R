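#' @include AllClasses.R genome-stats.R
NULL

#' Reference topologies for the six- and eight-taxon woody bamboo study design
#'
#' Fixed trees with branch lengths (expected substitutions/site) calibrated
#' so that simulated divergences match the published scale: pairwise
#' p-distance about 0.002 within the temperate clade (Arundinarieae: FR,
#' AP, IL, PE, PN), about 0.003 within the tropical clade (Bambuseae: BE,
#' BO, DL; 8-taxon tree), and about 0.014 between the two tribes. Tip
#' codes follow the usual abbreviations (BE \emph{Bambusa emeiensis}, FR
#' \emph{Ferrocalamus rimosivaginus}, AP \emph{Acidosasa purpurea}, IL
#' \emph{Indocalamus longiauritus}, PE \emph{Phyllostachys edulis}, PN
#' \emph{P. nigra} var. \emph{henonis}, BO \emph{B. oldhamii}, DL
#' \emph{Dendrocalamus latiflorus}).
#'
#' @param n 6 or 8 taxa
#' @return an \code{ape} \code{phylo} with branch lengths
#' @export
bambooTree <- function(n = 6) {
  txt <- if (n == 6)
    "(BE:0.0070,(FR:0.0010,(AP:0.0009,(IL:0.0008,(PE:0.0005,PN:0.0005):0.0003):0.0002):0.0003):0.0048);"
  else if (n == 8)
    "((BE:0.0015,(BO:0.0012,DL:0.0012):0.0008):0.0055,((FR:0.0010,(AP:0.0009,(IL:0.0008,(PE:0.0005,PN:0.0005):0.0003):0.0002):0.0003):0.0048):0.0000);"
  else stop("n must be 6 or 8")
  read.tree(text = txt)
}

## ---- architecture -----------------------------------------------------

.GENE_SETS <- local({
  g <- function(name, len, kind = "CDS", exons = NULL)
    list(name = name, len = len, kind = kind, exons = exons)
  t_ <- function(name, len = 74) g(name, len, "tRNA")
  full_lsc <- list(
    g("psbA", 1062), t_("trnK(UUU)", 75), g("rps16", 240), t_("trnQ(UUG)", 72),
    g("psbK", 186), g("psbI", 111), t_("trnS(GCU)", 88), t_("trnG(UCC)", 72),
    t_("trnT(GGU)", 72), t_("trnE(UUC)", 73), t_("trnY(GUA)", 84),
    t_("trnD(GUC)", 74), g("psbM", 105), t_("trnS(UGA)", 88),
    t_("trnC(GCA)", 71), g("petN", 90), g("rpoB", 3213), g("rpoC1", 2052),
    g("rpoC2", 4200), g("rps2", 711), g("atpI", 744), g("atpH", 246),
    g("atpF", 1255, exons = c(145, 410)), g("atpA", 1524), g("psbD", 1062),
    g("psbC", 1386), g("psbZ", 189), t_("trnfM(CAU)", 74), g("rps14", 303),
    g("psaB", 2205), g("psaA", 2253), g("ycf3", 507), t_("trnS(GGA)", 87),
    g("rps4", 606), t_("trnT(UGU)", 73), t_("trnL(UAA)", 81),
    t_("trnF(GAA)", 73), g("ndhJ", 477), g("ndhK", 678), g("ndhC", 363),
    t_("trnV(UAC)", 72), t_("trnM(CAU)", 73), g("atpE", 411), g("atpB", 1497),
    g("rbcL", 1431), g("psaI", 111), g("ycf4", 555), g("cemA", 690),
    g("petA", 963), g("psbJ", 123), g("psbL", 117), g("psbF", 120),
    g("psbE", 252), g("petL", 96), g("petG", 114), t_("trnW(CCA)", 74),
    t_("trnP(UGG)", 74), g("psaJ", 129), g("rpl33", 201), g("rps18", 306),
    g("rpl20", 354), g("clpP", 591), g("psbB", 1527), g("psbT", 108),
    g("psbN", 132), g("psbH", 222), g("petB", 648), g("petD", 483),
    g("rpoA", 1017), g("rps11", 432), g("rpl36", 114), g("infA", 234),
    g("rps8", 405), g("rpl14", 369), g("rpl16", 1311, exons = c(9, 402)),
    g("rps3", 657), g("rpl22", 449), g("rps19", 279))
  full_ssc <- list(
    g("ndhF", 2210), g("rpl32", 171), t_("trnL(UAG)", 80), g("ccsA", 960),
    g("ndhD", 1503), g("psaC", 246), g("ndhE", 306), g("ndhG", 531),
    g("ndhI", 543), g("ndhA", 1092), g("ndhH", 1182))
  full_ir <- list(
    g("rpl2", 1489), g("rpl23", 282), t_("trnI(CAU)", 74), g("ycf2", 6199),
    g("ndhB", 1533), g("rps7", 468), t_("trnV(GAC)", 72),
    g("rrn16", 1491, "rRNA"), t_("trnI(GAU)", 72), t_("trnA(UGC)", 73),
    g("rrn23", 2810, "rRNA"), g("rrn4.5", 95, "rRNA"), g("rrn5", 121, "rRNA"),
    t_("trnR(ACG)", 74), t_("trnN(GUU)", 72), g("rps15", 273))
  mini_lsc <- list(
    g("psbA", 300), t_("trnD(GUC)", 74), g("psbM", 105), t_("trnS(UGA)", 88),
    t_("trnC(GCA)", 71), g("rbcL", 600), g("psaI", 111), g("ycf4", 300),
    g("cemA", 300), g("rpl16", 811, exons = c(9, 402)))
  mini_ssc <- list(
    g("ndhF", 400), g("rpl32", 171), t_("trnL(UAG)", 80), g("psaC", 246),
    g("ndhE", 306), g("ndhH", 500))
  mini_ir <- list(g("rpl2", 489), g("rrn16", 700, "rRNA"),
                  g("rrn23", 900, "rRNA"), g("rps15", 273))
  list(full = list(lsc = full_lsc, ssc = full_ssc, ir = full_ir),
       mini = list(lsc = mini_lsc, ssc = mini_ssc, ir = mini_ir))
})

## spacers given elevated space so they pass the >350 bp marker filter
.WIDE_SPACERS <- c("trnD(GUC)-psbM", "ycf4-cemA", "trnG(UCC)-trnT(GGU)",
                   "ndhF-rpl32", "rpl32-trnL(UAG)", "trnK(UUU)-rps16",
                   "psbK-psbI", "ycf3-trnS(GGA)", "trnT(UGU)-trnL(UAA)",
                   "psbZ-trnfM(CAU)", "rbcL-psaI", "psaC-ndhE",
                   "trnT(GGU)-trnE(UUC)", "trnY(GUA)-trnD(GUC)",
                   "rps15-ndhF", "trnL(UAA)-trnF(GAA)", "trnF(GAA)-ndhJ",
                   "psaI-ycf4", "psaA-ycf3", "trnS(UGA)-trnC(GCA)")

## lay genes into [regionStart, regionEnd]; returns feature rows
.layout_region <- function(genes, regionStart, regionEnd, fid0) {
  glen <- vapply(genes, `[[`, numeric(1), "len")
  total <- regionEnd - regionStart + 1L
  spare <- total - sum(glen)
  ng <- length(genes)
  if (spare < ng + 1L) stop("architecture does not tile: region too small")
  nm <- vapply(genes, `[[`, "", "name")
  ## spacer i sits before gene i; weight wide (marker) spacers higher
  spn <- c(paste0("^", nm[1]), paste0(nm[-ng], "-", nm[-1]), paste0(nm[ng], "$"))
  w <- ifelse(spn %in% .WIDE_SPACERS, 3, 1)
  sp <- floor(spare * w / sum(w))
  sp[length(sp)] <- spare - sum(sp[-length(sp)])
  rows <- list(); pos <- regionStart; fid <- fid0
  for (i in seq_along(genes)) {
    pos <- pos + sp[i]
    gn <- genes[[i]]
    s <- pos; e <- pos + gn$len - 1L
    fid <- fid + 1L
    rows[[length(rows) + 1L]] <- data.frame(
      feature_id = fid, kind = "gene", name = gn$name, start = s, end = e,
      strand = "+", origin_spanning = FALSE)
    fid <- fid + 1L
    if (is.null(gn$exons)) {
      rows[[length(rows) + 1L]] <- data.frame(
        feature_id = fid, kind = gn$kind, name = gn$name, start = s, end = e,
        strand = "+", origin_spanning = FALSE)
    } else {
      ## two exons separated by an intron filling the remaining gene span
      e1 <- s + gn$exons[1] - 1L
      s2 <- e - gn$exons[2] + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        feature_id = fid, kind = gn$kind, name = gn$name,
        start = c(s, s2), end = c(e1, e), strand = "+",
        origin_spanning = FALSE)
    }
    pos <- e + 1L
  }
  list(rows = do.call(rbind, rows), fid = fid)
}

#' Quadripartite genome architecture for the simulator
#'
#' Builds the deterministic gene layout (LSC | IRb | SSC | IRa) used as the
#' simulation root: gene names and sizes follow a typical grass plastome,
#' IRa features mirror IRb, and \emph{ndhH} is placed across the SSC/IRa
#' junction with a configurable extension into the IR. Divergence-hotspot
#' spacers (the classic bamboo marker regions) are laid out wide enough to
#' pass the usual >350 bp marker length filter.
#'
#' @param lscLength,sscLength,irLength region lengths in bp; the defaults
#'   reproduce the published bamboo plastome scale (~139.4 kb total)
#' @param geneSet "full" (realistic gene count) or "mini" (small fast
#'   layout for toy runs)
#' @param ndhHExtension nt by which \emph{ndhH} extends into IRa
#' @return list: \code{features} (feature table on root coordinates),
#'   \code{lengths}, \code{irb}/\code{ira}/\code{lsc}/\code{ssc} intervals
#' @export
plastomeArchitecture <- function(lscLength = 83000, sscLength = 12800,
                                 irLength = 21800, geneSet = "full",
                                 ndhHExtension = 183) {
  gs <- .GENE_SETS[[match.arg(geneSet, names(.GENE_SETS))]]
  lsc <- c(1L, as.integer(lscLength))
  irb <- c(lsc[2] + 1L, lsc[2] + as.integer(irLength))
  ssc <- c(irb[2] + 1L, irb[2] + as.integer(sscLength))
  ira <- c(ssc[2] + 1L, ssc[2] + as.integer(irLength))
  total <- ira[2]

  r1 <- .layout_region(gs$lsc, lsc[1], lsc[2], 0L)
  r2 <- .layout_region(gs$ir, irb[1], irb[2], r1$fid)
  ## SSC: ndhH (last gene) must end ndhHExtension into IRa
  ssc_genes <- gs$ssc
  ndhh <- ssc_genes[[length(ssc_genes)]]
  stopifnot(ndhh$name == "ndhH")
  r3 <- .layout_region(ssc_genes[-length(ssc_genes)], ssc[1],
                       ssc[2] - (ndhh$len - ndhHExtension) - 10L, r2$fid)
  ndhh_start <- ssc[2] + ndhHExtension - ndhh$len + 1L
  fid <- r3$fid
  ndhh_rows <- data.frame(
    feature_id = c(fid + 1L, fid + 2L), kind = c("gene", "CDS"),
    name = "ndhH", start = ndhh_start, end = ssc[2] + ndhHExtension,
    strand = "+", origin_spanning = FALSE)
  fid <- fid + 2L
  ## mirror IRb features into IRa (reverse order, flipped strand)
  irb_rows <- r2$rows
  mirror <- function(x) ira[1] + (irb[2] - x)
  ira_rows <- irb_rows
  ira_rows$start <- mirror(irb_rows$end)
  ira_rows$end <- mirror(irb_rows$start)
  ira_rows$strand <- ifelse(irb_rows$strand == "+", "-", "+")
  ira_rows$feature_id <- fid + (irb_rows$feature_id - min(irb_rows$feature_id)) + 1L
  features <- rbind(r1$rows, r2$rows, r3$rows, ndhh_rows, ira_rows)
  rownames(features) <- NULL
  list(features = features,
       lengths = c(lsc = lscLength, ssc = sscLength, ir = irLength,
                   total = total),
       lsc = lsc, irb = irb, ssc = ssc, ira = ira,
       ndhHExtension = ndhHExtension)
}

## ---- configuration ----------------------------------------------------

#' Configure a plastome simulation
#'
#' Collects everything the simulator needs: the tree (branch lengths in
#' expected substitutions/site), the quadripartite architecture, the
#' substitution model, relative rate factors for coding/noncoding/IR
#' positions, indel and repeat-birth rates, planted inversions, and the
#' mandatory seed. Defaults reproduce the study conditions of the bamboo
#' plastome comparison: six taxa on \code{bambooTree(6)}, a ~139.4 kb
#' genome (LSC 83,000 / SSC 12,800 / IR 21,800), GC 38.9\%, divergences on
#' the 0.002--0.014 p-distance scale.
#'
#' @param tree phylo with branch lengths
#' @param seed integer seed (mandatory at simulation time)
#' @param lscLength,sscLength,irLength,geneSet,ndhHExtension architecture
#'   parameters, see \code{\link{plastomeArchitecture}}
#' @param gc genomic GC fraction
#' @param model substitution model: "JC", "K2P" or "GTR"
#' @param kappa transition/transversion rate ratio (K2P)
#' @param gtrRates named 6-vector of exchangeabilities (AC, AG, AT, CG, CT,
#'   GT) for GTR
#' @param codingFactor,noncodingFactor,irFactor relative substitution-rate
#'   multipliers by position class
#' @param indelRate indel events per site per unit branch length in
#'   single-copy noncoding DNA (exons get \code{indelRate/5}, lengths in
#'   multiples of 3; the IR receives no indels)
#' @param indelMeanLen mean indel length (geometric), bp, noncoding
#' @param repeatBirthRate repeat-gain events per unit branch length
#' @param rootRepeats number of repeats planted in the root genome
#' @param inversions list of planted inversion constructs; each a list with
#'   \code{spacer}, \code{armLength}, \code{segmentLength} and \code{branch}
#'   (edge index of the flip event, or NA to sample one)
#' @param hotRegions named numeric vector of rate multipliers per region
#'   name (see \code{\link{plantMarkers}})
#' @return a config list (class "plastomeSimConfig")
#' @export
simulationConfig <- function(tree = bambooTree(6), seed = NULL,
                             lscLength = 83000, sscLength = 12800,
                             irLength = 21800, geneSet = "full",
                             ndhHExtension = 183,
                             gc = 0.389, model = "JC", kappa = 2,
                             gtrRates = c(AC = 1, AG = 2, AT = 1, CG = 1,
                                          CT = 2, GT = 1),
                             codingFactor = 0.55, noncodingFactor = 1.34,
                             irFactor = 0.3,
                             indelRate = 0.15, indelMeanLen = 4,
                             repeatBirthRate = 6000, rootRepeats = 14,
                             inversions = list(
                               list(spacer = "rpl32-trnL(UAG)",
                                    armLength = 22, segmentLength = 30,
                                    branch = NA)),
                             hotRegions = NULL) {
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch length")
  arch <- plastomeArchitecture(lscLength, sscLength, irLength, geneSet,
                               ndhHExtension)
  cfg <- list(tree = tree, seed = seed, arch = arch, gc = gc,
              model = match.arg(model, c("JC", "K2P", "GTR")), kappa = kappa,
              gtrRates = gtrRates,
              codingFactor = codingFactor, noncodingFactor = noncodingFactor,
              irFactor = irFactor, indelRate = indelRate,
              indelMeanLen = indelMeanLen,
              repeatBirthRate = repeatBirthRate, rootRepeats = rootRepeats,
              inversions = inversions, hotRegions = hotRegions)
  class(cfg) <- c("plastomeSimConfig", "list")
  cfg
}

#' Multiply mutation rates in named regions
#'
#' Returns a modified config in which the substitution and indel rates of
#' the named regions (spacer, intron or gene names of the architecture) are
#' multiplied by \code{fold}; used to plant divergence hotspots whose
#' recovery by the marker-ranking stage can then be tested.
#'
#' @param cfg a \code{\link{simulationConfig}}
#' @param hotRegions character vector of region names
#' @param fold rate multiplier (0 allowed: frozen regions)
#' @return the modified config
#' @export
plantMarkers <- function(cfg, hotRegions, fold) {
  known <- .sim_regions(cfg)$name
  bad <- setdiff(hotRegions, known)
  if (length(bad))
    stop("unknown region(s): ", paste(bad, collapse = ", "))
  hot <- stats::setNames(rep(fold, length(hotRegions)), hotRegions)
  cfg$hotRegions <- c(cfg$hotRegions, hot)
  cfg
}

## region table of the architecture root: spacers/introns/exons via
## partitionRegions on a dummy record
.sim_regions <- function(cfg) {
  arch <- cfg$arch
  dummy <- genomeRecord(strrep("A", arch$lengths[["total"]]), id = "root",
                        features = arch$features)
  partitionRegions(dummy, minLen = 1)
}
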