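#' @include AllClasses.R
NULL

#' Construct a GenomeRecord
#'
#' @param seq nucleotide sequence (string or \code{DNAString})
#' @param id accession or name
#' @param taxon taxon label
#' @param features data.frame of feature intervals (columns \code{kind},
#'   \code{name}, \code{start}, \code{end}, \code{strand}, and optionally
#'   \code{feature_id}); 1-based inclusive coordinates
#' @param circular logical
#' @return a \linkS4class{GenomeRecord}
#' @export
genomeRecord <- function(seq, id = "genome", taxon = "", features = NULL,
                         circular = TRUE) {
  if (is.null(features))
    features <- data.frame(feature_id = integer(), kind = character(),
                           name = character(), start = integer(),
                           end = integer(), strand = character(),
                           origin_spanning = logical())
  if (!"feature_id" %in% names(features))
    features$feature_id <- seq_len(nrow(features))
  if (!"origin_spanning" %in% names(features))
    features$origin_spanning <- rep(FALSE, nrow(features))
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  new("GenomeRecord", id = id, taxon = taxon,
      seq = if (is(seq, "DNAString")) seq else DNAString(toupper(.as_seq_string(seq))),
      circular = circular, features = features)
}

## GenBank location strings: "a..b", "complement(a..b)",
## "join(a..b,c..d)", "complement(join(...))", and bare "a".
.parse_location <- function(loc) {
  strand <- "+"
  loc <- gsub("[<>]", "", gsub("\\s", "", loc))
  while (grepl("^(complement|join|order)\\(", loc)) {
    op <- sub("^([a-z]+)\\(.*", "\\1", loc)
    if (op == "complement") strand <- if (strand == "+") "-" else "+"
    if (!grepl("\\)$", loc)) stop("unbalanced location: ", loc)
    loc <- sub("^[a-z]+\\((.*)\\)$", "\\1", loc)
  }
  parts <- strsplit(loc, ",", fixed = TRUE)[[1]]
  ivs <- lapply(parts, function(p) {
    if (grepl("^[0-9]+$", p)) return(c(as.integer(p), as.integer(p)))
    if (!grepl("^[0-9]+\\.\\.[0-9]+$", p)) stop("unparseable location part: ", p)
    as.integer(strsplit(p, "..", fixed = TRUE)[[1]])
  })
  list(strand = strand, intervals = ivs)
}

#' Read a GenBank flat file into a GenomeRecord
#'
#' Parses the LOCUS line, organism, the feature table (gene, CDS, tRNA and
#' rRNA keys; \code{join} locations become multi-interval features) and the
#' ORIGIN sequence. Features with unparseable locations are skipped with a
#' warning; a missing sequence is an error.
#'
#' @param path path to a GenBank flat file
#' @return a \linkS4class{GenomeRecord}
#' @export
readGenBank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)
  id <- if (length(locus)) strsplit(trimws(sub("^LOCUS", "", locus[1])),
                                    "\\s+")[[1]][1] else basename(path)
  circular <- length(locus) > 0 && grepl("circular", locus[1], ignore.case = TRUE)
  org <- grep("^\\s+ORGANISM", lines, value = TRUE)
  taxon <- if (length(org)) trimws(sub("^\\s+ORGANISM", "", org[1])) else ""

  ostart <- grep("^ORIGIN", lines)
  if (!length(ostart)) stop("GenBank parse error: no ORIGIN sequence in ", path)
  oend <- grep("^//", lines)
  oend <- if (length(oend)) oend[oend > ostart[1]][1] else length(lines) + 1L
  seqlines <- lines[(ostart[1] + 1L):(oend - 1L)]
  seq <- toupper(gsub("[^A-Za-z]", "", paste(seqlines, collapse = "")))
  if (!nzchar(seq)) stop("GenBank parse error: empty sequence in ", path)

  fstart <- grep("^FEATURES", lines)
  feats <- list()
  if (length(fstart)) {
    block <- lines[(fstart[1] + 1L):(ostart[1] - 1L)]
    # a new feature starts with a key in column 6; qualifier/location
    # continuation lines are indented further
    keyline <- grepl("^ {5}\\S", block)
    idx <- cumsum(keyline)
    fid <- 0L
    for (g in split(block[idx > 0], idx[idx > 0])) {
      key <- sub("^\\s*(\\S+).*", "\\1", g[1])
      if (!key %in% c("gene", "CDS", "tRNA", "rRNA", "intron", "repeat_region"))
        next
      rest <- sub("^\\s*\\S+\\s*", "", g[1])
      qual_at <- grep("^\\s+/", g)
      loc_end <- if (length(qual_at)) qual_at[1] - 1L else length(g)
      loc <- paste0(rest, paste(trimws(g[seq_len(loc_end)][-1]), collapse = ""))
      name <- NA_character_
      gq <- grep("^\\s+/(gene|label)=", g, value = TRUE)
      if (length(gq)) name <- gsub("\"", "", sub("^\\s+/(gene|label)=", "", gq[1]))
      parsed <- tryCatch(.parse_location(loc), error = function(e) NULL)
      if (is.null(parsed)) {
        warning("skipping feature with unparseable location: ", key, " ", loc)
        next
      }
      fid <- fid + 1L
      for (iv in parsed$intervals)
        feats[[length(feats) + 1L]] <- data.frame(
          feature_id = fid, kind = key, name = name,
          start = iv[1], end = iv[2], strand = parsed$strand,
          origin_spanning = iv[1] > iv[2])
    }
  }
  features <- if (length(feats)) do.call(rbind, feats) else NULL
  genomeRecord(seq, id = id, taxon = taxon, features = features,
               circular = circular)
}

#' Write a GenomeRecord as a GenBank flat file
#'
#' Emits the subset of the format that \code{readGenBank} consumes, so a
#' read-write-read round trip preserves feature coordinates.
#'
#' @param rec a \linkS4class{GenomeRecord}
#' @param path output path
#' @export
writeGenBank <- function(rec, path) {
  n <- length(rec@seq)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("LOCUS       %s %d bp    DNA     %s PLN",
                     rec@id, n, if (rec@circular) "circular" else "linear"), con)
  writeLines(sprintf("DEFINITION  %s plastid genome.", rec@taxon), con)
  writeLines(c("SOURCE      .", sprintf("  ORGANISM  %s", rec@taxon)), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  f <- rec@features
  if (nrow(f)) {
    for (fid in unique(f$feature_id)) {
      rows <- f[f$feature_id == fid, , drop = FALSE]
      locs <- sprintf("%d..%d", rows$start, rows$end)
      loc <- if (length(locs) > 1L) sprintf("join(%s)", paste(locs, collapse = ","))
             else locs
      if (rows$strand[1] == "-") loc <- sprintf("complement(%s)", loc)
      writeLines(sprintf("     %-16s%s", rows$kind[1], loc), con)
      if (!is.na(rows$name[1]))
        writeLines(sprintf("                     /gene=\"%s\"", rows$name[1]), con)
    }
  }
  writeLines("ORIGIN", con)
  s <- tolower(as.character(rec@seq))
  starts <- seq(1L, n, by = 60L)
  for (st in starts) {
    chunk <- substring(s, st, min(st + 59L, n))
    tens <- substring(chunk, seq(1, nchar(chunk), 10), pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    writeLines(sprintf("%9d %s", st, paste(tens, collapse = " ")), con)
  }
  writeLines("//", con)
  invisible(path)
}

#' Read / write plain FASTA genomes
#'
#' Thin wrappers over Biostrings FASTA I/O returning unannotated
#' \linkS4class{GenomeRecord}s.
#'
#' @param path FASTA file
#' @return list of \linkS4class{GenomeRecord}
#' @export
readFastaGenomes <- function(path) {
  ss <- readDNAStringSet(path)
  lapply(seq_along(ss), function(i)
    genomeRecord(ss[[i]], id = strsplit(names(ss)[i], "\\s+")[[1]][1],
                 taxon = names(ss)[i]))
}

#' @rdname readFastaGenomes
#' @param recs list of \linkS4class{GenomeRecord}
#' @export
writeFastaGenomes <- function(recs, path) {
  if (is(recs, "GenomeRecord")) recs <- list(recs)
  ss <- DNAStringSet(vapply(recs, function(r) as.character(r@seq), ""))
  names(ss) <- vapply(recs, function(r) r@id, "")
  writeXStringSet(ss, path)
  invisible(path)
}
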