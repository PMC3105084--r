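# Low-level sequence helpers shared across modules. Sequences are handled as
# plain upper-case character strings or per-base character vectors in hot
# loops; Biostrings objects are accepted at the user-facing boundary.

DNA_BASES <- c("A", "C", "G", "T")

.as_seq_string <- function(x) {
  if (is(x, "DNAString") || is(x, "BString")) return(as.character(x))
  if (is(x, "GenomeRecord")) return(as.character(x@seq))
  if (is.character(x) && length(x) == 1L) return(toupper(x))
  stop("cannot interpret input as a single nucleotide sequence")
}

.seq_chars <- function(x) strsplit(.as_seq_string(x), "", fixed = TRUE)[[1]]

.collapse_chars <- function(x) paste(x, collapse = "")

COMPLEMENT_MAP <- local({
  from <- c("A", "C", "G", "T", "N", "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "-", "?")
  to   <- c("T", "G", "C", "A", "N", "Y", "R", "S", "W", "M", "K", "V", "H", "D", "B", "-", "?")
  stats::setNames(to, from)
})

.complement_chars <- function(x) {
  out <- COMPLEMENT_MAP[x]
  out[is.na(out)] <- "N"
  unname(out)
}

.revcomp_chars <- function(x) rev(.complement_chars(x))

.revcomp_string <- function(x) .collapse_chars(.revcomp_chars(.seq_chars(x)))

# Alignment inputs: accept a character matrix (taxa x columns), a named
# character vector of equal-length strings, or a DNAStringSet.
.as_aln_matrix <- function(aln) {
  if (is.matrix(aln) && is.character(aln)) {
    m <- toupper(aln)
    if (is.null(rownames(m))) rownames(m) <- paste0("t", seq_len(nrow(m)))
    return(m)
  }
  if (is(aln, "DNAStringSet") || is(aln, "BStringSet")) {
    aln <- stats::setNames(as.character(aln), names(aln))
  }
  if (is.character(aln)) {
    if (length(unique(nchar(aln))) != 1L)
      stop("aligned sequences must have equal length")
    nm <- names(aln)
    if (is.null(nm)) nm <- paste0("t", seq_along(aln))
    m <- do.call(rbind, strsplit(toupper(aln), "", fixed = TRUE))
    rownames(m) <- nm
    return(m)
  }
  stop("cannot interpret input as a multiple alignment")
}

.is_gapchar <- function(x) x == "-" | x == "?"
.is_base <- function(x) x %in% DNA_BASES

# deterministic RNG scoping: evaluate expr with a local seed, restoring the
# caller's RNG state afterwards
.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(as.integer(seed))
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
  }
  force(expr)
}

.stopifnot_scalar_seq <- function(seq) {
  if (!nzchar(seq)) stop("empty sequence")
  invisible(TRUE)
}
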