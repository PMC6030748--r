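#' Aligned sequence set
#'
#' Equal-length sequences over the alphabet {A,C,G,T,N,-}, with an optional
#' population label per sequence.
#'
#' @param seqs named character vector of equal-length sequence strings.
#' @param pop character vector of population labels (default `NA`).
#' @return an object of class `seq_alignment` with elements `seq`, `pop`,
#'   `length`.
#' @export
seq_alignment <- function(seqs, pop = NULL) {
  if (!length(seqs)) stop("empty alignment", call. = FALSE)
  seqs <- toupper(seqs)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L)
    stop("sequences are not aligned: unequal lengths", call. = FALSE)
  if (any(grepl("[^ACGTN-]", seqs)))
    stop("alphabet restricted to A,C,G,T,N,-", call. = FALSE)
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  if (is.null(pop)) pop <- rep(NA_character_, length(seqs))
  structure(list(seq = seqs, pop = as.character(pop),
                 length = unname(lens[1])),
            class = "seq_alignment")
}

#' @export
print.seq_alignment <- function(x, ...) {
  cat(sprintf("seq_alignment: %d sequences of length %d\n",
              length(x$seq), x$length))
  invisible(x)
}

#' Read an aligned FASTA file
#'
#' Sequences must share one length. A `pop=<label>` token anywhere in a
#' header is parsed into the population field.
#'
#' @param path FASTA file path.
#' @return a [seq_alignment()].
#' @export
read_fasta_alignment <- function(path) {
  dna <- suppressWarnings(ape::read.FASTA(path))
  if (is.null(dna) || !length(dna)) stop("empty FASTA file", call. = FALSE)
  chr <- vapply(as.character(dna), function(s) paste(toupper(s), collapse = ""),
                character(1))
  headers <- names(chr)
  pop <- rep(NA_character_, length(chr))
  hit <- regmatches(headers, regexpr("pop=[^ \t]+", headers))
  has <- grepl("pop=", headers)
  pop[has] <- sub("^pop=", "", hit)
  ids <- vapply(strsplit(headers, "[ \t]"), `[`, character(1), 1L)
  names(chr) <- ids
  seq_alignment(chr, pop)
}

#' Write an alignment as FASTA
#'
#' Population labels, where present, are emitted as a `pop=` header token so
#' that [read_fasta_alignment()] round-trips them.
#'
#' @param aln a [seq_alignment()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta_alignment <- function(aln, path) {
  hdr <- names(aln$seq)
  has <- !is.na(aln$pop)
  hdr[has] <- paste0(hdr[has], " pop=", aln$pop[has])
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(aln$seq)) {
    writeLines(paste0(">", hdr[i]), con)
    writeLines(aln$seq[i], con)
  }
  invisible(path)
}
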