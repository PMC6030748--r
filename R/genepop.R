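#' Read a Genepop genotype file
#'
#' Parses the Genepop dialect: a title line, one locus name per line (or a
#' single comma-separated line), then blocks introduced by a line reading
#' `Pop` (case-insensitive), each row `id , a1a2 a1a2 ...` with 2- or
#' 3-digit allele codes per allele. A code of 0 for either allele marks the
#' genotype missing (half-calls are collapsed to missing, which is all the
#' format can represent).
#'
#' Population labels are derived from the identifier of the first individual
#' of each block, with a trailing `_<digits>` suffix stripped when present
#' (so `DAN1_01` labels its block `DAN1`); labels can be overridden
#' afterwards from a metadata file.
#'
#' @param path file path.
#' @param loci optional locus table from [locus_set()] (or a numeric vector
#'   of motif lengths, matched by position). When omitted, all motif lengths
#'   default to 1 so no congruence constraint is imposed.
#' @return a [genotype_table()].
#' @export
read_genepop <- function(path, loci = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  if (length(lines) < 3L) stop("not a Genepop file: too short", call. = FALSE)
  body <- lines[-1L]                       # drop title
  is_pop <- toupper(trimws(body)) == "POP"
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop)) stop("not a Genepop file: no 'Pop' line", call. = FALSE)
  loc_lines <- trimws(body[seq_len(first_pop - 1L)])
  loc_lines <- loc_lines[nzchar(loc_lines)]
  loc_names <- unlist(strsplit(loc_lines, ","))
  loc_names <- trimws(loc_names)
  loc_names <- loc_names[nzchar(loc_names)]
  if (!length(loc_names)) stop("no locus names found", call. = FALSE)
  if (is.null(loci)) {
    loci <- locus_set(loc_names, 1L)
  } else if (is.numeric(loci)) {
    loci <- locus_set(loc_names, loci)
  } else {
    if (nrow(loci) != length(loc_names))
      stop(sprintf("locus table has %d rows but file declares %d loci",
                   nrow(loci), length(loc_names)), call. = FALSE)
    loci$name <- loc_names
  }
  nl <- length(loc_names)

  ids <- character(); pops <- character()
  a1 <- a2 <- NULL
  pop_idx <- 0L; cur_pop <- NA_character_
  width <- NA_integer_
  for (k in seq(first_pop, length(body))) {
    raw <- trimws(body[k])
    if (!nzchar(raw)) next
    if (toupper(raw) == "POP") { pop_idx <- pop_idx + 1L; cur_pop <- NA_character_; next }
    lineno <- k + 1L                        # account for the title line
    parts <- strsplit(raw, ",")[[1]]
    if (length(parts) < 2L)
      stop(sprintf("line %d: expected 'id , genotypes'", lineno), call. = FALSE)
    id <- trimws(parts[1])
    gts <- strsplit(trimws(paste(parts[-1], collapse = " ")), "[ \t]+")[[1]]
    if (length(gts) != nl)
      stop(sprintf("line %d: %d genotype fields, expected %d", lineno,
                   length(gts), nl), call. = FALSE)
    nch <- nchar(gts)
    if (any(!nch %in% c(4L, 6L)) || length(unique(nch)) != 1L ||
        any(grepl("[^0-9]", gts)))
      stop(sprintf("line %d: malformed genotype field", lineno), call. = FALSE)
    w <- nch[1] / 2L
    if (is.na(width)) width <- w
    else if (width != w)
      stop(sprintf("line %d: mixed 2- and 3-digit allele codes", lineno),
           call. = FALSE)
    x1 <- as.integer(substr(gts, 1L, w))
    x2 <- as.integer(substr(gts, w + 1L, 2L * w))
    miss <- x1 == 0L | x2 == 0L
    x1[miss] <- NA_integer_; x2[miss] <- NA_integer_
    if (is.na(cur_pop)) cur_pop <- sub("_[0-9]+$", "", id)
    ids <- c(ids, id); pops <- c(pops, cur_pop)
    a1 <- rbind(a1, x1); a2 <- rbind(a2, x2)
  }
  if (!length(ids)) stop("no individuals found", call. = FALSE)
  genotype_table(a1, a2, ids, pops, loci)
}

#' Write a genotype table as canonical 3-digit Genepop
#'
#' @param x a [genotype_table()].
#' @param path output file path.
#' @param title title line (first line of the file).
#' @return `path`, invisibly.
#' @export
write_genepop <- function(x, path, title = "hydropop genotype export") {
  if (!length(x$ind)) stop("cannot write an empty genotype table", call. = FALSE)
  if (any(x$a2 > 999L, na.rm = TRUE))
    stop("allele size > 999 cannot be 3-digit encoded", call. = FALSE)
  enc <- function(v) { v[is.na(v)] <- 0L; sprintf("%03d", v) }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(title, con)
  writeLines(x$loci$name, con)
  for (p in unique(x$pop)) {
    writeLines("Pop", con)
    for (i in which(x$pop == p)) {
      g <- paste0(enc(x$a1[i, ]), enc(x$a2[i, ]))
      writeLines(paste(x$ind[i], ",", paste(g, collapse = " ")), con)
    }
  }
  invisible(path)
}
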