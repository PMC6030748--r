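#' Collapse aligned sequences to haplotypes
#'
#' Alignment columns containing `N` or `-` in any sequence are excluded
#' alignment-wide; sequences identical over the remaining sites are merged
#' into one haplotype. Haplotypes are numbered `H01`, `H02`, ... by first
#' occurrence.
#'
#' @param aln a [seq_alignment()].
#' @return a `haplotype_set`: `haplotypes` (representative full-length
#'   sequence per haplotype), `core` (used-site string actually compared),
#'   `freq`, `members`, `pop_counts` (haplotype x population matrix),
#'   `used_sites`.
#' @export
collapse_haplotypes <- function(aln) {
  if (!length(aln$seq)) stop("empty alignment", call. = FALSE)
  m <- do.call(rbind, strsplit(aln$seq, ""))
  bad <- apply(m, 2, function(col) any(col %in% c("N", "-")))
  used <- which(!bad)
  core <- apply(m[, used, drop = FALSE], 1, paste, collapse = "")
  first <- !duplicated(core)
  keys <- core[first]
  hid <- sprintf("H%02d", seq_along(keys))
  map <- stats::setNames(hid, keys)
  assign_ <- map[core]
  freq <- table(factor(assign_, levels = hid))
  members <- split(names(aln$seq), assign_)
  pops <- unique(aln$pop[!is.na(aln$pop)])
  pc <- matrix(0L, length(hid), length(pops), dimnames = list(hid, pops))
  for (i in seq_along(assign_)) {
    p <- aln$pop[i]
    if (!is.na(p)) pc[assign_[i], p] <- pc[assign_[i], p] + 1L
  }
  structure(list(haplotypes = stats::setNames(aln$seq[first], hid),
                 core = stats::setNames(keys, hid),
                 freq = stats::setNames(as.integer(freq), hid),
                 members = members[hid], pop_counts = pc,
                 used_sites = used),
            class = "haplotype_set")
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat(sprintf("haplotype_set: %d haplotypes from %d sequences (%d usable sites)\n",
              length(x$freq), sum(x$freq), length(x$used_sites)))
  invisible(x)
}

.hamming_matrix <- function(seqs) {
  m <- do.call(rbind, strsplit(seqs, ""))
  n <- nrow(m)
  d <- matrix(0L, n, n)
  if (n > 1) for (i in 1:(n - 1)) for (j in (i + 1):n) {
    d[i, j] <- d[j, i] <- sum(m[i, ] != m[j, ])
  }
  d
}

# epsilon-relaxed minimum spanning network: an edge of weight d is kept iff
# its endpoints are not already connected using only edges of weight
# < d - epsilon (epsilon = 0 gives the union of all minimum spanning trees)
.msn_edges <- function(d, epsilon = 0) {
  n <- nrow(d)
  if (n < 2) return(matrix(integer(), 0, 3,
                           dimnames = list(NULL, c("from", "to", "weight"))))
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  w <- d[upper.tri(d)]
  ord <- order(w, pairs[, 1], pairs[, 2])
  pairs <- pairs[ord, , drop = FALSE]; w <- w[ord]
  keep <- logical(length(w))
  for (e in seq_along(w)) {
    # connectivity with edges strictly below w[e] - epsilon
    thr <- w[e] - epsilon
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
    sel <- which(w < thr)
    for (q in sel) {
      a <- find(pairs[q, 1]); b <- find(pairs[q, 2])
      if (a != b) parent[a] <- b
    }
    keep[e] <- find(pairs[e, 1]) != find(pairs[e, 2])
  }
  cbind(from = pairs[keep, 1], to = pairs[keep, 2], weight = w[keep])
}

# sitewise majority consensus of three equal-length strings; ties take the
# state of the lexicographically smallest sequence among the three
.median_vector <- function(s1, s2, s3) {
  m <- rbind(strsplit(s1, "")[[1]], strsplit(s2, "")[[1]], strsplit(s3, "")[[1]])
  ord <- order(c(s1, s2, s3))
  apply_site <- function(col, lead) {
    tb <- table(col)
    if (max(tb) >= 2) names(tb)[which.max(tb)] else col[lead]
  }
  lead <- ord[1]
  paste(vapply(seq_len(ncol(m)), function(j) apply_site(m[, j], lead),
               character(1)), collapse = "")
}

#' Median-joining haplotype network
#'
#' Iteratively builds the epsilon-relaxed minimum spanning network on
#' Hamming distances, adds majority-consensus (median) vectors for triples
#' of connected nodes whenever the median shortens the connection of the
#' triple, and finally prunes inferred medians of degree < 3. With
#' `epsilon = 0` and homoplasy-free data the result is the minimum
#' spanning tree. Ties in median construction are broken by lexicographic
#' order, making the network independent of input order.
#'
#' @param haps a `haplotype_set` from [collapse_haplotypes()].
#' @param epsilon relaxation parameter of the spanning network (>= 0).
#' @param max_iter safety cap on median-addition rounds.
#' @return a `haplo_network`: `nodes` (id, type, freq, sequence over used
#'   sites), `edges` (from, to, weight = substitutions).
#' @export
median_joining <- function(haps, epsilon = 0, max_iter = 20L) {
  seqs <- unname(haps$core)
  ids <- names(haps$core)
  if (length(seqs) < 2L) stop("need >= 2 haplotypes", call. = FALSE)
  type <- rep("haplotype", length(seqs))
  n_median <- 0L
  repeat {
    d <- .hamming_matrix(seqs)
    ed <- .msn_edges(d, epsilon)
    if (max_iter <= 0L) break
    max_iter <- max_iter - 1L
    # adjacency for triple scan
    n <- length(seqs)
    adj <- matrix(FALSE, n, n)
    adj[ed[, c("from", "to"), drop = FALSE]] <- TRUE
    adj <- adj | t(adj)
    new_m <- character(0)
    for (u in seq_len(n - 1)) for (v in seq(u + 1, n)) {
      if (n >= 3) for (w_ in seq_len(n)) {
        if (w_ == u || w_ == v) next
        links <- adj[u, v] + adj[u, w_] + adj[v, w_]
        if (links < 2) next
        med <- .median_vector(seqs[u], seqs[v], seqs[w_])
        if (med %in% seqs || med %in% new_m) next
        dm <- c(sum(strsplit(med, "")[[1]] != strsplit(seqs[u], "")[[1]]),
                sum(strsplit(med, "")[[1]] != strsplit(seqs[v], "")[[1]]),
                sum(strsplit(med, "")[[1]] != strsplit(seqs[w_], "")[[1]]))
        trip <- sort(c(d[u, v], d[u, w_], d[v, w_]))
        if (sum(dm) < trip[1] + trip[2]) new_m <- c(new_m, med)
      }
    }
    if (!length(new_m)) break
    new_m <- sort(unique(new_m))
    seqs <- c(seqs, new_m)
    type <- c(type, rep("median", length(new_m)))
    ids <- c(ids, sprintf("mv%02d", n_median + seq_along(new_m)))
    n_median <- n_median + length(new_m)
  }
  # prune medians with degree < 3, rebuilding until stable
  repeat {
    d <- .hamming_matrix(seqs)
    ed <- .msn_edges(d, epsilon)
    deg <- tabulate(c(ed[, "from"], ed[, "to"]), nbins = length(seqs))
    drop <- which(type == "median" & deg < 3L)
    if (!length(drop)) break
    seqs <- seqs[-drop]; type <- type[-drop]; ids <- ids[-drop]
  }
  freq <- ifelse(type == "haplotype", haps$freq[ids], 0L)
  nodes <- data.frame(id = ids, type = type, freq = as.integer(freq),
                      sequence = seqs, stringsAsFactors = FALSE)
  edges <- data.frame(from = ids[ed[, "from"]], to = ids[ed[, "to"]],
                      weight = as.integer(ed[, "weight"]),
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges), class = "haplo_network")
}

#' @export
print.haplo_network <- function(x, ...) {
  cat(sprintf("haplo_network: %d nodes (%d inferred medians), %d edges\n",
              nrow(x$nodes), sum(x$nodes$type == "median"), nrow(x$edges)))
  invisible(x)
}

#' Write a haplotype network as edge-list TSV and GML
#'
#' @param net a `haplo_network`.
#' @param tsv_path edge-list TSV path (`NULL` to skip).
#' @param gml_path GML path (`NULL` to skip).
#' @return invisibly, the paths written.
#' @export
write_network <- function(net, tsv_path = NULL, gml_path = NULL) {
  if (!is.null(tsv_path))
    utils::write.table(net$edges, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(gml_path)) {
    con <- file(gml_path, "w")
    writeLines("graph [", con)
    for (i in seq_len(nrow(net$nodes)))
      writeLines(sprintf('  node [ id %d label "%s" freq %d ]',
                         i - 1L, net$nodes$id[i], net$nodes$freq[i]), con)
    idx <- stats::setNames(seq_len(nrow(net$nodes)) - 1L, net$nodes$id)
    for (i in seq_len(nrow(net$edges)))
      writeLines(sprintf('  edge [ source %d target %d weight %d ]',
                         idx[net$edges$from[i]], idx[net$edges$to[i]],
                         net$edges$weight[i]), con)
    writeLines("]", con)
    close(con)
  }
  invisible(c(tsv_path, gml_path))
}
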