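#' Population grouping scheme
#'
#' Maps populations to higher-level groups (watersheds), carries sampling
#' coordinates and a symmetric pairwise distance matrix in kilometres,
#' tagged by how the distances were obtained (`"great_circle"` from
#' coordinates or `"hydrographic"` when supplied explicitly).
#'
#' @param populations character vector of population labels.
#' @param group character vector, one group label per population.
#' @param coords optional matrix/data.frame with columns `lat`, `lon`.
#' @param dist optional symmetric distance matrix (km) with dimnames equal
#'   to `populations`; when omitted and coordinates are given, great-circle
#'   distances are computed.
#' @param dist_type tag recorded on the distance matrix.
#' @return an object of class `grouping_scheme`.
#' @export
grouping_scheme <- function(populations, group, coords = NULL, dist = NULL,
                            dist_type = if (is.null(dist)) "great_circle" else "hydrographic") {
  populations <- as.character(populations)
  if (anyDuplicated(populations))
    stop("duplicated population label", call. = FALSE)
  stopifnot(length(group) == length(populations))
  group <- stats::setNames(as.character(group), populations)
  if (!is.null(coords)) {
    coords <- as.matrix(coords[, c("lat", "lon")])
    rownames(coords) <- populations
  }
  if (is.null(dist) && !is.null(coords)) {
    # great-circle distances in km from lat/lon
    n <- length(populations)
    dist <- matrix(0, n, n, dimnames = list(populations, populations))
    if (n > 1L) {
      ll <- coords[, c("lon", "lat"), drop = FALSE]
      dist <- geosphere::distm(ll, fun = geosphere::distHaversine) / 1000
      dimnames(dist) <- list(populations, populations)
    }
  }
  if (!is.null(dist)) {
    dist <- as.matrix(dist)
    if (is.null(dimnames(dist)))
      dimnames(dist) <- list(populations, populations)
    if (!isTRUE(all.equal(unname(dist), unname(t(dist)), tolerance = 1e-8)))
      stop("distance matrix is not symmetric", call. = FALSE)
    diag(dist) <- 0
    attr(dist, "dist_type") <- dist_type
  }
  structure(list(populations = populations, group = group,
                 coords = coords, dist = dist),
            class = "grouping_scheme")
}

#' @export
print.grouping_scheme <- function(x, ...) {
  cat(sprintf("grouping_scheme: %d populations in %d groups (%d pairs)\n",
              length(x$populations), length(unique(x$group)),
              n_population_pairs(x)))
  invisible(x)
}

#' Number of unordered population pairs
#' @param x a `grouping_scheme`.
#' @return integer n(n-1)/2.
#' @export
n_population_pairs <- function(x) {
  n <- length(x$populations)
  n * (n - 1L) / 2L
}

#' Read population metadata
#'
#' Reads a delimited file (TSV or CSV, sniffed from the extension) with
#' columns `population`, `group` and optionally `lat`, `lon`. An explicit
#' pairwise-distance matrix (delimited, populations as header and first
#' column) may be supplied and takes precedence over coordinate-derived
#' great-circle distances; it is then tagged hydrographic.
#'
#' @param path metadata file.
#' @param dist_path optional path of an explicit distance matrix in km.
#' @return a [grouping_scheme()].
#' @export
read_metadata <- function(path, dist_path = NULL) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  md <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, comment.char = "#")
  need <- c("population", "group")
  if (!all(need %in% names(md)))
    stop("metadata must have columns population, group", call. = FALSE)
  if (anyDuplicated(md$population))
    stop("duplicated population in metadata", call. = FALSE)
  coords <- NULL
  if (all(c("lat", "lon") %in% names(md)))
    coords <- md[, c("lat", "lon")]
  dist <- NULL
  if (!is.null(dist_path)) {
    dsep <- if (grepl("\\.csv$", dist_path, ignore.case = TRUE)) "," else "\t"
    dm <- as.matrix(utils::read.table(dist_path, header = TRUE, sep = dsep,
                                      row.names = 1, check.names = FALSE))
    dm <- dm[md$population, md$population]
    if (!isTRUE(all.equal(unname(dm), unname(t(dm)), tolerance = 1e-8)))
      stop("explicit distance matrix is not symmetric", call. = FALSE)
    dist <- dm
  }
  grouping_scheme(md$population, md$group, coords = coords, dist = dist,
                  dist_type = if (is.null(dist)) "great_circle" else "hydrographic")
}

#' Write the metadata of a grouping scheme
#' @param x a `grouping_scheme`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(x, path) {
  md <- data.frame(population = x$populations,
                   group = unname(x$group[x$populations]),
                   stringsAsFactors = FALSE)
  if (!is.null(x$coords)) {
    md$lat <- x$coords[x$populations, "lat"]
    md$lon <- x$coords[x$populations, "lon"]
  }
  utils::write.table(md, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
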