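# Atom-pair fingerprints and Tanimoto similarity.
#
# A feature is an unordered pair of atom descriptors (element,
# heavy-neighbour count, pi-electron count) plus the topological distance in
# bonds between them.  Features are presence/absence: a fingerprint is a set.
# The canonical identity of a feature is its rendered string (see
# render_feature), which doubles as the serialisation key.

#' Atom-pair fingerprint of a molecular graph
#'
#' Enumerates every unordered pair of heavy atoms at topological distance
#' between 1 and `max_distance` and records the distinct (descriptor,
#' descriptor, distance) triples.  A single-atom molecule yields an empty
#' fingerprint.
#'
#' @param g a `molgraph`.
#' @param max_distance maximum topological distance (bonds) considered;
#'   default 15.
#' @return an object of class `atompair_fp`: list with `id` and `features`,
#'   a sorted character vector of rendered feature strings.
#' @examples
#' atom_pairs(parse_smiles("c1ccccc1", "benzene"))$features
#' @export
atom_pairs <- function(g, max_distance = 15L) {
  stopifnot(inherits(g, "molgraph"), max_distance >= 1L)
  tab <- atom_pair_table(g, max_distance)
  new_fingerprint(g$id, unique(tab$key))
}

new_fingerprint <- function(id, features) {
  structure(list(id = id, features = sort(unique(features))),
            class = "atompair_fp")
}

# Full pair table (one row per atom pair, not deduplicated): used by
# atom_pairs() and by the synthetic-data generator to identify which feature
# types touch planted motif atoms.
atom_pair_table <- function(g, max_distance = 15L) {
  n <- n_atoms(g)
  if (n < 2L) {
    return(data.frame(i = integer(0), j = integer(0), d = integer(0),
                      key = character(0), stringsAsFactors = FALSE))
  }
  dmat <- topological_distances(g)
  idx <- which(upper.tri(dmat) & dmat >= 1L & dmat <= max_distance,
               arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    return(data.frame(i = integer(0), j = integer(0), d = integer(0),
                      key = character(0), stringsAsFactors = FALSE))
  }
  i <- idx[, 1L]; j <- idx[, 2L]
  desc <- sprintf("%s|%d|%d", g$elements, g$heavy_neighbors, g$pi_electrons)
  da <- desc[i]; db <- desc[j]
  lo <- pmin(da, db); hi <- pmax(da, db)
  d <- dmat[idx]
  key <- render_feature_key(lo, hi, d)
  data.frame(i = i, j = j, d = d, key = key, stringsAsFactors = FALSE)
}

render_feature_key <- function(lo, hi, d) {
  fmt <- function(s) {
    p <- strsplit(s, "|", fixed = TRUE)
    vapply(p, function(x) sprintf("%s [%s neighbor(s),%s pi electrons]",
                                  x[1], x[2], x[3]), character(1))
  }
  sprintf("%s <-%d-> %s", fmt(lo), d, fmt(hi))
}

#' Render an atom-pair feature as a human-readable string
#'
#' Produces the conventional alert notation, e.g.
#' `"C [2 neighbor(s),1 pi electrons] <-3-> C [2 neighbor(s),1 pi electrons]"`.
#' The two descriptors are put in canonical (lexicographic) order first, so
#' the rendering is independent of argument order.  [parse_feature()] is the
#' exact inverse.
#'
#' @param desc_a,desc_b atom descriptors: lists or vectors with elements
#'   `element`, `heavy_neighbors`, `pi_electrons` (in that order).
#' @param distance topological distance in bonds, >= 1.
#' @return a single string.
#' @examples
#' render_feature(c("C", 2, 1), c("C", 2, 1), 3)
#' @export
render_feature <- function(desc_a, desc_b, distance) {
  stopifnot(length(desc_a) == 3L, length(desc_b) == 3L, distance >= 1)
  a <- sprintf("%s|%d|%d", as.character(desc_a[[1]]),
               as.integer(desc_a[[2]]), as.integer(desc_a[[3]]))
  b <- sprintf("%s|%d|%d", as.character(desc_b[[1]]),
               as.integer(desc_b[[2]]), as.integer(desc_b[[3]]))
  render_feature_key(pmin(a, b), pmax(a, b), as.integer(distance))
}

#' Parse a rendered atom-pair feature string
#'
#' Inverse of [render_feature()].
#'
#' @param s a rendered feature string.
#' @return a list with `desc_a`, `desc_b` (each a list of `element`,
#'   `heavy_neighbors`, `pi_electrons`) and `distance`.
#' @export
parse_feature <- function(s) {
  rx <- paste0("^([A-Z][a-z]?) \\[(\\d+) neighbor\\(s\\),(\\d+) pi electrons\\]",
               " <-(\\d+)-> ",
               "([A-Z][a-z]?) \\[(\\d+) neighbor\\(s\\),(\\d+) pi electrons\\]$")
  m <- regmatches(s, regexec(rx, s))[[1]]
  if (length(m) == 0L) stop(sprintf("not a rendered atom-pair feature: '%s'", s),
                            call. = FALSE)
  list(
    desc_a = list(element = m[2], heavy_neighbors = as.integer(m[3]),
                  pi_electrons = as.integer(m[4])),
    desc_b = list(element = m[6], heavy_neighbors = as.integer(m[7]),
                  pi_electrons = as.integer(m[8])),
    distance = as.integer(m[5])
  )
}

#' Tanimoto similarity between two fingerprints
#'
#' Set similarity |A∩B| / |A∪B|.  Undefined (an error) when both
#' fingerprints are empty.  `tanimoto_distance()` is `1 - similarity` and is
#' a metric on feature sets.
#'
#' @param a,b `atompair_fp` objects, or plain character vectors of feature
#'   keys.
#' @return similarity in `[0, 1]`.
#' @export
tanimoto_similarity <- function(a, b) {
  fa <- if (inherits(a, "atompair_fp")) a$features else as.character(a)
  fb <- if (inherits(b, "atompair_fp")) b$features else as.character(b)
  fa <- unique(fa); fb <- unique(fb)
  un <- length(union(fa, fb))
  if (un == 0L) {
    stop("Tanimoto similarity is undefined for two empty fingerprints",
         call. = FALSE)
  }
  length(intersect(fa, fb)) / un
}

#' @rdname tanimoto_similarity
#' @export
tanimoto_distance <- function(a, b) 1 - tanimoto_similarity(a, b)

#' @export
print.atompair_fp <- function(x, ...) {
  cat(sprintf("<atompair_fp '%s': %d features>\n", x$id, length(x$features)))
  invisible(x)
}

#' Fingerprint a set of chemicals
#'
#' @param graphs a list of `molgraph` objects (or a named character vector
#'   of SMILES strings, which are parsed first).
#' @param max_distance passed to [atom_pairs()].
#' @return a named list of `atompair_fp`, keyed by chemical id.
#' @export
fingerprint_all <- function(graphs, max_distance = 15L) {
  if (is.character(graphs)) {
    ids <- names(graphs)
    if (is.null(ids)) ids <- sprintf("mol%d", seq_along(graphs))
    graphs <- Map(parse_smiles, graphs, ids)
  }
  fps <- lapply(graphs, atom_pairs, max_distance = max_distance)
  names(fps) <- vapply(fps, `[[`, character(1), "id")
  fps
}

#' Serialise fingerprints to JSON
#'
#' Writes `{id: [sorted feature strings], ...}`; [read_fingerprints_json()]
#' restores the same named list of `atompair_fp`.
#'
#' @param fps named list of `atompair_fp`.
#' @param path output file.
#' @export
write_fingerprints_json <- function(fps, path) {
  obj <- lapply(fps, `[[`, "features")
  jsonlite::write_json(obj, path, auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_fingerprints_json
#' @export
read_fingerprints_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  fps <- Map(new_fingerprint, names(obj), lapply(obj, as.character))
  names(fps) <- names(obj)
  fps
}
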