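# Topological distances and structure-file readers.

#' Topological distance matrix of a molecular graph
#'
#' Shortest-path distances in bonds between every pair of heavy atoms.
#' The graph is connected by construction (fragment selection happens at
#' parse time), so all entries are finite.
#'
#' @param g a `molgraph`.
#' @return a symmetric integer matrix with zeros on the diagonal.
#' @examples
#' d <- topological_distances(parse_smiles("c1ccccc1"))
#' max(d)  # para carbons are 3 bonds apart
#' @export
topological_distances <- function(g) {
  stopifnot(inherits(g, "molgraph"))
  n <- n_atoms(g)
  ig <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(g$bonds) > 0L) {
    ig <- igraph::add_edges(ig, rbind(g$bonds$a, g$bonds$b))
  }
  d <- igraph::distances(ig)
  if (any(!is.finite(d))) {
    stop(sprintf("molecular graph '%s' is not connected", g$id), call. = FALSE)
  }
  storage.mode(d) <- "integer"
  dimnames(d) <- NULL
  d
}

#' Read a SMILES file into molecular graphs
#'
#' Expects one record per line: a SMILES string, whitespace, then an
#' identifier.  Lines without an identifier get `mol<line>`.  Blank lines
#' and lines starting with `#` are skipped.
#'
#' @param path file path.
#' @return a named list of `molgraph` objects (names are the ids).
#' @export
read_smiles_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  lines <- lines[keep]; lineno <- which(keep)
  out <- vector("list", length(lines))
  ids <- character(length(lines))
  for (i in seq_along(lines)) {
    parts <- strsplit(trimws(lines[[i]]), "[ \t]+")[[1]]
    id <- if (length(parts) >= 2L) parts[[2]] else sprintf("mol%d", lineno[[i]])
    out[[i]] <- parse_smiles(parts[[1]], id)
    ids[[i]] <- id
  }
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate id(s) in %s: %s", path,
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")),
         call. = FALSE)
  }
  names(out) <- ids
  out
}

#' Read an SDF (V2000) file into molecular graphs
#'
#' Parsing of the MDL format is delegated to \pkg{ChemmineR}; the atom and
#' bond blocks are then mapped onto heavy-atom graphs with the same
#' normalisation as [parse_smiles()] (hydrogen removal, largest fragment,
#' aromaticity re-perception of kekulized rings, nitro canonicalisation).
#' Bond order 4 in the SDF is honoured as aromatic.
#'
#' @param path file path to an SDF file.
#' @return a named list of `molgraph` objects keyed by the molecule titles.
#' @export
read_sdf_file <- function(path) {
  if (!requireNamespace("ChemmineR", quietly = TRUE)) {
    stop("reading SDF files requires the ChemmineR package", call. = FALSE)
  }
  sdf <- ChemmineR::read.SDFset(path)
  ids <- ChemmineR::sdfid(sdf)
  ids[!nzchar(ids)] <- sprintf("mol%d", which(!nzchar(ids)))
  out <- vector("list", length(sdf))
  for (i in seq_along(sdf)) {
    ab <- ChemmineR::atomblock(sdf[[i]])
    bb <- ChemmineR::bondblock(sdf[[i]])
    elements <- sub("_.*$", "", rownames(ab))
    bonds <- data.frame(a = as.integer(bb[, 1]), b = as.integer(bb[, 2]),
                        order = as.integer(bb[, 3]))
    out[[i]] <- build_molgraph(ids[[i]], elements,
                               aromatic = rep(FALSE, length(elements)),
                               bonds = bonds)
  }
  names(out) <- ids
  out
}
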