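# SMILES -> heavy-atom molecular graph.
#
# The parser covers the organic subset plus bracket atoms, branches, ring
# closures (incl. %nn), explicit bond symbols (- = # : / \), aromatic
# lowercase atoms and dot-separated fragments.  Directional bonds are read as
# single bonds; stereochemistry and isotopes are parsed and discarded.

ORGANIC_SUBSET <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
AROMATIC_ORGANIC <- c("b", "c", "n", "o", "p", "s")

# bond order codes: 1, 2, 3 sigma/pi multiplicities; 4 = aromatic
BOND_AROMATIC <- 4L

parse_error <- function(id, pos, msg) {
  stop(structure(
    class = c("toxbasket_parse_error", "error", "condition"),
    list(message = sprintf("SMILES parse error for '%s' at position %d: %s",
                           id, pos, msg),
         call = NULL, id = id, position = pos)
  ))
}

#' Parse a SMILES string into a heavy-atom molecular graph
#'
#' Builds an aromaticity-perceived molecular graph over heavy atoms only:
#' explicit and implicit hydrogens are discarded and never counted as
#' neighbours.  For disconnected inputs (e.g. salts) only the fragment with
#' the most heavy atoms is kept, ties going to the fragment that appears
#' first in the string.  Nitro groups written in the neutral form
#' `N(=O)=O` are normalised to the charge-separated form before atom
#' descriptors are derived, so nitroaromatic fingerprints do not depend on
#' how the group was drawn.
#'
#' Each atom carries the three descriptor fields used by atom-pair
#' fingerprints: element symbol, heavy-neighbour count, and pi-electron
#' count.  Pi electrons are counted as (incident double bonds) + 2 *
#' (incident triple bonds) + 1 if the atom is aromatic, capped at 2; an
#' aromatic ring carbon therefore has 1 pi electron and a carbonyl oxygen
#' has 1.
#'
#' @param smiles a single SMILES string.
#' @param id chemical identifier used in error messages and downstream
#'   tables (default `"mol"`).
#' @return an object of class `molgraph`: a list with elements `id`,
#'   `elements` (character), `aromatic` (logical), `heavy_neighbors`
#'   (integer), `pi_electrons` (integer) and `bonds` (data frame with
#'   columns `a`, `b`, `order`; order 4 denotes an aromatic bond).
#' @examples
#' g <- parse_smiles("c1ccccc1", "benzene")
#' g$heavy_neighbors   # all 2
#' g$pi_electrons      # all 1
#' @export
parse_smiles <- function(smiles, id = "mol") {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
      !nzchar(smiles)) {
    parse_error(id, 0L, "input must be a single non-empty string")
  }

  chars <- strsplit(smiles, "", fixed = TRUE)[[1]]
  n <- length(chars)

  element <- character(0)   # capitalized symbol
  aromatic <- logical(0)
  frag <- integer(0)        # fragment index (dot-separated / branch-derived)
  bond_a <- integer(0); bond_b <- integer(0); bond_o <- integer(0)

  prev <- NA_integer_       # atom awaiting the next bond
  stack <- integer(0)       # branch return points
  pending_bond <- NA_integer_
  ring <- list()            # closure digit -> list(atom, order)
  frag_id <- 1L

  add_bond <- function(a, b, o) {
    bond_a[[length(bond_a) + 1L]] <<- a
    bond_b[[length(bond_b) + 1L]] <<- b
    bond_o[[length(bond_o) + 1L]] <<- o
  }

  add_atom <- function(sym, arom, pos) {
    element[[length(element) + 1L]] <<- sym
    aromatic[[length(aromatic) + 1L]] <<- arom
    idx <- length(element)
    frag[[idx]] <<- frag_id
    if (!is.na(prev)) {
      o <- pending_bond
      if (is.na(o)) {
        o <- if (aromatic[[prev]] && arom) BOND_AROMATIC else 1L
      }
      add_bond(prev, idx, o)
    }
    prev <<- idx
    pending_bond <<- NA_integer_
    idx
  }

  close_ring <- function(key, pos) {
    if (is.na(prev)) parse_error(id, pos, "ring bond before any atom")
    if (is.null(ring[[key]])) {
      ring[[key]] <<- list(atom = prev, order = pending_bond)
      pending_bond <<- NA_integer_
    } else {
      open <- ring[[key]]
      ring[[key]] <<- NULL
      o <- pending_bond
      if (is.na(o)) o <- open$order
      if (!is.na(open$order) && !is.na(pending_bond) &&
          open$order != pending_bond) {
        parse_error(id, pos, sprintf("conflicting bond orders on ring closure %s", key))
      }
      if (is.na(o)) {
        o <- if (aromatic[[open$atom]] && aromatic[[prev]]) BOND_AROMATIC else 1L
      }
      if (open$atom == prev) parse_error(id, pos, "ring bond to self")
      add_bond(open$atom, prev, o)
      pending_bond <<- NA_integer_
    }
  }

  i <- 1L
  while (i <= n) {
    ch <- chars[[i]]
    if (ch == "[") {
      j <- i + 1L
      while (j <= n && chars[[j]] != "]") j <- j + 1L
      if (j > n) parse_error(id, i, "unterminated bracket atom")
      body <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      m <- regmatches(body, regexec(
        "^([0-9]*)([A-Za-z][a-z]?)(@{0,2})(H[0-9]*)?([+-][0-9]*|\\++|-+)?(:[0-9]+)?$",
        body))[[1]]
      if (length(m) == 0L) parse_error(id, i, sprintf("bad bracket atom [%s]", body))
      sym <- m[3]
      arom <- sym %in% AROMATIC_ORGANIC || sym == "se" || sym == "as"
      sym_cap <- paste0(toupper(substr(sym, 1, 1)), substring(sym, 2))
      if (sym_cap == "H") {
        # explicit hydrogen atom: record it, dropped later
        add_atom("H", FALSE, i)
      } else {
        add_atom(sym_cap, arom, i)
      }
      i <- j + 1L
    } else if (ch %in% c("C", "B") && i < n && chars[[i + 1L]] %in% c("l", "r") &&
               paste0(ch, chars[[i + 1L]]) %in% c("Cl", "Br")) {
      add_atom(paste0(ch, chars[[i + 1L]]), FALSE, i)
      i <- i + 2L
    } else if (ch %in% ORGANIC_SUBSET) {
      add_atom(ch, FALSE, i)
      i <- i + 1L
    } else if (ch %in% AROMATIC_ORGANIC) {
      add_atom(toupper(ch), TRUE, i)
      i <- i + 1L
    } else if (ch == "-") {
      pending_bond <- 1L; i <- i + 1L
    } else if (ch == "=") {
      pending_bond <- 2L; i <- i + 1L
    } else if (ch == "#") {
      pending_bond <- 3L; i <- i + 1L
    } else if (ch == ":") {
      pending_bond <- BOND_AROMATIC; i <- i + 1L
    } else if (ch %in% c("/", "\\")) {
      pending_bond <- 1L; i <- i + 1L
    } else if (ch == "(") {
      if (is.na(prev)) parse_error(id, i, "branch with no preceding atom")
      stack <- c(stack, prev); i <- i + 1L
    } else if (ch == ")") {
      if (length(stack) == 0L) parse_error(id, i, "unmatched ')'")
      prev <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (grepl("^[0-9]$", ch)) {
      close_ring(ch, i); i <- i + 1L
    } else if (ch == "%") {
      if (i + 2L > n || !grepl("^[0-9]{2}$", paste0(chars[[i + 1L]], chars[[i + 2L]]))) {
        parse_error(id, i, "'%' must be followed by two digits")
      }
      close_ring(paste0("%", chars[[i + 1L]], chars[[i + 2L]]), i)
      i <- i + 3L
    } else if (ch == ".") {
      prev <- NA_integer_
      pending_bond <- NA_integer_
      frag_id <- frag_id + 1L
      i <- i + 1L
    } else if (ch == "*") {
      parse_error(id, i, "wildcard atoms are not supported")
    } else {
      parse_error(id, i, sprintf("unexpected character '%s'", ch))
    }
  }
  if (length(stack) > 0L) parse_error(id, n, "unclosed branch")
  if (length(ring) > 0L) {
    parse_error(id, n, sprintf("unclosed ring bond(s): %s",
                               paste(names(ring), collapse = ", ")))
  }
  if (length(element) == 0L) parse_error(id, n, "no atoms parsed")

  build_molgraph(id, element, aromatic,
                 data.frame(a = bond_a, b = bond_b, order = bond_o))
}

# Shared finishing steps for all structure readers: drop hydrogens, keep the
# largest connected fragment (earliest on tie), re-perceive aromaticity of
# kekulized rings, normalise nitro groups, derive atom descriptors.
build_molgraph <- function(id, element, aromatic, bonds) {
  keep <- element != "H"
  if (!any(keep)) {
    stop(sprintf("structure '%s' has no heavy atoms", id), call. = FALSE)
  }
  remap <- cumsum(keep)
  bonds <- bonds[keep[bonds$a] & keep[bonds$b], , drop = FALSE]
  bonds$a <- remap[bonds$a]; bonds$b <- remap[bonds$b]
  element <- element[keep]; aromatic <- aromatic[keep]
  n <- length(element)

  # duplicate / self bonds are structural errors
  if (any(bonds$a == bonds$b)) {
    stop(sprintf("structure '%s': self-bond", id), call. = FALSE)
  }
  key <- paste(pmin(bonds$a, bonds$b), pmax(bonds$a, bonds$b))
  if (anyDuplicated(key)) {
    stop(sprintf("structure '%s': duplicate bond", id), call. = FALSE)
  }

  # largest fragment wins; tie -> fragment containing the earliest atom
  comp <- fragment_components(n, bonds)
  sizes <- tabulate(comp)
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) best <- comp[match(TRUE, comp %in% best)]
  sel <- comp == best[1L]
  if (!any(sel)) stop(sprintf("structure '%s': empty after fragment selection", id),
                      call. = FALSE)
  remap <- cumsum(sel)
  bonds <- bonds[sel[bonds$a] & sel[bonds$b], , drop = FALSE]
  bonds$a <- remap[bonds$a]; bonds$b <- remap[bonds$b]
  element <- element[sel]; aromatic <- aromatic[sel]
  n <- length(element)

  res <- perceive_kekulized_aromaticity(element, aromatic, bonds)
  aromatic <- res$aromatic; bonds <- res$bonds
  bonds <- normalize_nitro(element, bonds)

  deg <- tabulate(c(bonds$a, bonds$b), nbins = n)
  dbl <- tabulate(c(bonds$a[bonds$order == 2L], bonds$b[bonds$order == 2L]), nbins = n)
  trp <- tabulate(c(bonds$a[bonds$order == 3L], bonds$b[bonds$order == 3L]), nbins = n)
  arom_bond <- tabulate(c(bonds$a[bonds$order == BOND_AROMATIC],
                          bonds$b[bonds$order == BOND_AROMATIC]), nbins = n) > 0L
  aromatic <- aromatic | arom_bond
  pi <- pmin(2L, dbl + 2L * trp + as.integer(aromatic))

  structure(list(
    id = id,
    elements = element,
    aromatic = aromatic,
    heavy_neighbors = as.integer(deg),
    pi_electrons = as.integer(pi),
    bonds = bonds[order(pmin(bonds$a, bonds$b), pmax(bonds$a, bonds$b)), ,
                  drop = FALSE]
  ), class = "molgraph")
}

fragment_components <- function(n, bonds) {
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(bonds) > 0L) {
    g <- igraph::add_edges(g, rbind(bonds$a, bonds$b))
  }
  igraph::components(g)$membership
}

# Mark 5- and 6-membered rings written in kekulized form (alternating
# single/double bonds around the cycle, all atoms sp2) as aromatic.  SMILES
# written with lowercase aromatic atoms bypasses this entirely.
perceive_kekulized_aromaticity <- function(element, aromatic, bonds) {
  if (nrow(bonds) == 0L) return(list(aromatic = aromatic, bonds = bonds))
  n <- length(element)
  bkey <- function(a, b) paste(pmin(a, b), pmax(a, b))
  order_of <- structure(bonds$order, names = bkey(bonds$a, bonds$b))

  adj <- vector("list", n)
  for (r in seq_len(nrow(bonds))) {
    adj[[bonds$a[r]]] <- c(adj[[bonds$a[r]]], bonds$b[r])
    adj[[bonds$b[r]]] <- c(adj[[bonds$b[r]]], bonds$a[r])
  }

  # candidate rings: for every bond, shortest cycle through it (BFS on the
  # graph minus that bond); molecules here are small so this is cheap
  g <- igraph::make_empty_graph(n, directed = FALSE)
  g <- igraph::add_edges(g, rbind(bonds$a, bonds$b))
  ring_atoms <- integer(0); ring_bonds <- character(0)
  seen <- character(0)
  for (r in seq_len(nrow(bonds))) {
    g2 <- igraph::delete_edges(g, r)
    sp <- suppressWarnings(igraph::shortest_paths(g2, bonds$a[r], bonds$b[r],
                                                  mode = "all"))$vpath[[1]]
    len <- length(sp)
    if (len < 5L || len > 6L) next
    cyc <- as.integer(sp)
    ckey <- paste(sort(cyc), collapse = "-")
    if (ckey %in% seen) next
    seen <- c(seen, ckey)
    # bond orders around the cycle
    nxt <- c(cyc[-1L], cyc[1L])
    orders <- unname(order_of[bkey(cyc, nxt)])
    if (any(is.na(orders))) next
    if (any(orders == BOND_AROMATIC)) next       # already aromatic
    nd <- sum(orders == 2L)
    alternating <- all(orders %in% c(1L, 2L)) &&
      !any(orders == 2L & c(orders[-1L], orders[1L]) == 2L) &&
      nd == floor(length(cyc) / 2L)
    if (!alternating) next
    # 5-rings need exactly one heteroatom contributing a lone pair between
    # the two formally single-bonded positions; accept N/O/S there
    if (len == 5L) {
      lone <- cyc[orders == 1L & c(orders[length(orders)], orders[-length(orders)]) == 1L]
      if (length(lone) != 1L || !element[lone] %in% c("N", "O", "S")) next
    }
    ring_atoms <- union(ring_atoms, cyc)
    ring_bonds <- union(ring_bonds, bkey(cyc, nxt))
  }
  if (length(ring_atoms) > 0L) {
    aromatic[ring_atoms] <- TRUE
    hit <- bkey(bonds$a, bonds$b) %in% ring_bonds
    bonds$order[hit] <- BOND_AROMATIC
  }
  list(aromatic = aromatic, bonds = bonds)
}

# Canonicalise nitro groups to the charge-separated form: an N bonded to two
# terminal oxygens by two double bonds keeps the double bond to the
# lower-indexed oxygen; the other becomes single.  Makes fingerprints
# independent of whether -N(=O)=O or -[N+](=O)[O-] was written.
normalize_nitro <- function(element, bonds) {
  deg <- tabulate(c(bonds$a, bonds$b), nbins = length(element))
  ns <- which(element == "N")
  for (nid in ns) {
    inc <- which(bonds$a == nid | bonds$b == nid)
    other <- ifelse(bonds$a[inc] == nid, bonds$b[inc], bonds$a[inc])
    term_o <- inc[element[other] == "O" & deg[other] == 1L]
    if (length(term_o) < 2L) next
    dbl <- term_o[bonds$order[term_o] == 2L]
    if (length(dbl) >= 2L) {
      o_idx <- ifelse(bonds$a[dbl] == nid, bonds$b[dbl], bonds$a[dbl])
      keep <- dbl[which.min(o_idx)]
      bonds$order[setdiff(dbl, keep)] <- 1L
    }
  }
  bonds
}

#' @export
print.molgraph <- function(x, ...) {
  cat(sprintf("<molgraph '%s': %d heavy atoms, %d bonds%s>\n",
              x$id, length(x$elements), nrow(x$bonds),
              if (any(x$aromatic)) ", aromatic" else ""))
  invisible(x)
}

#' Number of heavy atoms in a molecular graph
#' @param g a `molgraph`.
#' @return integer atom count.
#' @export
n_atoms <- function(g) {
  stopifnot(inherits(g, "molgraph"))
  length(g$elements)
}
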