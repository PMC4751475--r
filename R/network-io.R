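#' Build an InteractionNetwork from an edge table
#'
#' Constructor used by the readers and the synthetic benchmark generator.
#' Self-loops are dropped and duplicate (including reversed) edges collapsed
#' to a single undirected edge; when weights are supplied the first
#' occurrence of a pair wins.
#'
#' @param from,to character vectors of protein IDs (parallel).
#' @param weight optional numeric vector of edge weights (NA allowed).
#' @param nodes optional character vector of additional isolated proteins.
#' @return an \linkS4class{InteractionNetwork}.
#' @export
makeInteractionNetwork <- function(from, to, weight = NULL, nodes = NULL) {
  from <- as.character(from); to <- as.character(to)
  stopifnot(length(from) == length(to))
  keep <- from != to
  from <- from[keep]; to <- to[keep]
  if (!is.null(weight)) weight <- weight[keep]
  # canonical order so A-B and B-A collapse
  lo <- pmin(from, to); hi <- pmax(from, to)
  key <- paste(lo, hi, sep = "\r")
  first <- !duplicated(key)
  lo <- lo[first]; hi <- hi[first]
  if (!is.null(weight)) weight <- weight[first]
  verts <- unique(c(lo, hi, as.character(nodes)))
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(verts), name = verts)
  if (length(lo) > 0) {
    g <- igraph::add_edges(g, rbind(match(lo, verts), match(hi, verts)))
    if (!is.null(weight) && any(!is.na(weight)))
      igraph::E(g)$weight <- as.numeric(weight)
  }
  new("InteractionNetwork", graph = g)
}

#' Build a ComplexCatalog from a list of member sets
#'
#' @param sets list of character vectors of protein IDs; duplicates within a
#'   set are removed.
#' @param scores optional per-complex numeric scores.
#' @return a \linkS4class{ComplexCatalog}.
#' @export
makeComplexCatalog <- function(sets, scores = numeric(0)) {
  sets <- lapply(sets, function(s) unique(as.character(s)))
  new("ComplexCatalog", complexes = sets, scores = as.numeric(scores))
}

#' Read a PPI network from a tab/whitespace-separated edge list
#'
#' Accepts two or three columns per line (protein_A, protein_B, optional
#' numeric weight); lines starting with \code{#} are comments. Self-loops
#' are removed and reversed or repeated pairs are collapsed; a message
#' reports how many records were dropped.
#'
#' @param path path to the edge-list file.
#' @return an \linkS4class{InteractionNetwork}.
#' @export
readNetwork <- function(path) {
  if (!file.exists(path)) stop("network file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  content <- !grepl("^\\s*#", lines) & !grepl("^\\s*$", lines)
  idx <- which(content)
  if (length(idx) == 0)
    return(makeInteractionNetwork(character(0), character(0)))
  toks <- strsplit(trimws(lines[idx]), "[ \t]+")
  bad <- which(vapply(toks, length, integer(1)) < 2)
  if (length(bad) > 0)
    stop("line ", idx[bad[1]], " of ", path, " has fewer than 2 fields")
  from <- vapply(toks, `[[`, character(1), 1)
  to <- vapply(toks, `[[`, character(1), 2)
  w <- vapply(toks, function(tk) {
    if (length(tk) >= 3) suppressWarnings(as.numeric(tk[3])) else NA_real_
  }, numeric(1))
  nSelf <- sum(from == to)
  net <- makeInteractionNetwork(from, to,
                                weight = if (any(!is.na(w))) w else NULL)
  nDup <- length(from) - nSelf - interactionCount(net)
  if (nSelf + nDup > 0)
    message("readNetwork: dropped ", nSelf, " self-interaction(s) and ",
            nDup, " duplicate edge(s)")
  net
}

#' Read a complex catalogue (one complex per line)
#'
#' Each non-empty line holds the whitespace-separated protein IDs of one
#' complex; duplicate IDs within a line are removed. Identical lines are
#' retained as distinct catalogue entries (training-set deduplication is
#' handled by \code{\link{buildPositiveInstances}}).
#'
#' @param path path to the catalogue file.
#' @return a \linkS4class{ComplexCatalog}.
#' @export
readComplexes <- function(path) {
  if (!file.exists(path)) stop("complex file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & !grepl("^\\s*$", lines)]
  makeComplexCatalog(strsplit(trimws(lines), "[ \t]+"))
}

#' Read a per-protein attribute table
#'
#' Header-less TSV with columns: protein ID, sequence length (residues),
#' and optionally molecular weight. Non-numeric or non-positive lengths and
#' duplicate IDs are errors.
#'
#' @param path path to the attribute file.
#' @return data.frame with columns \code{length}, \code{weight} and protein
#'   IDs as row names; \code{weight} is NA where absent.
#' @export
readAttributes <- function(path) {
  if (!file.exists(path)) stop("attribute file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & !grepl("^\\s*$", lines)]
  if (length(lines) == 0)
    return(data.frame(length = numeric(0), weight = numeric(0)))
  toks <- strsplit(trimws(lines), "[ \t]+")
  ids <- vapply(toks, `[[`, character(1), 1)
  if (anyDuplicated(ids))
    stop("duplicate protein ID in attribute table: ",
         ids[duplicated(ids)][1])
  len <- suppressWarnings(as.numeric(vapply(toks, `[[`, character(1), 2)))
  if (any(is.na(len))) stop("non-numeric sequence length in attribute table")
  if (any(len <= 0)) stop("sequence lengths must be positive")
  wt <- vapply(toks, function(tk) {
    if (length(tk) >= 3) suppressWarnings(as.numeric(tk[3])) else NA_real_
  }, numeric(1))
  if (any(is.na(wt) & vapply(toks, length, integer(1)) >= 3))
    stop("non-numeric molecular weight in attribute table")
  data.frame(length = len, weight = wt, row.names = ids)
}

#' Write a network, catalogue or attribute table to its flat-file format
#'
#' \code{writeNetwork} writes a 2- or 3-column edge list,
#' \code{writeComplexes} one complex per line (members tab-separated, sorted
#' for determinism), \code{writeAttributes} the id/length/weight TSV.
#'
#' @param x the object to write.
#' @param path destination file.
#' @return the path, invisibly.
#' @export
writeNetwork <- function(x, path) {
  g <- networkGraph(x)
  el <- igraph::as_edgelist(g)
  if (nrow(el) > 0) {
    o <- order(el[, 1], el[, 2])
    el <- el[o, , drop = FALSE]
    lines <- if (!is.null(igraph::E(g)$weight))
      paste(el[, 1], el[, 2], igraph::E(g)$weight[o], sep = "\t")
    else paste(el[, 1], el[, 2], sep = "\t")
  } else lines <- character(0)
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeNetwork
#' @export
writeComplexes <- function(x, path) {
  lines <- vapply(complexes(x),
                  function(s) paste(sort(s), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeNetwork
#' @export
writeAttributes <- function(x, path) {
  stopifnot(is.data.frame(x))
  lines <- vapply(seq_len(nrow(x)), function(i) {
    if (is.na(x$weight[i])) paste(rownames(x)[i], x$length[i], sep = "\t")
    else paste(rownames(x)[i], x$length[i], x$weight[i], sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
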