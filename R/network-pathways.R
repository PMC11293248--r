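#' Undirected gene network
#'
#' Stores an undirected graph as a canonical edge table (each unordered pair
#' once, endpoints sorted) plus a node set. Self-loops are dropped with a
#' warning, duplicate edges in either orientation are collapsed.
#'
#' @param edges two-column character matrix or data.frame of gene-id pairs.
#' @param nodes optional character vector of node ids; defaults to the union
#'   of edge endpoints, and is extended by any endpoint not listed.
#' @return object of class `gene_network` with elements `nodes` (character)
#'   and `edges` (two-column character matrix).
#' @export
gene_network <- function(edges = NULL, nodes = NULL) {
  if (is.null(edges) || NROW(edges) == 0L) {
    edges <- matrix(character(0), 0, 2)
  } else {
    edges <- as.matrix(edges)[, 1:2, drop = FALSE]
    storage.mode(edges) <- "character"
    loops <- edges[, 1] == edges[, 2]
    if (any(loops)) {
      warning(sum(loops), " self-loop(s) dropped")
      edges <- edges[!loops, , drop = FALSE]
    }
    edges <- t(apply(edges, 1, sort))
    if (nrow(edges)) edges <- unique(edges)
  }
  nodes <- sort(unique(c(as.character(nodes), as.vector(edges))))
  structure(list(nodes = nodes, edges = edges), class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("gene_network: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Neighbors of a gene in a network
#' @param network a `gene_network`.
#' @param gene gene identifier (must be a network node).
#' @return character vector of adjacent gene ids (possibly empty).
#' @export
neighbors_of <- function(network, gene) {
  if (!gene %in% network$nodes) stop("gene not in network: ", gene)
  e <- network$edges
  unique(c(e[e[, 1] == gene, 2], e[e[, 2] == gene, 1]))
}

#' Read a two-column edge list
#'
#' @param path tab-separated file with two gene ids per line, no header.
#' @return a `gene_network`.
#' @export
read_edge_list <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(gene_network())
  parts <- strsplit(lines, "\t")
  bad <- which(vapply(parts, length, 1L) < 2L)
  if (length(bad))
    stop("malformed edge at line ", bad[1], ": ", lines[bad[1]])
  gene_network(cbind(vapply(parts, `[[`, "", 1L),
                     vapply(parts, `[[`, "", 2L)))
}

#' Pathway membership map
#'
#' @param sets named list of character vectors (pathway id -> member genes).
#' @param descriptions optional named character vector of pathway descriptions.
#' @return object of class `pathway_map`.
#' @export
pathway_map <- function(sets = list(), descriptions = NULL) {
  if (length(sets)) {
    if (is.null(names(sets)) || anyDuplicated(names(sets)))
      stop("pathway ids must be unique and named")
    sets <- lapply(sets, function(s) unique(as.character(s)))
    if (any(!lengths(sets))) stop("pathway gene sets must be non-empty")
  }
  structure(list(sets = sets, descriptions = descriptions),
            class = "pathway_map")
}

#' @export
print.pathway_map <- function(x, ...) {
  cat(sprintf("pathway_map: %d pathways, median size %s\n", length(x$sets),
              if (length(x$sets)) stats::median(lengths(x$sets)) else NA))
  invisible(x)
}

#' Read a GMT pathway annotation file
#'
#' Standard GMT: per line a pathway name, a description, then member genes,
#' all tab-separated. Duplicate members within a line are collapsed.
#'
#' @param path path to the GMT file.
#' @return a `pathway_map`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(pathway_map())
  parts <- strsplit(lines, "\t")
  bad <- which(vapply(parts, length, 1L) < 3L)
  if (length(bad))
    stop("GMT line ", bad[1], " has fewer than 3 fields")
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, "", 1L)
  desc <- vapply(parts, `[[`, "", 2L)
  names(desc) <- names(sets)
  pathway_map(sets, desc)
}

#' Write a pathway map as GMT
#' @param pathways a `pathway_map`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(pathways, path) {
  desc <- pathways$descriptions
  lines <- vapply(names(pathways$sets), function(id) {
    d <- if (!is.null(desc) && !is.na(desc[id])) desc[[id]] else "na"
    paste(c(id, d, pathways$sets[[id]]), collapse = "\t")
  }, "")
  writeLines(lines, path, useBytes = FALSE)
  invisible(path)
}

#' Write a network as a two-column edge list
#' @param network a `gene_network`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(network, path) {
  writeLines(paste(network$edges[, 1], network$edges[, 2], sep = "\t"), path)
  invisible(path)
}
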