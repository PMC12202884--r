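#' Load a protein-protein interaction background network
#'
#' Reads an edge list in STRING \code{protein.links} layout (three or more
#' whitespace- or tab-separated columns: \code{protein1}, \code{protein2},
#' \code{combined_score}, with an optional header line) and keeps the edges
#' whose combined score is at least \code{min_score}. The resulting
#' undirected graph defines, for every gene, the candidate cause set used
#' when the reference causal network is fit.
#'
#' Self-loops are dropped, reciprocal duplicates are collapsed to a single
#' undirected edge, and when several identifiers map to the same symbol via
#' \code{id_map} the merged edge keeps the maximum score (the strongest
#' evidence wins).
#'
#' @param path Path to the edge-list file.
#' @param min_score Minimum combined score retained, on the STRING 0--1000
#'   scale. Edges scoring below the threshold are removed; the threshold
#'   value itself is kept. Default 700, the usual high-confidence cutoff.
#' @param id_map Optional identifier mapping: a named character vector or a
#'   two-column data frame (identifier, symbol) translating protein IDs to
#'   gene symbols. Unmapped identifiers are kept as-is.
#' @return A \code{background_net} object: list with \code{edges} (data frame
#'   \code{a}, \code{b}, \code{score}, with \code{a < b}) and a neighbour
#'   index.
#' @seealso [bg_neighbors()], [restrict_background()], [write_background()]
#' @export
#' @examples
#' f <- tempfile()
#' writeLines(c("p1 p2 900", "p1 p3 650", "p2 p3 700"), f)
#' bg <- load_background(f, min_score = 700)
#' bg$edges
load_background <- function(path, min_score = 700, id_map = NULL) {
  if (!is.numeric(min_score) || length(min_score) != 1 ||
      min_score < 0 || min_score > 1000)
    stop_("`min_score` must be a single number in [0, 1000]")
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop_("empty background file: ", path)
  fields <- strsplit(trimws(lines), "[ \t]+")
  start <- 1L
  if (is.na(suppressWarnings(as.numeric(fields[[1]][3]))))
    start <- 2L  # header line
  if (start > length(fields)) stop_("background file has a header but no data")
  fields <- fields[start:length(fields)]
  nf <- lengths(fields)
  bad <- which(nf < 3L)
  if (length(bad))
    stop_("unparseable background line ", bad[1] + start - 1L,
          ": expected >= 3 columns, found ", nf[bad[1]])
  a <- vapply(fields, `[[`, "", 1L)
  b <- vapply(fields, `[[`, "", 2L)
  score <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(score))
  if (length(bad))
    stop_("unparseable score on background line ", bad[1] + start - 1L)
  if (!is.null(id_map)) {
    map <- id_map
    if (is.data.frame(map)) map <- stats::setNames(as.character(map[[2]]),
                                                   as.character(map[[1]]))
    a <- ifelse(a %in% names(map), unname(map[a]), a)
    b <- ifelse(b %in% names(map), unname(map[b]), b)
  }
  keep <- score >= min_score & a != b
  if (!any(keep))
    stop_("no edges left after filtering at min_score = ", min_score)
  edges <- data.frame(a = pmin(a[keep], b[keep]),
                      b = pmax(a[keep], b[keep]),
                      score = score[keep], stringsAsFactors = FALSE)
  # collapse duplicates (including reciprocal pairs), keeping the max score
  key <- paste(edges$a, edges$b, sep = "\r")
  o <- order(key, -edges$score)
  edges <- edges[o, , drop = FALSE][!duplicated(key[o]), , drop = FALSE]
  edges <- edges[order(edges$a, edges$b), , drop = FALSE]
  rownames(edges) <- NULL
  new_background(edges)
}

new_background <- function(edges) {
  nbr <- split(c(edges$b, edges$a), c(edges$a, edges$b))
  nbr <- lapply(nbr, function(x) sort(unique(x)))
  structure(list(edges = edges, nbr = nbr), class = "background_net")
}

#' @export
print.background_net <- function(x, ...) {
  cat("Background PPI network: ", length(x$nbr), " genes, ",
      nrow(x$edges), " undirected edges\n", sep = "")
  if (nrow(x$edges))
    cat("Score range: [", min(x$edges$score), ", ", max(x$edges$score),
        "]\n", sep = "")
  invisible(x)
}

#' Restrict a background network to a gene set
#'
#' Induced subgraph on `genes`; genes left without any edge disappear.
#'
#' @param bg A `background_net`.
#' @param genes Character vector of gene identifiers to keep.
#' @return A `background_net` on the surviving edges.
#' @export
restrict_background <- function(bg, genes) {
  stopifnot(inherits(bg, "background_net"))
  keep <- bg$edges$a %in% genes & bg$edges$b %in% genes
  new_background(bg$edges[keep, , drop = FALSE])
}

#' Candidate cause set: first-order neighbours of a gene
#'
#' Returns the genes adjacent to `gene` in the background network, sorted
#' lexicographically so downstream regression design matrices are
#' reproducible.
#'
#' @param bg A `background_net`.
#' @param gene A gene identifier present in the network.
#' @return Character vector of neighbour genes (possibly empty for a node
#'   that only appears through `restrict_background` bookkeeping).
#' @export
bg_neighbors <- function(bg, gene) {
  stopifnot(inherits(bg, "background_net"))
  if (!gene %in% names(bg$nbr)) stop_("gene not in background network: ", gene)
  bg$nbr[[gene]]
}

#' Genes present in a background network
#' @param bg A `background_net`.
#' @return Sorted character vector of gene identifiers.
#' @export
bg_genes <- function(bg) sort(names(bg$nbr))

#' Write a background network as a three-column TSV
#'
#' Output columns `geneA`, `geneB`, `score`; the file is readable back with
#' [load_background()] (round-trip identity at `min_score = 0`).
#'
#' @param bg A `background_net`.
#' @param path Output file path.
#' @export
write_background <- function(bg, path) {
  stopifnot(inherits(bg, "background_net"))
  out <- bg$edges
  names(out) <- c("geneA", "geneB", "score")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
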