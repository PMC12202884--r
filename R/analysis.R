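# Coerce a cell -> group assignment (named vector or 2-column data frame)
# into a named character vector covering `cells`.
group_map <- function(groups, cells) {
  if (is.data.frame(groups))
    groups <- stats::setNames(as.character(groups[[2]]),
                              as.character(groups[[1]]))
  if (is.null(names(groups)) && length(groups) == length(cells))
    names(groups) <- cells
  miss <- setdiff(cells, names(groups))
  if (length(miss)) stop_("cell without group assignment: ", miss[1])
  stats::setNames(as.character(groups[cells]), cells)
}

#' Differential regulators between two cell groups
#'
#' Two-sided Student's t test (equal-variance) per gene row of the ODM,
#' comparing outdegree between two groups of cells, with
#' Benjamini--Hochberg FDR correction across genes. A gene whose regulatory
#' activity (outgoing-edge count) differs significantly between conditions
#' is a candidate driver of the transition between them.
#'
#' @param odm Genes x cells outdegree matrix (any genes x cells matrix
#'   works, e.g. expression for a conventional differential test).
#' @param groups Cell-to-group assignment: named vector or two-column data
#'   frame (cell, group).
#' @param group_a,group_b The two group labels to compare (each needs >= 2
#'   cells).
#' @param alpha FDR threshold for the `significant` flag; default 0.05.
#' @return Data frame with one row per gene: group means, t statistic, raw
#'   p, BH-adjusted q, `significant`, and `direction` (`"up"` = higher mean
#'   in `group_b`). Rows sorted by q, ties by gene. Genes constant in both
#'   groups get `statistic = NA`, `p = 1`.
#' @export
differential_regulators <- function(odm, groups, group_a, group_b,
                                    alpha = 0.05) {
  stopifnot(is.matrix(odm))
  g <- group_map(groups, colnames(odm))
  ia <- which(g == group_a)
  ib <- which(g == group_b)
  if (length(ia) < 2 || length(ib) < 2)
    stop_("both groups need at least 2 cells")
  res <- t(apply(odm, 1, function(x) {
    xa <- x[ia]; xb <- x[ib]
    out <- tryCatch({
      tt <- stats::t.test(xa, xb, var.equal = TRUE)
      c(tt$statistic, tt$p.value)
    }, error = function(e) c(NA_real_, 1))
    c(mean(xa), mean(xb), out)
  }))
  tab <- data.frame(gene = rownames(odm),
                    mean_a = res[, 1], mean_b = res[, 2],
                    statistic = res[, 3], p = res[, 4],
                    stringsAsFactors = FALSE)
  tab$q <- stats::p.adjust(tab$p, method = "BH")
  tab$significant <- tab$q < alpha
  tab$direction <- ifelse(tab$mean_b > tab$mean_a, "up", "down")
  tab <- tab[order(tab$q, tab$gene), ]
  rownames(tab) <- NULL
  tab
}

#' Per-edge activity counts by group
#'
#' For every reference edge, counts in each cell group how many cells carry
#' the edge in their cell-specific network (active) and how many do not
#' (inactive).
#'
#' @param nets A `cell_network_set`.
#' @param groups Cell-to-group assignment (named vector or two-column data
#'   frame); every cell must be labeled.
#' @return Data frame keyed by (`cause`, `target`) with columns
#'   `active_<group>` and `n_<group>` for every group.
#' @export
edge_activity_table <- function(nets, groups) {
  stopifnot(inherits(nets, "cell_network_set"))
  g <- group_map(groups, nets$cells)
  pres <- nets$omega > 0
  tab <- nets$edges
  for (lv in sort(unique(g))) {
    idx <- which(g == lv)
    tab[[paste0("active_", lv)]] <- as.integer(
      rowSums(pres[, idx, drop = FALSE]))
    tab[[paste0("n_", lv)]] <- length(idx)
  }
  attr(tab, "groups") <- sort(unique(g))
  tab
}

#' Chi-square test of edge activity change between two groups
#'
#' For each reference edge, tests whether the fraction of cells carrying
#' the edge differs between two groups via a 2x2 chi-square test
#' (active/inactive x group) with Yates continuity correction, followed by
#' Benjamini--Hochberg FDR correction across edges. An *up-regulated link*
#' is a significant edge whose active rate is higher in `group_b`.
#'
#' @param table Output of [edge_activity_table()].
#' @param group_a,group_b Group labels (baseline and target condition).
#' @param alpha FDR threshold; default 0.05.
#' @param correct Apply the Yates continuity correction (default `TRUE`,
#'   the standard 2x2 behaviour); `FALSE` gives the uncorrected statistic.
#' @return The table augmented with `statistic`, `p`, `q`, `significant`,
#'   `up_regulated`, sorted by q then edge. Edges active in no cell (or in
#'   all cells) of both groups get statistic 0, p 1.
#' @export
edge_activity_test <- function(table, group_a, group_b, alpha = 0.05,
                               correct = TRUE) {
  ca <- paste0("active_", group_a); na_ <- paste0("n_", group_a)
  cb <- paste0("active_", group_b); nb_ <- paste0("n_", group_b)
  miss <- setdiff(c(ca, na_, cb, nb_), names(table))
  if (length(miss)) stop_("missing count column: ", miss[1])
  if (any(table[[na_]] == 0) || any(table[[nb_]] == 0))
    stop_("empty group in activity table")
  res <- vapply(seq_len(nrow(table)), function(i) {
    m <- matrix(c(table[[ca]][i], table[[na_]][i] - table[[ca]][i],
                  table[[cb]][i], table[[nb_]][i] - table[[cb]][i]),
                nrow = 2)
    if (any(rowSums(m) == 0)) return(c(0, 1))
    ct <- suppressWarnings(stats::chisq.test(m, correct = correct))
    c(unname(ct$statistic), ct$p.value)
  }, numeric(2))
  out <- table
  out$rate_a <- out[[ca]] / out[[na_]]
  out$rate_b <- out[[cb]] / out[[nb_]]
  out$statistic <- res[1, ]
  out$p <- res[2, ]
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$q < alpha
  out$up_regulated <- out$significant & out$rate_b > out$rate_a
  out <- out[order(out$q, out$cause, out$target), ]
  rownames(out) <- NULL
  out
}

#' Consensus (cluster-specific) networks by edge prevalence
#'
#' For every cell cluster, keeps the reference edges present in at least
#' `prevalence_cutoff` of the cluster's cell-specific networks; edges
#' present in less than the cutoff fraction are removed (an edge exactly at
#' the boundary is kept). The result is one refined network per cluster,
#' e.g. a cell-type-specific regulatory network.
#'
#' @param nets A `cell_network_set`.
#' @param clusters Cell-to-cluster assignment (named vector or two-column
#'   data frame); every cell must be assigned and every cluster nonempty.
#' @param prevalence_cutoff Fraction in `[0, 1]`; default 0.70.
#' @return Named list of `causal_network` objects (role `"consensus"`),
#'   one per cluster, with `omega` = edge prevalence in the cluster.
#' @export
consensus_network <- function(nets, clusters, prevalence_cutoff = 0.70) {
  stopifnot(inherits(nets, "cell_network_set"),
            prevalence_cutoff >= 0, prevalence_cutoff <= 1)
  g <- group_map(clusters, nets$cells)
  pres <- nets$omega > 0
  out <- lapply(sort(unique(g)), function(lv) {
    idx <- which(g == lv)
    prop <- rowMeans(pres[, idx, drop = FALSE])
    keep <- prop >= prevalence_cutoff
    edges <- nets$edges[keep, , drop = FALSE]
    edges$omega <- prop[keep]
    rownames(edges) <- NULL
    causal_network(edges, role = "consensus", genes = nets$genes)
  })
  names(out) <- sort(unique(g))
  out
}

#' Top regulators of a network by outdegree
#'
#' Ranks the cause genes of a (binarized) network by their number of
#' targets, descending, ties broken lexicographically, and returns the
#' first `k`.
#'
#' @param net A `causal_network`.
#' @param k Number of regulators to return (fewer if the network has fewer
#'   cause genes).
#' @return Character vector of gene identifiers.
#' @export
top_regulators <- function(net, k = 10) {
  stopifnot(inherits(net, "causal_network"), k >= 1)
  e <- binarize(net)$edges
  if (!nrow(e)) return(character())
  deg <- sort(table(e$cause), decreasing = TRUE)
  ord <- names(deg)[order(-as.integer(deg), names(deg))]
  utils::head(ord, k)
}

#' Jaccard similarity of two networks
#'
#' Size of the intersection over the size of the union of the directed edge
#' sets. Two empty networks compare as 1 by convention.
#'
#' @param net_a,net_b `causal_network` objects.
#' @return Value in `[0, 1]`.
#' @export
jaccard_similarity <- function(net_a, net_b) {
  ea <- unique(paste(net_a$edges$cause, net_a$edges$target, sep = "\r"))
  eb <- unique(paste(net_b$edges$cause, net_b$edges$target, sep = "\r"))
  if (!length(ea) && !length(eb)) return(1)
  length(intersect(ea, eb)) / length(union(ea, eb))
}

#' Regulator activity along a cell ordering
#'
#' Extracts one regulator's outdegree across cells arranged along an
#' externally supplied ordering (e.g. a pseudotime rank over a lineage) and
#' smooths it with a centered moving average; positions near the ends use
#' symmetrically shrunken windows. The ordering is an input --- no
#' trajectory inference happens here.
#'
#' @param odm Genes x cells outdegree matrix.
#' @param cell_order Cell identifiers in the desired order (a subset of the
#'   ODM's cells).
#' @param regulator Gene whose activity curve is wanted.
#' @param window Odd moving-average width, `1` (no smoothing) to the series
#'   length.
#' @return List with `cells`, `raw` and `smoothed` numeric series.
#' @export
activity_curve <- function(odm, cell_order, regulator, window = 1) {
  stopifnot(is.matrix(odm))
  if (!regulator %in% rownames(odm))
    stop_("unknown regulator: ", regulator)
  miss <- setdiff(cell_order, colnames(odm))
  if (length(miss)) stop_("cell not in ODM: ", miss[1])
  raw <- odm[regulator, cell_order]
  n <- length(raw)
  if (window %% 2 != 1 || window < 1 || window > n)
    stop_("`window` must be an odd integer in [1, ", n, "]")
  h <- (window - 1) / 2
  smoothed <- vapply(seq_len(n), function(i)
    mean(raw[max(1, i - h):min(n, i + h)]), 0)
  list(cells = cell_order, raw = unname(raw), smoothed = smoothed)
}
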