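#' Network outdegree matrix (ODM)
#'
#' Aggregates a set of binarized cell-specific networks into a genes x
#' cells integer matrix: entry (g, k) is the number of outgoing edges of
#' gene g in cell k's network. The ODM has the same shape contract as the
#' expression matrix (same genes in rows, same cells in columns) and is a
#' drop-in replacement for it in clustering and embedding pipelines; it
#' encodes each gene's regulatory activity rather than its expression
#' level.
#'
#' @param nets A `cell_network_set` (from [infer_cell_networks()]) or a
#'   list of cell-role `causal_network` objects. Binarization (omega > 0)
#'   is applied internally.
#' @param gene_order Ordered gene identifiers for the rows; defaults to the
#'   gene order carried by the network set (the reference network's genes).
#'   Must cover every gene appearing as a cause.
#' @return Integer matrix, genes x cells.
#' @export
compute_odm <- function(nets, gene_order = NULL) {
  if (inherits(nets, "cell_network_set")) {
    gene_order <- gene_order %||% nets$genes
    check_gene_order(gene_order, nets$edges$cause)
    odm <- matrix(0L, length(gene_order), length(nets$cells),
                  dimnames = list(gene_order, nets$cells))
    if (nrow(nets$edges)) {
      pres <- (nets$omega > 0) * 1L
      counts <- rowsum(pres, nets$edges$cause)
      odm[rownames(counts), ] <- as.integer(counts)
    }
    return(odm)
  }
  stopifnot(is.list(nets), all(vapply(nets, inherits, TRUE,
                                      "causal_network")))
  gene_order <- gene_order %||%
    sort(unique(unlist(lapply(nets, `[[`, "genes"))))
  check_gene_order(gene_order,
                   unlist(lapply(nets, function(n) n$edges$cause)))
  cells <- vapply(seq_along(nets), function(k)
    nets[[k]]$cell_id %||% as.character(k), "")
  odm <- matrix(0L, length(gene_order), length(nets),
                dimnames = list(gene_order, cells))
  for (k in seq_along(nets)) {
    e <- binarize(nets[[k]])$edges
    if (nrow(e)) {
      tab <- table(e$cause)
      odm[names(tab), k] <- as.integer(tab)
    }
  }
  odm
}

check_gene_order <- function(gene_order, causes) {
  if (anyDuplicated(gene_order))
    stop_("duplicate gene in gene_order: ",
          gene_order[duplicated(gene_order)][1])
  miss <- setdiff(unique(causes), gene_order)
  if (length(miss)) stop_("gene_order does not cover gene: ", miss[1])
}

#' Concatenate ODMs along the cell dimension
#'
#' Joins per-condition ODMs (e.g. one per tissue region) into a single
#' integrated matrix, keeping all genes and stacking the cell columns in
#' list order. All parts must share an identical gene list in identical
#' order, and cell identifiers must be globally unique.
#'
#' @param parts List of ODMs (integer matrices with dimnames).
#' @return The concatenated ODM.
#' @export
concat_odm <- function(parts) {
  stopifnot(is.list(parts), length(parts) >= 1)
  genes <- rownames(parts[[1]])
  for (p in parts[-1])
    if (!identical(rownames(p), genes))
      stop_("gene lists differ between ODM parts")
  out <- do.call(cbind, parts)
  if (anyDuplicated(colnames(out)))
    stop_("duplicate cell identifier across ODM parts: ",
          colnames(out)[duplicated(colnames(out))][1])
  out
}
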