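# Predict one target for many cells from stored coefficients.
# `X` is parents x cells; an intercept-only model gives a constant row.
store_predict <- function(beta, X, intercept) {
  ncells <- ncol(X)
  if (intercept) {
    if (length(beta) == 1L) return(rep(unname(beta[1L]), ncells))
    drop(beta[1L] + crossprod(X[names(beta)[-1L], , drop = FALSE],
                              beta[-1L]))
  } else {
    if (!length(beta)) return(rep(0, ncells))
    drop(crossprod(X[names(beta), , drop = FALSE], beta))
  }
}

#' Infer the causal network of a single cell
#'
#' Re-evaluates every reference edge inside one cell: the target's observed
#' expression is compared against the reference-trained full-model
#' prediction (error `eps1`, the single-observation RMSE, i.e. the absolute
#' residual) and against each leave-one-parent-out prediction (`eps2`). The
#' edge `parent -> target` is present in the cell exactly when
#' `csi(eps2, eps1) > 0`, i.e. when removing the parent worsens the
#' prediction of the target **in this cell**. Cell networks are therefore
#' always edge subsets of the reference network.
#'
#' @param cell_profile Named numeric vector of expression values covering
#'   every gene referenced by the store.
#' @param store A `model_store` from [fit_model_store()].
#' @param omega_max Cap for degenerate error ratios; see [csi()].
#' @param cell_id Optional identifier attached to the returned network.
#' @return A cell-role `causal_network` with per-edge omega.
#' @export
infer_cell_network <- function(cell_profile, store, omega_max = 50,
                               cell_id = NULL) {
  stopifnot(inherits(store, "model_store"))
  miss <- setdiff(store$genes, names(cell_profile))
  if (length(miss)) stop_("gene missing from cell profile: ", miss[1])
  m <- matrix(cell_profile[store$genes], ncol = 1,
              dimnames = list(store$genes, cell_id %||% "cell"))
  nets <- infer_cell_networks(m, store, omega_max)
  edges <- nets$edges
  edges$omega <- nets$omega[, 1L]
  edges <- edges[edges$omega > 0, , drop = FALSE]
  rownames(edges) <- NULL
  causal_network(edges, role = "cell", genes = store$gene_order,
                 cell_id = cell_id)
}

#' Infer cell-specific networks for every cell of a matrix
#'
#' Applies the per-cell edge re-evaluation of [infer_cell_network()] to
#' every column of an objective expression matrix. Cells are processed
#' independently, so the result does not depend on column order beyond the
#' ordering of the output.
#'
#' @param expr_obj Genes x cells objective expression matrix covering all
#'   genes referenced by the store.
#' @param store A `model_store`.
#' @param omega_max Cap for degenerate error ratios; see [csi()].
#' @return A `cell_network_set`: reference edge table (`cause`, `target`)
#'   plus an edges x cells matrix of omega values; an edge is present in a
#'   cell when its omega is positive. Individual networks are extracted
#'   with `[[` or [get_cell_network()].
#' @export
infer_cell_networks <- function(expr_obj, store, omega_max = 50) {
  stopifnot(is.matrix(expr_obj), inherits(store, "model_store"))
  miss <- setdiff(store$genes, rownames(expr_obj))
  if (length(miss)) stop_("gene missing from expression matrix: ", miss[1])
  cells <- colnames(expr_obj) %||% as.character(seq_len(ncol(expr_obj)))
  blocks <- lapply(store$targets, function(t) {
    y <- expr_obj[t$target, ]
    X <- expr_obj[t$parents, , drop = FALSE]
    eps1 <- abs(y - store_predict(t$coef_full, X, store$intercept))
    om <- vapply(t$parents, function(p) {
      eps2 <- abs(y - store_predict(t$coef_reduced[[p]], X,
                                    store$intercept))
      csi(eps2, eps1, omega_max)
    }, numeric(ncol(expr_obj)))
    # vapply over parents gives cells x parents; transpose to edge rows
    if (ncol(expr_obj) == 1L) om <- matrix(om, nrow = 1L)
    t(om)
  })
  edges <- data.frame(
    cause = unlist(lapply(store$targets, `[[`, "parents"),
                   use.names = FALSE),
    target = rep(names(store$targets),
                 vapply(store$targets, function(t) length(t$parents), 0L)),
    stringsAsFactors = FALSE)
  omega <- do.call(rbind, blocks)
  dimnames(omega) <- list(NULL, cells)
  structure(list(edges = edges, omega = omega, cells = cells,
                 genes = store$gene_order),
            class = "cell_network_set")
}

#' @export
print.cell_network_set <- function(x, ...) {
  pres <- x$omega > 0
  cat("Cell-specific network set: ", length(x$cells), " cells, ",
      nrow(x$edges), " reference edges\n", sep = "")
  if (length(pres))
    cat("Mean edges per cell: ", round(mean(colSums(pres)), 1), "\n",
        sep = "")
  invisible(x)
}

#' @export
length.cell_network_set <- function(x) length(x$cells)

#' Extract one cell's network from a set
#'
#' @param nets A `cell_network_set`.
#' @param cell Cell identifier or column index.
#' @return A cell-role `causal_network`.
#' @export
get_cell_network <- function(nets, cell) {
  stopifnot(inherits(nets, "cell_network_set"))
  if (is.character(cell)) {
    k <- match(cell, nets$cells)
    if (is.na(k)) stop_("unknown cell: ", cell)
  } else k <- cell
  edges <- nets$edges
  edges$omega <- nets$omega[, k]
  edges <- edges[edges$omega > 0, , drop = FALSE]
  rownames(edges) <- NULL
  causal_network(edges, role = "cell", genes = nets$genes,
                 cell_id = nets$cells[k])
}

#' @export
`[[.cell_network_set` <- function(x, i) get_cell_network(x, i)

#' Write a cell-network set as long-format TSV
#'
#' One row per (cell, present edge): columns `cause`, `target`, `omega`,
#' `cell_id`.
#' @param nets A `cell_network_set`.
#' @param path File path.
#' @export
write_cell_networks <- function(nets, path) {
  stopifnot(inherits(nets, "cell_network_set"))
  pres <- nets$omega > 0
  idx <- which(pres, arr.ind = TRUE)
  out <- data.frame(cause = nets$edges$cause[idx[, 1]],
                    target = nets$edges$target[idx[, 1]],
                    omega = nets$omega[pres],
                    cell_id = nets$cells[idx[, 2]],
                    stringsAsFactors = FALSE)
  out <- out[order(match(out$cell_id, nets$cells), idx[, 1]), ]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
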