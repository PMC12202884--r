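#' Fit a cell-specific causal network model
#'
#' The main entry point. Fits the reference causal network from a reference
#' expression dataset over a PPI background ([build_reference_network()]),
#' then freezes the reference-trained predictors ([fit_model_store()]).
#' The returned model predicts a causal network for any individual cell:
#' `predict()` re-evaluates every reference edge inside each cell of a new
#' (objective) dataset and can return the cell networks or their outdegree
#' matrix directly.
#'
#' For each target gene the candidate causes are its first-order
#' neighbours in the score-filtered background. Cross-validated linear
#' regressions with and without each candidate give held-out errors
#' `eps_full` and `eps_reduced`; the causal strength index
#' `omega = ln(eps_reduced / eps_full)` admits the edge when positive.
#'
#' @param expr_ref Genes x cells reference expression matrix (normalized;
#'   see [normalize_expression()]).
#' @param background A `background_net` (see [load_background()]).
#' @param folds Cross-validation folds for the reference step; default 5.
#' @param seed Integer seed controlling the fold assignment.
#' @param intercept Fit regressions with an intercept; default `TRUE`.
#' @param omega_max Cap for degenerate error ratios; see [csi()].
#' @return An object of class `"sicnet"`: list with `network` (the
#'   reference `causal_network`), `store` (the `model_store`), `genes`,
#'   and the call/fit settings. Methods: [print.sicnet()],
#'   [summary.sicnet()], [coef.sicnet()], [predict.sicnet()],
#'   [plot.sicnet()].
#' @export
#' @examples
#' scn <- simulate_grn(10, 6, n_distractors = 5, seed = 7)
#' expr <- simulate_expression(scn, 120, seed = 8)
#' fit <- sicnet(expr, scn$background, seed = 1)
#' fit
#' odm <- predict(fit, simulate_expression(scn, 20, seed = 9), type = "odm")
sicnet <- function(expr_ref, background, folds = 5, seed = 1,
                   intercept = TRUE, omega_max = 50) {
  cl <- match.call()
  net <- build_reference_network(expr_ref, background, folds = folds,
                                 seed = seed, intercept = intercept,
                                 omega_max = omega_max)
  store <- fit_model_store(expr_ref, net, intercept = intercept)
  structure(list(network = net, store = store, genes = net$genes,
                 folds = folds, seed = seed, intercept = intercept,
                 omega_max = omega_max, n_ref_cells = ncol(expr_ref),
                 call = cl),
            class = "sicnet")
}

#' @export
print.sicnet <- function(x, ...) {
  cat("Cell-specific causal network model\n")
  cat("Call: ", deparse(x$call), "\n", sep = "")
  cat("Reference network: ", nrow(x$network$edges), " directed edges over ",
      length(x$genes), " genes (", x$n_ref_cells, " reference cells, ",
      x$folds, "-fold CV)\n", sep = "")
  invisible(x)
}

#' Summarize a fitted causal network model
#'
#' @param object A `sicnet` fit.
#' @param ... Unused.
#' @return A `summary.sicnet` with edge counts, omega distribution and the
#'   top regulators by outdegree.
#' @export
summary.sicnet <- function(object, ...) {
  e <- object$network$edges
  structure(list(call = object$call, n_genes = length(object$genes),
                 n_edges = nrow(e), n_ref_cells = object$n_ref_cells,
                 folds = object$folds,
                 omega = if (nrow(e)) summary(e$omega) else NULL,
                 top = top_regulators(object$network, 10)),
            class = "summary.sicnet")
}

#' @export
print.summary.sicnet <- function(x, ...) {
  cat("Cell-specific causal network model\n")
  cat("Call: ", deparse(x$call), "\n\n", sep = "")
  cat(x$n_edges, " reference edges over ", x$n_genes, " genes; ",
      x$n_ref_cells, " reference cells, ", x$folds, "-fold CV\n", sep = "")
  if (!is.null(x$omega)) {
    cat("\nCausal strength (omega) of retained edges:\n")
    print(x$omega)
  }
  if (length(x$top))
    cat("\nTop regulators by outdegree: ",
        paste(x$top, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Reference-model coefficients
#'
#' Full-model regression coefficients per target gene (parents of the
#' target in the reference network, plus the intercept when fitted).
#'
#' @param object A `sicnet` fit.
#' @param target Optional single target gene; default all targets.
#' @param ... Unused.
#' @return A named list of coefficient vectors (or one vector when
#'   `target` is given).
#' @export
coef.sicnet <- function(object, target = NULL, ...) {
  co <- lapply(object$store$targets, `[[`, "coef_full")
  if (is.null(target)) return(co)
  if (!target %in% names(co)) stop_("no model for target: ", target)
  co[[target]]
}

#' Predict cell-specific networks for new cells
#'
#' Applies the reference-trained predictors to every cell of a new
#' expression matrix and returns either the cell-specific networks or
#' their network outdegree matrix.
#'
#' @param object A `sicnet` fit.
#' @param newdata Genes x cells expression matrix covering the model's
#'   genes (same normalization as the reference data).
#' @param type `"networks"` for the `cell_network_set`, `"odm"` for the
#'   genes x cells outdegree matrix.
#' @param ... Unused.
#' @return See `type`.
#' @export
predict.sicnet <- function(object, newdata,
                           type = c("networks", "odm"), ...) {
  type <- match.arg(type)
  nets <- infer_cell_networks(newdata, object$store,
                              omega_max = object$omega_max)
  if (type == "odm") compute_odm(nets) else nets
}

#' Plot a fitted causal network model
#'
#' Two base-graphics panels: the distribution of the causal strength index
#' over retained reference edges, and the outdegree distribution of the
#' reference network.
#'
#' @param x A `sicnet` fit.
#' @param ... Passed to [graphics::hist()].
#' @export
plot.sicnet <- function(x, ...) {
  e <- x$network$edges
  if (!nrow(e)) {
    warning("empty reference network; nothing to plot", call. = FALSE)
    return(invisible(x))
  }
  old <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(old))
  graphics::hist(e$omega, main = "Causal strength index",
                 xlab = expression(omega), col = "grey80", ...)
  deg <- table(factor(e$cause, levels = x$genes))
  graphics::hist(as.integer(deg), main = "Reference outdegree",
                 xlab = "outgoing edges per gene", col = "grey80", ...)
  invisible(x)
}
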