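#' Fit the reference predictor store
#'
#' Freezes the reference causal network into a set of reference-trained
#' linear predictors used for per-cell inference. For each target gene with
#' parent set P in the reference network, the full model (target on P) and
#' every leave-one-parent-out reduced model are fit on **all** reference
#' cells (no cross-validation here: the CV folds exist only to estimate the
#' reference-network errors robustly). When a target has a single parent the
#' reduced model degenerates to the intercept-only predictor (or the
#' constant zero without an intercept). Targets with no parents get no
#' models.
#'
#' @param expr_ref Genes x cells reference expression matrix (the same data
#'   the reference network was built from).
#' @param ref_net A reference-role `causal_network`.
#' @param intercept Fit with an intercept; default `TRUE`. Must match the
#'   choice used for the reference network.
#' @return A `model_store`: per-target parent lists and coefficient vectors,
#'   plus a fingerprint of the reference data.
#' @seealso [infer_cell_network()], [write_model_store()]
#' @export
fit_model_store <- function(expr_ref, ref_net, intercept = TRUE) {
  stopifnot(is.matrix(expr_ref), inherits(ref_net, "causal_network"))
  if (ref_net$role != "reference")
    stop_("model store must be fit from a reference-role network")
  miss <- setdiff(unique(c(ref_net$edges$cause, ref_net$edges$target)),
                  rownames(expr_ref))
  if (length(miss)) stop_("gene not in expression matrix: ", miss[1])
  by_target <- split(ref_net$edges$cause, ref_net$edges$target)
  targets <- lapply(names(by_target), function(g) {
    parents <- sort(unique(by_target[[g]]))
    y <- expr_ref[g, ]
    X <- t(expr_ref[parents, , drop = FALSE])
    full <- ridge_lstsq(X, y, intercept)
    reduced <- lapply(seq_along(parents), function(j) {
      if (length(parents) > 1)
        ridge_lstsq(X[, -j, drop = FALSE], y, intercept)
      else if (intercept) c(`(Intercept)` = mean(y)) else numeric(0)
    })
    names(reduced) <- parents
    list(target = g, parents = parents, coef_full = full,
         coef_reduced = reduced)
  })
  names(targets) <- names(by_target)
  structure(list(targets = targets, intercept = intercept,
                 genes = sort(unique(c(ref_net$edges$cause,
                                       ref_net$edges$target))),
                 gene_order = ref_net$genes,
                 fingerprint = sprintf("%dx%d/%.10g", nrow(expr_ref),
                                       ncol(expr_ref), sum(expr_ref))),
            class = "model_store")
}

#' @export
print.model_store <- function(x, ...) {
  np <- vapply(x$targets, function(t) length(t$parents), 0L)
  cat("Reference model store: ", length(x$targets), " targets, ",
      sum(np), " parent edges (max in-degree ", if (length(np)) max(np) else 0,
      ")\n", sep = "")
  invisible(x)
}

#' Serialize / load a model store
#'
#' JSON serialization with full double precision; `read_model_store`
#' restores an object whose predictions are identical to the original's.
#'
#' @param store A `model_store`.
#' @param path File path (JSON).
#' @export
write_model_store <- function(store, path) {
  stopifnot(inherits(store, "model_store"))
  payload <- list(
    format = "sicnet-model-store", version = 1L,
    intercept = store$intercept, genes = store$genes,
    gene_order = store$gene_order, fingerprint = store$fingerprint,
    targets = lapply(store$targets, function(t) {
      list(target = t$target, parents = as.list(t$parents),
           coef_full = as.list(t$coef_full),
           coef_reduced = lapply(t$coef_reduced, as.list))
    }))
  writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA),
             path)
  invisible(path)
}

#' @rdname write_model_store
#' @export
read_model_store <- function(path) {
  p <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(p$format, "sicnet-model-store"))
    stop_("not a sicnet model store: ", path)
  targets <- lapply(p$targets, function(t) {
    list(target = t$target,
         parents = as.character(unlist(t$parents)),
         coef_full = unlist(t$coef_full),
         coef_reduced = lapply(t$coef_reduced, function(v)
           if (length(v)) unlist(v) else numeric(0)))
  })
  structure(list(targets = targets, intercept = p$intercept,
                 genes = as.character(unlist(p$genes)),
                 gene_order = as.character(unlist(p$gene_order)),
                 fingerprint = p$fingerprint),
            class = "model_store")
}
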