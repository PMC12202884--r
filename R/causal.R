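#' Causal strength index (CSI)
#'
#' The log ratio of the prediction error without a candidate cause to the
#' error with it: \code{omega = ln(eps_excluded / eps_full)}. A positive
#' value means the candidate improves held-out (or per-cell) prediction of
#' the target, which is read as evidence for a causal edge; zero or negative
#' values mean no edge.
#'
#' Boundary conventions: when both errors are zero there is no evidence
#' either way and the index is 0; when exactly one error is zero the ratio
#' is capped at `+omega_max` (perfect full model) or `-omega_max`, keeping
#' the antisymmetry `csi(a, b) == -csi(b, a)` on the whole domain.
#'
#' @param eps_excluded Nonnegative error of the reduced (cause-removed)
#'   model.
#' @param eps_full Nonnegative error of the full model.
#' @param omega_max Cap applied when one error is exactly zero; default 50.
#' @return The index omega (vectorized over its first two arguments).
#' @export
#' @examples
#' csi(0.3, 0.2)        # log(1.5)
#' csi(exp(1) * 2, 2)   # 1
csi <- function(eps_excluded, eps_full, omega_max = 50) {
  if (any(eps_excluded < 0) || any(eps_full < 0))
    stop_("errors must be nonnegative")
  omega <- suppressWarnings(log(eps_excluded / eps_full))
  omega[eps_excluded == 0 & eps_full == 0] <- 0
  omega[eps_full == 0 & eps_excluded > 0] <- omega_max
  omega[eps_excluded == 0 & eps_full > 0] <- -omega_max
  omega
}

#' Cross-validated paired-regression errors for one target gene
#'
#' The error side of the reference-network edge test. Cells are split into
#' `folds` nearly equal random subsets; in each round one subset is held
#' out, the full linear model (target on all candidate regulators) and every
#' leave-one-regulator-out model are fit on the remaining cells, and the
#' root-mean-square prediction error is measured on the held-out cells. The
#' per-fold RMSEs are averaged to give `eps_full` (one value) and
#' `eps_reduced` (one value per regulator). The full model is fit once per
#' fold and shared across all the single-regulator comparisons of the
#' target.
#'
#' @param expr_ref Genes x cells reference expression matrix.
#' @param target Target gene identifier (a row of `expr_ref`).
#' @param regulators Candidate cause genes (rows of `expr_ref`, excluding
#'   the target).
#' @param folds Number of CV folds; default 5.
#' @param seed Integer seed for the fold assignment.
#' @param intercept Fit models with an intercept (default `TRUE`); the
#'   intercept-free variant assumes centered expression.
#' @param fold_id Optional precomputed fold assignment (integer vector over
#'   cells); overrides `folds`/`seed`, used internally so all targets share
#'   one split of the cells.
#' @return A `neighborhood_fit`: list with `target`, `regulators`,
#'   `eps_full`, `eps_reduced` (named vector), plus the coefficient vectors
#'   of the models refit on all cells.
#' @export
cv_rmse_pair <- function(expr_ref, target, regulators, folds = 5, seed = 1,
                         intercept = TRUE, fold_id = NULL) {
  stopifnot(is.matrix(expr_ref))
  if (!length(regulators)) stop_("`regulators` must be nonempty")
  if (target %in% regulators) stop_("target cannot be its own regulator")
  miss <- setdiff(c(target, regulators), rownames(expr_ref))
  if (length(miss)) stop_("gene not in expression matrix: ", miss[1])
  n <- ncol(expr_ref)
  if (is.null(fold_id)) {
    if (folds < 2) stop_("`folds` must be >= 2")
    if (n < folds) stop_(n, " cells cannot be split into ", folds, " folds")
    fold_id <- make_folds(n, folds, seed)
  }
  folds <- max(fold_id)
  y <- expr_ref[target, ]
  X <- t(expr_ref[regulators, , drop = FALSE])
  p <- length(regulators)
  rmse_full <- numeric(folds)
  rmse_red <- matrix(NA_real_, folds, p, dimnames = list(NULL, regulators))
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    if (stats::var(y[tr]) == 0)
      warning("zero-variance target '", target, "' in training fold ", f,
              call. = FALSE)
    bfull <- ridge_lstsq(X[tr, , drop = FALSE], y[tr], intercept)
    res <- y[!tr] - lstsq_predict(bfull, X[!tr, , drop = FALSE], intercept)
    rmse_full[f] <- sqrt(mean(res^2))
    for (j in seq_len(p)) {
      Xr <- X[, -j, drop = FALSE]
      bred <- if (p > 1)
        ridge_lstsq(Xr[tr, , drop = FALSE], y[tr], intercept)
      else if (intercept) mean(y[tr]) else 0
      pred <- if (p > 1)
        lstsq_predict(bred, Xr[!tr, , drop = FALSE], intercept)
      else rep(if (intercept) bred else 0, sum(!tr))
      rmse_red[f, j] <- sqrt(mean((y[!tr] - pred)^2))
    }
  }
  structure(list(target = target, regulators = regulators,
                 eps_full = mean(rmse_full),
                 eps_reduced = colMeans(rmse_red),
                 fold_rmse_full = rmse_full, fold_rmse_reduced = rmse_red,
                 intercept = intercept),
            class = "neighborhood_fit")
}

# Shuffle cells with the run seed and deal them into `folds` nearly equal
# parts.
make_folds <- function(n, folds, seed) {
  with_seed(seed, {
    id <- rep_len(seq_len(folds), n)
    sample(id)
  })
}

#' Build the reference causal network
#'
#' For every gene present in both the reference expression matrix and the
#' background network, its first-order background neighbours are taken as
#' candidate causes and [cv_rmse_pair()] measures how much each candidate
#' improves cross-validated prediction of the target. Candidate edges with
#' positive causal strength index ([csi()]) enter the network as
#' `cause -> target`. Both orientations of every background pair are
#' evaluated independently, each gene taking its turn as target; genes
#' without candidate causes are skipped.
#'
#' @param expr_ref Genes x cells reference expression matrix.
#' @param bg A `background_net` defining candidate causes.
#' @param folds CV folds; default 5.
#' @param seed Seed controlling the (single, shared) fold assignment.
#' @param intercept Fit regressions with an intercept; default `TRUE`.
#' @param omega_max Cap for degenerate error ratios; see [csi()].
#' @param keep_all Diagnostic mode: retain every evaluated candidate edge
#'   with its omega, including nonpositive ones (default `FALSE`, keeping
#'   only positive-omega edges). Useful for null calibration; [binarize()]
#'   restores the positive-only contract.
#' @return A `causal_network` with `role = "reference"`: edge data frame
#'   with columns `cause`, `target`, `omega` (only positive omega retained
#'   unless `keep_all`).
#' @export
build_reference_network <- function(expr_ref, bg, folds = 5, seed = 1,
                                    intercept = TRUE, omega_max = 50,
                                    keep_all = FALSE) {
  stopifnot(is.matrix(expr_ref), inherits(bg, "background_net"))
  genes <- intersect(rownames(expr_ref), names(bg$nbr))
  if (!length(genes)) stop_("expression matrix and background share no genes")
  fold_id <- make_folds(ncol(expr_ref), folds, seed)
  res <- vector("list", length(genes))
  for (i in seq_along(genes)) {
    g <- genes[i]
    regs <- intersect(bg$nbr[[g]], rownames(expr_ref))
    if (!length(regs)) next
    fit <- cv_rmse_pair(expr_ref, g, regs, intercept = intercept,
                        fold_id = fold_id)
    omega <- csi(fit$eps_reduced, fit$eps_full, omega_max)
    pos <- if (keep_all) rep(TRUE, length(omega)) else omega > 0
    if (any(pos))
      res[[i]] <- data.frame(cause = regs[pos], target = g,
                             omega = unname(omega[pos]),
                             stringsAsFactors = FALSE)
  }
  edges <- do.call(rbind, res)
  if (is.null(edges))
    edges <- data.frame(cause = character(), target = character(),
                        omega = numeric(), stringsAsFactors = FALSE)
  rownames(edges) <- NULL
  causal_network(edges, role = "reference", genes = genes)
}

#' Construct a causal network object
#'
#' Thin container for a directed gene network with per-edge causal strength.
#'
#' @param edges Data frame with columns `cause`, `target`, `omega`.
#' @param role `"reference"`, `"cell"`, or `"consensus"` (a
#'   prevalence-filtered cluster network).
#' @param genes Gene universe of the network (defaults to genes on edges).
#' @param cell_id Optional cell identifier for cell-role networks.
#' @return A `causal_network` object.
#' @export
causal_network <- function(edges, role = c("reference", "cell", "consensus"),
                           genes = NULL, cell_id = NULL) {
  role <- match.arg(role)
  stopifnot(all(c("cause", "target") %in% names(edges)))
  if (any(edges$cause == edges$target)) stop_("self-loop edge not allowed")
  genes <- genes %||% sort(unique(c(edges$cause, edges$target)))
  structure(list(edges = edges, role = role, genes = genes,
                 cell_id = cell_id),
            class = "causal_network")
}

#' @export
print.causal_network <- function(x, ...) {
  cat("Causal network (", x$role,
      if (!is.null(x$cell_id)) paste0(", cell ", x$cell_id), "): ",
      nrow(x$edges), " directed edges over ", length(x$genes), " genes\n",
      sep = "")
  invisible(x)
}

#' Keep only positive-strength edges at unit weight
#'
#' Network binarization: edges with positive causal strength survive with
#' weight 1, all others are dropped. Idempotent; reference and cell networks
#' are binarized before any counting-based downstream analysis.
#'
#' @param net A `causal_network`.
#' @return The binarized `causal_network`.
#' @export
binarize <- function(net) {
  stopifnot(inherits(net, "causal_network"))
  keep <- net$edges$omega > 0
  edges <- net$edges[keep, , drop = FALSE]
  edges$omega <- rep(1, nrow(edges))
  rownames(edges) <- NULL
  causal_network(edges, role = net$role, genes = net$genes,
                 cell_id = net$cell_id)
}

#' Write / read a causal network as edge-list TSV
#'
#' Columns `cause`, `target`, `omega` (plus `cell_id` when present).
#' @param net A `causal_network`.
#' @param path File path.
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "causal_network"))
  out <- net$edges
  if (!is.null(net$cell_id)) out$cell_id <- net$cell_id
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_network
#' @param role Role to assign to the network read back.
#' @export
read_network <- function(path, role = "reference") {
  edges <- utils::read.delim(path, stringsAsFactors = FALSE)
  causal_network(edges[, c("cause", "target", "omega")], role = role)
}
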