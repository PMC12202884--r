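#' Simulate a ground-truth gene regulatory network scenario
#'
#' Draws a random directed acyclic GRN over a random topological order of
#' the genes, assigns each edge a coefficient drawn uniformly from
#' `+/- coeff_range`, and embeds it in an undirected background graph made
#' of the truth skeleton plus `n_distractors` non-edge pairs. The scenario
#' is the ground truth against which network recovery is scored, and the
#' input to [simulate_expression()].
#'
#' @param n_genes Number of genes; identifiers are zero-padded (`G01`, ...)
#'   so lexicographic and numeric order coincide.
#' @param n_true_edges Number of directed edges in the truth DAG (at most
#'   `choose(n_genes, 2)`).
#' @param n_distractors Extra background pairs drawn from the non-edges.
#' @param coeff_range Length-2 magnitude interval for edge coefficients,
#'   excluding 0; signs are random. Default `c(0.8, 1.5)`.
#' @param noise_sd Standard deviation of the per-gene Gaussian noise in the
#'   structural equations; default 0.2.
#' @param group_edits Optional named list: group label -> data frame
#'   (`cause`, `target`) of truth edges whose coefficient is zeroed when
#'   simulating that group (an edge knockout).
#' @param seed Integer seed; the scenario is fully determined by it.
#' @return A `truth_scenario`: truth edge table (`cause`, `target`,
#'   `coef`), `background` (a `background_net`), `genes`, `noise_sd`,
#'   `group_edits`, `seed`.
#' @export
simulate_grn <- function(n_genes, n_true_edges, n_distractors = 0,
                         coeff_range = c(0.8, 1.5), noise_sd = 0.2,
                         group_edits = NULL, seed = 1) {
  stopifnot(n_genes >= 2, noise_sd > 0, length(coeff_range) == 2,
            min(coeff_range) > 0)
  npairs <- choose(n_genes, 2)
  if (n_true_edges > npairs)
    stop_("cannot place ", n_true_edges, " edges among ", n_genes, " genes")
  if (n_true_edges + n_distractors > npairs)
    stop_("truth edges plus distractors exceed the number of gene pairs")
  genes <- sprintf(paste0("G%0", nchar(n_genes), "d"), seq_len(n_genes))
  with_seed(seed, {
    topo <- sample(genes)                      # topological order
    pairs <- utils::combn(n_genes, 2)          # index pairs i < j in topo
    pick <- sample(ncol(pairs), n_true_edges)
    truth <- data.frame(
      cause = topo[pairs[1, pick]], target = topo[pairs[2, pick]],
      coef = stats::runif(n_true_edges, coeff_range[1], coeff_range[2]) *
        sample(c(-1, 1), n_true_edges, replace = TRUE),
      stringsAsFactors = FALSE)
    rest <- setdiff(seq_len(ncol(pairs)), pick)
    dist_pick <- if (n_distractors) sample(rest, n_distractors) else integer()
    bg_edges <- data.frame(
      a = c(pmin(truth$cause, truth$target), topo[pairs[1, dist_pick]]),
      b = c(pmax(truth$cause, truth$target), topo[pairs[2, dist_pick]]),
      score = 999, stringsAsFactors = FALSE)
    bg_edges[, 1:2] <- data.frame(a = pmin(bg_edges$a, bg_edges$b),
                                  b = pmax(bg_edges$a, bg_edges$b))
    bg_edges <- bg_edges[order(bg_edges$a, bg_edges$b), , drop = FALSE]
    rownames(bg_edges) <- NULL
    structure(list(truth = truth, background = new_background(bg_edges),
                   genes = genes, topo_order = topo, noise_sd = noise_sd,
                   group_edits = group_edits, seed = seed),
              class = "truth_scenario")
  })
}

#' @export
print.truth_scenario <- function(x, ...) {
  cat("Truth scenario: ", length(x$genes), " genes, ", nrow(x$truth),
      " true directed edges, ",
      nrow(x$background$edges) - nrow(x$truth),
      " distractor pairs, noise sd ", x$noise_sd, "\n", sep = "")
  invisible(x)
}

#' Simulate expression from a truth scenario
#'
#' Linear-Gaussian structural equation model: root genes are standard
#' normal; every other gene is the coefficient-weighted sum of its parents
#' plus `Normal(0, noise_sd)` noise, evaluated in topological order ---
#' exactly the model class the causal-inference regressions assume. If
#' `group` names an entry of the scenario's `group_edits`, the listed
#' edges' coefficients are zeroed for these cells (a group-wise knockout).
#'
#' @param scn A `truth_scenario`.
#' @param n_cells Number of cells to draw.
#' @param group Optional group label selecting a knockout edit set.
#' @param seed Integer seed.
#' @param cell_prefix Prefix for generated cell identifiers.
#' @return Genes x cells numeric matrix.
#' @export
simulate_expression <- function(scn, n_cells, group = NULL, seed = 1,
                                cell_prefix = "cell") {
  stopifnot(inherits(scn, "truth_scenario"), n_cells >= 1)
  truth <- scn$truth
  if (!is.null(group)) {
    if (is.null(scn$group_edits) || !group %in% names(scn$group_edits))
      stop_("unknown group label: ", group)
    ko <- scn$group_edits[[group]]
    drop_idx <- paste(truth$cause, truth$target) %in%
      paste(ko$cause, ko$target)
    truth$coef[drop_idx] <- 0
  }
  parents <- split(seq_len(nrow(truth)), truth$target)
  with_seed(seed, {
    m <- matrix(0, length(scn$genes), n_cells,
                dimnames = list(scn$genes,
                                paste0(cell_prefix, seq_len(n_cells))))
    for (g in scn$topo_order) {
      pid <- parents[[g]]
      noise <- stats::rnorm(n_cells,
                            sd = if (length(pid)) scn$noise_sd else 1)
      m[g, ] <- noise
      for (i in pid)
        m[g, ] <- m[g, ] + truth$coef[i] * m[truth$cause[i], ]
    }
    m
  })
}

#' Score an inferred network against the truth
#'
#' Directed-edge precision, recall and F1 of an inferred causal network
#' against the scenario's truth edges, restricted to ordered pairs whose
#' unordered pair is in the background (the only candidates the method can
#' ever test). Precision of an empty network is 1 by convention.
#'
#' @param truth A `truth_scenario`.
#' @param inferred A `causal_network`.
#' @return Named numeric vector `precision`, `recall`, `f1`, plus `tp`,
#'   `n_inferred`, `n_truth`.
#' @export
recovery_report <- function(truth, inferred) {
  stopifnot(inherits(truth, "truth_scenario"),
            inherits(inferred, "causal_network"))
  bg_key <- paste(truth$background$edges$a, truth$background$edges$b,
                  sep = "\r")
  dir_key <- function(c_, t_) paste(c_, t_, sep = "\r")
  und_key <- function(c_, t_) paste(pmin(c_, t_), pmax(c_, t_), sep = "\r")
  inf <- inferred$edges[und_key(inferred$edges$cause,
                                inferred$edges$target) %in% bg_key, ,
                        drop = FALSE]
  true_set <- dir_key(truth$truth$cause, truth$truth$target)
  inf_set <- unique(dir_key(inf$cause, inf$target))
  tp <- length(intersect(inf_set, true_set))
  precision <- if (!length(inf_set)) 1 else tp / length(inf_set)
  recall <- if (!length(true_set)) 1 else tp / length(true_set)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  c(precision = precision, recall = recall, f1 = f1, tp = tp,
    n_inferred = length(inf_set), n_truth = length(true_set))
}
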