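test_that("differential regulators flag a constructed strong difference", {
  set.seed(71)
  na_ <- 50; nb <- 50
  odm <- rbind(
    hit = c(rep(0, na_), pmax(0, round(rnorm(nb, 8, 1)))),
    flat = c(rpois(na_, 3), rpois(nb, 3)),
    const = rep(2, na_ + nb))
  colnames(odm) <- paste0("c", seq_len(na_ + nb))
  groups <- setNames(rep(c("A", "B"), c(na_, nb)), colnames(odm))
  tab <- differential_regulators(odm, groups, "A", "B")
  hit <- tab[tab$gene == "hit", ]
  expect_true(hit$significant)
  expect_equal(hit$direction, "up")
  # hand-computed pooled-variance t statistic for the hit gene
  xa <- odm["hit", 1:na_]; xb <- odm["hit", na_ + 1:nb]
  sp2 <- (sum((xa - mean(xa))^2) + sum((xb - mean(xb))^2)) / (na_ + nb - 2)
  t_hand <- (mean(xa) - mean(xb)) / sqrt(sp2 * (1 / na_ + 1 / nb))
  expect_equal(hit$statistic, t_hand, tolerance = 1e-12)
  # constant-in-both-groups gene recorded with p = 1, never dropped
  cst <- tab[tab$gene == "const", ]
  expect_true(is.na(cst$statistic))
  expect_equal(cst$p, 1)
  # q >= p elementwise and sorted by q
  expect_true(all(tab$q >= tab$p - 1e-15))
  expect_false(is.unsorted(tab$q))
  expect_error(differential_regulators(odm, groups, "A", "missing"),
               "at least 2 cells")
  # alpha = 0 admits nothing
  expect_equal(sum(differential_regulators(odm, groups, "A", "B",
                                           alpha = 0)$significant), 0)
})

test_that("null outdegrees yield no significant regulators", {
  set.seed(72)
  hits <- vapply(1:20, function(s) {
    set.seed(1000 + s)
    odm <- matrix(rpois(30 * 40, 4), 30, 40,
                  dimnames = list(paste0("g", 1:30), paste0("c", 1:40)))
    groups <- setNames(rep(c("A", "B"), each = 20), colnames(odm))
    sum(differential_regulators(odm, groups, "A", "B")$significant)
  }, 0)
  expect_lt(mean(hits), 0.5)
})

test_that("edge activity counts split active/inactive per group", {
  edges <- data.frame(cause = c("A", "B"), target = c("B", "C"),
                      stringsAsFactors = FALSE)
  omega <- rbind(c(1, 1, 1, -1, -1), c(-1, -1, -1, -1, -1))
  nets <- structure(list(edges = edges, omega = omega,
                         cells = paste0("c", 1:5),
                         genes = c("A", "B", "C")),
                    class = "cell_network_set")
  groups <- setNames(rep("A", 5), nets$cells)
  tab <- edge_activity_table(nets, groups)
  expect_equal(tab$active_A, c(3L, 0L))
  expect_equal(tab$n_A, c(5L, 5L))
  expect_error(edge_activity_table(nets, groups[-3]), "without group")
})

test_that("chi-square edge test matches the hand-computed Yates statistic", {
  tab <- data.frame(cause = "A", target = "B",
                    active_h = 10L, n_h = 100L,
                    active_c = 50L, n_c = 100L)
  res <- edge_activity_test(tab, "h", "c")
  # expected counts 30/70 per group; |O-E| = 20, Yates-corrected 19.5
  chi_hand <- 19.5^2 * (1 / 30 + 1 / 70 + 1 / 30 + 1 / 70)
  expect_equal(res$statistic, chi_hand, tolerance = 1e-10)
  expect_equal(res$statistic, 36.214, tolerance = 1e-3)
  expect_true(res$up_regulated)
  # without continuity correction the statistic is the classic Pearson one
  res2 <- edge_activity_test(tab, "h", "c", correct = FALSE)
  expect_equal(res2$statistic, 20^2 * (1 / 30 + 1 / 70 + 1 / 30 + 1 / 70),
               tolerance = 1e-10)
  # identical rates: zero statistic, not significant
  same <- data.frame(cause = "A", target = "B",
                     active_h = 30L, n_h = 100L,
                     active_c = 30L, n_c = 100L)
  r3 <- edge_activity_test(same, "h", "c")
  expect_equal(r3$statistic, 0)
  expect_false(r3$significant)
  # significant in the wrong direction is excluded from up-regulated
  down <- data.frame(cause = "A", target = "B",
                     active_h = 50L, n_h = 100L,
                     active_c = 10L, n_c = 100L)
  r4 <- edge_activity_test(down, "h", "c")
  expect_true(r4$significant)
  expect_false(r4$up_regulated)
  # all-inactive edge degenerates to no evidence
  none <- data.frame(cause = "A", target = "B",
                     active_h = 0L, n_h = 100L,
                     active_c = 0L, n_c = 100L)
  expect_equal(edge_activity_test(none, "h", "c")$p, 1)
})

test_that("consensus networks keep the prevalence boundary and are
          cutoff-monotone", {
  edges <- data.frame(cause = c("A", "B"), target = c("B", "C"),
                      stringsAsFactors = FALSE)
  omega <- rbind(c(rep(1, 7), rep(-1, 3)),   # edge in 7/10 cells
                 c(rep(1, 6), rep(-1, 4)))   # edge in 6/10 cells
  nets <- structure(list(edges = edges, omega = omega,
                         cells = paste0("c", 1:10),
                         genes = c("A", "B", "C")),
                    class = "cell_network_set")
  cl <- setNames(rep("k1", 10), nets$cells)
  cons <- consensus_network(nets, cl, prevalence_cutoff = 0.70)
  expect_equal(nrow(cons$k1$edges), 1)       # 7/10 kept, 6/10 removed
  expect_equal(cons$k1$edges$cause, "A")
  union_net <- consensus_network(nets, cl, 0)$k1
  inter_net <- consensus_network(nets, cl, 1)$k1
  expect_equal(nrow(union_net$edges), 2)
  expect_equal(nrow(inter_net$edges), 0)
  prev_edges <- Inf
  for (cut in c(0, 0.3, 0.6, 0.65, 0.7, 1)) {
    ne <- nrow(consensus_network(nets, cl, cut)$k1$edges)
    expect_lte(ne, prev_edges)
    prev_edges <- ne
  }
})

test_that("top regulators rank by outdegree with lexicographic ties", {
  net <- causal_network(data.frame(
    cause = c(rep("A", 5), rep("C", 3), rep("B", 3)),
    target = c(paste0("t", 1:5), paste0("u", 1:3), paste0("v", 1:3)),
    omega = 1), role = "reference")
  expect_equal(top_regulators(net, 2), c("A", "B"))
  expect_equal(top_regulators(net, 10), c("A", "B", "C"))
  empty <- causal_network(data.frame(cause = character(),
                                     target = character(),
                                     omega = numeric()), role = "reference")
  expect_equal(top_regulators(empty, 3), character())
})

test_that("jaccard similarity behaves on directed edge sets", {
  mk <- function(cause, target) causal_network(
    data.frame(cause = cause, target = target, omega = 1), role = "cell")
  a <- mk(c("A", "B", "C"), c("B", "C", "D"))
  b <- mk(c("A", "B", "X"), c("B", "C", "Y"))
  expect_equal(jaccard_similarity(a, a), 1)
  expect_equal(jaccard_similarity(a, b), 2 / 4)
  expect_equal(jaccard_similarity(a, b), jaccard_similarity(b, a))
  disj <- mk("P", "Q")
  expect_equal(jaccard_similarity(a, disj), 0)
  empty <- causal_network(data.frame(cause = character(),
                                     target = character(),
                                     omega = numeric()), role = "cell")
  expect_equal(jaccard_similarity(empty, empty), 1)
  # direction matters: the reversed edge is a different edge
  rev_a <- mk(c("B", "C", "D"), c("A", "B", "C"))
  expect_equal(jaccard_similarity(a, rev_a), 0)
})

test_that("activity curves smooth with shrunken edge windows", {
  odm <- matrix(c(rep(0, 10), rep(4, 10)), 1, 20,
                dimnames = list("R", paste0("c", 1:20)))
  ord <- paste0("c", 1:20)
  cv <- activity_curve(odm, ord, "R", window = 5)
  expect_equal(cv$smoothed, oracle_moving_average(cv$raw, 5))
  expect_false(is.unsorted(cv$smoothed))    # step stays monotone
  expect_equal(activity_curve(odm, ord, "R", window = 1)$smoothed,
               as.numeric(odm[1, ]))
  const <- matrix(3, 1, 10, dimnames = list("R", paste0("c", 1:10)))
  expect_equal(activity_curve(const, paste0("c", 1:10), "R", 5)$smoothed,
               rep(3, 10))
  expect_error(activity_curve(odm, ord, "nope", 3), "unknown regulator")
  expect_error(activity_curve(odm, ord, "R", 4), "odd")
})
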