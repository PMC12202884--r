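# Independent fold-by-fold CV oracle: plain lm() fits on the same fold
# assignment, no code shared with cv_rmse_pair.
oracle_cv <- function(expr, target, regs, fold_id) {
  folds <- max(fold_id)
  rf <- numeric(folds)
  rr <- matrix(0, folds, length(regs), dimnames = list(NULL, regs))
  df <- as.data.frame(t(expr[c(target, regs), , drop = FALSE]))
  names(df) <- c("y", regs)
  for (f in seq_len(folds)) {
    tr <- df[fold_id != f, ]; te <- df[fold_id == f, ]
    fit <- lm(y ~ ., data = tr)
    rf[f] <- sqrt(mean((te$y - predict(fit, te))^2))
    for (r in regs) {
      tr2 <- tr[, setdiff(names(tr), r)]
      fit2 <- lm(y ~ ., data = tr2)
      rr[f, r] <- sqrt(mean((te$y - predict(fit2, te))^2))
    }
  }
  list(eps_full = mean(rf), eps_reduced = colMeans(rr))
}

test_that("csi is the log error ratio with symmetric zero-handling", {
  expect_equal(csi(0.5, 0.5), 0)
  expect_equal(csi(exp(1) * 0.37, 0.37), 1)
  expect_equal(csi(0.3, 0.2), log(1.5))
  expect_equal(csi(0.1, 0), 50)
  expect_equal(csi(0, 0.1), -50)
  expect_equal(csi(0, 0), 0)
  expect_error(csi(-1, 1), "nonnegative")
  # antisymmetry on the positive domain
  set.seed(42)
  a <- runif(50, 1e-3, 10); b <- runif(50, 1e-3, 10)
  expect_equal(csi(a, b), -csi(b, a))
})

test_that("cross-validated errors match an independent lm-based oracle", {
  set.seed(11)
  n <- 100
  A <- rnorm(n); B <- rnorm(n); C <- rnorm(n)
  y <- 1.2 * A - 0.7 * B + rnorm(n, sd = 0.3)
  expr <- rbind(Y = y, A = A, B = B, C = C)
  colnames(expr) <- paste0("c", 1:n)
  fold_id <- rep_len(1:5, n)
  fit <- cv_rmse_pair(expr, "Y", c("A", "B", "C"), fold_id = fold_id)
  orc <- oracle_cv(expr, "Y", c("A", "B", "C"), fold_id)
  expect_equal(fit$eps_full, orc$eps_full, tolerance = 1e-6)
  expect_equal(unname(fit$eps_reduced), unname(orc$eps_reduced),
               tolerance = 1e-6)
  # removing real causes hurts, removing noise does not
  expect_gt(fit$eps_reduced[["A"]], fit$eps_full)
  expect_gt(fit$eps_reduced[["B"]], fit$eps_full)
  expect_lt(abs(fit$eps_reduced[["C"]] - fit$eps_full), 0.05)
})

test_that("a noiseless dependency gives near-zero full error", {
  set.seed(12)
  A <- rnorm(100); B <- rnorm(100)
  expr <- rbind(Y = 2 * A, A = A, B = B)
  colnames(expr) <- paste0("c", 1:100)
  fit <- cv_rmse_pair(expr, "Y", c("A", "B"), folds = 5, seed = 3)
  expect_lt(fit$eps_full, 1e-4)
  expect_gt(fit$eps_reduced[["A"]], 0.5)
  expect_lt(fit$eps_reduced[["B"]], 1e-4)
})

test_that("a duplicated regulator carries no removable information", {
  set.seed(13)
  A <- rnorm(120)
  expr <- rbind(Y = A + rnorm(120, sd = 0.2), A = A, Acopy = A)
  colnames(expr) <- paste0("c", 1:120)
  fit <- cv_rmse_pair(expr, "Y", c("A", "Acopy"), folds = 5, seed = 3)
  expect_equal(fit$eps_reduced[["A"]], fit$eps_full, tolerance = 1e-3)
})

test_that("preconditions are enforced", {
  expr <- rbind(Y = 1:3, A = 3:1)
  colnames(expr) <- paste0("c", 1:3)
  expect_error(cv_rmse_pair(expr, "Y", "A", folds = 5), "folds")
  expect_error(cv_rmse_pair(expr, "Y", character()), "nonempty")
  expect_error(cv_rmse_pair(expr, "Y", "Y"), "own regulator")
  expect_error(cv_rmse_pair(expr, "Y", "Z"), "Z")
})

test_that("reference network recovers a strong planted edge and is
          deterministic under the seed", {
  scn <- simulate_grn(8, 5, n_distractors = 4, seed = 21)
  expr <- simulate_expression(scn, 250, seed = 22)
  net1 <- build_reference_network(expr, scn$background, seed = 5)
  net2 <- build_reference_network(expr, scn$background, seed = 5)
  expect_identical(net1$edges, net2$edges)
  # every true edge present (recall 1 at this signal strength)
  expect_true(all(paste(scn$truth$cause, scn$truth$target) %in%
                    paste(net1$edges$cause, net1$edges$target)))
  expect_true(all(net1$edges$omega > 0))
  # empty background rejected via empty intersection
  em <- matrix(rnorm(20), 2, 10,
               dimnames = list(c("zz1", "zz2"), paste0("c", 1:10)))
  expect_error(build_reference_network(em, scn$background), "no genes")
})

test_that("model store fits exact coefficients and round-trips", {
  set.seed(31)
  A <- rnorm(80); B <- rnorm(80)
  expr <- rbind(Y = 3 * A, A = A, B = B)
  colnames(expr) <- paste0("c", 1:80)
  net <- causal_network(data.frame(cause = c("A", "B"), target = "Y",
                                   omega = c(2, 0.1)), role = "reference")
  store <- fit_model_store(expr, net)
  cf <- store$targets[["Y"]]$coef_full
  expect_equal(unname(cf["A"]), 3, tolerance = 1e-4)
  expect_equal(unname(cf["(Intercept)"]), 0, tolerance = 1e-4)
  # single-parent target gets an intercept-only reduced model
  net1 <- causal_network(data.frame(cause = "A", target = "Y", omega = 1),
                         role = "reference")
  st1 <- fit_model_store(expr, net1)
  expect_named(st1$targets[["Y"]]$coef_reduced[["A"]], "(Intercept)")
  # serialization round-trip gives identical predictions
  f <- tempfile(fileext = ".json")
  write_model_store(store, f)
  store2 <- read_model_store(f)
  probe <- c(Y = 1.5, A = 0.4, B = -1)
  n1 <- infer_cell_network(probe, store)
  n2 <- infer_cell_network(probe, store2)
  expect_equal(n1$edges, n2$edges)
  expect_error(fit_model_store(expr, infer_cell_network(probe, store)),
               "reference-role")
})

test_that("per-cell inference handles the boundary cases", {
  # store with exact coefficients: Y = 1 + 2 A (full), Y = 8 (reduced)
  store <- structure(list(
    targets = list(Y = list(target = "Y", parents = "A",
                            coef_full = c(`(Intercept)` = 1, A = 2),
                            coef_reduced = list(A = c(`(Intercept)` = 8)))),
    intercept = TRUE, genes = c("A", "Y"), gene_order = c("A", "Y"),
    fingerprint = "manual"), class = "model_store")
  # cell generated exactly by the full model: eps1 = 0 => capped omega,
  # edge present
  n <- infer_cell_network(c(A = 10, Y = 21), store)
  expect_equal(n$edges$omega, 50)
  expect_equal(nrow(n$edges), 1)
  # full and reduced predictions coinciding => omega = 0 => edge absent;
  # the set view keeps nonpositive omegas so the boundary is observable
  tie <- matrix(c(3.5, 0), 2, 1, dimnames = list(c("A", "Y"), "t"))
  s <- infer_cell_networks(tie, store)
  expect_identical(unname(s$omega[1, 1]), 0)
  expect_equal(nrow(get_cell_network(s, 1)$edges), 0)
  expect_error(infer_cell_network(c(A = 1), store), "Y")
})

test_that("cell networks are reference subsets, order-equivariant and
          deterministic", {
  scn <- simulate_grn(8, 5, n_distractors = 4, seed = 41)
  expr <- simulate_expression(scn, 200, seed = 42)
  fit <- sicnet(expr, scn$background, seed = 2)
  obj <- simulate_expression(scn, 12, seed = 43, cell_prefix = "obj")
  nets <- predict(fit, obj)
  ref_keys <- paste(fit$network$edges$cause, fit$network$edges$target)
  for (k in seq_along(nets)) {
    ck <- nets[[k]]$edges
    expect_true(all(paste(ck$cause, ck$target) %in% ref_keys))
  }
  # permuting the columns permutes the output identically
  perm <- c(5, 1, 12, 3, 2, 4, 7, 6, 9, 8, 11, 10)
  nets_p <- predict(fit, obj[, perm])
  expect_identical(nets_p$omega, nets$omega[, perm])
  # duplicated cell column gives identical networks
  dup <- obj[, c(1, 1)]
  colnames(dup) <- c("d1", "d2")
  nd <- predict(fit, dup)
  expect_equal(unname(nd$omega[, 1]), unname(nd$omega[, 2]))
  # singleton matrix equals the single-cell path
  n1 <- infer_cell_network(obj[, 3], fit$store, cell_id = "x")
  s1 <- predict(fit, obj[, 3, drop = FALSE])
  expect_equal(n1$edges, get_cell_network(s1, 1)$edges,
               ignore_attr = TRUE)
})

test_that("fit object methods expose the model sensibly", {
  scn <- simulate_grn(6, 4, n_distractors = 2, seed = 51)
  expr <- simulate_expression(scn, 150, seed = 52)
  fit <- sicnet(expr, scn$background, seed = 4)
  expect_s3_class(fit, "sicnet")
  expect_output(print(fit), "Reference network")
  s <- summary(fit)
  expect_output(print(s), "Top regulators")
  expect_true(all(names(coef(fit)) %in% fit$genes))
  expect_error(coef(fit, target = "nope"), "no model")
  odm <- predict(fit, simulate_expression(scn, 10, seed = 53),
                 type = "odm")
  expect_identical(dim(odm), c(length(fit$genes), 10L))
})
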