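g_sub <- ngn_grammar("smiles_subset")

test_that("fold plans produce the prescribed trial counts", {
  p20 <- ngn_folds(10, "leave20_cv", seed = 1)
  expect_length(p20$folds, 5L)
  expect_true(all(lengths(p20$folds) == 2L))
  expect_identical(p20$n_trials, 50L)
  p5 <- ngn_folds(20, "leave5_cv", seed = 1)
  expect_length(p5$folds, 20L)
  expect_true(all(lengths(p5$folds) == 1L))
  expect_identical(p5$n_trials, 20L)
  expect_error(ngn_folds(3, "leave20_cv"), "design error")
})

test_that("fold plans partition the indices with near-equal sizes", {
  set.seed(2)
  for (n in c(11, 23, 57)) {
    p <- ngn_folds(n, "leave20_cv", seed = n)
    expect_identical(sort(unlist(p$folds)), seq_len(n))
    expect_lte(diff(range(lengths(p$folds))), 1L)
  }
})

test_that("grouped folds deal round-robin over the sorted targets", {
  p <- ngn_folds(10, "grouped5", targets = 10:1, seed = 3)
  # ranks {1,6},{2,7},...: with targets 10..1, rank r sits at index 11-r
  expect_identical(p$folds[[1]], c(10L, 5L))
  expect_identical(p$folds[[5]], c(6L, 1L))
  expect_identical(sort(unlist(p$folds)), 1:10)
  # cluster target means stay close together on uniform targets
  tg <- seq(0, 1, length.out = 50)
  pb <- ngn_folds(50, "grouped5", targets = tg, seed = 4)
  means <- vapply(pb$folds, function(f) mean(tg[f]), 0)
  expect_lt(diff(range(means)), diff(range(tg)) / 5)
  expect_error(ngn_folds(10, "grouped5"), "requires")
})

test_that("designed plans carry an explicit test set", {
  p <- ngn_folds(10, "designed", test = c(2, 4, 6), seed = 1)
  expect_identical(p$folds[[1]], c(2L, 4L, 6L))
  expect_identical(p$n_trials, 10L)
  expect_error(ngn_folds(10, "designed"), "explicit test")
})

test_that("trial runs are reproducible and book-keep convergence", {
  mols <- c("CCO", "CC(C)O", "CCC", "OCO", "CC", "OCC(C)C", "CCCC", "COC")
  y <- c("pos", "pos", "neg", "pos", "neg", "pos", "neg", "pos")
  ctl <- ngn_control(max_epochs = 400)
  plan <- ngn_folds(8, "leave20_cv", seed = 5, reps = 1)
  plan$folds <- plan$folds[1]          # one fold, two repetitions
  plan$reps_per_fold <- 2L
  plan$n_trials <- 2L
  r1 <- ngn_run_trials(mols, y, g_sub, ctl, plan)
  r2 <- ngn_run_trials(mols, y, g_sub, ctl, plan)
  expect_identical(nrow(r1$trials), 2L)
  expect_identical(r1$trials, r2$trials)
  expect_true(all(c("Q", "SE", "SP", "MCC") %in% names(r1$trials)))
  expect_identical(r1$n_converged, sum(r1$trials$converged))
})

test_that("a synthetic contains-oxygen run reaches high held-out accuracy", {
  task <- ngn_synth_task("classification", "contains_token", token = "O",
                         n = 60, max_depth = 10, seed = 6)
  ds <- ngn_make_dataset(task, g_sub)
  plan <- ngn_folds(nrow(ds), "leave20_cv", seed = 7, reps = 1)
  plan$folds <- plan$folds[1:2]; plan$n_trials <- 2L
  rep <- ngn_run_trials(ds$molecule, ds$label, g_sub,
                        ngn_control(max_epochs = 2500), plan)
  expect_gte(rep$n_converged, 1L)
  expect_gte(rep$aggregates$mean[rep$aggregates$metric == "Q"], 0.85)
})

test_that("regression trials report PRESS, q2, Epsilon and CC", {
  task <- ngn_synth_task("regression", "scaled_token_count", token = "C",
                         n = 40, max_depth = 10, seed = 8)
  ds <- ngn_make_dataset(task, g_sub)
  plan <- ngn_folds(nrow(ds), "leave5_cv", seed = 9)
  plan$folds <- plan$folds[1:2]; plan$n_trials <- 2L; plan$reps_per_fold <- 1L
  rep <- ngn_run_trials(ds$molecule, ds$target, g_sub,
                        ngn_control("regression_cv", max_epochs = 1500), plan)
  expect_true(all(c("press", "sd", "q2", "epsilon", "epsilon_sd", "cc") %in%
                  names(rep$trials)))
  expect_identical(rep$task, "regression")
})

test_that("descriptor vectors count tokens and length", {
  x <- ngn_descriptors(c("CCO", "CC(C)CCO"), g_sub)
  expect_equal(unname(x[1, c("C", "O", "(", "n_tokens")]), c(2, 1, 0, 3))
  expect_equal(unname(x[2, c("(", "C")]), c(1, 5))
  expect_error(ngn_descriptors("", g_sub), "empty")
})

test_that("the baseline ANN fits one exemplar and passes a gradient check", {
  x <- matrix(c(1, 2, 0.5), 1, 3)
  fit <- ngn_ann(x, 0.7, max_epochs = 5000, seed = 1, normalize = FALSE)
  expect_true(fit$converged)
  expect_lt(abs(predict(fit, x) - 0.7), 0.06)
  # finite differences on the fused input layer
  plan <- list(node_sizes = c(2L, 1L), edge_parent = c(1L, 2L),
               edge_key = c(1L, 2L), edge_type = c(2L, 0L),
               edge_child = c(1L, 1L), dense = list(c(1, 2, 0.5)))
  layers <- fit$layers
  target <- 0.3
  gr <- ngn:::cpp_backprop(layers, plan, target, 1.0)
  an <- gr$dw[[1]][1, 2]
  h <- 1e-5
  E <- function(w) {
    l <- layers; l$input$w[1, 2] <- w
    0.5 * (target - ngn:::cpp_forward(l, plan)$output)^2
  }
  fd <- -(E(layers$input$w[1, 2] + h) - E(layers$input$w[1, 2] - h)) / (2 * h)
  expect_lt(rel_err(an, fd), 1e-4)
})

test_that("the baseline ANN can learn XOR within a few restarts", {
  x <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  y <- c(0.2, 0.8, 0.8, 0.2)
  fit <- ngn_ann(x, y, hidden = 2, rmse_threshold = 0.05,
                 max_epochs = 20000, max_restarts = 4, seed = 3,
                 normalize = FALSE)
  expect_true(fit$converged)
  expect_lt(fit$final_rmse, 0.05)
})

test_that("method comparison pairs trials and enumerates exactly", {
  mk <- function(eps) {
    structure(list(trials = data.frame(trial = seq_along(eps), fold = 1L,
                                       epsilon = eps,
                                       epsilon_sd = eps / 2),
                   n_trials = length(eps), task = "regression"),
              class = "ngn_report")
  }
  a <- mk(c(1, 2, 3, 4, 5, 6, 7, 8))
  expect_identical(ngn_compare(a, a)$winner, "none")
  b <- mk(c(2, 3, 4, 5, 6, 7, 8, 9))     # a uniformly smaller
  cmp <- ngn_compare(a, b, alternative = "less")
  expect_equal(cmp$p, 1 / 256)            # exact: all 8 differences negative
  expect_identical(cmp$winner, "a")
  expect_identical(ngn_compare(a, b)$winner, "a")   # two-sided: p = 1/128
  # three trials cannot reach significance by enumeration
  a3 <- mk(c(1, 2, 3)); b3 <- mk(c(2, 3, 4))
  expect_gte(ngn_compare(a3, b3)$p, 0.25)
  expect_identical(ngn_compare(a3, b3)$winner, "none")
  expect_error(ngn_compare(a, mk(1:3)), "mismatched")
})

test_that("the grammar network beats count descriptors on a topology task", {
  # label depends on *where* tokens occur (substring C(C), i.e. a branch
  # opening right after a carbon) -- information count descriptors discard
  task <- ngn_synth_task("classification", "substring_presence",
                         token = "C(C", n = 120, max_depth = 12, seed = 77)
  ds <- ngn_make_dataset(task, g_sub)
  x <- ngn_descriptors(ds$molecule, g_sub)
  qs <- vapply(1:2, function(seed) {
    set.seed(seed)
    test <- sample(nrow(ds), 24)
    train <- setdiff(seq_len(nrow(ds)), test)
    fit <- ngn(ds$molecule[train], ds$label[train], g_sub,
               ngn_control("classification"), seed = seed)
    qn <- ngn_classification_metrics(
      ngn_confusion(ngn_predict_raw(fit$library, ds$molecule[test]),
                    ds$label[test]))$Q
    ann <- ngn_ann(x[train, ], ds$label[train], seed = seed)
    qa <- ngn_classification_metrics(
      ngn_confusion(predict(ann, x[test, ]), ds$label[test]))$Q
    c(qn, qa)
  }, c(0, 0))
  expect_gt(mean(qs[1, ]), mean(qs[2, ]))
})
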