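g_sub <- ngn_grammar("smiles_subset")
ctl <- ngn_control()

test_that("initial weights fall in the two-band range, deterministically", {
  lib1 <- ngn_init_library(g_sub, ctl, seed = 11)
  lib2 <- ngn_init_library(g_sub, ctl, seed = 11)
  expect_identical(lib1$layers, lib2$layers)
  vals <- unlist(lapply(lib1$layers, function(l) c(l$w, l$b)))
  expect_true(all(abs(vals) >= ctl$init_low & abs(vals) <= ctl$init_high))
  expect_true(all(unlist(lapply(lib1$layers, function(l) c(l$dw, l$db))) == 0))
})

test_that("the positive band is chosen about half the time", {
  big <- ngn_control(hidden_size = 40L)   # enough entries for a tight check
  set.seed(5)
  vals <- unlist(lapply(ngn_init_library(g_sub, big)$layers, `[[`, "w"))
  expect_gte(length(vals), 10000L)
  vals <- vals[seq_len(10000)]
  expect_gt(mean(vals > 0), 0.48)
  expect_lt(mean(vals > 0), 0.52)
})

test_that("assembly mirrors the parse tree and shares library layers", {
  lib <- ngn_init_library(g_sub, ctl, seed = 2)
  net <- ngn_assemble(ngn_parse("CC(C)CCO", g_sub), lib)
  # 17 internal parse nodes + the output layer
  expect_length(net$plan$node_sizes, 18L)
  tab <- table(net$bindings)
  # six atoms feed six instantiations of the merged token layer, six of
  # the chain->atom slot (rules 2,3,4 share it); four continuation slots
  expect_identical(as.integer(tab[c("atom->{C,O}#1", "chain->atom#1",
                                    "chain->chain#2")]), c(6L, 6L, 4L))
  # every binding resolves in the library
  expect_true(all(names(tab) %in% c(lib$keys$name)))
  # rule-3 chain nodes leave the Nbranch slot zero-flushed
  expect_true(all(c("chain->Nbranch#3", "chain->chain#2") %in%
                  net$zero_slots$key))
  expect_identical(nrow(net$zero_slots), 7L)
})

test_that("the single-atom network is a four-layer spine plus output head", {
  lib <- ngn_init_library(g_sub, ctl, seed = 2)
  net <- ngn_assemble(ngn_parse("C", g_sub), lib)
  expect_length(net$plan$node_sizes, 4L)   # atom, chain, smiles, output
  expect_identical(net$bindings,
                   c("atom->{C,O}#1", "chain->atom#1", "smiles->chain#1",
                     "output"))
})

test_that("a library mismatch is caught at assembly", {
  lib <- ngn_init_library(ngn_grammar("smiles_extended"), ctl, seed = 1)
  expect_error(ngn_assemble(ngn_parse("CC", g_sub), lib), "does not match")
})

test_that("an all-zero library feeds forward to 0.5 everywhere", {
  lib <- ngn_init_library(g_sub, ctl, seed = 3)
  for (k in seq_along(lib$layers)) {
    lib$layers[[k]]$w[] <- 0
    lib$layers[[k]]$b[] <- 0
  }
  ff <- ngn_feedforward(ngn_assemble(ngn_parse("CC(C)CCO", g_sub), lib), lib)
  expect_equal(ff$output, 0.5)
  expect_true(all(abs(unlist(ff$activations) - 0.5) < 1e-12))
  expect_equal(ngn_predict_raw(lib, "CC(C)CCO"), 0.5)
})

test_that("feedforward matches a hand-computed logistic chain", {
  one <- ngn_control(hidden_size = 1L)
  lib <- ngn_init_library(g_sub, one, seed = 4)
  L <- function(x) 1 / (1 + exp(-x))
  set_layer <- function(key, w, b) {
    lib$layers[[key]]$w[] <<- w
    lib$layers[[key]]$b[] <<- b
  }
  set_layer("atom->{C,O}#1", c(0.7, -0.4), 0.1)  # columns: C, O
  set_layer("chain->atom#1", 0.5, -0.2)
  set_layer("smiles->chain#1", -1.1, 0.3)
  set_layer("output", 0.9, -0.6)
  net <- ngn_assemble(ngn_parse("C", g_sub), lib)
  a1 <- L(0.7 * 1.0 + 0.1)         # token C hits column 1
  a2 <- L(0.5 * a1 - 0.2)
  a3 <- L(-1.1 * a2 + 0.3)
  expect_equal(ngn_feedforward(net, lib)$output, L(0.9 * a3 - 0.6),
               tolerance = 1e-12)
})

test_that("feedforward is pure and keeps activations strictly inside (0,1)", {
  lib <- ngn_init_library(g_sub, ctl, seed = 6)
  net <- ngn_assemble(ngn_parse("CC(C)CCO", g_sub), lib)
  f1 <- ngn_feedforward(net, lib)
  f2 <- ngn_feedforward(net, lib)
  expect_identical(f1, f2)
  acts <- unlist(f1$activations)
  expect_true(all(acts > 0 & acts < 1))
})

test_that("backprop needs a forward pass and zeroes out at the target", {
  lib <- ngn_init_library(g_sub, ctl, seed = 7)
  net <- ngn_assemble(ngn_parse("CCO", g_sub), lib)
  expect_error(ngn_backprop(net, lib, 0.5), "feedforward")
  ff <- ngn_feedforward(net, lib)
  gr <- ngn_backprop(net, lib, ff$output, ff)   # target equals output
  deltas <- unlist(lapply(gr$by_key, function(g)
    lapply(g, function(i) c(i$dw, i$db))))
  expect_true(all(abs(deltas) < 1e-12))
})

test_that("shared keys carry one instantiation group per occurrence", {
  lib <- ngn_init_library(g_sub, ctl, seed = 8)
  net <- ngn_assemble(ngn_parse("CC(C)CCO", g_sub), lib)
  ff <- ngn_feedforward(net, lib)
  gr <- ngn_backprop(net, lib, 0.8, ff)
  counts <- vapply(gr$by_key, length, 0L)
  expect_identical(counts[["chain->atom#1"]], 6L)
  expect_identical(counts[["atom->{C,O}#1"]], 6L)
  expect_identical(counts[["chain->chain#2"]], 4L)
  expect_identical(counts[["output"]], 1L)
})

test_that("analytic deltas match central finite differences", {
  small <- ngn_control(hidden_size = 3L)
  set.seed(31)
  for (rep in 1:5) {
    s <- ngn_sample_string(g_sub, 8)
    lib <- ngn_init_library(g_sub, small)
    net <- ngn_assemble(ngn_parse(s, g_sub), lib)
    target <- runif(1, 0.2, 0.8)
    ff <- ngn_feedforward(net, lib)
    gr <- ngn_backprop(net, lib, target, ff)
    for (key in names(gr$by_key)) {
      tot_w <- Reduce(`+`, lapply(gr$by_key[[key]], `[[`, "dw"))
      tot_b <- Reduce(`+`, lapply(gr$by_key[[key]], `[[`, "db"))
      probe <- unique(c(1L, length(tot_w)))
      for (idx in probe)
        expect_lt(rel_err(fd_delta(lib, net, target, key, idx, "w"),
                          tot_w[idx]), 1e-4)
      expect_lt(rel_err(fd_delta(lib, net, target, key, 1L, "b"),
                        tot_b[1]), 1e-4)
    }
  }
})

test_that("updates sum instantiation deltas and respect momentum buffers", {
  lib <- ngn_init_library(g_sub, ngn_control(momentum = 0), seed = 9)
  net <- ngn_assemble(ngn_parse("CC", g_sub), lib)
  ff <- ngn_feedforward(net, lib)
  gr <- ngn_backprop(net, lib, 0.7, ff)
  key <- "chain->atom#1"               # two instantiations in "CC"
  expect_length(gr$by_key[[key]], 2L)
  d1 <- gr$by_key[[key]][[1]]$dw
  d2 <- gr$by_key[[key]][[2]]$dw
  lib2 <- ngn_apply_updates(lib, gr)
  expect_identical(lib2$layers[[key]]$dw, d1 + d2)   # the applied change
  expect_lt(max(abs((lib2$layers[[key]]$w - lib$layers[[key]]$w) -
                    (d1 + d2))), 1e-12)
  # first-ever update: momentum buffers start at zero, so even with a large
  # momentum coefficient the applied change is just the delta sum
  libm <- ngn_init_library(g_sub, ngn_control(momentum = 0.9), seed = 9)
  grm <- ngn_backprop(net, libm, 0.7, ngn_feedforward(net, libm))
  libm2 <- ngn_apply_updates(libm, grm)
  s1 <- Reduce(`+`, lapply(grm$by_key[[key]], `[[`, "dw"))
  expect_identical(libm2$layers[[key]]$dw, s1)
  # keys absent from the parse stay untouched, momentum buffers included
  untouched <- setdiff(lib$keys$name, names(gr$by_key))
  expect_true(length(untouched) > 0)
  for (k in untouched) expect_identical(lib2$layers[[k]], lib$layers[[k]])
})

test_that("the fused training step equals backprop plus apply_updates", {
  for (mode in c("per_symbol_pair", "per_rule")) {
    cc <- ngn_control(sharing_mode = mode, momentum = 0.5)
    lib <- ngn_init_library(g_sub, cc, seed = 12)
    net <- ngn_assemble(ngn_parse("CC(C)CCO", g_sub), lib)
    # two consecutive steps so the momentum path is exercised
    for (target in c(0.8, 0.3)) {
      gr <- ngn_backprop(net, lib, target, ngn_feedforward(net, lib))
      ref <- ngn_apply_updates(lib, gr)
      fused <- ngn:::cpp_step(lib$layers, net$plan, target, cc$eta,
                              cc$momentum)
      for (k in names(ref$layers)) {
        expect_equal(fused$layers[[k]]$w, ref$layers[[k]]$w,
                     tolerance = 1e-13)
        expect_equal(fused$layers[[k]]$b, ref$layers[[k]]$b,
                     tolerance = 1e-13)
      }
      lib <- ref
    }
  }
})

test_that("per-rule sharing instantiates layers once per rule application", {
  cc <- ngn_control(sharing_mode = "per_rule")
  lib <- ngn_init_library(g_sub, cc, seed = 13)
  net <- ngn_assemble(ngn_parse("CC(C)CCO", g_sub), lib)
  ff <- ngn_feedforward(net, lib)
  gr <- ngn_backprop(net, lib, 0.8, ff)
  counts <- vapply(gr$by_key, length, 0L)
  expect_identical(counts[["r2:chain->atom#1"]], 2L)
  expect_identical(counts[["r3:chain->atom#1"]], 3L)
  expect_identical(counts[["r5:atom->{C}#1"]], 5L)
  expect_identical(nrow(net$zero_slots), 0L)   # no slot sharing, no flushing
})

test_that("a single exemplar is fit to within the convergence threshold", {
  fit <- ngn("CC(C)CCO", 0.7, g_sub,
             ngn_control(max_epochs = 2000), seed = 21, normalize = FALSE)
  expect_true(fit$converged)
  expect_lt(fit$final_rmse, fit$control$rmse_threshold)
  expect_lt(abs(predict(fit) - 0.7), 0.05)
})

test_that("contradictory exemplars exhaust restarts without converging", {
  fit <- ngn(c("CCO", "CCO"), c(0.2, 0.8), g_sub,
             ngn_control(max_epochs = 40, max_restarts = 2),
             seed = 22, normalize = FALSE)
  expect_false(fit$converged)
  expect_identical(fit$restarts, 2L)
  expect_gte(fit$final_rmse, 0.3)   # RMSE floor forced by the contradiction
})

test_that("training is bit-reproducible from the seed", {
  mols <- c("CCO", "CC(C)O", "CCC", "OCO", "CC")
  y <- c(0.8, 0.8, 0.2, 0.8, 0.2)
  f1 <- ngn(mols, y, g_sub, ngn_control(max_epochs = 50), seed = 33,
            normalize = FALSE)
  f2 <- ngn(mols, y, g_sub, ngn_control(max_epochs = 50), seed = 33,
            normalize = FALSE)
  expect_identical(f1$library$layers, f2$library$layers)
  expect_identical(f1$rmse_history, f2$rmse_history)
})

test_that("library storage depends on the grammar, not the dataset", {
  f1 <- ngn("C", 0.5, g_sub, ngn_control(max_epochs = 5), seed = 1,
            normalize = FALSE)
  f2 <- ngn(c("CC(C)CCO", "CC(CC(C)C)CO", "CCCCCCCCCO"), c(0.3, 0.5, 0.7),
            g_sub, ngn_control(max_epochs = 5), seed = 1, normalize = FALSE)
  expect_identical(f1$library$keys, f2$library$keys)
  expect_identical(lapply(f1$library$layers, function(l) dim(l$w)),
                   lapply(f2$library$layers, function(l) dim(l$w)))
})

test_that("classification fits map labels through the output scale", {
  mols <- c("CCO", "CCC", "COC", "CC", "OCCO", "CCCC")
  y <- factor(c("pos", "neg", "pos", "neg", "pos", "neg"))
  fit <- ngn(mols, y, g_sub, ngn_control(max_epochs = 3000), seed = 44)
  expect_true(fit$converged)
  expect_identical(as.character(predict(fit, type = "class")),
                   as.character(y))
  expect_true(all(predict(fit) > 0 & predict(fit) < 1))
})

test_that("regression fits normalize targets and invert them on predict", {
  mols <- c("C", "CC", "CCC", "CCCC", "CCCCC", "CCCCCC")
  act <- c(1.2, 2.3, 3.1, 4.4, 5.0, 6.2)    # arbitrary activity units
  fit <- ngn(mols, act, g_sub, ngn_control("regression_cv",
                                           max_epochs = 4000), seed = 55)
  expect_true(fit$converged)
  expect_identical(fit$target_range, range(act))
  back <- predict(fit, type = "original")
  expect_lt(max(abs(back - act)), 0.6)      # within ~10% of the 5-unit span
  expect_error(predict(fit, newdata = "XX"), "error")
})
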