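#' Build a cross-validation fold plan
#'
#' Supported schemes: `leave20_cv` (five random folds, each used as the
#' test set ten times, 50 trials in all), `leave5_cv` (twenty folds, one
#' trial each), `designed` (an explicit, externally supplied test set,
#' ten trials), `grouped5` (sort by target, deal round-robin into five
#' clusters evenly spread across the output range), and `random5` (a fresh
#' random fifth held out for every trial).
#'
#' @param n Number of exemplars.
#' @param scheme Fold scheme name.
#' @param targets Numeric targets; required for `grouped5`.
#' @param seed Integer seed for the partition and per-trial randomness.
#' @param reps Repetitions per fold (or total trials for `random5`);
#'   defaults: 10 for `leave20_cv`/`designed`/`grouped5`, 1 for
#'   `leave5_cv`, 50 trials for `random5`.
#' @param test Explicit 1-based test indices (for `designed`).
#' @return An object of class `ngn_fold_plan`.
#' @examples
#' plan <- ngn_folds(10, "leave20_cv", seed = 1)
#' lengths(plan$folds); plan$n_trials
#' @export
ngn_folds <- function(n, scheme = c("leave20_cv", "leave5_cv", "designed",
                                    "grouped5", "random5"),
                      targets = NULL, seed = 1L, reps = NULL, test = NULL) {
  scheme <- match.arg(scheme)
  k <- switch(scheme, leave20_cv = 5L, leave5_cv = 20L, grouped5 = 5L,
              random5 = 5L, designed = NA_integer_)
  if (!is.na(k) && n < k)
    stop("design error: ", n, " exemplars cannot fill ", k, " folds",
         call. = FALSE)
  reps <- if (!is.null(reps)) as.integer(reps)
          else switch(scheme, leave20_cv = 10L, leave5_cv = 1L,
                      designed = 10L, grouped5 = 10L, random5 = 50L)
  set.seed(seed)
  folds <- switch(scheme,
    leave20_cv = .partition(sample.int(n), 5L),
    leave5_cv = .partition(sample.int(n), 20L),
    grouped5 = {
      if (is.null(targets) || length(targets) != n)
        stop("grouped5 requires one target per exemplar", call. = FALSE)
      ord <- order(targets)               # round-robin deal over sorted order
      lapply(1:5, function(i) ord[seq(i, n, by = 5L)])
    },
    designed = {
      if (is.null(test)) stop("designed scheme requires explicit test indices",
                              call. = FALSE)
      stopifnot(all(test %in% seq_len(n)))
      list(as.integer(test))
    },
    random5 = NULL)
  n_trials <- if (scheme == "random5") reps else length(folds) * reps
  structure(list(scheme = scheme, folds = folds, reps_per_fold = reps,
                 n_trials = n_trials, n = as.integer(n), seed = as.integer(seed)),
            class = "ngn_fold_plan")
}

# consecutive chunks of a permutation, sizes differing by at most one
.partition <- function(perm, k) {
  n <- length(perm)
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  ends <- cumsum(sizes)
  starts <- c(1L, ends[-k] + 1L)
  lapply(seq_len(k), function(i) sort(perm[starts[i]:ends[i]]))
}

#' @export
print.ngn_fold_plan <- function(x, ...) {
  cat("Fold plan '", x$scheme, "': ", sep = "")
  if (is.null(x$folds)) cat("fresh random fifth per trial, ")
  else cat(length(x$folds), " folds (sizes ",
           paste(lengths(x$folds), collapse = "/"), ") x ",
           x$reps_per_fold, " reps, ", sep = "")
  cat(x$n_trials, " trials, seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Run repeated cross-validation trials of an NGN
#'
#' For every trial a fresh randomly initialized NGN is trained on the
#' training portion and evaluated on the held-out portion with the
#' package's statistics (Q/SE/SP/MCC for classification; PRESS/SD/q2,
#' Epsilon and the correlation coefficient for regression).  Regression
#' targets are min-max scaled onto the output scale once, over the whole
#' dataset, before the trials.  Trials whose training never converges are
#' flagged and excluded from the aggregate mean and standard deviation.
#' The full run is reproducible from `(plan seed, control, data order)`.
#'
#' @param molecules Character vector of molecular strings.
#' @param targets Labels (classification) or numeric activities
#'   (regression).
#' @param grammar Grammar or built-in grammar name.
#' @param control An [ngn_control()].
#' @param plan An [ngn_folds()] plan over `length(molecules)`.
#' @param threshold Classification decision threshold.
#' @return An object of class `ngn_report`: per-trial records, aggregate
#'   mean and sample standard deviation per metric over converged trials,
#'   and convergence bookkeeping.
#' @export
ngn_run_trials <- function(molecules, targets, grammar = "smiles_subset",
                           control = ngn_control(), plan,
                           threshold = 0.5) {
  stopifnot(inherits(plan, "ngn_fold_plan"),
            length(molecules) == plan$n, length(targets) == plan$n)
  g <- ngn_grammar(grammar)
  task <- if (is.numeric(targets)) "regression" else "classification"
  if (task == "regression") {
    scaled <- ngn_normalize(targets, control$output_lo, control$output_hi)
  } else {
    labels <- .as_posneg(targets)
  }
  set.seed(plan$seed)
  trial_seeds <- sample.int(.Machine$integer.max - 1L, plan$n_trials)
  random_tests <- if (plan$scheme == "random5")
    lapply(seq_len(plan$n_trials),
           function(i) sort(sample.int(plan$n, round(plan$n / 5)))) else NULL
  rows <- vector("list", plan$n_trials)
  t <- 0L
  fold_of <- if (is.null(plan$folds)) rep(NA_integer_, plan$n_trials)
             else rep(seq_along(plan$folds), each = plan$reps_per_fold)
  for (t in seq_len(plan$n_trials)) {
    test <- if (is.null(plan$folds)) random_tests[[t]]
            else plan$folds[[fold_of[t]]]
    train <- setdiff(seq_len(plan$n), test)
    fit <- if (task == "regression")
      ngn(molecules[train], scaled[train], g, control,
          seed = trial_seeds[t], normalize = FALSE)
    else
      ngn(molecules[train], labels[train], g, control, seed = trial_seeds[t])
    preds <- ngn_predict_raw(fit$library, molecules[test])
    rec <- list(trial = t, fold = fold_of[t],
                converged = fit$converged, epochs = fit$epochs,
                restarts = fit$restarts)
    if (task == "classification") {
      m <- ngn_classification_metrics(ngn_confusion(preds, labels[test],
                                                    threshold))
      rec <- c(rec, m)
    } else {
      q <- ngn_q2(preds, scaled[test])
      e <- ngn_epsilon(preds, scaled[test])
      cc <- tryCatch(ngn_cc(scaled[test], preds), error = function(e) NA_real_)
      rec <- c(rec, list(press = q$press, sd = q$sd, q2 = q$q2,
                         epsilon = e$epsilon, epsilon_sd = e$epsilon_sd,
                         cc = cc))
    }
    rows[[t]] <- rec
  }
  trials <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  metric_cols <- setdiff(names(trials),
                         c("trial", "fold", "converged", "epochs", "restarts"))
  conv <- trials$converged
  agg <- data.frame(metric = metric_cols,
                    mean = vapply(metric_cols, function(m)
                      if (any(conv)) mean(trials[[m]][conv]) else NA_real_, 0),
                    sd = vapply(metric_cols, function(m)
                      if (sum(conv) > 1) stats::sd(trials[[m]][conv])
                      else NA_real_, 0),
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(trials = trials, aggregates = agg, task = task,
                 scheme = plan$scheme, n_trials = plan$n_trials,
                 n_converged = sum(conv), seed = plan$seed),
            class = "ngn_report")
}

#' @export
print.ngn_report <- function(x, ...) {
  cat("NGN ", x$task, " report, scheme '", x$scheme, "': ",
      x$n_converged, "/", x$n_trials, " converged trials\n", sep = "")
  a <- x$aggregates
  for (i in seq_len(nrow(a)))
    cat(sprintf("  %-10s %8.4f +/- %.4f\n", a$metric[i], a$mean[i], a$sd[i]))
  invisible(x)
}

#' String-computable descriptor vector
#'
#' The fixed-length feature vector used by the descriptor-ANN baseline:
#' the count of every token the grammar can accept (element symbols,
#' branch parentheses, ring-closure digits, bond symbols, ...) plus the
#' total token count.  These descriptors see *what* occurs in a string but
#' not *where* -- the contrast the grammar network is designed to expose.
#'
#' @param molecules Character vector of strings.
#' @param g Grammar or built-in grammar name used for tokenization.
#' @return Numeric matrix, one row per molecule, with token names (and
#'   `n_tokens`) as column names.
#' @export
ngn_descriptors <- function(molecules, g) {
  g <- ngn_grammar(g)
  vocab <- sort(g$lr$tokens)
  out <- matrix(0, length(molecules), length(vocab) + 1L,
                dimnames = list(NULL, c(vocab, "n_tokens")))
  for (i in seq_along(molecules)) {
    toks <- ngn_tokenize(molecules[i], g)
    tab <- table(toks$text)
    out[i, names(tab)] <- as.numeric(tab)
    out[i, "n_tokens"] <- nrow(toks)
  }
  out
}

#' Fit the descriptor-vector baseline neural network
#'
#' A standard fully connected three-layer logistic network (inputs ->
#' hidden -> single output) trained online with momentum under the same
#' convergence-and-restart contract as the NGN.  Defaults follow the
#' published baseline protocol: 2 hidden units, learning rate 0.9,
#' momentum 0.3, initial weights uniform in (-0.3, 0.3), up to 50000
#' epochs, training RMSE threshold 0.05.
#'
#' @param x Numeric descriptor matrix (rows = exemplars).
#' @param targets Labels or numeric activities, as in [ngn()].
#' @param hidden Hidden units.
#' @param eta,momentum,init,rmse_threshold,max_epochs,max_restarts
#'   Training parameters; `init` is the half-width of the uniform
#'   initialization range.
#' @param output_lo,output_hi Output scale for target mapping.
#' @param seed Integer seed.
#' @param normalize Min-max scale numeric targets onto the output scale.
#' @return An object of class `ngn_ann`.
#' @export
ngn_ann <- function(x, targets, hidden = 2L, eta = 0.9, momentum = 0.3,
                    init = 0.3, rmse_threshold = 0.05, max_epochs = 50000L,
                    max_restarts = 3L, output_lo = 0.2, output_hi = 0.8,
                    seed = 1L, normalize = TRUE) {
  x <- as.matrix(x)
  stopifnot(nrow(x) == length(targets), nrow(x) >= 1L)
  task <- if (is.numeric(targets)) "regression" else "classification"
  if (task == "classification") {
    y <- .as_posneg(targets)
    scaled <- ifelse(y == "pos", output_hi, output_lo)
    target_range <- NULL
  } else if (normalize) {
    target_range <- range(targets)
    scaled <- ngn_normalize(targets, output_lo, output_hi)
  } else {
    target_range <- NULL
    scaled <- targets
  }
  p <- ncol(x)
  init_layers <- function() {
    list(input = list(w = matrix(stats::runif(hidden * p, -init, init),
                                 hidden, p),
                      b = stats::runif(hidden, -init, init),
                      dw = matrix(0, hidden, p), db = rep(0, hidden)),
         output = list(w = matrix(stats::runif(hidden, -init, init), 1, hidden),
                       b = stats::runif(1, -init, init),
                       dw = matrix(0, 1, hidden), db = 0))
  }
  plans <- lapply(seq_len(nrow(x)), function(i)
    list(node_sizes = c(hidden, 1L),
         edge_parent = c(1L, 2L), edge_key = c(1L, 2L),
         edge_type = c(2L, 0L), edge_child = c(1L, 1L),
         dense = list(x[i, ])))
  set.seed(seed)
  layers <- init_layers()
  restarts <- 0L
  repeat {
    res <- cpp_train(layers, plans, scaled, eta, momentum, rmse_threshold,
                     as.integer(max_epochs))
    if (res$converged || restarts >= max_restarts) break
    restarts <- restarts + 1L
    layers <- init_layers()
  }
  fitted <- vapply(plans, function(pl)
    cpp_forward(res$layers, pl)$output, 0)
  structure(list(layers = res$layers, hidden = hidden, p = p,
                 eta = eta, momentum = momentum,
                 task = task, converged = res$converged,
                 epochs = res$epochs, restarts = restarts,
                 final_rmse = res$final_rmse,
                 output_lo = output_lo, output_hi = output_hi,
                 target_range = target_range,
                 fitted.values = fitted, targets_scaled = scaled,
                 seed = seed),
            class = "ngn_ann")
}

#' @export
print.ngn_ann <- function(x, ...) {
  cat("Descriptor-ANN baseline (", x$p, " inputs, ", x$hidden,
      " hidden): ", if (x$converged) "converged" else "NOT converged",
      " after ", x$epochs, " epochs (", x$restarts, " restarts), RMSE ",
      signif(x$final_rmse, 4), "\n", sep = "")
  invisible(x)
}

#' @export
predict.ngn_ann <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted.values)
  newdata <- as.matrix(newdata)
  stopifnot(ncol(newdata) == object$p)
  vapply(seq_len(nrow(newdata)), function(i)
    cpp_forward(object$layers,
                list(node_sizes = c(object$hidden, 1L),
                     edge_parent = c(1L, 2L), edge_key = c(1L, 2L),
                     edge_type = c(2L, 0L), edge_child = c(1L, 1L),
                     dense = list(newdata[i, ])))$output, 0)
}

#' Compare two methods' trial reports with the Wilcoxon signed-rank test
#'
#' Pairs the per-trial values of a statistic (Epsilon or its standard
#' deviation -- smaller is better for both) across two reports with
#' matching trial structure and tests whether one method performs
#' systematically better.  A winner is declared at p < 0.05.
#'
#' @param report_a,report_b `ngn_report` objects with equal trial counts
#'   and matching fold assignments.
#' @param statistic `"epsilon"` or `"epsilon_sd"`.
#' @param alternative Passed to [ngn_wilcoxon()].
#' @return List with `W`, `p`, `winner` (`"a"`, `"b"` or `"none"`) and
#'   `statistic`.
#' @export
ngn_compare <- function(report_a, report_b,
                        statistic = c("epsilon", "epsilon_sd"),
                        alternative = "two.sided") {
  statistic <- match.arg(statistic)
  stopifnot(inherits(report_a, "ngn_report"), inherits(report_b, "ngn_report"))
  if (report_a$n_trials != report_b$n_trials ||
      !identical(report_a$trials$fold, report_b$trials$fold))
    stop("design error: reports have mismatched trial structure", call. = FALSE)
  va <- report_a$trials[[statistic]]
  vb <- report_b$trials[[statistic]]
  if (is.null(va) || is.null(vb))
    stop("statistic '", statistic, "' not present in both reports",
         call. = FALSE)
  if (all(va == vb))
    return(list(W = NA_real_, p = NA_real_, winner = "none",
                statistic = statistic, note = "no difference between methods"))
  w <- ngn_wilcoxon(va, vb, alternative = alternative)
  winner <- if (w$p < 0.05) {
    if (mean(va) < mean(vb)) "a" else "b"   # smaller epsilon is better
  } else "none"
  list(W = w$W, p = w$p, winner = winner, statistic = statistic,
       n_used = w$n_used)
}
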