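#' Training control parameters for neural grammar networks
#'
#' Collects the tunable parameters of NGN training.  Four named presets
#' reproduce the published parameter sets: `"classification"` (the default:
#' eta 0.60, momentum 0.90, convergence RMSE 0.05, 5000 epochs, 8 hidden
#' units, initial weights drawn from \eqn{[-1.6,-1.0] \cup [1.0,1.6]},
#' output scale (0.2, 0.8)), `"regression_cv"` (eta 0.30, momentum 0.10,
#' RMSE 0.03, 7500 epochs), `"regression_designed"` (eta 0.33, momentum
#' 0.66, RMSE 0.04, init bands 0.4--1.2) and `"toxicology_ngn"` (12 hidden
#' units, eta 0.3, momentum 0.3, 10000 epochs, training RMSE 0.05 with a
#' 0.03 convergence pre-test threshold).
#'
#' @param preset Name of a preset; explicit arguments override its values.
#' @param eta Learning rate (training constant), > 0.
#' @param momentum Momentum coefficient in [0, 1): fraction of the previous
#'   weight change carried into the current update.
#' @param rmse_threshold Training stops (converged) when the epoch root
#'   mean squared error drops below this.
#' @param pretest_rmse Optional stricter threshold used by convergence
#'   pre-tests on a whole dataset (`NA` to disable).
#' @param max_epochs Epoch budget per restart.
#' @param max_restarts Re-initializations attempted after an unconverged
#'   run before giving up.
#' @param hidden_size Processing units per internal-symbol node layer.
#' @param init_low,init_high Initial weights and biases are drawn uniformly
#'   from \eqn{[-high,-low] \cup [low,high]} with the band chosen
#'   equiprobably; `init_low = 0` gives plain uniform \eqn{[-high, high]}.
#' @param output_lo,output_hi Output scale: targets are mapped into this
#'   sub-range of the logistic output (0, 1).
#' @param sharing_mode `"per_symbol_pair"` keys weight layers by (parent
#'   symbol, child slot), shared across productions with the same left-hand
#'   side; `"per_rule"` keys them by (production, position).
#' @return An object of class `ngn_control`.
#' @export
ngn_control <- function(preset = c("classification", "regression_cv",
                                   "regression_designed", "toxicology_ngn"),
                        eta = NULL, momentum = NULL, rmse_threshold = NULL,
                        pretest_rmse = NULL, max_epochs = NULL,
                        max_restarts = 3L, hidden_size = NULL,
                        init_low = NULL, init_high = NULL,
                        output_lo = 0.2, output_hi = 0.8,
                        sharing_mode = c("per_symbol_pair", "per_rule")) {
  preset <- match.arg(preset)
  sharing_mode <- match.arg(sharing_mode)
  base <- switch(preset,
    classification = list(eta = 0.60, momentum = 0.90, rmse_threshold = 0.05,
                          max_epochs = 5000L, hidden_size = 8L,
                          init_low = 1.0, init_high = 1.6,
                          pretest_rmse = NA_real_),
    regression_cv = list(eta = 0.30, momentum = 0.10, rmse_threshold = 0.03,
                         max_epochs = 7500L, hidden_size = 8L,
                         init_low = 1.0, init_high = 1.6,
                         pretest_rmse = NA_real_),
    regression_designed = list(eta = 0.33, momentum = 0.66,
                               rmse_threshold = 0.04, max_epochs = 7500L,
                               hidden_size = 8L,
                               init_low = 0.4, init_high = 1.2,
                               pretest_rmse = NA_real_),
    toxicology_ngn = list(eta = 0.3, momentum = 0.3, rmse_threshold = 0.05,
                          max_epochs = 10000L, hidden_size = 12L,
                          init_low = 1.0, init_high = 1.6,
                          pretest_rmse = 0.03))
  pick <- function(x, d) if (is.null(x)) d else x
  ctl <- list(preset = preset,
              eta = pick(eta, base$eta),
              momentum = pick(momentum, base$momentum),
              rmse_threshold = pick(rmse_threshold, base$rmse_threshold),
              pretest_rmse = pick(pretest_rmse, base$pretest_rmse),
              max_epochs = as.integer(pick(max_epochs, base$max_epochs)),
              max_restarts = as.integer(max_restarts),
              hidden_size = as.integer(pick(hidden_size, base$hidden_size)),
              init_low = pick(init_low, base$init_low),
              init_high = pick(init_high, base$init_high),
              output_lo = output_lo, output_hi = output_hi,
              sharing_mode = sharing_mode)
  .validate_control(ctl)
  structure(ctl, class = "ngn_control")
}

.validate_control <- function(ctl) {
  chk <- function(ok, field, why)
    if (!isTRUE(ok)) stop("invalid control: '", field, "' ", why, call. = FALSE)
  chk(is.numeric(ctl$eta) && ctl$eta > 0, "eta", "must be > 0")
  chk(ctl$momentum >= 0 && ctl$momentum < 1, "momentum", "must be in [0, 1)")
  chk(ctl$rmse_threshold > 0, "rmse_threshold", "must be > 0")
  chk(ctl$max_epochs >= 1, "max_epochs", "must be >= 1")
  chk(ctl$max_restarts >= 0, "max_restarts", "must be >= 0")
  chk(ctl$hidden_size >= 1, "hidden_size", "must be >= 1")
  chk(ctl$init_low >= 0, "init_low", "must be >= 0")
  chk(ctl$init_high > ctl$init_low, "init_high", "must exceed init_low")
  chk(ctl$output_lo > 0 && ctl$output_lo < ctl$output_hi && ctl$output_hi < 1,
      "output scale", "must satisfy 0 < lo < hi < 1")
  invisible(ctl)
}

#' @export
print.ngn_control <- function(x, ...) {
  cat("NGN training control (preset '", x$preset, "')\n", sep = "")
  cat(sprintf("  eta %.2f, momentum %.2f, RMSE threshold %.3f, %d epochs x %d restarts\n",
              x$eta, x$momentum, x$rmse_threshold, x$max_epochs,
              x$max_restarts + 1L))
  cat(sprintf("  %d hidden units, init [-%.1f,-%.1f]U[%.1f,%.1f], output scale (%.1f, %.1f), %s sharing\n",
              x$hidden_size, x$init_high, x$init_low, x$init_low, x$init_high,
              x$output_lo, x$output_hi, x$sharing_mode))
  invisible(x)
}

# Enumerate the weight-layer keys a grammar induces under a sharing mode.
# Returns data.frame(name, parent_size, child_size, kind) plus a lookup
# environment mapping "sym#slot" / "r<idx>#<pos>" -> key index.  The final
# key "output" is the 1-unit output head above the start symbol.
.library_keys <- function(g, hidden, sharing) {
  name <- character(0); psz <- integer(0); csz <- integer(0); kind <- character(0)
  lookup <- new.env(parent = emptyenv())
  add <- function(nm, ref, p, c, kd) {
    name <<- c(name, nm); psz <<- c(psz, p); csz <<- c(csz, c)
    kind <<- c(kind, kd)
    assign(ref, length(name), envir = lookup)
  }
  if (sharing == "per_symbol_pair") {
    for (sym in g$internal) {
      sig <- g$signatures[[sym]]
      tab <- sig$table
      for (i in seq_len(nrow(tab))) {
        cs <- switch(tab$kind[i],
                     internal = hidden,
                     terminal = length(sig$tok_vocab),
                     literal = 1L)
        lab <- if (tab$kind[i] == "internal") tab$symbol[i]
               else paste0("{", paste(tab$tokens[[i]], collapse = ","), "}")
        add(paste0(sym, "->", lab, "#", tab$slot[i]),
            paste0(sym, "#", tab$slot[i]), hidden, cs, tab$kind[i])
      }
    }
  } else {
    for (r in g$rules) {
      if (r$kind == "acceptance") {
        add(paste0("r", r$index, ":", r$lhs, "->{",
                   paste(r$tokens, collapse = ","), "}#1"),
            paste0("r", r$index, "#1"), hidden, length(r$tokens), "terminal")
      } else {
        for (j in seq_along(r$rhs)) {
          cs <- if (r$rhs_is_token[j]) 1L else hidden
          kd <- if (r$rhs_is_token[j]) "literal" else "internal"
          add(paste0("r", r$index, ":", r$lhs, "->", r$rhs[j], "#", j),
              paste0("r", r$index, "#", j), hidden, cs, kd)
        }
      }
    }
  }
  add("output", "output", 1L, hidden, "output")
  list(table = data.frame(name = name, parent_size = psz, child_size = csz,
                          kind = kind, stringsAsFactors = FALSE),
       lookup = lookup)
}

#' Initialize a persistent weight-layer library for a grammar
#'
#' Creates one weight layer (matrix, bias vector, and zeroed momentum
#' buffers) per library key of the grammar under the control's sharing
#' mode, plus the output head.  Entries are drawn uniformly from the
#' symmetric two-band range \eqn{[-high,-low] \cup [low,high]}, band chosen
#' equiprobably.  The library is the persistent state of an NGN: it is
#' shared by every molecule's network and accumulates all training.
#'
#' @param g An `ngn_grammar` or built-in grammar name.
#' @param control An [ngn_control()] object.
#' @param seed Optional integer; if given, `set.seed(seed)` is called first.
#' @return An object of class `ngn_library`.
#' @export
ngn_init_library <- function(g, control = ngn_control(), seed = NULL) {
  g <- ngn_grammar(g)
  .validate_control(control)
  if (!is.null(seed)) set.seed(seed)
  ks <- .library_keys(g, control$hidden_size, control$sharing_mode)
  layers <- vector("list", nrow(ks$table))
  for (k in seq_along(layers)) {
    p <- ks$table$parent_size[k]; c <- ks$table$child_size[k]
    draw <- function(n) {
      mag <- stats::runif(n, control$init_low, control$init_high)
      sgn <- ifelse(stats::runif(n) < 0.5, -1, 1)
      mag * sgn
    }
    layers[[k]] <- list(w = matrix(draw(p * c), p, c),
                        b = draw(p),
                        dw = matrix(0, p, c), db = rep(0, p))
  }
  names(layers) <- ks$table$name
  structure(list(grammar = g, keys = ks$table, lookup = ks$lookup,
                 layers = layers, control = control),
            class = "ngn_library")
}

#' @export
print.ngn_library <- function(x, ...) {
  npar <- sum(vapply(x$layers, function(l) length(l$w) + length(l$b), 0))
  cat("NGN weight-layer library for grammar '", x$grammar$name, "'\n", sep = "")
  cat("  ", length(x$layers), " shared layers (", x$control$sharing_mode,
      "), ", npar, " parameters, hidden size ", x$control$hidden_size,
      "\n", sep = "")
  invisible(x)
}

#' Assemble the per-molecule network for a parse tree
#'
#' Builds the tree-shaped network whose topology mirrors the parse tree:
#' one hidden node layer per internal parse node, a one-hot input leaf per
#' token (a single unit per accepted token, the matched unit set to 1.0),
#' and a 1-unit output layer above the start symbol.  Every edge references
#' a shared layer of the library; layers are bound, never copied.
#' Signature slots that the applied production does not use are recorded in
#' `zero_slots` and contribute a zero activation vector (and no update)
#' during the passes.
#'
#' @param tree An `ngn_parse_tree` from [ngn_parse()].
#' @param lib An `ngn_library` built for the same grammar.
#' @return An object of class `ngn_network`.
#' @export
ngn_assemble <- function(tree, lib) {
  stopifnot(inherits(tree, "ngn_parse_tree"), inherits(lib, "ngn_library"))
  g <- lib$grammar
  if (!identical(tree$grammar, g$name))
    stop("parse tree (grammar '", tree$grammar,
         "') does not match library (grammar '", g$name, "')", call. = FALSE)
  sharing <- lib$control$sharing_mode
  hidden <- lib$control$hidden_size
  lookup <- lib$lookup
  key_of <- function(ref) {
    k <- get0(ref, envir = lookup, inherits = FALSE)
    if (is.null(k)) stop("unbound library key '", ref, "'", call. = FALSE)
    k
  }
  sizes <- integer(0)
  ep <- integer(0); ek <- integer(0); et <- integer(0); ec <- integer(0)
  bindings <- character(0)
  zs_node <- integer(0); zs_slot <- integer(0); zs_key <- character(0)
  walk <- function(node) {
    rule <- g$rules[[node$rule]]
    sig <- g$signatures[[node$symbol]]
    if (rule$kind == "acceptance") {
      my <- length(sizes) + 1L
      sizes[my] <<- hidden
      k <- if (sharing == "per_symbol_pair") {
        tok <- match(node$children[[1]]$token, sig$tok_vocab)
        key_of(paste0(node$symbol, "#", sig$tok_slot))
      } else key_of(paste0("r", node$rule, "#1"))
      tok <- if (sharing == "per_symbol_pair")
        match(node$children[[1]]$token, sig$tok_vocab)
      else match(node$children[[1]]$token, rule$tokens)
      ep[length(ep) + 1L] <<- my; ek[length(ek) + 1L] <<- k
      et[length(et) + 1L] <<- 1L; ec[length(ec) + 1L] <<- tok
      bindings[length(bindings) + 1L] <<- lib$keys$name[k]
      return(my)
    }
    kids <- integer(length(node$children))
    for (j in seq_along(node$children)) {
      ch <- node$children[[j]]
      kids[j] <- if (is.null(ch$token)) walk(ch) else NA_integer_
    }
    my <- length(sizes) + 1L
    sizes[my] <<- hidden
    for (j in seq_along(node$children)) {
      k <- if (sharing == "per_symbol_pair")
        key_of(paste0(node$symbol, "#", node$slots[j]))
      else key_of(paste0("r", node$rule, "#", j))
      ep[length(ep) + 1L] <<- my; ek[length(ek) + 1L] <<- k
      if (is.na(kids[j])) {         # inline literal leaf: one-token slot
        et[length(et) + 1L] <<- 1L; ec[length(ec) + 1L] <<- 1L
      } else {
        et[length(et) + 1L] <<- 0L; ec[length(ec) + 1L] <<- kids[j]
      }
      bindings[length(bindings) + 1L] <<- lib$keys$name[k]
    }
    if (sharing == "per_symbol_pair") {
      absent <- setdiff(sig$table$slot, node$slots)
      for (s in absent) {
        zs_node[length(zs_node) + 1L] <<- my
        zs_slot[length(zs_slot) + 1L] <<- s
        zs_key[length(zs_key) + 1L] <<-
          lib$keys$name[key_of(paste0(node$symbol, "#", s))]
      }
    }
    my
  }
  root_idx <- walk(tree$root)
  out_idx <- length(sizes) + 1L
  sizes[out_idx] <- 1L
  ko <- key_of("output")
  ep <- c(ep, out_idx); ek <- c(ek, ko); et <- c(et, 0L); ec <- c(ec, root_idx)
  bindings <- c(bindings, "output")
  structure(list(
    plan = list(node_sizes = sizes, edge_parent = ep, edge_key = ek,
                edge_type = et, edge_child = ec, dense = NULL),
    bindings = bindings,
    zero_slots = data.frame(node = zs_node, slot = zs_slot, key = zs_key,
                            stringsAsFactors = FALSE),
    tree = tree, grammar = g$name,
    sharing = sharing), class = "ngn_network")
}

#' @export
print.ngn_network <- function(x, ...) {
  cat("Assembled NGN for \"", x$tree$source, "\": ",
      length(x$plan$node_sizes), " node layers, ",
      length(x$plan$edge_parent), " weight-layer instantiations, ",
      nrow(x$zero_slots), " zero-flushed slots\n", sep = "")
  invisible(x)
}

#' Forward pass through an assembled network
#'
#' Computes activations child-before-parent: each internal layer applies
#' its bound weight layers to the present children's activations (absent
#' signature slots contribute zero), adds the biases, and passes the net
#' input through the logistic function, so all hidden and output
#' activations lie strictly in (0, 1).
#'
#' @param net An `ngn_network`.
#' @param lib The `ngn_library` the network was assembled against.
#' @return An object of class `ngn_forward` with elements `output` (the
#'   single output-unit activation) and `activations` (per node layer).
#' @export
ngn_feedforward <- function(net, lib) {
  stopifnot(inherits(net, "ngn_network"), inherits(lib, "ngn_library"))
  r <- cpp_forward(lib$layers, net$plan)
  structure(list(output = r$output, activations = r$activations),
            class = "ngn_forward")
}

#' Backpropagation through structure
#'
#' Starting from the output error gradient
#' \eqn{\delta = (t - o)\,o\,(1 - o)}, gradients flow from the root toward
#' the leaves; every weight-layer instantiation records its own delta
#' \eqn{\Delta w_{ij} = \eta\,\delta_i\,\alpha_j} and
#' \eqn{\Delta b_i = \eta\,\delta_i} (the learning rate is folded in here).
#' Deltas are grouped by library key but *not* yet summed, so a shared
#' layer occurring k times carries k instantiation groups.
#'
#' @param net An `ngn_network`.
#' @param lib The matching `ngn_library`.
#' @param target Target output in (0, 1).
#' @param forward The result of [ngn_feedforward()]; backpropagation
#'   requires a completed forward pass.
#' @return An `ngn_gradients` object: `output`, and `by_key`, a named list
#'   mapping each used library key to its list of per-instantiation
#'   `list(dw, db)` deltas.
#' @export
ngn_backprop <- function(net, lib, target, forward) {
  if (missing(forward) || !inherits(forward, "ngn_forward"))
    stop("backprop requires a completed forward pass: ",
         "call ngn_feedforward() first and pass its result", call. = FALSE)
  stopifnot(is.numeric(target), length(target) == 1L)
  r <- cpp_backprop(lib$layers, net$plan, target, lib$control$eta)
  keys <- lib$keys$name[r$keys]
  insts <- lapply(seq_along(r$keys), function(e)
    list(dw = r$dw[[e]], db = r$db[[e]]))
  structure(list(output = r$output,
                 by_key = split(insts, factor(keys, levels = unique(keys)))),
            class = "ngn_gradients")
}

#' Apply accumulated gradients to the shared library
#'
#' For every library key used by the exemplar, the applied change is the
#' *sum* of that key's per-instantiation deltas plus the momentum fraction
#' of the key's previous change; the momentum buffer is then replaced by
#' the applied change.  Keys absent from the exemplar's parse are left
#' completely untouched (weights, biases, and momentum buffers).
#'
#' @param lib An `ngn_library`.
#' @param grads An `ngn_gradients` object computed against `lib`.
#' @param control Training control; defaults to the library's own.
#' @return The updated `ngn_library`.
#' @export
ngn_apply_updates <- function(lib, grads, control = lib$control) {
  stopifnot(inherits(lib, "ngn_library"), inherits(grads, "ngn_gradients"))
  mom <- control$momentum
  for (key in names(grads$by_key)) {
    lay <- lib$layers[[key]]
    if (is.null(lay)) stop("gradient for unknown key '", key, "'", call. = FALSE)
    insts <- grads$by_key[[key]]
    tw <- Reduce(`+`, lapply(insts, `[[`, "dw")) + mom * lay$dw
    tb <- Reduce(`+`, lapply(insts, `[[`, "db")) + mom * lay$db
    if (!identical(dim(tw), dim(lay$w)))
      stop("shape mismatch applying update to key '", key, "'", call. = FALSE)
    lay$w <- lay$w + tw; lay$dw <- tw
    lay$b <- lay$b + tb; lay$db <- tb
    lib$layers[[key]] <- lay
  }
  lib
}

#' Predict from a weight-layer library
#'
#' Parses each string, assembles its network against the library, and runs
#' the forward pass.  The library is not modified.
#'
#' @param lib An `ngn_library`.
#' @param molecules Character vector of molecular strings.
#' @return Numeric vector of output activations in (0, 1).
#' @export
ngn_predict_raw <- function(lib, molecules) {
  stopifnot(inherits(lib, "ngn_library"))
  vapply(molecules, function(s) {
    net <- ngn_assemble(ngn_parse(s, lib$grammar), lib)
    cpp_forward(lib$layers, net$plan)$output
  }, 0, USE.NAMES = FALSE)
}

#' Fit a neural grammar network
#'
#' The main fitting function.  Each molecule's string is parsed under the
#' grammar; the resulting parse tree defines a per-molecule network wired
#' through a persistent library of weight layers bound to grammar
#' productions.  Training is online (per-exemplar) gradient descent with
#' momentum: per epoch the exemplars are reshuffled, each is
#' forward-propagated, backpropagated through its tree structure, and the
#' summed instantiation deltas are applied to the shared layers.  Training
#' converges when epoch RMSE drops below the control threshold; if the
#' epoch budget is exhausted the library is re-initialized from fresh
#' random weights, up to `max_restarts` times.
#'
#' @param molecules Character vector of molecular strings (e.g. SMILES).
#' @param targets Class labels (factor/character/logical, positive =
#'   `"pos"`, `"1"` or `TRUE`) for classification, or a numeric activity
#'   for regression.
#' @param grammar An `ngn_grammar` or built-in grammar name.
#' @param control An [ngn_control()] object.
#' @param seed Integer seed; fixes initialization and epoch shuffling, so
#'   identical inputs and seed reproduce the fit exactly.
#' @param normalize For regression, min-max scale the targets onto the
#'   output scale (the default); set `FALSE` if targets are already within
#'   `(output_lo, output_hi)`.
#' @return An object of class `"ngn"`; see [predict.ngn()], `summary()`,
#'   `coef()`, `plot()`.
#' @examples
#' \donttest{
#' set.seed(1)
#' mols <- replicate(60, ngn_sample_string(ngn_grammar("smiles_subset"), 8))
#' y <- factor(ifelse(grepl("O", mols), "pos", "neg"))
#' fit <- ngn(mols, y, control = ngn_control(max_epochs = 500), seed = 7)
#' table(predict(fit, type = "class"), y)
#' }
#' @export
ngn <- function(molecules, targets, grammar = "smiles_subset",
                control = ngn_control(), seed = 1L, normalize = TRUE) {
  cl <- match.call()
  g <- ngn_grammar(grammar)
  .validate_control(control)
  stopifnot(is.character(molecules), length(molecules) >= 1L,
            length(targets) == length(molecules))
  task <- if (is.numeric(targets)) "regression" else "classification"
  if (task == "classification") {
    y <- .as_posneg(targets)
    scaled <- ifelse(y == "pos", control$output_hi, control$output_lo)
    target_range <- NULL
  } else {
    if (normalize) {
      if (diff(range(targets)) == 0)
        stop("regression targets are constant; cannot normalize", call. = FALSE)
      target_range <- range(targets)
      scaled <- ngn_normalize(targets, control$output_lo, control$output_hi)
    } else {
      if (any(targets <= 0 | targets >= 1))
        stop("with normalize = FALSE, targets must lie strictly in (0, 1)",
             call. = FALSE)
      target_range <- NULL
      scaled <- targets
    }
    y <- targets
  }
  trees <- lapply(molecules, function(s)
    tryCatch(ngn_parse(s, g),
             error = function(e) stop("exemplar \"", s, "\" failed to parse: ",
                                      conditionMessage(e), call. = FALSE)))
  set.seed(seed)
  lib <- ngn_init_library(g, control)
  nets <- lapply(trees, ngn_assemble, lib = lib)
  plans <- lapply(nets, `[[`, "plan")
  history <- numeric(0)
  restart_at <- integer(0)
  restarts <- 0L
  repeat {
    res <- cpp_train(lib$layers, plans, scaled, control$eta, control$momentum,
                     control$rmse_threshold, control$max_epochs)
    history <- c(history, res$rmse_history)
    if (res$converged || restarts >= control$max_restarts) break
    restarts <- restarts + 1L
    restart_at <- c(restart_at, length(history))
    lib <- ngn_init_library(g, control)   # fresh draw from the RNG stream
  }
  lib$layers <- res$layers
  fitted <- vapply(plans, function(p) cpp_forward(lib$layers, p)$output, 0)
  structure(list(library = lib, grammar = g$name, control = control,
                 task = task, converged = res$converged,
                 epochs = res$epochs, restarts = restarts,
                 final_rmse = res$final_rmse,
                 rmse_history = history, restart_at = restart_at,
                 target_range = target_range,
                 molecules = molecules, y = y, targets_scaled = scaled,
                 fitted.values = fitted,
                 residuals = scaled - fitted,
                 seed = seed, call = cl),
            class = "ngn")
}

.as_posneg <- function(x) {
  if (is.logical(x)) return(ifelse(x, "pos", "neg"))
  x <- tolower(as.character(x))
  if (!all(x %in% c("pos", "neg", "1", "0", "true", "false")))
    stop("class labels must be pos/neg (or 1/0, TRUE/FALSE)", call. = FALSE)
  ifelse(x %in% c("pos", "1", "true"), "pos", "neg")
}

#' Predict method for fitted neural grammar networks
#'
#' @param object A fitted `"ngn"` object.
#' @param newdata Character vector of molecular strings; defaults to the
#'   training molecules.
#' @param type `"response"` returns the raw output activation in (0, 1);
#'   `"class"` thresholds it at the midpoint of the output scale (or
#'   `threshold`) into pos/neg; `"original"` maps it back to the original
#'   target units for normalized regression fits.
#' @param threshold Classification decision threshold; predictions at or
#'   above it are positive.
#' @param ... Unused.
#' @return Numeric vector, or factor for `type = "class"`.
#' @export
predict.ngn <- function(object, newdata = NULL,
                        type = c("response", "class", "original"),
                        threshold = NULL, ...) {
  type <- match.arg(type)
  out <- if (is.null(newdata)) object$fitted.values
         else ngn_predict_raw(object$library, newdata)
  switch(type,
    response = out,
    class = {
      thr <- if (is.null(threshold))
        (object$control$output_lo + object$control$output_hi) / 2
      else threshold
      factor(ifelse(out >= thr, "pos", "neg"), levels = c("neg", "pos"))
    },
    original = {
      if (is.null(object$target_range))
        stop("fit has no stored target range; predictions are already on ",
             "the output scale", call. = FALSE)
      lo <- object$control$output_lo; hi <- object$control$output_hi
      mn <- object$target_range[1]; mx <- object$target_range[2]
      mn + (out - lo) / (hi - lo) * (mx - mn)
    })
}

#' @export
print.ngn <- function(x, ...) {
  cat("Neural grammar network (", x$task, "), grammar '", x$grammar, "'\n",
      sep = "")
  cat("  ", length(x$molecules), " exemplars; ",
      if (x$converged) "converged" else "NOT converged", " after ",
      x$epochs, " epochs (", x$restarts, " restarts), final RMSE ",
      signif(x$final_rmse, 4), "\n", sep = "")
  invisible(x)
}

#' @export
summary.ngn <- function(object, ...) {
  ans <- list(fit = object,
              n = length(object$molecules),
              layers = object$library$keys,
              n_par = sum(vapply(object$library$layers,
                                 function(l) length(l$w) + length(l$b), 0)))
  class(ans) <- "summary.ngn"
  ans
}

#' @export
print.summary.ngn <- function(x, ...) {
  print(x$fit)
  cat("  shared weight-layer library: ", nrow(x$layers), " layers, ",
      x$n_par, " parameters\n", sep = "")
  k <- x$layers
  cat(paste0("    ", format(k$name), "  ", k$parent_size, "x", k$child_size,
             collapse = "\n"), "\n")
  invisible(x)
}

#' @export
coef.ngn <- function(object, ...) {
  lapply(object$library$layers, function(l) list(w = l$w, b = l$b))
}

#' @export
fitted.ngn <- function(object, ...) object$fitted.values

#' @export
residuals.ngn <- function(object, ...) object$residuals

#' @export
plot.ngn <- function(x, ...) {
  plot(seq_along(x$rmse_history), x$rmse_history, type = "l",
       xlab = "epoch (across restarts)", ylab = "training RMSE",
       main = "NGN training", ...)
  graphics::abline(h = x$control$rmse_threshold, lty = 2)
  if (length(x$restart_at))
    graphics::abline(v = x$restart_at + 0.5, lty = 3, col = "grey40")
  invisible(x)
}
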