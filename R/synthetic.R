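#' Sample a random string from a grammar
#'
#' Performs a stochastic leftmost derivation: at each internal symbol a
#' production is chosen uniformly among those that can still terminate
#' within the remaining depth budget (so recursion is forced to bottom out),
#' and acceptance rules emit a uniformly chosen token.  Every sampled
#' string parses under the generating grammar by construction.
#'
#' @param g An `ngn_grammar` or built-in grammar name.
#' @param max_depth Depth budget counted in internal-symbol levels; must be
#'   at least the grammar's minimal derivation depth.
#' @param seed Optional integer seed.
#' @param token_weights Optional named numeric vector of relative sampling
#'   weights for individual tokens (unnamed tokens default to 1).  An
#'   acceptance rule's selection weight is the sum of its tokens' weights,
#'   and the token within the rule is drawn with the same weights, so e.g.
#'   `c(O = 0.25)` makes oxygen atoms four times rarer than carbon.
#'   Expansion rules keep weight 1.
#' @return A single string.
#' @examples
#' ngn_sample_string("smiles_subset", max_depth = 3, seed = 1)  # "C" or "O"
#' @export
ngn_sample_string <- function(g, max_depth, seed = NULL, token_weights = NULL) {
  g <- ngn_grammar(g)
  if (!is.null(seed)) set.seed(seed)
  md <- .min_depths(g)
  rules_of <- split(g$rules, vapply(g$rules, `[[`, "", "lhs"))
  twt <- function(tok) {
    if (is.null(token_weights)) return(rep(1, length(tok)))
    w <- token_weights[tok]
    w[is.na(w)] <- 1
    unname(w)
  }
  expand <- function(sym, budget) {
    feasible <- Filter(function(r) {
      if (r$kind == "acceptance") return(budget >= 1)
      internal <- r$rhs[!r$rhs_is_token]
      budget >= 1 + max(c(0, md[internal]))
    }, rules_of[[sym]])
    if (length(feasible) == 0L)
      stop("generation error: no derivation of '", sym, "' fits within depth ",
           budget, call. = FALSE)
    rw <- vapply(feasible, function(r)
      if (r$kind == "acceptance") sum(twt(r$tokens)) else 1, 0)
    r <- feasible[[sample.int(length(feasible), 1L, prob = rw)]]
    if (r$kind == "acceptance") {
      if (length(r$tokens) == 1L) return(r$tokens)
      return(r$tokens[sample.int(length(r$tokens), 1L, prob = twt(r$tokens))])
    }
    parts <- character(length(r$rhs))
    for (j in seq_along(r$rhs)) {
      parts[j] <- if (r$rhs_is_token[j]) r$rhs[j]
                  else expand(r$rhs[j], budget - 1L)
    }
    paste(parts, collapse = "")
  }
  expand(g$start, max_depth)
}

# Minimal derivation depth of each internal symbol (acceptance = depth 1);
# inline literals cost nothing.
.min_depths <- function(g) {
  md <- stats::setNames(rep(Inf, length(g$internal)), g$internal)
  repeat {
    changed <- FALSE
    for (r in g$rules) {
      d <- if (r$kind == "acceptance") 1
           else {
             internal <- r$rhs[!r$rhs_is_token]
             1 + max(c(0, md[internal]))
           }
      if (d < md[r$lhs]) { md[r$lhs] <- d; changed <- TRUE }
    }
    if (!changed) break
  }
  md
}

#' Describe a synthetic QSAR-style task
#'
#' A task specifies how grammar-sampled strings are labeled or scored so
#' every training and evaluation stage can be exercised without external
#' datasets.  Label rules: `contains_token` (positive iff the token
#' occurs), `substring_presence` (positive iff the literal substring
#' occurs -- a topology-sensitive rule count descriptors cannot express),
#' `token_count_threshold` (positive iff the token occurs at least `k`
#' times), `scaled_token_count` (regression: the token count, plus optional
#' Gaussian noise, min-max scaled onto (0.2, 0.8)).
#'
#' @param kind `"classification"` or `"regression"`.
#' @param label_rule One of the rules above.
#' @param token Token (or substring for `substring_presence`) the rule
#'   inspects.
#' @param k Count threshold for `token_count_threshold`.
#' @param noise_sd Gaussian noise added to regression scores before
#'   normalization.
#' @param n Number of unique strings to generate.
#' @param max_depth Depth budget passed to [ngn_sample_string()].
#' @param seed Integer seed; the dataset is a deterministic function of
#'   the task.
#' @param token_weights Named sampling weights forwarded to
#'   [ngn_sample_string()].  The default down-weights heteroatom-style
#'   tokens relative to carbon (`c(O = 0.25)`), which both mirrors the
#'   carbon-dominated composition of organic molecules and keeps the
#'   token-absent class populous enough to balance classification sets.
#' @return A list of class `ngn_synth_task`.
#' @export
ngn_synth_task <- function(kind = c("classification", "regression"),
                           label_rule = c("contains_token",
                                          "substring_presence",
                                          "token_count_threshold",
                                          "scaled_token_count"),
                           token = "O", k = 2L, noise_sd = 0, n = 100L,
                           max_depth = 12L, seed = 1L,
                           token_weights = c(O = 0.25)) {
  kind <- match.arg(kind)
  label_rule <- match.arg(label_rule)
  if (kind == "regression" && label_rule != "scaled_token_count")
    stop("regression tasks use label_rule = 'scaled_token_count'",
         call. = FALSE)
  if (kind == "classification" && label_rule == "scaled_token_count")
    stop("'scaled_token_count' is a regression rule", call. = FALSE)
  stopifnot(noise_sd >= 0, n >= 2L, max_depth >= 1L)
  structure(list(kind = kind, label_rule = label_rule, token = token,
                 k = as.integer(k), noise_sd = noise_sd, n = as.integer(n),
                 max_depth = as.integer(max_depth), seed = as.integer(seed),
                 token_weights = token_weights),
            class = "ngn_synth_task")
}

.task_score <- function(task, s, g) {
  switch(task$label_rule,
    substring_presence = as.integer(grepl(task$token, s, fixed = TRUE)),
    {
      toks <- ngn_tokenize(s, g)
      sum(toks$text == task$token)
    })
}

.task_label <- function(task, score) {
  switch(task$label_rule,
    contains_token = ,
    substring_presence = if (score >= 1) "pos" else "neg",
    token_count_threshold = if (score >= task$k) "pos" else "neg",
    stop("not a classification rule"))
}

#' Generate a labeled grammar-valid dataset
#'
#' Samples unique strings from the grammar and labels or scores them per
#' the task.  Classification datasets are balanced by resampling until
#' each class holds its share of `n` (an exact 50/50 split up to
#' rounding); regression targets are the (optionally noised) scores
#' min-max scaled onto (0.2, 0.8).  Generation is deterministic given the
#' task seed, and every emitted string parses under the grammar.
#'
#' @param task An [ngn_synth_task()].
#' @param g An `ngn_grammar` or built-in grammar name.
#' @return A data frame with columns `molecule`, `score`, and `label`
#'   (classification) or `target` (regression).
#' @export
ngn_make_dataset <- function(task, g) {
  stopifnot(inherits(task, "ngn_synth_task"))
  g <- ngn_grammar(g)
  set.seed(task$seed)
  n <- task$n
  seen <- new.env(parent = emptyenv())
  max_tries <- 500L * n
  tries <- 0L
  draw <- function() {
    while (tries < max_tries) {
      tries <<- tries + 1L
      s <- ngn_sample_string(g, task$max_depth,
                             token_weights = task$token_weights)
      if (is.null(seen[[s]])) { seen[[s]] <- TRUE; return(s) }
    }
    stop("generation error: could not draw enough unique strings (",
         tries, " attempts)", call. = FALSE)
  }
  if (task$kind == "classification") {
    need_pos <- ceiling(n / 2); need_neg <- n - need_pos
    pos <- character(0); neg <- character(0)
    pos_s <- integer(0); neg_s <- integer(0)
    while (length(pos) < need_pos || length(neg) < need_neg) {
      s <- draw()
      sc <- .task_score(task, s, g)
      if (.task_label(task, sc) == "pos") {
        if (length(pos) < need_pos) { pos <- c(pos, s); pos_s <- c(pos_s, sc) }
      } else {
        if (length(neg) < need_neg) { neg <- c(neg, s); neg_s <- c(neg_s, sc) }
      }
    }
    out <- data.frame(molecule = c(pos, neg), score = c(pos_s, neg_s),
                      label = rep(c("pos", "neg"), c(need_pos, need_neg)),
                      stringsAsFactors = FALSE)
    out[sample.int(nrow(out)), , drop = FALSE]
  } else {
    mols <- character(n); score <- numeric(n)
    for (i in seq_len(n)) {
      mols[i] <- draw()
      score[i] <- .task_score(task, mols[i], g)
    }
    raw <- score + stats::rnorm(n, 0, task$noise_sd)
    if (max(raw) == min(raw))
      stop("generation error: degenerate regression scores", call. = FALSE)
    data.frame(molecule = mols, score = score,
               target = ngn_normalize(raw, 0.2, 0.8),
               stringsAsFactors = FALSE)
  }
}
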