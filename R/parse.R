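#' Tokenize a molecular string under a grammar
#'
#' Breaks the input into tokens by greedy longest-match scanning over the
#' union of all tokens the grammar accepts (acceptance-rule tokens and
#' inline literals).  Longest match is what lets two-character element
#' symbols such as `Cl` and `Br` win over `C` and `B`.
#'
#' @param s A single non-empty string.
#' @param g An `ngn_grammar` or built-in grammar name.
#' @return A data frame with one row per token: `text`, `class` (the
#'   accepting symbol, or the quoted literal), `rule` (index of the
#'   acceptance rule, `NA` for inline literals), and `pos` (0-based
#'   character offset).
#' @examples
#' ngn_tokenize("CC(C)CCO", "smiles_subset")
#' @export
ngn_tokenize <- function(s, g) {
  g <- ngn_grammar(g)
  stopifnot(is.character(s), length(s) == 1L)
  if (!nzchar(s)) stop("cannot tokenize an empty string", call. = FALSE)
  lr <- g$lr
  toks <- lr$tokens                     # sorted by decreasing length
  tlen <- nchar(toks)
  n <- nchar(s)
  out_text <- character(0); out_rule <- integer(0)
  out_term <- integer(0); out_pos <- integer(0)
  i <- 1L
  while (i <= n) {
    hit <- NA_integer_
    for (k in seq_along(toks)) {
      if (i + tlen[k] - 1L <= n &&
          substr(s, i, i + tlen[k] - 1L) == toks[k]) { hit <- k; break }
    }
    if (is.na(hit))
      stop("tokenization error in \"", s, "\": unrecognized character '",
           substr(s, i, i), "' at offset ", i - 1L, call. = FALSE)
    tk <- toks[hit]
    out_text <- c(out_text, tk)
    out_rule <- c(out_rule, lr$tok_rule[[tk]])
    out_term <- c(out_term, lr$tok_term[[tk]])
    out_pos <- c(out_pos, i - 1L)
    i <- i + tlen[hit]
  }
  cls <- ifelse(is.na(out_rule), paste0("'", out_text, "'"),
                vapply(out_rule, function(r)
                  if (is.na(r)) "" else g$rules[[r]]$lhs, ""))
  data.frame(text = out_text, class = cls, rule = out_rule,
             term = out_term, pos = out_pos, stringsAsFactors = FALSE)
}

#' Parse a molecular string into its unique parse tree
#'
#' Runs the grammar's LR(1) shift-reduce parser over the token stream.  For
#' a deterministic grammar the resulting rooted, directed, acyclic tree is
#' the string's unique structural interpretation: internal nodes record the
#' production applied, leaves carry the input tokens, and concatenating the
#' leaves left-to-right reproduces the input.
#'
#' @param s A string, or a token data frame from [ngn_tokenize()].
#' @param g An `ngn_grammar` or built-in grammar name.
#' @return An object of class `ngn_parse_tree` with elements `root`,
#'   `source` and `grammar`.
#' @examples
#' tr <- ngn_parse("CC(C)CCO", "smiles_subset")
#' ngn_derivation(tr)
#' @export
ngn_parse <- function(s, g) {
  g <- ngn_grammar(g)
  if (is.character(s)) {
    src <- s
    toks <- ngn_tokenize(s, g)
  } else {
    toks <- s
    src <- paste(toks$text, collapse = "")
  }
  lr <- g$lr
  terms <- c(toks$term, lr$eof)
  states <- integer(512); states[1L] <- 1L; sp <- 1L
  nodes <- vector("list", 512)
  i <- 1L
  root <- NULL
  repeat {
    act <- lr$action[states[sp], terms[i]]
    if (act > 0L) {                         # shift
      sp <- sp + 1L
      states[sp] <- act
      nodes[[sp]] <- list(symbol = toks$class[i], rule = NA_integer_,
                          token = toks$text[i], pos = toks$pos[i],
                          children = NULL)
      i <- i + 1L
    } else if (act < 0L) {                  # reduce / accept
      p <- lr$prods[[-act]]
      if (is.na(p$rule)) { root <- nodes[[sp]]; break }
      k <- length(p$rhs)
      rule <- g$rules[[p$rule]]
      sig <- g$signatures[[rule$lhs]]
      if (rule$kind == "acceptance") {
        leaf <- nodes[[sp]]
        node <- list(symbol = rule$lhs, rule = p$rule, token = NULL,
                     children = list(leaf),
                     slots = sig$slot_of[[as.character(p$rule)]][
                       match(leaf$token, rule$tokens)][1],
                     tok_index = match(leaf$token, sig$tok_vocab))
        node$slots <- sig$tok_slot
      } else {
        children <- nodes[seq.int(sp - k + 1L, sp)]
        node <- list(symbol = rule$lhs, rule = p$rule, token = NULL,
                     children = children,
                     slots = sig$slot_of[[as.character(p$rule)]],
                     tok_index = NA_integer_)
      }
      sp <- sp - k
      nxt <- lr$goto[states[sp], p$lhs]
      sp <- sp + 1L
      states[sp] <- nxt
      nodes[[sp]] <- node
    } else {
      where <- if (i <= nrow(toks))
        paste0("token '", toks$text[i], "' at offset ", toks$pos[i])
      else "end of input"
      stop("syntax error in \"", src, "\" at ", where, call. = FALSE)
    }
  }
  structure(list(root = root, source = src, grammar = g$name),
            class = "ngn_parse_tree")
}

#' Leftmost derivation of a parse tree
#'
#' Emits the production indices of a pre-order (leftmost) traversal of the
#' tree: the sequence of rewrite steps that derives the string from the
#' start symbol.  Replaying these steps as leftmost rewrites regenerates
#' exactly the token string.
#'
#' @param tree An `ngn_parse_tree`.
#' @return Integer vector of rule indices.
#' @export
ngn_derivation <- function(tree) {
  stopifnot(inherits(tree, "ngn_parse_tree"))
  out <- integer(0)
  walk <- function(node) {
    if (is.na(node$rule)) return(invisible())
    out[[length(out) + 1L]] <<- node$rule
    for (ch in node$children) walk(ch)
  }
  walk(tree$root)
  out
}

#' Production usage counts of a parse tree
#'
#' Counts how many times each production is applied in the tree; these are
#' exactly the numbers of instantiations of the corresponding shared weight
#' layers when the tree is assembled into a network.  The counts sum to the
#' length of [ngn_derivation()].
#'
#' @param tree An `ngn_parse_tree`.
#' @return Named integer vector (names are rule indices, ascending).
#' @examples
#' ngn_rule_counts(ngn_parse("CC(C)CCO", "smiles_subset"))
#' @export
ngn_rule_counts <- function(tree) {
  d <- ngn_derivation(tree)
  tab <- table(d)
  out <- as.integer(tab)
  names(out) <- names(tab)
  out[order(as.integer(names(out)))]
}

#' Leaf tokens of a parse tree, left to right
#'
#' @param tree An `ngn_parse_tree`.
#' @return Character vector of token texts whose concatenation is the
#'   source string.
#' @export
ngn_leaf_tokens <- function(tree) {
  stopifnot(inherits(tree, "ngn_parse_tree"))
  out <- character(0)
  walk <- function(node) {
    if (!is.null(node$token)) {
      out[[length(out) + 1L]] <<- node$token
      return(invisible())
    }
    for (ch in node$children) walk(ch)
  }
  walk(tree$root)
  out
}

#' @export
print.ngn_parse_tree <- function(x, ...) {
  d <- ngn_derivation(x)
  cat("Parse tree for \"", x$source, "\" under grammar '", x$grammar, "'\n",
      sep = "")
  cat("  ", length(d), " rule applications: ", paste(d, collapse = " "),
      "\n", sep = "")
  invisible(x)
}
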