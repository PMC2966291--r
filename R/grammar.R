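#' Deterministic context-free grammars for molecular line notations
#'
#' An `ngn_grammar` holds the four-tuple of a formal grammar: internal
#' symbols, terminal token classes, a start symbol and an ordered list of
#' production rules.  Two kinds of rule are allowed.  An *expansion* rule
#' rewrites its left-hand symbol as a sequence of internal symbols,
#' optionally interleaved with quoted literal tokens (e.g. the parenthesis
#' that opens a SMILES branch).  An *acceptance* rule rewrites its left-hand
#' symbol as exactly one input token drawn from the rule's token list.
#' Grammars must parse deterministically; see [ngn_validate_grammar()].
#'
#' @section Grammar file format:
#' One rule per line, `lhs <- rhs1 rhs2 ...`.  Unquoted right-hand names are
#' internal symbols (each must appear as a left-hand side somewhere);
#' quoted names (single quotes) are literal input tokens.  A rule whose
#' right-hand side is entirely quoted tokens is an acceptance rule accepting
#' any *one* of the listed tokens.  `#` starts a comment.  Rule indices
#' follow file order, starting at 1.
#'
#' @name ngn_grammar_objects
NULL

.rule_new <- function(index, lhs, rhs_syms, rhs_is_token) {
  all_tok <- all(rhs_is_token)
  kind <- if (all_tok) "acceptance" else "expansion"
  if (kind == "acceptance") {
    if (anyDuplicated(rhs_syms))
      stop("rule ", index, ": duplicate token in acceptance rule for '", lhs, "'",
           call. = FALSE)
    list(index = index, lhs = lhs, kind = "acceptance",
         rhs = rhs_syms, rhs_is_token = rhs_is_token,
         tokens = rhs_syms)
  } else {
    list(index = index, lhs = lhs, kind = "expansion",
         rhs = rhs_syms, rhs_is_token = rhs_is_token,
         tokens = NULL)
  }
}

#' Read a grammar from text or a file
#'
#' @param text Character vector of grammar-file lines, or a single string
#'   containing newlines.
#' @param name Identifier stored on the grammar.
#' @param allow_conflicts If `FALSE` (default), a grammar whose LR(1) parse
#'   table has shift/reduce or reduce/reduce conflicts is rejected; if
#'   `TRUE` it is accepted with a warning and conflicts are resolved by
#'   preferring shifts and the first-listed rule.
#' @return An object of class `ngn_grammar`.
#' @seealso [ngn_grammar()] for the built-in molecular grammars.
#' @examples
#' g <- ngn_read_grammar(c("s <- x", "x <- 'a' 'b'"), name = "toy")
#' length(g$rules)
#' @export
ngn_read_grammar <- function(text, name = "grammar", allow_conflicts = FALSE) {
  if (length(text) == 1L && grepl("\n", text, fixed = TRUE))
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  # strip comments, but leave '#' alone inside quoted tokens
  lines <- vapply(text, function(line) {
    chars <- strsplit(line, "", fixed = TRUE)[[1]]
    inq <- FALSE; esc <- FALSE
    for (i in seq_along(chars)) {
      ch <- chars[i]
      if (esc) { esc <- FALSE; next }
      if (ch == "\\") { esc <- TRUE; next }
      if (ch == "'") inq <- !inq
      else if (ch == "#" && !inq) return(substr(line, 1L, i - 1L))
    }
    line
  }, "", USE.NAMES = FALSE)
  keep <- which(trimws(lines) != "")
  rules <- vector("list", length(keep))
  for (k in seq_along(keep)) {
    ln <- keep[k]
    line <- trimws(lines[ln])
    m <- regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*<-\\s*(.+)$", line)
    parts <- regmatches(line, m)[[1]]
    if (length(parts) != 3L)
      stop("malformed grammar line ", ln, ": '", line, "'", call. = FALSE)
    lhs <- parts[2]
    # split rhs into quoted tokens and bare symbols
    rhs_raw <- parts[3]
    toks <- regmatches(rhs_raw,
      gregexpr("'(\\\\.|[^'\\\\])*'|[^\\s']+", rhs_raw, perl = TRUE))[[1]]
    if (length(toks) == 0L)
      stop("malformed grammar line ", ln, ": empty right-hand side", call. = FALSE)
    is_tok <- startsWith(toks, "'")
    syms <- ifelse(is_tok,
                   gsub("\\\\(.)", "\\1",
                        substr(toks, 2L, nchar(toks) - 1L)),
                   toks)
    if (any(is_tok & nchar(syms) == 0L))
      stop("malformed grammar line ", ln, ": empty token literal", call. = FALSE)
    rules[[k]] <- .rule_new(k, lhs, syms, is_tok)
  }
  if (length(rules) == 0L) stop("grammar has no rules", call. = FALSE)
  g <- .grammar_finalize(rules, name)
  rep <- ngn_validate_grammar(g)
  if (!rep$is_deterministic) {
    if (!allow_conflicts)
      stop("grammar '", name, "' is not deterministic: ",
           length(rep$conflicts), " LR(1) conflict(s); first: ",
           rep$conflicts[[1]]$description, call. = FALSE)
    warning("grammar '", name, "' has ", length(rep$conflicts),
            " LR(1) conflict(s); resolved by preferring shift / first-listed rule",
            call. = FALSE)
  }
  g
}

# Assemble and validate the grammar object from a rule list.
.grammar_finalize <- function(rules, name) {
  lhss <- vapply(rules, `[[`, "", "lhs")
  internal <- unique(lhss)
  start <- lhss[1]
  # every bare rhs symbol must be declared (appear as some lhs)
  for (r in rules) {
    bare <- r$rhs[!r$rhs_is_token]
    und <- setdiff(bare, internal)
    if (length(und))
      stop("rule ", r$index, ": undeclared symbol '", und[1], "'", call. = FALSE)
  }
  # token -> owner uniqueness: a token may appear in exactly one acceptance
  # rule, or as an inline literal (possibly in several expansion rules), but
  # not both; acceptance tokens for one lhs must not collide across rules.
  acc_tok <- list(); lit_tok <- character(0)
  for (r in rules) {
    if (r$kind == "acceptance") {
      for (tk in r$tokens) {
        if (!is.null(acc_tok[[tk]]))
          stop("token '", tk, "' accepted by both rule ",
               acc_tok[[tk]], " and rule ", r$index, call. = FALSE)
        acc_tok[[tk]] <- r$index
      }
    } else {
      lit_tok <- c(lit_tok, r$rhs[r$rhs_is_token])
    }
  }
  both <- intersect(names(acc_tok), lit_tok)
  if (length(both))
    stop("token '", both[1],
         "' used both in an acceptance rule and as an inline literal",
         call. = FALSE)
  g <- structure(list(name = name, rules = rules,
                      internal = internal, start = start),
                 class = "ngn_grammar")
  g$signatures <- .all_signatures(g)
  g$lr <- .lr_tables(g)
  g
}

#' @export
print.ngn_grammar <- function(x, ...) {
  nacc <- sum(vapply(x$rules, function(r) r$kind == "acceptance", TRUE))
  cat("Deterministic context-free grammar '", x$name, "'\n", sep = "")
  cat("  ", length(x$rules), " rules (", nacc, " acceptance), ",
      length(x$internal), " internal symbols, start symbol '",
      x$start, "'\n", sep = "")
  invisible(x)
}

#' @export
format.ngn_grammar <- function(x, ...) {
  vapply(x$rules, function(r) {
    rhs <- ifelse(r$rhs_is_token, paste0("'", r$rhs, "'"), r$rhs)
    sprintf("%-14s <- %-28s %d", r$lhs, paste(rhs, collapse = " "), r$index)
  }, "")
}

#' Serialize a grammar back to its file format
#'
#' @param g An `ngn_grammar`.
#' @return A character vector of grammar-file lines that [ngn_read_grammar()]
#'   parses back to an identical grammar.
#' @export
ngn_serialize_grammar <- function(g) {
  stopifnot(inherits(g, "ngn_grammar"))
  vapply(g$rules, function(r) {
    rhs <- ifelse(r$rhs_is_token,
                  paste0("'", gsub("('|\\\\)", "\\\\\\1", r$rhs), "'"),
                  r$rhs)
    paste(r$lhs, "<-", paste(rhs, collapse = " "))
  }, "")
}

#' Built-in molecular grammars
#'
#' Three grammars ship with the package, as plain-text grammar files under
#' `inst/grammars/`:
#' \describe{
#'   \item{`smiles_subset`}{The ten-rule teaching subset of the SMILES
#'     grammar: unbranched/branched chains over the atoms C and O.}
#'   \item{`smiles_extended`}{A practical SMILES grammar covering the
#'     organic-subset elements (and their aromatic lowercase forms), bond
#'     symbols, ring-closure digits, branches, and bracket atoms with
#'     optional isotope, chirality, hydrogen-count and charge fields.}
#'   \item{`inchi_basic`}{A simplified InChI grammar: version prefix,
#'     formula layer, and the connectivity (`/c`) and hydrogen (`/h`)
#'     layers as opaque token sequences.}
#' }
#' All three construct conflict-free LR(1) parse tables.
#'
#' @param name One of `"smiles_subset"`, `"smiles_extended"`, `"inchi_basic"`.
#' @return An `ngn_grammar`.
#' @examples
#' g <- ngn_grammar("smiles_subset")
#' print(g)
#' @export
ngn_grammar <- function(name = c("smiles_subset", "smiles_extended",
                                 "inchi_basic")) {
  if (inherits(name, "ngn_grammar")) return(name)
  name <- match.arg(name)
  cache <- .grammar_cache
  if (!is.null(cache[[name]])) return(cache[[name]])
  path <- system.file("grammars", paste0(name, ".g"), package = "ngn",
                      mustWork = TRUE)
  g <- ngn_read_grammar(readLines(path, warn = FALSE), name = name)
  cache[[name]] <- g
  g
}

.grammar_cache <- new.env(parent = emptyenv())

#' Child-slot signature of an internal symbol
#'
#' Under per-symbol-pair weight sharing, the weight layers feeding a hidden
#' layer are keyed by the parent symbol and a *slot*, the union over all of
#' the symbol's productions of right-hand positions, in order of first
#' appearance by rule index.  All acceptance rules of one symbol merge into
#' a single terminal slot whose vocabulary is the ordered union of their
#' tokens (one processing unit per token); each distinct inline literal is a
#' one-token slot.  Slots present in the signature but absent from the rule
#' applied at a given parse node are zero-flushed during the forward pass.
#'
#' @param g An `ngn_grammar`.
#' @param lhs Name of an internal symbol.
#' @return A data frame with columns `slot`, `kind`
#'   (`"internal"`/`"terminal"`/`"literal"`), `symbol`, and a list column
#'   `tokens` (the slot vocabulary, for non-internal slots).
#' @export
ngn_child_signature <- function(g, lhs) {
  g <- ngn_grammar(g)
  if (!lhs %in% g$internal)
    stop("'", lhs, "' is not an internal symbol of grammar '", g$name, "'",
         call. = FALSE)
  g$signatures[[lhs]]$table
}

# Compute signatures for every internal symbol.  For each symbol we return:
#   table    : the user-facing slot table (see ngn_child_signature)
#   slot_of  : per rule of this lhs, integer vector mapping rhs position ->
#              slot (acceptance rules: single %tok slot)
#   tok_index: per acceptance token, its index in the merged terminal slot
.all_signatures <- function(g) {
  sigs <- list()
  for (sym in g$internal) {
    rules <- Filter(function(r) r$lhs == sym, g$rules)
    keys <- character(0); kinds <- character(0); syms <- character(0)
    toks <- list()
    slot_of <- list()
    tok_index <- character(0)   # named by token -> slot index stored separately
    tok_slot <- NA_integer_
    for (r in rules) {
      if (r$kind == "acceptance") {
        if (is.na(tok_slot)) {
          keys <- c(keys, "%tok"); kinds <- c(kinds, "terminal")
          syms <- c(syms, "%tok"); toks <- c(toks, list(character(0)))
          tok_slot <- length(keys)
        }
        toks[[tok_slot]] <- c(toks[[tok_slot]], r$tokens)
        slot_of[[as.character(r$index)]] <- rep(tok_slot, length(r$tokens))
      } else {
        occ <- integer(0); names(occ) <- character(0)
        pos_slots <- integer(length(r$rhs))
        cnt <- c()
        for (j in seq_along(r$rhs)) {
          base <- if (r$rhs_is_token[j]) paste0("'", r$rhs[j], "'") else r$rhs[j]
          n_prev <- sum(names(cnt) == base)
          cnt <- c(cnt, stats::setNames(1L, base))
          key <- paste0(base, "#", n_prev + 1L)
          hit <- match(key, keys)
          if (is.na(hit)) {
            keys <- c(keys, key)
            kinds <- c(kinds, if (r$rhs_is_token[j]) "literal" else "internal")
            syms <- c(syms, r$rhs[j])
            toks <- c(toks, list(if (r$rhs_is_token[j]) r$rhs[j] else character(0)))
            hit <- length(keys)
          }
          pos_slots[j] <- hit
        }
        slot_of[[as.character(r$index)]] <- pos_slots
      }
    }
    tok_vocab <- if (!is.na(tok_slot)) toks[[tok_slot]] else character(0)
    tab <- data.frame(slot = seq_along(keys), kind = kinds, symbol = syms,
                      stringsAsFactors = FALSE)
    tab$symbol[kinds == "terminal"] <- paste0(sym, ".tokens")
    tab$tokens <- toks
    sigs[[sym]] <- list(table = tab, slot_of = slot_of,
                        tok_slot = tok_slot, tok_vocab = tok_vocab)
  }
  sigs
}

#' Check that a grammar parses deterministically
#'
#' Builds the canonical LR(1) parse tables for the grammar and reports every
#' shift/reduce and reduce/reduce conflict.  A conflict-free table means
#' every string in the language has exactly one parse tree and the
#' shift-reduce parser needs no backtracking.  (Canonical LR(1) accepts a
#' superset of the LALR(1) grammars, so a clean report here is at least as
#' strong a guarantee.)
#'
#' @param g An `ngn_grammar` or built-in grammar name.
#' @return A list of class `ngn_conflict_report` with elements
#'   `is_deterministic` (logical) and `conflicts` (list of conflict records,
#'   each with a state description and the conflicting actions).
#' @examples
#' ngn_validate_grammar(ngn_grammar("smiles_subset"))$is_deterministic
#' @export
ngn_validate_grammar <- function(g) {
  g <- if (inherits(g, "ngn_grammar")) g else ngn_grammar(g)
  lr <- if (is.null(g$lr)) .lr_tables(g) else g$lr
  structure(list(is_deterministic = length(lr$conflicts) == 0L,
                 conflicts = lr$conflicts,
                 n_states = lr$n_states),
            class = "ngn_conflict_report")
}

#' @export
print.ngn_conflict_report <- function(x, ...) {
  if (x$is_deterministic) {
    cat("Deterministic: LR(1) table (", x$n_states,
        " states) has no conflicts\n", sep = "")
  } else {
    cat("NOT deterministic: ", length(x$conflicts), " LR(1) conflict(s)\n",
        sep = "")
    for (cf in x$conflicts) cat("  - ", cf$description, "\n", sep = "")
  }
  invisible(x)
}
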