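# Canonical LR(1) table construction.
#
# The parser-level grammar is derived from the rule list: every acceptance
# rule contributes one terminal (its whole token class -- token identity
# within a class never affects the parse), every inline literal contributes
# one terminal, and expansion rules keep their shape.  Canonical LR(1)
# item-set construction then yields ACTION/GOTO tables; any shift/reduce or
# reduce/reduce collision is reported as a conflict.  No epsilon productions
# exist in this formalism, which keeps FIRST computation and closure simple.

.lr_tables <- function(g) {
  internal <- g$internal
  ni <- length(internal)
  # ---- terminals ----------------------------------------------------------
  term_label <- character(0)   # human-readable
  term_key <- character(0)     # unique key ("r<idx>" / "lit:<tok>" / "$")
  add_term <- function(key, label) {
    hit <- match(key, term_key)
    if (!is.na(hit)) return(hit)
    term_key <<- c(term_key, key)
    term_label <<- c(term_label, label)
    length(term_key)
  }
  tok_tab <- list()  # token -> list(term, rule)
  for (r in g$rules) {
    if (r$kind == "acceptance") {
      tid <- add_term(paste0("r", r$index),
                      paste0(r$lhs, ":", paste(r$tokens, collapse = "|")))
      for (tk in r$tokens) tok_tab[[tk]] <- list(term = tid, rule = r$index)
    } else {
      for (j in which(r$rhs_is_token)) {
        tk <- r$rhs[j]
        tid <- add_term(paste0("lit:", tk), paste0("'", tk, "'"))
        if (is.null(tok_tab[[tk]])) tok_tab[[tk]] <- list(term = tid, rule = NA_integer_)
      }
    }
  }
  eof <- add_term("$", "<end of input>")
  nt <- length(term_key)

  # ---- productions (symbols coded: 1..ni internal, ni+1..ni+nt terminal) --
  sym_id <- function(s) match(s, internal)
  prods <- list(list(lhs = 0L, rhs = sym_id(g$start), rule = NA_integer_))
  for (r in g$rules) {
    if (r$kind == "acceptance") {
      rhs <- ni + match(paste0("r", r$index), term_key)
    } else {
      rhs <- integer(length(r$rhs))
      for (j in seq_along(r$rhs)) {
        rhs[j] <- if (r$rhs_is_token[j])
          ni + match(paste0("lit:", r$rhs[j]), term_key)
        else sym_id(r$rhs[j])
      }
    }
    prods[[length(prods) + 1L]] <- list(lhs = sym_id(r$lhs), rhs = rhs,
                                        rule = r$index)
  }
  np <- length(prods)
  plen <- vapply(prods, function(p) length(p$rhs), 0L)
  lmax <- max(plen)
  prods_of <- vector("list", ni)
  for (pi in seq_len(np)) {
    lh <- prods[[pi]]$lhs
    if (lh > 0L) prods_of[[lh]] <- c(prods_of[[lh]], pi)
  }
  prods_of_start <- which(vapply(prods, function(p) p$lhs == 0L, TRUE))

  # ---- FIRST sets (no epsilon) -------------------------------------------
  first <- rep(list(integer(0)), ni)
  repeat {
    changed <- FALSE
    for (p in prods[-1]) {
      x <- p$rhs[1]
      fs <- if (x > ni) x - ni else first[[x]]
      cur <- first[[p$lhs]]
      nw <- union(cur, fs)
      if (length(nw) > length(cur)) { first[[p$lhs]] <- nw; changed <- TRUE }
    }
    if (!changed) break
  }

  # ---- item encoding ------------------------------------------------------
  enc <- function(p, d, a) ((p - 1L) * (lmax + 1L) + d) * nt + a
  id_space <- np * (lmax + 1L) * nt

  closure <- function(kernel) {
    seen <- logical(id_space)
    seen[kernel] <- TRUE
    work <- kernel
    while (length(work)) {
      i <- work[length(work)]; work <- work[-length(work)]
      a <- ((i - 1L) %% nt) + 1L
      rest <- (i - a) %/% nt
      d <- rest %% (lmax + 1L)
      p <- rest %/% (lmax + 1L) + 1L
      len <- plen[p]
      if (d >= len) next
      x <- prods[[p]]$rhs[d + 1L]
      if (x > ni) next
      las <- if (d + 1L < len) {
        y <- prods[[p]]$rhs[d + 2L]
        if (y > ni) y - ni else first[[y]]
      } else a
      for (q in prods_of[[x]]) {
        ids <- enc(q, 0L, las)
        new <- ids[!seen[ids]]
        if (length(new)) { seen[new] <- TRUE; work <- c(work, new) }
      }
    }
    which(seen)
  }

  # ---- canonical collection ----------------------------------------------
  kernels <- list(enc(1L, 0L, eof))
  keys <- paste(kernels[[1]], collapse = ",")
  trans <- list()   # per state: named int vector (names = symbol code)
  items_of <- list()
  s <- 0L
  while (s < length(kernels)) {
    s <- s + 1L
    items <- closure(kernels[[s]])
    items_of[[s]] <- items
    # group shiftable items by next symbol
    a <- ((items - 1L) %% nt) + 1L
    rest <- (items - a) %/% nt
    d <- rest %% (lmax + 1L)
    p <- rest %/% (lmax + 1L) + 1L
    movable <- d < plen[p]
    nxt <- integer(length(items))
    nxt[movable] <- vapply(which(movable),
                           function(k) prods[[p[k]]]$rhs[d[k] + 1L], 0L)
    tr <- integer(0)
    for (x in sort(unique(nxt[movable]))) {
      sel <- movable & nxt == x
      kern <- sort(items[sel] + nt)   # advance dot: d+1 adds nt to the code
      key <- paste(kern, collapse = ",")
      hit <- match(key, keys)
      if (is.na(hit)) {
        kernels[[length(kernels) + 1L]] <- kern
        keys <- c(keys, key)
        hit <- length(kernels)
      }
      tr[as.character(x)] <- hit
    }
    trans[[s]] <- tr
  }
  ns <- length(kernels)

  # ---- ACTION / GOTO ------------------------------------------------------
  action <- matrix(0L, ns, nt)      # >0 shift, <0 reduce (-prod), 0 error
  goto <- matrix(0L, ns, max(ni, 1L))
  conflicts <- list()
  describe <- function(act, term) {
    if (act > 0L) return("shift")
    p <- prods[[-act]]
    if (is.na(p$rule)) "accept" else paste0("reduce rule ", p$rule)
  }
  for (s in seq_len(ns)) {
    tr <- trans[[s]]
    for (xs in names(tr)) {
      x <- as.integer(xs)
      if (x > ni) action[s, x - ni] <- tr[[xs]] else goto[s, x] <- tr[[xs]]
    }
    items <- items_of[[s]]
    a <- ((items - 1L) %% nt) + 1L
    rest <- (items - a) %/% nt
    d <- rest %% (lmax + 1L)
    p <- rest %/% (lmax + 1L) + 1L
    done <- which(d == plen[p])
    for (k in done) {
      cur <- action[s, a[k]]
      new <- -p[k]
      if (cur == 0L) {
        action[s, a[k]] <- new
      } else if (cur != new) {
        conflicts[[length(conflicts) + 1L]] <- list(
          state = s, terminal = term_label[a[k]],
          actions = c(describe(cur, a[k]), describe(new, a[k])),
          description = paste0("state ", s, ", on ", term_label[a[k]], ": ",
                               describe(cur, a[k]), " vs ",
                               describe(new, a[k])))
        # resolution: keep shift; among reduces keep lower production index
        if (cur < 0L && new < 0L && -new < -cur) action[s, a[k]] <- new
      }
    }
  }

  tokens <- names(tok_tab)
  list(action = action, goto = goto,
       prods = prods, plen = plen,
       internal = internal, n_internal = ni,
       terminals = term_key, term_label = term_label, eof = eof,
       tokens = tokens[order(-nchar(tokens))],
       tok_term = vapply(tok_tab, `[[`, 0L, "term"),
       tok_rule = vapply(tok_tab, `[[`, 0L, "rule"),
       conflicts = conflicts, n_states = ns)
}
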