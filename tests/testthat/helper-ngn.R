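# Shared fixtures and independent oracles for the test suite.
# Oracles are deliberately naive re-derivations (direct formulas, exhaustive
# enumeration, finite differences) kept separate from the implementation
# paths they check.

# The ten-rule SMILES teaching subset, written out inline so grammar-file
# loading itself is under test.
subset_grammar_text <- c(
  "smiles <- chain",
  "chain <- atom",
  "chain <- atom chain",
  "chain <- atom Nbranch chain",
  "atom <- 'C'",
  "atom <- 'O'",
  "Nbranch <- branch",
  "branch <- '(' chain_rparen",
  "chain_rparen <- chain rparen",
  "rparen <- ')'")

# The printed leftmost derivation of isopentanol under the subset grammar.
isopentanol_derivation <- c(1L, 3L, 5L, 4L, 5L, 7L, 8L, 9L, 2L, 5L,
                            10L, 3L, 5L, 3L, 5L, 2L, 6L)

# --- metric oracles ---------------------------------------------------------

oracle_class_metrics <- function(tp, tn, fp, fn) {
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  list(Q = (tp + tn) / (tp + tn + fp + fn),
       SE = tp / (tp + fn),
       SP = tn / (tn + fp),
       MCC = if (den == 0) 0 else (tp * tn - fp * fn) / sqrt(den))
}

oracle_q2 <- function(preds, targets) {
  press <- sum((targets - preds)^2)
  sd <- sum((targets - mean(targets))^2)
  1 - press / sd
}

oracle_pearson <- function(x, y) {
  xm <- x - mean(x); ym <- y - mean(y)
  sum(xm * ym) / sqrt(sum(xm^2) * sum(ym^2))
}

# Exhaustive sign-pattern enumeration of the Wilcoxon signed-rank null.
oracle_wilcoxon <- function(a, b, alternative = "two.sided") {
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  all_w <- vapply(0:(2^n - 1), function(bits) {
    sum(r[bitwAnd(bits, 2^(seq_len(n) - 1)) > 0])
  }, 0)
  p_ge <- mean(all_w >= W - 1e-9)
  p_le <- mean(all_w <= W + 1e-9)
  p <- switch(alternative, greater = p_ge, less = p_le,
              two.sided = min(1, 2 * min(p_ge, p_le)))
  list(W = W, p = p)
}

# --- gradient oracle --------------------------------------------------------

# Central finite difference of eta * (-dE/dtheta), E = (target - out)^2 / 2,
# for one entry of one layer's weight matrix or bias.
fd_delta <- function(lib, net, target, key, idx, what = c("w", "b"),
                     h = 1e-5) {
  what <- match.arg(what)
  eta <- lib$control$eta
  perturbed <- function(sign) {
    l2 <- lib
    l2$layers[[key]][[what]][idx] <- l2$layers[[key]][[what]][idx] + sign * h
    out <- ngn_feedforward(net, l2)$output
    0.5 * (target - out)^2
  }
  -(perturbed(1) - perturbed(-1)) / (2 * h) * eta
}

rel_err <- function(a, b) abs(a - b) / pmax(abs(a), abs(b), 1e-8)
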