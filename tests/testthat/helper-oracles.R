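# Independent brute-force oracles. These deliberately re-derive each
# quantity from its definition and share no code with the implementation.

# Benjamini-Hochberg step-up from the definition:
# adj_(i) = min_{j >= i} min(1, n * p_(j) / j) at the sorted positions.
bhOracle <- function(p) {
  n <- length(p)
  ord <- order(p)
  raw <- n * p[ord] / seq_len(n)
  adj <- rev(cummin(rev(pmin(raw, 1))))
  out <- numeric(n)
  out[ord] <- adj
  out
}

# Squared Pearson correlation from raw sums.
r2Oracle <- function(a, b) {
  n <- length(a)
  sxy <- sum(a * b) - sum(a) * sum(b) / n
  sxx <- sum(a^2) - sum(a)^2 / n
  syy <- sum(b^2) - sum(b)^2 / n
  sxy^2 / (sxx * syy)
}

# Mann-Whitney U and its exact two-sided p by full enumeration of the
# permutation distribution (no ties assumed).
uStat <- function(x, y) sum(outer(x, y, ">"))
mwuOracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  z <- c(x, y)
  combos <- utils::combn(n1 + n2, n1)
  perm <- apply(combos, 2L, function(idx) uStat(z[idx], z[-idx]))
  u <- uStat(x, y)
  p <- if (u > n1 * n2 / 2) mean(perm >= u) else mean(perm <= u)
  list(u = u, p = min(1, 2 * p))
}

# Truth table of the two plausibility rules, written out case by case.
plausibilityOracle <- function(beta_sign, meth, expr, r_sign, or_side) {
  rule1 <- r_sign == "neg" &&
    ((meth == "High" && expr == "Low") || (meth == "Low" && expr == "High"))
  predicted <- if ((beta_sign == "+" && meth == "High") ||
                   (beta_sign == "-" && meth == "Low")) "risk" else "protective"
  rule2 <- (predicted == "risk" && or_side == "gt1") ||
    (predicted == "protective" && or_side == "lt1")
  list(rule1 = rule1, predicted = predicted, rule2 = rule2,
       overall = rule1 && rule2)
}
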