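# Five-feature worked example used throughout: raw p-values with known
# Z-values, BH adjusted p-values, BH FDR estimates and Gaussian lower bounds.
example5 <- function() c(0.005, 0.049, 0.050, 0.051, 0.700)

# Brute-force adjusted p-values straight from the defining min/max forms,
# independent of the package's cummin/cummax path.
bruteAdjust <- function(p, method, cm = NULL) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  base <- switch(method,
    BH   = function(j) ps[j] * m / j,
    BY   = function(j) ps[j] * m * (if (is.null(cm)) sum(1 / seq_len(m)) else cm) / j,
    Holm = function(j) ps[j] * (m + 1 - j),
    Hoch = function(j) ps[j] * (m + 1 - j))
  adj <- vapply(seq_len(m), function(i) {
    js <- if (method == "Holm") seq_len(i) else i:m
    v <- vapply(js, base, numeric(1))
    if (method == "Holm") max(v) else min(v)
  }, numeric(1))
  out <- numeric(m)
  out[o] <- pmin(1, adj)
  out
}
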