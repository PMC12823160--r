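# Independent oracles, deliberately coded apart from the package internals.

# Independent transcription of the published metric formulas.
oracle_metrics <- function(tp, tn, fp, fn) {
  sdiv <- function(num, den) if (den > 0) num / den else NA_real_
  list(
    TPR = sdiv(tp, tp + fn),
    TNR = sdiv(tn, fp + tn),
    FPR = sdiv(fp, fp + tn),
    FNR = sdiv(fn, fn + tp),
    PPV = sdiv(tp, tp + fp),
    NPV = sdiv(tn, tn + fn),
    FDR = sdiv(fp, fp + tp),
    FOR = sdiv(fn, fn + tn),
    ACC = sdiv(tp + tn, tp + tn + fp + fn),
    ERR = sdiv(fp + fn, tp + tn + fp + fn),
    F1  = sdiv(2 * tp, (2 * tp) + fp + fn),
    MCC = {
      den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
      if (den > 0) ((tp * tn) - (fp * fn)) / den else NA_real_
    })
}

# all permutations of a vector (recursively; fine up to length 5)
perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
  out
}

# exact QAP p-value by full enumeration of all row x column label
# permutations (3x3: 3! * 3! = 36)
enumerate_qap_p <- function(a, b, stat_fn, alternative) {
  vals <- c()
  for (pr in perms(seq_along(b$plants))) {
    for (pc in perms(seq_along(b$animals))) {
      w <- b$weights[pr, pc, drop = FALSE]
      dimnames(w) <- list(b$plants, b$animals)
      vals <- c(vals, stat_fn(a, bipartite_network(w)))
    }
  }
  obs <- stat_fn(a, b)
  if (alternative == "less") mean(vals <= obs) else mean(vals >= obs)
}
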