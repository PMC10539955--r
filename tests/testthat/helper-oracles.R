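# Independent brute-force oracles: exhaustive enumeration over isotope
# assignments (and label-site states), no convolution machinery shared with
# the package. Keep compositions tiny — the state space is the product of
# per-atom options.

enum_natural_pattern <- function(comp, isotopes, max_shift = 6L) {
  atoms <- rep(names(comp), comp)
  opts <- lapply(atoms, function(el) isotopes[[el]])
  idx <- expand.grid(lapply(opts, seq_along))
  out <- numeric(max_shift + 1L)
  for (i in seq_len(nrow(idx))) {
    ii <- as.integer(idx[i, ])
    shift <- sum(ii - 1L)
    prob <- prod(mapply(function(o, j) o[j], opts, ii))
    if (shift <= max_shift) out[shift + 1L] <- out[shift + 1L] + prob
  }
  out
}

# joint enumeration: each of n sites carries a label with probability p,
# on top of the atoms' natural isotopes
enum_labeled_pattern <- function(comp, n, p, isotopes, max_shift = 6L) {
  nat <- enum_natural_pattern(comp, isotopes, max_shift)
  out <- numeric(max_shift + 1L)
  if (n == 0) return(nat)
  states <- expand.grid(rep(list(c(0L, 1L)), n))
  for (s in seq_len(nrow(states))) {
    lab <- sum(states[s, ])
    prob <- p^lab * (1 - p)^(n - lab)
    for (k in 0:(max_shift - lab)) {
      if (k + lab <= max_shift)
        out[k + lab + 1L] <- out[k + lab + 1L] + prob * nat[k + 1L]
    }
  }
  out
}

# reference three-ion excess ratio computed from first principles
oracle_excess_ratio <- function(pattern, baseline) {
  fr <- pattern[1:3] / sum(pattern[1:3])
  bf <- baseline[1:3] / sum(baseline[1:3])
  (fr[3] - bf[3]) / (fr[2] - bf[2])
}

ref_table_path <- function() {
  system.file("extdata", "em2em1_reference.csv", package = "gngmida")
}

read_ref_table <- function() {
  read.csv(ref_table_path())
}
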