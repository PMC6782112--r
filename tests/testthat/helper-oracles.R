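# Independent brute-force oracles used to validate the statistics code.

# KS D by exhaustive evaluation of both ECDFs at every pooled sample point.
brute_force_ks_d <- function(a, b) {
  pts <- c(a, b)
  max(vapply(pts, function(t) abs(mean(a <= t) - mean(b <= t)), numeric(1)))
}

# Mann-Whitney U (ties counted 1/2) by direct pair counting.
brute_force_u <- function(a, b) {
  sum(outer(a, b, function(x, y) (x > y) + 0.5 * (x == y)))
}

# Exact two-sided Mann-Whitney p by full enumeration of all group-1 subsets
# of the pooled sample (feasible for small n). Two-sided convention: total
# probability of rank sums at least as far from the null mean as observed.
enumeration_u_p <- function(a, b) {
  n1 <- length(a)
  pooled <- c(a, b)
  r <- rank(pooled)
  idx <- utils::combn(length(pooled), n1)
  sums <- colSums(matrix(r[idx], nrow = n1))
  obs <- sum(r[seq_len(n1)])
  center <- n1 * (length(pooled) + 1) / 2
  mean(abs(sums - center) >= abs(obs - center) - 1e-9)
}

# CG dinucleotide count by a plain character scan.
brute_force_cg <- function(seq_string) {
  chars <- strsplit(toupper(seq_string), "")[[1]]
  if (length(chars) < 2) return(0L)
  sum(chars[-length(chars)] == "C" & chars[-1] == "G")
}
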