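# Small simulated trials shared across test files. Built once per test run;
# sizes kept small so the suite stays fast.

quiet_trial <- function(duration_s = 60, noise_sd_mm = 0, seed = 42, ...) {
  generate_trial(trial_config(duration_s = duration_s,
                              noise_sd_mm = noise_sd_mm, seed = seed, ...))
}

# pairwise-count Mann-Whitney U: independent of the midrank formula
u_pairwise <- function(a, b) {
  sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
}

# exact two-sided Mann-Whitney p by direct enumeration over assignments,
# using the pairwise-count U (independent of the package's rank-based path)
p_enumerate <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  mu <- n1 * length(b) / 2
  obs <- u_pairwise(a, b)
  combos <- utils::combn(length(pooled), n1)
  us <- apply(combos, 2, function(idx) u_pairwise(pooled[idx], pooled[-idx]))
  mean(abs(us - mu) >= abs(obs - mu) - 1e-9)
}

# random 3-D rigid rotation matrix
random_rotation <- function() {
  m <- matrix(rnorm(9), 3, 3)
  q <- qr.Q(qr(m))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
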