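# Independent brute-force oracles. Each re-derives its quantity from first
# principles (enumeration or the literal definition) without touching the
# package's code paths.

# two-sided rank-sum p by enumeration over all label assignments
wilcox_enum_p <- function(a, b) {
  pool <- c(a, b)
  n <- length(pool)
  na <- length(a)
  r <- rank(pool)
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  assign <- utils::combn(n, na)
  u_all <- apply(assign, 2L, function(idx)
    sum(r[idx]) - na * (na + 1) / 2)
  hi <- mean(u_all >= u_obs - 1e-9)
  lo <- mean(u_all <= u_obs + 1e-9)
  min(1, 2 * min(hi, lo))
}

# literal step-up definition: adj_(i) = min(1, min_{j >= i} m p_(j) / j)
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  po <- p[o]
  adj <- vapply(seq_len(m), function(i)
    min(1, min(m * po[i:m] / (i:m))), 0)
  out <- numeric(m)
  out[o] <- adj
  out
}

# straight-line re-implementation of the recovery classifier (scalar)
classify_oracle <- function(L, O, C, tau = 0.10, eps = 1e-6) {
  lo <- min(L, O)
  hi <- max(L, O)
  rl <- abs(C - L) / max(abs(L), eps)
  ro <- abs(C - O) / max(abs(O), eps)
  if ((C < lo || C > hi) && rl > tau && ro > tau) return("Different")
  if (abs(C - L) < abs(C - O)) return("Recovered")
  "NotRecovered"
}

# upper-tail hypergeometric probability by enumerating every draw of n
# elements from a universe of N containing K marked elements
hyper_enum_p <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  overlap <- apply(draws, 2L, function(d) sum(d <= K))
  mean(overlap >= k)
}

# textbook quadratic agglomerative complete-linkage clustering: returns the
# merge heights in merge order
complete_linkage_heights <- function(m) {
  D <- as.matrix(stats::dist(m))
  diag(D) <- Inf
  heights <- numeric(0)
  while (nrow(D) > 1L) {
    ij <- which(D == min(D), arr.ind = TRUE)[1L, ]
    i <- min(ij); j <- max(ij)
    heights <- c(heights, D[i, j])
    merged <- pmax(D[i, ], D[j, ])      # complete linkage update
    D[i, ] <- merged
    D[, i] <- merged
    D[i, i] <- Inf
    D <- D[-j, -j, drop = FALSE]
  }
  heights
}
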