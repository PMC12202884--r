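# Independent brute-force oracles for the clustering-agreement metrics.
# Everything here works from first principles (item-pair enumeration and
# direct probability sums) and shares no code with the package internals.

# Pair counts by O(n^2) enumeration over all item pairs.
oracle_pair_counts <- function(u, v) {
  n <- length(u)
  ss <- sd_ <- ds <- dd <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    same_u <- u[i] == u[j]
    same_v <- v[i] == v[j]
    if (same_u && same_v) ss <- ss + 1
    else if (same_u) sd_ <- sd_ + 1
    else if (same_v) ds <- ds + 1
    else dd <- dd + 1
  }
  c(ss = ss, sd = sd_, ds = ds, dd = dd)
}

oracle_ari <- function(u, v) {
  pc <- oracle_pair_counts(u, v)
  a <- pc["ss"]; b <- pc["sd"]; c_ <- pc["ds"]; d <- pc["dd"]
  num <- 2 * (a * d - b * c_)
  den <- (a + b) * (b + d) + (a + c_) * (c_ + d)
  if (den == 0) return(1)
  unname(num / den)
}

oracle_fmi <- function(u, v) {
  pc <- oracle_pair_counts(u, v)
  tp <- pc["ss"]; fp <- pc["ds"]; fn <- pc["sd"]
  if (tp == 0) return(0)
  unname(tp / sqrt((tp + fp) * (tp + fn)))
}

oracle_entropy <- function(u) {
  p <- as.vector(table(u)) / length(u)
  -sum(p * log(p))
}

oracle_mi <- function(u, v) {
  n <- length(u)
  s <- 0
  for (cu in unique(u)) for (cv in unique(v)) {
    nij <- sum(u == cu & v == cv)
    if (nij > 0)
      s <- s + nij / n * log(nij * n / (sum(u == cu) * sum(v == cv)))
  }
  s
}

# Expected MI under the permutation model via dhyper (stats' hypergeometric
# density), an independent route from the package's log-factorial sum.
oracle_emi <- function(u, v) {
  n <- length(u)
  a <- as.vector(table(u)); b <- as.vector(table(v))
  s <- 0
  for (ai in a) for (bj in b) {
    for (nij in max(1, ai + bj - n):min(ai, bj)) {
      if (nij < 1) next
      s <- s + nij / n * log(n * nij / (ai * bj)) *
        stats::dhyper(nij, ai, n - ai, bj)
    }
  }
  s
}

oracle_ami <- function(u, v) {
  hu <- oracle_entropy(u); hv <- oracle_entropy(v)
  if (hu == 0 && hv == 0) return(1)
  emi <- oracle_emi(u, v)
  den <- max(hu, hv) - emi
  if (den == 0) return(1)
  (oracle_mi(u, v) - emi) / den
}

oracle_nmi <- function(u, v) {
  hu <- oracle_entropy(u); hv <- oracle_entropy(v)
  if (hu == 0 && hv == 0) return(1)
  if (hu == 0 || hv == 0) return(0)
  oracle_mi(u, v) / sqrt(hu * hv)
}

# Moving-average oracle with shrunken edge windows.
oracle_moving_average <- function(x, window) {
  h <- (window - 1) / 2
  n <- length(x)
  sapply(seq_len(n), function(i) mean(x[max(1, i - h):min(n, i + h)]))
}

# Write a small background edge file and return its path.
write_toy_links <- function(lines) {
  f <- tempfile(fileext = ".txt")
  writeLines(lines, f)
  f
}
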