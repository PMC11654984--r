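# Independent brute-force oracles for the partition-agreement metrics, built
# from explicit pair counting and scalar-loop formulas (deliberately written
# differently from the package implementations).

# All set partitions of n elements as label vectors (restricted growth strings).
all_partitions <- function(n) {
  out <- list()
  recurse <- function(labels, next_max) {
    k <- length(labels)
    if (k == n) { out[[length(out) + 1]] <<- labels; return(invisible()) }
    for (v in seq_len(next_max + 1))
      recurse(c(labels, v), max(next_max, v))
  }
  recurse(integer(0), 0)
  out
}

# ARI by exhaustive pair enumeration (N1..N4 counts -> standard adjusted form).
oracle_ari <- function(p, t) {
  n <- length(p)
  n1 <- n2 <- n3 <- n4 <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sp <- p[i] == p[j]; st <- t[i] == t[j]
    if (sp && st) n1 <- n1 + 1
    else if (!sp && !st) n2 <- n2 + 1
    else if (sp && !st) n3 <- n3 + 1
    else n4 <- n4 + 1
  }
  tot <- choose(n, 2)
  a <- n1 + n3   # same-cluster pairs in P
  b <- n1 + n4   # same-cluster pairs in T
  exp_idx <- a * b / tot
  denom <- (a + b) / 2 - exp_idx
  if (denom == 0) return(1)
  (n1 - exp_idx) / denom
}

oracle_entropy <- function(x) {
  h <- 0
  n <- length(x)
  for (g in unique(x)) {
    pr <- sum(x == g) / n
    h <- h - pr * log(pr)
  }
  h
}

oracle_mi <- function(p, t) {
  n <- length(p)
  mi <- 0
  for (a in unique(p)) for (b in unique(t)) {
    nij <- sum(p == a & t == b)
    if (nij == 0) next
    mi <- mi + nij / n * log(n * nij / (sum(p == a) * sum(t == b)))
  }
  mi
}

oracle_nmi <- function(p, t) {
  hp <- oracle_entropy(p); ht <- oracle_entropy(t)
  if (hp == 0 && ht == 0) return(1)
  if (hp == 0 || ht == 0) return(0)
  oracle_mi(p, t) / max(hp, ht)
}

# Exact expected MI via scalar loops and prod()-based hypergeometric weights.
oracle_emi <- function(p, t) {
  n <- length(p)
  a <- as.vector(table(p)); b <- as.vector(table(t))
  emi <- 0
  for (ai in a) for (bj in b) {
    for (nij in max(1, ai + bj - n):min(ai, bj)) {
      if (nij < 1) next
      w <- exp(lchoose(bj, nij) + lchoose(n - bj, ai - nij) - lchoose(n, ai))
      emi <- emi + nij / n * log(n * nij / (ai * bj)) * w
    }
  }
  emi
}

oracle_ami <- function(p, t) {
  hp <- oracle_entropy(p); ht <- oracle_entropy(t)
  if (hp == 0 && ht == 0) return(1)
  if (hp == 0 || ht == 0) return(0)
  emi <- oracle_emi(p, t)
  denom <- max(hp, ht) - emi
  if (abs(denom) < .Machine$double.eps) return(0)
  (oracle_mi(p, t) - emi) / denom
}

# Exact Shapley values by exhaustive subset enumeration for a model f over d
# features, with a single background row b.
oracle_shapley <- function(f, x, b) {
  d <- length(x)
  phi <- numeric(d)
  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), d))
  val <- function(mask) {
    row <- b; row[mask] <- x[mask]
    f(matrix(row, 1))
  }
  for (j in seq_len(d)) {
    for (si in seq_len(nrow(subsets))) {
      s <- unlist(subsets[si, ])
      if (s[j]) next
      k <- sum(s)
      w <- factorial(k) * factorial(d - k - 1) / factorial(d)
      s_with <- s; s_with[j] <- TRUE
      phi[j] <- phi[j] + w * (val(s_with) - val(s))
    }
  }
  phi
}
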