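# Independent oracles used across the suite. Each is written from the
# defining formula, not by calling the package code it checks.

# all n! permutations, built iteratively (insertion construction) so it
# does not share code with the package's recursive generator
oraclePerms <- function(n) {
  out <- matrix(1L, 1, 1)
  for (m in 2:n) {
    new <- vector("list", m)
    for (pos in 1:m) {
      block <- matrix(0L, nrow(out), m)
      block[, pos] <- m
      block[, -pos] <- out
      new[[pos]] <- block
    }
    out <- do.call(rbind, new)
  }
  out
}

# exact two-sided Spearman (rho, p) by full enumeration
oracleSpearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  rho <- cor(rx, ry)
  P <- oraclePerms(length(x))
  rhos <- apply(P, 1, function(p) cor(rx, ry[p]))
  list(rho = rho, p = mean(abs(rhos) >= abs(rho) - 1e-12))
}

# hypergeometric tails by direct summation of choose() products
oracleHyperTails <- function(k, K, n, N) {
  pmf <- function(i) choose(K, i) * choose(N - K, n - i) / choose(N, n)
  sup <- max(0, n - (N - K)):min(n, K)
  list(p_over = sum(vapply(sup[sup >= k], pmf, numeric(1))),
       p_under = sum(vapply(sup[sup <= k], pmf, numeric(1))))
}

# TOM by the defining triple loop
oracleTOM <- function(A) {
  n <- nrow(A)
  tom <- diag(n)
  k <- sapply(1:n, function(i) sum(A[i, -i]))
  for (i in 1:n) for (j in 1:n) if (i != j) {
    L <- 0
    for (u in 1:n) if (u != i && u != j) L <- L + A[i, u] * A[u, j]
    tom[i, j] <- (L + A[i, j]) / (min(k[i], k[j]) + 1 - A[i, j])
  }
  tom
}

# leading principal component of row-standardized data by power iteration
oraclePC1 <- function(x) {
  xs <- t(scale(t(x)))
  C <- crossprod(xs)           # sample x sample
  v <- rep(1, ncol(xs)) / sqrt(ncol(xs))
  for (i in 1:2000) {
    v2 <- C %*% v
    v2 <- v2 / sqrt(sum(v2^2))
    if (max(abs(v2 - v)) < 1e-13) break
    v <- v2
  }
  as.numeric(v)
}

# single-component PLS weights/VIP by the NIPALS iteration
oracleNipalsVIP <- function(X, y) {
  X <- scale(X)
  u <- y - mean(y)
  w <- rep(1, ncol(X)) / sqrt(ncol(X))
  for (i in 1:500) {
    w2 <- as.numeric(crossprod(X, u))
    w2 <- w2 / sqrt(sum(w2^2))
    tt <- as.numeric(X %*% w2)
    u <- u  # univariate y: u is fixed
    if (max(abs(w2 - w)) < 1e-12) { w <- w2; break }
    w <- w2
  }
  sqrt(ncol(X)) * abs(w)
}

# adjusted Rand index from the contingency-table formula
oracleARI <- function(a, b) {
  tab <- table(a, b)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  exp <- si * sj / n2
  (sij - exp) / ((si + sj) / 2 - exp)
}

# small StageExperiment with chosen stage-mean log2 profiles
makeExpr <- function(profiles, reps = 3, noiseSd = 0, seed = 1,
                     stages = 6) {
  set.seed(seed)
  st <- rep(seq_len(stages), each = reps)
  m <- 2^(profiles[, st, drop = FALSE] +
            matrix(rnorm(nrow(profiles) * length(st), 0, noiseSd),
                   nrow(profiles)))
  rownames(m) <- rownames(profiles)
  StageExperiment(m, st, assayName = "fpkm")
}

# strip types/attributes for truth JSON round-trip comparison:
# lists of atomic scalars collapse to vectors, integers to doubles
normalizeTruth <- function(x) {
  if (is.list(x)) {
    scalar <- length(x) > 0 &&
      all(vapply(x, function(e) is.atomic(e) && length(e) == 1,
                 logical(1)))
    if (scalar && length(unique(vapply(x, typeof, character(1)))) == 1) {
      v <- unlist(x)
      if (is.numeric(v)) storage.mode(v) <- "double"
      return(v)
    }
    return(lapply(x, normalizeTruth))
  }
  if (is.numeric(x)) storage.mode(x) <- "double"
  x
}
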