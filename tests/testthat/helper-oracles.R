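# shared fixtures and independent oracles for the test suite

# small genotype matrix builder
toy_geno <- function(counts, chrom = NULL, pos = NULL) {
  counts <- as.matrix(counts)
  m <- ncol(counts)
  map <- data.frame(id = sprintf("m%d", seq_len(m)),
                    chrom = chrom %||% rep("chr1", m),
                    pos = pos %||% seq(0, by = 1000, length.out = m),
                    ref = rep("A", m), alt = rep("G", m),
                    stringsAsFactors = FALSE)
  gainscan::genotype_matrix(counts, map)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force all-pairs interval overlap count (half-open)
naive_overlap <- function(fixed, query) {
  cnt <- 0L
  for (i in seq_len(nrow(query))) {
    hit <- FALSE
    for (j in seq_len(nrow(fixed))) {
      if (query$chrom[i] == fixed$chrom[j] &&
          query$start[i] < fixed$end[j] &&
          query$end[i] > fixed$start[j]) hit <- TRUE
    }
    cnt <- cnt + hit
  }
  cnt
}

random_regions <- function(k, chroms = c("c1", "c2"), max_pos = 100,
                           max_len = 30) {
  s <- sample(0:max_pos, k, replace = TRUE)
  gainscan::region_set(sample(chroms, k, replace = TRUE), s,
                       s + sample(seq_len(max_len), k, replace = TRUE))
}

# independent oracle for the Gaussian marginal likelihood under the
# normal-Wishart prior: sequential posterior-predictive Student-t
# decomposition (one multivariate-t density per observation)
lmvt_density <- function(x, mu, S, df) {
  d <- length(x)
  q <- as.numeric(t(x - mu) %*% solve(S) %*% (x - mu))
  lgamma((df + d) / 2) - lgamma(df / 2) - d / 2 * log(df * pi) -
    0.5 * determinant(S)$modulus[1] - (df + d) / 2 * log1p(q / df)
}

sequential_ml_oracle <- function(X, idx, aw, am = 1) {
  d <- length(idx)
  nv <- ncol(X)
  df0 <- aw - nv + d
  t0 <- am * (aw - nv - 1) / (am + 1)
  kap <- am; nu <- df0; mu <- rep(0, d); Lam <- diag(t0, d)
  ll <- 0
  for (i in seq_len(nrow(X))) {
    x <- X[i, idx]
    Sc <- Lam * (kap + 1) / (kap * (nu - d + 1))
    ll <- ll + lmvt_density(x, mu, Sc, nu - d + 1)
    mun <- (kap * mu + x) / (kap + 1)
    Lam <- Lam + kap / (kap + 1) * tcrossprod(x - mu)
    mu <- mun; kap <- kap + 1; nu <- nu + 1
  }
  ll
}

# Markov-equivalence class signature: skeleton + v-structures
cpdag_signature <- function(amat) {
  und <- amat | t(amat)
  skel <- which(und & upper.tri(und), arr.ind = TRUE)
  vs <- character(0)
  n <- nrow(amat)
  for (c in seq_len(n)) {
    pa <- which(amat[, c])
    if (length(pa) >= 2) {
      for (a in pa) for (b in pa) {
        if (a < b && !und[a, b]) vs <- c(vs, paste(a, b, c))
      }
    }
  }
  paste(paste(skel[, 1], skel[, 2], collapse = ";"),
        paste(sort(vs), collapse = ";"), sep = "|")
}

# enumerate every DAG on `n` nodes as a list of adjacency matrices
enumerate_dags <- function(n) {
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  np <- nrow(pairs)
  out <- list()
  # each unordered pair is absent, forward, or backward: 3^np graphs
  for (code in 0:(3^np - 1)) {
    amat <- matrix(FALSE, n, n)
    c0 <- code
    for (k in seq_len(np)) {
      st <- c0 %% 3
      c0 <- c0 %/% 3
      if (st == 1) amat[pairs[k, 1], pairs[k, 2]] <- TRUE
      if (st == 2) amat[pairs[k, 2], pairs[k, 1]] <- TRUE
    }
    if (gainscan:::.is_acyclic(amat)) out[[length(out) + 1]] <- amat
  }
  out
}
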