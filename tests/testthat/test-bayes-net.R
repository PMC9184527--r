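test_that("BGe score is decomposable and matches the predictive-t oracle", {
  set.seed(42)
  n <- 10
  X <- scale(matrix(rnorm(3 * n), n, 3))
  colnames(X) <- c("A", "B", "C")
  full <- dag_model(c("A", "B", "C"),
                    rbind(c("A", "B"), c("A", "C"), c("B", "C")))
  s <- bge_score(full, X, iss = 5)
  expect_equal(as.numeric(s), sum(attr(s, "family_scores")),
               tolerance = 1e-10)
  # the saturated-DAG score is the joint marginal likelihood: compare with
  # the sequential normal-Wishart posterior-predictive decomposition
  expect_equal(as.numeric(s), sequential_ml_oracle(X, 1:3, aw = 5),
               tolerance = 1e-9)
  # and a non-saturated family: chain A -> B, marginals telescope
  chain <- dag_model(c("A", "B"), rbind(c("A", "B")))
  s2 <- bge_score(chain, X[, 1:2], iss = 4)
  expect_equal(as.numeric(s2), sequential_ml_oracle(X[, 1:2], 1:2, aw = 4),
               tolerance = 1e-9)
})

test_that("two-node score is identical in both orientations", {
  set.seed(1)
  X <- scale(matrix(rnorm(60), 30, 2)); colnames(X) <- c("A", "B")
  X[, 2] <- scale(0.5 * X[, 1] + rnorm(30, 0, 0.5))
  ab <- bge_score(dag_model(c("A", "B"), rbind(c("A", "B"))), X)
  ba <- bge_score(dag_model(c("A", "B"), rbind(c("B", "A"))), X)
  expect_equal(as.numeric(ab), as.numeric(ba), tolerance = 1e-12)
})

test_that("BGe is constant on every Markov-equivalence class of 4-node DAGs", {
  set.seed(7)
  n <- 30
  Z <- matrix(rnorm(4 * n), n, 4)
  Z[, 2] <- 0.6 * Z[, 1] + rnorm(n, 0, 0.8)
  Z[, 4] <- 0.5 * Z[, 2] - 0.4 * Z[, 3] + rnorm(n, 0, 0.7)
  X <- scale(Z)
  colnames(X) <- c("A", "B", "C", "D")
  dags <- enumerate_dags(4)
  expect_equal(length(dags), 543L)             # known DAG count on 4 nodes
  scores <- numeric(length(dags))
  sigs <- character(length(dags))
  for (k in seq_along(dags)) {
    amat <- dags[[k]]
    dimnames(amat) <- list(colnames(X), colnames(X))
    arcs <- which(amat, arr.ind = TRUE)
    d <- dag_model(colnames(X),
                   if (nrow(arcs)) cbind(colnames(X)[arcs[, 1]],
                                         colnames(X)[arcs[, 2]]) else NULL)
    scores[k] <- bge_score(d, X)
    sigs[k] <- cpdag_signature(amat)
  }
  spread <- tapply(scores, sigs, function(s) max(s) - min(s))
  expect_lt(max(spread), 1e-10)
  # sanity: different classes have genuinely different scores
  expect_gt(length(unique(round(tapply(scores, sigs, mean), 6))), 10)
})

test_that("structural constraints are always respected by the search", {
  set.seed(9)
  nodes <- c("A", "B", "C", "D")
  bl <- rbind(c("B", "A"), c("C", "A"), c("D", "A"), c("D", "B"))
  for (rep in 1:100) {
    X <- scale(matrix(rnorm(4 * 40), 40, 4))
    colnames(X) <- nodes
    dag <- learn_structure(X, blacklist = bl)
    expect_false(any(dag$amat[bl]))
  }
  wl <- rbind(c("A", "B"))
  X <- scale(matrix(rnorm(4 * 40), 40, 4)); colnames(X) <- nodes
  dagw <- learn_structure(X, whitelist = wl)
  expect_true(dagw$amat["A", "B"])
  expect_error(learn_structure(X, blacklist = wl, whitelist = wl),
               "blacklisted")
})

test_that("a planted chain is recovered at high signal-to-noise", {
  set.seed(13)
  n <- 500
  year <- rnorm(n)
  veg <- 0.9 * year + rnorm(n, 0, 0.3)
  gn <- 0.9 * veg + rnorm(n, 0, 0.3)
  X <- scale(cbind(year = year, veg = veg, gn = gn))
  bl <- year_trait_blacklist(colnames(X), year = "year", gn = "gn",
                             pre_gn = "veg")
  dag <- learn_structure(X, blacklist = bl)
  expect_true(dag$amat["year", "veg"])
  expect_true(dag$amat["veg", "gn"])
  expect_equal(sum(dag$amat), 2)
  empty <- bge_score(dag_model(colnames(X)), X)
  expect_gte(dag$score, as.numeric(empty))
})

test_that("whitelisting the generating arcs never lowers the score", {
  set.seed(17)
  n <- 200
  a <- rnorm(n); b <- 0.7 * a + rnorm(n, 0, 0.6)
  cc <- 0.6 * b + rnorm(n, 0, 0.6)
  X <- scale(cbind(A = a, B = b, C = cc))
  free <- learn_structure(X)
  forced <- learn_structure(X, whitelist = rbind(c("A", "B"), c("B", "C")))
  expect_gte(forced$score, free$score - 1e-9)
})

test_that("bootstrap strengths are symmetric, oriented, and reproducible", {
  set.seed(23)
  n <- 80
  a <- rnorm(n); b <- a                        # deterministic copy
  cc <- rnorm(n)
  X <- cbind(A = a, B = b + rnorm(n, 0, 1e-8), C = cc)
  avg <- bootstrap_average(X, B = 50, seed = 5)
  st <- avg$strengths
  key <- function(f, t) st$strength[st$from == f & st$to == t]
  dir <- function(f, t) st$direction[st$from == f & st$to == t]
  expect_equal(key("A", "B"), key("B", "A"))
  expect_equal(key("A", "B"), 1)               # noiseless arc always found
  for (p in list(c("A", "B"), c("A", "C"), c("B", "C"))) {
    if (key(p[1], p[2]) > 0) {
      expect_equal(dir(p[1], p[2]) + dir(p[2], p[1]), 1)
    }
  }
  avg2 <- bootstrap_average(X, B = 50, seed = 5)
  expect_identical(avg$strengths, avg2$strengths)
  avg3 <- bootstrap_average(X, B = 50, seed = 6)
  expect_false(identical(avg$strengths$strength, avg3$strengths$strength))
})

test_that("independent variables yield an empty averaged network", {
  set.seed(30)
  X <- matrix(rnorm(200 * 4), 200, 4)
  colnames(X) <- c("A", "B", "C", "D")
  # premise check: the draw must actually be independent in-sample
  cc <- cor(X); diag(cc) <- 0
  expect_lt(max(abs(cc)), 0.14)
  avg <- bootstrap_average(X, B = 100, seed = 7)
  expect_equal(sum(avg$dag$amat), 0)
})

test_that("cross-validated correlations separate functional and noise nodes", {
  set.seed(31)
  n <- 100
  a <- rnorm(n)
  b <- 2 * a                                   # noiseless child
  nz <- rnorm(n)                               # pure noise
  X <- cbind(A = a, B = b, N = nz)
  dag <- dag_model(c("A", "B", "N"), rbind(c("A", "B"), c("A", "N")))
  cv <- cv_predict(dag, X, folds = 5, repeats = 3, seed = 11)
  expect_true(is.na(cv["A"]))                  # root: no parents
  expect_gt(cv["B"], 0.999)
  expect_lt(abs(cv["N"]), 2 / sqrt(n))
})

test_that("consensus keeps only arcs shared by all scenario networks", {
  d1 <- dag_model(c("A", "B", "C"), rbind(c("A", "B"), c("B", "C")))
  d2 <- dag_model(c("A", "B", "C"), rbind(c("A", "B")))
  cons <- consensus_network(list(d1, d2))
  expect_true(cons$amat["A", "B"])
  expect_equal(sum(cons$amat), 1)
})
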