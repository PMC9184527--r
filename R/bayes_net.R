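## Constrained Gaussian Bayesian networks over year-of-release, traits and
## grain number: BGe scoring, tabu structure search, bootstrap arc
## averaging, cross-validated prediction.

#' Directed acyclic graph model
#'
#' @param nodes character vector of node names.
#' @param arcs two-column matrix/data frame of directed arcs (from, to);
#'   may have zero rows.
#' @return Object of class `dag_model` with a logical adjacency matrix
#'   `amat` (`amat[i, j]` is the arc i -> j).
#' @export
dag_model <- function(nodes, arcs = NULL) {
  .assert(!anyDuplicated(nodes), "node names must be unique")
  amat <- matrix(FALSE, length(nodes), length(nodes),
                 dimnames = list(nodes, nodes))
  if (!is.null(arcs) && NROW(arcs) > 0) {
    arcs <- as.matrix(arcs)
    .assert(ncol(arcs) == 2, "arcs need two columns (from, to)")
    .assert(all(arcs %in% nodes), "arc endpoint not in node set")
    amat[arcs] <- TRUE
    .assert(!any(diag(amat)), "self-loops are not allowed")
  }
  dag <- structure(list(nodes = nodes, amat = amat), class = "dag_model")
  .assert(.is_acyclic(amat), "arc set contains a cycle")
  dag
}

.is_acyclic <- function(amat) {
  # repeated leaf-stripping (Kahn); TRUE iff all nodes removable
  m <- amat
  repeat {
    sinks <- which(rowSums(m) == 0 & colSums(m) >= 0 & !is.na(diag(m)))
    alive <- which(!is.na(diag(m)))
    if (length(alive) == 0) return(TRUE)
    out_deg <- rowSums(m, na.rm = TRUE)
    removable <- alive[out_deg[alive] == 0]
    if (length(removable) == 0) return(FALSE)
    m[removable, ] <- NA
    m[, removable] <- NA
    diag(m)[removable] <- NA
  }
}

.has_path <- function(amat, from, to) {
  # DFS: is there a directed path from -> to?
  seen <- rep(FALSE, nrow(amat))
  stack <- from
  while (length(stack)) {
    v <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    if (v == to) return(TRUE)
    if (seen[v]) next
    seen[v] <- TRUE
    stack <- c(stack, which(amat[v, ]))
  }
  FALSE
}

#' @export
print.dag_model <- function(x, ...) {
  arcs <- which(x$amat, arr.ind = TRUE)
  cat(sprintf("dag_model: %d nodes, %d arcs\n", length(x$nodes), nrow(arcs)))
  if (nrow(arcs)) {
    cat(paste(sprintf("  %s -> %s", x$nodes[arcs[, 1]], x$nodes[arcs[, 2]]),
              collapse = "\n"), "\n")
  }
  invisible(x)
}

## log multivariate gamma
.lmgamma <- function(a, d) {
  d * (d - 1) / 4 * log(pi) + sum(lgamma(a + (1 - seq_len(d)) / 2))
}

## BGe scoring engine. Normal-Wishart prior with zero mean vector,
## scale T = t * I where t = am * (aw - nvars - 1) / (am + 1), Wishart
## degrees of freedom aw (the imaginary sample size), mean precision am.
## The marginal likelihood of the columns in subset A (size d) is
##   pi^(-nd/2) (am/(am+n))^(d/2) Gamma_d((df+n)/2)/Gamma_d(df/2)
##     |T_A|^(df/2) |R_A|^(-(df+n)/2),   df = aw - nvars + d,
## with R_A = T_A + S_A + am n/(am+n) xbar_A xbar_A'.
.bge_engine <- function(data, iss, alpha_mu = 1) {
  X <- as.matrix(data)
  n <- nrow(X); nv <- ncol(X)
  .assert(iss > nv, "iss must exceed the number of variables")
  aw <- iss; am <- alpha_mu
  t0 <- am * (aw - nv - 1) / (am + 1)
  xbar <- colMeans(X)
  S <- crossprod(sweep(X, 2, xbar))
  Rfull <- diag(t0, nv) + S + (am * n / (am + n)) * tcrossprod(xbar)
  cache <- new.env(parent = emptyenv())
  subset_ml <- function(idx) {
    d <- length(idx)
    if (d == 0) return(0)
    key <- paste(sort(idx), collapse = ",")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    df <- aw - nv + d
    R <- Rfull[idx, idx, drop = FALSE]
    ch <- tryCatch(chol(R), error = function(e) NULL)
    .assert(!is.null(ch), "singular posterior matrix for variable set {%s}",
            paste(colnames(X)[idx], collapse = ", "))
    logdetR <- 2 * sum(log(diag(ch)))
    val <- -n * d / 2 * log(pi) + d / 2 * (log(am) - log(am + n)) +
      .lmgamma((df + n) / 2, d) - .lmgamma(df / 2, d) +
      df / 2 * d * log(t0) - (df + n) / 2 * logdetR
    cache[[key]] <- val
    val
  }
  family_score <- function(node, parents) {
    subset_ml(c(node, parents)) - subset_ml(parents)
  }
  list(family_score = family_score, n = n, nv = nv,
       nodes = colnames(X))
}

#' BGe score of a DAG on standardised Gaussian data
#'
#' Log marginal likelihood of the data under the DAG with a
#' normal-Wishart prior (zero prior mean, identity prior scale scaled to
#' the standard minimal-information choice, Wishart imaginary sample size
#' `iss`). The score decomposes into per-node family scores and is equal
#' across Markov-equivalent DAGs.
#'
#' @param dag a [dag_model()].
#' @param data numeric data frame/matrix; columns should be centred and
#'   scaled (see [scale()]).
#' @param iss imaginary sample size of the Wishart prior
#'   (default `ncol(data) + 2`).
#' @param alpha_mu precision of the prior mean (default 1).
#' @return Total score; attribute `family_scores` gives the per-node
#'   decomposition.
#' @export
bge_score <- function(dag, data, iss = ncol(data) + 2, alpha_mu = 1) {
  stopifnot(inherits(dag, "dag_model"))
  .assert(!anyNA(data), "data must be complete")
  .assert(identical(sort(dag$nodes), sort(colnames(as.matrix(data)))),
          "dag nodes must match data columns")
  X <- as.matrix(data)[, dag$nodes, drop = FALSE]
  eng <- .bge_engine(X, iss = iss, alpha_mu = alpha_mu)
  fams <- vapply(seq_along(dag$nodes), function(j) {
    eng$family_score(j, which(dag$amat[, j]))
  }, numeric(1))
  names(fams) <- dag$nodes
  structure(sum(fams), family_scores = fams)
}

.norm_constraint <- function(x, nodes) {
  if (is.null(x) || NROW(x) == 0) {
    return(matrix(integer(), 0, 2))
  }
  m <- as.matrix(x)
  .assert(ncol(m) == 2, "constraint lists need two columns (from, to)")
  .assert(all(m %in% nodes), "constraint endpoint not in node set")
  cbind(match(m[, 1], nodes), match(m[, 2], nodes))
}

#' Constrained structure learning by tabu search with the BGe score
#'
#' Greedy add/delete/reverse search with a tabu list over recent moves,
#' deterministic lexicographic tie-breaking, and hard structural
#' constraints: blacklisted arcs never appear, whitelisted arcs are always
#' present. For era-panel trait analysis the canonical blacklist forbids
#' all arcs into year-of-release and all arcs from grain number back to
#' traits determined during the vegetative and flowering periods (see
#' [year_trait_blacklist()]).
#'
#' @param data complete numeric data (columns = variables); standardised
#'   internally.
#' @param blacklist,whitelist two-column (from, to) arc lists.
#' @param tabu_length length of the tabu move list and the number of
#'   non-improving escape steps allowed (default 10).
#' @param max_iter iteration cap (default 1e4).
#' @param iss,alpha_mu BGe prior parameters, as in [bge_score()].
#' @param seed unused (the search is deterministic); kept for interface
#'   uniformity.
#' @return A [dag_model()] with elements `score` and `family_scores`.
#' @export
learn_structure <- function(data, blacklist = NULL, whitelist = NULL,
                            tabu_length = 10, max_iter = 1e4,
                            iss = ncol(data) + 2, alpha_mu = 1, seed = NULL) {
  X <- scale(as.matrix(data))
  .assert(!anyNA(X), "data must be complete with non-constant columns")
  nodes <- colnames(X)
  nv <- length(nodes)
  bl <- .norm_constraint(blacklist, nodes)
  wl <- .norm_constraint(whitelist, nodes)
  if (nrow(bl) && nrow(wl)) {
    clash <- paste(wl[, 1], wl[, 2]) %in% paste(bl[, 1], bl[, 2])
    .assert(!any(clash), "whitelisted arc is also blacklisted")
  }
  blm <- matrix(FALSE, nv, nv); blm[bl] <- TRUE
  wlm <- matrix(FALSE, nv, nv); wlm[wl] <- TRUE
  eng <- .bge_engine(X, iss = iss, alpha_mu = alpha_mu)

  amat <- matrix(FALSE, nv, nv, dimnames = list(nodes, nodes))
  amat[wl] <- TRUE
  .assert(.is_acyclic(amat), "whitelist arcs contain a cycle")
  fam <- vapply(seq_len(nv), function(j) eng$family_score(j, which(amat[, j])),
                numeric(1))
  score <- sum(fam)
  best_amat <- amat; best_score <- score

  tabu <- character(0)
  push_tabu <- function(key) {
    tabu <<- utils::tail(c(tabu, key), tabu_length)
  }
  amat_key <- function(m) paste(which(m), collapse = ";")
  push_tabu(amat_key(amat))
  stagnation <- 0

  for (iter in seq_len(max_iter)) {
    best_move <- NULL; best_delta <- -Inf
    for (i in seq_len(nv)) for (j in seq_len(nv)) {
      if (i == j) next
      if (!amat[i, j]) {
        # add i -> j
        if (blm[i, j] || amat[j, i]) next
        if (.has_path(amat, j, i)) next
        cand <- amat; cand[i, j] <- TRUE
        key <- amat_key(cand)
        if (key %in% tabu) next
        delta <- eng$family_score(j, which(cand[, j])) - fam[j]
        if (delta > best_delta + 1e-12) {
          best_delta <- delta
          best_move <- list(type = "add", i = i, j = j, cand = cand,
                            newfam = stats::setNames(delta + fam[j], "j"))
        }
      } else {
        # delete i -> j
        if (!wlm[i, j]) {
          cand <- amat; cand[i, j] <- FALSE
          key <- amat_key(cand)
          if (!(key %in% tabu)) {
            delta <- eng$family_score(j, which(cand[, j])) - fam[j]
            if (delta > best_delta + 1e-12) {
              best_delta <- delta
              best_move <- list(type = "delete", i = i, j = j, cand = cand)
            }
          }
        }
        # reverse i -> j
        if (!wlm[i, j] && !blm[j, i]) {
          cand <- amat; cand[i, j] <- FALSE
          if (!.has_path(cand, i, j)) {
            cand[j, i] <- TRUE
            key <- amat_key(cand)
            if (!(key %in% tabu)) {
              delta <- (eng$family_score(j, which(cand[, j])) - fam[j]) +
                (eng$family_score(i, which(cand[, i])) - fam[i])
              if (delta > best_delta + 1e-12) {
                best_delta <- delta
                best_move <- list(type = "reverse", i = i, j = j, cand = cand)
              }
            }
          }
        }
      }
    }
    if (is.null(best_move)) break
    amat <- best_move$cand
    for (j in unique(c(best_move$i, best_move$j))) {
      fam[j] <- eng$family_score(j, which(amat[, j]))
    }
    score <- sum(fam)
    push_tabu(amat_key(amat))
    if (score > best_score + 1e-12) {
      best_score <- score; best_amat <- amat; stagnation <- 0
    } else {
      stagnation <- stagnation + 1
      if (stagnation >= tabu_length) break
    }
  }
  dag <- structure(list(nodes = nodes, amat = best_amat), class = "dag_model")
  fams <- vapply(seq_len(nv), function(j) {
    eng$family_score(j, which(best_amat[, j]))
  }, numeric(1))
  names(fams) <- nodes
  dag$family_scores <- fams
  dag$score <- sum(fams)
  dag
}

#' Canonical constraint list for era-panel trait networks
#'
#' Year of release is treated as an exogenous driver (no arcs into it),
#' and traits determined during the vegetative and flowering periods are
#' assumed not conditionally dependent on grain number (no arcs from
#' grain number back to them).
#'
#' @param nodes all variable names.
#' @param year name of the year-of-release column (default `"year"`).
#' @param gn name of the grain-number column (default `"gn"`).
#' @param pre_gn traits determined before grain filling; default all
#'   nodes except `year` and `gn`.
#' @return Two-column matrix of blacklisted arcs.
#' @export
year_trait_blacklist <- function(nodes, year = "year", gn = "gn",
                                 pre_gn = setdiff(nodes, c(year, gn))) {
  into_year <- cbind(setdiff(nodes, year), year)
  from_gn <- if (length(pre_gn)) cbind(gn, pre_gn) else NULL
  out <- rbind(into_year, from_gn)
  colnames(out) <- c("from", "to")
  out
}

#' Bootstrap model averaging of learned networks
#'
#' Learns a network on each of `B` nonparametric row resamples, tabulates
#' per-arc strengths (fraction of networks containing the arc in either
#' direction) and directions (fraction of those with the given
#' orientation), and builds an averaged network keeping arcs whose
#' strength exceeds a threshold: either the data-driven L1-minimising
#' significance threshold over the empirical strength distribution
#' (default) or a fixed value. Kept arcs are oriented by majority
#' direction, added in decreasing strength, skipping any that would
#' create a cycle.
#'
#' @param data complete numeric data.
#' @param B number of bootstrap resamples (default 500).
#' @param blacklist,whitelist arc constraints passed to
#'   [learn_structure()].
#' @param threshold `"l1"` (data-driven) or `"fixed"`.
#' @param t_fixed strength cutoff when `threshold = "fixed"` (default 0.5).
#' @param seed RNG seed; fixes the resamples bit-identically.
#' @param ... further arguments to [learn_structure()].
#' @return List of class `bn_average`: `strengths` (data frame `from`,
#'   `to`, `strength`, `direction`), `dag` (averaged [dag_model()]),
#'   `threshold` (numeric cutoff used), `B`.
#' @export
bootstrap_average <- function(data, B = 500, blacklist = NULL,
                              whitelist = NULL,
                              threshold = c("l1", "fixed"), t_fixed = 0.5,
                              seed = 1, ...) {
  threshold <- match.arg(threshold)
  X <- as.matrix(data)
  n <- nrow(X)
  nodes <- colnames(X)
  nv <- length(nodes)
  counts <- matrix(0, nv, nv, dimnames = list(nodes, nodes))
  with_seed(seed, {
    for (b in seq_len(B)) {
      idx <- sample.int(n, n, replace = TRUE)
      Xb <- X[idx, , drop = FALSE]
      # guard against degenerate resamples of tiny data sets
      if (any(apply(Xb, 2, stats::sd) < 1e-12)) next
      dag <- learn_structure(Xb, blacklist = blacklist,
                             whitelist = whitelist, ...)
      counts <- counts + dag$amat
    }
  })
  either <- counts + t(counts)
  pairs <- which(upper.tri(either), arr.ind = TRUE)
  from <- nodes[c(pairs[, 1], pairs[, 2])]
  to <- nodes[c(pairs[, 2], pairs[, 1])]
  strength <- c(either[pairs], either[pairs]) / B
  n_either <- c(either[pairs], either[pairs])
  n_dir <- c(counts[pairs], counts[pairs[, c(2, 1), drop = FALSE]])
  direction <- ifelse(n_either > 0, n_dir / n_either, 0.5)
  strengths <- data.frame(from = from, to = to, strength = strength,
                          direction = direction, stringsAsFactors = FALSE)
  thr <- if (threshold == "fixed") t_fixed else {
    .l1_threshold(either[pairs] / B)
  }
  # build averaged DAG: significant arcs, majority orientation,
  # decreasing strength, never closing a cycle
  sig <- strengths[strengths$strength > thr & strengths$direction >= 0.5, ]
  sig <- sig[order(-sig$strength, sig$from, sig$to), ]
  amat <- matrix(FALSE, nv, nv, dimnames = list(nodes, nodes))
  for (k in seq_len(nrow(sig))) {
    i <- match(sig$from[k], nodes); j <- match(sig$to[k], nodes)
    if (amat[i, j] || amat[j, i]) next
    if (.has_path(amat, j, i)) next
    amat[i, j] <- TRUE
  }
  dag <- structure(list(nodes = nodes, amat = amat), class = "dag_model")
  structure(list(strengths = strengths, dag = dag, threshold = thr, B = B),
            class = "bn_average")
}

## L1-minimising significance threshold over the empirical strength
## distribution: model the ideal strength CDF as the step function
## F(x) = t on [0, 1); choose t minimising the L1 distance to the
## empirical CDF, then cut at the t-quantile of the strengths.
.l1_threshold <- function(p) {
  p <- sort(p)
  if (length(p) == 0) return(0.5)
  if (all(p == p[1])) return(max(p[1] - 1e-9, 0))
  xs <- unique(c(0, p, 1))
  widths <- diff(xs)
  Fvals <- stats::ecdf(p)(utils::head(xs, -1))
  l1 <- function(t) sum(abs(Fvals - t) * widths)
  cand <- unique(Fvals)
  t_star <- cand[which.min(vapply(cand, l1, numeric(1)))]
  stats::quantile(p, probs = t_star, type = 1, names = FALSE)
}

#' Cross-validated predictive correlation of an averaged network
#'
#' Repeated k-fold cross-validation: within each training fold every node
#' is fitted as a linear-Gaussian function of its parents in the averaged
#' network; on the held-out fold the node is predicted from its parents'
#' observed values. Per-node correlations between predicted and observed
#' values are averaged over folds and repeats. Root nodes (no parents)
#' give `NA`.
#'
#' @param avg a [bootstrap_average()] result or a [dag_model()].
#' @param data complete numeric data.
#' @param folds number of folds (default 5).
#' @param repeats number of repeats (default 10).
#' @param seed RNG seed for fold assignment.
#' @return Named vector of mean per-node correlations; attribute `mean`
#'   is the average over non-root nodes.
#' @export
cv_predict <- function(avg, data, folds = 5, repeats = 10, seed = 1) {
  dag <- if (inherits(avg, "bn_average")) avg$dag else avg
  stopifnot(inherits(dag, "dag_model"))
  X <- as.matrix(data)[, dag$nodes, drop = FALSE]
  n <- nrow(X)
  .assert(n >= folds, "need at least as many rows as folds")
  cors <- matrix(NA_real_, repeats, length(dag$nodes),
                 dimnames = list(NULL, dag$nodes))
  with_seed(seed, {
    for (r in seq_len(repeats)) {
      fold <- sample(rep_len(seq_len(folds), n))
      pred <- matrix(NA_real_, n, length(dag$nodes))
      for (f in seq_len(folds)) {
        tr <- fold != f; te <- !tr
        for (j in seq_along(dag$nodes)) {
          pa <- which(dag$amat[, j])
          if (length(pa) == 0) {
            pred[te, j] <- mean(X[tr, j])
          } else {
            df_tr <- data.frame(y = X[tr, j], X[tr, pa, drop = FALSE])
            fit <- stats::lm(y ~ ., data = df_tr)
            df_te <- as.data.frame(X[te, pa, drop = FALSE])
            pred[te, j] <- stats::predict(fit, newdata = df_te)
          }
        }
      }
      for (j in seq_along(dag$nodes)) {
        if (any(dag$amat[, j])) {
          cors[r, j] <- stats::cor(pred[, j], X[, j])
        }
      }
    }
  })
  out <- colMeans(cors)
  attr(out, "mean") <- mean(out, na.rm = TRUE)
  out
}

#' Arc intersection of several averaged networks
#'
#' Consensus network across environmental scenarios: keeps only the arcs
#' present (same orientation) in every input network.
#'
#' @param dags list of [dag_model()]s or [bootstrap_average()] results on
#'   the same node set.
#' @return A [dag_model()].
#' @export
consensus_network <- function(dags) {
  dags <- lapply(dags, function(d) if (inherits(d, "bn_average")) d$dag else d)
  .assert(length(dags) >= 1, "need at least one network")
  nodes <- dags[[1]]$nodes
  amat <- Reduce(`&`, lapply(dags, function(d) {
    .assert(identical(d$nodes, nodes), "node sets differ")
    d$amat
  }))
  structure(list(nodes = nodes, amat = amat), class = "dag_model")
}

#' Write an averaged network as an edge list or Graphviz DOT text
#'
#' @param avg a [bootstrap_average()] result.
#' @param path output file.
#' @param format `"csv"` (from, to, strength, direction) or `"dot"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(avg, path, format = c("csv", "dot")) {
  stopifnot(inherits(avg, "bn_average"))
  format <- match.arg(format)
  if (format == "csv") {
    utils::write.csv(avg$strengths, path, row.names = FALSE, quote = FALSE)
  } else {
    arcs <- which(avg$dag$amat, arr.ind = TRUE)
    lines <- c("digraph trait_network {",
               sprintf("  \"%s\" -> \"%s\";",
                       avg$dag$nodes[arcs[, 1]], avg$dag$nodes[arcs[, 2]]),
               "}")
    writeLines(lines, path)
  }
  invisible(path)
}
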