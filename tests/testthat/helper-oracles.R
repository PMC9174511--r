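# Independent oracles and shared fixtures, kept deliberately naive: each
# recomputes its quantity by direct enumeration or a literal reading of the
# scoring rules, never by calling the implementation under test.

# Literal one-record evaluation of the ICD-11 screening rules.
oracle_diagnose_one <- function(r) {
  e <- function(nm) r[[nm]] >= 2
  ptsd_sym <- (e("Re1") || e("Re2")) && (e("Av1") || e("Av2")) &&
    (e("Hyp1") || e("Hyp2"))
  dso_sym <- (e("Dys1") || e("Dys2")) && (e("Nsc1") || e("Nsc2")) &&
    (e("Rel1") || e("Rel2"))
  pimp <- e("Pimp1") || e("Pimp2") || e("Pimp3")
  dimp <- e("Dimp1") || e("Dimp2") || e("Dimp3")
  ptsd_ok <- isTRUE(r[["trauma_exposed"]]) && ptsd_sym && pimp
  if (ptsd_ok && dso_sym && dimp) "cPTSD" else if (ptsd_ok) "PTSD" else "none"
}

# A record template with every criterion satisfied.
record_all_met <- function() {
  out <- as.list(setNames(rep(2L, 18),
                          c(itqnet::itq_symptom_items(),
                            itqnet::itq_impairment_items())))
  out$trauma_exposed <- TRUE
  out
}

random_records <- function(n, seed) {
  set.seed(seed)
  items <- c(itqnet::itq_symptom_items(), itqnet::itq_impairment_items())
  d <- as.data.frame(matrix(sample(0:4, n * 18, replace = TRUE), nrow = n))
  names(d) <- items
  d$trauma_exposed <- sample(c(TRUE, FALSE), n, replace = TRUE, prob = c(0.9, 0.1))
  d
}

# Exhaustive shortest-path centrality on a small weighted graph:
# Floyd-Warshall distances, then enumeration of every simple path that
# attains the shortest distance, with fractional betweenness credit.
brute_centrality <- function(w, tol = 1e-9) {
  p <- nrow(w)
  d <- ifelse(w == 0, Inf, 1 / abs(w))
  diag(d) <- Inf
  D <- d
  diag(D) <- 0
  for (k in 1:p) for (i in 1:p) for (j in 1:p) {
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  }
  btw <- numeric(p)
  for (s in 1:(p - 1)) for (t in (s + 1):p) {
    if (!is.finite(D[s, t])) next
    paths <- list()
    rec <- function(u, acc, visited) {
      if (u == t) {
        paths[[length(paths) + 1]] <<- visited
        return(invisible())
      }
      for (v in seq_len(p)) {
        if (is.finite(d[u, v]) && !(v %in% visited) &&
            abs(acc + d[u, v] + D[v, t] - D[s, t]) < tol) {
          rec(v, acc + d[u, v], c(visited, v))
        }
      }
    }
    rec(s, 0, s)
    sigma <- length(paths)
    if (sigma == 0) next
    for (v in setdiff(seq_len(p), c(s, t))) {
      through <- sum(vapply(paths, function(pa) v %in% pa, logical(1)))
      btw[v] <- btw[v] + through / sigma
    }
  }
  clo <- vapply(seq_len(p), function(i) {
    r <- D[i, -i]
    r <- r[is.finite(r)]
    if (length(r) == 0) 0 else 1 / sum(r)
  }, numeric(1))
  list(betweenness = btw, closeness = clo, strength = rowSums(abs(w)))
}

random_graph_weights <- function(p, seed, edge_prob = 0.35) {
  set.seed(seed)
  w <- matrix(0, p, p)
  u <- upper.tri(w)
  vals <- ifelse(runif(sum(u)) < edge_prob,
                 runif(sum(u), 0.05, 0.9) * sign(runif(sum(u)) - 0.3), 0)
  w[u] <- vals
  w <- w + t(w)
  w
}

# M2-generating conditions for the recovery study: loadings spread over
# 0.70-0.85, heterogeneous factor correlations in 0.35-0.80.
recovery_conditions <- function() {
  fc <- diag(6)
  fc[upper.tri(fc)] <- c(0.75, 0.80, 0.70,
                         0.55, 0.50, 0.60,
                         0.42, 0.45, 0.48, 0.72,
                         0.35, 0.38, 0.40, 0.68, 0.78)
  fc[lower.tri(fc)] <- t(fc)[lower.tri(fc)]
  f <- c("Re", "Av", "Hyp", "Dys", "Nsc", "Rel")
  dimnames(fc) <- list(f, f)
  list(loadings = seq(0.70, 0.85, length.out = 12), factor_corr = fc)
}

# Sparse 12-node precision matrix with 20 true edges in two clusters plus
# two bridges; partial correlations +/-0.12.
true_precision_12 <- function() {
  p <- 12
  edges <- rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 5), c(5, 6), c(6, 1),
                 c(1, 3), c(2, 5), c(4, 6),
                 c(7, 8), c(8, 9), c(9, 10), c(10, 11), c(11, 12), c(12, 7),
                 c(7, 9), c(8, 11), c(10, 12),
                 c(3, 9), c(6, 12))
  K <- diag(p)
  for (i in seq_len(nrow(edges))) {
    v <- 0.30 * ifelse(i %% 4 == 0, -1, 1)
    K[edges[i, 1], edges[i, 2]] <- K[edges[i, 2], edges[i, 1]] <- v
  }
  diag(K) <- 2.5
  K
}

# Draw a 3-category outcome from a baseline-logit model.
draw_multinomial <- function(X, beta_ptsd, beta_cptsd) {
  ep <- exp(X %*% beta_ptsd)
  ec <- exp(X %*% beta_cptsd)
  pn <- 1 / (1 + ep + ec)
  u <- runif(nrow(X))
  factor(ifelse(u < pn, "none", ifelse(u < pn * (1 + ep), "PTSD", "cPTSD")),
         levels = c("none", "PTSD", "cPTSD"))
}
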