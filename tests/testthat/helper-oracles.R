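# Independent oracles used to validate package computations. These are
# deliberately naive re-derivations (ratio arithmetic, enumeration, dense
# matrix algebra) that share no code with the implementation paths they
# check.

# log-binomial coefficient by direct product/ratio arithmetic
oracle_lchoose <- function(a, b) {
  if (b < 0 || b > a) return(-Inf)
  if (b == 0 || b == a) return(0)
  sum(log(seq(a - b + 1, a))) - sum(log(seq_len(b)))
}

# hypergeometric pmf: P(X = x) drawing n from N with K marked
oracle_hyper_pmf <- function(x, n, K, N) {
  exp(
    oracle_lchoose(K, x) + oracle_lchoose(N - K, n - x) -
      oracle_lchoose(N, n)
  )
}

oracle_hyper_tail <- function(x, n, K, N) {
  hi <- min(n, K)
  if (x > hi) return(0)
  sum(vapply(seq(max(x, 0), hi), oracle_hyper_pmf, numeric(1),
             n = n, K = K, N = N))
}

oracle_hyper_moments <- function(n, K, N) {
  xs <- 0:min(n, K)
  pmf <- vapply(xs, oracle_hyper_pmf, numeric(1), n = n, K = K, N = N)
  mu <- sum(xs * pmf)
  list(
    mu = mu,
    sigma = sqrt(sum((xs - mu)^2 * pmf)),
    mu4 = sum((xs - mu)^4 * pmf)
  )
}

# exact one-sided rank-sum p-value by full enumeration (inclusive tail)
oracle_ranksum_p <- function(a, b, alternative = "greater") {
  r <- rank(c(a, b))
  n1 <- length(a)
  s_obs <- sum(r[seq_len(n1)])
  combs <- utils::combn(length(r), n1)
  s_perm <- colSums(matrix(r[combs], nrow = n1))
  if (alternative == "greater") mean(s_perm >= s_obs - 1e-9)
  else mean(s_perm <= s_obs + 1e-9)
}

# hand-rolled Benjamini-Hochberg step-up
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# dense transfer matrix built edge by edge with explicit loops
oracle_dense_W <- function(tri, beta, gamma) {
  nodes <- tri$nodes$node
  n <- length(nodes)
  W <- matrix(0, n, n, dimnames = list(nodes, nodes))
  deg <- setNames(tri$nodes$degree, nodes)
  for (j in nodes) {
    type_j <- tri$nodes$type[tri$nodes$node == j]
    if (type_j == "drug") {
      tg <- tri$dt_edges$target[tri$dt_edges$drug == j]
      ss <- tri$ds_edges$key[tri$ds_edges$drug == j]
      bt <- if (length(ss) == 0) 1 else if (length(tg) == 0) 0 else 1 - beta
      bs <- 1 - bt
      for (i in tg) W[i, j] <- bt / length(tg)
      for (i in ss) W[i, j] <- bs / length(ss)
    } else if (type_j == "target") {
      dr <- tri$dt_edges$drug[tri$dt_edges$target == j]
      for (i in dr) W[i, j] <- 1 / length(dr)
    } else {
      dr <- tri$ds_edges$drug[tri$ds_edges$key == j]
      for (i in dr) W[i, j] <- 1 / length(dr)
    }
  }
  for (i in nodes) {
    if (deg[i] > 0) W[i, ] <- W[i, ] * as.numeric(deg[i])^gamma
  }
  W
}

# random small tripartite network (connected drugs, some substructures)
random_tripartite <- function(n_drugs = 5, n_targets = 8, n_subs = 6,
                              p_dt = 0.4, p_ds = 0.3) {
  drugs <- sprintf("d%02d", seq_len(n_drugs))
  targets <- sprintf("t%02d", seq_len(n_targets))
  subs <- sprintf("s%02d", seq_len(n_subs))
  dt <- expand.grid(drug = drugs, target = targets,
                    stringsAsFactors = FALSE)
  dt <- dt[stats::runif(nrow(dt)) < p_dt, ]
  # ensure every drug has at least one target
  missing <- setdiff(drugs, dt$drug)
  if (length(missing)) {
    dt <- rbind(dt, data.frame(
      drug = missing, target = sample(targets, length(missing),
                                      replace = TRUE)
    ))
  }
  ds <- expand.grid(drug = drugs, key = subs, stringsAsFactors = FALSE)
  ds <- ds[stats::runif(nrow(ds)) < p_ds, ]
  net <- build_dti_network(tibble::as_tibble(dt))
  build_tripartite(
    net,
    profiles = tibble::tibble(compound_id = ds$drug, key = ds$key)
  )
}
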