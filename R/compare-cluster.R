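#' One-sided rank-sum comparison of two degree distributions
#'
#' Mann-Whitney/Wilcoxon rank-sum test with midranks for ties. For small
#' samples (both sides <= 8) the permutation distribution of the rank sum
#' is enumerated exactly and the p-value is the inclusive tail
#' `P(S >= observed)` (or `<=` for `alternative = "less"`); larger samples
#' use the tie-corrected normal approximation with continuity correction.
#' A fully tied degenerate input therefore yields p = 1.
#'
#' @param sample_a,sample_b Numeric degree vectors (non-empty).
#' @param alternative `"greater"` (a stochastically greater than b) or
#'   `"less"`.
#' @return One-row tibble: `statistic` (Mann-Whitney U of sample a),
#'   `p_value`, `method`.
#' @export
compare_degree_distributions <- function(sample_a, sample_b,
                                         alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  assert_that(
    length(sample_a) > 0 && length(sample_b) > 0,
    "both samples must be non-empty"
  )
  n1 <- length(sample_a)
  n2 <- length(sample_b)
  pooled <- c(sample_a, sample_b)
  r <- rank(pooled)
  s_obs <- sum(r[seq_len(n1)])
  u_obs <- s_obs - n1 * (n1 + 1) / 2
  if (max(n1, n2) <= 8) {
    combs <- utils::combn(n1 + n2, n1)
    s_perm <- colSums(matrix(r[combs], nrow = n1))
    p <- if (alternative == "greater") {
      mean(s_perm >= s_obs - 1e-9)
    } else {
      mean(s_perm <= s_obs + 1e-9)
    }
    method <- "exact rank-sum enumeration (midranks)"
  } else {
    mu <- n1 * n2 / 2
    nn <- n1 + n2
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (nn * (nn - 1))
    sigma <- sqrt(n1 * n2 / 12 * (nn + 1 - tie_term))
    z <- if (alternative == "greater") {
      (u_obs - mu - 0.5) / sigma
    } else {
      (u_obs - mu + 0.5) / sigma
    }
    p <- if (alternative == "greater") {
      pnorm(z, lower.tail = FALSE)
    } else {
      pnorm(z)
    }
    method <- "normal approximation with midrank tie correction"
  }
  tibble(statistic = u_obs, p_value = p, method = method)
}

#' Pairwise Tanimoto distances between substructure profiles
#'
#' `d(A, B) = 1 - |A intersect B| / |A union B|` on the key sets of each
#' compound. Two empty profiles have distance 0; an empty against a
#' non-empty profile has distance 1.
#'
#' @param profiles Long tibble `compound_id`, `key`.
#' @param compound_ids Optional character vector fixing the compound set
#'   and order (includes compounds with empty profiles); defaults to the
#'   ids present in `profiles`.
#' @return A [stats::dist] object.
#' @export
tanimoto_distance <- function(profiles, compound_ids = NULL) {
  ids <- compound_ids %||% sort(unique(profiles$compound_id))
  keys <- sort(unique(profiles$key))
  m <- matrix(
    0, nrow = length(ids), ncol = max(length(keys), 1L),
    dimnames = list(ids, if (length(keys)) keys else "none")
  )
  if (nrow(profiles) > 0) {
    pr <- profiles |> filter(.data$compound_id %in% ids)
    m[cbind(pr$compound_id, pr$key)] <- 1
  }
  inter <- m %*% t(m)
  sizes <- rowSums(m)
  uni <- outer(sizes, sizes, "+") - inter
  sim <- ifelse(uni == 0, 1, inter / pmax(uni, 1))
  stats::as.dist(1 - sim)
}

#' Cluster compounds by Tanimoto distance (k-medoids)
#'
#' Partition-around-medoids clustering under Tanimoto distance. The medoid
#' of each cluster is the member minimizing the summed distance to its
#' cluster mates; the algorithm is deterministic for a given input.
#'
#' @param profiles Long tibble `compound_id`, `key`.
#' @param k Number of clusters; must not exceed the number of compounds.
#' @param compound_ids Optional explicit compound set (see
#'   [tanimoto_distance()]).
#' @return List with `clusters` (tibble `compound_id`, `cluster`) and
#'   `medoids` (character vector, one id per cluster).
#' @export
cluster_compounds <- function(profiles, k = 10, compound_ids = NULL) {
  d <- tanimoto_distance(profiles, compound_ids)
  ids <- attr(d, "Labels")
  n <- length(ids)
  assert_that(k >= 1 && k <= n, sprintf("`k` must be in [1, %d]", n))
  if (k == n) {
    return(list(
      clusters = tibble(compound_id = ids, cluster = seq_len(n)),
      medoids = ids
    ))
  }
  if (k == 1L) {
    sums <- colSums(as.matrix(d))
    medoid <- ids[which.min(sums)]
    return(list(
      clusters = tibble(compound_id = ids, cluster = 1L),
      medoids = medoid
    ))
  }
  fit <- cluster::pam(d, k = k, diss = TRUE)
  list(
    clusters = tibble(
      compound_id = ids, cluster = as.integer(fit$clustering)
    ),
    medoids = fit$medoids
  )
}
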