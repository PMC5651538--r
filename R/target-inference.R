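#' Diffusion parameters for substructure-drug-target inference
#'
#' Defaults follow the published balanced network-based inference setup:
#' `alpha = beta = 0.1`, `gamma = -0.5`, `k = 2`, `top_n = 20`.
#'
#' @param alpha Initial-resource split across a drug's neighbour classes;
#'   by default the minority share `alpha` goes to substructure
#'   neighbours (`alpha_to = "substructures"`); set
#'   `alpha_to = "targets"` to flip the convention.
#' @param beta Edge-type weight split for mass leaving a drug node
#'   (share `beta` to substructure edges, `1 - beta` to target edges).
#' @param gamma Hub-influence exponent: incoming mass to node `i` is
#'   damped by `deg(i)^gamma`; `gamma = 0` is the mass-conserving limit.
#' @param k Number of diffusion steps (must be even for target ranking).
#' @param top_n Number of predicted candidates retained per drug.
#' @param alpha_to `"substructures"` (default) or `"targets"`.
#' @return List of class `inference_params`.
#' @export
inference_params <- function(alpha = 0.1, beta = 0.1, gamma = -0.5,
                             k = 2, top_n = 20,
                             alpha_to = c("substructures", "targets")) {
  alpha_to <- match.arg(alpha_to)
  assert_that(alpha >= 0 && alpha <= 1, "`alpha` must be in [0, 1]")
  assert_that(beta >= 0 && beta <= 1, "`beta` must be in [0, 1]")
  assert_that(k >= 0 && k == as.integer(k), "`k` must be a non-negative integer")
  assert_that(top_n >= 1, "`top_n` must be positive")
  structure(
    list(alpha = alpha, beta = beta, gamma = gamma, k = as.integer(k),
         top_n = as.integer(top_n), alpha_to = alpha_to),
    class = "inference_params"
  )
}

#' Build a substructure-drug-target tripartite network
#'
#' Integrates the known bipartite DTI network with drug-substructure
#' incidence profiles. Edges run only drug-target and drug-substructure;
#' substructure keys incident to no compound are dropped. Profiled
#' compounds absent from the DTI network must be declared as new chemical
#' entities (NCEs) -- they join with substructure edges only.
#'
#' @param net A `dti_network`.
#' @param profiles Long tibble `compound_id`, `key` (may be empty).
#' @param nce Character vector of compound ids allowed to appear in
#'   `profiles` without being drug nodes.
#' @return List of class `tripartite_network`: `nodes` (tibble `node`,
#'   `type`, `degree`), `dt_edges`, `ds_edges`.
#' @export
build_tripartite <- function(net, profiles = NULL, nce = character()) {
  stopifnot(inherits(net, "dti_network"))
  profiles <- profiles %||% tibble(compound_id = character(),
                                   key = character())
  drugs <- union(net$drugs$drug, nce)
  unknown <- setdiff(unique(profiles$compound_id), drugs)
  assert_that(
    length(unknown) == 0L,
    paste("profiles reference unknown compounds:",
          paste(head(unknown, 5), collapse = ", "))
  )
  dt <- net$edges |> distinct(.data$drug, .data$target)
  ds <- profiles |>
    distinct(.data$compound_id, .data$key) |>
    rename(drug = "compound_id")
  ids <- c(drugs, net$targets$target, unique(ds$key))
  assert_that(
    !anyDuplicated(ids),
    "node identifiers must be unique across drugs, targets, substructures"
  )
  nodes <- tibble(
    node = ids,
    type = c(
      rep("drug", length(drugs)),
      rep("target", nrow(net$targets)),
      rep("substructure", length(unique(ds$key)))
    )
  )
  deg <- c(table(c(dt$drug, dt$target, ds$drug, ds$key)))
  nodes$degree <- as.integer(deg[nodes$node])
  nodes$degree[is.na(nodes$degree)] <- 0L
  # substructure nodes always have degree >= 1 by construction (they come
  # from profiles); isolated drugs/targets are retained with degree 0
  structure(
    list(nodes = nodes, dt_edges = dt, ds_edges = ds),
    class = "tripartite_network"
  )
}

#' @export
print.tripartite_network <- function(x, ...) {
  tt <- table(x$nodes$type)
  cat(sprintf(
    "Tripartite network: %d drugs, %d targets, %d substructures; %d DT + %d DS edges\n",
    tt["drug"], tt["target"],
    ifelse(is.na(tt["substructure"]), 0L, tt["substructure"]),
    nrow(x$dt_edges), nrow(x$ds_edges)
  ))
  invisible(x)
}

#' @noRd
drug_neighbours <- function(tri, drug) {
  list(
    targets = tri$dt_edges$target[tri$dt_edges$drug == drug],
    subs = tri$ds_edges$key[tri$ds_edges$drug == drug]
  )
}

#' Initial resource vector for a query drug
#'
#' Places unit mass on the drug's neighbours: target neighbours share
#' `1 - alpha` equally and substructure neighbours share `alpha` equally
#' (flipped under `alpha_to = "targets"`). If one class is empty the other
#' receives all mass -- an NCE with no known targets starts with all its
#' resource on substructures.
#'
#' @param drug Drug node id.
#' @param tri A `tripartite_network`.
#' @param alpha Split parameter in `[0, 1]`.
#' @param alpha_to Which neighbour class receives the `alpha` share.
#' @return Named numeric vector over all nodes, summing to 1.
#' @export
initial_resource_vector <- function(drug, tri, alpha = 0.1,
                                    alpha_to = c("substructures", "targets")) {
  alpha_to <- match.arg(alpha_to)
  nb <- drug_neighbours(tri, drug)
  assert_that(
    length(nb$targets) + length(nb$subs) > 0,
    sprintf("drug '%s' is isolated; no resource can be placed", drug)
  )
  sub_share <- if (alpha_to == "substructures") alpha else 1 - alpha
  tgt_share <- 1 - sub_share
  if (length(nb$subs) == 0L) {
    sub_share <- 0
    tgt_share <- 1
  } else if (length(nb$targets) == 0L) {
    sub_share <- 1
    tgt_share <- 0
  }
  f0 <- setNames(numeric(nrow(tri$nodes)), tri$nodes$node)
  if (length(nb$targets)) f0[nb$targets] <- tgt_share / length(nb$targets)
  if (length(nb$subs)) f0[nb$subs] <- sub_share / length(nb$subs)
  f0
}

#' Transfer matrix of the resource-diffusion process
#'
#' Outgoing shares: a drug sends `1 - beta` of its mass split equally over
#' its target neighbours and `beta` over its substructure neighbours (all
#' mass to the non-empty class if one is empty); targets and substructures
#' send their whole mass split equally over their drug neighbours. The
#' incoming mass at node `i` is then damped by `deg(i)^gamma` with no
#' renormalization, so hub nodes are penalized for `gamma < 0`; at
#' `gamma = 0` every column sums to 1 and total resource is conserved.
#'
#' @param tri A `tripartite_network`.
#' @param beta,gamma See [inference_params()].
#' @return Sparse matrix `W` (class `dgCMatrix`) with `W[i, j]` the mass
#'   fraction flowing `j -> i` in one step.
#' @export
transfer_matrix <- function(tri, beta = 0.1, gamma = -0.5) {
  nodes <- tri$nodes$node
  assert_that(length(nodes) > 0, "network is empty")
  n_t <- table(factor(tri$dt_edges$drug, levels = nodes))
  n_s <- table(factor(tri$ds_edges$drug, levels = nodes))
  # drug -> target and drug -> substructure shares
  beta_eff <- function(drug) {
    nt <- n_t[[drug]]
    ns <- n_s[[drug]]
    if (ns == 0L) c(t = 1, s = 0)
    else if (nt == 0L) c(t = 0, s = 1)
    else c(t = 1 - beta, s = beta)
  }
  triplets <- list()
  if (nrow(tri$dt_edges) > 0) {
    shares_t <- vapply(tri$dt_edges$drug, function(d) {
      beta_eff(d)[["t"]] / n_t[[d]]
    }, numeric(1))
    triplets <- c(triplets, list(
      tibble(from = tri$dt_edges$drug, to = tri$dt_edges$target,
             w = shares_t)
    ))
    # target -> drug: equal split over drug neighbours
    deg_t <- table(factor(tri$dt_edges$target, levels = nodes))
    triplets <- c(triplets, list(
      tibble(from = tri$dt_edges$target, to = tri$dt_edges$drug,
             w = 1 / as.numeric(deg_t[tri$dt_edges$target]))
    ))
  }
  if (nrow(tri$ds_edges) > 0) {
    shares_s <- vapply(tri$ds_edges$drug, function(d) {
      beta_eff(d)[["s"]] / n_s[[d]]
    }, numeric(1))
    triplets <- c(triplets, list(
      tibble(from = tri$ds_edges$drug, to = tri$ds_edges$key, w = shares_s)
    ))
    deg_s <- table(factor(tri$ds_edges$key, levels = nodes))
    triplets <- c(triplets, list(
      tibble(from = tri$ds_edges$key, to = tri$ds_edges$drug,
             w = 1 / as.numeric(deg_s[tri$ds_edges$key]))
    ))
  }
  tr <- bind_rows(triplets)
  deg <- setNames(tri$nodes$degree, nodes)
  damp <- ifelse(deg[tr$to] > 0, as.numeric(deg[tr$to])^gamma, 0)
  Matrix::sparseMatrix(
    i = match(tr$to, nodes), j = match(tr$from, nodes),
    x = tr$w * damp,
    dims = c(length(nodes), length(nodes)),
    dimnames = list(nodes, nodes)
  )
}

#' Apply k resource-diffusion steps
#'
#' @param W Transfer matrix from [transfer_matrix()].
#' @param f0 Initial resource vector (or a matrix of column vectors).
#' @param k Non-negative number of steps; `k = 0` returns `f0`.
#' @return Diffused resource vector/matrix (`W^k f0`).
#' @export
diffuse <- function(W, f0, k = 2) {
  assert_that(k >= 0 && k == as.integer(k), "`k` must be a non-negative integer")
  nr <- if (is.matrix(f0) || inherits(f0, "Matrix")) nrow(f0) else length(f0)
  assert_that(nr == ncol(W), "dimension mismatch between `W` and `f0`")
  f <- f0
  for (i in seq_len(k)) f <- as.matrix(W %*% f)
  if (is.null(dim(f0))) {
    f <- drop(f)
    names(f) <- rownames(W)
  }
  f
}

#' Rank candidate targets for one drug
#'
#' Candidates are target nodes with strictly positive diffused resource
#' that are not already linked to the drug, sorted by descending score
#' with ties broken by ascending target id.
#'
#' @param drug Drug node id.
#' @param final Diffused resource vector (named over all nodes).
#' @param tri The `tripartite_network` diffusion ran on.
#' @param top_n Maximum number of candidates returned.
#' @return Tibble `drug`, `target`, `score`, `rank`.
#' @export
rank_candidate_targets <- function(drug, final, tri, top_n = 20) {
  targets <- tri$nodes$node[tri$nodes$type == "target"]
  known <- tri$dt_edges$target[tri$dt_edges$drug == drug]
  cand <- setdiff(targets, known)
  scores <- final[cand]
  keep <- which(scores > 0)
  cand <- cand[keep]
  scores <- scores[keep]
  ord <- order(-scores, cand)
  idx <- head(ord, top_n)
  tibble(
    drug = drug, target = cand[idx], score = unname(scores[idx]),
    rank = seq_along(idx)
  )
}

#' Predict new drug-target interactions for every drug
#'
#' Batch driver: builds the tripartite network, runs `k` diffusion steps
#' from each drug's initial resource vector and collects the top-ranked
#' unknown targets per drug. Requires even `k` so that resource sits on
#' target/substructure nodes when ranking.
#'
#' @param net A `dti_network` (the known, experimental network).
#' @param profiles Long tibble `compound_id`, `key`; may be empty, in
#'   which case predictions reduce to bipartite network-based inference.
#' @param params An [inference_params()] object.
#' @param nce Character vector of NCE ids (profiled, no known targets).
#' @return Tibble `drug`, `target`, `score`, `rank` over all drugs.
#' @export
predict_dti_network <- function(net, profiles = NULL,
                                params = inference_params(),
                                nce = character()) {
  assert_that(
    params$k %% 2L == 0L,
    "`k` must be even: resource must reside on targets when ranking"
  )
  tri <- build_tripartite(net, profiles, nce = nce)
  W <- transfer_matrix(tri, beta = params$beta, gamma = params$gamma)
  drugs <- tri$nodes$node[tri$nodes$type == "drug"]
  connected <- drugs[tri$nodes$degree[tri$nodes$type == "drug"] > 0]
  f0 <- vapply(
    setNames(connected, connected),
    function(d) initial_resource_vector(d, tri, alpha = params$alpha,
                                        alpha_to = params$alpha_to),
    numeric(nrow(tri$nodes))
  )
  fk <- diffuse(W, f0, k = params$k)
  preds <- map(connected, function(d) {
    rank_candidate_targets(d, setNames(fk[, d], rownames(W)), tri,
                           top_n = params$top_n)
  })
  bind_rows(preds)
}
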