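test_that("tripartite assembly counts nodes and edges correctly", {
  net <- build_dti_network(tibble::tibble(
    drug = c("d1", "d1", "d2"), target = c("t1", "t2", "t2")
  ))
  prof <- tibble::tibble(
    compound_id = c("d1", "d2", "d2"), key = c("s1", "s1", "s2")
  )
  tri <- build_tripartite(net, prof)
  expect_equal(sum(tri$nodes$type == "substructure"), 2)
  expect_equal(nrow(tri$ds_edges), 3)
  expect_equal(nrow(tri$dt_edges), 3)
  # degrees count both edge layers
  expect_equal(
    tri$nodes$degree[tri$nodes$node == "d2"], 2L + 1L
  )
  # no profiles: substructure layer absent
  tri0 <- build_tripartite(net, NULL)
  expect_equal(sum(tri0$nodes$type == "substructure"), 0)
  # NCE with profile but no DTIs joins with DS edges only
  tri_nce <- build_tripartite(
    net, dplyr::bind_rows(prof, tibble::tibble(compound_id = "nce1",
                                               key = "s2")),
    nce = "nce1"
  )
  expect_true("nce1" %in% tri_nce$nodes$node)
  # unknown profiled compound rejected
  expect_error(build_tripartite(net, tibble::tibble(
    compound_id = "ghost", key = "s1"
  )), "unknown compounds")
})

test_that("initial resource splits follow the alpha convention", {
  net <- build_dti_network(tibble::tibble(
    drug = "d1", target = c("t1", "t2")
  ))
  prof <- tibble::tibble(compound_id = "d1", key = c("s1", "s2"))
  tri <- build_tripartite(net, prof)
  f0 <- initial_resource_vector("d1", tri, alpha = 0.1)
  expect_equal(unname(f0[c("t1", "t2")]), c(0.45, 0.45))
  expect_equal(unname(f0[c("s1", "s2")]), c(0.05, 0.05))
  expect_equal(sum(f0), 1)
  # alpha = 0: all mass to targets
  f0z <- initial_resource_vector("d1", tri, alpha = 0)
  expect_equal(sum(f0z[c("t1", "t2")]), 1)
  # NCE fallback: no targets -> substructures get everything
  tri_nce <- build_tripartite(
    net,
    dplyr::bind_rows(prof, tibble::tibble(
      compound_id = "nce", key = sprintf("n%d", 1:4)
    )),
    nce = "nce"
  )
  f0n <- initial_resource_vector("nce", tri_nce, alpha = 0.1)
  expect_equal(unname(f0n[sprintf("n%d", 1:4)]), rep(0.25, 4))
  # flipped convention
  f0f <- initial_resource_vector("d1", tri, alpha = 0.1,
                                 alpha_to = "targets")
  expect_equal(unname(f0f[c("t1", "t2")]), c(0.05, 0.05))
  expect_error(
    initial_resource_vector("lonely", build_tripartite(
      build_dti_network(
        tibble::tibble(drug = "d9", target = "t9"),
        drugs = tibble::tibble(drug = c("d9", "lonely"))
      )
    )),
    "isolated"
  )
})

test_that("transfer matrix reproduces hand arithmetic on a path network", {
  tri <- build_tripartite(path_net())
  W <- as.matrix(transfer_matrix(tri, beta = 0.5, gamma = 0))
  expect_equal(W["t1", "d1"], 0.5)
  expect_equal(W["t2", "d1"], 0.5)
  expect_equal(W["d1", "t1"], 1)
  expect_equal(W["d1", "t2"], 1)
  # gamma = 0: every column is stochastic
  expect_equal(unname(Matrix::colSums(W)), rep(1, 3))
  # degree-1 recipients are never damped (1^gamma = 1)
  W2 <- as.matrix(transfer_matrix(tri, beta = 0.5, gamma = -0.7))
  expect_equal(W2["t1", "d1"], 0.5 * 1^-0.7)
  # the drug (degree 2) is damped when receiving
  expect_equal(W2["d1", "t1"], 2^-0.7)
})

test_that("gamma = 0 diffusion conserves resource on random networks", {
  withr::with_seed(41, {
    for (i in 1:5) {
      tri <- random_tripartite()
      W <- transfer_matrix(tri, beta = 0.1, gamma = 0)
      d <- tri$nodes$node[tri$nodes$type == "drug"][1]
      f0 <- initial_resource_vector(d, tri, alpha = 0.1)
      for (k in c(1, 2, 5)) {
        expect_lt(abs(sum(diffuse(W, f0, k)) - 1), 1e-10)
      }
    }
  })
})

test_that("diffusion equals the dense matrix-power oracle", {
  withr::with_seed(43, {
    for (i in 1:5) {
      tri <- random_tripartite(n_drugs = 8, n_targets = 12, n_subs = 10)
      W <- transfer_matrix(tri, beta = 0.1, gamma = -0.5)
      Wd <- oracle_dense_W(tri, beta = 0.1, gamma = -0.5)
      expect_lt(max(abs(as.matrix(W) - Wd)), 1e-12)
      d <- tri$nodes$node[tri$nodes$type == "drug"][1]
      f0 <- initial_resource_vector(d, tri, alpha = 0.1)
      got <- diffuse(W, f0, 2)
      want <- drop(Wd %*% (Wd %*% f0))
      expect_lt(max(abs(got - want[names(got)])), 1e-9)
      expect_true(all(got >= 0))
    }
  })
  # k = 0 is the identity
  tri <- build_tripartite(path_net())
  W <- transfer_matrix(tri)
  f0 <- initial_resource_vector("d1", tri)
  expect_equal(diffuse(W, f0, 0), f0)
  expect_error(diffuse(W, f0[1:2], 2), "dimension")
})

test_that("isomorphic targets receive identical scores", {
  # d1 bound to hub t0; t0 shared with d2 and d3, whose other targets
  # t2 and t3 sit in exchangeable positions
  net <- build_dti_network(tibble::tibble(
    drug = c("d1", "d2", "d2", "d3", "d3"),
    target = c("t0", "t0", "t2", "t0", "t3")
  ))
  tri <- build_tripartite(net)
  W <- transfer_matrix(tri, beta = 0.1, gamma = -0.5)
  f0 <- initial_resource_vector("d1", tri, alpha = 0.1)
  fk <- diffuse(W, f0, 2)
  expect_equal(fk[["t2"]], fk[["t3"]])
})

test_that("candidate ranking excludes known targets and breaks ties by id", {
  net <- build_dti_network(tibble::tibble(
    drug = c("d1", "d2", "d2", "d3", "d3"),
    target = c("t0", "t0", "t2", "t0", "t3")
  ))
  tri <- build_tripartite(net)
  W <- transfer_matrix(tri, beta = 0.1, gamma = -0.5)
  fk <- diffuse(W, initial_resource_vector("d1", tri), 2)
  ranked <- rank_candidate_targets("d1", fk, tri, top_n = 20)
  expect_false("t0" %in% ranked$target)       # already known
  expect_equal(ranked$target, c("t2", "t3"))  # equal scores: id order
  expect_equal(ranked$rank, 1:2)
  # top_n truncation
  expect_equal(nrow(rank_candidate_targets("d1", fk, tri, top_n = 1)), 1)
  # drug already linked to every target: nothing to predict
  full <- build_dti_network(tibble::tibble(
    drug = "d1", target = c("t1", "t2")
  ))
  tri_f <- build_tripartite(full)
  fk_f <- diffuse(transfer_matrix(tri_f),
                  initial_resource_vector("d1", tri_f), 2)
  expect_equal(nrow(rank_candidate_targets("d1", fk_f, tri_f)), 0)
})

test_that("batch prediction is deterministic and needs even k", {
  net <- build_dti_network(tibble::tibble(
    drug = c("d1", "d1", "d2", "d3"),
    target = c("t1", "t2", "t2", "t3")
  ))
  prof <- tibble::tibble(
    compound_id = c("d1", "d3"), key = c("s1", "s1")
  )
  p1 <- predict_dti_network(net, prof)
  p2 <- predict_dti_network(net, prof)
  expect_identical(p1, p2)
  expect_true(all(p1$score >= 0))
  # without profiles: pure bipartite network-based inference still works
  p0 <- predict_dti_network(net, NULL)
  expect_gt(nrow(p0), 0)
  expect_error(
    predict_dti_network(net, prof, params = inference_params(k = 3)),
    "even"
  )
})

test_that("substructure-sharing drugs gain each other's targets", {
  # d1 and d2 share a key; d2 binds t9, unknown to d1. Diffusion must
  # surface t9 for d1 ahead of the unreachable t8.
  net <- build_dti_network(tibble::tibble(
    drug = c("d1", "d2", "d3"),
    target = c("t1", "t9", "t8")
  ))
  prof <- tibble::tibble(
    compound_id = c("d1", "d2"), key = c("sA", "sA")
  )
  preds <- predict_dti_network(net, prof)
  d1_preds <- preds[preds$drug == "d1", ]
  expect_true("t9" %in% d1_preds$target)
  expect_false("t8" %in% d1_preds$target)
})
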