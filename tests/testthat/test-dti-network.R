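base_record <- function(...) {
  defaults <- tibble::tibble(
    compound_id = "c1", smiles = "CCO", inchikey = NA_character_,
    uniprot = "P00001", organism = "Homo sapiens",
    activity_type = "IC50", activity_value = 1, activity_units = "uM"
  )
  args <- list(...)
  for (nm in names(args)) defaults[[nm]] <- args[[nm]]
  defaults
}

test_that("the five filter criteria apply in order with a rejection log", {
  recs <- dplyr::bind_rows(
    base_record(activity_value = 10),                      # boundary pass
    base_record(activity_type = "Ki", activity_value = 15),  # i
    base_record(activity_type = "AC50"),                     # i
    base_record(organism = "Rattus norvegicus"),             # ii
    base_record(uniprot = ""),                               # iii
    base_record(smiles = "junk(("),                          # iv
    base_record(smiles = "[Na+].[Cl-]"),                     # v
    # fails both i and ii: first criterion recorded
    base_record(activity_value = 20, organism = "Mus musculus")
  )
  kept <- filter_activity_records(recs)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$activity_value, 10)  # <= 10 uM is inclusive
  log <- rejection_log(kept)
  expect_equal(log$criterion, c("i", "i", "ii", "iii", "iv", "v", "i"))
  expect_equal(log$index, 2:8)
})

test_that("filtering is order-independent", {
  recs <- dplyr::bind_rows(
    base_record(compound_id = "a", activity_value = 2),
    base_record(compound_id = "b", activity_value = 12),
    base_record(compound_id = "c", organism = "Bos taurus"),
    base_record(compound_id = "d", activity_value = 9.99)
  )
  kept1 <- filter_activity_records(recs)
  withr::with_seed(3, {
    perm <- sample(nrow(recs))
  })
  kept2 <- filter_activity_records(recs[perm, ])
  expect_setequal(kept1$compound_id, kept2$compound_id)
})

test_that("compounds deduplicate by InChIKey keeping first-seen ids", {
  recs <- dplyr::bind_rows(
    base_record(compound_id = "first", smiles = "CCO"),
    base_record(compound_id = "alias", smiles = "OCC"),  # same molecule
    base_record(compound_id = "other", smiles = "CCCO")
  )
  kept <- filter_activity_records(recs)
  comp <- dedup_compounds(kept)
  expect_equal(nrow(comp), 2)
  expect_true("first" %in% comp$compound_id)
  expect_false("alias" %in% comp$compound_id)
  expect_setequal(
    comp$aliases[comp$compound_id == "first"][[1]], c("first", "alias")
  )
  expect_equal(nrow(dedup_compounds(kept[0, ])), 0)
})

test_that("network construction and merging follow set-union semantics", {
  exp_net <- build_dti_network(
    tibble::tibble(
      drug = c("d1", "d1", "d2", "d2", "d3"),
      target = c("t1", "t2", "t1", "t3", "t4")
    ),
    provenance = "experimental"
  )
  pred_net <- build_dti_network(
    tibble::tibble(
      drug = c("d1", "d2", "d3"),
      target = c("t2", "t4", "t5")  # d1-t2 also experimental
    ),
    provenance = "predicted"
  )
  m <- merge_networks(exp_net, pred_net)
  expect_equal(nrow(m$edges), 7)
  both <- m$edges$provenance[m$edges$drug == "d1" & m$edges$target == "t2"]
  expect_equal(both, "experimental;predicted")
  # commutativity
  m2 <- merge_networks(pred_net, exp_net)
  expect_equal(m$edges, m2$edges)
  # identity: merging an empty predicted set changes nothing
  empty <- build_dti_network(
    exp_net$edges[0, c("drug", "target")], provenance = "predicted"
  )
  expect_equal(merge_networks(exp_net, empty)$edges$provenance,
               exp_net$edges$provenance)
  # duplicate edges in one input stored once
  dup <- build_dti_network(
    tibble::tibble(drug = c("d1", "d1"), target = c("t1", "t1"),
                   activity = c(5, 2))
  )
  expect_equal(nrow(dup$edges), 1)
  expect_equal(dup$edges$activity, 2)  # most potent kept
  # dangling endpoints rejected when node tables are supplied
  expect_error(
    build_dti_network(
      tibble::tibble(drug = "dX", target = "t1"),
      drugs = tibble::tibble(drug = "d1")
    ),
    "unknown drugs"
  )
})

test_that("network statistics satisfy the degree-sum identity", {
  net <- build_dti_network(tibble::tibble(
    drug = c("d1", "d1", "d1", "d2"),
    target = c("t1", "t2", "t3", "t1")
  ))
  s <- network_stats(net)
  expect_equal(sum(s$drug_degrees$degree), s$n_edges)
  expect_equal(sum(s$target_degrees$degree), s$n_edges)
  expect_equal(s$mean_drug_degree, 2)
  # single-edge network: 100% sparsity
  s1 <- network_stats(path_net())
  expect_equal(network_stats(
    build_dti_network(tibble::tibble(drug = "d", target = "t"))
  )$sparsity_pct, 100)
  expect_equal(s1$n_edges, 2)
  # empty network rejected
  empty <- build_dti_network(
    tibble::tibble(drug = character(), target = character())
  )
  expect_error(network_stats(empty), "empty")
  # glance row mirrors the stats
  g <- glance(net)
  expect_equal(g$n_edges, 4)
})

test_that("AAP annotation flags mapped targets only", {
  net <- build_dti_network(tibble::tibble(
    drug = "d1", target = c("P1", "P2", "P3")
  ))
  gene_map <- tibble::tibble(
    uniprot = c("P1", "P2"), gene_symbol = c("SIRT1", "ALB")
  )
  expect_warning(
    ann <- annotate_aap_targets(net, c("SIRT1", "MTOR"), gene_map),
    "without a gene-symbol mapping"
  )
  expect_equal(sum(ann$targets$is_aap), 1)
  expect_true(ann$targets$is_aap[ann$targets$target == "P1"])
  # empty AAG set: nothing flagged
  expect_warning(none <- annotate_aap_targets(net, character(), gene_map))
  expect_equal(sum(none$targets$is_aap), 0)
  # all targets AAG
  full_map <- tibble::tibble(
    uniprot = paste0("P", 1:3), gene_symbol = c("A", "B", "C")
  )
  all_ann <- annotate_aap_targets(net, c("A", "B", "C"), full_map)
  expect_equal(sum(all_ann$targets$is_aap), 3)
})

test_that("drug subnetwork extraction induces the right neighbourhood", {
  net <- build_dti_network(tibble::tibble(
    drug = c("d1", "d1", "d2", "d3"),
    target = c("t1", "t2", "t1", "t3")
  ))
  sub <- extract_drug_subnetwork(net, c("d1", "d2"))
  expect_equal(nrow(sub$drugs), 2)
  expect_setequal(sub$targets$target, c("t1", "t2"))  # shared t1 once
  expect_equal(nrow(sub$edges), 3)
  expect_error(extract_drug_subnetwork(net, "nope"), "unknown drug")
})

test_that("rank-sum comparison matches enumeration and the stats oracle", {
  # pinned: separated triples, exact p = 1/20
  expect_equal(
    compare_degree_distributions(c(4, 5, 6), c(1, 2, 3), "greater")$p_value,
    0.05
  )
  # symmetry: identical samples cannot look greater
  expect_gte(
    compare_degree_distributions(c(1, 2, 3), c(1, 2, 3), "greater")$p_value,
    0.5
  )
  # exact branch agrees with the independent enumeration oracle
  withr::with_seed(9, {
    for (i in 1:10) {
      a <- sample(1:20, sample(2:6, 1), replace = TRUE)
      b <- sample(1:20, sample(2:6, 1), replace = TRUE)
      expect_equal(
        compare_degree_distributions(a, b, "greater")$p_value,
        oracle_ranksum_p(a, b, "greater"),
        tolerance = 1e-12
      )
      expect_equal(
        compare_degree_distributions(a, b, "less")$p_value,
        oracle_ranksum_p(a, b, "less"),
        tolerance = 1e-12
      )
    }
  })
  # untied exact case agrees with wilcox.test's exact p
  a <- c(12, 15, 17, 19)
  b <- c(1, 3, 5, 8)
  expect_equal(
    compare_degree_distributions(a, b, "greater")$p_value,
    stats::wilcox.test(a, b, alternative = "greater", exact = TRUE)$p.value,
    tolerance = 1e-12
  )
  # large-sample normal branch tracks wilcox.test's corrected approximation
  withr::with_seed(31, {
    x <- rpois(40, 5)
    y <- rpois(35, 3)
  })
  ours <- compare_degree_distributions(x, y, "greater")$p_value
  ref <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "greater", exact = FALSE,
                       correct = TRUE)$p.value
  )
  expect_equal(ours, ref, tolerance = 1e-10)
  expect_error(compare_degree_distributions(numeric(), 1), "non-empty")
})

test_that("Tanimoto distance is a proper dissimilarity on profiles", {
  prof <- tibble::tibble(
    compound_id = c("a", "a", "b", "b", "c"),
    key = c("k1", "k2", "k1", "k3", "k4")
  )
  d <- as.matrix(tanimoto_distance(prof))
  expect_equal(diag(d), setNames(rep(0, 3), c("a", "b", "c")))
  expect_equal(d["a", "b"], 1 - 1 / 3)
  expect_equal(d["a", "c"], 1)
  expect_equal(d, t(d))
  # random profiles: identity and symmetry
  withr::with_seed(17, {
    pr <- tibble::tibble(
      compound_id = rep(sprintf("m%02d", 1:8), each = 4),
      key = sample(sprintf("k%02d", 1:12), 32, replace = TRUE)
    ) |> dplyr::distinct()
  })
  dm <- as.matrix(tanimoto_distance(pr))
  expect_true(all(abs(diag(dm)) < 1e-12))
  expect_equal(dm, t(dm))
})

test_that("k-medoids clustering honours structure and edge cases", {
  # two disjoint key groups split perfectly at k = 2
  prof <- tibble::tibble(
    compound_id = c("a1", "a2", "a3", "b1", "b2"),
    key = c("x", "x", "x", "y", "y")
  )
  cl <- cluster_compounds(prof, k = 2)
  grp <- split(cl$clusters$compound_id, cl$clusters$cluster)
  expect_setequal(lengths(grp), c(3, 2))
  expect_true(all(c("a1", "a2", "a3") %in%
                    grp[[which(lengths(grp) == 3)]]))
  # identical profiles, k = 1: lowest-id medoid
  same <- tibble::tibble(compound_id = c("z2", "z1", "z3"), key = "k")
  one <- cluster_compounds(same, k = 1)
  expect_equal(unique(one$clusters$cluster), 1)
  expect_equal(one$medoids, "z1")
  # n = k: singletons
  solo <- cluster_compounds(prof, k = 5)
  expect_equal(sort(solo$medoids), sort(unique(prof$compound_id)))
  expect_error(cluster_compounds(prof, k = 6), "k")
})
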