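test_that("generators are bit-reproducible under a fixed seed", {
  cfg <- generator_config(seed = 5, n_genes = 500, n_aap = 50,
                          n_human = 30, n_orth_multi = 25,
                          human_orth_overlap = 5,
                          organism_singles = c(CE = 10, DM = 10, MM = 10,
                                               SC = 10),
                          n_drugs = 20, n_targets = 30, n_aap_targets = 8,
                          n_planted = 5)
  expect_identical(gen_universe(cfg), gen_universe(cfg))
  expect_identical(gen_ortholog_catalog(cfg), gen_ortholog_catalog(cfg))
  expect_identical(gen_dti_network(cfg), gen_dti_network(cfg))
  expect_identical(gen_compounds(cfg), gen_compounds(cfg))
})

test_that("the universe has exactly K AAP genes inside N", {
  cfg <- generator_config(seed = 2, n_genes = 100, n_aap = 10,
                          n_human = 7, n_orth_multi = 5,
                          human_orth_overlap = 2,
                          organism_singles = c(CE = 5, DM = 5, MM = 5,
                                               SC = 5),
                          n_drugs = 5, n_targets = 20, n_aap_targets = 5,
                          n_planted = 2, min_degree = 2, max_degree = 8)
  u <- gen_universe(cfg)
  expect_length(u$genes, 100)
  expect_length(u$aap, 10)
  expect_true(all(u$aap %in% u$genes))
  # K = 0 allowed
  cfg0 <- generator_config(seed = 2, n_genes = 100, n_aap = 0,
                           n_human = 0, n_orth_multi = 0,
                           human_orth_overlap = 0,
                           organism_singles = c(CE = 1, DM = 1, MM = 1,
                                                SC = 1),
                           n_drugs = 5, n_targets = 20, n_aap_targets = 0,
                           n_planted = 2, min_degree = 2, max_degree = 8)
  expect_length(gen_universe(cfg0)$aap, 0)
})

test_that("curation generator reproduces the configured set arithmetic", {
  cfg <- generator_config(seed = 31)  # study-shaped defaults
  u <- gen_universe(cfg)
  cur <- gen_ortholog_catalog(cfg, u)
  # rebuild the catalogue through the public curation path
  lists <- cur$gene_lists
  human <- lists$symbol[lists$organism == "HS"]
  orth_sets <- lapply(
    setNames(nm = c("CE", "DM", "MM", "SC")),
    function(o) map_to_human_orthologs(
      lists$symbol[lists$organism == o], o, cur$ortholog_table
    )
  )
  catalog <- build_aag_catalog(human, orth_sets)
  multi <- filter_by_organism_support(catalog, 2)
  expect_length(multi, 130)
  expect_equal(multi, cur$truth$multi)
  pooled <- pool_aag_sets(multi, human)
  expect_length(pooled, 411)
  expect_equal(pooled, sort(u$aap))
  # support >= 1 over the non-human organisms recovers the m=1 union
  m1 <- filter_by_organism_support(catalog, 1)
  expect_length(m1, cur$truth$union_m1)
  # infeasible arithmetic is rejected
  expect_error(
    gen_ortholog_catalog(generator_config(n_orth_multi = 131)),
    "infeasible"
  )
})

test_that("activity-record truth labels validate against the filter", {
  cfg <- generator_config(seed = 13, n_drugs = 15, n_targets = 25,
                          n_aap_targets = 6, n_planted = 3,
                          min_degree = 2, max_degree = 8)
  u <- gen_universe(cfg)
  gn <- gen_dti_network(cfg, u)
  cmp <- gen_compounds(cfg, target_map = gn$net$edges)
  act <- gen_activity_records(cfg, gn$net, cmp$compounds)
  kept <- filter_activity_records(act$records)
  # filter keeps exactly the labelled-pass records
  expect_equal(nrow(kept), sum(act$truth$pass))
  expect_equal(rejection_log(kept)$index,
               act$truth$index[!act$truth$pass])
  expect_equal(rejection_log(kept)$criterion,
               act$truth$criterion[!act$truth$pass])
  # the boundary record sits exactly on the inclusive threshold
  expect_equal(act$records$activity_value[1], 10)
  # and the kept records rebuild exactly the generated network edges
  net2 <- dti_from_records(kept)
  expect_equal(net2$edges[c("drug", "target")],
               gn$net$edges[c("drug", "target")])
})

test_that("planted network respects degrees and the AAP edge fractions", {
  cfg <- generator_config(seed = 19)
  u <- gen_universe(cfg)
  gn <- gen_dti_network(cfg, u)
  deg <- gn$truth$degrees
  expect_true(all(deg >= 3 & deg <= 30))
  expect_length(gn$truth$planted, 20)
  # truth x-counts validate against the emitted network annotation
  x_net <- tidy(gn$net) |>
    dplyr::group_by(drug) |>
    dplyr::summarise(x = sum(is_aap))
  expect_equal(gn$truth$x_by_drug$x, x_net$x)
  # planted drugs hit AAP targets far above background on average
  planted_x <- gn$truth$x_by_drug |>
    dplyr::filter(drug %in% gn$truth$planted)
  null_x <- gn$truth$x_by_drug |>
    dplyr::filter(!drug %in% gn$truth$planted)
  expect_gt(mean(planted_x$x / planted_x$n),
            mean(null_x$x / null_x$n) + 0.2)
  # pi = 1: every planted edge is an AAP target
  cfg1 <- generator_config(seed = 3, planted_aap_fraction = 1,
                           n_drugs = 30, n_targets = 60,
                           n_aap_targets = 40, n_planted = 5)
  gn1 <- gen_dti_network(cfg1, gen_universe(cfg1))
  px <- gn1$truth$x_by_drug |>
    dplyr::filter(drug %in% gn1$truth$planted)
  expect_true(all(px$x == px$n))
  # infeasible configs rejected
  expect_error(generator_config(n_planted = 500), "n_planted")
  expect_error(generator_config(min_degree = 40, max_degree = 20),
               "min_degree")
})

test_that("compound generator controls profile sharing", {
  cfg0 <- generator_config(seed = 7, n_drugs = 6, n_targets = 20,
                           n_aap_targets = 5, n_planted = 2,
                           profile_sharing = 0,
                           min_degree = 2, max_degree = 8)
  prof0 <- gen_compounds(cfg0)$profiles
  # sharing = 0: pairwise disjoint key sets
  by_drug <- split(prof0$key, prof0$compound_id)
  pairs <- utils::combn(names(by_drug), 2)
  for (j in seq_len(ncol(pairs))) {
    expect_length(
      intersect(by_drug[[pairs[1, j]]], by_drug[[pairs[2, j]]]), 0
    )
  }
  # n = 0 drugs: empty output
  cfg_empty <- generator_config(seed = 7, n_drugs = 0, n_targets = 20,
                                n_aap_targets = 5, n_planted = 0,
                                min_degree = 1, max_degree = 5)
  out <- gen_compounds(cfg_empty)
  expect_equal(nrow(out$compounds), 0)
  # unique SMILES per compound so InChIKey dedup keeps them apart
  cfg <- generator_config(seed = 7)
  cmp <- gen_compounds(cfg)$compounds
  expect_equal(anyDuplicated(cmp$smiles), 0)
})

test_that("simulate_study writes a coherent fixture with truth JSON", {
  sim <- planted_study()
  expect_true(all(file.exists(unlist(sim$paths))))
  truth <- jsonlite::read_json(sim$paths$truth, simplifyVector = TRUE)
  expect_equal(truth$n_pooled, 411)
  expect_equal(truth$n_multi, 130)
  expect_equal(truth$curation$overlap, 28)
  expect_length(truth$planted, 20)
  expect_equal(truth$planted, sim$truth$planted)
})
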