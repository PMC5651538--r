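# Shared fixtures, built once per test run and cached. The planted study
# uses the generator defaults (200 drugs, 20 planted at pi = 0.5, degrees
# 3..30) with a fixed seed; scoring uses 2,000 permutations per drug,
# enough to resolve the q < 0.05 decision across 200 drugs while keeping
# the suite fast.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, build) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, build(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

planted_study <- function() {
  cached("planted_study", function() {
    dir <- file.path(tempdir(), "senopharm_fixture")
    simulate_study(generator_config(seed = 202), dir)
  })
}

study_pipeline_config <- function(sim, out_dir, inference = TRUE) {
  pipeline_config(
    gene_lists = sim$paths$gene_lists,
    orthologs = sim$paths$orthologs,
    activity_records = sim$paths$activity_records,
    target_gene_map = sim$paths$target_gene_map,
    profiles = sim$paths$profiles,
    out_dir = out_dir, seed = 7, inference = inference,
    perm = permutation_config(n_perm = 2000)
  )
}

planted_run_comnet <- function() {
  cached("planted_run_comnet", function() {
    sim <- planted_study()
    run_pipeline(study_pipeline_config(
      sim, file.path(tempdir(), "senopharm_run_comnet")
    ))
  })
}

planted_run_expnet <- function() {
  cached("planted_run_expnet", function() {
    sim <- planted_study()
    run_pipeline(study_pipeline_config(
      sim, file.path(tempdir(), "senopharm_run_expnet"), inference = FALSE
    ))
  })
}

# tiny two-target path network: one drug bound to two targets
path_net <- function() {
  build_dti_network(
    tibble::tibble(drug = "d1", target = c("t1", "t2"))
  )
}
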