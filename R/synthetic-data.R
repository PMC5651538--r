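#' Configuration of the synthetic study generator
#'
#' Defaults emulate the shapes of the real study: a 20,462-gene
#' protein-coding universe with a 411-gene AAP subset; a curation scenario
#' with 309 human AAGs, 130 cross-organism orthologous AAGs and 28 genes
#' in common (pooling to the 411); and a planted drug-target network of
#' 200 compounds with heavy-tailed degrees in 3..30, of which 20 planted
#' compounds hit AAP-encoded targets with probability `planted_aap_fraction
#' = 0.5` per edge while null compounds hit them at the genomic background
#' rate `n_aap / n_genes`.
#'
#' @param seed Base seed; every generator derives substreams from it.
#' @param n_genes,n_aap Universe and AAP-subset sizes.
#' @param n_human,n_orth_multi,human_orth_overlap Curation scenario sizes;
#'   must satisfy `n_orth_multi + n_human - human_orth_overlap = n_aap` so
#'   the curated pool and the planted AAP set coincide.
#' @param organism_singles Named counts of genes supported by exactly one
#'   non-human organism (not part of the pooled AAP set).
#' @param multi_support_probs Probabilities that a multi-organism gene is
#'   supported by exactly 2, 3, or 4 non-human organisms.
#' @param n_drugs,n_targets,n_aap_targets Network sizes.
#' @param degree_exponent,min_degree,max_degree Truncated discrete
#'   power-law drug-degree distribution.
#' @param n_planted,planted_aap_fraction Planted-signal parameters.
#' @param keys_per_target,n_keys,profile_fidelity,noise_key_rate,
#'   profile_sharing Substructure-profile generation (see
#'   [gen_compounds()]).
#' @param n_fail_per_criterion Failing activity records emitted per filter
#'   criterion.
#' @param activity_threshold Potency cutoff the passing records respect.
#' @return List of class `generator_config`.
#' @export
generator_config <- function(seed = 1,
                             n_genes = 20462, n_aap = 411,
                             n_human = 309, n_orth_multi = 130,
                             human_orth_overlap = 28,
                             organism_singles = c(CE = 300, DM = 250,
                                                  MM = 200, SC = 126),
                             multi_support_probs = c(0.85, 0.10, 0.05),
                             n_drugs = 200, n_targets = 150,
                             n_aap_targets = 40,
                             degree_exponent = 2.2, min_degree = 3,
                             max_degree = 30,
                             n_planted = 20, planted_aap_fraction = 0.5,
                             keys_per_target = 2, n_keys = 300,
                             profile_fidelity = 0.9, noise_key_rate = 1,
                             profile_sharing = 0.5,
                             n_fail_per_criterion = 2,
                             activity_threshold = 10) {
  cfg <- list(
    seed = seed, n_genes = n_genes, n_aap = n_aap, n_human = n_human,
    n_orth_multi = n_orth_multi, human_orth_overlap = human_orth_overlap,
    organism_singles = organism_singles,
    multi_support_probs = multi_support_probs,
    n_drugs = n_drugs, n_targets = n_targets,
    n_aap_targets = n_aap_targets,
    degree_exponent = degree_exponent, min_degree = min_degree,
    max_degree = max_degree, n_planted = n_planted,
    planted_aap_fraction = planted_aap_fraction,
    keys_per_target = keys_per_target, n_keys = n_keys,
    profile_fidelity = profile_fidelity,
    noise_key_rate = noise_key_rate, profile_sharing = profile_sharing,
    n_fail_per_criterion = n_fail_per_criterion,
    activity_threshold = activity_threshold
  )
  assert_that(n_aap <= n_genes, "`n_aap` cannot exceed `n_genes`")
  assert_that(n_planted <= n_drugs, "`n_planted` cannot exceed `n_drugs`")
  assert_that(
    planted_aap_fraction >= 0 && planted_aap_fraction <= 1,
    "`planted_aap_fraction` must be in [0, 1]"
  )
  assert_that(
    n_aap_targets <= n_targets && n_aap_targets <= n_aap,
    "`n_aap_targets` must fit in both the target set and the AAP set"
  )
  assert_that(
    min_degree >= 1 && max_degree >= min_degree &&
      max_degree <= n_targets,
    "need 1 <= min_degree <= max_degree <= n_targets"
  )
  assert_that(
    human_orth_overlap <= min(n_human, n_orth_multi),
    "overlap cannot exceed either curation set"
  )
  structure(cfg, class = "generator_config")
}

#' Generate the gene universe and its AAP subset
#'
#' @param config A [generator_config()].
#' @return List `genes` (N synthetic symbols `G000001`...), `aap`
#'   (K-subset, sampled without replacement).
#' @export
gen_universe <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  genes <- sprintf("G%06d", seq_len(config$n_genes))
  aap <- with_seed(
    substream_seed(config$seed, "universe"),
    sort(sample(genes, config$n_aap))
  )
  list(genes = genes, aap = aap)
}

#' Generate per-organism AAG lists and an ortholog table
#'
#' Constructs a curation scenario whose outcome is known exactly: the
#' multi-organism orthologous set, the human set and their overlap have
#' the configured sizes, so [filter_by_organism_support()] at
#' `min_organisms = 2` recovers the multi set and [pool_aag_sets()] yields
#' `n_orth_multi + n_human - human_orth_overlap` genes -- by default the
#' planted 411-gene AAP set itself. Single-organism genes (support 1) are
#' drawn from outside the AAP set.
#'
#' @param config A [generator_config()].
#' @param universe Output of [gen_universe()] (regenerated if omitted).
#' @return List with `gene_lists` (tibble `organism`, `symbol`; organism
#'   lists use source-organism gene ids), `ortholog_table`, and `truth`
#'   (expected pooled set, multi set, per-support counts).
#' @export
gen_ortholog_catalog <- function(config, universe = gen_universe(config)) {
  stopifnot(inherits(config, "generator_config"))
  assert_that(
    config$n_orth_multi + config$n_human - config$human_orth_overlap ==
      config$n_aap,
    paste("infeasible curation spec:",
          "n_orth_multi + n_human - human_orth_overlap must equal n_aap")
  )
  orgs <- setdiff(ORGANISMS, "HS")
  assert_that(
    all(names(config$organism_singles) %in% orgs),
    "`organism_singles` must be named by CE, DM, MM, SC"
  )
  non_aap <- setdiff(universe$genes, universe$aap)
  assert_that(
    sum(config$organism_singles) <= length(non_aap),
    "not enough non-AAP genes for the configured singles"
  )
  with_seed(substream_seed(config$seed, "ortholog_catalog"), {
    aap <- sample(universe$aap) # random order, then partition
    both <- aap[seq_len(config$human_orth_overlap)]
    orth_only <- aap[config$human_orth_overlap +
                       seq_len(config$n_orth_multi -
                                 config$human_orth_overlap)]
    human_only <- setdiff(aap, c(both, orth_only))
    multi <- sort(c(both, orth_only))
    human <- sort(c(both, human_only))
    # assign each multi gene to >= 2 non-human organisms
    support <- sample(2:4, length(multi), replace = TRUE,
                      prob = config$multi_support_probs)
    multi_orgs <- map(support, function(s) sample(orgs, s))
    singles_pool <- sample(non_aap, sum(config$organism_singles))
    singles <- split(
      singles_pool,
      rep(names(config$organism_singles), config$organism_singles)
    )
    org_members <- map(setNames(orgs, orgs), function(o) {
      sort(c(multi[map_int(multi_orgs, ~ sum(.x == o)) > 0],
             singles[[o]] %||% character()))
    })
    ortholog_table <- bind_rows(map(orgs, function(o) {
      hs <- org_members[[o]]
      tibble(
        organism = o,
        source_gene = sprintf("%s_%s", tolower(o), tolower(hs)),
        human_symbol = hs
      )
    }))
    gene_lists <- bind_rows(
      tibble(organism = "HS", symbol = human),
      bind_rows(map(orgs, function(o) {
        tibble(
          organism = o,
          symbol = sprintf("%s_%s", tolower(o), tolower(org_members[[o]]))
        )
      }))
    )
    truth <- list(
      pooled = sort(c(multi, human_only)),
      multi = multi,
      human = human,
      overlap = length(intersect(multi, human)),
      union_m1 = length(unique(c(multi, unlist(singles)))),
      n_support_ge3 = sum(support >= 3)
    )
    stopifnot(
      identical(truth$pooled, sort(universe$aap)),
      truth$overlap == config$human_orth_overlap,
      length(truth$multi) == config$n_orth_multi
    )
    list(gene_lists = gene_lists, ortholog_table = ortholog_table,
         truth = truth)
  })
}

#' @noRd
power_law_degrees <- function(n, exponent, lo, hi) {
  support <- lo:hi
  probs <- support^(-exponent)
  sample(support, n, replace = TRUE, prob = probs / sum(probs))
}

#' Generate a planted drug-target network
#'
#' Drug degrees follow a truncated discrete power law. Every edge of a
#' planted drug lands on an AAP-encoded target with probability
#' `planted_aap_fraction`; null drugs hit AAP targets at the genomic
#' background rate `n_aap / n_genes`. Target accessions carry gene symbols
#' drawn from the universe (AAP targets from the AAP subset).
#'
#' @param config A [generator_config()].
#' @param universe Output of [gen_universe()] (regenerated if omitted).
#' @return List `net` (an annotated `dti_network`), `target_gene_map`,
#'   `truth` (planted ids, per-drug observed AAP counts, background rate).
#' @export
gen_dti_network <- function(config, universe = gen_universe(config)) {
  stopifnot(inherits(config, "generator_config"))
  with_seed(substream_seed(config$seed, "dti_network"), {
    drugs <- sprintf("NP%04d", seq_len(config$n_drugs))
    targets <- sprintf("T%05d", seq_len(config$n_targets))
    aap_targets <- targets[seq_len(config$n_aap_targets)]
    non_aap_targets <- setdiff(targets, aap_targets)
    syms <- c(
      sample(universe$aap, config$n_aap_targets),
      sample(setdiff(universe$genes, universe$aap),
             config$n_targets - config$n_aap_targets)
    )
    target_tbl <- tibble(
      target = targets, gene_symbol = syms,
      is_aap = targets %in% aap_targets
    )
    planted <- sort(sample(drugs, config$n_planted))
    background <- config$n_aap / config$n_genes
    degrees <- power_law_degrees(
      config$n_drugs, config$degree_exponent,
      config$min_degree, config$max_degree
    )
    edges <- map(seq_along(drugs), function(i) {
      d <- drugs[i]
      p_aap <- if (d %in% planted) config$planted_aap_fraction else
        background
      chosen <- character(0)
      for (e in seq_len(degrees[i])) {
        pool <- if (stats::runif(1) < p_aap) aap_targets else
          non_aap_targets
        pool <- setdiff(pool, chosen)
        if (length(pool) == 0L) {
          pool <- setdiff(targets, chosen)
        }
        chosen <- c(chosen, pool[sample.int(length(pool), 1L)])
      }
      tibble(drug = d, target = chosen)
    }) |>
      bind_rows()
    net <- build_dti_network(
      edges, provenance = "experimental",
      drugs = tibble(drug = drugs), targets = target_tbl
    )
    target_gene_map <- tibble(
      uniprot = target_tbl$target, gene_symbol = target_tbl$gene_symbol
    )
    x_by_drug <- tidy(net) |>
      group_by(.data$drug) |>
      summarise(x = sum(.data$is_aap), n = dplyr::n())
    degrees <- setNames(degrees, drugs)
    truth <- list(
      planted = planted,
      degrees = degrees,
      x_by_drug = x_by_drug,
      background_rate = background,
      planted_aap_fraction = config$planted_aap_fraction
    )
    # self-check: emitted truth must validate against the emitted network
    stopifnot(
      all(x_by_drug$n == degrees[x_by_drug$drug]),
      all(x_by_drug$n >= config$min_degree),
      all(x_by_drug$n <= config$max_degree)
    )
    list(net = net, target_gene_map = target_gene_map, truth = truth)
  })
}

#' Generate synthetic compounds and substructure profiles
#'
#' Compound structures are simple, unique, valid SMILES (n-alkanols of
#' increasing chain length; a few carry a sodium counter-ion so the
#' standardization path is exercised). Profiles are drawn over a synthetic
#' key dictionary: when `target_map` is given, every target is assigned
#' `keys_per_target` keys and a compound inherits its targets' keys with
#' probability `profile_fidelity` plus Poisson(`noise_key_rate`) random
#' keys -- compounds sharing targets therefore share keys, the premise of
#' substructure-mediated inference. Without a map, compounds draw
#' `profile_sharing` of their keys from a common pool and the rest from a
#' private range (so `profile_sharing = 0` yields pairwise disjoint
#' profiles).
#'
#' @param config A [generator_config()].
#' @param target_map Optional tibble `drug`, `target` (e.g. network edges).
#' @return List `compounds` (tibble `compound_id`, `smiles`), `profiles`
#'   (long tibble `compound_id`, `key`).
#' @export
gen_compounds <- function(config, target_map = NULL) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n_drugs
  if (n == 0L) {
    return(list(
      compounds = tibble(compound_id = character(), smiles = character()),
      profiles = tibble(compound_id = character(), key = character())
    ))
  }
  with_seed(substream_seed(config$seed, "compounds"), {
    ids <- sprintf("NP%04d", seq_len(n))
    smiles <- paste0(strrep("C", seq_len(n)), "O")
    salted <- seq_len(n) %% 10 == 0
    smiles[salted] <- paste0(
      sub("O$", "C(=O)[O-]", smiles[salted]), ".[Na+]"
    )
    keys <- sprintf("K%03d", seq_len(config$n_keys))
    if (!is.null(target_map)) {
      targets <- sort(unique(target_map$target))
      target_keys <- map(
        setNames(targets, targets),
        function(t) sample(keys, config$keys_per_target)
      )
      profiles <- map(ids, function(d) {
        tg <- target_map$target[target_map$drug == d]
        inherited <- unique(unlist(target_keys[tg], use.names = FALSE))
        inherited <- inherited[
          stats::runif(length(inherited)) < config$profile_fidelity
        ]
        noise <- sample(keys, min(rpois(1, config$noise_key_rate),
                                  length(keys)))
        ks <- unique(c(inherited, noise))
        if (length(ks) == 0L) return(NULL)
        tibble(compound_id = d, key = sort(ks))
      }) |>
        bind_rows()
    } else {
      shared_pool <- keys
      profiles <- map(seq_len(n), function(i) {
        k_shared <- stats::rbinom(1, 4, config$profile_sharing)
        ks <- character(0)
        if (k_shared > 0) ks <- sample(shared_pool, k_shared)
        n_priv <- 4 - k_shared
        if (n_priv > 0) {
          ks <- c(ks, sprintf("P%04d_%d", i, seq_len(n_priv)))
        }
        tibble(compound_id = ids[i], key = sort(unique(ks)))
      }) |>
        bind_rows()
    }
    list(
      compounds = tibble(compound_id = ids, smiles = smiles),
      profiles = profiles
    )
  })
}

#' Generate activity records with known pass/fail labels
#'
#' Emits one passing record per network edge (potency sampled below the
#' threshold; the very first record sits exactly on the threshold to pin
#' the inclusive boundary) plus `n_fail_per_criterion` records violating
#' each of the five filter criteria: (i) over-threshold or disallowed
#' activity type, (ii) non-human organism, (iii) missing accession,
#' (iv) unparsable SMILES, (v) carbon-free structure.
#'
#' @param config A [generator_config()].
#' @param net The `dti_network` the passing records must reproduce.
#' @param compounds Compound table from [gen_compounds()].
#' @return List `records` (activity-record tibble) and `truth` (tibble
#'   `index`, `pass`, `criterion`).
#' @export
gen_activity_records <- function(config, net, compounds) {
  stopifnot(inherits(config, "generator_config"))
  smiles_of <- setNames(compounds$smiles, compounds$compound_id)
  with_seed(substream_seed(config$seed, "activity_records"), {
    edges <- net$edges
    n_pass <- nrow(edges)
    types <- c("Ki", "Kd", "IC50", "EC50")
    pass <- tibble(
      compound_id = edges$drug,
      smiles = unname(smiles_of[edges$drug]),
      inchikey = NA_character_,
      uniprot = edges$target,
      organism = "Homo sapiens",
      activity_type = sample(types, n_pass, replace = TRUE),
      activity_value = 10^stats::runif(n_pass, -3, 1) *
        config$activity_threshold / 10,
      activity_units = "uM"
    )
    if (n_pass > 0) pass$activity_value[1] <- config$activity_threshold
    k <- config$n_fail_per_criterion
    some_smiles <- compounds$smiles[1]
    some_target <- net$targets$target[1]
    fail <- bind_rows(
      tibble(compound_id = "BAD_i_value", smiles = some_smiles,
             uniprot = some_target, organism = "Homo sapiens",
             activity_type = "Ki",
             activity_value = config$activity_threshold * 1.5 +
               seq_len(k)),
      tibble(compound_id = "BAD_ii", smiles = some_smiles,
             uniprot = some_target, organism = "Rattus norvegicus",
             activity_type = "IC50", activity_value = rep(1, k)),
      tibble(compound_id = "BAD_iii", smiles = some_smiles,
             uniprot = rep_len(c("", NA_character_), k),
             organism = "Homo sapiens",
             activity_type = "IC50", activity_value = rep(1, k)),
      tibble(compound_id = "BAD_iv", smiles = "not_a_smiles((",
             uniprot = some_target, organism = "Homo sapiens",
             activity_type = "IC50", activity_value = rep(1, k)),
      tibble(compound_id = "BAD_v", smiles = "[Na+].[Cl-]",
             uniprot = some_target, organism = "Homo sapiens",
             activity_type = "IC50", activity_value = rep(1, k))
    ) |>
      mutate(inchikey = NA_character_, activity_units = "uM")
    crit <- rep(c("i", "ii", "iii", "iv", "v"), each = k)
    records <- bind_rows(pass, fail)
    truth <- tibble(
      index = seq_len(nrow(records)),
      pass = c(rep(TRUE, n_pass), rep(FALSE, nrow(fail))),
      criterion = c(rep(NA_character_, n_pass), crit)
    )
    list(records = records, truth = truth)
  })
}

#' Materialize a complete synthetic study on disk
#'
#' Runs every generator with a shared configuration and writes the files
#' the pipeline reads: `gene_lists.tsv`, `orthologs.tsv`,
#' `activity_records.csv`, `target_gene_map.tsv`, `profiles.tsv`, plus
#' `truth.json` with the planted ground truth.
#'
#' @param config A [generator_config()].
#' @param dir Output directory (created if missing).
#' @return Invisible list: file `paths`, the generated objects and the
#'   combined `truth`.
#' @export
simulate_study <- function(config = generator_config(), dir) {
  stopifnot(inherits(config, "generator_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  universe <- gen_universe(config)
  curation <- gen_ortholog_catalog(config, universe)
  network <- gen_dti_network(config, universe)
  compounds <- gen_compounds(config, target_map = network$net$edges)
  activity <- gen_activity_records(config, network$net,
                                   compounds$compounds)
  paths <- list(
    gene_lists = file.path(dir, "gene_lists.tsv"),
    orthologs = file.path(dir, "orthologs.tsv"),
    activity_records = file.path(dir, "activity_records.csv"),
    target_gene_map = file.path(dir, "target_gene_map.tsv"),
    profiles = file.path(dir, "profiles.tsv"),
    truth = file.path(dir, "truth.json")
  )
  readr::write_tsv(curation$gene_lists, paths$gene_lists,
                   col_names = FALSE)
  readr::write_tsv(curation$ortholog_table, paths$orthologs,
                   col_names = FALSE)
  readr::write_csv(activity$records, paths$activity_records, na = "")
  readr::write_tsv(network$target_gene_map, paths$target_gene_map)
  write_profiles(compounds$profiles, paths$profiles)
  truth <- list(
    curation = curation$truth[c("overlap", "union_m1", "n_support_ge3")],
    n_pooled = length(curation$truth$pooled),
    n_multi = length(curation$truth$multi),
    planted = network$truth$planted,
    background_rate = network$truth$background_rate,
    planted_aap_fraction = network$truth$planted_aap_fraction,
    n_pass_records = sum(activity$truth$pass),
    n_fail_records = sum(!activity$truth$pass)
  )
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(list(
    paths = paths, universe = universe, curation = curation,
    network = network, compounds = compounds, activity = activity,
    truth = truth
  ))
}
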