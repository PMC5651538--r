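#' Pipeline configuration
#'
#' Collects the input paths, stage parameters and stage toggles of a full
#' curation -> network -> inference -> scoring run. Defaults mirror the
#' published analysis parameters (10 uM potency threshold, alpha = beta =
#' 0.1, gamma = -0.5, k = 2, top 20 candidates, 100,000 permutations over
#' a 20,462-gene universe).
#'
#' @param gene_lists,orthologs,activity_records,target_gene_map,profiles
#'   Input file paths (see the `read_*` readers for formats).
#' @param out_dir Output directory for stage artifacts.
#' @param seed Seed propagated to every stochastic stage.
#' @param min_organisms Non-human organism support required of an
#'   orthologous AAG.
#' @param threshold,organism Activity-filter parameters.
#' @param standardize Run structure standardization during filtering.
#' @param inference `TRUE` scores the merged experimental + predicted
#'   network ("ExpNet&ComNet"); `FALSE` skips target inference and scores
#'   the experimental network alone ("ExpNet only").
#' @param infer An [inference_params()] object.
#' @param perm A [permutation_config()]; its seed is overridden by `seed`.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(gene_lists, orthologs, activity_records,
                            target_gene_map, profiles = NULL,
                            out_dir = tempfile("senopharm_run"),
                            seed = 1, min_organisms = 2,
                            threshold = 10, organism = "Homo sapiens",
                            standardize = TRUE, inference = TRUE,
                            infer = inference_params(),
                            perm = permutation_config()) {
  cfg <- list(
    gene_lists = gene_lists, orthologs = orthologs,
    activity_records = activity_records,
    target_gene_map = target_gene_map, profiles = profiles,
    out_dir = out_dir, seed = seed, min_organisms = min_organisms,
    threshold = threshold, organism = organism,
    standardize = isTRUE(standardize), inference = isTRUE(inference),
    infer = infer, perm = perm
  )
  cfg$perm$seed <- seed
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; nested
#' `infer:` and `perm:` blocks override individual diffusion/permutation
#' parameters.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  infer <- do.call(inference_params, y$infer %||% list())
  perm <- do.call(permutation_config, y$perm %||% list())
  y$infer <- NULL
  y$perm <- NULL
  do.call(pipeline_config, c(y, list(infer = infer, perm = perm)))
}

#' Run the full prioritization pipeline
#'
#' Executes the four stages in order: (A) curate the AAG/AAP set from
#' per-organism gene lists and the ortholog table; (B) filter activity
#' records and build the experimental DTI network with AAP annotation;
#' (C) predict new targets by tripartite resource diffusion and merge
#' them in (skipped when `config$inference` is `FALSE`); (D) score every
#' drug's anti-aging indication by genome-wide permutation. Identical
#' configuration and seed give byte-identical outputs; the stage toggle
#' never alters upstream artifacts.
#'
#' @param config A [pipeline_config()].
#' @return List of class `run_report`: per-stage counts, the scored
#'   table (`scores`), the networks, the config echo and elapsed time.
#'   Artifacts are written under `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }

  # A: curation
  curated <- stage("curate", {
    lists <- read_gene_lists(config$gene_lists)
    orth_tab <- read_ortholog_table(config$orthologs)
    human <- lists$symbol[lists$organism == "HS"]
    orth_sets <- map(
      setNames(nm = intersect(unique(lists$organism),
                              setdiff(ORGANISMS, "HS"))),
      function(o) {
        map_to_human_orthologs(
          lists$symbol[lists$organism == o], o, orth_tab
        )
      }
    )
    catalog <- build_aag_catalog(human, orth_sets)
    orth <- filter_by_organism_support(catalog, config$min_organisms)
    pooled <- pool_aag_sets(orth, human)
    write_aag_catalog(catalog, file.path(config$out_dir,
                                         "aag_catalog.tsv"))
    list(catalog = catalog, human = unique(norm_symbol(human)),
         orth = orth, pooled = pooled)
  })

  # B: experimental network
  built <- stage("build-net", {
    records <- read_activity_records(config$activity_records)
    kept <- filter_activity_records(
      records, threshold = config$threshold,
      organism = config$organism, standardize = config$standardize
    )
    readr::write_tsv(rejection_log(kept),
                     file.path(config$out_dir, "rejections.tsv"))
    gene_map <- read_target_gene_map(config$target_gene_map)
    net <- dti_from_records(kept) |>
      annotate_aap_targets(curated$pooled, gene_map)
    export_network(net, file.path(config$out_dir,
                                  "network_experimental.tsv"),
                   format = "edge_tsv")
    list(records = records, kept = kept, net = net)
  })

  # C: inference (optional)
  inferred <- if (config$inference) {
    stage("predict", {
      profiles <- if (!is.null(config$profiles)) {
        read_profiles(config$profiles)
      } else {
        tibble(compound_id = character(), key = character())
      }
      preds <- predict_dti_network(built$net, profiles,
                                   params = config$infer)
      readr::write_tsv(preds,
                       file.path(config$out_dir, "predictions.tsv"))
      pred_net <- build_dti_network(
        preds |> select("drug", "target", "score"),
        provenance = "predicted",
        drugs = built$net$drugs, targets = built$net$targets
      )
      merged <- merge_networks(built$net, pred_net)
      export_network(merged,
                     file.path(config$out_dir, "network_merged.tsv"),
                     format = "edge_tsv")
      list(predictions = preds, net = merged)
    })
  } else {
    list(predictions = tibble(), net = built$net)
  }

  # D: scoring
  scores <- stage("score", {
    profiles <- tidy(inferred$net) |>
      transmute(drug = .data$drug, gene_symbol = .data$gene_symbol)
    s <- prioritize_indications(
      profiles, curated$pooled, config = config$perm,
      all_drugs = inferred$net$drugs$drug
    )
    readr::write_tsv(tidy(s),
                     file.path(config$out_dir, "indication_scores.tsv"))
    s
  })

  rej <- rejection_log(built$kept)
  report <- list(
    counts = list(
      genes_catalog = nrow(curated$catalog),
      genes_orthologous = length(curated$orth),
      genes_human = length(curated$human),
      genes_pooled = length(curated$pooled),
      records_in = nrow(built$records),
      records_kept = nrow(built$kept),
      records_rejected = nrow(rej),
      rejected_by_criterion = as.list(table(rej$criterion)),
      edges_experimental = nrow(built$net$edges),
      edges_predicted = nrow(inferred$predictions),
      edges_total = nrow(inferred$net$edges),
      aap_targets = sum(inferred$net$targets$is_aap %in% TRUE),
      drugs_scored = nrow(scores),
      significant_q05 = sum(scores$q_value < 0.05)
    ),
    config = list(
      seed = config$seed, min_organisms = config$min_organisms,
      threshold = config$threshold, organism = config$organism,
      inference = config$inference,
      infer = unclass(config$infer), perm = unclass(config$perm)
    ),
    versions = list(
      senopharm = as.character(utils::packageVersion("senopharm")),
      r = paste(R.version$major, R.version$minor, sep = ".")
    ),
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  jsonlite::write_json(
    report, file.path(config$out_dir, "report.json"),
    auto_unbox = TRUE, digits = NA
  )
  out <- c(report, list(
    scores = scores, net_experimental = built$net, net = inferred$net,
    curated = curated
  ))
  class(out) <- "run_report"
  out
}

#' @export
print.run_report <- function(x, ...) {
  cat("Pipeline run report\n")
  for (nm in names(x$counts)) {
    v <- x$counts[[nm]]
    if (is.list(v)) v <- paste(names(v), unlist(v), sep = "=", collapse = " ")
    cat(sprintf("  %-22s %s\n", nm, paste(v, collapse = " ")))
  }
  invisible(x)
}

#' Export a DTI network
#'
#' `edge_tsv` writes a lossless edge list (drug, target, gene symbol, AAP
#' flag, provenance, activity, score) that [read_network_edges()] restores
#' exactly; `graphml` writes a Cytoscape-importable graph with node
#' attributes `type`, `gene_symbol`, `aap`, `degree` and edge attribute
#' `provenance`.
#'
#' @param net A non-empty `dti_network`.
#' @param path Output file path.
#' @param format `"edge_tsv"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path, format = c("edge_tsv", "graphml")) {
  stopifnot(inherits(net, "dti_network"))
  format <- match.arg(format)
  assert_that(nrow(net$edges) > 0, "refusing to export an empty network")
  if (format == "edge_tsv") {
    readr::write_tsv(tidy(net), path, na = "NA")
  } else {
    g <- as_igraph(net)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Convert a DTI network to an igraph object
#'
#' @param net A `dti_network`.
#' @return An undirected [igraph::graph] with typed, annotated nodes.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "dti_network"))
  nodes <- bind_rows(
    tibble(name = net$drugs$drug, type = "drug",
           gene_symbol = NA_character_, aap = FALSE),
    tibble(name = net$targets$target, type = "target",
           gene_symbol = net$targets$gene_symbol,
           aap = net$targets$is_aap %in% TRUE)
  )
  deg <- table(c(net$edges$drug, net$edges$target))
  nodes$degree <- as.integer(deg[nodes$name])
  nodes$degree[is.na(nodes$degree)] <- 0L
  igraph::graph_from_data_frame(
    net$edges |> select("drug", "target", "provenance"),
    directed = FALSE, vertices = nodes
  )
}

#' Restore a DTI network from an exported edge TSV
#'
#' @param path File written by [export_network()] with `format =
#'   "edge_tsv"`.
#' @return A `dti_network`.
#' @export
read_network_edges <- function(path) {
  x <- readr::read_tsv(
    path,
    col_types = readr::cols(
      drug = "c", target = "c", gene_symbol = "c", is_aap = "l",
      provenance = "c", activity = "d", score = "d"
    ),
    na = "NA", progress = FALSE
  )
  structure(
    list(
      drugs = tibble(drug = sort(unique(x$drug))),
      targets = x |>
        distinct(.data$target, .data$gene_symbol, .data$is_aap) |>
        arrange(.data$target),
      edges = x |>
        select("drug", "target", "provenance", "activity", "score") |>
        arrange(.data$drug, .data$target)
    ),
    class = "dti_network"
  )
}
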