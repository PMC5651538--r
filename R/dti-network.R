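#' Filter raw bioactivity records into high-quality DTIs
#'
#' Applies, in order, the five quality criteria used to build the
#' experimental drug-target network: (i) activity type in Ki, Kd, IC50,
#' EC50 with value <= `threshold` micromolar (boundary inclusive); (ii)
#' target organism exactly `organism` after trimming and case folding;
#' (iii) a non-empty UniProt accession; (iv) the structure standardizes to
#' canonical SMILES ([standardize_structures()]); (v) the standardized
#' structure contains at least one carbon atom. Each rejected record is
#' logged with the first criterion it failed.
#'
#' @param records Activity-record tibble (see [read_activity_records()]):
#'   columns `compound_id`, `smiles`, `uniprot`, `organism`,
#'   `activity_type`, `activity_value` (micromolar).
#' @param threshold Potency cutoff in micromolar; default 10.
#' @param organism Required target organism; default `"Homo sapiens"`.
#' @param standardize If `FALSE`, skip chemistry (criteria iv/v); records
#'   must then already carry `canonical_smiles` and `inchikey` columns.
#' @return Tibble of kept records with `canonical_smiles` and `inchikey`
#'   columns added; the rejection log (tibble `index`, `compound_id`,
#'   `criterion`) is attached as attribute `"rejections"` and available via
#'   [rejection_log()].
#' @export
filter_activity_records <- function(records, threshold = 10,
                                    organism = "Homo sapiens",
                                    standardize = TRUE) {
  assert_that(threshold > 0, "`threshold` must be positive")
  allowed_types <- c("KI", "KD", "IC50", "EC50")
  n <- nrow(records)
  fail <- rep(NA_character_, n)

  type_ok <- toupper(trimws(records$activity_type)) %in% allowed_types
  value_ok <- is.finite(records$activity_value) &
    records$activity_value > 0 & records$activity_value <= threshold
  fail[is.na(fail) & !(type_ok & value_ok)] <- "i"

  org_ok <- tolower(trimws(records$organism)) ==
    tolower(trimws(organism))
  org_ok[is.na(org_ok)] <- FALSE
  fail[is.na(fail) & !org_ok] <- "ii"

  acc_ok <- !is.na(records$uniprot) & nzchar(trimws(records$uniprot))
  fail[is.na(fail) & !acc_ok] <- "iii"

  if (standardize) {
    todo <- which(is.na(fail))
    std <- standardize_structures(records$smiles[todo])
    records$canonical_smiles <- NA_character_
    records$inchikey <- NA_character_
    records$canonical_smiles[todo] <- std$canonical_smiles
    records$inchikey[todo] <- std$inchikey
    fail[todo[std$status == "unparsable"]] <- "iv"
    fail[todo[std$status == "no_carbon"]] <- "v"
  } else {
    assert_that(
      all(c("canonical_smiles", "inchikey") %in% names(records)),
      "`standardize = FALSE` requires canonical_smiles and inchikey columns"
    )
  }

  kept <- records[is.na(fail), , drop = FALSE]
  rejections <- tibble(
    index = which(!is.na(fail)),
    compound_id = records$compound_id[!is.na(fail)],
    criterion = fail[!is.na(fail)]
  )
  attr(kept, "rejections") <- rejections
  kept
}

#' Rejection log of a filtered record set
#' @param x Result of [filter_activity_records()].
#' @return Tibble `index`, `compound_id`, `criterion`.
#' @export
rejection_log <- function(x) {
  attr(x, "rejections") %||%
    tibble(index = integer(), compound_id = character(),
           criterion = character())
}

#' Deduplicate compounds by InChIKey
#'
#' One compound per InChIKey; the first-seen `compound_id` becomes the
#' representative and later ids are recorded as aliases.
#'
#' @param records Standardized records with `compound_id`,
#'   `canonical_smiles`, `inchikey` columns.
#' @return Tibble `compound_id`, `canonical_smiles`, `inchikey`, `aliases`
#'   (list column of all ids sharing the key).
#' @export
dedup_compounds <- function(records) {
  if (nrow(records) == 0L) {
    return(tibble(
      compound_id = character(), canonical_smiles = character(),
      inchikey = character(), aliases = list()
    ))
  }
  assert_that(
    all(c("compound_id", "canonical_smiles", "inchikey") %in%
          names(records)),
    "records must be standardized first (canonical_smiles, inchikey)"
  )
  records |>
    mutate(.row = dplyr::row_number()) |>
    group_by(.data$inchikey) |>
    summarise(
      aliases = list(unique(.data$compound_id)),
      canonical_smiles = .data$canonical_smiles[which.min(.data$.row)],
      compound_id = .data$compound_id[which.min(.data$.row)],
      .groups = "drop"
    ) |>
    select("compound_id", "canonical_smiles", "inchikey", "aliases") |>
    arrange(.data$compound_id)
}

#' Construct a bipartite drug-target network
#'
#' @param edges Tibble with columns `drug`, `target`, optional `activity`
#'   (micromolar). Duplicate pairs collapse to one edge carrying the most
#'   potent (smallest) activity.
#' @param provenance `"experimental"` or `"predicted"`, stamped on every
#'   edge.
#' @param drugs,targets Optional node tibbles (`drug`; `target` with
#'   optional `gene_symbol`, `is_aap`). When supplied, every edge endpoint
#'   must appear in them; unknown endpoints are an error. Defaults are
#'   derived from the edges.
#' @return A `dti_network`: list of tibbles `drugs`, `targets`, `edges`
#'   (with `provenance`, `activity`, `score` columns).
#' @export
build_dti_network <- function(edges, provenance = "experimental",
                              drugs = NULL, targets = NULL) {
  assert_that(
    all(c("drug", "target") %in% names(edges)),
    "`edges` needs columns drug, target"
  )
  assert_that(
    provenance %in% c("experimental", "predicted"),
    "`provenance` must be 'experimental' or 'predicted'"
  )
  edges <- as_tibble(edges)
  if (!"activity" %in% names(edges)) edges$activity <- NA_real_
  if (!"score" %in% names(edges)) edges$score <- NA_real_
  if (is.null(drugs)) {
    drugs <- tibble(drug = sort(unique(edges$drug)))
  } else {
    drugs <- as_tibble(drugs)
    dangling <- setdiff(edges$drug, drugs$drug)
    assert_that(
      length(dangling) == 0L,
      paste("edges reference unknown drugs:",
            paste(head(dangling, 5), collapse = ", "))
    )
  }
  if (is.null(targets)) {
    targets <- tibble(target = sort(unique(edges$target)))
  } else {
    targets <- as_tibble(targets)
    dangling <- setdiff(edges$target, targets$target)
    assert_that(
      length(dangling) == 0L,
      paste("edges reference unknown targets:",
            paste(head(dangling, 5), collapse = ", "))
    )
  }
  if (!"gene_symbol" %in% names(targets)) {
    targets$gene_symbol <- NA_character_
  }
  if (!"is_aap" %in% names(targets)) targets$is_aap <- NA
  edges <- edges |>
    group_by(.data$drug, .data$target) |>
    summarise(
      activity = if (all(is.na(.data$activity))) NA_real_ else
        min(.data$activity, na.rm = TRUE),
      score = if (all(is.na(.data$score))) NA_real_ else
        max(.data$score, na.rm = TRUE),
      .groups = "drop"
    ) |>
    mutate(provenance = provenance) |>
    select("drug", "target", "provenance", "activity", "score") |>
    arrange(.data$drug, .data$target)
  structure(
    list(drugs = drugs, targets = targets, edges = edges),
    class = "dti_network"
  )
}

#' Build a DTI network directly from filtered activity records
#'
#' Deduplicates compounds by InChIKey ([dedup_compounds()]), maps every
#' record to its representative compound id, and assembles the
#' experimental network keeping the most potent activity per (drug,
#' target) pair.
#'
#' @param kept Output of [filter_activity_records()].
#' @return A `dti_network` with attribute `"compounds"` (the dedup table).
#' @export
dti_from_records <- function(kept) {
  comp <- dedup_compounds(kept)
  alias_map <- comp |>
    select("compound_id", "aliases") |>
    tidyr::unnest("aliases") |>
    rename(rep_id = "compound_id", compound_id = "aliases")
  edges <- kept |>
    left_join(alias_map, by = "compound_id") |>
    transmute(
      drug = .data$rep_id, target = trimws(.data$uniprot),
      activity = .data$activity_value
    )
  net <- build_dti_network(edges, provenance = "experimental")
  attr(net, "compounds") <- comp
  net
}

#' Merge two DTI networks
#'
#' Edge set union; an edge present in both inputs carries both provenance
#' labels (sorted, semicolon-joined) and the most potent activity / best
#' score seen. Node annotations (gene symbols, AAP flags) are combined with
#' the first network taking precedence. The operation is symmetric in its
#' edge and node sets.
#'
#' @param a,b `dti_network` objects.
#' @return Merged `dti_network`.
#' @export
merge_networks <- function(a, b) {
  stopifnot(inherits(a, "dti_network"), inherits(b, "dti_network"))
  edges <- bind_rows(a$edges, b$edges) |>
    tidyr::separate_rows("provenance", sep = ";") |>
    group_by(.data$drug, .data$target) |>
    summarise(
      provenance = paste(sort(unique(.data$provenance)), collapse = ";"),
      activity = if (all(is.na(.data$activity))) NA_real_ else
        min(.data$activity, na.rm = TRUE),
      score = if (all(is.na(.data$score))) NA_real_ else
        max(.data$score, na.rm = TRUE),
      .groups = "drop"
    ) |>
    arrange(.data$drug, .data$target)
  combine_nodes <- function(x, y, id) {
    bind_rows(x, y) |>
      group_by(.data[[id]]) |>
      slice(1L) |>
      ungroup() |>
      arrange(.data[[id]])
  }
  structure(
    list(
      drugs = combine_nodes(a$drugs, b$drugs, "drug"),
      targets = combine_nodes(a$targets, b$targets, "target"),
      edges = edges
    ),
    class = "dti_network"
  )
}

#' Network statistics of a DTI network
#'
#' Node/edge counts, sparsity and degree distributions. Sparsity is
#' `100 * edges / (drugs * targets)`; `sparsity_pct` is the 2-decimal
#' value truncated toward zero (the convention of the printed summary
#' tables this mirrors), `sparsity` the full-precision percentage.
#'
#' @param net A `dti_network` with at least one drug, target and edge.
#' @return List of class `network_stats`: `n_drugs`, `n_targets`,
#'   `n_aap_targets`, `n_edges`, `sparsity`, `sparsity_pct`,
#'   `mean_drug_degree`, `drug_degrees` and `target_degrees` tibbles.
#' @export
network_stats <- function(net) {
  stopifnot(inherits(net, "dti_network"))
  nd <- nrow(net$drugs)
  nt <- nrow(net$targets)
  ne <- nrow(net$edges)
  assert_that(nd >= 1 && nt >= 1 && ne >= 1, "network is empty")
  dd <- net$edges |> count(.data$drug, name = "degree")
  dd <- net$drugs |>
    left_join(dd, by = "drug") |>
    mutate(degree = ifelse(is.na(.data$degree), 0L, .data$degree))
  td <- net$edges |> count(.data$target, name = "degree")
  td <- net$targets |>
    select("target") |>
    left_join(td, by = "target") |>
    mutate(degree = ifelse(is.na(.data$degree), 0L, .data$degree))
  sparsity <- 100 * ne / (nd * nt)
  structure(
    list(
      n_drugs = nd, n_targets = nt,
      n_aap_targets = sum(net$targets$is_aap %in% TRUE),
      n_edges = ne,
      sparsity = sparsity,
      sparsity_pct = trunc(sparsity * 100) / 100,
      mean_drug_degree = ne / nd,
      drug_degrees = dd,
      target_degrees = td
    ),
    class = "network_stats"
  )
}

#' Flag aging-associated protein (AAP) targets
#'
#' Maps target accessions to gene symbols and flags each target whose
#' symbol is in the supplied AAG set. Targets without a mapping are flagged
#' `FALSE` with a warning.
#'
#' @param net A `dti_network`.
#' @param aag_symbols Character vector of AAG gene symbols.
#' @param target_gene_map Tibble `uniprot`, `gene_symbol`.
#' @return The network with `gene_symbol` and `is_aap` filled on its
#'   target table.
#' @export
annotate_aap_targets <- function(net, aag_symbols, target_gene_map) {
  stopifnot(inherits(net, "dti_network"))
  aag <- unique(norm_symbol(aag_symbols))
  map_tbl <- target_gene_map |>
    transmute(
      target = trimws(.data$uniprot),
      .sym = norm_symbol(.data$gene_symbol)
    ) |>
    distinct(.data$target, .keep_all = TRUE)
  targets <- net$targets |>
    left_join(map_tbl, by = "target") |>
    mutate(
      gene_symbol = coalesce(.data$.sym, .data$gene_symbol),
      is_aap = !is.na(.data$gene_symbol) & .data$gene_symbol %in% aag
    ) |>
    select(-".sym")
  n_unmapped <- sum(is.na(targets$gene_symbol))
  if (n_unmapped > 0) {
    warn(sprintf(
      "%d target(s) without a gene-symbol mapping flagged as non-AAP",
      n_unmapped
    ))
  }
  net$targets <- targets
  net
}

#' Induced subnetwork around selected drugs
#'
#' Keeps the given drugs, all their target neighbours and the edges
#' between them; provenance, activities and AAP flags are preserved.
#'
#' @param net A `dti_network`.
#' @param drug_ids Character vector of drug ids present in the network.
#' @return A `dti_network`.
#' @export
extract_drug_subnetwork <- function(net, drug_ids) {
  stopifnot(inherits(net, "dti_network"))
  unknown <- setdiff(drug_ids, net$drugs$drug)
  assert_that(
    length(unknown) == 0L,
    paste("unknown drug id(s):", paste(unknown, collapse = ", "))
  )
  edges <- net$edges |> filter(.data$drug %in% drug_ids)
  structure(
    list(
      drugs = net$drugs |> filter(.data$drug %in% drug_ids),
      targets = net$targets |> filter(.data$target %in% edges$target),
      edges = edges
    ),
    class = "dti_network"
  )
}

#' @export
print.dti_network <- function(x, ...) {
  cat(sprintf(
    "DTI network: %d drugs, %d targets (%d AAP), %d edges\n",
    nrow(x$drugs), nrow(x$targets), sum(x$targets$is_aap %in% TRUE),
    nrow(x$edges)
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname network_stats
#' @param x A `dti_network`.
#' @param ... Unused.
#' @export
tidy.dti_network <- function(x, ...) {
  x$edges |>
    left_join(
      x$targets |> select("target", "gene_symbol", "is_aap"),
      by = "target"
    )
}

#' @rdname network_stats
#' @export
glance.dti_network <- function(x, ...) {
  s <- network_stats(x)
  tibble(
    n_drugs = s$n_drugs, n_targets = s$n_targets,
    n_aap_targets = s$n_aap_targets, n_edges = s$n_edges,
    sparsity_pct = s$sparsity_pct,
    mean_drug_degree = s$mean_drug_degree
  )
}

#' @importFrom ggplot2 geom_histogram scale_x_log10
#' @export
autoplot.dti_network <- function(object, ...) {
  s <- network_stats(object)
  ggplot(s$drug_degrees, aes(x = .data$degree)) +
    geom_histogram(bins = 30) +
    scale_x_log10() +
    labs(
      x = "drug degree (targets per compound)", y = "compounds",
      title = "Drug connectivity distribution"
    )
}
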