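#' Map a non-human gene list to human ortholog symbols
#'
#' Translates gene identifiers from one of the four non-human model
#' organisms (CE, DM, MM, SC) to human gene symbols through an ortholog
#' table. One source gene may map to several human symbols; all mappings
#' are kept and the result is deduplicated. Genes without any mapping are
#' dropped -- they contribute no human-orthologous evidence.
#'
#' @param genes Character vector of source-organism gene identifiers.
#' @param organism Organism code, one of `"CE"`, `"DM"`, `"MM"`, `"SC"`.
#' @param ortholog_table Data frame with columns `organism`, `source_gene`,
#'   `human_symbol` (see [read_ortholog_table()]).
#' @return Character vector of unique upper-cased human gene symbols.
#' @examples
#' tab <- tibble::tibble(
#'   organism = "CE", source_gene = c("daf-2", "daf-16"),
#'   human_symbol = c("IGF1R", "FOXO3")
#' )
#' map_to_human_orthologs(c("daf-2", "daf-16"), "CE", tab)
#' @export
map_to_human_orthologs <- function(genes, organism, ortholog_table) {
  check_organism(organism, allow_hs = FALSE)
  assert_that(
    all(c("organism", "source_gene", "human_symbol") %in%
          names(ortholog_table)),
    "`ortholog_table` needs columns organism, source_gene, human_symbol"
  )
  genes <- norm_symbol(genes)
  hits <- ortholog_table |>
    filter(
      toupper(trimws(.data$organism)) == !!organism,
      norm_symbol(.data$source_gene) %in% genes
    )
  sort(unique(norm_symbol(hits$human_symbol)))
}

#' Build the pooled aging-associated gene (AAG) catalogue
#'
#' Combines a human AAG list with per-organism sets of human-orthologous
#' AAGs (already mapped to human symbols, e.g. by
#' [map_to_human_orthologs()]). Each catalogue entry records which
#' organisms support it; `support` counts only the four non-human
#' organisms, matching the "identified in at least m non-human organisms"
#' filter used downstream.
#'
#' @param human_genes Character vector of human AAG symbols (HS evidence).
#' @param ortholog_sets Named list keyed by a subset of
#'   `c("CE","DM","MM","SC")`; each element a character vector of human
#'   symbols with evidence in that organism.
#' @return A tibble of class `aag_catalog` with columns `symbol`, one
#'   logical column per organism (`HS`, `CE`, `DM`, `MM`, `SC`) and the
#'   non-human `support` count (0--4).
#' @examples
#' build_aag_catalog("SIRT1", list(CE = c("SIRT1", "FOXO3"), MM = "SIRT1"))
#' @export
build_aag_catalog <- function(human_genes = character(),
                              ortholog_sets = list()) {
  assert_that(
    all(names(ortholog_sets) %in% setdiff(ORGANISMS, "HS")),
    "`ortholog_sets` must be keyed by a subset of CE, DM, MM, SC"
  )
  evidence <- c(
    list(HS = norm_symbol(human_genes)),
    map(ortholog_sets, norm_symbol)
  )
  symbols <- sort(unique(unlist(evidence, use.names = FALSE)))
  cat <- tibble(symbol = symbols)
  for (org in ORGANISMS) {
    cat[[org]] <- symbols %in% (evidence[[org]] %||% character())
  }
  cat$support <- as.integer(rowSums(cat[setdiff(ORGANISMS, "HS")]))
  class(cat) <- c("aag_catalog", class(cat))
  cat
}

#' Filter catalogue entries by non-human organism support
#'
#' Returns the human-orthologous AAG symbols reported in at least
#' `min_organisms` of the four non-human organisms. Human (HS) evidence is
#' deliberately not counted: the filter selects genes whose aging
#' association replicates across model organisms.
#'
#' @param catalog An `aag_catalog` from [build_aag_catalog()].
#' @param min_organisms Integer in 1..4; default 2.
#' @return Sorted character vector of symbols.
#' @export
filter_by_organism_support <- function(catalog, min_organisms = 2) {
  assert_that(
    length(min_organisms) == 1L && min_organisms >= 1 && min_organisms <= 4,
    "`min_organisms` must be a single integer in [1, 4]"
  )
  assert_that(
    all(c("symbol", "support") %in% names(catalog)),
    "`catalog` must be an aag_catalog (columns symbol, support)"
  )
  sort(catalog$symbol[catalog$support >= min_organisms])
}

#' Pool two gene sets by union
#'
#' The final AAG set is the union of the cross-organism-supported
#' orthologous set and the human set; `|A| + |B| - |A intersect B|` genes.
#'
#' @param orthologous_set,human_set Character vectors of gene symbols.
#' @return Sorted character vector, the deduplicated union.
#' @export
pool_aag_sets <- function(orthologous_set, human_set) {
  sort(union(norm_symbol(orthologous_set), norm_symbol(human_set)))
}

#' Over-representation test for the overlap of two gene sets
#'
#' One-sided hypergeometric tail probability (Fisher's exact test for
#' over-representation) of observing at least the actual overlap between
#' two sets drawn from a common gene universe, plus the sample odds ratio
#' of the 2x2 classification table.
#'
#' @param set_a,set_b Character vectors of gene symbols.
#' @param universe_size Number of genes in the background universe; default
#'   20462, the NCBI protein-coding gene count used throughout.
#' @return One-row tibble: `overlap`, `n_a`, `n_b`, `universe`, `p_value`,
#'   `odds_ratio`.
#' @export
overlap_enrichment <- function(set_a, set_b, universe_size = 20462) {
  a <- unique(norm_symbol(set_a))
  b <- unique(norm_symbol(set_b))
  k <- length(intersect(a, b))
  na <- length(a)
  nb <- length(b)
  assert_that(
    universe_size >= na && universe_size >= nb,
    "`universe_size` smaller than a set"
  )
  assert_that(
    universe_size >= na + nb - k,
    "`universe_size` cannot hold both sets with the observed overlap"
  )
  p <- phyper(k - 1, na, universe_size - na, nb, lower.tail = FALSE)
  d <- universe_size - na - nb + k
  or <- (k * d) / ((na - k) * (nb - k))
  tibble(
    overlap = k, n_a = na, n_b = nb, universe = universe_size,
    p_value = p, odds_ratio = or
  )
}

#' Hypergeometric enrichment of a gene set against named collections
#'
#' Generic gene-set over-representation analysis: each term in `collections`
#' (e.g. read from a GMT file with [read_gmt()]) is tested against the query
#' with the same one-sided hypergeometric tail as [overlap_enrichment()],
#' and p-values are corrected across terms with [bh_adjust()].
#'
#' @param genes Character vector, the query gene set.
#' @param collections Named list of character vectors (term -> member genes).
#' @param universe_size Background universe size; default 20462.
#' @return Tibble with one row per term: `term`, `n_term`, `overlap`,
#'   `p_value`, `q_value`, sorted by ascending p.
#' @export
enrich_gene_sets <- function(genes, collections, universe_size = 20462) {
  assert_that(
    is.list(collections) && !is.null(names(collections)) &&
      all(lengths(collections) > 0),
    "`collections` must be a named list of non-empty gene sets"
  )
  genes <- unique(norm_symbol(genes))
  if (length(genes) == 0L) {
    warn("empty query gene set; returning an empty enrichment table")
    return(tibble(
      term = character(), n_term = integer(), overlap = integer(),
      p_value = double(), q_value = double()
    ))
  }
  res <- imap(collections, function(members, term) {
    e <- overlap_enrichment(genes, members, universe_size)
    tibble(
      term = term, n_term = e$n_b, overlap = e$overlap, p_value = e$p_value
    )
  }) |>
    bind_rows()
  res$q_value <- bh_adjust(res$p_value)
  arrange(res, .data$p_value, .data$term)
}

#' @export
print.aag_catalog <- function(x, ...) {
  cat(sprintf(
    "AAG catalogue: %d genes (%d with >=2 non-human organisms)\n",
    nrow(x), sum(x$support >= 2)
  ))
  NextMethod()
}

#' @importFrom ggplot2 autoplot ggplot aes geom_col labs
#' @export
autoplot.aag_catalog <- function(object, ...) {
  counts <- object |>
    count(.data$support) |>
    mutate(support = factor(.data$support, levels = 0:4))
  ggplot(counts, aes(x = .data$support, y = .data$n)) +
    geom_col() +
    labs(
      x = "non-human organisms with evidence",
      y = "genes",
      title = "AAG catalogue organism support"
    )
}
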