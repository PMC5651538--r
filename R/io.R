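#' Read per-organism gene lists
#'
#' Two-column TSV `organism<TAB>symbol`, `#` comments allowed, no header.
#'
#' @param path File path.
#' @return Tibble with columns `organism`, `symbol`.
#' @export
read_gene_lists <- function(path) {
  x <- readr::read_tsv(
    path,
    col_names = c("organism", "symbol"),
    col_types = "cc", comment = "#", progress = FALSE
  )
  x |>
    mutate(
      organism = toupper(trimws(.data$organism)),
      symbol = norm_symbol(.data$symbol)
    ) |>
    distinct()
}

#' Read an ortholog table
#'
#' Three-column TSV `organism<TAB>source_gene<TAB>human_symbol` (BioMart
#' style), `#` comments allowed, no header. One-to-many mappings are
#' allowed and preserved.
#'
#' @param path File path.
#' @return Tibble with columns `organism`, `source_gene`, `human_symbol`.
#' @export
read_ortholog_table <- function(path) {
  x <- readr::read_tsv(
    path,
    col_names = c("organism", "source_gene", "human_symbol"),
    col_types = "ccc", comment = "#", progress = FALSE
  )
  bad <- !stats::complete.cases(x) |
    x$organism == "" | x$source_gene == "" | x$human_symbol == ""
  assert_that(!any(bad), "ortholog table contains rows with empty fields")
  x
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: `term<TAB>description<TAB>member1<TAB>member2...`.
#'
#' @param path File path.
#' @return Named list of character vectors (term -> member gene symbols).
#' @export
read_gmt <- function(path) {
  sets <- fgsea::gmtPathways(path)
  map(sets, norm_symbol)
}

#' Read compound bioactivity records
#'
#' CSV or TSV (sniffed from the extension) with header columns
#' `compound_id, smiles, inchikey, uniprot, organism, activity_type,
#' activity_value, activity_units`. `activity_units` defaults to `uM` when
#' absent; only micromolar records are understood (`uM`; `nM` and `mM` are
#' converted).
#'
#' @param path File path.
#' @return Tibble of activity records with `activity_value` in micromolar.
#' @export
read_activity_records <- function(path) {
  reader <- if (grepl("\\.csv$", path)) readr::read_csv else readr::read_tsv
  x <- reader(path, col_types = readr::cols(), progress = FALSE)
  need <- c(
    "compound_id", "smiles", "uniprot", "organism",
    "activity_type", "activity_value"
  )
  assert_that(
    all(need %in% names(x)),
    paste("activity records need columns:", paste(need, collapse = ", "))
  )
  if (!"inchikey" %in% names(x)) x$inchikey <- NA_character_
  if (!"activity_units" %in% names(x)) x$activity_units <- "uM"
  x$activity_units[is.na(x$activity_units)] <- "uM"
  fac <- c(nM = 1e-3, uM = 1, mM = 1e3)
  u <- x$activity_units
  assert_that(
    all(u %in% names(fac)),
    "activity_units must be one of nM, uM, mM"
  )
  x$activity_value <- x$activity_value * unname(fac[u])
  x$activity_units <- "uM"
  as_tibble(x)
}

#' Read an accession-to-gene-symbol map
#'
#' Two-column TSV `uniprot<TAB>gene_symbol` with header.
#'
#' @param path File path.
#' @return Tibble with columns `uniprot`, `gene_symbol`.
#' @export
read_target_gene_map <- function(path) {
  x <- readr::read_tsv(path, col_types = "cc", progress = FALSE)
  assert_that(
    all(c("uniprot", "gene_symbol") %in% names(x)),
    "target gene map needs columns uniprot, gene_symbol"
  )
  x |> mutate(gene_symbol = norm_symbol(.data$gene_symbol))
}

#' Write an AAG catalogue as TSV
#'
#' Columns: `symbol`, `evidence` (semicolon-joined organism codes),
#' `support`.
#'
#' @param catalog An `aag_catalog`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_aag_catalog <- function(catalog, path) {
  ev <- apply(
    as.matrix(catalog[ORGANISMS]), 1L,
    function(row) paste(ORGANISMS[row], collapse = ";")
  )
  readr::write_tsv(
    tibble(
      symbol = catalog$symbol, evidence = ev, support = catalog$support
    ),
    path
  )
  invisible(path)
}

#' Read substructure profiles
#'
#' TSV with header `compound_id<TAB>keys`, keys semicolon-joined; an empty
#' keys field is an empty profile.
#'
#' @param path File path.
#' @return Tibble in long form: `compound_id`, `key`.
#' @export
read_profiles <- function(path) {
  x <- readr::read_tsv(path, col_types = "cc", progress = FALSE)
  assert_that(
    all(c("compound_id", "keys") %in% names(x)),
    "profiles need columns compound_id, keys"
  )
  x |>
    mutate(keys = ifelse(is.na(.data$keys), "", .data$keys)) |>
    mutate(key = strsplit(.data$keys, ";", fixed = TRUE)) |>
    select("compound_id", "key") |>
    tidyr::unnest("key", keep_empty = FALSE) |>
    filter(.data$key != "") |>
    distinct()
}

#' Write substructure profiles (inverse of [read_profiles()])
#' @param profiles Long tibble `compound_id`, `key`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  wide <- profiles |>
    group_by(.data$compound_id) |>
    summarise(keys = paste(sort(unique(.data$key)), collapse = ";"))
  readr::write_tsv(wide, path)
  invisible(path)
}
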