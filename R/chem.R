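# Structure handling goes through Open Babel (via ChemmineOB), the same
# toolkit used for the original catalogue curation.

#' @noRd
ob_convert <- function(from, to, source) {
  out <- tryCatch(
    ChemmineOB::convertFormat(from, to, source),
    error = function(e) ""
  )
  out <- trimws(out)
  if (identical(out, "")) NA_character_ else out
}

#' Element counts from an InChI formula layer, e.g. "C7H6O2" or "ClH.Na"
#' @noRd
formula_counts <- function(inchi) {
  if (is.na(inchi)) return(NULL)
  parts <- strsplit(inchi, "/", fixed = TRUE)[[1]]
  if (length(parts) < 2L) return(NULL)
  formula <- parts[2]
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  toks <- regmatches(formula, list(m))[[1]]
  toks <- toks[toks != ""]
  el <- sub("[0-9]*$", "", toks)
  n <- as.integer(sub("^[A-Za-z]+", "", toks))
  n[is.na(n)] <- 1L
  tapply(n, el, sum)
}

#' @noRd
standardize_one <- function(smiles) {
  failed <- list(
    canonical_smiles = NA_character_, inchikey = NA_character_,
    status = "unparsable"
  )
  if (is.na(smiles) || !nzchar(trimws(smiles))) return(failed)
  frags <- strsplit(trimws(smiles), ".", fixed = TRUE)[[1]]
  frags <- frags[nzchar(frags)]
  info <- map(frags, function(f) {
    inchi <- ob_convert("SMI", "INCHI", f)
    counts <- formula_counts(inchi)
    if (is.null(counts)) return(NULL)
    heavy <- sum(counts[setdiff(names(counts), "H")])
    list(
      frag = f, carbon = isTRUE(counts["C"] > 0), heavy = heavy
    )
  })
  if (any(vapply(info, is.null, logical(1)))) return(failed)
  carbons <- keep(info, ~ .x$carbon)
  if (length(carbons) == 0L) {
    failed$status <- "no_carbon"
    return(failed)
  }
  # salt stripping: largest carbon-containing fragment; ties by canonical
  # SMILES string order for determinism
  heavies <- vapply(carbons, function(x) x$heavy, numeric(1))
  best <- carbons[heavies == max(heavies)]
  cans <- vapply(
    best, function(x) ob_convert("SMI", "CAN", x$frag), character(1)
  )
  if (anyNA(cans)) return(failed)
  can <- sort(cans)[1]
  key <- ob_convert("SMI", "INCHIKEY", can)
  if (is.na(key)) return(failed)
  list(canonical_smiles = can, inchikey = key, status = "ok")
}

#' Standardize compound structures
#'
#' Strips salt counter-ions by keeping the largest carbon-containing
#' fragment, canonicalizes the SMILES (Open Babel canonical form, invariant
#' to input atom ordering) and derives the standard 27-character InChIKey
#' from the standardized structure. Structures that do not parse are
#' flagged `unparsable`; parseable structures without any carbon atom are
#' flagged `no_carbon`. Both flags exclude the record downstream (filter
#' criteria iv and v).
#'
#' @param smiles Character vector of SMILES strings.
#' @return Tibble with one row per input: `smiles`, `canonical_smiles`,
#'   `inchikey`, `status` (`"ok"`, `"unparsable"`, `"no_carbon"`).
#' @examples
#' \donttest{
#' standardize_structures(c("CC(=O)[O-].[Na+]", "c1ccccc1", "[Na+].[Cl-]"))
#' }
#' @export
standardize_structures <- function(smiles) {
  smiles <- as.character(smiles)
  uniq <- unique(smiles)
  res <- map(uniq, standardize_one)
  idx <- match(smiles, uniq)
  tibble(
    smiles = smiles,
    canonical_smiles = map_chr(res, "canonical_smiles")[idx],
    inchikey = map_chr(res, "inchikey")[idx],
    status = map_chr(res, "status")[idx]
  )
}

#' Built-in substructure dictionary
#'
#' A compact SMARTS dictionary of ~50 common functional groups and ring
#' systems used to connect compounds to substructure nodes of the
#' tripartite diffusion network. It plays the role of a full fingerprint
#' dictionary (e.g. the 4,860-key Klekota-Roth set) at a scale suited to
#' synthetic studies; supply your own dictionary via
#' [read_substructure_dictionary()] for real applications.
#'
#' @return Tibble with columns `key`, `smarts`.
#' @export
default_substructure_dictionary <- function() {
  tibble::tribble(
    ~key, ~smarts,
    "fg_hydroxyl",        "[OX2H]",
    "fg_phenol",          "[OX2H][cX3]",
    "fg_primary_alcohol", "[CH2][OX2H]",
    "fg_carbonyl",        "[CX3]=[OX1]",
    "fg_aldehyde",        "[CX3H1](=O)",
    "fg_ketone",          "[#6][CX3](=O)[#6]",
    "fg_carboxylic_acid", "[CX3](=O)[OX2H1]",
    "fg_carboxylate",     "[CX3](=O)[O-]",
    "fg_ester",           "[CX3](=O)[OX2H0][#6]",
    "fg_amide",           "[NX3][CX3](=[OX1])",
    "fg_primary_amine",   "[NX3;H2][#6]",
    "fg_secondary_amine", "[NX3;H1]([#6])[#6]",
    "fg_tertiary_amine",  "[NX3]([#6])([#6])[#6]",
    "fg_guanidine",       "[NX3][CX3](=[NX2])[NX3]",
    "fg_nitro",           "[NX3](=O)=O",
    "fg_nitrile",         "[NX1]#[CX2]",
    "fg_ether",           "[OD2]([#6])[#6]",
    "fg_thiol",           "[SX2H]",
    "fg_thioether",       "[SX2]([#6])[#6]",
    "fg_sulfoxide",       "[SX3]=[OX1]",
    "fg_sulfone",         "[SX4](=[OX1])(=[OX1])",
    "fg_sulfonamide",     "[SX4](=[OX1])(=[OX1])[NX3]",
    "fg_phosphate",       "[PX4](=[OX1])",
    "fg_halogen_f",       "[F]",
    "fg_halogen_cl",      "[Cl]",
    "fg_halogen_br",      "[Br]",
    "fg_halogen_i",       "[I]",
    "fg_alkene",          "[CX3]=[CX3]",
    "fg_alkyne",          "[CX2]#[CX2]",
    "fg_methyl",          "[CH3]",
    "fg_gem_dimethyl",    "[CH3][CX4][CH3]",
    "fg_cf3",             "[CX4](F)(F)F",
    "fg_aromatic6",       "c1ccccc1",
    "fg_aromatic_n",      "[nX2]",
    "fg_pyridine",        "c1ccncc1",
    "fg_pyrimidine",      "c1cncnc1",
    "fg_imidazole",       "c1cnc[nH]1",
    "fg_pyrrole",         "c1cc[nH]c1",
    "fg_furan",           "c1ccoc1",
    "fg_thiophene",       "c1ccsc1",
    "fg_indole",          "c1ccc2[nH]ccc2c1",
    "fg_naphthalene",     "c1ccc2ccccc2c1",
    "fg_biphenyl",        "c1ccccc1-c1ccccc1",
    "fg_benzylic",        "[CX4][c]",
    "fg_anisole",         "[OX2]([CH3])[c]",
    "fg_catechol",        "[OX2H][c][c][OX2H]",
    "fg_enol_ether",      "[OX2][CX3]=[CX3]",
    "fg_lactone",         "[CX3](=O)[OX2][CX4]",
    "fg_urea",            "[NX3][CX3](=[OX1])[NX3]",
    "fg_ring5_carbon",    "C1CCCC1",
    "fg_ring6_carbon",    "C1CCCCC1"
  )
}

#' Read a substructure dictionary
#'
#' TSV with header `key<TAB>smarts`.
#' @param path File path.
#' @return Tibble with columns `key`, `smarts`.
#' @export
read_substructure_dictionary <- function(path) {
  x <- readr::read_tsv(path, col_types = "cc", progress = FALSE)
  assert_that(
    all(c("key", "smarts") %in% names(x)),
    "dictionary needs columns key, smarts"
  )
  x
}

#' Compute substructure incidence profiles by SMARTS matching
#'
#' Matches every dictionary pattern against every compound structure and
#' returns the incidence in long form; deterministic given identical
#' structures.
#'
#' @param compounds Data frame with columns `compound_id` and `smiles`
#'   (canonical SMILES preferred).
#' @param dictionary Tibble with columns `key`, `smarts`; defaults to
#'   [default_substructure_dictionary()].
#' @return Long tibble `compound_id`, `key` (one row per matched pattern);
#'   compounds matching nothing are absent (empty profile).
#' @export
compute_substructure_profiles <- function(
    compounds, dictionary = default_substructure_dictionary()) {
  assert_that(
    all(c("compound_id", "smiles") %in% names(compounds)),
    "`compounds` needs columns compound_id, smiles"
  )
  if (nrow(compounds) == 0L || nrow(dictionary) == 0L) {
    return(tibble(compound_id = character(), key = character()))
  }
  sdf <- tryCatch(
    ChemmineR::smiles2sdf(
      setNames(compounds$smiles, compounds$compound_id)
    ),
    error = function(e) abort(
      paste("unparsable structure among compounds:", conditionMessage(e))
    )
  )
  hits <- map(seq_len(nrow(dictionary)), function(i) {
    counts <- ChemmineR::smartsSearchOB(
      sdf, dictionary$smarts[i], uniqueMatches = FALSE
    )
    tibble(
      compound_id = compounds$compound_id[counts > 0],
      key = dictionary$key[i]
    )
  })
  bind_rows(hits) |> arrange(.data$compound_id, .data$key)
}
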