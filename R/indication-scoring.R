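#' Configuration of the genome-wide permutation test
#'
#' Defaults mirror the published analysis: a universe of 20,462 human
#' protein-coding genes, an AAP draw the size of the supplied AAP set, and
#' 100,000 permutations.
#'
#' @param universe_size Number of protein-coding genes `N`.
#' @param aap_size Number of genes `K` drawn per permutation; `NULL`
#'   (default) means "size of the AAP set actually supplied" at scoring
#'   time.
#' @param n_perm Number of permutations (>= 1).
#' @param seed Base RNG seed; per-drug substreams are derived from it.
#' @param tail_mode `"at_least"` (default; counts permutation overlaps
#'   `>= x`) or `"strict_greater"` (the literal `> x` reading; makes
#'   `P(x = 0) < 1` and so misorders degenerate profiles).
#' @param pseudocount If `TRUE`, report `(b + 1) / (n_perm + 1)` instead of
#'   `b / n_perm`, avoiding exact zeros.
#' @return List of class `permutation_config`.
#' @export
permutation_config <- function(universe_size = 20462, aap_size = NULL,
                               n_perm = 1e5, seed = 1,
                               tail_mode = c("at_least", "strict_greater"),
                               pseudocount = FALSE) {
  tail_mode <- match.arg(tail_mode)
  assert_that(n_perm >= 1, "`n_perm` must be >= 1")
  if (!is.null(aap_size)) {
    assert_that(
      aap_size <= universe_size,
      "`aap_size` cannot exceed `universe_size`"
    )
  }
  structure(
    list(
      universe_size = as.integer(universe_size),
      aap_size = if (is.null(aap_size)) NULL else as.integer(aap_size),
      n_perm = as.integer(n_perm), seed = seed,
      tail_mode = tail_mode, pseudocount = isTRUE(pseudocount)
    ),
    class = "permutation_config"
  )
}

#' Observed AAP-target count of a drug
#'
#' @param targets Character vector of the drug's target gene symbols.
#' @param aap_set Character vector of AAP gene symbols.
#' @return Integer `x = |targets intersect AAP|`.
#' @export
observed_aap_count <- function(targets, aap_set) {
  length(intersect(unique(norm_symbol(targets)),
                   unique(norm_symbol(aap_set))))
}

#' Closed-form moments and tail of the permutation null
#'
#' Drawing `K` genes uniformly without replacement from an `N`-gene
#' universe and counting hits in a fixed `n`-gene target set is a
#' hypergeometric experiment, so the permutation null has closed-form
#' mean `n K / N`, variance `n (K/N)(1 - K/N)(N - n)/(N - 1)`, and upper
#' tail `P(X >= x)`. This is the analytic oracle the Monte-Carlo
#' permutation is validated against.
#'
#' @param n Drug target-set size.
#' @param K AAP set size.
#' @param N Universe size.
#' @return List `mu`, `sigma`, and `tail` (a function of `x` returning
#'   `P(X >= x)`).
#' @export
hypergeom_moments <- function(n, K, N) {
  assert_that(
    n >= 0 && K >= 0 && n <= N && K <= N,
    "need 0 <= n, K <= N"
  )
  mu <- n * K / N
  sigma2 <- if (N > 1) n * (K / N) * (1 - K / N) * (N - n) / (N - 1) else 0
  tail <- function(x) {
    vapply(x, function(xi) {
      if (xi <= 0) return(1)
      hi <- min(n, K)
      if (xi > hi) return(0)
      sum(dhyper(seq(xi, hi), K, N - K, n))
    }, numeric(1))
  }
  list(mu = mu, sigma = sqrt(sigma2), tail = tail)
}

#' Monte-Carlo permutation null for a drug's AAP-overlap count
#'
#' Each permutation draws `K` genes uniformly without replacement from the
#' `N`-gene universe and records the overlap with the drug's `n` fixed
#' targets. Seeded and reproducible; `sigma` uses the sample (n-1)
#' denominator.
#'
#' @param n_targets Number of targets `n` of the drug (<= universe size).
#' @param config A [permutation_config()]; `aap_size` must be set.
#' @return List `overlaps` (integer vector of length `n_perm`), `mu`,
#'   `sigma`.
#' @export
permutation_null <- function(n_targets, config) {
  stopifnot(inherits(config, "permutation_config"))
  N <- config$universe_size
  K <- config$aap_size
  assert_that(!is.null(K), "`config$aap_size` must be set")
  assert_that(n_targets <= N, "`n_targets` exceeds the universe size")
  # by exchangeability the drug's targets can be relabelled 1..n
  overlaps <- with_seed(config$seed, {
    vapply(
      seq_len(config$n_perm),
      function(i) sum(sample.int(N, K) <= n_targets),
      integer(1)
    )
  })
  list(
    overlaps = overlaps,
    mu = mean(overlaps),
    sigma = sd(overlaps)
  )
}

#' Nominal permutation p-value
#'
#' Fraction of permutation overlaps at least (`"at_least"`, default) or
#' strictly above (`"strict_greater"`) the observed count `x`.
#'
#' @param x Observed AAP-target count (>= 0).
#' @param overlaps Integer vector of permutation overlap counts.
#' @param mode Tail convention.
#' @param pseudocount Add-one smoothing of numerator and denominator.
#' @return Nominal p-value in `[0, 1]`.
#' @export
permutation_pvalue <- function(x, overlaps,
                               mode = c("at_least", "strict_greater"),
                               pseudocount = FALSE) {
  mode <- match.arg(mode)
  assert_that(x >= 0, "`x` must be non-negative")
  assert_that(length(overlaps) > 0, "`overlaps` must be non-empty")
  b <- if (mode == "at_least") sum(overlaps >= x) else sum(overlaps > x)
  if (pseudocount) (b + 1) / (length(overlaps) + 1) else b / length(overlaps)
}

#' Permutation Z-score
#'
#' `Z = (x - mu) / sigma`. Undefined (NA) when `sigma = 0`.
#'
#' @param x Observed AAP-target count.
#' @param mu,sigma Null mean and standard deviation (permutation or
#'   closed-form).
#' @return Z-score, or `NA` if `sigma` is zero.
#' @export
z_score <- function(x, mu, sigma) {
  ifelse(sigma > 0, (x - mu) / sigma, NA_real_)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR correction with enforced monotonicity; input order is
#' preserved.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Vector of q-values, same order as the input.
#' @export
bh_adjust <- function(p_values) {
  assert_that(
    all(is.finite(p_values) & p_values >= 0 & p_values <= 1),
    "all p-values must lie in [0, 1]"
  )
  p.adjust(p_values, method = "BH")
}

#' Score and rank compounds for anti-aging indications
#'
#' For every drug: count observed AAP targets `x`, run the seeded
#' permutation null (per-drug substreams derived from `(seed, drug id)`,
#' so results do not depend on iteration order), compute the nominal
#' permutation p-value and `Z = (x - mu)/sigma`, then apply
#' Benjamini-Hochberg correction across all scored drugs. Drugs with an
#' empty target set are flagged and score `x = 0`, `P = 1`.
#'
#' @param profiles Long tibble `drug`, `gene_symbol` (one row per target
#'   gene of a drug) -- e.g. `tidy(net)` joined to symbols; drugs with no
#'   rows can be added via `all_drugs`.
#' @param aap_set Character vector of AAP gene symbols.
#' @param config A [permutation_config()]; a `NULL` `aap_size` defaults to
#'   `length(unique(aap_set))`.
#' @param all_drugs Optional character vector forcing rows (with empty
#'   profiles) for drugs absent from `profiles`.
#' @return Tibble of class `indication_scores`, one row per drug:
#'   `drug`, `n`, `x`, `mu`, `sigma`, `z`, `p_value`, `q_value`,
#'   `empty_profile`; ranked by ascending q, then descending Z, then drug
#'   id. The configuration is attached as attribute `"config"`.
#' @export
prioritize_indications <- function(profiles, aap_set,
                                   config = permutation_config(),
                                   all_drugs = NULL) {
  stopifnot(inherits(config, "permutation_config"))
  assert_that(
    all(c("drug", "gene_symbol") %in% names(profiles)),
    "`profiles` needs columns drug, gene_symbol"
  )
  aap <- unique(norm_symbol(aap_set))
  if (is.null(config$aap_size)) config$aap_size <- length(aap)
  targets_by_drug <- profiles |>
    filter(!is.na(.data$gene_symbol)) |>
    mutate(gene_symbol = norm_symbol(.data$gene_symbol)) |>
    distinct(.data$drug, .data$gene_symbol) |>
    group_by(.data$drug) |>
    summarise(targets = list(.data$gene_symbol))
  drugs <- sort(union(targets_by_drug$drug, all_drugs %||% character()))
  assert_that(length(drugs) > 0, "no drugs to score")
  tset <- setNames(targets_by_drug$targets, targets_by_drug$drug)
  rows <- map(drugs, function(d) {
    tg <- tset[[d]] %||% character()
    n <- length(tg)
    if (n == 0L) {
      return(tibble(
        drug = d, n = 0L, x = 0L, mu = NA_real_, sigma = NA_real_,
        z = NA_real_, p_value = 1, empty_profile = TRUE
      ))
    }
    x <- observed_aap_count(tg, aap)
    cfg <- config
    cfg$seed <- substream_seed(config$seed, d)
    null <- permutation_null(n, cfg)
    tibble(
      drug = d, n = n, x = x, mu = null$mu, sigma = null$sigma,
      z = z_score(x, null$mu, null$sigma),
      p_value = permutation_pvalue(
        x, null$overlaps, mode = config$tail_mode,
        pseudocount = config$pseudocount
      ),
      empty_profile = FALSE
    )
  })
  out <- bind_rows(rows)
  out$q_value <- bh_adjust(out$p_value)
  out <- out |>
    arrange(.data$q_value, dplyr::desc(.data$z), .data$drug) |>
    select("drug", "n", "x", "mu", "sigma", "z", "p_value", "q_value",
           "empty_profile")
  class(out) <- c("indication_scores", class(out))
  attr(out, "config") <- config
  out
}

#' @rdname prioritize_indications
#' @param x An `indication_scores` table.
#' @param ... Unused.
#' @export
tidy.indication_scores <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "indication_scores")
  attr(out, "config") <- NULL
  out
}

#' @rdname prioritize_indications
#' @export
glance.indication_scores <- function(x, ...) {
  cfg <- attr(x, "config")
  tibble(
    n_drugs = nrow(x),
    n_significant = sum(x$q_value < 0.05),
    n_perm = cfg$n_perm,
    universe_size = cfg$universe_size,
    aap_size = cfg$aap_size %||% NA_integer_
  )
}

#' @importFrom ggplot2 geom_point geom_hline scale_colour_manual
#' @export
autoplot.indication_scores <- function(object, q_threshold = 0.05, ...) {
  df <- tidy(object) |>
    mutate(
      rank = dplyr::row_number(),
      significant = .data$q_value < q_threshold
    )
  ggplot(df, aes(x = .data$rank, y = .data$z,
                 colour = .data$significant)) +
    geom_point() +
    scale_colour_manual(values = c(`TRUE` = "#D55E00",
                                   `FALSE` = "grey50")) +
    labs(
      x = "rank (by q, then Z)", y = "permutation Z-score",
      colour = sprintf("q < %.2g", q_threshold),
      title = "Anti-aging indication prioritization"
    )
}
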