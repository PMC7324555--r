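#' COG single-letter category codes
#'
#' The 22 testable Clusters of Orthologous Groups functional categories plus
#' `"-"` for ORFs without an assignment. Inputs using the typographic en dash
#' are normalised to `"-"`.
#'
#' @format Character vector of length 23.
#' @export
cog_codes <- c("J", "A", "K", "L", "B", "D", "V", "T", "M", "N", "U", "O",
               "C", "G", "E", "F", "H", "I", "P", "Q", "R", "S", "-")

normalise_cog <- function(code) {
  code <- as.character(code)
  code[code %in% c("–", "—", "", NA)] <- "-"
  bad <- setdiff(unique(code), cog_codes)
  if (length(bad)) {
    abort_input("unknown COG code(s): %s.", paste0("`", bad, "`", collapse = ", "))
  }
  code
}

#' Tally DE-set and genome counts per COG category
#'
#' Builds the per-category 2x2 ingredients for enrichment testing: `k` ORFs
#' of the DE set and `K` ORFs of the genome in each category, with DE-set
#' size `n` and genome size `N`. A DE ORF absent from the annotation is
#' counted as unassigned (`"-"`) with a warning.
#'
#' @param annotations Data frame with columns `orf_id`, `cog_code` covering
#'   the genome (one row per ORF). Alternatively a data frame with columns
#'   `cog_code`, `genome_count` giving pre-tabulated genome totals.
#' @param de_orfs Character vector of DE ORF ids, or (with pre-tabulated
#'   genome counts) a data frame with columns `cog_code`, `de_count`.
#' @return A tibble, one row per COG code present: `cog_code`, `k`, `n`,
#'   `K`, `N`.
#' @examples
#' de <- kt2440_de_table()
#' tally_by_cog(kt2440_cog_genome(),
#'              dplyr::count(de, cog_code, name = "de_count"))
#' @export
tally_by_cog <- function(annotations, de_orfs) {
  pretab <- is.data.frame(annotations) && "genome_count" %in% names(annotations)
  if (pretab) {
    check_columns(annotations, c("cog_code", "genome_count"))
    check_columns(de_orfs, c("cog_code", "de_count"), arg = "de_orfs")
    genome <- annotations |>
      mutate(cog_code = normalise_cog(.data$cog_code)) |>
      group_by(.data$cog_code) |>
      summarise(K = sum(.data$genome_count), .groups = "drop")
    de <- de_orfs |>
      mutate(cog_code = normalise_cog(.data$cog_code)) |>
      group_by(.data$cog_code) |>
      summarise(k = sum(.data$de_count), .groups = "drop")
  } else {
    check_columns(annotations, c("orf_id", "cog_code"))
    if (!is.character(de_orfs)) abort_input("`de_orfs` must be a character vector of ORF ids.")
    ann <- mutate(as_tibble(annotations), cog_code = normalise_cog(.data$cog_code))
    missing <- setdiff(de_orfs, ann$orf_id)
    if (length(missing)) {
      rlang::warn(sprintf("%d DE ORF(s) missing from the annotation; counted as unassigned",
                          length(missing)),
                  class = "plasfit_unannotated_de")
    }
    genome <- ann |> group_by(.data$cog_code) |> summarise(K = n(), .groups = "drop")
    de_codes <- c(ann$cog_code[match(intersect(de_orfs, ann$orf_id), ann$orf_id)],
                  rep("-", length(missing)))
    de <- tibble(cog_code = de_codes) |>
      group_by(.data$cog_code) |> summarise(k = n(), .groups = "drop")
  }
  out <- genome |>
    left_join(de, by = "cog_code") |>
    mutate(k = ifelse(is.na(.data$k), 0L, .data$k))
  extra <- setdiff(de$cog_code, genome$cog_code)
  if (length(extra)) {
    abort_input("DE categories absent from the genome tally: %s.",
                paste(extra, collapse = ", "))
  }
  out |>
    mutate(n = sum(.data$k), N = sum(.data$K)) |>
    select("cog_code", "k", "n", "K", "N") |>
    arrange(match(.data$cog_code, cog_codes))
}

#' One-sided hypergeometric enrichment p-value
#'
#' Upper-tail probability P(X >= k) for X ~ Hypergeometric(N, K, n): the
#' chance that a random sample of `n` ORFs from a genome of `N`, of which
#' `K` belong to the category, contains `k` or more category members. This
#' is the one-sided Fisher exact test for over-representation. The mass is
#' summed directly over x = k..min(n, K) on the log scale (log-factorial
#' terms via `lgamma`) for numerical stability.
#'
#' @param k Observed category count in the DE set.
#' @param n DE-set size.
#' @param K Category count in the genome.
#' @param N Genome size.
#' @return p-value in \[0, 1\]; vectorised over `k`, `K`.
#' @examples
#' hypergeom_enrichment_p(5, 33, 165, 5350)
#' @export
hypergeom_enrichment_p <- function(k, n, K, N) {
  check_count(k, "k"); check_count(n, "n"); check_count(K, "K"); check_count(N, "N")
  if (any(n > N) || any(K > N) || any(k > pmin(n, K))) {
    abort_input("inconsistent counts: need k <= min(n, K), n <= N, K <= N.")
  }
  lfact <- function(x) lgamma(x + 1)
  lch <- function(a, b) lfact(a) - lfact(b) - lfact(a - b)
  mapply(function(ki, ni, Ki, Ni) {
    xs <- ki:min(ni, Ki)
    lp <- lch(Ki, xs) + lch(Ni - Ki, ni - xs) - lch(Ni, ni)
    mx <- max(lp)
    min(1, exp(mx) * sum(exp(lp - mx)))
  }, k, n, K, N)
}

#' COG enrichment table
#'
#' Tests every assigned COG category for over-representation of the DE set
#' against the genome background. The default is the one-sided (upper-tail)
#' hypergeometric test without multiple-testing correction, i.e. each raw
#' p-value compared to `alpha`; a two-sided Fisher test and a Bonferroni
#' correction are available as options. Unassigned ORFs (`"-"`) contribute
#' to the totals `n` and `N` but are not themselves tested.
#'
#' @param tallies Output of [tally_by_cog()] (columns `cog_code`, `k`, `n`,
#'   `K`, `N`).
#' @param alpha Significance level (default 0.05).
#' @param alternative `"greater"` (one-sided enrichment, default) or
#'   `"two.sided"` (Fisher exact via [stats::fisher.test()]).
#' @param correction `"none"` (default) or `"bonferroni"` across the tested
#'   categories.
#' @return A tibble of class `plasfit_enrichment`: `cog_code`, `k`, `n`,
#'   `K`, `N`, `p_value`, `significant`. The unassigned row is retained
#'   with `NA` p-value.
#' @examples
#' tt <- tally_by_cog(kt2440_cog_genome(),
#'                    dplyr::count(kt2440_de_table(), cog_code, name = "de_count"))
#' enrich_table(tt)
#' @export
enrich_table <- function(tallies, alpha = 0.05,
                         alternative = c("greater", "two.sided"),
                         correction = c("none", "bonferroni")) {
  alternative <- arg_match(alternative)
  correction <- arg_match(correction)
  check_columns(tallies, c("cog_code", "k", "n", "K", "N"), arg = "tallies")
  check_number(alpha, "alpha", positive = TRUE, allow_vec = FALSE)
  tallies <- as_tibble(tallies)
  tested <- tallies$cog_code != "-"
  p <- rep(NA_real_, nrow(tallies))
  if (alternative == "greater") {
    p[tested] <- hypergeom_enrichment_p(tallies$k[tested], tallies$n[tested],
                                        tallies$K[tested], tallies$N[tested])
  } else {
    p[tested] <- purrr::pmap_dbl(tallies[tested, ], function(cog_code, k, n, K, N, ...) {
      m <- matrix(c(k, n - k, K - k, N - K - (n - k)), 2)
      stats::fisher.test(m)$p.value
    })
  }
  if (correction == "bonferroni") {
    p[tested] <- pmin(1, p[tested] * sum(tested))
  }
  out <- tallies |>
    mutate(p_value = p, significant = .data$p_value < alpha)
  structure(out, alpha = alpha, alternative = alternative,
            correction = correction,
            class = c("plasfit_enrichment", class(out)))
}
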