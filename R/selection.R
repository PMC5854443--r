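#' Per-gene splice-site variant density
#'
#' Counts low-frequency single-nucleotide variants falling in the
#' canonical splice-site windows of each intron-containing gene and
#' divides by the gene's number of splice sites. Genes with no
#' qualifying variants get density 0; intronless genes are excluded.
#' When `prone_genes` is supplied the output gains a `group` column
#' and a rank-sum comparison (prone vs other) is attached as the
#' `"comparison"` attribute.
#'
#' @param variants Tibble with `gene_id`, `position` (0-based) and
#'   `maf`.
#' @param models A [gene_models()] tibble.
#' @param maf_cutoff Keep variants with `maf < maf_cutoff`
#'   (default 1e-4, i.e. MAF < 0.01%).
#' @param prone_genes Optional character vector of predicted
#'   SSM-prone gene ids.
#' @return Tibble: `gene_id`, `n_variants`, `gene_ss`, `density`.
#' @export
ss_variant_density <- function(variants, models, maf_cutoff = 1e-4,
                               prone_genes = NULL) {
  stopifnot(all(c("gene_id", "position", "maf") %in% names(variants)))
  intronful <- models[models$n_introns > 0, ]
  if (nrow(intronful) == 0) abort("no intron-containing genes")
  id_cols <- intersect(c("gene_id", "position", "ref", "alt"), names(variants))
  v <- variants %>%
    dplyr::distinct(across(all_of(id_cols)), .keep_all = TRUE) %>%
    filter(.data$maf < maf_cutoff, .data$gene_id %in% intronful$gene_id)
  if (nrow(v) > 0) {
    v <- classify_regions(v, intronful, on_outside = "na")
    v <- filter(v, .data$region %in% c("ss5_window", "ss3_window"))
  }
  counts <- v %>% count(.data$gene_id, name = "n_variants")
  out <- tibble(gene_id = intronful$gene_id,
                gene_ss = intronful$n_splice_sites) %>%
    left_join(counts, by = "gene_id") %>%
    mutate(n_variants = dplyr::coalesce(.data$n_variants, 0L),
           density = .data$n_variants / .data$gene_ss) %>%
    select("gene_id", "n_variants", "gene_ss", "density")
  if (!is.null(prone_genes)) {
    out$group <- if_else(out$gene_id %in% prone_genes, "prone", "other")
    attr(out, "comparison") <- group_rank_tests(out$density, out$group,
                                                test = "mann_whitney")
  }
  out
}

#' Compare splice-site score deltas between MAF strata
#'
#' Stratifies splice-region variants into rare and common by minor
#' allele frequency and contrasts the distribution of the
#' reference-minus-alternate PWM delta. Reports, per stratum, the
#' share of site-abolishing (`delta > loss_cut`, default 5) and
#' site-strengthening (`delta < gain_cut`, default -2) variants, the
#' depletion factor of the loss class among common variants
#' (share among rare / share among common), and the mirror-image
#' enrichment factor of the gain class.
#'
#' @param variants Tibble with `delta` and either `stratum` or `maf`.
#' @param loss_cut,gain_cut Delta thresholds.
#' @param maf_rare,maf_common Stratum cutoffs used when only `maf` is
#'   present; intermediates are excluded.
#' @return List of class `"delta_strata"`: `strata` summary tibble,
#'   `depletion_loss`, `enrichment_gain`, and the stratified `deltas`
#'   for plotting. Factors are `NA` (with a message) when a stratum
#'   or class is empty.
#' @export
delta_strata_compare <- function(variants, loss_cut = 5, gain_cut = -2,
                                 maf_rare = 1e-4, maf_common = 0.01) {
  stopifnot("delta" %in% names(variants))
  if (!"stratum" %in% names(variants)) {
    stopifnot("maf" %in% names(variants))
    variants$stratum <- case_when(
      variants$maf < maf_rare ~ "rare",
      variants$maf > maf_common ~ "common",
      TRUE ~ "intermediate"
    )
  }
  d <- filter(variants, .data$stratum %in% c("rare", "common"))
  strata <- d %>%
    group_by(.data$stratum) %>%
    summarise(
      n = dplyr::n(),
      share_loss = mean(.data$delta > loss_cut),
      share_gain = mean(.data$delta < gain_cut),
      .groups = "drop"
    )
  get_share <- function(st, col) {
    v <- strata[[col]][strata$stratum == st]
    if (length(v) == 0) NA_real_ else v
  }
  sr <- get_share("rare", "share_loss"); sc <- get_share("common", "share_loss")
  gr <- get_share("rare", "share_gain"); gc_ <- get_share("common", "share_gain")
  depletion <- if (isTRUE(sc > 0)) sr / sc else NA_real_
  gain <- if (isTRUE(gr > 0)) gc_ / gr else NA_real_
  if (is.na(depletion) || is.na(gain)) {
    inform("empty stratum or class: some factors are undefined (NA)")
  }
  structure(
    list(strata = strata, depletion_loss = depletion, enrichment_gain = gain,
         deltas = select(d, "stratum", "delta"),
         loss_cut = loss_cut, gain_cut = gain_cut),
    class = "delta_strata"
  )
}

#' @export
print.delta_strata <- function(x, ...) {
  cat("<delta_strata>\n")
  print(x$strata)
  cat(sprintf("depletion of delta > %g among common: %.3g\n",
              x$loss_cut, x$depletion_loss))
  cat(sprintf("enrichment of delta < %g among common: %.3g\n",
              x$gain_cut, x$enrichment_gain))
  invisible(x)
}

#' Fisher exact test for gene-set overlap
#'
#' Two-sided exact hypergeometric test (point-probability summation)
#' of the overlap between two gene sets within a universe, with fold
#' enrichment relative to independence.
#'
#' @param set_a,set_b Character vectors of gene ids, subsets of
#'   `universe`.
#' @param universe Character vector of all eligible gene ids.
#' @return One-row tibble: overlap counts, `odds_ratio`, `p_value`,
#'   `fold` (= observed / (|A||B|/|U|)).
#' @export
#' @examples
#' overlap_fisher(c("a", "b"), c("b", "c"), letters[1:10])
overlap_fisher <- function(set_a, set_b, universe) {
  universe <- unique(universe)
  if (length(universe) == 0) abort("empty universe")
  set_a <- unique(set_a); set_b <- unique(set_b)
  if (!all(set_a %in% universe) || !all(set_b %in% universe)) {
    abort("sets must be subsets of the universe")
  }
  n11 <- length(intersect(set_a, set_b))
  n1_ <- length(set_a); n_1 <- length(set_b); nn <- length(universe)
  tab <- matrix(c(n11, n1_ - n11, n_1 - n11, nn - n1_ - n_1 + n11), nrow = 2)
  ft <- fisher.test(tab, alternative = "two.sided")
  expected <- n1_ * n_1 / nn
  tibble(
    n_overlap = n11, n_a = n1_, n_b = n_1, n_universe = nn,
    odds_ratio = unname(ft$estimate), p_value = ft$p.value,
    fold = if (expected > 0) n11 / expected else NA_real_
  )
}

#' Permutation test for category enrichment
#'
#' Draws `|category_genes|` genes uniformly from the universe
#' `n_perm` times and reports the add-one tail probability that the
#' simulated overlap with `marked_genes` reaches the observed
#' overlap, plus the fold enrichment over expectation. This is the
#' Monte Carlo analogue of the hypergeometric tail.
#'
#' @param category_genes Genes in the category of interest (e.g. the
#'   SSM-prone set).
#' @param marked_genes Genes carrying the mark (e.g. cancer genes).
#' @param universe All eligible genes.
#' @param n_perm Number of permutations (default 1e4).
#' @param seed Integer seed.
#' @return One-row tibble: `observed`, `expected`, `fold`,
#'   `p_value`.
#' @export
category_permutation <- function(category_genes, marked_genes, universe,
                                 n_perm = 1e4, seed = 1L) {
  universe <- unique(universe)
  category_genes <- unique(category_genes); marked_genes <- unique(marked_genes)
  if (length(category_genes) > length(universe)) {
    abort("category larger than universe")
  }
  stopifnot(all(category_genes %in% universe), all(marked_genes %in% universe))
  obs <- length(intersect(category_genes, marked_genes))
  k <- length(category_genes)
  is_marked <- universe %in% marked_genes
  set.seed(substream_seed(seed, "category_perm"))
  sims <- vapply(seq_len(n_perm), function(i) {
    sum(is_marked[sample.int(length(universe), k)])
  }, double(1))
  expected <- k * sum(is_marked) / length(universe)
  tibble(
    observed = obs, expected = expected,
    fold = if (expected > 0) obs / expected else NA_real_,
    p_value = (1 + sum(sims >= obs)) / (1 + n_perm)
  )
}

#' Rank-based group comparisons
#'
#' Mann-Whitney (two groups, exact when both groups have at most 8
#' untied observations) or Kruskal-Wallis (any number of groups),
#' with tie correction.
#'
#' @param values Numeric vector.
#' @param group Grouping vector.
#' @param test `"mann_whitney"` or `"kruskal_wallis"`.
#' @return One-row tibble: `statistic`, `p_value`, `method`.
#' @export
group_rank_tests <- function(values, group,
                             test = c("mann_whitney", "kruskal_wallis")) {
  test <- match.arg(test)
  group <- as.factor(group)
  sizes <- table(group)
  if (any(sizes == 0) || length(sizes) < 2) abort("each group needs >= 1 value")
  if (test == "mann_whitney") {
    if (length(sizes) != 2) abort("mann_whitney requires exactly two groups")
    g <- levels(group)
    x <- values[group == g[1]]; y <- values[group == g[2]]
    n1 <- length(x); n2 <- length(y)
    if (max(n1, n2) <= 8) {
      # exact two-sided p by full enumeration of group assignments,
      # midranks handle ties (wilcox.test cannot be exact with ties)
      r <- rank(values)
      u_of <- function(ix) sum(r[ix]) - n1 * (n1 + 1) / 2
      u_obs <- u_of(which(group == g[1]))
      mu <- n1 * n2 / 2
      combs <- utils::combn(n1 + n2, n1)
      u_all <- apply(combs, 2, u_of)
      p <- mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
      tibble(statistic = u_obs, p_value = p, method = "mann_whitney_exact")
    } else {
      ht <- suppressWarnings(wilcox.test(x, y))
      tibble(statistic = unname(ht$statistic), p_value = ht$p.value,
             method = "mann_whitney")
    }
  } else {
    ht <- kruskal.test(values, group)
    tibble(statistic = unname(ht$statistic), p_value = ht$p.value,
           method = "kruskal_wallis")
  }
}
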