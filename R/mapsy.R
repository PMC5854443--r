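#' Splicing efficiency of pooled reporter species
#'
#' For each species in a pooled splicing assay, the log2 ratio of its
#' share of the spliced pool to its share of the input pool:
#' `log2((spl_i / sum(spl)) / (inp_i / sum(inp)))`, with a pseudocount
#' added to every raw count first. Pools are formed within `assay`
#' when that column is present. Efficiency 0 means the species splices
#' exactly at the pool-average rate; the measure is invariant to
#' rescaling either pool.
#'
#' @param counts Tibble with `inp` and `spl` columns (one row per
#'   species), optionally `assay` and identifier columns which are
#'   carried through.
#' @param pseudocount Added to each raw count (default 0.5; use 0 to
#'   reproduce textbook arithmetic on non-zero counts).
#' @return `counts` with an added `efficiency` column.
#' @export
#' @examples
#' splicing_efficiency(
#'   tibble::tibble(inp = c(25, 25, 50), spl = c(10, 20, 70)),
#'   pseudocount = 0
#' )
splicing_efficiency <- function(counts, pseudocount = 0.5) {
  stopifnot(all(c("inp", "spl") %in% names(counts)))
  if (nrow(counts) == 0) abort("empty count table")
  if (any(counts$inp < 0) || any(counts$spl < 0)) abort("negative counts")
  grouped <- if ("assay" %in% names(counts)) group_by(counts, .data$assay) else counts
  out <- grouped %>%
    mutate(
      .spl_tot = sum(.data$spl), .inp_tot = sum(.data$inp),
      efficiency = log2(((.data$spl + pseudocount) / sum(.data$spl + pseudocount)) /
                          ((.data$inp + pseudocount) / sum(.data$inp + pseudocount)))
    ) %>%
    ungroup()
  if (any(out$.spl_tot == 0)) abort("no spliced output in pool")
  if (any(out$.inp_tot == 0)) abort("no input counts in pool")
  select(out, -".spl_tot", -".inp_tot")
}

#' Log2 allele ratio from four counts
#'
#' `log2((mi_e/mi_i) / (mj_e/mj_i))` with a pseudocount added to each
#' count: the enrichment of allele *i* over allele *j* between a
#' selected pool (`_e`) and the input (`_i` suffix on the count
#' names). Antisymmetric under swapping the two alleles.
#'
#' @param mi_e,mi_i Selected-pool and input counts of the first
#'   (minor) allele.
#' @param mj_e,mj_i Same for the second (major) allele.
#' @param pseudocount Added to each count (0 for exact arithmetic).
#' @return Numeric vector of log2 ratios.
#' @export
#' @examples
#' log2_allele_ratio(5, 10, 40, 20, pseudocount = 0)  # -2
log2_allele_ratio <- function(mi_e, mi_i, mj_e, mj_i, pseudocount = 0.5) {
  log2(((mi_e + pseudocount) / (mi_i + pseudocount)) /
         ((mj_e + pseudocount) / (mj_i + pseudocount)))
}

#' Allelic ratio of wt/mt pairs across spliceosomal fractions
#'
#' For each pair and fraction, the log2 ratio of the minor allele's
#' enrichment (selected pool over input) to the major allele's. The
#' major allele is the one that splices more efficiently, fixed per
#' pair from the `mRNA` fraction before any other fraction is
#' computed; ratios are therefore <= 0 in the mRNA fraction by
#' construction and antisymmetric under swapping the allele labels.
#'
#' @param counts Tibble with `pair_id`, `allele` (`"wt"`/`"mt"`),
#'   `fraction` (e.g. `"E"`, `"A"`, `"BC"`, `"mRNA"`, `"lariat"`),
#'   `sel` (counts in the selected pool) and `inp` (input counts).
#' @param pseudocount Added to each raw count.
#' @return Tibble with `pair_id`, `fraction`, `minor_allele`,
#'   `log2_ratio` (minor over major), and `log2_mt_over_wt` (the same
#'   ratio oriented mutant-over-wildtype).
#' @export
allelic_ratio <- function(counts, pseudocount = 0.5) {
  need <- c("pair_id", "allele", "fraction", "sel", "inp")
  stopifnot(all(need %in% names(counts)))
  wide <- counts %>%
    tidyr::pivot_wider(id_cols = c("pair_id", "fraction"),
                       names_from = "allele", values_from = c("sel", "inp"))
  if (anyNA(wide)) abort("missing allele rows for some pair/fraction")
  mrna <- wide %>%
    filter(.data$fraction == "mRNA") %>%
    mutate(
      eff_wt = (.data$sel_wt + pseudocount) / (.data$inp_wt + pseudocount),
      eff_mt = (.data$sel_mt + pseudocount) / (.data$inp_mt + pseudocount),
      minor_allele = if_else(.data$eff_mt <= .data$eff_wt, "mt", "wt")
    ) %>%
    select("pair_id", "minor_allele")
  if (nrow(mrna) == 0) abort("mRNA fraction required to assign major/minor alleles")
  wide %>%
    inner_join(mrna, by = "pair_id") %>%
    mutate(
      mi_e = if_else(.data$minor_allele == "mt", .data$sel_mt, .data$sel_wt),
      mi_i = if_else(.data$minor_allele == "mt", .data$inp_mt, .data$inp_wt),
      mj_e = if_else(.data$minor_allele == "mt", .data$sel_wt, .data$sel_mt),
      mj_i = if_else(.data$minor_allele == "mt", .data$inp_wt, .data$inp_mt),
      log2_ratio = log2_allele_ratio(.data$mi_e, .data$mi_i, .data$mj_e, .data$mj_i,
                                     pseudocount),
      log2_mt_over_wt = if_else(.data$minor_allele == "mt",
                                .data$log2_ratio, -.data$log2_ratio)
    ) %>%
    select("pair_id", "fraction", "minor_allele", "log2_ratio", "log2_mt_over_wt")
}

#' Call exonic splicing mutations from paired assay counts
#'
#' A wt/mt pair is called an ESM when, in *both* assays, the mutant's
#' allelic imbalance `log2((mt_spl/mt_inp) / (wt_spl/wt_inp))` exceeds
#' the fold threshold in magnitude *and* a two-proportion chi-square
#' test on the (input vs spliced) x (wt vs mt) counts rejects at
#' Benjamini-Hochberg FDR `alpha` within the panel. Pairs with a zero
#' input count for either allele, or with an assay missing, are
#' `indeterminate`.
#'
#' @param counts Long tibble: `pair_id`, `allele`, `assay`, `inp`,
#'   `spl` (as produced by [gen_mapsy_counts()]).
#' @param fold_threshold Minimal fold change in either direction
#'   (default 1.5).
#' @param alpha FDR level for the count test (default 0.05).
#' @param pseudocount Added to counts in the imbalance estimate (not
#'   in the test).
#' @return Tibble with one row per pair: per-assay `log2_ratio_*` and
#'   `q_*` columns, and `call` in `{ESM, no-effect, indeterminate}`.
#' @export
call_esm <- function(counts, fold_threshold = 1.5, alpha = 0.05, pseudocount = 0.5) {
  need <- c("pair_id", "allele", "assay", "inp", "spl")
  stopifnot(all(need %in% names(counts)))
  assays <- sort(unique(counts$assay))
  wide <- counts %>%
    tidyr::pivot_wider(id_cols = c("pair_id", "assay"),
                       names_from = "allele", values_from = c("inp", "spl")) %>%
    mutate(
      log2_ratio = log2_allele_ratio(.data$spl_mt, .data$inp_mt,
                                     .data$spl_wt, .data$inp_wt, pseudocount),
      p = two_prop_test_p(.data$spl_wt, .data$spl_mt, .data$inp_wt, .data$inp_mt),
      degenerate = .data$inp_wt == 0 | .data$inp_mt == 0
    ) %>%
    group_by(.data$assay) %>%
    mutate(q = p.adjust(.data$p, method = "BH")) %>%
    ungroup()
  per_pair <- wide %>%
    group_by(.data$pair_id) %>%
    summarise(
      n_assays = dplyr::n(),
      degenerate = any(.data$degenerate),
      pass_all = all(abs(.data$log2_ratio) >= log2(fold_threshold) &
                       .data$q < alpha),
      any_na = anyNA(.data$log2_ratio) || anyNA(.data$q),
      .groups = "drop"
    )
  calls <- per_pair %>%
    mutate(call = case_when(
      .data$n_assays < length(assays) | .data$degenerate | .data$any_na ~ "indeterminate",
      .data$pass_all ~ "ESM",
      TRUE ~ "no-effect"
    )) %>%
    select("pair_id", "call")
  ratios <- wide %>%
    select("pair_id", "assay", "log2_ratio", "q") %>%
    tidyr::pivot_wider(names_from = "assay", values_from = c("log2_ratio", "q"))
  left_join(ratios, calls, by = "pair_id")
}

# Vectorised two-proportion chi-square (no continuity correction) on
# the 2x2 table [spl_wt, spl_mt; inp_wt, inp_mt]: does the mutant's
# share differ between the spliced pool and the input pool?
two_prop_test_p <- function(spl_wt, spl_mt, inp_wt, inp_mt) {
  a <- spl_wt; b <- spl_mt; c <- inp_wt; d <- inp_mt
  n <- a + b + c + d
  num <- n * (a * d - b * c)^2
  den <- (a + b) * (c + d) * (a + c) * (b + d)
  stat <- ifelse(den > 0, num / den, NA_real_)
  pchisq(stat, df = 1, lower.tail = FALSE)
}

#' Spliceosomal-complex blockage profile of a mutant allele
#'
#' Expresses each pair's mutant allele as percent retention relative
#' to wild type per fraction (`100 x 2^log2(mt/wt enrichment)`;
#' wild type = 100%) and flags assembly transitions where the mutant
#' accumulates upstream (retention >= `enrich_fold x 100`) of a
#' depleted later fraction (retention <= `100 / deplete_fold`). The
#' primary block is the flagged transition with maximal upstream
#' retention; a pair may flag several transitions; a flat or monotone
#' profile yields `"no block"`.
#'
#' @param counts As for [allelic_ratio()]; fractions are interpreted
#'   in assembly order `E`, `A`, `BC`, then the products `mRNA` and
#'   `lariat`.
#' @param enrich_fold,deplete_fold Retention thresholds (defaults 1.5).
#' @param pseudocount Added to each raw count.
#' @return A list with `retention` (pair x fraction percent retention,
#'   long tibble) and `blocks` (per pair: `blocked_transitions`,
#'   `primary_block`, `n_blocks`).
#' @export
complex_blockage <- function(counts, enrich_fold = 1.5, deplete_fold = 1.5,
                             pseudocount = 0.5) {
  stage_order <- c("E", "A", "BC", "mRNA", "lariat")
  ratios <- allelic_ratio(counts, pseudocount = pseudocount)
  if (length(unique(ratios$fraction)) < 2) abort("need at least two fractions")
  retention <- ratios %>%
    mutate(retention = 100 * 2^.data$log2_mt_over_wt) %>%
    select("pair_id", "fraction", "retention")
  complexes <- c("E", "A", "BC")
  transitions <- c(E = "E->A", A = "A->B", BC = "B->mRNA")
  blocks <- retention %>%
    group_by(.data$pair_id) %>%
    dplyr::group_modify(function(d, key) {
      d <- d[match(stage_order, d$fraction), ]
      d <- d[!is.na(d$fraction), ]
      present <- d$fraction
      flagged <- character(0)
      ret <- setNames(d$retention, d$fraction)
      for (f in intersect(complexes, present)) {
        later <- present[match(present, stage_order) > match(f, stage_order)]
        if (length(later) == 0) next
        if (ret[f] >= 100 * enrich_fold && min(ret[later]) <= 100 / deplete_fold) {
          flagged <- c(flagged, transitions[[f]])
        }
      }
      primary <- if (length(flagged) == 0) "no block" else {
        up <- names(transitions)[match(flagged, transitions)]
        flagged[which.max(ret[up])]
      }
      tibble(
        blocked_transitions = paste(flagged, collapse = ";"),
        primary_block = primary,
        n_blocks = length(flagged)
      )
    }) %>%
    ungroup()
  list(retention = retention, blocks = blocks)
}
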