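#' Tally mutations and splice-site mutations per gene
#'
#' Classifies every catalog record against its gene model and counts,
#' per intron-containing gene, total mutations (`n_muts`) and
#' canonical splice-site mutations (`n_ssm`: in-window *and* labelled
#' `"splicing"`). Records in genes absent from `models` are skipped
#' with a message; intronless genes are excluded. Catalog-wide totals
#' (`totalspl`, `totalmuts`, `totalSS`, `totalCDS`) are attached as
#' the `"globals"` attribute and reported by [glance()].
#'
#' @param catalog Mutation records (`gene_id`, `position`,
#'   `dm_class`).
#' @param models A [gene_models()] tibble.
#' @return Tibble of class `"ssm_tally"`: `gene_id`, `n_muts`,
#'   `n_ssm`, `gene_ss`, `gene_cds`.
#' @export
tally_genes <- function(catalog, models) {
  known <- catalog$gene_id %in% models$gene_id
  if (any(!known)) {
    inform(sprintf("skipping %d record(s) in unknown genes", sum(!known)))
    catalog <- catalog[known, ]
  }
  intronful <- models[models$n_introns > 0, ]
  catalog <- catalog[catalog$gene_id %in% intronful$gene_id, ]
  classified <- classify_regions(catalog, intronful)
  tallies <- classified %>%
    group_by(.data$gene_id) %>%
    summarise(n_muts = dplyr::n(), n_ssm = sum(.data$is_ssm), .groups = "drop") %>%
    left_join(
      tibble(gene_id = intronful$gene_id, gene_ss = intronful$n_splice_sites,
             gene_cds = intronful$cds_length),
      by = "gene_id"
    )
  globals <- list(
    totalspl = sum(tallies$n_ssm), totalmuts = sum(tallies$n_muts),
    totalSS = sum(tallies$gene_ss), totalCDS = sum(tallies$gene_cds)
  )
  attr(tallies, "globals") <- globals
  class(tallies) <- c("ssm_tally", class(tallies))
  tallies
}

#' Global sampling weights of a tally
#'
#' @param tallies An `"ssm_tally"` from [tally_genes()].
#' @return Named list: `totalspl`, `totalmuts`, `totalSS`, `totalCDS`.
#' @export
global_weights <- function(tallies) {
  g <- attr(tallies, "globals")
  if (is.null(g)) {
    g <- list(totalspl = sum(tallies$n_ssm), totalmuts = sum(tallies$n_muts),
              totalSS = sum(tallies$gene_ss), totalCDS = sum(tallies$gene_cds))
  }
  g
}

#' Monte Carlo sampling envelope for splice-site mutation counts
#'
#' For each gene, simulates the SSM count `n_reps` times as
#' `Binomial(n_muts, w)` and compares the observed count with the
#' empirical envelope. In `"global"` mode the weight is the
#' catalog-wide SSM proportion `totalspl/totalmuts`; in
#' `"normalized"` mode each gene's weight is additionally scaled by
#' its splice-site density,
#' `(totalspl/totalmuts) (totalCDS/totalSS) (gene_ss/gene_cds)`,
#' clipped to \[0, 1\] with a warning. Envelope bounds are the order
#' statistics at `ceil(q n_reps)` for the two tail fractions of
#' `ci_level`; a gene is `Upper`/`Lower` only when the observed count
#' falls strictly outside the simulated bounds. Each gene draws from
#' its own RNG substream keyed by its identifier, so results do not
#' depend on catalog order.
#'
#' @param tallies An `"ssm_tally"` (or any tibble with `gene_id`,
#'   `n_muts`, `n_ssm`, and for normalized mode `gene_ss`,
#'   `gene_cds`).
#' @param mode `"global"` or `"normalized"`.
#' @param n_reps Replicates (>= 100; default 1000).
#' @param ci_level Envelope coverage (default 0.999).
#' @param seed Integer seed.
#' @param weights Optional list overriding [global_weights()].
#' @return Tibble of class `"ssm_envelope"`: `gene_id`, `n_muts`,
#'   `observed`, `weight`, `lower`, `upper`, `p_emp` (two-sided
#'   add-one empirical p, `2 min(tails)` capped at 1) and `category`
#'   in `{Upper, Expected, Lower}`. Genes with `n_muts = 0` are
#'   `Expected` by definition.
#' @export
mc_envelope <- function(tallies, mode = c("global", "normalized"),
                        n_reps = 1000, ci_level = 0.999, seed = 1L,
                        weights = NULL) {
  mode <- match.arg(mode)
  stopifnot(n_reps >= 100, ci_level > 0, ci_level < 1)
  g <- weights %||% global_weights(tallies)
  w_global <- if (g$totalmuts > 0) g$totalspl / g$totalmuts else 0
  w <- if (mode == "global") {
    rep(w_global, nrow(tallies))
  } else {
    stopifnot(all(c("gene_ss", "gene_cds") %in% names(tallies)))
    wg <- w_global * (g$totalCDS / g$totalSS) * (tallies$gene_ss / tallies$gene_cds)
    if (any(wg > 1)) {
      warn(sprintf("%d gene weight(s) > 1 clipped to 1", sum(wg > 1)))
      wg <- pmin(wg, 1)
    }
    wg
  }
  sim_envelope(
    entity_id = tallies$gene_id, n = tallies$n_muts, observed = tallies$n_ssm,
    weight = w, n_reps = n_reps, ci_level = ci_level, seed = seed,
    stream_prefix = "envelope:"
  )
}

#' Exon-level envelope for exonic splicing mutations
#'
#' The same sampling machinery applied per exon: the number of
#' assay-positive exonic splicing mutations (ESM) among `n_tested`
#' mutations is simulated as `Binomial(n_tested, weight)`, with the
#' weight defaulting to the pooled ESM proportion
#' `sum(n_esm)/sum(n_tested)`. Exons with `n_tested = 0` are
#' excluded. Upper exons carry more ESM than expected.
#'
#' @param exon_tallies Tibble with `exon_id`, `n_tested`, `n_esm`.
#' @param weight Sampling weight in \[0, 1\]; default pooled.
#' @param n_reps,ci_level,seed As in [mc_envelope()].
#' @return An `"ssm_envelope"` tibble keyed by `exon_id`.
#' @export
#' @examples
#' exon_esm_envelope(mlh1_exon_tallies(), weight = 0.10, seed = 1)
exon_esm_envelope <- function(exon_tallies, weight = NULL, n_reps = 1000,
                              ci_level = 0.999, seed = 1L) {
  stopifnot(all(c("exon_id", "n_tested", "n_esm") %in% names(exon_tallies)),
            all(exon_tallies$n_esm <= exon_tallies$n_tested))
  keep <- exon_tallies$n_tested > 0
  exon_tallies <- exon_tallies[keep, ]
  w <- weight %||% (sum(exon_tallies$n_esm) / sum(exon_tallies$n_tested))
  stopifnot(w >= 0, w <= 1)
  out <- sim_envelope(
    entity_id = exon_tallies$exon_id, n = exon_tallies$n_tested,
    observed = exon_tallies$n_esm, weight = rep(w, nrow(exon_tallies)),
    n_reps = n_reps, ci_level = ci_level, seed = seed,
    stream_prefix = "exon_envelope:"
  )
  rename(out, exon_id = "gene_id", n_tested = "n_muts")
}

sim_envelope <- function(entity_id, n, observed, weight, n_reps, ci_level, seed,
                         stream_prefix) {
  tail_q <- (1 - ci_level) / 2
  lo_idx <- max(1, ceiling(tail_q * n_reps))
  hi_idx <- min(n_reps, ceiling((1 - tail_q) * n_reps))
  m <- length(entity_id)
  lower <- upper <- p_emp <- numeric(m)
  category <- character(m)
  for (i in seq_len(m)) {
    if (n[i] == 0) {
      lower[i] <- 0; upper[i] <- 0; p_emp[i] <- 1; category[i] <- "Expected"
      next
    }
    sims <- with_substream(seed, paste0(stream_prefix, entity_id[i]), {
      rbinom(n_reps, n[i], weight[i])
    })
    sorted <- sort.int(sims, method = "quick")
    lower[i] <- sorted[lo_idx]
    upper[i] <- sorted[hi_idx]
    p_hi <- (1 + sum(sims >= observed[i])) / (1 + n_reps)
    p_lo <- (1 + sum(sims <= observed[i])) / (1 + n_reps)
    p_emp[i] <- min(1, 2 * min(p_hi, p_lo))
    category[i] <- if (observed[i] > upper[i]) "Upper" else if (observed[i] < lower[i]) "Lower" else "Expected"
  }
  out <- tibble(gene_id = entity_id, n_muts = n, observed = observed,
                weight = weight, lower = lower, upper = upper, p_emp = p_emp,
                category = category)
  out$category <- factor(out$category, levels = c("Lower", "Expected", "Upper"))
  class(out) <- c("ssm_envelope", class(out))
  out
}

#' Exact binomial envelope bounds
#'
#' Closed-form counterpart of the Monte Carlo envelope, for
#' validation: the binomial quantiles at the same two tail fractions,
#' computed by CDF inversion.
#'
#' @param n Number of trials (<= 1e4).
#' @param w Success probability.
#' @param ci_level Envelope coverage.
#' @return Named numeric vector `c(lower, upper)`.
#' @export
#' @examples
#' binomial_oracle(100, 0.134, 0.999)
binomial_oracle <- function(n, w, ci_level = 0.999) {
  stopifnot(n <= 1e4, n >= 0, w >= 0, w <= 1)
  if (n == 0) return(c(lower = 0, upper = 0))
  tail_q <- (1 - ci_level) / 2
  c(lower = qbinom(tail_q, n, w), upper = qbinom(1 - tail_q, n, w))
}

#' Tested-mutation and ESM counts for the five assayed MLH1 exons
#'
#' The published per-exon results of the mismatch-repair gene MLH1's
#' massively parallel splicing assay panel: all 6 mutations in exon 8
#' and 5 of 7 in exon 15 disrupted splicing, while the 23 mutations in
#' exons 4, 5 and 7 did not (here split 8/8/7; any split leaves those
#' exons unflagged since their observed count is zero). Total: 36
#' tested, 11 ESM.
#'
#' @return Tibble with `exon_id`, `n_tested`, `n_esm`.
#' @export
mlh1_exon_tallies <- function() {
  tibble(
    exon_id = c("MLH1_exon4", "MLH1_exon5", "MLH1_exon7", "MLH1_exon8", "MLH1_exon15"),
    n_tested = c(8L, 8L, 7L, 6L, 7L),
    n_esm = c(0L, 0L, 0L, 6L, 5L)
  )
}
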