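#' Synthetic gene models
#'
#' Generates one canonical transcript per gene with log-normal exon and
#' intron lengths (medians ~140 nt and ~800 nt), a Poisson number of
#' introns, random strand, and optionally a random nucleotide sequence
#' with splice-site windows drawn from built-in donor/acceptor base
#' frequency models. Each gene has its own RNG substream keyed by its
#' identifier, so enlarging the set does not perturb existing genes.
#'
#' @param n_genes Number of genes.
#' @param seed Integer seed.
#' @param min_exons Minimum exon count (default 2: every gene has
#'   introns, as the enrichment analysis requires).
#' @param mean_extra_exons Poisson mean for exons beyond the minimum.
#' @param with_sequence If `TRUE`, attach a `sequence` column (the
#'   genomic sequence of the gene span, plus strand).
#' @return A [gene_models()] tibble (with `sequence` when requested).
#' @export
gen_gene_models <- function(n_genes, seed = 1L, min_exons = 2L,
                            mean_extra_exons = 6, with_sequence = FALSE) {
  ids <- sprintf("sgene%04d", seq_len(n_genes))
  rows <- purrr::map(ids, function(id) {
    with_substream(seed, paste0("model:", id), {
      k <- min_exons + rpois(1, mean_extra_exons)
      exon_len <- pmax(30, round(exp(rnorm(k, log(140), 0.45))))
      intron_len <- if (k > 1) pmax(80, round(exp(rnorm(k - 1, log(800), 0.6)))) else integer(0)
      start0 <- 1000 + round(runif(1, 0, 1e5))
      starts <- start0 + cumsum(c(0, head(exon_len, -1) + intron_len))
      strand <- sample(c("+", "-"), 1)
      list(id = id, strand = strand,
           exons = tibble(start = starts, end = starts + exon_len))
    })
  })
  models <- gene_models(
    gene_id = purrr::map_chr(rows, "id"),
    chrom = "chrS1",
    strand = purrr::map_chr(rows, "strand"),
    exons = purrr::map(rows, "exons")
  )
  if (with_sequence) {
    models$sequence <- purrr::map_chr(seq_len(nrow(models)), function(i) {
      with_substream(seed, paste0("seq:", models$gene_id[i]), {
        gene_sequence_with_sites(models[i, ])
      })
    })
  }
  models
}

# Random gene-span sequence with donor/acceptor windows overwritten by
# draws from the built-in splice-site base-frequency models. The
# returned string covers [gene_start, gene_end) in *transcript*
# orientation.
gene_sequence_with_sites <- function(model) {
  len <- model$gene_end - model$gene_start
  seq <- sample(c("A", "C", "G", "T"), len, replace = TRUE,
                prob = c(0.27, 0.23, 0.23, 0.27))
  sites <- splice_sites(model)
  for (j in seq_len(nrow(sites))) {
    kind <- sites$site_kind[j]
    win <- site_window_positions(sites$junction[j], kind, model$strand[1])
    win <- win - model$gene_start  # 0-based within span, transcript-ordered
    drawn <- sample_site_sequence(kind)
    keep <- win >= 0 & win < len
    idx <- if (model$strand[1] == "+") win[keep] + 1 else len - win[keep]
    seq[idx] <- strsplit(drawn, "")[[1]][keep]
  }
  paste(seq, collapse = "")
}

# Genomic 0-based positions of a splice-site window, ordered by
# transcript offset (-3..+6 for donors, -20..+3 for acceptors).
site_window_positions <- function(junction, site_kind, strand) {
  offs <- if (site_kind == "5ss") c(-3:-1, 1:6) else c(-20:-1, 1:3)
  if (strand == "+") junction + offs - (offs > 0) else junction - offs - (offs < 0)
}

#' Built-in splice-site base-frequency models
#'
#' Synthetic per-position base frequencies approximating the mammalian
#' donor (9 positions, -3..+6) and acceptor (23 positions, -20..+3)
#' consensus. These drive the sequence generator and supply training
#' material for [build_pwm()]; they are stand-ins, not estimates from
#' any real splice-site compilation.
#'
#' @param site_kind `"5ss"` or `"3ss"`.
#' @return A 4 x L matrix of base frequencies (rows A, C, G, T).
#' @export
site_base_freqs <- function(site_kind = c("5ss", "3ss")) {
  site_kind <- match.arg(site_kind)
  if (site_kind == "5ss") {
    m <- cbind(
      c(0.33, 0.37, 0.18, 0.12),  # -3
      c(0.60, 0.13, 0.12, 0.15),  # -2
      c(0.08, 0.04, 0.80, 0.08),  # -1
      c(0.004, 0.003, 0.99, 0.003),  # +1 G
      c(0.003, 0.004, 0.003, 0.99),  # +2 T
      c(0.50, 0.03, 0.42, 0.05),  # +3
      c(0.70, 0.08, 0.12, 0.10),  # +4
      c(0.08, 0.06, 0.80, 0.06),  # +5
      c(0.17, 0.16, 0.20, 0.47)   # +6
    )
  } else {
    ppt <- c(0.08, 0.32, 0.10, 0.50)  # pyrimidine tract column
    m <- cbind(
      matrix(rep(ppt, 18), nrow = 4),  # -20..-3
      c(0.99, 0.004, 0.003, 0.003),    # -2 A
      c(0.004, 0.003, 0.99, 0.003),    # -1 G  (the intron-terminal AG)
      c(0.25, 0.30, 0.24, 0.21),       # +1
      c(0.25, 0.25, 0.25, 0.25),       # +2
      c(0.25, 0.25, 0.25, 0.25)        # +3
    )
  }
  rownames(m) <- c("A", "C", "G", "T")
  m
}

# One site sequence drawn column-wise from the base-frequency model.
sample_site_sequence <- function(site_kind) {
  f <- site_base_freqs(site_kind)
  paste(apply(f, 2, function(p) sample(rownames(f), 1, prob = p)), collapse = "")
}

#' Sample aligned splice-site training sequences
#'
#' @param n Number of sequences.
#' @param site_kind `"5ss"` or `"3ss"`.
#' @param seed Integer seed.
#' @return Character vector of length `n` (width 9 or 23).
#' @export
sample_splice_sites <- function(n, site_kind = c("5ss", "3ss"), seed = 1L) {
  site_kind <- match.arg(site_kind)
  f <- site_base_freqs(site_kind)
  set.seed(seed)
  vapply(seq_len(n), function(i) {
    paste(apply(f, 2, function(p) sample(rownames(f), 1, prob = p)), collapse = "")
  }, character(1))
}

#' Synthetic disease-mutation catalog with known enrichment truth
#'
#' Emulates a hereditary-disease mutation catalog: per-gene mutation
#' counts follow a long-tailed law (default 1 + negative binomial with
#' mean 20 and shape 2), and each mutation is a canonical splice-site
#' mutation (SSM) with probability `global_ssm_weight`, multiplied by
#' `multiplier` for the enriched minority of genes (clipped to 1 with a
#' warning). SSM records are placed inside donor/acceptor windows and
#' labelled `"splicing"`; the remainder are exonic and split
#' missense:nonsense 3:1.
#'
#' @param n_genes Number of genes (ignored when `models` is supplied).
#' @param seed Integer seed.
#' @param models Optional [gene_models()] tibble; generated internally
#'   by default.
#' @param mut_count_law Function `n -> integer counts` for per-gene
#'   mutation totals.
#' @param enriched_fraction Fraction of genes with elevated SSM rate.
#' @param multiplier SSM-probability multiplier for enriched genes.
#' @param global_ssm_weight Null per-mutation SSM probability
#'   (default 0.134).
#' @return A list with `catalog` (mutation records), `models`, and
#'   `truth` (per-gene `enriched`, `multiplier`, `p_ssm`, `n_muts`,
#'   `n_ssm`).
#' @export
#' @examples
#' sim <- gen_catalog(n_genes = 50, seed = 1)
#' mean(sim$catalog$dm_class == "splicing")
gen_catalog <- function(n_genes = 2000, seed = 1L, models = NULL,
                        mut_count_law = function(n) 1L + rnbinom(n, size = 2, mu = 20),
                        enriched_fraction = 0, multiplier = 1,
                        global_ssm_weight = 0.134) {
  stopifnot(enriched_fraction >= 0, enriched_fraction <= 1, multiplier >= 0)
  if (is.null(models)) models <- gen_gene_models(n_genes, seed = seed)
  n_genes <- nrow(models)
  set.seed(substream_seed(seed, "catalog:frame"))
  n_muts <- mut_count_law(n_genes)
  enriched <- runif(n_genes) < enriched_fraction
  p_ssm <- global_ssm_weight * ifelse(enriched, multiplier, 1)
  if (any(p_ssm > 1)) {
    warn("SSM probability clipped to 1 for some enriched genes")
    p_ssm <- pmin(p_ssm, 1)
  }
  sites <- splice_sites(models)
  site_by_gene <- split(seq_len(nrow(sites)), sites$gene_id)
  bases <- c("A", "C", "G", "T")
  parts <- purrr::map(seq_len(n_genes), function(i) {
    gid <- models$gene_id[i]
    with_substream(seed, paste0("catalog:", gid), {
      n <- n_muts[i]
      sidx <- site_by_gene[[gid]]
      k_ssm <- if (!is.null(sidx)) rbinom(1, n, p_ssm[i]) else 0L
      win_pos <- unlist(lapply(sidx, function(s) {
        site_window_positions(sites$junction[s], sites$site_kind[s],
                              models$strand[i])
      }))
      win_pos <- win_pos[win_pos >= models$gene_start[i] & win_pos < models$gene_end[i]]
      ex <- models$exons[[i]]
      exonic_pos <- unlist(mapply(function(s, e) s:(e - 1), ex$start, ex$end,
                                  SIMPLIFY = FALSE))
      ssm_pos <- if (k_ssm > 0) sample(win_pos, k_ssm, replace = TRUE) else double(0)
      other_pos <- if (n - k_ssm > 0) sample(exonic_pos, n - k_ssm, replace = TRUE) else double(0)
      other_class <- if (n - k_ssm > 0) {
        sample(c("missense", "nonsense"), n - k_ssm, replace = TRUE, prob = c(0.75, 0.25))
      } else character(0)
      ref_i <- sample.int(4, n, replace = TRUE)
      alt_i <- (ref_i + sample.int(3, n, replace = TRUE) - 1L) %% 4L + 1L
      list(gene_id = rep(gid, n), chrom = rep(models$chrom[i], n),
           position = c(ssm_pos, other_pos),
           ref = bases[ref_i], alt = bases[alt_i],
           dm_class = c(rep("splicing", k_ssm), other_class))
    })
  })
  recs <- tibble(
    gene_id = unlist(purrr::map(parts, "gene_id")),
    chrom = unlist(purrr::map(parts, "chrom")),
    position = unlist(purrr::map(parts, "position")),
    ref = unlist(purrr::map(parts, "ref")),
    alt = unlist(purrr::map(parts, "alt")),
    dm_class = unlist(purrr::map(parts, "dm_class"))
  )
  truth <- tibble(
    gene_id = models$gene_id, enriched = enriched,
    multiplier = ifelse(enriched, multiplier, 1), p_ssm = p_ssm,
    n_muts = n_muts,
    n_ssm = as.integer(table(factor(recs$gene_id[recs$dm_class == "splicing"],
                                    levels = models$gene_id)))
  )
  list(catalog = recs, models = models, truth = truth)
}

#' Synthetic MaPSy-style count tables
#'
#' Each wild-type/mutant pair gets overdispersed (gamma-Poisson) input
#' read counts around `depth` in both assays; spliced counts are
#' Poisson around `input x base_splicing`, with the mutant's rate
#' multiplied by `2^effect` for the `esm_fraction` of pairs that are
#' true exonic splicing mutations. Non-ESM pairs preserve allele
#' proportions, so their expected log2 allelic imbalance is zero.
#'
#' @param n_pairs Number of wt/mt pairs.
#' @param depth Mean input read count per allele.
#' @param esm_fraction Fraction of pairs with a real splicing effect
#'   (default 0.10, the background ESM rate among assayed disease
#'   alleles).
#' @param effect_law Function `n -> log2 effects` for ESM pairs
#'   (default uniform on \[-4, -1\]).
#' @param dispersion Gamma-Poisson shape for input counts.
#' @param base_splicing Baseline spliced/input rate.
#' @param assays Assay labels (both are generated independently with
#'   the same true effect).
#' @param seed Integer seed.
#' @return A list with `counts` (long tibble: `pair_id`, `allele`,
#'   `assay`, `inp`, `spl`) and `truth` (`pair_id`, `is_esm`,
#'   `effect`).
#' @export
gen_mapsy_counts <- function(n_pairs = 5000, depth = 2000, esm_fraction = 0.10,
                             effect_law = function(n) runif(n, -4, -1),
                             dispersion = 10, base_splicing = 0.5,
                             assays = c("in_vivo", "in_vitro"), seed = 1L) {
  stopifnot(depth > 0, esm_fraction >= 0, esm_fraction <= 1)
  set.seed(substream_seed(seed, "mapsy"))
  pair_id <- sprintf("pair%05d", seq_len(n_pairs))
  is_esm <- runif(n_pairs) < esm_fraction
  effect <- ifelse(is_esm, effect_law(n_pairs), 0)
  counts <- purrr::map(assays, function(a) {
    wt_inp <- pmax(1, rnbinom(n_pairs, size = dispersion, mu = depth))
    mt_inp <- pmax(1, rnbinom(n_pairs, size = dispersion, mu = depth))
    wt_spl <- rpois(n_pairs, wt_inp * base_splicing)
    mt_spl <- rpois(n_pairs, mt_inp * base_splicing * 2^effect)
    bind_rows(
      tibble(pair_id = pair_id, allele = "wt", assay = a, inp = wt_inp, spl = wt_spl),
      tibble(pair_id = pair_id, allele = "mt", assay = a, inp = mt_inp, spl = mt_spl)
    )
  }) %>% bind_rows()
  list(
    counts = arrange(counts, .data$pair_id, .data$assay, desc(.data$allele)),
    truth = tibble(pair_id = pair_id, is_esm = is_esm, effect = effect)
  )
}

#' Synthetic gene-level feature table with planted class differences
#'
#' Emulates the 19-feature genomic table used to classify SSM-prone
#' (Upper) genes against Expected genes. At `effect_profile = 1`,
#' Upper genes have 2.5x more introns, higher haploinsufficiency,
#' shorter exons, more structured exons and splice-site flanks (lower
#' free energy), and lower population-variant conservation; the other
#' features carry no signal. `effect_profile = 0` makes all features
#' exchangeable across labels.
#'
#' @param labels Character vector over `{upper, expected, lower}`, or
#'   an integer total `n_genes` to draw labels as 5% upper / 90%
#'   expected / 5% lower.
#' @param effect_profile Scalar scaling of the planted shifts.
#' @param noise Scalar multiplying every feature's spread.
#' @param seed Integer seed.
#' @return Tibble with `gene_id`, `label`, and 19 numeric features;
#'   the planted shift table is attached as attribute `"signal"` (also
#'   available via [feature_signal_directions()]).
#' @export
gen_feature_table <- function(labels = 600, effect_profile = 1, noise = 1, seed = 1L) {
  if (is.numeric(labels) && length(labels) == 1) {
    set.seed(substream_seed(seed, "features:labels"))
    labels <- sample(c("upper", "expected", "lower"), labels,
                     replace = TRUE, prob = c(0.05, 0.90, 0.05))
  }
  stopifnot(all(labels %in% c("upper", "expected", "lower")))
  n <- length(labels)
  up <- labels == "upper"
  sig <- feature_signal_directions()
  set.seed(substream_seed(seed, "features:values"))
  # intron count: multiplicative 2.5-fold at effect_profile = 1
  base_lambda <- 6.8
  ratio <- 1 + (2.5 - 1) * effect_profile
  lambda_up <- ratio * (1 + base_lambda) - 1  # mean ratio upper:expected = `ratio`
  intron_count <- 1 + rpois(n, ifelse(up, lambda_up, base_lambda))
  gauss <- function(base, sd0, shift_sd) {
    base + ifelse(up, shift_sd * effect_profile * sd0, 0) + rnorm(n, 0, sd0 * noise)
  }
  out <- tibble(
    gene_id = sprintf("fgene%04d", seq_len(n)),
    label = labels,
    intron_count = intron_count,
    mean_exon_length = gauss(145, 35, -0.8),
    mean_intron_length = gauss(1200, 400, 0),
    cds_length = gauss(1800, 600, 0),
    gene_length = gauss(25000, 9000, 0),
    gc_content = gauss(0.46, 0.05, 0),
    exon_dg = gauss(-30, 8, -0.7),
    ss_dg = gauss(-25, 7, -0.8),
    hi_score = gauss(0.45, 0.18, 0.9),
    exon_snp_density = gauss(0.012, 0.004, 0),
    gene_snp_density = gauss(0.008, 0.003, 0),
    exon_conservation = gauss(0.75, 0.1, 0),
    gene_conservation = gauss(0.6, 0.12, 0),
    exac_variant_conservation = gauss(0.5, 0.12, -0.8),
    ese_density = gauss(0.06, 0.015, 0),
    ess_density = gauss(0.04, 0.012, 0),
    esr_density = gauss(0.10, 0.02, 0),
    mean_5ss_strength = gauss(8, 1.8, 0),
    mean_3ss_strength = gauss(7, 1.6, 0)
  )
  attr(out, "signal") <- sig
  attr(out, "effect_profile") <- effect_profile
  out
}

#' Planted feature-signal directions of the synthetic feature table
#'
#' @return Tibble with `feature`, `direction` (+1 higher in Upper
#'   genes, -1 lower, 0 no signal) and `strength` (approximate shift in
#'   SD units at `effect_profile = 1`; intron count is multiplicative
#'   and is the strongest planted signal).
#' @export
feature_signal_directions <- function() {
  tibble(
    feature = c("intron_count", "mean_exon_length", "mean_intron_length",
                "cds_length", "gene_length", "gc_content", "exon_dg", "ss_dg",
                "hi_score", "exon_snp_density", "gene_snp_density",
                "exon_conservation", "gene_conservation",
                "exac_variant_conservation", "ese_density", "ess_density",
                "esr_density", "mean_5ss_strength", "mean_3ss_strength"),
    direction = c(1, -1, 0, 0, 0, 0, -1, -1, 1, 0, 0, 0, 0, -1, 0, 0, 0, 0, 0),
    strength = c(2.5, 0.8, 0, 0, 0, 0, 0.7, 0.8, 0.9, 0, 0, 0, 0, 0.8, 0, 0, 0, 0, 0)
  )
}

#' Synthetic population splice-site variants under purifying selection
#'
#' Draws splice-site sequences from the built-in donor (or acceptor)
#' model, applies one random substitution per variant, and scores the
#' reference-minus-alternate PWM difference (positive = weakening).
#' Minor allele frequencies follow a log-uniform law; variants that
#' abolish the site (delta above `delta_cut`) have their draws of a
#' common MAF thinned by `1/selection_strength` (rejected draws are
#' retaken from the full law), emulating removal by selection before
#' reaching high frequency.
#'
#' @param n_variants Number of variants (ignored if `models` given and
#'   `per_site` used).
#' @param selection_strength Thinning factor for common site-abolishing
#'   alleles; values at or below 1 (including 0) mean no selection.
#' @param site_kind `"5ss"` or `"3ss"`.
#' @param delta_cut Weakening threshold defining the selected class
#'   (default 5).
#' @param maf_log10_range Range of log10 MAF for the neutral law.
#' @param models Optional [gene_models()] tibble; when supplied each
#'   variant is assigned to a random in-window genomic position of a
#'   random gene, and genes listed in `prone_genes` receive
#'   `1/prone_depletion` as many variants (site-level purifying
#'   selection on predicted SSM-prone genes).
#' @param prone_genes,prone_depletion See `models`.
#' @param maf_rare,maf_common Stratum cutoffs.
#' @param seed Integer seed.
#' @return Tibble of variants (`gene_id`, `site_kind`, `position`,
#'   `ref_site`, `alt_site`, `delta`, `maf`, `stratum`), with
#'   attributes `"expected_depletion"` (closed-form depletion factor of
#'   the delta > cut class among common vs rare implied by the
#'   generator) and `"params"`.
#' @export
gen_population_variants <- function(n_variants = 10000, selection_strength = 4,
                                    site_kind = c("5ss", "3ss"), delta_cut = 5,
                                    maf_log10_range = c(-6.5, -0.5),
                                    models = NULL, prone_genes = character(0),
                                    prone_depletion = 1,
                                    maf_rare = 1e-4, maf_common = 0.01,
                                    seed = 1L) {
  site_kind <- match.arg(site_kind)
  stopifnot(selection_strength >= 0, prone_depletion >= 1)
  # values <= 1 (including 0) mean no selection
  selection_strength <- max(1, selection_strength)
  pwm <- build_pwm(sample_splice_sites(2000, site_kind, seed = substream_seed(seed, "pwmtrain")),
                   site_kind = site_kind)
  set.seed(substream_seed(seed, "popvar"))
  f <- site_base_freqs(site_kind)
  L <- ncol(f)
  bases <- rownames(f)
  ref_mat <- apply(f, 2, function(p) sample(bases, n_variants, replace = TRUE, prob = p))
  pos <- sample.int(L, n_variants, replace = TRUE)
  ref_base <- ref_mat[cbind(seq_len(n_variants), pos)]
  alt_base <- vapply(ref_base, function(b) sample(setdiff(bases, b), 1), character(1))
  alt_mat <- ref_mat
  alt_mat[cbind(seq_len(n_variants), pos)] <- alt_base
  ref_site <- apply(ref_mat, 1, paste, collapse = "")
  alt_site <- apply(alt_mat, 1, paste, collapse = "")
  delta <- score_splice_seq(pwm, ref_site) - score_splice_seq(pwm, alt_site)

  draw_maf <- function(n) 10^runif(n, maf_log10_range[1], maf_log10_range[2])
  maf <- draw_maf(n_variants)
  selected <- delta > delta_cut
  if (selection_strength > 1) {
    # rejection: a common draw for a selected variant survives w.p. 1/s
    redo <- selected & maf > maf_common & runif(n_variants) > 1 / selection_strength
    while (any(redo)) {
      maf[redo] <- draw_maf(sum(redo))
      redo <- redo & maf > maf_common & runif(length(maf)) > 1 / selection_strength
    }
  }
  stratum <- case_when(
    maf < maf_rare ~ "rare",
    maf > maf_common ~ "common",
    TRUE ~ "intermediate"
  )
  out <- tibble(
    gene_id = sprintf("site%05d", seq_len(n_variants)),
    site_kind = site_kind, position = NA_real_,
    ref_site = ref_site, alt_site = alt_site,
    delta = delta, maf = maf, stratum = stratum
  )
  if (!is.null(models)) {
    sites <- splice_sites(models)
    keep_p <- ifelse(sites$gene_id %in% prone_genes, 1 / prone_depletion, 1)
    w <- keep_p / sum(keep_p)
    pick <- sample.int(nrow(sites), n_variants, replace = TRUE, prob = w)
    out$gene_id <- sites$gene_id[pick]
    out$site_kind <- sites$site_kind[pick]
    out$position <- purrr::map_dbl(pick, function(ix) {
      wp <- site_window_positions(sites$junction[ix], sites$site_kind[ix],
                                  sites$strand[ix])
      wp[sample.int(length(wp), 1)]
    })
  }
  # closed-form depletion factor implied by the thinning scheme
  q <- mean(selected)
  lo <- maf_log10_range[1]; hi <- maf_log10_range[2]
  p_r <- (log10(maf_rare) - lo) / (hi - lo)
  p_c <- (hi - log10(maf_common)) / (hi - lo)
  z <- 1 - p_c * (1 - 1 / selection_strength)
  share_rare_sel <- q * (p_r / z) / (q * (p_r / z) + (1 - q) * p_r)
  share_common_sel <- q * (p_c / (selection_strength * z)) /
    (q * (p_c / (selection_strength * z)) + (1 - q) * p_c)
  attr(out, "expected_depletion") <- share_rare_sel / share_common_sel
  attr(out, "params") <- list(selection_strength = selection_strength,
                              delta_cut = delta_cut, q_selected = q)
  out
}
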