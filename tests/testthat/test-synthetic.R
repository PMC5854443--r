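test_that("generators are bit-reproducible and stable under set growth", {
  a <- gen_catalog(n_genes = 40, seed = 11)
  b <- gen_catalog(n_genes = 40, seed = 11)
  expect_identical(a$catalog, b$catalog)
  expect_identical(a$truth, b$truth)

  m10 <- gen_gene_models(10, seed = 11)
  m20 <- gen_gene_models(20, seed = 11)
  expect_identical(as.data.frame(m10), as.data.frame(m20[1:10, ]))

  p1 <- gen_population_variants(500, seed = 4)
  p2 <- gen_population_variants(500, seed = 4)
  expect_identical(p1$delta, p2$delta)
  f1 <- gen_feature_table(100, seed = 4)
  expect_identical(f1, gen_feature_table(100, seed = 4))
  ms <- gen_mapsy_counts(n_pairs = 50, seed = 4)
  expect_identical(ms, gen_mapsy_counts(n_pairs = 50, seed = 4))
})

test_that("null catalogs hit the global SSM weight and mark no genes enriched", {
  sim <- gen_catalog(n_genes = 40, seed = 2, enriched_fraction = 0.5, multiplier = 1)
  expect_true(all(!sim$truth$enriched) || all(sim$truth$multiplier == 1))
  expect_true(all(sim$truth$p_ssm == 0.134))

  sim <- gen_catalog(n_genes = 1200, seed = 5)
  frac <- mean(sim$catalog$dm_class == "splicing")
  se <- sqrt(0.134 * 0.866 / nrow(sim$catalog))
  expect_lt(abs(frac - 0.134), 4 * se)
  # non-SSM classes split missense:nonsense ~ 3:1
  other <- sim$catalog$dm_class[sim$catalog$dm_class != "splicing"]
  expect_lt(abs(mean(other == "missense") - 0.75), 0.02)
})

test_that("enriched genes carry the multiplied SSM rate (clipped mean 26.8 at n=50)", {
  sim <- gen_catalog(
    n_genes = 400, seed = 9, enriched_fraction = 1, multiplier = 4,
    mut_count_law = function(n) rep(50L, n)
  )
  expect_true(all(sim$truth$enriched))
  expect_true(all(sim$truth$p_ssm == 0.536))
  # closed-form mean: 50 x 0.134 x 4 = 26.8
  se <- sqrt(50 * 0.536 * 0.464 / 400)
  expect_lt(abs(mean(sim$truth$n_ssm) - 26.8), 4 * se)
  expect_warning(
    gen_catalog(n_genes = 10, seed = 1, enriched_fraction = 1, multiplier = 10),
    "clipped"
  )
})

test_that("per-gene mutation counts follow the shifted negative binomial law", {
  sim <- gen_catalog(n_genes = 2000, seed = 13)
  n <- sim$truth$n_muts
  expect_true(all(n >= 1))
  # chi-square GoF against 1 + NB(size 2, mu 20), pooled tails
  breaks <- c(seq(1, 61, by = 5), Inf)
  obs <- table(cut(n, breaks, right = FALSE))
  pr <- diff(c(pnbinom(breaks - 1 - 1, size = 2, mu = 20), 1))
  pr <- pr[seq_along(obs)] / sum(pr[seq_along(obs)])
  gof <- suppressWarnings(chisq.test(as.vector(obs), p = pr))
  expect_gt(gof$p.value, 0.001)
})

test_that("MaPSy generator plants recoverable allelic effects", {
  # no-effect limit: imbalance shrinks with depth
  null_lo <- gen_mapsy_counts(n_pairs = 300, depth = 100, esm_fraction = 0, seed = 3)
  null_hi <- gen_mapsy_counts(n_pairs = 300, depth = 2e4, esm_fraction = 0, seed = 3)
  imbalance <- function(x) {
    w <- tidyr::pivot_wider(x$counts, id_cols = c("pair_id", "assay"),
                            names_from = "allele", values_from = c("inp", "spl"))
    mean(abs(log2_allele_ratio(w$spl_mt, w$inp_mt, w$spl_wt, w$inp_wt)))
  }
  expect_lt(imbalance(null_hi), imbalance(null_lo))
  expect_lt(imbalance(null_hi), 0.05)

  # planted effect -2 at depth 1e4 recovered within sampling error
  eff <- gen_mapsy_counts(n_pairs = 400, depth = 1e4, esm_fraction = 1,
                          effect_law = function(n) rep(-2, n), seed = 6)
  w <- tidyr::pivot_wider(eff$counts, id_cols = c("pair_id", "assay"),
                          names_from = "allele", values_from = c("inp", "spl"))
  est <- log2_allele_ratio(w$spl_mt, w$inp_mt, w$spl_wt, w$inp_wt)
  expect_lt(abs(mean(est) + 2), 0.05)
})

test_that("feature generator reproduces the planted class structure", {
  ft <- gen_feature_table(c(rep("upper", 250), rep("expected", 1500)), seed = 8)
  up <- ft$label == "upper"
  # 2.5-fold intron excess in SSM-prone genes
  ratio <- mean(ft$intron_count[up]) / mean(ft$intron_count[!up])
  expect_lt(abs(ratio - 2.5), 0.25)
  # stated directions: higher HI, shorter exons, lower variant conservation
  expect_gt(mean(ft$hi_score[up]), mean(ft$hi_score[!up]))
  expect_lt(mean(ft$mean_exon_length[up]), mean(ft$mean_exon_length[!up]))
  expect_lt(mean(ft$exac_variant_conservation[up]),
            mean(ft$exac_variant_conservation[!up]))
  kw <- group_rank_tests(ft$intron_count, ft$label, "kruskal_wallis")
  expect_lt(kw$p_value, 1e-6)

  # no signal when the effect profile is zero
  f0 <- gen_feature_table(c(rep("upper", 300), rep("expected", 300)),
                          effect_profile = 0, seed = 8)
  kw0 <- group_rank_tests(f0$intron_count, f0$label, "kruskal_wallis")
  expect_gt(kw0$p_value, 0.001)
  expect_equal(ncol(ft) - 2, 19)
})

test_that("population variants show selection only when configured", {
  neutral <- gen_population_variants(4000, selection_strength = 0, seed = 21)
  ks_ps <- vapply(21:25, function(s) {
    v <- gen_population_variants(3000, selection_strength = 0, seed = s)
    r <- v$delta[v$stratum == "rare"]; c <- v$delta[v$stratum == "common"]
    suppressWarnings(stats::ks.test(r, c)$p.value)
  }, double(1))
  expect_true(all(ks_ps > 0.01))
  expect_equal(attr(neutral, "expected_depletion"), 1)

  strong <- gen_population_variants(4000, selection_strength = 1e6, seed = 22)
  expect_equal(sum(strong$delta > 5 & strong$stratum == "common"), 0)
  expect_gt(sum(strong$delta > 5 & strong$stratum == "rare"), 0)
})

test_that("variants mapped onto gene models land in splice-site windows", {
  m <- gen_gene_models(15, seed = 30)
  v <- gen_population_variants(400, models = m, seed = 30)
  expect_true(all(v$gene_id %in% m$gene_id))
  cls <- classify_regions(
    tibble::tibble(gene_id = v$gene_id, position = v$position), m
  )
  expect_true(all(cls$region %in% c("ss5_window", "ss3_window")))
})
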