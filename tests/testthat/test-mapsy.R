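test_that("splicing efficiency matches hand arithmetic and its invariances", {
  # single species, spliced == input -> 0
  expect_equal(splicing_efficiency(tibble::tibble(inp = 10, spl = 10),
                                   pseudocount = 0)$efficiency, 0)
  # pool of 3: species 1 share 0.1 vs 0.25 -> log2(0.4)
  out <- splicing_efficiency(
    tibble::tibble(inp = c(25, 25, 50), spl = c(10, 20, 70)), pseudocount = 0
  )
  expect_equal(out$efficiency[1], log2(0.1 / 0.25), tolerance = 1e-12)
  expect_equal(out$efficiency[1], -1.3219, tolerance = 1e-4)
  # pool-level identity: sum over species of 2^eff x input share = 1
  expect_equal(sum(2^out$efficiency * c(25, 25, 50) / 100), 1, tolerance = 1e-12)
  # scale invariance: spl = 2 x inp per species -> all zero;
  # rescaling either pool changes nothing
  prop <- splicing_efficiency(
    tibble::tibble(inp = c(5, 10, 15), spl = c(10, 20, 30)), pseudocount = 0
  )
  expect_equal(prop$efficiency, rep(0, 3))
  sc <- splicing_efficiency(
    tibble::tibble(inp = c(25, 25, 50) * 7, spl = c(10, 20, 70)), pseudocount = 0
  )
  expect_equal(sc$efficiency, out$efficiency, tolerance = 1e-12)
  # pools are formed within assay
  two <- splicing_efficiency(
    tibble::tibble(assay = c("a", "a", "b", "b"),
                   inp = c(1, 1, 30, 10), spl = c(2, 2, 60, 20)),
    pseudocount = 0
  )
  expect_equal(two$efficiency, rep(0, 4))
  expect_error(splicing_efficiency(tibble::tibble(inp = double(0), spl = double(0))),
               "empty")
  expect_error(splicing_efficiency(tibble::tibble(inp = c(1, 2), spl = c(0, 0))),
               "no spliced")
})

test_that("allele ratios follow the minor/major convention", {
  expect_equal(log2_allele_ratio(5, 10, 40, 20, pseudocount = 0), -2)
  expect_equal(log2_allele_ratio(12, 6, 30, 15, pseudocount = 0), 0)
  # antisymmetry under swapping minor and major
  expect_equal(log2_allele_ratio(5, 10, 40, 20, pseudocount = 0),
               -log2_allele_ratio(40, 20, 5, 10, pseudocount = 0))

  counts <- tibble::tibble(
    pair_id = "p1",
    allele = rep(c("wt", "mt"), times = 3),
    fraction = rep(c("mRNA", "A", "BC"), each = 2),
    sel = c(40, 5, 10, 40, 20, 20),
    inp = c(20, 10, 20, 10, 20, 20)
  )
  r <- allelic_ratio(counts, pseudocount = 0)
  # mt splices less in mRNA -> minor allele is mt everywhere
  expect_true(all(r$minor_allele == "mt"))
  expect_equal(r$log2_ratio[r$fraction == "mRNA"], -2)
  # mt enriched 4x relative to wt in A complex
  expect_equal(r$log2_mt_over_wt[r$fraction == "A"], 3)
  expect_equal(r$log2_ratio, r$log2_mt_over_wt)  # minor is mt here
  expect_error(allelic_ratio(dplyr::filter(counts, fraction != "mRNA")), "mRNA")
})

test_that("ESM calling combines fold change and FDR-corrected count tests", {
  # identical wt/mt counts -> no effect
  flat <- tibble::tibble(
    pair_id = "p", allele = rep(c("wt", "mt"), 2),
    assay = rep(c("in_vivo", "in_vitro"), each = 2),
    inp = 1000, spl = 500
  )
  expect_equal(call_esm(flat)$call, "no-effect")
  # zero input for one allele -> indeterminate
  degen <- flat; degen$inp[2] <- 0
  expect_equal(call_esm(degen)$call, "indeterminate")
  # missing assay -> indeterminate
  one <- dplyr::filter(flat, assay == "in_vivo")
  one$spl[one$allele == "mt"] <- 10
  both <- dplyr::bind_rows(flat[flat$assay == "in_vitro", ], one)
  both$pair_id <- rep(c("pA", "pB"), each = 2)
  expect_equal(call_esm(both)$call[call_esm(both)$pair_id == "pB"], "indeterminate")

  # planted effect -2 at depth 1e4 -> ESM with probability ~ 1
  sim <- gen_mapsy_counts(n_pairs = 60, depth = 1e4, esm_fraction = 0.5,
                          effect_law = function(n) rep(-2, n), seed = 17)
  calls <- call_esm(sim$counts)
  joined <- dplyr::left_join(calls, sim$truth, by = "pair_id")
  expect_true(all(joined$call[joined$is_esm] == "ESM"))
  expect_true(all(joined$call[!joined$is_esm] == "no-effect"))

  # null panel: false-call rate controlled at the FDR level
  null <- gen_mapsy_counts(n_pairs = 800, depth = 2000, esm_fraction = 0, seed = 18)
  expect_lte(mean(call_esm(null$counts)$call == "ESM"), 0.05)
})

test_that("per-pair effect estimates are unbiased for the planted effect", {
  sim <- gen_mapsy_counts(n_pairs = 500, depth = 1e4, esm_fraction = 1, seed = 19)
  w <- tidyr::pivot_wider(sim$counts, id_cols = c("pair_id", "assay"),
                          names_from = "allele", values_from = c("inp", "spl"))
  w <- dplyr::left_join(w, sim$truth, by = "pair_id")
  est <- log2_allele_ratio(w$spl_mt, w$inp_mt, w$spl_wt, w$inp_wt)
  expect_lt(abs(mean(est - w$effect)), 0.05)
})

test_that("complex blockage profiles identify the failing transition", {
  make_counts <- function(mt_sel) {
    tibble::tibble(
      pair_id = "p",
      allele = rep(c("wt", "mt"), times = length(mt_sel)),
      fraction = rep(names(mt_sel), each = 2),
      sel = as.vector(rbind(100, unlist(mt_sel))),
      inp = 1000
    )
  }
  # 4x accumulation in A, depleted beyond -> block at A -> B
  cb <- complex_blockage(
    make_counts(c(E = 100, A = 400, BC = 20, mRNA = 20)), pseudocount = 0
  )
  expect_equal(cb$blocks$primary_block, "A->B")
  expect_equal(cb$blocks$n_blocks, 1)
  ret <- cb$retention
  expect_equal(ret$retention[ret$fraction == "A"], 400)
  # flat profile -> no block
  flat <- complex_blockage(
    make_counts(c(E = 100, A = 100, BC = 100, mRNA = 100)), pseudocount = 0
  )
  expect_equal(flat$blocks$primary_block, "no block")
  # accumulation in B/C with depleted products -> block at catalysis
  cat_block <- complex_blockage(
    make_counts(c(E = 100, A = 100, BC = 300, mRNA = 20, lariat = 20)),
    pseudocount = 0
  )
  expect_equal(cat_block$blocks$primary_block, "B->mRNA")
  # a mutant may reduce more than one step
  multi <- complex_blockage(
    make_counts(c(E = 100, A = 300, BC = 400, mRNA = 10)), pseudocount = 0
  )
  expect_equal(multi$blocks$n_blocks, 2)
  expect_equal(multi$blocks$primary_block, "B->mRNA")
  expect_error(complex_blockage(make_counts(c(mRNA = 100))), "two fractions")
})
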