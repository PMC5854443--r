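test_that("gene tallies apply the SSM definition and aggregate global weights", {
  gm <- gene_models(
    c("g1", "g2", "mono"), "chr1", "+",
    list(data.frame(start = c(0, 200), end = c(100, 300)),
         data.frame(start = c(0, 500), end = c(200, 700)),
         data.frame(start = 0, end = 400))
  )
  catalog <- tibble::tibble(
    gene_id = c(rep("g1", 10), "mono", "missing"),
    position = c(100, 101, 99, 50, 60, 70, 80, 90, 20, 210, 10, 5),
    dm_class = c("splicing", "splicing", "missense", rep("missense", 6),
                 "splicing", "splicing", "splicing")
  )
  expect_message(tal <- tally_genes(catalog, gm), "unknown genes")
  # 3 window hits (100, 101 intronic; 99 exonic -3) but only 2 splicing-labelled
  expect_equal(tal$n_ssm[tal$gene_id == "g1"], 2)
  expect_equal(tal$n_muts[tal$gene_id == "g1"], 10)
  # intronless gene excluded entirely
  expect_false("mono" %in% tal$gene_id)
  g <- global_weights(tal)
  # the splicing-labelled record at 210 is exonic (outside the 200..202
  # acceptor window) so it does not count as SSM
  expect_equal(g$totalspl, 2)
  expect_equal(g$totalmuts, 10)
  expect_equal(g$totalSS, 2)
  expect_equal(g$totalCDS, 200)

  # no splicing-labelled records -> zero weight
  cat0 <- dplyr::mutate(catalog[1:9, ], dm_class = "missense")
  tal0 <- tally_genes(cat0, gm)
  expect_equal(global_weights(tal0)$totalspl, 0)
})

test_that("envelope categories respect the exact binomial null", {
  # observed at the null center -> nothing flagged
  tal <- tibble::tibble(
    gene_id = sprintf("g%d", 1:50),
    n_muts = rep(c(10, 30, 60, 100, 200), 10),
    n_ssm = round(rep(c(10, 30, 60, 100, 200), 10) * 0.134)
  )
  env <- mc_envelope(tal, weights = list(totalspl = 134, totalmuts = 1000,
                                         totalSS = 1, totalCDS = 1),
                     n_reps = 1000, seed = 3)
  expect_true(all(env$category == "Expected"))

  # n = 10, w = 0.134, observed 9: exact binomial tail < 1e-6 -> Upper
  expect_lt(pbinom(8, 10, 0.134, lower.tail = FALSE), 1e-6)
  one <- mc_envelope(tibble::tibble(gene_id = "g", n_muts = 10, n_ssm = 9),
                     weights = list(totalspl = 134, totalmuts = 1000,
                                    totalSS = 1, totalCDS = 1),
                     n_reps = 1000, seed = 3)
  expect_equal(as.character(one$category), "Upper")
  expect_lt(one$p_emp, 0.01)

  # genes with no mutations are Expected by definition
  zero <- mc_envelope(tibble::tibble(gene_id = "z", n_muts = 0, n_ssm = 0),
                      weights = list(totalspl = 1, totalmuts = 10,
                                     totalSS = 1, totalCDS = 1), seed = 1)
  expect_equal(as.character(zero$category), "Expected")
  expect_equal(zero$p_emp, 1)
})

test_that("increasing the observed count never moves a gene toward Lower", {
  w <- list(totalspl = 134, totalmuts = 1000, totalSS = 1, totalCDS = 1)
  ranks <- vapply(0:30, function(k) {
    env <- mc_envelope(tibble::tibble(gene_id = "g", n_muts = 30, n_ssm = k),
                       weights = w, n_reps = 500, seed = 5)
    as.integer(env$category)  # Lower < Expected < Upper
  }, integer(1))
  expect_true(all(diff(ranks) >= 0))
})

test_that("envelope results are independent of gene order", {
  tal <- tibble::tibble(gene_id = sprintf("g%d", 1:20),
                        n_muts = 20 + 1:20, n_ssm = 3)
  w <- list(totalspl = 134, totalmuts = 1000, totalSS = 1, totalCDS = 1)
  fwd <- mc_envelope(tal, weights = w, n_reps = 500, seed = 7)
  rev_ <- mc_envelope(tal[20:1, ], weights = w, n_reps = 500, seed = 7)
  expect_equal(dplyr::arrange(as.data.frame(fwd), gene_id),
               dplyr::arrange(as.data.frame(rev_), gene_id))
})

test_that("normalized mode reduces to global mode for uniform site density", {
  tal <- tibble::tibble(
    gene_id = sprintf("g%d", 1:30), n_muts = 10 + 1:30, n_ssm = 2,
    gene_ss = 4L * (1:30), gene_cds = 400 * (1:30)  # constant ss/cds ratio
  )
  w <- list(totalspl = 200, totalmuts = 1500,
            totalSS = sum(tal$gene_ss), totalCDS = sum(tal$gene_cds))
  glob <- mc_envelope(tal, mode = "global", weights = w, n_reps = 500, seed = 9)
  norm <- mc_envelope(tal, mode = "normalized", weights = w, n_reps = 500, seed = 9)
  expect_equal(as.data.frame(glob), as.data.frame(norm))

  # intron-dense short-CDS genes can push the gene weight above 1
  hot <- tibble::tibble(gene_id = "h", n_muts = 10, n_ssm = 10,
                        gene_ss = 80L, gene_cds = 10)
  expect_warning(
    mc_envelope(hot, mode = "normalized",
                weights = list(totalspl = 500, totalmuts = 1000,
                               totalSS = 10, totalCDS = 1000), seed = 1),
    "clipped"
  )
})

test_that("Monte Carlo bounds track the exact binomial oracle", {
  expect_equal(binomial_oracle(0, 0.5), c(lower = 0, upper = 0))
  # independent CDF-enumeration check of the oracle itself
  n <- 100; w <- 0.134; tail_q <- 0.0005
  cdf <- cumsum(dbinom(0:n, n, w))
  expect_equal(unname(binomial_oracle(n, w, 0.999)),
               c(which(cdf >= tail_q)[1] - 1, which(cdf >= 1 - tail_q)[1] - 1))

  grid <- expand.grid(n = c(5, 20, 50, 200), w = c(0.05, 0.134, 0.4))
  ok <- mapply(function(n, w) {
    env <- mc_envelope(tibble::tibble(gene_id = "g", n_muts = n, n_ssm = 0),
                       weights = list(totalspl = w * 1e6, totalmuts = 1e6,
                                      totalSS = 1, totalCDS = 1),
                       n_reps = 1e4, seed = 42)
    ob <- binomial_oracle(n, w, 0.999)
    abs(env$lower - ob["lower"]) <= 1 && abs(env$upper - ob["upper"]) <= 1
  }, grid$n, grid$w)
  expect_true(all(ok))
})

test_that("exon ESM envelope flags the published MLH1 exons and only those", {
  env <- exon_esm_envelope(mlh1_exon_tallies(), weight = 0.10, seed = 1)
  upper <- env$exon_id[env$category == "Upper"]
  expect_setequal(upper, c("MLH1_exon8", "MLH1_exon15"))
  # exact binomial tails behind those calls
  expect_lt(pbinom(5, 6, 0.1, lower.tail = FALSE), 1e-5)   # 6/6
  expect_lt(pbinom(4, 7, 0.1, lower.tail = FALSE), 1e-3)   # 5/7

  # 0/8 can never be Upper; 1/10 is Expected (P(X >= 1) = 0.651)
  none <- exon_esm_envelope(tibble::tibble(exon_id = "e", n_tested = 8, n_esm = 0),
                            weight = 0.10, seed = 1)
  expect_equal(as.character(none$category), "Expected")
  mid <- exon_esm_envelope(tibble::tibble(exon_id = "e", n_tested = 10, n_esm = 1),
                           weight = 0.10, seed = 1)
  expect_equal(as.character(mid$category), "Expected")
  expect_equal(1 - pbinom(0, 10, 0.1), 0.6513, tolerance = 1e-4)
  # zero-tested exons are excluded
  mixed <- exon_esm_envelope(
    tibble::tibble(exon_id = c("a", "b"), n_tested = c(0, 5), n_esm = c(0, 1)),
    weight = 0.10, seed = 1
  )
  expect_equal(mixed$exon_id, "b")
})
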