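# Toy gene builders and independent oracles shared across tests.

toy_gene <- function(id = "toy", strand = "+", chrom = "chr1",
                     exon_starts = c(0, 200), exon_ends = c(100, 300)) {
  gene_models(id, chrom, strand,
              list(data.frame(start = exon_starts, end = exon_ends)))
}

# Independent brute-force region oracle: enumerates every window
# position of every splice site directly from the exon boundary
# arithmetic (derived separately from the package's offset formulas).
oracle_regions <- function(model_row) {
  ex <- model_row$exons[[1]]
  ex <- ex[order(ex$start), ]
  st <- model_row$strand[1]
  k <- nrow(ex)
  span <- model_row$gene_start[1]:(model_row$gene_end[1] - 1)
  # window maps: named numeric of |offset| per position, per site kind
  d_best <- setNames(rep(Inf, length(span)), span)
  a_best <- d_best
  note <- function(best, pos, offs) {
    for (i in seq_along(pos)) {
      key <- as.character(pos[i])
      if (key %in% names(best) && abs(offs[i]) < best[[key]]) {
        best[[key]] <- abs(offs[i])
      }
    }
    best
  }
  if (k > 1) {
    for (j in seq_len(k - 1)) {
      if (st == "+") {
        e <- ex$end[j]          # donor at end of exon j
        d_best <- note(d_best, c(e - 3, e - 2, e - 1, e, e + 1, e + 2, e + 3, e + 4, e + 5),
                       c(-3, -2, -1, 1, 2, 3, 4, 5, 6))
        s <- ex$start[j + 1]    # acceptor at start of exon j+1
        a_best <- note(a_best, c((s - 20):(s - 1), s, s + 1, s + 2),
                       c(-(20:1), 1, 2, 3))
      } else {
        s <- ex$start[j + 1]    # donor: transcript-upstream exon's genomic start
        d_best <- note(d_best, c(s, s + 1, s + 2, s - 1, s - 2, s - 3, s - 4, s - 5, s - 6),
                       c(-1, -2, -3, 1, 2, 3, 4, 5, 6))
        e <- ex$end[j]          # acceptor: genomic end of exon j
        a_best <- note(a_best, c(e - 1, e - 2, e - 3, e:(e + 19)),
                       c(1, 2, 3, -(1:20)))
      }
    }
  }
  in_exon <- vapply(span, function(p) any(p >= ex$start & p < ex$end), logical(1))
  region <- ifelse(in_exon, "exonic", "deep_intronic")
  d <- unname(d_best); a <- unname(a_best)
  win <- is.finite(d) | is.finite(a)
  region[win] <- ifelse(d[win] <= a[win] | !is.finite(a[win]),
                        "ss5_window", "ss3_window")
  tibble::tibble(position = span, region = region)
}

# Full-sequence rescan oracle for delta-ESR: total hexamer score of a
# sequence (all windows), so delta = total(wt) - total(mt).
total_hexamer_score <- function(seq, table) {
  n <- nchar(seq)
  if (n < 6) return(0)
  hex <- substring(seq, 1:(n - 5), 6:n)
  s <- setNames(table$score, table$hexamer)[hex]
  sum(s, na.rm = TRUE)
}

random_hexamer_table <- function(n = 25, seed = 1) {
  set.seed(seed)
  hx <- unique(replicate(n, paste(sample(c("A", "C", "G", "T"), 6, TRUE), collapse = "")))
  hexamer_table(hx, round(runif(length(hx), -3, 3), 2))
}

random_seq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
}

# Exact two-sided hypergeometric p by point-probability summation,
# enumerating every possible overlap.
enumerate_fisher_p <- function(n11, n_a, n_b, n_u) {
  ks <- max(0, n_a + n_b - n_u):min(n_a, n_b)
  probs <- dhyper(ks, n_b, n_u - n_b, n_a)
  p_obs <- dhyper(n11, n_b, n_u - n_b, n_a)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
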