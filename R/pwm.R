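#' Build a splice-site position weight matrix
#'
#' Per-position log2 odds over A/C/G/T with Dirichlet pseudocount
#' smoothing: `log2(((count + pc) / (n + 4 pc)) / background)`. Donor
#' models span 9 positions (-3..+6), acceptor models 23 (-20..+3); the
#' consensus sequence attains the maximal attainable score.
#'
#' @param training_sites Character vector of aligned site sequences
#'   (ACGT/ACGU; U is treated as T). At least 50 sites are required.
#' @param site_kind `"5ss"` or `"3ss"`.
#' @param pseudocount Pseudocount added per base (default 0.5).
#' @param background Background base frequencies (A, C, G, T).
#' @param width Expected site width; defaults to 9 (`"5ss"`) or 23
#'   (`"3ss"`). Override for toy models.
#' @return An object of class `"splice_pwm"`: list with `log_odds`
#'   (4 x width matrix), `site_kind`, `consensus`, `max_score`.
#' @export
#' @examples
#' pwm <- build_pwm(sample_splice_sites(200, "5ss", seed = 1), "5ss")
#' score_splice_seq(pwm, pwm$consensus) == pwm$max_score
build_pwm <- function(training_sites, site_kind = c("5ss", "3ss"),
                      pseudocount = 0.5, background = rep(0.25, 4),
                      width = NULL) {
  site_kind <- match.arg(site_kind)
  width <- width %||% if (site_kind == "5ss") 9L else 23L
  if (length(training_sites) < 1) abort("no training sites")
  if (length(training_sites) < 50) {
    warn("fewer than 50 training sites; PWM estimates will be noisy")
  }
  training_sites <- toupper(gsub("U", "T", toupper(training_sites)))
  bad <- which(nchar(training_sites) != width)
  if (length(bad) > 0) {
    abort(sprintf("training site(s) of wrong length at index: %s",
                  paste(head(bad, 5), collapse = ", ")))
  }
  bases <- c("A", "C", "G", "T")
  mat <- do.call(rbind, strsplit(training_sites, ""))
  counts <- apply(mat, 2, function(col) table(factor(col, levels = bases)))
  n <- length(training_sites)
  freqs <- (counts + pseudocount) / (n + 4 * pseudocount)
  log_odds <- log2(freqs / background)
  rownames(log_odds) <- bases
  consensus <- paste(bases[apply(log_odds, 2, which.max)], collapse = "")
  structure(
    list(log_odds = log_odds, site_kind = site_kind,
         consensus = consensus, max_score = sum(apply(log_odds, 2, max)),
         n_training = n, pseudocount = pseudocount, background = background),
    class = "splice_pwm"
  )
}

#' Score site sequences against a splice-site PWM
#'
#' @param pwm A [build_pwm()] model.
#' @param seqs Character vector of site sequences (same width as the
#'   model).
#' @return Numeric vector of summed per-position log2-odds scores.
#' @export
score_splice_seq <- function(pwm, seqs) {
  stopifnot(inherits(pwm, "splice_pwm"))
  seqs <- toupper(gsub("U", "T", toupper(seqs)))
  width <- ncol(pwm$log_odds)
  if (any(nchar(seqs) != width)) {
    abort(sprintf("sequences must have width %d", width))
  }
  mat <- do.call(rbind, strsplit(seqs, ""))
  idx <- match(mat, rownames(pwm$log_odds))
  if (anyNA(idx)) abort("sequences contain non-ACGT letters")
  scores <- matrix(pwm$log_odds[cbind(as.vector(idx),
                                      rep(seq_len(width), each = length(seqs)))],
                   nrow = length(seqs))
  rowSums(scores)
}

#' Reference-minus-alternate splice-site score difference
#'
#' Positive delta means the alternate allele weakens the site match;
#' delta > 5 marks site-abolishing variants and delta < -2
#' site-strengthening ones in the downstream selection analyses.
#'
#' @param ref_site,alt_site Site sequences of the model's width,
#'   differing by a single substitution.
#' @param pwm A [build_pwm()] model.
#' @return Numeric vector `score(ref) - score(alt)`.
#' @export
score_variant_delta <- function(ref_site, alt_site, pwm) {
  if (any(nchar(ref_site) != nchar(alt_site))) {
    abort("ref and alt site sequences must have equal length (indels unsupported)")
  }
  score_splice_seq(pwm, ref_site) - score_splice_seq(pwm, alt_site)
}

#' Score a splice-region variant from gene models and sequences
#'
#' Locates the splice-site window containing each variant, extracts
#' the site sequence from the gene's (transcript-oriented) span
#' sequence, substitutes the alternate base and returns the
#' reference-minus-alternate PWM delta. Variants outside any window
#' raise an error.
#'
#' @param variants Tibble with `gene_id`, `position` (0-based
#'   genomic), `alt` (transcript-strand base).
#' @param models A [gene_models()] tibble with a `sequence` column
#'   (e.g. from `gen_gene_models(..., with_sequence = TRUE)`).
#' @param pwm_5ss,pwm_3ss [build_pwm()] models for each site kind.
#' @return `variants` with added `site_kind`, `ref_site`, `alt_site`,
#'   `delta`.
#' @export
variant_site_delta <- function(variants, models, pwm_5ss, pwm_3ss) {
  stopifnot("sequence" %in% names(models))
  sites <- splice_sites(models)
  res <- purrr::pmap(variants, function(gene_id, position, alt, ...) {
    g <- models[models$gene_id == gene_id, ]
    if (nrow(g) == 0) abort(paste0("unknown gene: ", gene_id))
    gsites <- sites[sites$gene_id == gene_id, ]
    hit <- NULL
    for (j in seq_len(nrow(gsites))) {
      wp <- site_window_positions(gsites$junction[j], gsites$site_kind[j],
                                  gsites$strand[j])
      if (position %in% wp) {
        hit <- list(kind = gsites$site_kind[j], wp = wp)
        break
      }
    }
    if (is.null(hit)) abort(sprintf("not a splice-site variant: %s:%d", gene_id, position))
    # transcript-oriented index within the span sequence
    tx_index <- function(p) {
      if (g$strand[1] == "+") p - g$gene_start[1] + 1 else g$gene_end[1] - p
    }
    seqchars <- strsplit(g$sequence[1], "")[[1]]
    ref_site <- paste(seqchars[vapply(hit$wp, tx_index, double(1))], collapse = "")
    at <- which(hit$wp == position)
    alt_site <- ref_site
    substr(alt_site, at, at) <- alt
    pwm <- if (hit$kind == "5ss") pwm_5ss else pwm_3ss
    tibble(site_kind = hit$kind, ref_site = ref_site, alt_site = alt_site,
           delta = score_variant_delta(ref_site, alt_site, pwm))
  }) %>% bind_rows()
  dplyr::bind_cols(variants, res)
}

#' @export
print.splice_pwm <- function(x, ...) {
  cat(sprintf("<splice_pwm %s: %d positions, consensus %s, max score %.3f>\n",
              x$site_kind, ncol(x$log_odds), x$consensus, x$max_score))
  invisible(x)
}
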