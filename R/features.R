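#' Heuristic folding free-energy score
#'
#' A stand-in for thermodynamic RNA folding used as the default
#' `fold_backend`: the sum of dinucleotide stacking weights
#' (GC-containing stacks -2.1, mixed -1.4, AT-only -0.9, arbitrary
#' energy-like units) scaled by 0.12 to mimic the fraction of a
#' sequence engaged in structure. More negative means more
#' structured; GC-rich sequences score lower. Any function mapping a
#' sequence to a free-energy-like scalar can replace it.
#'
#' @param seq Character vector of sequences.
#' @return Numeric vector of energy-like scores (<= 0).
#' @export
fold_stack_heuristic <- function(seq) {
  vapply(seq, function(s) {
    s <- toupper(gsub("U", "T", toupper(s)))
    n <- nchar(s)
    if (n < 2) return(0)
    ch <- strsplit(s, "")[[1]]
    is_gc <- ch %in% c("G", "C")
    a <- is_gc[-n]; b <- is_gc[-1]
    w <- ifelse(a & b, -2.1, ifelse(a | b, -1.4, -0.9))
    0.12 * sum(w)
  }, double(1), USE.NAMES = FALSE)
}

# Exon sequences of one gene-model row, in transcript order.
exon_sequences <- function(model_row) {
  ex <- model_row$exons[[1]]  # transcript order
  seqchars <- strsplit(model_row$sequence[1], "")[[1]]
  tx_from <- function(s, e) {
    if (model_row$strand[1] == "+") {
      (s - model_row$gene_start[1] + 1):(e - model_row$gene_start[1])
    } else {
      (model_row$gene_end[1] - e + 1):(model_row$gene_end[1] - s)
    }
  }
  purrr::map2_chr(ex$start, ex$end, function(s, e) {
    paste(seqchars[tx_from(s, e)], collapse = "")
  })
}

# Site sequence (model width) at a junction, transcript orientation.
extract_site_seq <- function(model_row, junction, site_kind) {
  wp <- site_window_positions(junction, site_kind, model_row$strand[1])
  seqchars <- strsplit(model_row$sequence[1], "")[[1]]
  idx <- if (model_row$strand[1] == "+") {
    wp - model_row$gene_start[1] + 1
  } else {
    model_row$gene_end[1] - wp
  }
  ok <- idx >= 1 & idx <= length(seqchars)
  if (!all(ok)) return(NA_character_)
  paste(seqchars[idx], collapse = "")
}

# 140-nt windows (70 up- and downstream of the junction, transcript
# orientation) used for the splice-site folding feature.
ss_flank_seq <- function(model_row, junction, flank = 70) {
  len <- nchar(model_row$sequence[1])
  tx <- if (model_row$strand[1] == "+") {
    junction - model_row$gene_start[1] + 1
  } else {
    model_row$gene_end[1] - junction
  }
  lo <- max(1, tx - flank); hi <- min(len, tx + flank - 1)
  substr(model_row$sequence[1], lo, hi)
}

#' Assemble the gene-level genomic feature table
#'
#' Builds the 19-feature table used to classify SSM-prone genes from
#' gene models with sequences, a hexamer table, splice-site PWMs, and
#' per-gene annotation tracks. Motif densities are hits per exonic
#' nucleotide averaged over the gene; SNP densities are counts per
#' exonic (or gene) nucleotide; conservation features are base-pair
#' weighted means of interval scores over the exons (or the gene
#' span); splice-site free energy folds 70 nt up- and downstream of
#' each junction with `fold_backend`; splice-site strengths are mean
#' PWM scores over the gene's donor/acceptor sites. Missing
#' haploinsufficiency (or other track) values are median-imputed and
#' recorded in the `"imputed"` attribute; genes without sequence are
#' dropped with a message.
#'
#' @param models [gene_models()] with a `sequence` column.
#' @param hexamers A [hexamer_table()] with `ESE`/`ESS` classes (and
#'   optionally `ESR`).
#' @param pwm_5ss,pwm_3ss [build_pwm()] models.
#' @param tracks List with any of: `hi` (`gene_id`, `hi`),
#'   `conservation` (`gene_id`, `start`, `end`, `score` intervals),
#'   `snp` (`gene_id`, `position` of common SNPs), `exac` (`gene_id`,
#'   `position`, `cons` population-variant conservation).
#' @param fold_backend Function `sequence -> energy-like scalar`
#'   (default [fold_stack_heuristic()]).
#' @return Tibble: `gene_id` plus 19 numeric feature columns (the
#'   same columns [gen_feature_table()] emits, minus its `label`).
#' @export
assemble_features <- function(models, hexamers, pwm_5ss, pwm_3ss,
                              tracks = list(), fold_backend = fold_stack_heuristic) {
  if (!"sequence" %in% names(models)) abort("models must carry a sequence column")
  drop <- is.na(models$sequence) | !nzchar(models$sequence)
  if (any(drop)) {
    inform(sprintf("dropping %d gene(s) lacking sequence", sum(drop)))
    models <- models[!drop, ]
  }
  sites <- splice_sites(models)
  rows <- purrr::map(seq_len(nrow(models)), function(i) {
    m <- models[i, ]
    ex_seqs <- exon_sequences(m)
    ex_len <- sum(nchar(ex_seqs))
    all_ex <- paste(ex_seqs, collapse = "")
    gsites <- sites[sites$gene_id == m$gene_id, ]
    site_seqs <- purrr::map2_chr(gsites$junction, gsites$site_kind,
                                 ~ extract_site_seq(m, .x, .y))
    strengths <- tibble(kind = gsites$site_kind, seq = site_seqs) %>%
      filter(!is.na(.data$seq))
    s5 <- strengths$seq[strengths$kind == "5ss"]
    s3 <- strengths$seq[strengths$kind == "3ss"]
    flanks <- purrr::map2_chr(gsites$junction, gsites$site_kind,
                              ~ ss_flank_seq(m, .x))
    ch <- strsplit(all_ex, "")[[1]]
    ex_g <- arrange(m$exons[[1]], start)
    intron_len <- if (nrow(ex_g) > 1) ex_g$start[-1] - ex_g$end[-nrow(ex_g)] else NA_real_
    tibble(
      gene_id = m$gene_id,
      intron_count = m$n_introns,
      mean_exon_length = ex_len / nrow(ex_g),
      mean_intron_length = mean(intron_len),
      cds_length = m$cds_length,
      gene_length = m$gene_end - m$gene_start,
      gc_content = mean(ch %in% c("G", "C")),
      exon_dg = mean(fold_backend(ex_seqs)),
      ss_dg = if (length(flanks) > 0) mean(fold_backend(flanks)) else NA_real_,
      exon_snp_density = NA_real_, gene_snp_density = NA_real_,
      exon_conservation = NA_real_, gene_conservation = NA_real_,
      exac_variant_conservation = NA_real_, hi_score = NA_real_,
      ese_density = sum(vapply(ex_seqs, count_hexamer_hits, integer(1),
                               table = hexamers, class = "ESE")) / ex_len,
      ess_density = sum(vapply(ex_seqs, count_hexamer_hits, integer(1),
                               table = hexamers, class = "ESS")) / ex_len,
      esr_density = sum(vapply(ex_seqs, count_hexamer_hits, integer(1),
                               table = hexamers)) / ex_len,
      mean_5ss_strength = if (length(s5) > 0) mean(score_splice_seq(pwm_5ss, s5)) else NA_real_,
      mean_3ss_strength = if (length(s3) > 0) mean(score_splice_seq(pwm_3ss, s3)) else NA_real_
    )
  }) %>% bind_rows()

  # annotation tracks
  if (!is.null(tracks$hi)) {
    rows <- rows %>%
      left_join(rename(tracks$hi, hi_new = "hi"), by = "gene_id") %>%
      mutate(hi_score = .data$hi_new) %>% select(-"hi_new")
  }
  if (!is.null(tracks$snp)) {
    snp_counts <- purrr::map_dbl(seq_len(nrow(models)), function(i) {
      m <- models[i, ]
      p <- tracks$snp$position[tracks$snp$gene_id == m$gene_id]
      ex <- m$exons[[1]]
      sum(vapply(p, function(pp) any(pp >= ex$start & pp < ex$end), logical(1)))
    })
    all_counts <- purrr::map_dbl(models$gene_id,
                                 ~ sum(tracks$snp$gene_id == .x))
    rows$exon_snp_density <- snp_counts / rows$cds_length
    rows$gene_snp_density <- all_counts / rows$gene_length
  }
  if (!is.null(tracks$conservation)) {
    cons <- purrr::map(seq_len(nrow(models)), function(i) {
      m <- models[i, ]
      iv <- tracks$conservation[tracks$conservation$gene_id == m$gene_id, ]
      ex <- m$exons[[1]]
      ov_exon <- interval_weighted_mean(iv, ex$start, ex$end)
      ov_gene <- interval_weighted_mean(iv, m$gene_start, m$gene_end)
      c(ov_exon, ov_gene)
    })
    rows$exon_conservation <- purrr::map_dbl(cons, 1)
    rows$gene_conservation <- purrr::map_dbl(cons, 2)
  }
  if (!is.null(tracks$exac)) {
    rows$exac_variant_conservation <- purrr::map_dbl(models$gene_id, function(g) {
      v <- tracks$exac$cons[tracks$exac$gene_id == g]
      if (length(v) == 0) NA_real_ else mean(v)
    })
  }

  feature_cols <- setdiff(names(rows), "gene_id")
  imputed <- list()
  for (col in feature_cols) {
    miss <- is.na(rows[[col]])
    if (any(miss)) {
      imputed[[col]] <- rows$gene_id[miss]
      med <- median(rows[[col]], na.rm = TRUE)
      rows[[col]][miss] <- if (is.na(med)) 0 else med
    }
  }
  # fixed, documented column order (matching the synthetic generator)
  rows <- select(rows, "gene_id", all_of(feature_signal_directions()$feature))
  attr(rows, "imputed") <- imputed
  rows
}

# Base-pair weighted mean of interval scores over target intervals;
# NA when nothing overlaps.
interval_weighted_mean <- function(iv, t_start, t_end) {
  if (nrow(iv) == 0) return(NA_real_)
  tot <- 0; wsum <- 0
  for (k in seq_along(t_start)) {
    ov <- pmin(iv$end, t_end[k]) - pmax(iv$start, t_start[k])
    keep <- ov > 0
    tot <- tot + sum(iv$score[keep] * ov[keep])
    wsum <- wsum + sum(ov[keep])
  }
  if (wsum == 0) NA_real_ else tot / wsum
}
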