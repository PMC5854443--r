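#' Construct a gene-model table
#'
#' A gene model is one canonical transcript per gene: an ordered set of
#' exons on one strand. Internally all coordinates are 0-based
#' half-open; text formats (BED, GFF3, catalogs) use their native
#' conventions on disk. Exons in the `exons` list-column are stored in
#' transcript orientation, so the first row is the 5'-most exon.
#'
#' @param gene_id Character vector of gene identifiers (unique).
#' @param chrom Character vector of chromosome names.
#' @param strand Character vector, `"+"` or `"-"`.
#' @param exons List of two-column data frames (`start`, `end`),
#'   0-based half-open genomic intervals, in any order.
#'
#' @return A tibble of class `"gene_models"` with one row per gene and
#'   columns `gene_id`, `chrom`, `strand`, `exons` (list-column in
#'   transcript orientation), `gene_start`, `gene_end`, `cds_length`
#'   (total exonic length, the coding-length proxy used throughout),
#'   `n_introns` and `n_splice_sites` (= 2 x introns).
#' @export
#' @examples
#' gm <- gene_models(
#'   gene_id = "toy", chrom = "chr1", strand = "+",
#'   exons = list(data.frame(start = c(0, 200), end = c(100, 300)))
#' )
#' gm$n_introns
gene_models <- function(gene_id, chrom, strand, exons) {
  stopifnot(length(gene_id) == length(exons), !anyDuplicated(gene_id))
  if (!all(strand %in% c("+", "-"))) abort("strand must be '+' or '-'")
  exons <- purrr::map2(exons, strand, function(ex, st) {
    if (nrow(ex) == 0) abort("zero-exon record rejected")
    s <- as.numeric(ex$start); e <- as.numeric(ex$end)
    if (any(e <= s)) abort("exon with end <= start")
    o <- order(s)
    s <- s[o]; e <- e[o]
    if (length(s) > 1 && any(s[-1] < e[-length(e)])) abort("overlapping exons")
    if (st == "-") { s <- rev(s); e <- rev(e) }
    tibble(start = s, end = e)
  })
  out <- tibble(
    gene_id = as.character(gene_id),
    chrom = as.character(chrom),
    strand = strand,
    exons = exons,
    gene_start = purrr::map_dbl(exons, ~ min(.x$start)),
    gene_end = purrr::map_dbl(exons, ~ max(.x$end)),
    cds_length = purrr::map_dbl(exons, ~ sum(.x$end - .x$start)),
    n_introns = purrr::map_int(exons, ~ nrow(.x) - 1L)
  )
  out$n_splice_sites <- 2L * out$n_introns
  stopifnot(all(out$cds_length > 0))
  class(out) <- c("gene_models", class(out))
  out
}

#' Load gene models from BED12 or GFF3
#'
#' BED12 block structure or GFF3 `exon` features (grouped by `Parent`,
#' falling back to `gene_id`/`ID`) define one transcript per gene.
#'
#' @param path File path; format is inferred from the extension unless
#'   `format` is given.
#' @param format `"auto"`, `"bed"` or `"gff3"`.
#' @return A [gene_models()] tibble.
#' @export
load_gene_models <- function(path, format = c("auto", "bed", "gff3")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(gff3?|gtf)$", path, ignore.case = TRUE)) "gff3" else "bed"
  }
  if (format == "bed") load_gene_models_bed(path) else load_gene_models_gff3(path)
}

load_gene_models_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  rows <- purrr::imap(fields, function(f, i) {
    if (length(f) < 12) {
      abort(sprintf("BED12 parse error at line %d: %d fields (12 required)", i, length(f)))
    }
    n_blocks <- suppressWarnings(as.integer(f[10]))
    sizes <- suppressWarnings(as.numeric(strsplit(f[11], ",")[[1]]))
    starts <- suppressWarnings(as.numeric(strsplit(f[12], ",")[[1]]))
    chrom_start <- suppressWarnings(as.numeric(f[2]))
    if (is.na(n_blocks) || n_blocks < 1) {
      abort(sprintf("BED12 parse error at line %d: zero-exon record", i))
    }
    if (anyNA(c(sizes, starts, chrom_start)) ||
        length(sizes) != n_blocks || length(starts) != n_blocks) {
      abort(sprintf("BED12 parse error at line %d: malformed block fields", i))
    }
    list(
      gene_id = f[4], chrom = f[1], strand = f[6],
      exons = tibble(start = chrom_start + starts, end = chrom_start + starts + sizes)
    )
  })
  gene_models(
    gene_id = purrr::map_chr(rows, "gene_id"),
    chrom = purrr::map_chr(rows, "chrom"),
    strand = purrr::map_chr(rows, "strand"),
    exons = purrr::map(rows, "exons")
  )
}

load_gene_models_gff3 <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    abort("GFF3 input requires the rtracklayer package")
  }
  gr <- rtracklayer::import(path, format = "GFF3")
  ex <- gr[tolower(as.character(gr$type)) == "exon"]
  if (length(ex) == 0) abort("no exon features found in GFF3 file")
  meta <- as.data.frame(ex)
  gid <- if (!is.null(ex$Parent) && all(lengths(ex$Parent) > 0)) {
    vapply(ex$Parent, `[[`, character(1), 1)
  } else if (!is.null(ex$gene_id)) {
    as.character(ex$gene_id)
  } else {
    as.character(ex$ID)
  }
  d <- tibble(
    gene_id = gid, chrom = as.character(meta$seqnames),
    strand = as.character(meta$strand),
    start = meta$start - 1, end = meta$end
  )
  parts <- split(d, d$gene_id)
  gene_models(
    gene_id = names(parts),
    chrom = unname(purrr::map_chr(parts, ~ .x$chrom[1])),
    strand = unname(purrr::map_chr(parts, ~ .x$strand[1])),
    exons = unname(purrr::map(parts, ~ tibble(start = .x$start, end = .x$end)))
  )
}

#' Write gene models as BED12
#'
#' @param models A [gene_models()] tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(models, path) {
  lines <- purrr::pmap_chr(models, function(gene_id, chrom, strand, exons, gene_start,
                                            gene_end, ...) {
    ex <- arrange(exons, start)
    paste(
      chrom, format(gene_start, scientific = FALSE), format(gene_end, scientific = FALSE),
      gene_id, 0, strand,
      format(gene_start, scientific = FALSE), format(gene_end, scientific = FALSE),
      "0", nrow(ex),
      paste0(paste(format(ex$end - ex$start, scientific = FALSE, trim = TRUE),
                   collapse = ","), ","),
      paste0(paste(format(ex$start - gene_start, scientific = FALSE, trim = TRUE),
                   collapse = ","), ","),
      sep = "\t"
    )
  })
  writeLines(lines, path)
  invisible(path)
}

#' Splice sites of a gene-model table
#'
#' Each intron contributes a donor (5'ss) and an acceptor (3'ss). The
#' `junction` column holds the strand-specific genomic anchor from
#' which transcript-oriented offsets are computed: on `+` the 0-based
#' coordinate of the first base past the exon (donor) or the first
#' exonic base (acceptor); on `-` the first exonic base (donor) or the
#' first base past the exon (acceptor).
#'
#' @param models A [gene_models()] tibble.
#' @return Tibble with `gene_id`, `site_kind` (`"5ss"`/`"3ss"`),
#'   `intron_index` (transcript order), `junction`, `strand`.
#' @export
splice_sites <- function(models) {
  parts <- purrr::pmap(models, function(gene_id, strand, exons, ...) {
    k <- nrow(exons)
    if (k < 2) return(NULL)
    o <- order(exons$start)
    starts <- exons$start[o]; ends <- exons$end[o]  # genomic order
    if (strand == "+") {
      donors <- ends[-k]        # first intronic base
      acceptors <- starts[-1]   # first exonic base
      idx <- seq_len(k - 1)
    } else {
      donors <- starts[-1]      # first exonic base of transcript-upstream exon
      acceptors <- ends[-k]     # first base past the transcript-downstream exon
      idx <- rev(seq_len(k - 1))
    }
    list(gene_id = rep(gene_id, 2 * (k - 1)),
         site_kind = rep(c("5ss", "3ss"), each = k - 1),
         intron_index = c(idx, idx),
         junction = c(donors, acceptors),
         strand = rep(strand, 2 * (k - 1)))
  })
  parts <- parts[!vapply(parts, is.null, logical(1))]
  if (length(parts) == 0) {
    return(tibble(gene_id = character(), site_kind = character(),
                  intron_index = integer(), junction = double(),
                  strand = character()))
  }
  tibble(
    gene_id = unlist(purrr::map(parts, "gene_id")),
    site_kind = unlist(purrr::map(parts, "site_kind")),
    intron_index = unlist(purrr::map(parts, "intron_index")),
    junction = unlist(purrr::map(parts, "junction")),
    strand = unlist(purrr::map(parts, "strand"))
  )
}

# Transcript-oriented offset of position p from a junction j.
# Donor (5'ss): negative = exonic (-1 is the last exon base), +1.. = intron.
# Acceptor (3'ss): negative = intronic (-1 is the last intron base),
# +1.. = exon. The same arithmetic serves both kinds; only the window
# bounds differ.
site_offset <- function(p, j, strand) {
  if (strand == "+") p - j + (p >= j) else j - p - (p >= j)
}

#' Classify mutation positions relative to splice-site windows
#'
#' The canonical windows are -3 (exonic) to +6 (intronic) around the
#' donor and -20 (intronic) to +3 (exonic) around the acceptor, in
#' transcript orientation. Exonic positions inside a window take the
#' window tag; a position inside both windows (micro-exons) takes the
#' nearer boundary, ties going to the donor. A record counts as a
#' splice-site mutation (SSM) only if it lies in a window *and* is
#' labelled `"splicing"` in `dm_class`.
#'
#' @param records Tibble with `gene_id`, `position` (0-based genomic)
#'   and optionally `dm_class`.
#' @param models A [gene_models()] tibble covering the records' genes.
#' @param on_outside `"error"` (default) to fail on positions outside
#'   the gene span, `"na"` to return `NA` regions for them.
#' @return `records` with added `region` (one of `"exonic"`,
#'   `"ss5_window"`, `"ss3_window"`, `"deep_intronic"`) and, when
#'   `dm_class` is present, logical `is_ssm`.
#' @export
#' @examples
#' gm <- gene_models("g", "chr1", "+",
#'                   list(data.frame(start = c(0, 200), end = c(100, 300))))
#' classify_regions(tibble::tibble(gene_id = "g", position = 100), gm)$region
classify_regions <- function(records, models, on_outside = c("error", "na")) {
  on_outside <- match.arg(on_outside)
  stopifnot(all(c("gene_id", "position") %in% names(records)))
  missing_genes <- setdiff(unique(records$gene_id), models$gene_id)
  if (length(missing_genes) > 0) {
    abort(paste0("records reference unknown genes: ",
                 paste(head(missing_genes, 5), collapse = ", ")))
  }
  sites <- splice_sites(models)
  site_by_gene <- split(seq_len(nrow(sites)), sites$gene_id)
  mrow <- match(unique(records$gene_id), models$gene_id)
  names(mrow) <- unique(records$gene_id)
  rec_by_gene <- split(seq_len(nrow(records)), records$gene_id)
  region_all <- character(nrow(records))
  for (gid in names(rec_by_gene)) {
    ridx <- rec_by_gene[[gid]]
    gi <- mrow[[gid]]
    st <- models$strand[gi]
    ex <- models$exons[[gi]]
    p <- records$position[ridx]
    outside <- p < models$gene_start[gi] | p >= models$gene_end[gi]
    if (any(outside) && on_outside == "error") {
      abort(sprintf("position outside gene %s", gid))
    }
    in_exon <- vapply(p, function(pp) any(pp >= ex$start & pp < ex$end), logical(1))
    region <- ifelse(in_exon, "exonic", "deep_intronic")
    sidx <- site_by_gene[[gid]]
    if (!is.null(sidx)) {
      don <- sites$junction[sidx][sites$site_kind[sidx] == "5ss"]
      acc <- sites$junction[sidx][sites$site_kind[sidx] == "3ss"]
      # transcript-oriented offsets, vectorised over records x sites
      off_mat <- function(j) {
        d <- outer(p, j, "-")
        if (st == "+") d + (d >= 0) else -d - (d >= 0)
      }
      min_abs_in <- function(off, lo, hi) {
        off[off < lo | off > hi] <- NA
        suppressWarnings(apply(abs(off), 1, min, na.rm = TRUE))  # Inf when none
      }
      d_min <- min_abs_in(off_mat(don), -3, 6)
      a_min <- min_abs_in(off_mat(acc), -20, 3)
      win <- is.finite(d_min) | is.finite(a_min)
      region[win] <- ifelse(d_min[win] <= a_min[win] | !is.finite(a_min[win]),
                            "ss5_window", "ss3_window")
    }
    region[outside] <- NA_character_
    region_all[ridx] <- region
  }
  res <- records
  res$region <- region_all
  if ("dm_class" %in% names(res)) {
    res$is_ssm <- !is.na(res$region) &
      res$region %in% c("ss5_window", "ss3_window") &
      res$dm_class == "splicing"
  }
  res
}

#' @rdname classify_regions
#' @param gene_id,position,dm_class Scalar arguments for the
#'   single-record convenience form.
#' @export
classify_region <- function(gene_id, position, models, dm_class = NA_character_) {
  classify_regions(
    tibble(gene_id = gene_id, position = position, dm_class = dm_class),
    models
  )$region
}

#' Read / write a mutation catalog
#'
#' Catalogs are tab-delimited with header
#' `gene_id chrom pos_1based ref alt dm_class`; positions are 1-based
#' on disk and 0-based (`position`) in memory.
#'
#' @param path File path.
#' @return A tibble with columns `gene_id`, `chrom`, `position`,
#'   `ref`, `alt`, `dm_class`.
#' @export
read_mutation_catalog <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(
                         gene_id = "c", chrom = "c", pos_1based = "d",
                         ref = "c", alt = "c", dm_class = "c"
                       ))
  if (any(d$ref == d$alt)) abort("catalog contains records with ref == alt")
  tibble(
    gene_id = d$gene_id, chrom = d$chrom, position = d$pos_1based - 1,
    ref = d$ref, alt = d$alt, dm_class = d$dm_class
  )
}

#' @rdname read_mutation_catalog
#' @param catalog In-memory catalog tibble (0-based `position`).
#' @export
write_mutation_catalog <- function(catalog, path) {
  out <- tibble(
    gene_id = catalog$gene_id, chrom = catalog$chrom,
    pos_1based = catalog$position + 1,
    ref = catalog$ref, alt = catalog$alt, dm_class = catalog$dm_class
  )
  readr::write_tsv(out, path)
  invisible(path)
}
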