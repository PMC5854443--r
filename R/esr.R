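#' Read a hexamer score table
#'
#' Two-or-three-column TSV with header `hexamer`, `score` and
#' optionally `class` (`ESE`, `ESS` or `ESR`). Hexamers are 6-mers over
#' ACGT (U accepted and normalised to T).
#'
#' @param path File path.
#' @return Tibble of class `"hexamer_table"` with unique 6-mer keys.
#' @export
read_hexamer_table <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE)
  stopifnot(all(c("hexamer", "score") %in% names(d)))
  if (!"class" %in% names(d)) d$class <- "ESR"
  hexamer_table(d$hexamer, d$score, d$class)
}

#' @rdname read_hexamer_table
#' @param hexamer Character vector of 6-mers.
#' @param score Numeric scores.
#' @param class Optional element class per hexamer.
#' @export
hexamer_table <- function(hexamer, score, class = "ESR") {
  hexamer <- toupper(gsub("U", "T", toupper(hexamer)))
  if (any(nchar(hexamer) != 6)) abort("hexamer keys must have length 6")
  if (anyDuplicated(hexamer)) abort("duplicate hexamer keys")
  out <- tibble(hexamer = hexamer, score = as.numeric(score),
                class = rep_len(class, length(hexamer)))
  class(out) <- c("hexamer_table", class(out))
  out
}

hexamer_lookup <- function(table) {
  setNames(table$score, table$hexamer)
}

# Sum of hexamer scores over the 6-mer windows of `seq` starting at
# `starts` (1-based); hexamers absent from the table score 0.
window_score_sum <- function(seq, starts, lookup) {
  if (length(starts) == 0) return(0)
  hex <- substring(seq, starts, starts + 5)
  s <- lookup[hex]
  sum(s, na.rm = TRUE)
}

#' Wild-type minus mutant ESR score difference
#'
#' Scores the up-to-six hexamer windows overlapping a single-nucleotide
#' variant (sliding step 1, windows truncated at the exon ends) in the
#' wild-type and mutant sequence and returns the difference
#' wt - mt. Larger values mean the mutation removes more
#' enhancer/silencer signal than it creates.
#'
#' @param wt_seq,mt_seq Exon sequences of equal length differing at
#'   `variant_offset` only (indels are unsupported).
#' @param table A [hexamer_table()].
#' @param variant_offset 1-based position of the substitution within
#'   the sequences.
#' @return Scalar delta-ESR score.
#' @export
#' @examples
#' tab <- hexamer_table("AAAAAA", 2)
#' delta_esr(strrep("A", 8), paste0("AAAA", "C", "AAA"), tab, 5)
delta_esr <- function(wt_seq, mt_seq, table, variant_offset) {
  wt_seq <- toupper(gsub("U", "T", toupper(wt_seq)))
  mt_seq <- toupper(gsub("U", "T", toupper(mt_seq)))
  if (nchar(wt_seq) != nchar(mt_seq)) {
    abort("wt and mt sequences differ in length; indels are unsupported")
  }
  n <- nchar(wt_seq)
  stopifnot(variant_offset >= 1, variant_offset <= n)
  diffs <- which(strsplit(wt_seq, "")[[1]] != strsplit(mt_seq, "")[[1]])
  if (length(diffs) > 1) abort("sequences differ at more than one position")
  if (length(diffs) == 1 && diffs != variant_offset) {
    abort("variant_offset does not match the observed substitution")
  }
  lookup <- hexamer_lookup(table)
  starts <- max(1, variant_offset - 5):min(variant_offset, n - 5)
  starts <- starts[starts >= 1 & starts + 5 <= n]
  window_score_sum(wt_seq, starts, lookup) - window_score_sum(mt_seq, starts, lookup)
}

#' Count hexamer motif hits in a sequence
#'
#' Sliding-window (step 1) occurrence count of table hexamers,
#' optionally restricted to one element class.
#'
#' @param seq Sequence to scan.
#' @param table A [hexamer_table()].
#' @param class Optional class filter (`"ESE"`, `"ESS"`, `"ESR"`).
#' @return Integer hit count.
#' @export
count_hexamer_hits <- function(seq, table, class = NULL) {
  seq <- toupper(gsub("U", "T", toupper(seq)))
  if (!is.null(class)) table <- table[table$class %in% class, ]
  n <- nchar(seq)
  if (n < 6 || nrow(table) == 0) return(0L)
  hex <- substring(seq, 1:(n - 5), 6:n)
  sum(hex %in% table$hexamer)
}
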