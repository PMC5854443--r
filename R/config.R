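#' Pipeline configuration
#'
#' Bundles the tunable constants of the splicing-mutation enrichment
#' pipeline. Defaults follow the study conditions the analysis assumes:
#' a 13.4% genome-wide splice-site-mutation (SSM) rate among disease
#' alleles, a 10% background rate of exonic splicing mutations (ESM) in
#' assayed disease alleles, 1,000 Monte Carlo replicates and a 99.9%
#' simulation envelope.
#'
#' @param seed Integer seed for all stochastic steps.
#' @param n_reps Number of Monte Carlo replicates for the sampling
#'   envelope (>= 100).
#' @param ci_level Envelope coverage as a fraction (default 0.999).
#' @param global_ssm_weight Genome-wide proportion of disease alleles
#'   that are canonical splice-site mutations (default 0.134).
#' @param esm_background Background fraction of exonic disease alleles
#'   that disrupt splicing when assayed (default 0.10).
#' @param prob_threshold Classifier probability cutoff used to call a
#'   gene SSM-prone (default 0.6).
#' @param maf_rare,maf_common Minor-allele-frequency cutoffs defining
#'   the rare (< 0.0001, i.e. 0.01%) and common (> 0.01, i.e. 1%)
#'   population strata.
#' @param pseudocount Pseudocount added to raw read counts before
#'   ratios (default 0.5).
#'
#' @return A list of class `"spliceprone_config"`.
#' @export
#' @examples
#' cfg <- pipeline_config(seed = 1)
#' cfg$global_ssm_weight
pipeline_config <- function(seed = 1L,
                            n_reps = 1000L,
                            ci_level = 0.999,
                            global_ssm_weight = 0.134,
                            esm_background = 0.10,
                            prob_threshold = 0.6,
                            maf_rare = 1e-4,
                            maf_common = 0.01,
                            pseudocount = 0.5) {
  stopifnot(
    ci_level > 0, ci_level < 1,
    n_reps >= 100,
    global_ssm_weight >= 0, global_ssm_weight <= 1,
    esm_background >= 0, esm_background <= 1,
    maf_rare < maf_common,
    pseudocount >= 0
  )
  structure(
    list(
      seed = as.integer(seed),
      n_reps = as.integer(n_reps),
      ci_level = ci_level,
      global_ssm_weight = global_ssm_weight,
      esm_background = esm_background,
      prob_threshold = prob_threshold,
      maf_rare = maf_rare,
      maf_common = maf_common,
      pseudocount = pseudocount
    ),
    class = "spliceprone_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are rejected; missing keys fall back to the
#' [pipeline_config()] defaults.
#'
#' @param path Path to a YAML file.
#' @return A `"spliceprone_config"` list.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  extra <- setdiff(names(raw), known)
  if (length(extra) > 0) {
    abort(paste0("Unknown configuration keys: ", paste(extra, collapse = ", ")))
  }
  do.call(pipeline_config, raw)
}

#' @export
print.spliceprone_config <- function(x, ...) {
  cat("<spliceprone pipeline configuration>\n")
  for (nm in names(x)) cat(sprintf("  %-18s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
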