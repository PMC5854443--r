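#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy and glance methods
#'
#' `tidy()` returns the per-entity table of a result; `glance()` a
#' one-row summary. Available for envelope results, tallies,
#' classifiers and delta-strata comparisons.
#'
#' @param x A spliceprone result object.
#' @param ... Unused.
#' @return A tibble.
#' @name spliceprone-tidiers
NULL

#' @rdname spliceprone-tidiers
#' @export
tidy.ssm_envelope <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "ssm_envelope")
  out
}

#' @rdname spliceprone-tidiers
#' @export
glance.ssm_envelope <- function(x, ...) {
  tibble(
    n_entities = nrow(x),
    n_upper = sum(x$category == "Upper"),
    n_expected = sum(x$category == "Expected"),
    n_lower = sum(x$category == "Lower"),
    flagged_fraction = mean(x$category != "Expected")
  )
}

#' @rdname spliceprone-tidiers
#' @export
glance.ssm_tally <- function(x, ...) {
  g <- global_weights(x)
  tibble(
    n_genes = nrow(x),
    totalspl = g$totalspl, totalmuts = g$totalmuts,
    totalSS = g$totalSS, totalCDS = g$totalCDS,
    global_weight = g$totalspl / g$totalmuts
  )
}

#' @rdname spliceprone-tidiers
#' @export
tidy.splice_classifier <- function(x, ...) {
  x$importance
}

#' @rdname spliceprone-tidiers
#' @export
glance.splice_classifier <- function(x, ...) {
  tibble(method = x$method, auc = x$auc,
         n_features = length(x$feature_names),
         n_train = x$n_train, n_test = x$n_test)
}

#' @rdname spliceprone-tidiers
#' @export
tidy.delta_strata <- function(x, ...) {
  x$strata
}

#' @rdname spliceprone-tidiers
#' @export
glance.delta_strata <- function(x, ...) {
  tibble(depletion_loss = x$depletion_loss,
         enrichment_gain = x$enrichment_gain,
         loss_cut = x$loss_cut, gain_cut = x$gain_cut)
}
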