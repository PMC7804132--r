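# Phenotype score: weighted combination of output-node activities.

#' Phenotype scoring configuration
#'
#' The score weights the five pathological output phenotypes by clinical
#' priority — amyloid-beta 30, phosphorylated tau 30, synapse loss 20,
#' apoptosis 10, autophagy 10 — for a 0-100 range under the defaults.
#' Amyloid-beta, p-tau, synapse loss and apoptosis are desired *low*;
#' autophagy, whose up-regulation clears pathological protein, is desired
#' *high*.
#'
#' @param weights named non-negative weights over phenotype labels.
#' @param direction named `"low"`/`"high"` desired direction per phenotype.
#' @param orientation `"desirability"` (higher = closer to the healthy
#'   state; used for target ranking) or `"pathology"` (the complement).
#' @param mode `"activity"` scores the continuous basin-weighted output
#'   activity (default); `"membership"` assigns each attractor to a
#'   phenotype by thresholding its mean output activity at 0.5 and sums
#'   basin ratios — a sensitivity-check variant that coincides with the
#'   default when attractors are fixed points.
#' @return a `PhenotypeConfig` list.
#' @export
phenotype_config <- function(weights = c(Abeta = 30, ptau = 30,
                                         synapse_loss = 20, apoptosis = 10,
                                         autophagy = 10),
                             direction = c(Abeta = "low", ptau = "low",
                                           synapse_loss = "low",
                                           apoptosis = "low",
                                           autophagy = "high"),
                             orientation = c("desirability", "pathology"),
                             mode = c("activity", "membership")) {
  orientation <- match.arg(orientation)
  mode <- match.arg(mode)
  if (is.null(names(weights)) || any(!nzchar(names(weights))))
    stop("weights must be named by phenotype")
  if (any(weights < 0)) stop("weights must be non-negative")
  miss <- setdiff(names(weights), names(direction))
  if (length(miss)) stop("no desired direction for phenotype '", miss[1L], "'")
  if (!all(direction %in% c("low", "high")))
    stop("direction entries must be 'low' or 'high'")
  structure(list(weights = weights, direction = direction[names(weights)],
                 orientation = orientation, mode = mode),
            class = "PhenotypeConfig")
}

# output node carrying each weighted phenotype label
phenotype_nodes <- function(network, config) {
  out <- output_nodes(network)
  vapply(names(config$weights), function(p) {
    hit <- out[!is.na(network$phenotypes[out]) & network$phenotypes[out] == p]
    if (length(hit) == 0L)
      stop("no output node carries phenotype '", p, "'")
    hit[1L]
  }, "")
}

#' Phenotype score of a landscape
#'
#' For each weighted phenotype `p` with output activity `a_p`, the
#' desirability is `1 - a_p` when the desired direction is low and `a_p`
#' when high; the score is the weight-sum of desirabilities, ranging from 0
#' (fully pathological) to the weight total (100 under the defaults, the
#' desired state). `orientation = "pathology"` returns the complement.
#'
#' @param landscape an `AttractorLandscape` of a network whose output nodes
#'   carry the weighted phenotype labels.
#' @param config a [phenotype_config()].
#' @return numeric scalar in `[0, sum(weights)]`.
#' @export
phenotype_score <- function(landscape, config = phenotype_config()) {
  a <- phenotype_activity(landscape, config)
  d <- ifelse(config$direction == "low", 1 - a, a)
  score <- sum(config$weights * d)
  if (config$orientation == "pathology") sum(config$weights) - score else score
}

#' Per-phenotype output activity of a landscape
#'
#' @inheritParams phenotype_score
#' @return named numeric vector over the weighted phenotypes: under
#'   `mode = "activity"` the basin-weighted activity of each phenotype's
#'   output node; under `mode = "membership"` the total basin ratio of
#'   attractors whose mean output activity exceeds 0.5.
#' @export
phenotype_activity <- function(landscape, config = phenotype_config()) {
  nodes <- phenotype_nodes(landscape$network, config)
  if (config$mode == "activity") {
    act <- node_activity(landscape)
    stats::setNames(act[nodes], names(nodes))
  } else {
    w <- basin_ratio(landscape)
    acts <- activity_matrix(landscape)
    vapply(nodes, function(nd) sum(w[acts[, nd] > 0.5]), 0)
  }
}
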