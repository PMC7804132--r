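# Risk-factor conditions: named differential wirings (node pinnings plus
# rule overrides) that turn the normal-state model into a disease model,
# e.g. an ApoE e4-allele case or an LPL loss-of-function case.

#' Define a risk-factor condition
#'
#' @param name condition name (`"normal"` means: leave the network alone).
#' @param pins optional [perturbation()]: nodes clamped by the risk factor
#'   (e.g. a loss-of-function gene pinned to 0).
#' @param overrides optional named character vector / list of replacement
#'   rule expressions, keyed by target node. Pins and overrides must be
#'   disjoint.
#' @return a `RiskFactorCondition`.
#' @export
risk_factor_condition <- function(name, pins = NULL, overrides = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  pins <- perturbation(pins)
  if (!is.null(overrides)) {
    if (is.null(names(overrides)) || any(!nzchar(names(overrides))))
      stop("overrides must be named by target node")
    overrides <- lapply(overrides,
                        function(r) if (is.character(r)) parse_expr(r) else r)
    both <- intersect(names(overrides), names(pins))
    if (length(both))
      stop("node '", both[1L], "' is both pinned and overridden")
  } else {
    overrides <- list()
  }
  structure(list(name = name, pins = pins, overrides = overrides),
            class = "RiskFactorCondition")
}

#' Read / write a condition YAML file
#'
#' Format: `name:` string, `pins:` mapping node to 0/1, `overrides:`
#' mapping node to a rule-expression string.
#'
#' @param path YAML file.
#' @param condition a `RiskFactorCondition` (for writing).
#' @return the condition (reading) or the path, invisibly (writing).
#' @export
read_condition <- function(path) {
  doc <- yaml::read_yaml(path)
  risk_factor_condition(doc$name,
                        pins = unlist(doc$pins),
                        overrides = doc$overrides)
}

#' @rdname read_condition
#' @export
write_condition <- function(condition, path) {
  doc <- list(name = condition$name,
              pins = as.list(unclass(condition$pins)),
              overrides = lapply(condition$overrides, render_expr))
  yaml::write_yaml(doc, path)
  invisible(path)
}

cond_label <- function(condition)
  if (is.null(condition)) "normal" else condition$name

#' Apply a risk-factor condition to a network
#'
#' Substitutes the condition's rule overrides into the network and returns
#' the rewired network together with the condition's residual pins, which
#' must be composed with any further (therapeutic) pins when simulating.
#' A condition named `"normal"` with no pins/overrides returns the network
#' unchanged.
#'
#' @param network a `BooleanNetwork`.
#' @param condition a `RiskFactorCondition`, or `NULL` for none.
#' @return list with elements `network` (rules substituted) and `pins`.
#' @export
apply_risk_factor <- function(network, condition = NULL) {
  if (is.null(condition))
    return(list(network = network, pins = perturbation()))
  stopifnot(inherits(condition, "RiskFactorCondition"))
  bad <- setdiff(c(names(condition$pins), names(condition$overrides)),
                 network$nodes)
  if (length(bad))
    stop("condition '", condition$name, "' references undeclared node '",
         bad[1L], "'")
  rules <- network$rules
  for (nm in names(condition$overrides)) {
    miss <- setdiff(expr_vars(condition$overrides[[nm]]), network$nodes)
    if (length(miss))
      stop("override for '", nm, "' references undeclared node '", miss[1L], "'")
    rules[[nm]] <- condition$overrides[[nm]]
  }
  net <- boolean_network(rules,
                         roles = network$roles,
                         phenotypes = network$phenotypes[!is.na(network$phenotypes)])
  list(network = net, pins = condition$pins)
}
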