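# Synthetic model generators: Kauffman-style random NK networks, an exact
# link-count surrogate at full model scale, and the fixed mini pathway
# fixture whose rules transcribe the qualitative causal claims of the
# Alzheimer's-disease signaling literature (WNT canonical/non-canonical,
# PI3K-AKT/PTEN, mTORC1-autophagy, MAPK-APP, GSK-3beta-p-tau, apoptosis,
# synapse loss). The fixture is a hand-verifiable test double at reduced
# scale, not a published model.

#' Generate a random Kauffman NK Boolean network
#'
#' Each node receives `k` distinct regulators chosen uniformly at random
#' and a random truth table with ON-bias `bias` (probability an entry is
#' 1). Truth tables are rendered as disjunctive-normal-form expressions, so
#' generated networks round-trip through the rule-file writer/parser.
#' Designated output nodes (the last `n_outputs`) get phenotype labels
#' assigned cyclically. Deterministic per seed.
#'
#' @param n_nodes number of nodes.
#' @param k regulators per node (`1 <= k < n_nodes`).
#' @param bias probability that a truth-table entry is 1.
#' @param n_outputs how many trailing nodes to mark as outputs.
#' @param seed RNG seed.
#' @return a `BooleanNetwork`.
#' @export
generate_random_network <- function(n_nodes, k = 2L, bias = 0.5,
                                    n_outputs = 0L, seed = 1L) {
  stopifnot(k >= 1L, k < n_nodes, bias >= 0, bias <= 1,
            n_outputs <= n_nodes)
  nodes <- sprintf("v%02d", seq_len(n_nodes))
  rules <- withr::with_seed(seed, {
    lapply(seq_len(n_nodes), function(i) {
      regs <- sample(nodes, k)
      tt <- stats::runif(2L^k) < bias
      truth_table_expr(regs, tt)
    })
  })
  names(rules) <- nodes
  roles <- phen <- NULL
  if (n_outputs > 0L) {
    outs <- utils::tail(nodes, n_outputs)
    roles <- stats::setNames(rep("output", n_outputs), outs)
    phen <- stats::setNames(rep_len(PHENOTYPES, n_outputs), outs)
  }
  boolean_network(rules, roles = roles, phenotypes = phen)
}

# DNF rendering of a truth table: OR over minterms; constant when trivial.
# Row i (0-based) encodes regulator j ON iff bit j of i is set.
truth_table_expr <- function(regs, tt) {
  if (!any(tt)) return(list(type = "const", value = FALSE))
  if (all(tt)) return(list(type = "const", value = TRUE))
  k <- length(regs)
  minterm <- function(i) {
    lits <- lapply(seq_len(k), function(j) {
      v <- list(type = "var", name = regs[j])
      if (bitwAnd(bitwShiftR(i, j - 1L), 1L)) v else list(type = "not", x = v)
    })
    Reduce(function(a, b) list(type = "and", lhs = a, rhs = b), lits)
  }
  terms <- lapply(which(tt) - 1L, minterm)
  Reduce(function(a, b) list(type = "or", lhs = a, rhs = b), terms)
}

#' Generate a surrogate network with an exact node and link count
#'
#' Builds a random network with exactly `n_nodes` nodes and `n_links`
#' regulatory links by distributing in-degrees (at least 2 per node) and
#' wiring each node as a random AND- or OR-chain over distinct regulators
#' with random negations — every regulator appears irreducibly, so the
#' link count is exact. Used as a synthetic stand-in at the scale of the
#' published 77-node, 204-link disease model when exercising parsing and
#' full-scale sampling.
#'
#' @param n_nodes node count (default 77).
#' @param n_links total regulatory links (default 204).
#' @param seed RNG seed.
#' @return a `BooleanNetwork`.
#' @export
generate_surrogate_network <- function(n_nodes = 77L, n_links = 204L,
                                       seed = 1L) {
  stopifnot(n_links >= 2L * n_nodes, n_links <= n_nodes * (n_nodes - 1L))
  nodes <- sprintf("g%02d", seq_len(n_nodes))
  withr::with_seed(seed, {
    deg <- rep(2L, n_nodes)
    extra <- n_links - sum(deg)
    while (extra > 0L) {
      i <- sample.int(n_nodes, 1L)
      if (deg[i] < min(6L, n_nodes - 1L)) { deg[i] <- deg[i] + 1L; extra <- extra - 1L }
    }
    rules <- lapply(seq_len(n_nodes), function(i) {
      regs <- sample(setdiff(nodes, nodes[i]), deg[i])
      op <- sample(c("and", "or"), 1L)
      lits <- lapply(regs, function(r) {
        v <- list(type = "var", name = r)
        if (stats::runif(1) < 0.3) list(type = "not", x = v) else v
      })
      Reduce(function(a, b) list(type = op, lhs = a, rhs = b), lits)
    })
    names(rules) <- nodes
    boolean_network(rules)
  })
}

MINI_AD_RULES <- "
targets, factors
ROS, ROS
MAPK, ROS
CREB, MAPK
APP, MAPK
Dkk1, Abeta | ROS
WNT_can, !Dkk1
WNT_noncan, Dkk1 | Abeta
BACE1, WNT_noncan
Abeta, APP & (BACE1 | !autophagy)
NMDAR, !Abeta
PTEN, PTEN
PI3K_AKT, NMDAR & !PTEN
GSK3b, !WNT_can & !PI3K_AKT
mTORC1, PI3K_AKT
autophagy, !mTORC1
ptau, GSK3b & !autophagy
apoptosis, (ROS & !PI3K_AKT) | ptau
synapse_loss, Abeta & !CREB
"

#' The mini Alzheimer's-pathway fixture
#'
#' A fixed 18-node network encoding, one clause per rule, the qualitative
#' causal relations of the core disease pathways: oxidative stress (ROS,
#' the self-sustaining input) drives MAPK, which raises APP expression and
#' CREB (protective against synapse loss); amyloid-beta and ROS induce
#' Dkk1, which silences canonical WNT signaling and (with amyloid-beta)
#' activates the non-canonical branch that drives BACE1; amyloid-beta is
#' produced from APP when BACE1 is active or autophagic clearance fails,
#' and it suppresses synaptic NMDAR signaling; NMDAR activates PI3K-AKT
#' unless PTEN (self-sustaining) blocks it; GSK-3beta is active only when
#' both canonical WNT and PI3K-AKT are silent and, without autophagy,
#' yields phosphorylated tau; PI3K-AKT drives mTORC1, which shuts down
#' autophagy; apoptosis follows stress without AKT survival signaling or
#' p-tau; synapse loss follows amyloid-beta unopposed by CREB. The five
#' phenotype outputs are `Abeta`, `ptau`, `synapse_loss`, `apoptosis`,
#' `autophagy`.
#'
#' The same rules ship as plain text under `inst/extdata/mini_ad.bnet`
#' with the annotation sidecar `mini_ad_annotation.yaml`.
#'
#' @return a `BooleanNetwork` with 18 nodes and 5 outputs.
#' @export
build_mini_ad_network <- function() {
  parse_network(MINI_AD_RULES, annotations = list(
    ROS = list(role = "input"),
    Abeta = list(role = "output", phenotype = "Abeta"),
    ptau = list(role = "output", phenotype = "ptau"),
    synapse_loss = list(role = "output", phenotype = "synapse_loss"),
    apoptosis = list(role = "output", phenotype = "apoptosis"),
    autophagy = list(role = "output", phenotype = "autophagy")))
}
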