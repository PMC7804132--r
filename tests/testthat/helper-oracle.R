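# Independent slow-path oracle: plain-R synchronous dynamics built on the
# expression evaluator only, with no memoization and no shared code with
# the compiled engine. Used to cross-check landscapes and screens on small
# networks.

r_step <- function(net, state, pins = NULL) {
  out <- vapply(net$nodes,
                function(nm) eval_expr(net$rules[[nm]], state), TRUE)
  out <- as.integer(out)
  names(out) <- net$nodes
  if (!is.null(pins)) out[names(pins)] <- as.integer(pins)
  out
}

# returns canonical cycle key (bit strings joined by "|") for an initial state
r_attractor_key <- function(net, state, pins = NULL) {
  if (!is.null(pins)) state[names(pins)] <- as.integer(pins)
  seen <- character(0)
  s <- state
  repeat {
    key <- paste(s, collapse = "")
    hit <- match(key, seen)
    if (!is.na(hit)) {
      cyc <- seen[hit:length(seen)]
      rot <- order(cyc)[1L]
      return(paste(c(cyc[rot:length(cyc)], cyc[seq_len(rot - 1L)]),
                   collapse = "|"))
    }
    seen <- c(seen, key)
    s <- r_step(net, stats::setNames(s, net$nodes), pins)
  }
}

# exhaustive landscape by brute force: named vector basin counts by cycle key
r_landscape <- function(net, pins = NULL) {
  n <- length(net$nodes)
  free <- setdiff(net$nodes, names(pins))
  counts <- integer(0)
  for (i in seq_len(2L^length(free)) - 1L) {
    s <- stats::setNames(integer(n), net$nodes)
    bits <- as.integer(bitwAnd(bitwShiftR(i, seq_along(free) - 1L), 1L))
    s[free] <- bits
    key <- r_attractor_key(net, s, pins)
    counts[key] <- (if (is.na(counts[key])) 0L else counts[key]) + 1L
  }
  counts
}

# cycle keys of a computed AttractorLandscape, for set comparison
landscape_keys <- function(ls) {
  sort(vapply(ls$attractors, `[[`, "", "id"))
}

# two-node toggle network used across tests: A=B, B=A
toggle_net <- function() parse_network("targets, factors\nA, B\nB, A")

# tiny five-output network whose outputs are constants, for score arithmetic
const_output_net <- function(abeta, ptau, syn, apop, auto) {
  rules <- list(Abeta = if (abeta) "1" else "0",
                ptau = if (ptau) "1" else "0",
                synapse_loss = if (syn) "1" else "0",
                apoptosis = if (apop) "1" else "0",
                autophagy = if (auto) "1" else "0")
  boolean_network(rules,
                  roles = stats::setNames(rep("output", 5), names(rules)),
                  phenotypes = stats::setNames(names(rules), names(rules)))
}

# hand-built landscape over the five-output network with prescribed
# per-attractor output activities and basin counts; for scoring properties
fake_landscape <- function(activity_rows, basins) {
  net <- const_output_net(0, 0, 0, 0, 0)
  atts <- lapply(seq_len(nrow(activity_rows)), function(i) {
    act <- stats::setNames(activity_rows[i, ], net$nodes)
    list(id = paste0("a", i),
         cycle = matrix(as.integer(act > 0.5), nrow = 1,
                        dimnames = list(NULL, net$nodes)),
         mean_activity = act)
  })
  structure(list(attractors = atts, basin_count = basins,
                 total = sum(basins), method = "exhaustive",
                 seed = NA_integer_, pins = perturbation(),
                 network = net),
            class = "AttractorLandscape")
}
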