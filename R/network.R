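# BooleanNetwork container and the BoolNet-dialect rule-file reader/writer.

PHENOTYPES <- c("Abeta", "ptau", "synapse_loss", "apoptosis", "autophagy")

#' Construct a Boolean network
#'
#' A network is an ordered set of named nodes, one Boolean update rule per
#' node, and a role for each node: `input` (externally set, conventionally
#' self-sustaining), `internal`, or `output`. Output nodes carry a phenotype
#' label used by the phenotype score.
#'
#' @param rules named list of expression trees (see [parse_expr()]) or
#'   character rule strings; names are the target nodes and fix node order.
#' @param roles optional named character vector over node names with values
#'   `"input"`, `"internal"`, `"output"`; unmentioned nodes are `internal`.
#' @param phenotypes optional named character vector mapping output nodes to
#'   phenotype labels (`r paste(PHENOTYPES, collapse = ", ")`).
#' @return an object of class `BooleanNetwork`.
#' @export
boolean_network <- function(rules, roles = NULL, phenotypes = NULL) {
  nodes <- names(rules)
  if (is.null(nodes) || any(!nzchar(nodes)))
    stop("rules must be a fully named list")
  if (anyDuplicated(nodes))
    stop("duplicate rule target: ", nodes[duplicated(nodes)][1L])
  if (any(grepl("[[:space:]]", nodes)))
    stop("node names must not contain whitespace")
  rules <- lapply(rules, function(r) if (is.character(r)) parse_expr(r) else r)
  role <- rep("internal", length(nodes))
  names(role) <- nodes
  if (!is.null(roles)) {
    bad <- setdiff(names(roles), nodes)
    if (length(bad)) stop("role given for undeclared node: ", bad[1L])
    if (!all(roles %in% c("input", "internal", "output")))
      stop("roles must be input/internal/output")
    role[names(roles)] <- roles
  }
  phen <- rep(NA_character_, length(nodes))
  names(phen) <- nodes
  if (!is.null(phenotypes)) {
    bad <- setdiff(names(phenotypes), nodes)
    if (length(bad)) stop("phenotype label for undeclared node: ", bad[1L])
    phen[names(phenotypes)] <- phenotypes
  }
  if (any(role == "output" & is.na(phen)))
    stop("every output node needs a phenotype label")
  if (any(role != "output" & !is.na(phen)))
    stop("phenotype labels are only allowed on output nodes")
  # every referenced variable must be declared
  for (nm in nodes) {
    miss <- setdiff(expr_vars(rules[[nm]]), nodes)
    if (length(miss))
      stop("rule for '", nm, "' references undeclared node '", miss[1L], "'")
  }
  structure(list(nodes = nodes, rules = rules, roles = role,
                 phenotypes = phen),
            class = "BooleanNetwork")
}

#' @export
print.BooleanNetwork <- function(x, ...) {
  cat("BooleanNetwork:", length(x$nodes), "nodes,", count_links(x), "links\n")
  cat("  inputs: ", paste(input_nodes(x), collapse = ", "), "\n", sep = "")
  outs <- output_nodes(x)
  cat("  outputs:", paste(sprintf("%s[%s]", outs, x$phenotypes[outs]),
                          collapse = ", "), "\n")
  invisible(x)
}

#' Input / output node accessors
#' @param network a `BooleanNetwork`.
#' @return character vector of node names.
#' @export
input_nodes <- function(network) network$nodes[network$roles == "input"]

#' @rdname input_nodes
#' @export
output_nodes <- function(network) network$nodes[network$roles == "output"]

#' Parse a BoolNet-dialect rule document
#'
#' The format is the plain-text `targets, factors` table used by logical
#' modeling tools: a header line, then one `name, expression` line per node.
#' `#` comments and blank lines are ignored. Node order in the file defines
#' the state-vector indexing. Roles and phenotype labels come from a YAML
#' annotation sidecar (see [read_annotations()]), since the rule format has
#' no role field.
#'
#' @param text a character scalar (whole document) or vector of lines, or a
#'   file path to a rule file.
#' @param annotations optional: path to a YAML annotation file or a named
#'   list `node -> list(role =, phenotype =)`.
#' @return a `BooleanNetwork`.
#' @export
parse_network <- function(text, annotations = NULL) {
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text))
    text <- readLines(text, warn = FALSE)
  if (length(text) == 1L) text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  lines <- sub("#.*$", "", text)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty rule document")
  if (grepl("^targets[[:space:]]*,[[:space:]]*factors$", lines[1L],
            ignore.case = TRUE))
    lines <- lines[-1L]
  if (length(lines) == 0L) stop("rule document has a header but no rules")
  rules <- list()
  for (ln in lines) {
    comma <- regexpr(",", ln, fixed = TRUE)
    if (comma < 0) stop("malformed rule line (no comma): '", ln, "'")
    target <- trimws(substr(ln, 1L, comma - 1L))
    expr_txt <- trimws(substr(ln, comma + 1L, nchar(ln)))
    if (!nzchar(target)) stop("malformed rule line (empty target): '", ln, "'")
    if (target %in% names(rules)) stop("duplicate rule target: ", target)
    rules[[target]] <- parse_expr(expr_txt)
  }
  ann <- resolve_annotations(annotations)
  boolean_network(rules, roles = ann$roles, phenotypes = ann$phenotypes)
}

resolve_annotations <- function(annotations) {
  if (is.null(annotations)) return(list(roles = NULL, phenotypes = NULL))
  if (is.character(annotations) && length(annotations) == 1L)
    annotations <- yaml::read_yaml(annotations)
  roles <- vapply(annotations, function(a) a$role %||% "internal", "")
  phen_l <- lapply(annotations, function(a) a$phenotype)
  keep <- !vapply(phen_l, is.null, TRUE)
  phenotypes <- if (any(keep)) unlist(phen_l[keep]) else NULL
  list(roles = roles, phenotypes = phenotypes)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize a network to rule-file text
#' @param network a `BooleanNetwork`.
#' @param path optional file to write; when `NULL`, lines are returned.
#' @return character vector of lines, invisibly when writing to a file.
#' @export
serialize_network <- function(network, path = NULL) {
  lines <- c("targets, factors",
             vapply(network$nodes, function(nm)
               paste0(nm, ", ", render_expr(network$rules[[nm]])), ""))
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Read / write the YAML annotation sidecar
#'
#' The sidecar maps each annotated node to `role` and (for outputs) a
#' `phenotype` label; un-annotated nodes default to `internal`.
#'
#' @param path YAML file path.
#' @param network a `BooleanNetwork` (for writing).
#' @return `read_annotations`: the annotation list; `write_annotations`:
#'   the path, invisibly.
#' @export
read_annotations <- function(path) yaml::read_yaml(path)

#' @rdname read_annotations
#' @export
write_annotations <- function(network, path) {
  ann <- list()
  for (nm in network$nodes) {
    if (network$roles[[nm]] == "internal") next
    a <- list(role = network$roles[[nm]])
    if (!is.na(network$phenotypes[[nm]])) a$phenotype <- network$phenotypes[[nm]]
    ann[[nm]] <- a
  }
  yaml::write_yaml(ann, path)
  invisible(path)
}

#' Count regulatory links
#'
#' A link is a distinct (regulator, target) pair in which the regulator
#' appears in the target's update rule; a regulator occurring several times
#' in one rule counts once.
#'
#' @param network a `BooleanNetwork`.
#' @return integer link count.
#' @export
count_links <- function(network) {
  sum(vapply(network$rules, function(r) length(expr_vars(r)), 0L))
}

#' Define a node-pinning perturbation
#'
#' Pinning clamps a node to a fixed value throughout the dynamics: pin 0
#' models drug-like inhibition, pin 1 activation.
#'
#' @param pins named numeric/integer vector of 0/1 values over node names,
#'   e.g. `c(PTEN = 0, mTORC1 = 0)`; `NULL` means no perturbation.
#' @return a named integer vector of class `Perturbation`.
#' @export
perturbation <- function(pins = NULL) {
  if (is.null(pins) || length(pins) == 0L)
    return(structure(integer(0), class = "Perturbation"))
  if (is.null(names(pins)) || any(!nzchar(names(pins))))
    stop("pins must be a named vector")
  if (anyDuplicated(names(pins)))
    stop("duplicate pinned node: ", names(pins)[duplicated(names(pins))][1L])
  v <- as.integer(pins)
  if (!all(v %in% 0:1)) stop("pinned values must be 0 or 1")
  structure(stats::setNames(v, names(pins)), class = "Perturbation")
}

# pins as a full-length vector for the C++ engine: -1 free, else 0/1
pin_vector <- function(network, pins) {
  pins <- perturbation(pins)
  bad <- setdiff(names(pins), network$nodes)
  if (length(bad)) stop("pinned node not in network: ", bad[1L])
  v <- rep(-1L, length(network$nodes))
  names(v) <- network$nodes
  v[names(pins)] <- unclass(pins)
  v
}

# compiled postfix programs for the engine
compile_network <- function(network) {
  index <- stats::setNames(seq_along(network$nodes), network$nodes)
  lapply(network$nodes, function(nm) compile_expr(network$rules[[nm]], index))
}

as_state <- function(network, state) {
  n <- length(network$nodes)
  if (!is.null(names(state))) {
    miss <- setdiff(network$nodes, names(state))
    if (length(miss)) stop("state is missing node '", miss[1L], "'")
    state <- state[network$nodes]
  } else if (length(state) != n) {
    stop("state length ", length(state), " does not match node count ", n)
  }
  v <- as.integer(state)
  if (!all(v %in% 0:1)) stop("state entries must be 0 or 1")
  stats::setNames(v, network$nodes)
}

#' Advance a network one synchronous step
#'
#' Every non-pinned node takes the value of its rule evaluated on the input
#' state; pinned nodes take their pinned value.
#'
#' @param network a `BooleanNetwork`.
#' @param state 0/1 vector in node order (or named over all nodes).
#' @param pins optional [perturbation()].
#' @return named 0/1 integer vector: the successor state.
#' @export
step_state <- function(network, state, pins = NULL) {
  s <- as_state(network, state)
  out <- cpp_step(compile_network(network), pin_vector(network, pins), s)
  stats::setNames(out, network$nodes)
}

#' Evolve a state to its attractor
#'
#' Iterates the synchronous update until a state recurs. The attractor cycle
#' is returned in canonical rotation (lexicographically smallest state, as a
#' bit string in node order, first); a fixed point is a cycle of length 1.
#' Termination is guaranteed because the deterministic dynamics on a finite
#' state space must revisit a state within 2^n steps.
#'
#' @inheritParams step_state
#' @return list with `cycle` (L x n 0/1 matrix, one row per cycle state,
#'   columns named by node) and `transient` (number of pre-cycle steps).
#' @export
evolve_to_attractor <- function(network, state, pins = NULL) {
  s <- as_state(network, state)
  pv <- pin_vector(network, pins)
  # the contract assumes pinned nodes already hold their pinned value
  s[pv >= 0] <- pv[pv >= 0]
  res <- cpp_evolve(compile_network(network), pv, s)
  colnames(res$cycle) <- network$nodes
  res
}
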