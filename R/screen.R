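# Single- and double-node perturbation screens under a risk-factor
# condition: every candidate (pair of) node(s) is pinned, the attractor
# landscape recomputed, and the resulting phenotype score ranked.

#' Sampling control for screens and landscapes
#'
#' @param method `"auto"` enumerates exhaustively when the free-node count
#'   allows and samples otherwise; or force `"exhaustive"` / `"sampled"`.
#' @param n_samples samples per landscape when sampling.
#' @param seed base seed; each landscape in a screen uses a seed derived
#'   deterministically from it (base + entry index).
#' @param max_free exhaustive-enumeration limit on free nodes.
#' @return a `ScreenSampling` list.
#' @export
screen_sampling <- function(method = c("auto", "exhaustive", "sampled"),
                            n_samples = 1e4, seed = 1L, max_free = 20L) {
  structure(list(method = match.arg(method), n_samples = n_samples,
                 seed = as.integer(seed), max_free = as.integer(max_free)),
            class = "ScreenSampling")
}

condition_landscape <- function(network, pins, sampling, offset = 0L) {
  f <- sum(pin_vector(network, pins) < 0)
  method <- sampling$method
  if (method == "auto")
    method <- if (f <= sampling$max_free) "exhaustive" else "sampled"
  if (method == "exhaustive")
    enumerate_landscape(network, pins, max_free = sampling$max_free)
  else
    sample_landscape(network, pins, n_samples = sampling$n_samples,
                     seed = sampling$seed + offset)
}

screen_candidates <- function(network, cond_pins, condition) {
  excluded <- c(output_nodes(network), input_nodes(network),
                names(cond_pins),
                if (!is.null(condition)) names(condition$overrides))
  setdiff(network$nodes, excluded)
}

run_screen <- function(network, condition, config, sampling, pin_value, arity) {
  applied <- apply_risk_factor(network, condition)
  cnet <- applied$network
  cpins <- applied$pins
  base_ls <- condition_landscape(cnet, cpins, sampling, offset = 0L)
  base_score <- phenotype_score(base_ls, config)
  cands <- screen_candidates(cnet, cpins, condition)
  target_sets <- if (arity == 1L) as.list(cands) else
    utils::combn(sort(cands), 2L, simplify = FALSE)
  entries <- vector("list", length(target_sets))
  for (i in seq_along(target_sets)) {
    tg <- target_sets[[i]]
    pins_i <- perturbation(c(unclass(cpins),
                             stats::setNames(rep(pin_value, length(tg)), tg)))
    ls_i <- condition_landscape(cnet, pins_i, sampling, offset = i)
    sc <- phenotype_score(ls_i, config)
    act <- phenotype_activity(ls_i, config)
    entries[[i]] <- data.frame(targets = paste(tg, collapse = "+"),
                               n_targets = length(tg),
                               score = sc,
                               delta = sc - base_score,
                               t(act),
                               check.names = FALSE)
  }
  entries <- do.call(rbind, entries)
  if (!is.null(entries)) {
    # descending score; ties by fewer targets, then lexicographic names
    entries <- entries[order(-entries$score, entries$n_targets,
                             entries$targets), , drop = FALSE]
    entries$rank <- seq_len(nrow(entries))
    rownames(entries) <- NULL
  }
  structure(list(condition = if (is.null(condition)) "normal" else condition$name,
                 pin_value = pin_value,
                 baseline = list(landscape = base_ls, score = base_score),
                 entries = entries,
                 sampling = sampling),
            class = "ScreenResult")
}

#' Single-node perturbation screen
#'
#' Every candidate node — all nodes minus outputs, designated inputs,
#' condition-pinned nodes and condition-overridden nodes — is pinned (to 0
#' by default, modeling inhibition) on top of the risk-factor condition;
#' the landscape is recomputed and converted to a phenotype score, and
#' entries are ranked by descending score. `delta` is relative to the
#' unperturbed disease baseline (condition applied, no therapy).
#'
#' @param network the normal-state `BooleanNetwork`.
#' @param condition a [risk_factor_condition()], or `NULL`/"normal".
#' @param config a [phenotype_config()].
#' @param sampling a [screen_sampling()].
#' @param pin_value 0 (inhibition, default) or 1 (activation).
#' @return a `ScreenResult`: baseline landscape + score, ranked entry
#'   table (`targets`, `score`, `delta`, per-phenotype activities, `rank`).
#' @export
screen_single <- function(network, condition = NULL,
                          config = phenotype_config(),
                          sampling = screen_sampling(), pin_value = 0L) {
  stopifnot(pin_value %in% 0:1)
  run_screen(network, condition, config, sampling, as.integer(pin_value), 1L)
}

#' Double-node perturbation screen
#'
#' All unordered candidate pairs are pinned simultaneously (both to
#' `pin_value`); otherwise as [screen_single()].
#'
#' @inheritParams screen_single
#' @param max_pairs refuse to run when the pair count exceeds this budget.
#' @return a `ScreenResult` with `choose(m, 2)` entries for `m` candidates.
#' @export
screen_double <- function(network, condition = NULL,
                          config = phenotype_config(),
                          sampling = screen_sampling(), pin_value = 0L,
                          max_pairs = 5000L) {
  stopifnot(pin_value %in% 0:1)
  applied <- apply_risk_factor(network, condition)
  m <- length(screen_candidates(applied$network, applied$pins, condition))
  if (choose(m, 2) > max_pairs)
    stop("screen would evaluate ", choose(m, 2), " pairs (> max_pairs = ",
         max_pairs, "); restrict the candidate set or raise the budget")
  run_screen(network, condition, config, sampling, as.integer(pin_value), 2L)
}

#' @export
print.ScreenResult <- function(x, ...) {
  cat("ScreenResult [", x$condition, "], baseline score ",
      round(x$baseline$score, 2), ", ", nrow(x$entries), " entries\n", sep = "")
  print(utils::head(x$entries, 10L))
  invisible(x)
}

#' Write a ranked screen table
#' @param screen a `ScreenResult`.
#' @param path output TSV file.
#' @return the path, invisibly.
#' @export
write_screen_tsv <- function(screen, path) {
  utils::write.table(screen$entries, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
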