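# Attractor landscapes: exhaustive enumeration, random-initial-state
# sampling, basin sizes, and basin-weighted node activities.

new_landscape <- function(network, pins, raw, method, seed = NA_integer_) {
  nodes <- network$nodes
  atts <- lapply(seq_along(raw$cycles), function(i) {
    cyc <- raw$cycles[[i]]
    colnames(cyc) <- nodes
    key <- paste(apply(cyc, 1L, paste, collapse = ""), collapse = "|")
    list(id = key, cycle = cyc, mean_activity = colMeans(cyc))
  })
  counts <- raw$counts
  # order by descending basin, ties by id, for a stable presentation
  ids <- vapply(atts, `[[`, "", "id")
  ord <- order(-counts, ids)
  structure(list(attractors = atts[ord],
                 basin_count = counts[ord],
                 total = raw$total,
                 method = method,
                 seed = seed,
                 pins = perturbation(pins),
                 network = network),
            class = "AttractorLandscape")
}

#' Basin ratios of a landscape
#' @param landscape an `AttractorLandscape`.
#' @return numeric vector, one entry per attractor, summing to 1.
#' @export
basin_ratio <- function(landscape) landscape$basin_count / landscape$total

#' @export
print.AttractorLandscape <- function(x, ...) {
  cat("AttractorLandscape (", x$method, "): ", length(x$attractors),
      " attractor(s) over ", format(x$total, big.mark = ","),
      " initial states\n", sep = "")
  lens <- vapply(x$attractors, function(a) nrow(a$cycle), 0L)
  df <- data.frame(cycle_length = lens,
                   basin_count = x$basin_count,
                   basin_ratio = round(basin_ratio(x), 4))
  print(utils::head(df, 10L))
  invisible(x)
}

#' Exhaustive attractor landscape
#'
#' Enumerates all `2^f` initial states over the `f` free (non-pinned) nodes,
#' evolves each to its attractor, and counts basin sizes exactly. Visited
#' states are memoized across trajectories so each state is processed once.
#' This is the exact oracle against which [sample_landscape()] is checked.
#'
#' @param network a `BooleanNetwork`.
#' @param pins optional [perturbation()]; pinned nodes are fixed in the
#'   initial states and held throughout.
#' @param max_free refuse enumeration when the free-node count exceeds this
#'   (default 20, i.e. about a million initial states).
#' @return an `AttractorLandscape` with `method = "exhaustive"`.
#' @export
enumerate_landscape <- function(network, pins = NULL, max_free = 20L) {
  pv <- pin_vector(network, pins)
  f <- sum(pv < 0)
  if (f > max_free)
    stop("network has ", f, " free nodes (> max_free = ", max_free,
         "); use sample_landscape() instead")
  raw <- cpp_enumerate(compile_network(network), pv)
  new_landscape(network, pins, raw, "exhaustive")
}

#' Sampled attractor landscape
#'
#' Draws `n_samples` initial states uniformly at random over the free nodes
#' (with replacement; duplicate draws re-count, which keeps the basin-ratio
#' estimate unbiased), evolves each to its attractor, and accumulates basin
#' counts. Trajectories are memoized (state -> attractor) so large sample
#' counts on mid-sized models stay cheap; memoization does not change
#' counts, since each sample contributes exactly one count.
#'
#' @inheritParams enumerate_landscape
#' @param n_samples number of sampled initial states (the reference protocol
#'   for a ~77-node disease model uses 1e6).
#' @param seed RNG seed; the run is bitwise reproducible for a fixed seed,
#'   and the seed is recorded in the returned landscape.
#' @return an `AttractorLandscape` with `method = "sampled"`.
#' @export
sample_landscape <- function(network, pins = NULL, n_samples = 1e6, seed = 1L) {
  stopifnot(n_samples >= 1)
  raw <- withr::with_seed(seed,
    cpp_sample(compile_network(network), pin_vector(network, pins),
               as.integer(n_samples)))
  new_landscape(network, pins, raw, "sampled", seed = as.integer(seed))
}

#' Basin-weighted node activities
#'
#' The activity of a node is its mean value over each attractor's cycle,
#' averaged over attractors with basin-ratio weights. It estimates the
#' long-run expression/activity level of the gene or protein; pinned nodes
#' have activity exactly equal to their pinned value.
#'
#' @param landscape an `AttractorLandscape`.
#' @return named numeric vector in `[0, 1]`, one entry per node.
#' @export
node_activity <- function(landscape) {
  if (length(landscape$attractors) == 0L) stop("empty landscape")
  w <- basin_ratio(landscape)
  acts <- activity_matrix(landscape)          # attractors x nodes
  stats::setNames(drop(w %*% acts), landscape$network$nodes)
}

# one row per attractor, one column per node
activity_matrix <- function(landscape) {
  nodes <- landscape$network$nodes
  m <- matrix(0, nrow = length(landscape$attractors), ncol = length(nodes),
              dimnames = list(NULL, nodes))
  for (i in seq_along(landscape$attractors))
    m[i, ] <- landscape$attractors[[i]]$mean_activity
  m
}

# normal-approximation binomial standard errors for sampled basin ratios
basin_se <- function(landscape) {
  p <- basin_ratio(landscape)
  sqrt(p * (1 - p) / landscape$total)
}

#' Export a landscape
#'
#' `write_landscape_tsv` writes one row per attractor (id, cycle length,
#' basin count/ratio, per-node mean activity). `write_landscape_json`
#' embeds the full cycles.
#'
#' @param landscape an `AttractorLandscape`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_landscape_tsv <- function(landscape, path) {
  utils::write.table(landscape_table(landscape), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

landscape_table <- function(landscape) {
  acts <- activity_matrix(landscape)
  data.frame(attractor_id = vapply(landscape$attractors, `[[`, "", "id"),
             cycle_length = vapply(landscape$attractors,
                                   function(a) nrow(a$cycle), 0L),
             basin_count = landscape$basin_count,
             basin_ratio = basin_ratio(landscape),
             acts,
             check.names = FALSE)
}

#' @rdname write_landscape_tsv
#' @export
write_landscape_json <- function(landscape, path) {
  doc <- list(
    method = landscape$method,
    total = landscape$total,
    seed = landscape$seed,
    pins = as.list(unclass(landscape$pins)),
    nodes = landscape$network$nodes,
    attractors = lapply(seq_along(landscape$attractors), function(i) {
      a <- landscape$attractors[[i]]
      list(id = a$id,
           cycle = unname(apply(a$cycle, 1L, paste, collapse = "")),
           basin_count = landscape$basin_count[i],
           basin_ratio = basin_ratio(landscape)[i],
           mean_activity = as.list(a$mean_activity))
    }))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
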