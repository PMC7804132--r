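# Mapping screen-ranked targets onto an approved-drug library, and the
# property-based exclusion filters (carcinogenicity, blood-brain-barrier
# penetrability) applied to candidate therapies.

DRUG_COLUMNS <- c("name", "target_node", "action", "bbb", "safety",
                  "bbb_waiver", "original_indication")

#' Read a drug-library TSV
#'
#' Columns: `name`, `target_node` (model node the drug acts on), `action`
#' (`inhibit` maps to pin 0, `activate` to pin 1), `bbb` (`permeable`,
#' `poor`, `unknown`), `safety` (`ok`, `possible_carcinogen`), `bbb_waiver`
#' (logical: include despite non-permeable BBB status, e.g. a drug thought
#' to support blood-brain-barrier integrity), `original_indication`. Extra
#' columns (e.g. `note`) are carried through.
#'
#' @param path TSV file; defaults to the packaged library transcribed from
#'   the published drug-selection flow-chart (targets printed only in the
#'   supplement are synthetic placeholders, flagged in `note`).
#' @return a `data.frame` of drug records.
#' @export
read_drug_library <- function(path = system.file("extdata",
                                                 "drug_library.tsv",
                                                 package = "attractorscreen")) {
  lib <- utils::read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(DRUG_COLUMNS, names(lib))
  if (length(miss)) stop("drug library is missing column '", miss[1L], "'")
  if (anyDuplicated(lib$name))
    stop("duplicate drug name: ", lib$name[duplicated(lib$name)][1L])
  if (!all(lib$action %in% c("inhibit", "activate")))
    stop("action must be inhibit/activate")
  if (!all(lib$bbb %in% c("permeable", "poor", "unknown")))
    stop("bbb must be permeable/poor/unknown")
  if (!all(lib$safety %in% c("ok", "possible_carcinogen")))
    stop("safety must be ok/possible_carcinogen")
  lib$bbb_waiver <- as.logical(lib$bbb_waiver)
  lib
}

#' Map ranked screen targets to drug therapies
#'
#' For each of the top-ranked screen entries whose every target node is
#' covered by at least one library drug with the matching action (the
#' screen's pin value: 0 needs an inhibitor, 1 an activator), one candidate
#' therapy is emitted per drug combination. Entries with a target no drug
#' covers are skipped and reported in the `skipped` attribute.
#'
#' @param screen a `ScreenResult`.
#' @param library a drug-library `data.frame` (see [read_drug_library()]).
#' @param top_n how many ranked entries to consider (default all).
#' @return a `data.frame` of candidate therapies (`drugs` is a `+`-joined
#'   combination, with `targets`, `condition`, `score`, `delta`, and
#'   `status`/`exclusion_reason` left for [filter_candidates()]), with a
#'   `skipped` character-vector attribute of uncovered entries.
#' @export
map_targets_to_drugs <- function(screen, library, top_n = Inf) {
  stopifnot(inherits(screen, "ScreenResult"), nrow(library) >= 1L)
  action_needed <- if (screen$pin_value == 0L) "inhibit" else "activate"
  entries <- utils::head(screen$entries, top_n)
  therapies <- list()
  skipped <- character(0)
  for (i in seq_len(nrow(entries))) {
    targets <- strsplit(entries$targets[i], "+", fixed = TRUE)[[1]]
    per_target <- lapply(targets, function(tg)
      library$name[library$target_node == tg & library$action == action_needed])
    if (any(vapply(per_target, length, 0L) == 0L)) {
      skipped <- c(skipped, entries$targets[i])
      next
    }
    combos <- expand.grid(per_target, stringsAsFactors = FALSE)
    for (j in seq_len(nrow(combos))) {
      therapies[[length(therapies) + 1L]] <-
        data.frame(drugs = paste(unlist(combos[j, ]), collapse = "+"),
                   targets = entries$targets[i],
                   condition = screen$condition,
                   score = entries$score[i],
                   delta = entries$delta[i],
                   status = NA_character_,
                   exclusion_reason = NA_character_)
    }
  }
  out <- if (length(therapies)) do.call(rbind, therapies) else
    data.frame(drugs = character(0), targets = character(0),
               condition = character(0), score = numeric(0),
               delta = numeric(0), status = character(0),
               exclusion_reason = character(0))
  attr(out, "skipped") <- skipped
  out
}

#' Build candidate therapies from an explicit therapy table
#'
#' Convenience for encoding a published candidate list (one row per
#' therapy, `drugs` as a `+`-joined combination) against a drug library,
#' ready for [filter_candidates()].
#'
#' @param therapies `data.frame` with columns `drugs` and optionally
#'   `condition`, or a path to such a TSV.
#' @param library a drug-library `data.frame`.
#' @return candidate-therapy `data.frame` as in [map_targets_to_drugs()].
#' @export
therapies_from_table <- function(therapies, library) {
  if (is.character(therapies)) therapies <- utils::read.delim(therapies)
  all_drugs <- unique(unlist(strsplit(therapies$drugs, "+", fixed = TRUE)))
  miss <- setdiff(all_drugs, library$name)
  if (length(miss)) stop("therapy drug not in library: ", miss[1L])
  data.frame(drugs = therapies$drugs,
             targets = vapply(strsplit(therapies$drugs, "+", fixed = TRUE),
                              function(ds) paste(
                                library$target_node[match(ds, library$name)],
                                collapse = "+"), ""),
             condition = if ("condition" %in% names(therapies))
               therapies$condition else NA_character_,
             score = NA_real_, delta = NA_real_,
             status = NA_character_, exclusion_reason = NA_character_)
}

#' Filter candidate therapies on drug properties
#'
#' A therapy is excluded when any member drug is a possible carcinogen, or
#' has poor or unknown blood-brain-barrier penetrability without a waiver.
#' Carcinogenicity takes precedence when several reasons apply. No record
#' is dropped: every input row is returned with `status`
#' (`selected`/`excluded`) and, for exclusions, `exclusion_reason`
#' (`possible_carcinogen`, `poor_bbb`, `unknown_bbb`).
#'
#' @param candidates candidate-therapy `data.frame`
#'   (from [map_targets_to_drugs()] or [therapies_from_table()]).
#' @param library the drug-library `data.frame` supplying the properties.
#' @return the same `data.frame` with `status` and `exclusion_reason` set.
#' @export
filter_candidates <- function(candidates, library) {
  if (nrow(candidates) == 0L) return(candidates)
  for (i in seq_len(nrow(candidates))) {
    ds <- strsplit(candidates$drugs[i], "+", fixed = TRUE)[[1]]
    idx <- match(ds, library$name)
    if (anyNA(idx)) stop("drug '", ds[is.na(idx)][1L], "' not in library")
    reason <- NA_character_
    if (any(library$safety[idx] == "possible_carcinogen")) {
      reason <- "possible_carcinogen"
    } else {
      bad_bbb <- library$bbb[idx] != "permeable" & !library$bbb_waiver[idx]
      if (any(bad_bbb))
        reason <- if (any(library$bbb[idx][bad_bbb] == "poor"))
          "poor_bbb" else "unknown_bbb"
    }
    candidates$status[i] <- if (is.na(reason)) "selected" else "excluded"
    candidates$exclusion_reason[i] <- reason
  }
  candidates
}

#' Write a candidate-therapy report
#' @param candidates a filtered candidate `data.frame`.
#' @param path output file; `.json` extension switches to JSON.
#' @return the path, invisibly.
#' @export
write_candidates <- function(candidates, path) {
  if (grepl("\\.json$", path))
    jsonlite::write_json(candidates, path, auto_unbox = TRUE, digits = NA)
  else
    utils::write.table(candidates, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(path)
}
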