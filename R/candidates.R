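# Candidate-structure ranking and the candidate-set genotoxicity statistics
# (overall and top-decile percent active) that decide final feature
# priority. Similarity between a feature's fingerprint and candidate
# structure fingerprints is Jaccard/Tanimoto over bits — a documented
# stand-in for proprietary spectral-ranking scores; the statistics layer is
# agnostic to the score's scale.

#' Rank candidate structures against a feature fingerprint
#'
#' Candidates are sorted by Jaccard (Tanimoto) similarity of their binary
#' fingerprints to the feature's fingerprint, descending, with ties broken
#' by `structure_id` lexicographically.
#'
#' @param feature_fp 0/1 fingerprint vector of the feature.
#' @param structures 0/1 matrix of candidate fingerprints, rownames =
#'   structure ids.
#' @param feature_id Optional feature label attached to the result.
#' @return A `candidate_set` tibble `structure_id, similarity`, best first.
#' @export
rank_candidates <- function(feature_fp, structures, feature_id = NULL) {
  if (is.null(dim(structures)) || nrow(structures) == 0) {
    stop("empty candidate structure list")
  }
  if (ncol(structures) != length(feature_fp)) {
    stop("fingerprint length mismatch: feature ", length(feature_fp),
         " vs candidates ", ncol(structures))
  }
  f <- as.numeric(feature_fp)
  inter <- as.numeric(structures %*% f)
  uni <- sum(f) + rowSums(structures) - inter
  sim <- ifelse(uni > 0, inter / uni, 0)
  ord <- order(-sim, rownames(structures))
  out <- tibble::tibble(structure_id = rownames(structures)[ord],
                        similarity = unname(sim[ord]))
  attr(out, "feature_id") <- feature_id
  class(out) <- c("candidate_set", class(out))
  out
}

#' Size of the top decile of a ranked candidate list
#'
#' `n_total / 10` rounded half-up, clamped to at least 1 (so every feature
#' has a non-empty top-decile subset): 1085 candidates yield a decile of
#' 109, 311 yield 31.
#'
#' @param n_total Number of ranked candidates (>= 1).
#' @return Integer decile size.
#' @export
top_decile_size <- function(n_total) {
  stopifnot(is.numeric(n_total), n_total >= 1)
  max(1L, as.integer(round_half_up(n_total / 10)))
}

#' Genotoxicity statistics of a ranked candidate set
#'
#' Counts and percentages of predicted-genotoxic structures over the full
#' ranked list and over its top decile (the [top_decile_size()] prefix).
#' Percentages are reported half-up to one decimal; raw ratios are kept for
#' machine use.
#'
#' @param cs A `candidate_set` from [rank_candidates()] (or any data frame
#'   with a `structure_id` column in rank order).
#' @param active Named logical vector of genotoxicity calls covering every
#'   candidate.
#' @return A `candidate_stats` list: `n_total`, `n_active`, `pct_active`,
#'   `top_n`, `top_active`, `top_pct`, plus unrounded `frac_active` and
#'   `top_frac`.
#' @export
candidate_stats <- function(cs, active) {
  ids <- cs$structure_id
  missing_call <- setdiff(ids, names(active))
  if (length(missing_call)) {
    stop("missing activity call for: ",
         paste(utils::head(missing_call, 5), collapse = ", "))
  }
  act <- as.logical(active[ids])
  n_total <- length(ids)
  n_active <- sum(act)
  top_n <- top_decile_size(n_total)
  top_active <- sum(act[seq_len(top_n)])
  structure(list(
    n_total = n_total,
    n_active = n_active,
    pct_active = round_half_up(100 * n_active / n_total, 1),
    top_n = top_n,
    top_active = top_active,
    top_pct = round_half_up(100 * top_active / top_n, 1),
    frac_active = n_active / n_total,
    top_frac = top_active / top_n
  ), class = "candidate_stats")
}

#' @export
print.candidate_stats <- function(x, ...) {
  cat("<candidate_stats> ", x$n_active, "/", x$n_total, " (", x$pct_active,
      "%) active; top decile ", x$top_active, "/", x$top_n, " (", x$top_pct,
      "%)\n", sep = "")
  invisible(x)
}

#' Final priority report over prioritized features
#'
#' Orders features by the evidence hierarchy used to pick the top feature
#' of a zone: MS2-level any-endpoint activity first, then the top-decile
#' percent of genotoxic candidate structures, then the overall percent,
#' then parent abundance; feature id breaks any remaining ties so the order
#' is total and deterministic. In-source group membership is annotated,
#' but features are ranked independently.
#'
#' @param features Tibble with `feature_id` and `parent_area`.
#' @param predictions Tibble with `feature_id` and logical `active_any`
#'   (e.g. from [classify_any_endpoint()] per feature), optionally an
#'   `endpoints` character column naming the active endpoint(s).
#' @param stats Named list of [candidate_stats()] keyed by feature id.
#' @param groups Optional `insource_groups` for annotation.
#' @return Tibble, one row per feature in priority order, with a `rank`
#'   column.
#' @export
feature_priority_report <- function(features, predictions, stats,
                                    groups = NULL) {
  ids <- features$feature_id
  if (length(setdiff(ids, predictions$feature_id))) {
    stop("predictions missing for some features")
  }
  if (length(setdiff(ids, names(stats)))) {
    stop("candidate stats missing for some features")
  }
  pr <- predictions[match(ids, predictions$feature_id), ]
  st <- stats[ids]
  d <- tibble::tibble(
    feature_id = ids,
    active_any = pr$active_any,
    endpoints = if ("endpoints" %in% names(pr)) pr$endpoints else NA_character_,
    n_candidates = vapply(st, `[[`, numeric(1), "n_total"),
    n_active = vapply(st, `[[`, numeric(1), "n_active"),
    pct_active = vapply(st, `[[`, numeric(1), "pct_active"),
    top_n = vapply(st, `[[`, numeric(1), "top_n"),
    top_active = vapply(st, `[[`, numeric(1), "top_active"),
    top_pct = vapply(st, `[[`, numeric(1), "top_pct"),
    parent_area = features$parent_area
  )
  if (!is.null(groups)) {
    gmap <- do.call(rbind, lapply(groups$groups, function(g) {
      data.frame(feature_id = g$members, group_id = g$group_id,
                 representative = g$representative,
                 stringsAsFactors = FALSE)
    }))
    d <- dplyr::left_join(d, tibble::as_tibble(gmap), by = "feature_id")
  } else {
    d$group_id <- NA_character_
    d$representative <- NA_character_
  }
  ord <- order(-d$active_any, -d$top_pct, -d$pct_active, -d$parent_area,
               d$feature_id)
  d <- d[ord, ]
  d$rank <- seq_len(nrow(d))
  dplyr::relocate(d, "rank")
}
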