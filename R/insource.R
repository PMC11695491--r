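# In-source fragment grouping: features that are ionization artifacts of the
# same chemical co-elute and either share MS2 fragment ions or appear as a
# fragment of the higher-mass feature's MS2. Linked features are collapsed
# into chemical groups (connected components); the highest-mass member is
# the plausible intact compound.

#' Match fragment peaks shared by two MS2 spectra
#'
#' Greedy one-to-one matching of the two fragment lists: candidate pairs
#' within `mz_tol` are taken closest-first, each fragment used at most once.
#'
#' @param a,b Spectra (lists with a `peaks` data frame as from [read_mgf()]).
#' @param mz_tol Fragment m/z tolerance in Da (default 0.005).
#' @return Numeric vector of matched fragment m/z (values from spectrum `a`).
#' @export
shared_fragments <- function(a, b, mz_tol = 0.005) {
  ma <- a$peaks$mz
  mb <- b$peaks$mz
  if (!length(ma) || !length(mb)) return(numeric(0))
  d <- abs(outer(ma, mb, "-"))
  cand <- which(d <= mz_tol, arr.ind = TRUE)
  if (!nrow(cand)) return(numeric(0))
  cand <- cand[order(d[cand]), , drop = FALSE]
  used_a <- logical(length(ma)); used_b <- logical(length(mb))
  out <- numeric(0)
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1]; j <- cand[k, 2]
    if (!used_a[i] && !used_b[j]) {
      used_a[i] <- TRUE; used_b[j] <- TRUE
      out <- c(out, ma[i])
    }
  }
  sort(out)
}

#' Does a feature's ion appear as a fragment in another feature's MS2?
#'
#' Evidence that `fragment_mz` (the intact ion m/z of a lower-mass feature)
#' is an in-source fragment of the compound behind `parent_ms2`.
#'
#' @param parent_ms2 List of MS2 spectra of the higher-mass candidate.
#' @param fragment_mz Ion m/z of the lower-mass candidate.
#' @param mz_tol Fragment m/z tolerance in Da.
#' @return Logical.
#' @export
precursor_in_fragments <- function(parent_ms2, fragment_mz, mz_tol = 0.005) {
  if (!length(parent_ms2)) return(FALSE)
  any(vapply(parent_ms2, function(spec) {
    nrow(spec$peaks) > 0 && any(abs(spec$peaks$mz - fragment_mz) <= mz_tol)
  }, logical(1)))
}

#' Group co-eluting features linked by in-source fragmentation evidence
#'
#' Two features are linked when they co-elute (|Δrt| <= `rt_tol`) and either
#' share at least `min_shared` MS2 fragment ions or one's intact ion m/z
#' appears among the other's MS2 fragments. Chemical groups are the
#' connected components of the link graph; each group's representative is
#' its highest-neutral-mass member. Features without MS2 or without links
#' form singleton groups.
#'
#' @param ft A `feature_table` whose `ms2` holds spectra for (some of) the
#'   features.
#' @param feature_ids Features to group (default: all in the table).
#' @param rt_tol Co-elution tolerance in minutes (default 0.05: in-source
#'   artifacts elute at the intact compound's retention time).
#' @param mz_tol Fragment m/z tolerance in Da (default 0.005).
#' @param min_shared Minimum number of shared fragment ions (default 2).
#' @return List of class `insource_groups` with `groups` (list of
#'   `group_id`, `members`, `representative`) and `links` (tibble of
#'   evidence edges).
#' @export
group_insource <- function(ft, feature_ids = ft$features$feature_id,
                           rt_tol = 0.05, mz_tol = 0.005, min_shared = 2) {
  stopifnot(rt_tol > 0, mz_tol > 0, min_shared >= 1)
  ids <- sort(unique(feature_ids))
  unknown <- setdiff(ids, ft$features$feature_id)
  if (length(unknown)) stop("unknown feature(s): ", paste(unknown, collapse = ", "))
  f <- ft$features[match(ids, ft$features$feature_id), ]
  n <- length(ids)
  links <- list()
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (abs(f$rt[i] - f$rt[j]) > rt_tol) next
        si <- ft$ms2[[ids[i]]]
        sj <- ft$ms2[[ids[j]]]
        # shared fragments: best match count over spectrum pairs
        nshared <- 0L
        matched <- numeric(0)
        for (a in si) for (b in sj) {
          m <- shared_fragments(a, b, mz_tol)
          if (length(m) > nshared) { nshared <- length(m); matched <- m }
        }
        if (nshared >= min_shared) {
          links[[length(links) + 1L]] <- tibble::tibble(
            feature_a = ids[i], feature_b = ids[j],
            evidence = "shared_fragments",
            detail = paste(sprintf("%.4f", matched), collapse = ";"))
          next
        }
        pif_ij <- precursor_in_fragments(si, f$mz[j], mz_tol)
        pif_ji <- precursor_in_fragments(sj, f$mz[i], mz_tol)
        if (pif_ij || pif_ji) {
          frag <- if (pif_ij) f$mz[j] else f$mz[i]
          links[[length(links) + 1L]] <- tibble::tibble(
            feature_a = ids[i], feature_b = ids[j],
            evidence = "precursor_in_fragments",
            detail = sprintf("%.4f", frag))
        }
      }
    }
  }
  links <- if (length(links)) do.call(rbind, links) else
    tibble::tibble(feature_a = character(0), feature_b = character(0),
                   evidence = character(0), detail = character(0))
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(links)) {
    g <- igraph::add_edges(g, rbind(match(links$feature_a, ids),
                                    match(links$feature_b, ids)))
  }
  comp <- igraph::components(g)$membership
  groups <- lapply(split(seq_len(n), comp), function(idx) {
    members <- ids[idx]
    masses <- f$neutral_mass[idx]
    rep_id <- members[order(-masses, members)][1]
    list(members = sort(members), representative = rep_id)
  })
  # deterministic group order and ids, by smallest member id
  ord <- order(vapply(groups, function(gr) gr$members[1], character(1)))
  groups <- groups[ord]
  for (k in seq_along(groups)) groups[[k]]$group_id <- sprintf("G%02d", k)
  groups <- lapply(groups, function(gr) gr[c("group_id", "members", "representative")])
  structure(list(groups = unname(groups), links = links),
            class = "insource_groups")
}

#' @export
print.insource_groups <- function(x, ...) {
  nmem <- sum(vapply(x$groups, function(g) length(g$members), integer(1)))
  cat("<insource_groups> ", nmem, " features in ", length(x$groups),
      " chemical groups (", nrow(x$links), " evidence links)\n", sep = "")
  invisible(x)
}

#' Write an in-source grouping report to JSON
#'
#' @param groups An `insource_groups` object.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_insource_report <- function(groups, path) {
  jsonlite::write_json(
    list(groups = lapply(groups$groups, function(g) {
      list(group_id = g$group_id, members = g$members,
           representative = g$representative)
    }),
    links = groups$links),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
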