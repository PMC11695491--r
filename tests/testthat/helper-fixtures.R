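# Shared fixture builders and independent oracles. Oracles are written as
# plain loops / recursion, independent of the package's implementation
# paths, so they can serve as brute-force references.

make_samples <- function(zones = c("A", "B"), methods = "manual_methanol") {
  s <- list(
    data.frame(sample_id = paste0("parent_r", 1:3), role = "parent",
               zone_id = NA_character_, method = NA_character_,
               replicate = 1:3, stringsAsFactors = FALSE),
    data.frame(sample_id = paste0("blank_r", 1:3), role = "blank_fraction",
               zone_id = NA_character_, method = NA_character_,
               replicate = 1:3, stringsAsFactors = FALSE))
  for (z in zones) for (m in methods) {
    s[[length(s) + 1]] <- data.frame(
      sample_id = paste0("zone", z, "_", m, "_r", 1:3),
      role = "zone_fraction", zone_id = z, method = m, replicate = 1:3,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, s)
}

# A feature table with hand-set areas; `areas` is a data frame
# feature_id, sample_id, replicate, area, gap_filled.
make_table <- function(areas, zones = c("A", "B"),
                       methods = "manual_methanol", ms2 = list()) {
  ids <- unique(areas$feature_id)
  n <- length(ids)
  features <- data.frame(
    feature_id = ids,
    neutral_mass = 100 + seq_len(n) * 10,
    mz = 100 + seq_len(n) * 10 + 1.007276,
    adduct = "[M+H]+",
    rt = seq_len(n),
    stringsAsFactors = FALSE)
  feature_table(features, areas, make_samples(zones, methods), ms2 = ms2)
}

area_row <- function(fid, sid, rep, area, gap = FALSE) {
  data.frame(feature_id = fid, sample_id = sid, replicate = rep,
             area = area, gap_filled = gap, stringsAsFactors = FALSE)
}

# Random study-like table for cascade oracle tests: two zones, one method.
random_table <- function(seed, n_features = 12) {
  set.seed(seed)
  samples <- make_samples()
  rows <- list()
  for (i in seq_len(n_features)) {
    fid <- sprintf("f%02d", i)
    for (sid in samples$sample_id) {
      if (stats::runif(1) < 0.65) {
        rows[[length(rows) + 1]] <- area_row(
          fid, sid, samples$replicate[samples$sample_id == sid],
          10^stats::runif(1, 5, 8), gap = stats::runif(1) < 0.3)
      }
    }
  }
  # guarantee every feature has at least one row
  present <- unique(do.call(rbind, rows)$feature_id)
  for (i in seq_len(n_features)) {
    fid <- sprintf("f%02d", i)
    if (!fid %in% present) {
      rows[[length(rows) + 1]] <- area_row(fid, "parent_r1", 1L, 1e7)
    }
  }
  make_table(do.call(rbind, rows))
}

# Brute-force cascade oracle: plain loops over features and rules.
oracle_prioritize <- function(ft, zone_id, cfg = prioritization_config()) {
  a <- as.data.frame(ft$areas)
  s <- as.data.frame(ft$samples)
  parent <- s$sample_id[s$role == "parent"]
  blanks <- s$sample_id[s$role == "blank_fraction"]
  frac <- s$sample_id[s$role == "zone_fraction" & !is.na(s$zone_id) &
                        s$zone_id == zone_id]
  off <- s$sample_id[s$role %in% c("zone_fraction", "off_zone_fraction") &
                       !is.na(s$zone_id) & s$zone_id != zone_id]
  mean_of <- function(fid, grp) {
    vals <- c()
    for (k in seq_len(nrow(a))) {
      if (a$feature_id[k] == fid && a$sample_id[k] %in% grp &&
          !a$gap_filled[k]) {
        vals <- c(vals, a$area[k])
      }
    }
    if (length(vals)) mean(vals) else 0
  }
  max_of <- function(fid, grp) {
    best <- 0
    for (k in seq_len(nrow(a))) {
      if (a$feature_id[k] == fid && a$sample_id[k] %in% grp &&
          !a$gap_filled[k] && a$area[k] > best) {
        best <- a$area[k]
      }
    }
    best
  }
  surviving <- character(0)
  for (fid in ft$features$feature_id) {
    pm <- mean_of(fid, parent)
    if (!(pm > cfg$abundance_threshold)) next
    ratio <- mean_of(fid, frac) / pm
    if (!(ratio >= cfg$ratio_low && ratio <= cfg$ratio_high)) next
    if (!(mean_of(fid, frac) > cfg$blank_factor * max_of(fid, blanks))) next
    lim <- if (cfg$off_zone_any_peak) 0 else cfg$abundance_threshold
    if (max_of(fid, off) > lim) next
    surviving <- c(surviving, fid)
  }
  sort(surviving)
}

# Brute-force connected components via breadth-first search over an edge
# list (pairs of node labels).
oracle_components <- function(nodes, edges) {
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  if (nrow(edges)) {
    for (k in seq_len(nrow(edges))) {
      a <- edges[k, 1]; b <- edges[k, 2]
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
  }
  seen <- stats::setNames(rep(FALSE, length(nodes)), nodes)
  comps <- list()
  for (v in nodes) {
    if (seen[v]) next
    queue <- v; members <- character(0)
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      if (seen[u]) next
      seen[u] <- TRUE
      members <- c(members, u)
      queue <- c(queue, adj[[u]])
    }
    comps[[length(comps) + 1]] <- sort(members)
  }
  comps[order(vapply(comps, `[`, character(1), 1))]
}

# Brute-force maximum one-to-one matching count between two peak lists
# under a tolerance (exhaustive recursion; fine for <= 10 peaks).
oracle_match_count <- function(ma, mb, tol) {
  rec <- function(i, used_b) {
    if (i > length(ma)) return(0L)
    best <- rec(i + 1L, used_b)
    for (j in seq_along(mb)) {
      if (!used_b[j] && abs(ma[i] - mb[j]) <= tol) {
        used_b2 <- used_b; used_b2[j] <- TRUE
        best <- max(best, 1L + rec(i + 1L, used_b2))
      }
    }
    best
  }
  rec(1L, rep(FALSE, length(mb)))
}

spectrum <- function(mz, precursor = max(mz) + 1) {
  list(precursor_mz = precursor, rt = NA_real_,
       peaks = data.frame(mz = sort(mz),
                          intensity = rep(1e4, length(mz))))
}

# Ranked candidate set with planted counts: n_active actives of which
# top_active sit inside the top decile.
stats_from_counts <- function(n_total, n_active, top_active) {
  ids <- sprintf("s%05d", seq_len(n_total))
  cs <- tibble::tibble(structure_id = ids, similarity = seq(1, 0, length.out = n_total))
  top_n <- top_decile_size(n_total)
  active <- stats::setNames(rep(FALSE, n_total), ids)
  if (top_active > 0) active[seq_len(top_active)] <- TRUE
  rest <- n_active - top_active
  if (rest > 0) active[top_n + seq_len(rest)] <- TRUE
  candidate_stats(cs, active)
}

# Small study configuration reused by end-to-end tests.
small_study_config <- function(seed, spikes = list(), ...) {
  study_config(
    n_matrix_features = 60, n_blank_features = 8, spikes = spikes,
    insource_clusters = list(),
    n_structures = 25, n_decoy_suspects = 10,
    endpoints = list(ep1 = list(n = 200, active_fraction = 0.2)),
    fingerprint_length = 64, planted_rule = c(3, 30, 55),
    seed = seed, ...)
}
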