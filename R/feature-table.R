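# Data model and I/O for aligned non-target feature tables.
#
# A feature_table holds three tibbles plus optional MS2 spectra:
#   features: feature_id, neutral_mass, mz, adduct, rt   (rt in minutes)
#   areas:    feature_id, sample_id, replicate, area, gap_filled  (long)
#   samples:  sample_id, role, zone_id, method, replicate
# Areas are stored per injection replicate, never pre-averaged: the filter
# layer decides how to aggregate and whether gap-filled (imputed) values
# count as detections.

SAMPLE_ROLES <- c("parent", "zone_fraction", "blank_fraction", "off_zone_fraction")

#' Construct an aligned feature table
#'
#' @param features Data frame with columns `feature_id`, `neutral_mass`,
#'   `mz`, `adduct`, `rt` (minutes).
#' @param areas Long data frame `feature_id, sample_id, replicate, area,
#'   gap_filled`; one row per (feature, sample, injection replicate).
#'   `gap_filled = TRUE` marks values imputed below the picking threshold —
#'   not genuine detections.
#' @param samples Sample manifest `sample_id, role, zone_id, method,
#'   replicate`. `zone_id` is required exactly for fraction roles.
#' @param ms2 Named list (by feature_id) of lists of MS2 spectra as returned
#'   by [read_mgf()].
#' @param validate Check invariants (unique ids, resolvable samples, m/z
#'   consistency) on construction.
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(features, areas, samples, ms2 = list(), validate = TRUE) {
  features <- tibble::as_tibble(features)
  areas <- tibble::as_tibble(areas)
  samples <- tibble::as_tibble(samples)
  ft <- structure(
    list(features = features, areas = areas, samples = samples, ms2 = ms2),
    class = "feature_table"
  )
  if (validate) validate_feature_table(ft)
  ft
}

#' @export
print.feature_table <- function(x, ...) {
  cat("<feature_table> ", nrow(x$features), " features, ",
      nrow(x$samples), " samples, ", nrow(x$areas), " area measurements, ",
      length(x$ms2), " features with MS2\n", sep = "")
  invisible(x)
}

#' Validate feature-table invariants
#'
#' Errors on duplicate feature ids, area rows referencing unknown samples,
#' fraction samples without a zone label, and ion m/z inconsistent with the
#' neutral mass plus adduct offset beyond 2 ppm.
#'
#' @param ft A `feature_table`.
#' @return `ft`, invisibly.
#' @export
validate_feature_table <- function(ft) {
  f <- ft$features
  need <- c("feature_id", "neutral_mass", "mz", "adduct", "rt")
  missing_cols <- setdiff(need, names(f))
  if (length(missing_cols)) {
    stop("features table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  dup <- f$feature_id[duplicated(f$feature_id)]
  if (length(dup)) stop("duplicate feature_id: ", paste(unique(dup), collapse = ", "))
  if (any(f$rt < 0)) stop("negative retention time")
  if (any(f$mz <= 0)) stop("non-positive m/z")
  bad_sample <- setdiff(ft$areas$sample_id, ft$samples$sample_id)
  if (length(bad_sample)) {
    stop("area rows reference unknown sample(s): ", paste(bad_sample, collapse = ", "))
  }
  bad_role <- setdiff(ft$samples$role, SAMPLE_ROLES)
  if (length(bad_role)) stop("unknown sample role(s): ", paste(bad_role, collapse = ", "))
  frac <- ft$samples$role %in% c("zone_fraction", "off_zone_fraction")
  zone_missing <- frac & (is.na(ft$samples$zone_id) | ft$samples$zone_id == "")
  if (any(zone_missing)) {
    stop("fraction sample(s) without zone_id: ",
         paste(ft$samples$sample_id[zone_missing], collapse = ", "))
  }
  ish <- f$adduct == "[M+H]+"
  if (any(ish)) {
    dev <- abs(ppm_error(f$mz[ish], adduct_mz(f$neutral_mass[ish])))
    if (any(dev > 2 + 1e-9)) {
      stop("m/z inconsistent with neutral mass + adduct offset (> 2 ppm) for: ",
           paste(f$feature_id[ish][dev > 2 + 1e-9], collapse = ", "))
    }
  }
  invisible(ft)
}

# numeric formatting that survives a write/read round trip bit-exactly
.fmt_num <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.17g", x))
}

#' Write a feature table to delimited text
#'
#' Writes the long-format feature/area file (columns `feature_id,
#' neutral_mass, mz, adduct, rt_min, sample_id, replicate, area, gap_filled`)
#' and the sample manifest alongside it. Numbers are written with full
#' precision so that [read_feature_table()] reproduces the table bit-exactly.
#'
#' @param ft A `feature_table`.
#' @param path Output path for the feature file (CSV).
#' @param manifest_path Output path for the sample manifest; defaults to
#'   `<path minus extension>_samples.csv`.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(ft, path,
                                manifest_path = default_manifest_path(path)) {
  validate_feature_table(ft)
  long <- merge(as.data.frame(ft$areas), as.data.frame(ft$features),
                by = "feature_id", all.x = TRUE, sort = FALSE)
  long <- long[order(long$feature_id, long$sample_id, long$replicate), , drop = FALSE]
  header <- "feature_id,neutral_mass,mz,adduct,rt_min,sample_id,replicate,area,gap_filled"
  lines <- header
  if (nrow(long)) {
    lines <- c(header, paste(
      long$feature_id, .fmt_num(long$neutral_mass), .fmt_num(long$mz),
      long$adduct, .fmt_num(long$rt), long$sample_id, long$replicate,
      .fmt_num(long$area), tolower(long$gap_filled), sep = ","))
  }
  # features never measured in any sample still need a carrier row
  orphan <- setdiff(ft$features$feature_id, ft$areas$feature_id)
  if (length(orphan)) {
    fo <- ft$features[match(orphan, ft$features$feature_id), ]
    lines <- c(lines, paste(
      fo$feature_id, .fmt_num(fo$neutral_mass), .fmt_num(fo$mz), fo$adduct,
      .fmt_num(fo$rt), "", "", "", "", sep = ","))
  }
  writeLines(lines, path)
  s <- ft$samples
  mlines <- "sample_id,role,zone_id,method,replicate"
  if (nrow(s)) {
    mlines <- c(mlines, paste(
      s$sample_id, s$role,
      ifelse(is.na(s$zone_id), "", s$zone_id),
      ifelse(is.na(s$method), "", s$method),
      s$replicate, sep = ","))
  }
  writeLines(mlines, manifest_path)
  invisible(path)
}

default_manifest_path <- function(path) {
  ext <- tools::file_ext(path)
  base <- tools::file_path_sans_ext(path)
  paste0(base, "_samples", if (nzchar(ext)) paste0(".", ext) else ".csv")
}

#' Read a feature table from delimited text
#'
#' Inverse of [write_feature_table()]. Parse failures are reported with the
#' offending row numbers; duplicate ids and unresolvable sample references
#' are errors.
#'
#' @param path Feature file (CSV) written by [write_feature_table()] or
#'   following its column dialect.
#' @param manifest_path Sample manifest path.
#' @param mgf_path Optional MGF file of MS2 spectra (TITLE = feature_id).
#' @return A `feature_table`.
#' @export
read_feature_table <- function(path,
                               manifest_path = default_manifest_path(path),
                               mgf_path = NULL) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(feature_id = "character",
                                        sample_id = "character"))
  need <- c("feature_id", "neutral_mass", "mz", "adduct", "rt_min",
            "sample_id", "replicate", "area", "gap_filled")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    stop("feature file lacks mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  bad <- which(is.na(raw$neutral_mass) | is.na(raw$mz) | is.na(raw$rt_min))
  if (length(bad)) {
    stop("unparseable numeric field(s) at data row(s): ",
         paste(bad, collapse = ", "))
  }
  feats <- raw[!duplicated(raw$feature_id),
               c("feature_id", "neutral_mass", "mz", "adduct", "rt_min")]
  names(feats)[names(feats) == "rt_min"] <- "rt"
  # a feature must carry one consistent mass/rt across its rows
  chk <- tapply(raw$neutral_mass, raw$feature_id,
                function(v) max(v) - min(v))
  if (any(chk > 0)) {
    stop("feature_id rows disagree on neutral_mass: ",
         paste(names(chk)[chk > 0], collapse = ", "))
  }
  meas <- raw[!(is.na(raw$sample_id) | raw$sample_id == ""), , drop = FALSE]
  areas <- tibble::tibble(
    feature_id = meas$feature_id,
    sample_id = meas$sample_id,
    replicate = as.integer(meas$replicate),
    area = as.numeric(meas$area),
    gap_filled = as.logical(meas$gap_filled)
  )
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE,
                         colClasses = c(sample_id = "character"))
  samples <- tibble::tibble(
    sample_id = man$sample_id,
    role = man$role,
    zone_id = ifelse(is.na(man$zone_id) | man$zone_id == "", NA_character_,
                     as.character(man$zone_id)),
    method = ifelse(is.na(man$method) | man$method == "", NA_character_,
                    as.character(man$method)),
    replicate = as.integer(man$replicate)
  )
  ms2 <- if (!is.null(mgf_path)) read_mgf(mgf_path) else list()
  feature_table(tibble::as_tibble(feats), areas, samples, ms2 = ms2)
}

#' Merge aligned feature tables across runs
#'
#' Features from all tables are clustered by connected components under
#' the joint tolerance (|Δmass| <= `ppm_tol` of the larger mass AND
#' |Δrt| <= `rt_tol`); each cluster becomes one feature whose mass and
#' retention time are the area-weighted means of its members, and whose
#' per-sample areas are the concatenation of member areas. The merge is
#' order-invariant and idempotent on the feature set.
#'
#' @param tables List of `feature_table` objects with disjoint sample ids.
#' @param ppm_tol Mass tolerance in ppm (default 2, the usual alignment
#'   tolerance for Orbitrap non-target data).
#' @param rt_tol Retention-time tolerance in minutes (default 0.2; narrow
#'   relative to a ~27-min gradient).
#' @return A merged `feature_table`.
#' @export
merge_feature_tables <- function(tables, ppm_tol = 2, rt_tol = 0.2) {
  if (inherits(tables, "feature_table")) tables <- list(tables)
  stopifnot(length(tables) >= 1)
  feats <- do.call(rbind, lapply(tables, function(t) as.data.frame(t$features)))
  areas <- do.call(rbind, lapply(tables, function(t) as.data.frame(t$areas)))
  samples <- do.call(rbind, lapply(tables, function(t) as.data.frame(t$samples)))
  ms2 <- do.call(c, lapply(tables, function(t) t$ms2))
  if (anyDuplicated(samples$sample_id)) {
    stop("input tables share sample ids; merge requires disjoint sample namespaces")
  }
  # canonical order first so that clustering is independent of input order
  ord <- order(feats$feature_id)
  feats <- feats[ord, , drop = FALSE]
  n <- nrow(feats)
  comp <- merge_components(feats$neutral_mass, feats$rt, ppm_tol, rt_tol)
  tot_area <- tapply(areas$area, areas$feature_id, sum)
  w <- as.numeric(tot_area[feats$feature_id])
  w[is.na(w) | w <= 0] <- 0
  out_feats <- lapply(split(seq_len(n), comp), function(idx) {
    wi <- w[idx]
    if (sum(wi) <= 0) wi <- rep(1, length(idx))
    rep_id <- sort(feats$feature_id[idx])[1]
    data.frame(
      feature_id = rep_id,
      neutral_mass = sum(feats$neutral_mass[idx] * wi) / sum(wi),
      mz = sum(feats$mz[idx] * wi) / sum(wi),
      adduct = feats$adduct[idx][1],
      rt = sum(feats$rt[idx] * wi) / sum(wi),
      stringsAsFactors = FALSE
    )
  })
  out_feats <- do.call(rbind, out_feats)
  out_feats <- out_feats[order(out_feats$feature_id), , drop = FALSE]
  cluster_id <- vapply(split(feats$feature_id, comp),
                       function(ids) sort(ids)[1], character(1))
  member_map <- stats::setNames(cluster_id[as.character(comp)], feats$feature_id)
  areas$feature_id <- unname(member_map[areas$feature_id])
  ms2_merged <- list()
  for (fid in names(ms2)) {
    tgt <- if (fid %in% names(member_map)) unname(member_map[fid]) else fid
    ms2_merged[[tgt]] <- c(ms2_merged[[tgt]], ms2[[fid]])
  }
  feature_table(tibble::as_tibble(out_feats), tibble::as_tibble(areas),
                tibble::as_tibble(samples), ms2 = ms2_merged)
}

# connected components under |dmass| <= ppm_tol of max(mass) and |drt| <= rt_tol
merge_components <- function(mass, rt, ppm_tol, rt_tol) {
  n <- length(mass)
  if (n == 1) return(1L)
  pairs <- which(outer(seq_len(n), seq_len(n), "<"), arr.ind = TRUE)
  i <- pairs[, 1]; j <- pairs[, 2]
  dm <- abs(mass[i] - mass[j])
  tol <- ppm_tol * 1e-6 * pmax(mass[i], mass[j])
  ok <- dm <= tol & abs(rt[i] - rt[j]) <= rt_tol
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (any(ok)) {
    g <- igraph::add_edges(g, rbind(i[ok], j[ok]))
  }
  igraph::components(g)$membership
}

#' Mean area of a feature over a replicate group
#'
#' Arithmetic mean over the qualifying replicates that are present in the
#' table: with `exclude_gap_filled = TRUE` (the default), gap-filled values
#' are not genuine detections and are dropped from both numerator and
#' denominator. A group with no qualifying replicates yields 0.
#'
#' @param ft A `feature_table`.
#' @param feature_id Feature to aggregate.
#' @param sample_ids The replicate group (e.g. injection triplicates of one
#'   fraction).
#' @param exclude_gap_filled Drop gap-filled (imputed) replicates.
#' @return Mean abundance (same arbitrary units as the input areas).
#' @export
replicate_mean_area <- function(ft, feature_id, sample_ids,
                                exclude_gap_filled = TRUE) {
  if (!length(sample_ids)) stop("replicate group is empty")
  unknown <- setdiff(sample_ids, ft$samples$sample_id)
  if (length(unknown)) {
    stop("unknown sample(s) in replicate group: ", paste(unknown, collapse = ", "))
  }
  a <- ft$areas
  sel <- a$feature_id == feature_id & a$sample_id %in% sample_ids
  if (exclude_gap_filled) sel <- sel & !a$gap_filled
  v <- a$area[sel]
  if (!length(v)) return(0)
  mean(v)
}
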