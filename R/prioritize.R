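# Four-rule filter cascade selecting, per bioactive HPTLC zone, the LC-HRMS
# features plausibly responsible for the observed genotoxicity:
#   1. parent abundance  — genuinely detected in the unfractionated extract
#                          above the picking threshold (no filled gaps);
#   2. fraction/parent ratio — zone-fraction abundance a plausible recovery
#                          of the parent abundance (default 10-75%);
#   3. blank exclusion   — well above anything in blank-plate fractions;
#   4. zone exclusivity  — not detected in fractions of any other zone.
# The cascade is a pure conjunction: rule order never changes the result.

#' Prioritization filter configuration
#'
#' @param abundance_threshold Peak-picking abundance threshold (area units);
#'   parent detections at or below it do not count. Default `1e6`.
#' @param ratio_low,ratio_high Inclusive bounds on the fraction/parent mean
#'   area ratio. Defaults 0.10 and 0.75: fractionation recovers only part of
#'   a compound, so a ratio near 1 indicates background and a very low ratio
#'   indicates carry-over or noise. Relax `ratio_low` (e.g. to 0.05) for
#'   low-recovery elution methods.
#' @param blank_factor Fraction mean must exceed `blank_factor` times the
#'   largest blank-fraction peak of the feature. Default 10.
#' @param suspect_ppm_tol Exact-mass tolerance (ppm) for suspect matching.
#' @param off_zone_any_peak If `TRUE`, any genuine off-zone peak (no
#'   abundance threshold) disqualifies a feature; by default only off-zone
#'   peaks above `abundance_threshold` count as detections, since
#'   threshold-free exclusion is dominated by gap-filling noise.
#' @return A `prioritization_config` list.
#' @export
prioritization_config <- function(abundance_threshold = 1e6,
                                  ratio_low = 0.10,
                                  ratio_high = 0.75,
                                  blank_factor = 10,
                                  suspect_ppm_tol = 2,
                                  off_zone_any_peak = FALSE) {
  stopifnot(abundance_threshold > 0, blank_factor > 0,
            ratio_low > 0, ratio_low < ratio_high, ratio_high <= 1)
  structure(list(abundance_threshold = abundance_threshold,
                 ratio_low = ratio_low, ratio_high = ratio_high,
                 blank_factor = blank_factor,
                 suspect_ppm_tol = suspect_ppm_tol,
                 off_zone_any_peak = off_zone_any_peak),
            class = "prioritization_config")
}

# ---- sample-group helpers ---------------------------------------------------

parent_sample_ids <- function(ft) {
  ft$samples$sample_id[ft$samples$role == "parent"]
}

zone_sample_ids <- function(ft, zone_id, method = NULL) {
  s <- ft$samples
  sel <- s$role == "zone_fraction" & !is.na(s$zone_id) & s$zone_id == zone_id
  if (!is.null(method)) sel <- sel & !is.na(s$method) & s$method == method
  s$sample_id[sel]
}

blank_sample_ids <- function(ft) {
  ft$samples$sample_id[ft$samples$role == "blank_fraction"]
}

off_zone_sample_ids <- function(ft, zone_id) {
  s <- ft$samples
  sel <- s$role %in% c("zone_fraction", "off_zone_fraction") &
    !is.na(s$zone_id) & s$zone_id != zone_id
  s$sample_id[sel]
}

# ---- per-feature rules ------------------------------------------------------

#' Rule 1: genuine parent abundance
#'
#' Passes when the mean of the non-gap-filled parent replicate areas exceeds
#' the abundance threshold (strictly) and at least one parent replicate is a
#' genuine (non-imputed) detection.
#'
#' @param ft A `feature_table`.
#' @param feature_id Feature to test.
#' @param cfg A [prioritization_config()].
#' @return Logical.
#' @export
rule_parent_abundance <- function(ft, feature_id, cfg = prioritization_config()) {
  ps <- parent_sample_ids(ft)
  if (!length(ps)) stop("study has no parent samples")
  m <- replicate_mean_area(ft, feature_id, ps, exclude_gap_filled = TRUE)
  m > cfg$abundance_threshold
}

#' Rule 2: fraction/parent abundance ratio
#'
#' The ratio of the zone-fraction mean area to the parent mean area must lie
#' inside `[ratio_low, ratio_high]` (inclusive).
#'
#' @inheritParams rule_parent_abundance
#' @param zone_id Zone label of the fraction of interest.
#' @param method Optional elution method restricting the fraction samples.
#' @return List with `pass` (logical) and `ratio` (numeric).
#' @export
rule_fraction_ratio <- function(ft, feature_id, zone_id, method = NULL,
                                cfg = prioritization_config()) {
  ps <- parent_sample_ids(ft)
  fs <- zone_sample_ids(ft, zone_id, method)
  pm <- replicate_mean_area(ft, feature_id, ps, exclude_gap_filled = TRUE)
  if (pm <= 0) stop("zero parent mean area; apply rule_parent_abundance first")
  fm <- replicate_mean_area(ft, feature_id, fs, exclude_gap_filled = TRUE)
  ratio <- fm / pm
  list(pass = ratio >= cfg$ratio_low & ratio <= cfg$ratio_high, ratio = ratio)
}

#' Rule 3: blank-plate exclusion
#'
#' The fraction mean must be strictly greater than `blank_factor` times the
#' largest genuine peak of the feature in any blank HPTLC-plate fraction.
#' A feature absent from all blanks has blank maximum 0 and passes whenever
#' its fraction mean is positive.
#'
#' @inheritParams rule_fraction_ratio
#' @return Logical.
#' @export
rule_blank <- function(ft, feature_id, zone_id, method = NULL,
                       cfg = prioritization_config()) {
  fs <- zone_sample_ids(ft, zone_id, method)
  bs <- blank_sample_ids(ft)
  fm <- replicate_mean_area(ft, feature_id, fs, exclude_gap_filled = TRUE)
  a <- ft$areas
  sel <- a$feature_id == feature_id & a$sample_id %in% bs & !a$gap_filled
  bmax <- if (any(sel)) max(a$area[sel]) else 0
  fm > cfg$blank_factor * bmax
}

#' Rule 4: zone exclusivity
#'
#' The feature must not be detected in any fraction belonging to a different
#' zone. "Detected" means a genuine (non-gap-filled) replicate peak, by
#' default above the abundance threshold (see
#' [prioritization_config()]`$off_zone_any_peak`).
#'
#' @inheritParams rule_fraction_ratio
#' @return Logical.
#' @export
rule_zone_exclusivity <- function(ft, feature_id, zone_id,
                                  cfg = prioritization_config()) {
  os <- off_zone_sample_ids(ft, zone_id)
  a <- ft$areas
  sel <- a$feature_id == feature_id & a$sample_id %in% os & !a$gap_filled
  lim <- if (cfg$off_zone_any_peak) 0 else cfg$abundance_threshold
  !any(a$area[sel] > lim)
}

# ---- cascade ----------------------------------------------------------------

#' Prioritize features for one bioactive zone
#'
#' Applies the four-rule conjunction to every feature of the table and
#' returns the surviving set together with a complete per-feature audit of
#' each rule's outcome and the computed ratio values.
#'
#' @param ft A `feature_table` with at least one parent sample and one
#'   fraction for `zone_id`.
#' @param zone_id Zone of interest (e.g. `"C"`).
#' @param method Optional elution method (`"interface"`,
#'   `"manual_methanol"`, `"manual_ethylacetate"`) restricting which
#'   fractions represent the zone.
#' @param cfg A [prioritization_config()].
#' @return A `zone_prioritization`: list with `zone_id`, `method`,
#'   `surviving` (sorted character vector of feature ids) and `audit`
#'   (tibble, one row per feature).
#' @export
prioritize_zone <- function(ft, zone_id, method = NULL,
                            cfg = prioritization_config()) {
  ps <- parent_sample_ids(ft)
  fs <- zone_sample_ids(ft, zone_id, method)
  if (!length(ps)) stop("study has no parent samples")
  if (!length(fs)) stop("no fraction samples for zone ", zone_id,
                        if (!is.null(method)) paste0(" with method ", method))
  bs <- blank_sample_ids(ft)
  os <- off_zone_sample_ids(ft, zone_id)
  ids <- ft$features$feature_id
  a <- as.data.frame(ft$areas)

  grp_mean <- function(sample_ids) {
    rows <- a[a$sample_id %in% sample_ids & !a$gap_filled, , drop = FALSE]
    if (!nrow(rows)) return(stats::setNames(numeric(length(ids)), ids))
    sums <- rowsum(rows$area, rows$feature_id)
    cnts <- table(rows$feature_id)
    m <- stats::setNames(numeric(length(ids)), ids)
    m[rownames(sums)] <- sums[, 1] / as.numeric(cnts[rownames(sums)])
    m
  }
  grp_max <- function(sample_ids) {
    rows <- a[a$sample_id %in% sample_ids & !a$gap_filled, , drop = FALSE]
    m <- stats::setNames(numeric(length(ids)), ids)
    if (nrow(rows)) {
      mx <- tapply(rows$area, rows$feature_id, max)
      m[names(mx)] <- as.numeric(mx)
    }
    m
  }

  parent_mean <- grp_mean(ps)
  frac_mean <- grp_mean(fs)
  blank_max <- grp_max(bs)
  off_max <- grp_max(os)

  parent_pass <- parent_mean > cfg$abundance_threshold
  ratio <- ifelse(parent_mean > 0, frac_mean / parent_mean, NA_real_)
  ratio_pass <- !is.na(ratio) & ratio >= cfg$ratio_low & ratio <= cfg$ratio_high
  blank_pass <- frac_mean > cfg$blank_factor * blank_max
  lim <- if (cfg$off_zone_any_peak) 0 else cfg$abundance_threshold
  excl_pass <- off_max <= lim
  pass <- parent_pass & ratio_pass & blank_pass & excl_pass

  audit <- tibble::tibble(
    feature_id = ids,
    parent_mean = unname(parent_mean[ids]),
    parent_pass = unname(parent_pass[ids]),
    fraction_mean = unname(frac_mean[ids]),
    ratio = unname(ratio[ids]),
    ratio_pass = unname(ratio_pass[ids]),
    blank_max = unname(blank_max[ids]),
    blank_pass = unname(blank_pass[ids]),
    off_zone_max = unname(off_max[ids]),
    exclusivity_pass = unname(excl_pass[ids]),
    pass = unname(pass[ids])
  )
  structure(list(zone_id = zone_id, method = method,
                 surviving = sort(ids[pass[ids]]), audit = audit),
            class = "zone_prioritization")
}

#' @export
print.zone_prioritization <- function(x, ...) {
  cat("<zone_prioritization> zone ", x$zone_id,
      if (!is.null(x$method)) paste0(" (", x$method, ")"), ": ",
      length(x$surviving), "/", nrow(x$audit), " features survive\n", sep = "")
  invisible(x)
}

#' Features prioritized by two elution methods of the same zone
#'
#' A feature consistently recovered by two independent extraction methods of
#' the same zone (e.g. manual methanol and manual ethyl acetate) is stronger
#' evidence than either method alone; this returns the intersection of the
#' surviving sets.
#'
#' @param a,b `zone_prioritization` objects for the same zone.
#' @return Sorted character vector of common feature ids.
#' @export
intersect_methods <- function(a, b) {
  stopifnot(inherits(a, "zone_prioritization"), inherits(b, "zone_prioritization"))
  if (!identical(a$zone_id, b$zone_id)) {
    stop("zone mismatch: ", a$zone_id, " vs ", b$zone_id)
  }
  sort(intersect(a$surviving, b$surviving))
}

# ---- suspect screening ------------------------------------------------------

#' Read a suspect list
#'
#' Delimited text with columns `name, formula, neutral_mass`; the mass may be
#' omitted when a formula is given (it is then computed), and when both are
#' present they must agree within 2 ppm.
#'
#' @param path CSV file.
#' @return Tibble `name, formula, neutral_mass`.
#' @export
read_suspect_list <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "formula")
  if (length(setdiff(need, names(d)))) {
    stop("suspect list needs columns name, formula[, neutral_mass]")
  }
  if (is.null(d$neutral_mass)) d$neutral_mass <- NA_real_
  calc <- vapply(d$formula, function(f) {
    if (is.na(f) || !nzchar(f)) NA_real_ else monoisotopic_mass(f)
  }, numeric(1))
  have_both <- !is.na(d$neutral_mass) & !is.na(calc)
  if (any(have_both)) {
    dev <- abs(ppm_error(d$neutral_mass[have_both], calc[have_both]))
    if (any(dev > 2)) {
      stop("suspect mass disagrees with formula by > 2 ppm: ",
           paste(d$name[have_both][dev > 2], collapse = ", "))
    }
  }
  d$neutral_mass <- ifelse(is.na(d$neutral_mass), calc, d$neutral_mass)
  if (any(is.na(d$neutral_mass))) {
    stop("suspect entries with neither mass nor formula: ",
         paste(d$name[is.na(d$neutral_mass)], collapse = ", "))
  }
  tibble::as_tibble(d[, c("name", "formula", "neutral_mass")])
}

#' Match features against a suspect list by exact neutral mass
#'
#' A feature is annotated with a suspect when their neutral monoisotopic
#' masses agree within `ppm_tol` of the suspect mass. All hits are returned,
#' ordered within each feature by absolute mass error.
#'
#' @param ft A `feature_table`.
#' @param suspects Tibble from [read_suspect_list()] (columns `name`,
#'   `neutral_mass`, optionally `formula`).
#' @param ppm_tol Mass tolerance in ppm (default taken from
#'   [prioritization_config()]).
#' @return Tibble `feature_id, name, suspect_mass, delta_ppm`.
#' @export
suspect_match <- function(ft, suspects,
                          ppm_tol = prioritization_config()$suspect_ppm_tol) {
  if (!nrow(suspects)) {
    return(tibble::tibble(feature_id = character(0), name = character(0),
                          suspect_mass = numeric(0), delta_ppm = numeric(0)))
  }
  f <- ft$features
  hits <- lapply(seq_len(nrow(f)), function(i) {
    dppm <- (f$neutral_mass[i] - suspects$neutral_mass) /
      suspects$neutral_mass * 1e6
    j <- which(abs(dppm) <= ppm_tol)
    if (!length(j)) return(NULL)
    j <- j[order(abs(dppm[j]), suspects$name[j])]
    tibble::tibble(feature_id = f$feature_id[i], name = suspects$name[j],
                   suspect_mass = suspects$neutral_mass[j],
                   delta_ppm = dppm[j])
  })
  out <- do.call(rbind, hits)
  if (is.null(out)) {
    return(tibble::tibble(feature_id = character(0), name = character(0),
                          suspect_mass = numeric(0), delta_ppm = numeric(0)))
  }
  out
}

#' Percent reduction in feature counts along a workflow
#'
#' Workflow accounting for fractionation: `100 * (1 - n_after / n_before)`,
#' reported half-up to one decimal (e.g. 2693 parent features reduced to 50
#' prioritized features is a 98.1% reduction).
#'
#' @param n_before,n_after Feature counts before and after a workflow stage.
#' @return Percentage reduction, one decimal.
#' @export
percent_reduction <- function(n_before, n_after) {
  stopifnot(n_before > 0, n_after >= 0, n_after <= n_before)
  round_half_up(100 * (1 - n_after / n_before), 1)
}
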