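# Packaged worked example: the 13 prioritized features of a bioactive
# printed-paperboard zone ("zone D"), with their masses, retention times,
# parent areas, formula assignments, per-assay activity calls, and
# candidate-structure counts. The accompanying MS2 spectra are synthetic:
# peak lists constructed to carry the reported in-source evidence (a
# five-feature co-elution cluster sharing fragments 85.0283 / 99.0440 /
# 127.0389, and a pair linked by the lower feature's ion appearing as a
# fragment of the higher one).

#' Load the zone-D worked example
#'
#' @return A list:
#'   \describe{
#'     \item{feature_table}{`feature_table` of the 13 features with one
#'       parent sample carrying their parent-extract areas and the
#'       synthetic MS2 spectra attached.}
#'     \item{info}{Tibble with the source columns: `formula`,
#'       `mass_error_ppm`, `active_assay` (empty when no endpoint call),
#'       `n_candidates`, `n_active_total`, `n_active_top`.}
#'   }
#' @examples
#' zd <- zone_d_example()
#' groups <- group_insource(zd$feature_table)
#' length(groups$groups)  # 8 chemicals behind 13 features
#' @export
zone_d_example <- function() {
  csv <- system.file("extdata", "zoneD_features.csv", package = "edatox",
                     mustWork = TRUE)
  mgf <- system.file("extdata", "zoneD_ms2_synthetic.mgf", package = "edatox",
                     mustWork = TRUE)
  d <- utils::read.csv(csv, stringsAsFactors = FALSE,
                       colClasses = c(feature_id = "character"))
  d$active_assay[is.na(d$active_assay)] <- ""
  features <- tibble::as_tibble(
    d[, c("feature_id", "neutral_mass", "mz", "adduct", "rt")])
  samples <- tibble::tibble(sample_id = "parent_r1", role = "parent",
                            zone_id = NA_character_, method = NA_character_,
                            replicate = 1L)
  areas <- tibble::tibble(feature_id = d$feature_id, sample_id = "parent_r1",
                          replicate = 1L, area = d$parent_area,
                          gap_filled = FALSE)
  ft <- feature_table(features, areas, samples, ms2 = read_mgf(mgf))
  list(feature_table = ft,
       info = tibble::as_tibble(
         d[, c("feature_id", "formula", "mass_error_ppm", "active_assay",
               "n_candidates", "n_active_total", "n_active_top")]))
}
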