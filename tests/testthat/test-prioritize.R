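# Hand-built tables exercising each filter rule at its boundaries, plus
# oracle-equivalence and monotonicity properties for the full cascade.

zoneA <- paste0("zoneA_manual_methanol_r", 1:3)
zoneB <- paste0("zoneB_manual_methanol_r", 1:3)
parent <- paste0("parent_r", 1:3)
blanks <- paste0("blank_r", 1:3)

test_that("configuration bounds are validated", {
  expect_error(prioritization_config(ratio_low = 0.8, ratio_high = 0.7))
  expect_error(prioritization_config(abundance_threshold = 0))
  expect_error(prioritization_config(blank_factor = -1))
})

test_that("parent-abundance rule requires genuine detections above threshold", {
  rows <- rbind(
    area_row("hi", parent[1], 1, 3.9e7), area_row("hi", parent[2], 2, 3.9e7),
    area_row("hi", parent[3], 3, 3.9e7),
    area_row("edge", parent[1], 1, 1e6),
    area_row("gapped", parent[1], 1, 5e6, gap = TRUE),
    area_row("gapped", parent[2], 2, 5e6, gap = TRUE))
  ft <- make_table(rows)
  expect_true(rule_parent_abundance(ft, "hi"))
  # exactly at the threshold fails: the comparison is strict
  expect_false(rule_parent_abundance(ft, "edge"))
  # imputed gaps are not detections
  expect_false(rule_parent_abundance(ft, "gapped"))
})

test_that("fraction/parent ratio rule is inclusive at both bounds", {
  mk <- function(frac_area) {
    make_table(rbind(
      area_row("f", parent[1], 1, 1e7), area_row("f", parent[2], 2, 1e7),
      area_row("f", parent[3], 3, 1e7),
      area_row("f", zoneA[1], 1, frac_area),
      area_row("f", zoneA[2], 2, frac_area),
      area_row("f", zoneA[3], 3, frac_area)))
  }
  expect_true(rule_fraction_ratio(mk(3.8e6), "f", "A")$pass)   # 0.38
  expect_equal(rule_fraction_ratio(mk(3.8e6), "f", "A")$ratio, 0.38)
  expect_true(rule_fraction_ratio(mk(1.0e6), "f", "A")$pass)   # 0.10 inclusive
  expect_true(rule_fraction_ratio(mk(7.5e6), "f", "A")$pass)   # 0.75 inclusive
  expect_false(rule_fraction_ratio(mk(8.0e6), "f", "A")$pass)  # 0.80
  expect_false(rule_fraction_ratio(mk(5e5), "f", "A")$pass)    # 0.05 at defaults
  relaxed <- prioritization_config(ratio_low = 0.05)
  expect_true(rule_fraction_ratio(mk(5e5), "f", "A", cfg = relaxed)$pass)
})

test_that("blank rule compares fraction mean against 10x the blank maximum", {
  mk <- function(frac, blank = NULL) {
    rows <- rbind(
      area_row("f", parent[1], 1, 1e8),
      area_row("f", zoneA[1], 1, frac), area_row("f", zoneA[2], 2, frac),
      area_row("f", zoneA[3], 3, frac))
    if (!is.null(blank)) rows <- rbind(rows, area_row("f", blanks[1], 1, blank))
    make_table(rows)
  }
  expect_true(rule_blank(mk(2e7, 1e6), "f", "A"))    # 20x > 10x
  expect_false(rule_blank(mk(5e6, 1e6), "f", "A"))   # 5x fails
  expect_false(rule_blank(mk(1e7, 1e6), "f", "A"))   # exactly 10x fails (strict)
  expect_true(rule_blank(mk(2e6), "f", "A"))         # absent from blanks
})

test_that("zone exclusivity ignores gap-filled off-zone signals", {
  mk <- function(off_area, off_gap = FALSE) {
    make_table(rbind(
      area_row("f", parent[1], 1, 1e8),
      area_row("f", zoneB[1], 1, 3e7),
      area_row("f", zoneA[1], 1, off_area, gap = off_gap)))
  }
  own_zone_only <- make_table(rbind(
    area_row("f", parent[1], 1, 1e8), area_row("f", zoneB[1], 1, 3e7)))
  expect_true(rule_zone_exclusivity(own_zone_only, "f", "B"))
  expect_false(rule_zone_exclusivity(mk(2e6), "f", "B"))
  expect_true(rule_zone_exclusivity(mk(2e6, off_gap = TRUE), "f", "B"))
  # below the abundance threshold an off-zone peak is not a detection...
  expect_true(rule_zone_exclusivity(mk(5e5), "f", "B"))
  # ...unless the threshold-free switch is on
  any_peak <- prioritization_config(off_zone_any_peak = TRUE)
  expect_false(rule_zone_exclusivity(mk(5e5), "f", "B", cfg = any_peak))
})

test_that("the cascade equals brute-force enumeration on random tables", {
  for (seed in 1:40) {
    ft <- random_table(seed)
    for (z in c("A", "B")) {
      zp <- prioritize_zone(ft, z)
      expect_identical(zp$surviving, oracle_prioritize(ft, z),
                       label = paste("seed", seed, "zone", z))
      # audit covers every feature and is consistent with the survivors
      expect_setequal(zp$audit$feature_id, ft$features$feature_id)
      expect_identical(sort(zp$audit$feature_id[zp$audit$pass]), zp$surviving)
    }
  }
})

test_that("the cascade is monotone in its thresholds and bounded by rule 1", {
  for (seed in 41:55) {
    ft <- random_table(seed)
    base <- prioritize_zone(ft, "A")
    wide <- prioritize_zone(ft, "A",
                            cfg = prioritization_config(ratio_low = 0.02,
                                                        ratio_high = 0.95,
                                                        blank_factor = 2))
    expect_true(all(base$surviving %in% wide$surviving))
    rule1 <- ft$features$feature_id[
      vapply(ft$features$feature_id, rule_parent_abundance, logical(1), ft = ft)]
    expect_true(all(base$surviving %in% rule1))
  }
})

test_that("prioritize_zone validates its inputs", {
  ft <- random_table(1)
  expect_error(prioritize_zone(ft, "Z"), "no fraction samples")
  no_parent <- ft
  no_parent$samples <- no_parent$samples[no_parent$samples$role != "parent", ]
  no_parent$areas <- no_parent$areas[
    no_parent$areas$sample_id %in% no_parent$samples$sample_id, ]
  expect_error(prioritize_zone(feature_table(no_parent$features,
                                             no_parent$areas,
                                             no_parent$samples), "A"),
               "no parent samples")
})

test_that("method intersection mirrors the two-solvent accounting", {
  mk <- function(ids) {
    structure(list(zone_id = "D", method = NULL, surviving = sort(ids),
                   audit = NULL), class = "zone_prioritization")
  }
  expect_identical(intersect_methods(mk(c("a", "b")), mk(c("a", "b"))),
                   c("a", "b"))
  expect_identical(intersect_methods(mk("a"), mk("b")), character(0))
  # 32 and 24 survivors with 13 planted common ids
  common <- sprintf("c%02d", 1:13)
  only_m <- sprintf("m%02d", 1:19)
  only_e <- sprintf("e%02d", 1:11)
  expect_identical(length(intersect_methods(mk(c(common, only_m)),
                                            mk(c(common, only_e)))), 13L)
  bad <- mk("a"); bad$zone_id <- "C"
  expect_error(intersect_methods(mk("a"), bad), "zone mismatch")
})

test_that("suspect matching is a ppm window around computed exact masses", {
  cmit_mass <- monoisotopic_mass("C4H4ClNOS")
  feats <- data.frame(
    feature_id = c("hit_exact", "hit_edge", "miss"),
    neutral_mass = c(cmit_mass, cmit_mass * (1 + 1.9e-6), cmit_mass * (1 + 3e-6)),
    adduct = "[M+H]+", rt = c(1, 2, 3))
  feats$mz <- feats$neutral_mass + 1.007276
  ft <- feature_table(feats,
                      area_row("hit_exact", "parent_r1", 1, 1e7),
                      make_samples())
  suspects <- tibble::tibble(name = "CMIT", formula = "C4H4ClNOS",
                             neutral_mass = cmit_mass)
  ann <- suspect_match(ft, suspects)
  expect_setequal(ann$feature_id, c("hit_exact", "hit_edge"))
  expect_equal(ann$delta_ppm[ann$feature_id == "hit_exact"], 0, tolerance = 1e-9)
  # wider tolerance picks up the 3-ppm feature too
  expect_identical(nrow(suspect_match(ft, suspects, ppm_tol = 5)), 3L)
  # empty suspect list
  expect_identical(nrow(suspect_match(ft, suspects[0, ])), 0L)
  # hits sorted by absolute mass error within a feature
  many <- tibble::tibble(
    name = c("far", "near"), formula = NA_character_,
    neutral_mass = c(cmit_mass * (1 + 1.5e-6), cmit_mass * (1 + 0.5e-6)))
  ann2 <- suspect_match(ft, many)
  expect_identical(ann2$name[ann2$feature_id == "hit_exact"], c("near", "far"))
})

test_that("suspect-list files validate mass/formula agreement", {
  p <- tempfile(fileext = ".csv")
  writeLines(c("name,formula,neutral_mass",
               sprintf("CMIT,C4H4ClNOS,%.6f", monoisotopic_mass("C4H4ClNOS")),
               "noMass,C12H10O2,"), p)
  s <- read_suspect_list(p)
  expect_equal(s$neutral_mass[2], monoisotopic_mass("C12H10O2"))
  writeLines(c("name,formula,neutral_mass", "bad,C12H10O2,186.08"), p)
  expect_error(read_suspect_list(p), "disagrees")
})

test_that("percent reduction reproduces the workflow accounting", {
  expect_equal(percent_reduction(2693, 50), 98.1)
  expect_equal(percent_reduction(2693, 20), 99.3)
  expect_equal(percent_reduction(1695, 1695), 0)
  expect_error(percent_reduction(0, 0))
})
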