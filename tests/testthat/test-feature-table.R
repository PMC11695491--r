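test_that("construction enforces the table invariants", {
  rows <- rbind(area_row("f1", "parent_r1", 1, 2e6),
                area_row("f1", "zoneA_manual_methanol_r1", 1, 5e5))
  expect_s3_class(make_table(rows), "feature_table")
  # duplicate feature id
  feats <- data.frame(feature_id = c("f1", "f1"), neutral_mass = c(110, 120),
                      mz = c(111.007276, 121.007276), adduct = "[M+H]+",
                      rt = c(1, 2))
  expect_error(feature_table(feats, rows, make_samples()), "duplicate")
  # unresolvable sample reference
  bad <- area_row("f1", "nosuch_sample", 1, 1e6)
  expect_error(make_table(rbind(rows, bad)), "unknown sample")
  # fraction sample without zone assignment
  s <- make_samples()
  s$zone_id[s$role == "zone_fraction"][1] <- NA
  feats1 <- data.frame(feature_id = "f1", neutral_mass = 110,
                       mz = 111.007276, adduct = "[M+H]+", rt = 1)
  expect_error(feature_table(feats1, rows[1, ], s), "without zone_id")
  # ion m/z must agree with neutral mass + proton within 2 ppm
  feats2 <- feats1; feats2$mz <- 111.01
  expect_error(feature_table(feats2, rows[1, ], make_samples()),
               "inconsistent")
})

test_that("write/read round trip is bit-exact, including on synthetic studies", {
  # header-only file from an empty table
  empty <- feature_table(
    data.frame(feature_id = character(0), neutral_mass = numeric(0),
               mz = numeric(0), adduct = character(0), rt = numeric(0)),
    data.frame(feature_id = character(0), sample_id = character(0),
               replicate = integer(0), area = numeric(0),
               gap_filled = logical(0)),
    make_samples())
  p <- tempfile(fileext = ".csv")
  write_feature_table(empty, p)
  expect_identical(length(readLines(p)), 1L)

  for (seed in c(1, 2)) {
    st <- simulate_study(small_study_config(seed))
    ft <- st$feature_table
    p <- tempfile(fileext = ".csv")
    mgf <- tempfile(fileext = ".mgf")
    write_feature_table(ft, p)
    write_mgf(ft$ms2, mgf)
    back <- read_feature_table(p, mgf_path = mgf)
    expect_equal(back$features[order(back$features$feature_id), ],
                 ft$features[order(ft$features$feature_id), ],
                 ignore_attr = TRUE)
    key <- function(a) a[order(a$feature_id, a$sample_id, a$replicate), ]
    expect_equal(key(back$areas), key(ft$areas), ignore_attr = TRUE)
    expect_equal(back$samples, ft$samples, ignore_attr = TRUE)
    expect_equal(back$ms2[sort(names(back$ms2))], ft$ms2[sort(names(ft$ms2))],
                 tolerance = 1e-12)
  }
})

test_that("reading rejects malformed files with informative errors", {
  rows <- area_row("f1", "parent_r1", 1, 2e6)
  ft <- make_table(rows)
  p <- tempfile(fileext = ".csv")
  write_feature_table(ft, p)
  # missing mandatory column
  d <- utils::read.csv(p)
  d$mz <- NULL
  p2 <- tempfile(fileext = ".csv")
  utils::write.csv(d, p2, row.names = FALSE)
  file.copy(sub("\\.csv$", "_samples.csv", p),
            sub("\\.csv$", "_samples.csv", p2))
  expect_error(read_feature_table(p2), "mz")
  # conflicting duplicate rows for one feature id
  lines <- readLines(p)
  clash <- sub("^f1,1[0-9.]+", "f1,999.9", lines[2])
  writeLines(c(lines, clash), p3 <- tempfile(fileext = ".csv"))
  file.copy(sub("\\.csv$", "_samples.csv", p), sub("\\.csv$", "_samples.csv", p3))
  expect_error(read_feature_table(p3), "disagree")
})

test_that("merging clusters features by mass and rt tolerance", {
  two_feature_table <- function(m2, rt2, sample_prefix) {
    feats <- data.frame(feature_id = paste0(sample_prefix, c("a", "b")),
                        neutral_mass = c(200, m2),
                        mz = c(200, m2) + 1.007276, adduct = "[M+H]+",
                        rt = c(5, rt2))
    areas <- rbind(
      area_row(paste0(sample_prefix, "a"), paste0(sample_prefix, "_s1"), 1, 1e7),
      area_row(paste0(sample_prefix, "b"), paste0(sample_prefix, "_s1"), 1, 3e7))
    samples <- data.frame(sample_id = paste0(sample_prefix, "_s1"),
                          role = "parent", zone_id = NA_character_,
                          method = NA_character_, replicate = 1L)
    feature_table(feats, areas, samples)
  }
  # 1 ppm apart, same rt: merged
  m <- merge_feature_tables(list(two_feature_table(200 * (1 + 1e-6), 5, "x")))
  expect_identical(nrow(m$features), 1L)
  # area-weighted representative mass
  expect_equal(m$features$neutral_mass,
               (200 * 1e7 + 200 * (1 + 1e-6) * 3e7) / 4e7)
  # 3 ppm apart: not merged
  m <- merge_feature_tables(list(two_feature_table(200 * (1 + 3e-6), 5, "x")))
  expect_identical(nrow(m$features), 2L)
  # inside mass tolerance but rt too far: not merged
  m <- merge_feature_tables(list(two_feature_table(200 * (1 + 1e-6), 6, "x")))
  expect_identical(nrow(m$features), 2L)
  expect_error(
    merge_feature_tables(list(two_feature_table(300, 5, "x"),
                              two_feature_table(300, 5, "x"))),
    "disjoint")
})

test_that("merge equals brute-force pairwise clustering and is order-invariant", {
  random_singletons <- function(seed, n = 50) {
    set.seed(seed)
    base <- stats::runif(n, 100, 500)
    mass <- base + stats::rnorm(n, 0, 2e-4)
    rt <- round(stats::runif(n, 1, 5), 1)
    lapply(seq_len(n), function(i) {
      feature_table(
        data.frame(feature_id = sprintf("s%02d", i), neutral_mass = mass[i],
                   mz = mass[i] + 1.007276, adduct = "[M+H]+", rt = rt[i]),
        area_row(sprintf("s%02d", i), sprintf("smp%02d", i), 1, 1e7),
        data.frame(sample_id = sprintf("smp%02d", i), role = "parent",
                   zone_id = NA_character_, method = NA_character_,
                   replicate = 1L))
    })
  }
  for (seed in c(11, 12, 13)) {
    tabs <- random_singletons(seed)
    merged <- merge_feature_tables(tabs, ppm_tol = 2, rt_tol = 0.2)
    # oracle: BFS over the explicit pairwise tolerance graph
    mass <- vapply(tabs, function(t) t$features$neutral_mass, numeric(1))
    rt <- vapply(tabs, function(t) t$features$rt, numeric(1))
    ids <- vapply(tabs, function(t) t$features$feature_id, character(1))
    edges <- NULL
    for (i in 1:(length(ids) - 1)) for (j in (i + 1):length(ids)) {
      if (abs(mass[i] - mass[j]) <= 2e-6 * max(mass[i], mass[j]) &&
          abs(rt[i] - rt[j]) <= 0.2) {
        edges <- rbind(edges, c(ids[i], ids[j]))
      }
    }
    if (is.null(edges)) edges <- matrix(character(0), ncol = 2)
    comps <- oracle_components(ids, edges)
    expect_identical(nrow(merged$features), length(comps))
    expect_setequal(merged$features$feature_id,
                    vapply(comps, function(cc) sort(cc)[1], character(1)))
    # order invariance
    merged_rev <- merge_feature_tables(rev(tabs), ppm_tol = 2, rt_tol = 0.2)
    expect_equal(merged$features[order(merged$features$feature_id), ],
                 merged_rev$features[order(merged_rev$features$feature_id), ],
                 ignore_attr = TRUE)
  }
})

test_that("re-merging a merged table keeps the feature count and doubles replicates", {
  st <- simulate_study(small_study_config(5))
  m1 <- merge_feature_tables(list(st$feature_table))
  copy <- m1
  copy$samples$sample_id <- paste0("dup_", copy$samples$sample_id)
  copy$areas$sample_id <- paste0("dup_", copy$areas$sample_id)
  m2 <- merge_feature_tables(list(m1, copy))
  expect_identical(nrow(m2$features), nrow(m1$features))
  expect_identical(nrow(m2$areas), 2L * nrow(m1$areas))
})

test_that("replicate means honour gap-filled exclusion and scale equivariance", {
  rows <- rbind(
    area_row("f1", "parent_r1", 1, 1e7), area_row("f1", "parent_r2", 2, 1e7),
    area_row("f1", "parent_r3", 3, 1e7),
    area_row("f2", "parent_r1", 1, 2e6), area_row("f2", "parent_r2", 2, 4e6),
    area_row("f2", "parent_r3", 3, 9e6, gap = TRUE),
    area_row("f3", "parent_r1", 1, 5e6, gap = TRUE),
    area_row("f3", "parent_r2", 2, 6e6, gap = TRUE))
  ft <- make_table(rows)
  parent <- paste0("parent_r", 1:3)
  expect_equal(replicate_mean_area(ft, "f1", parent), 1e7)
  expect_equal(replicate_mean_area(ft, "f2", parent), 3e6)
  expect_equal(replicate_mean_area(ft, "f3", parent), 0)
  expect_equal(replicate_mean_area(ft, "f3", parent, exclude_gap_filled = FALSE),
               5.5e6)
  expect_error(replicate_mean_area(ft, "f1", c("parent_r1", "ghost")),
               "unknown sample")
  expect_error(replicate_mean_area(ft, "f1", character(0)), "empty")
  # scale equivariance
  ft2 <- ft; ft2$areas$area <- ft2$areas$area * 3.7
  expect_equal(replicate_mean_area(ft2, "f2", parent),
               3.7 * replicate_mean_area(ft, "f2", parent))
})

test_that("MGF round trip preserves spectra", {
  ms2 <- list(
    fA = list(spectrum(c(85.0283, 99.0440, 127.0389), precursor = 187.06011)),
    fB = list(spectrum(c(91.0542, 187.0753), precursor = 406.18602),
              spectrum(c(60.1), precursor = 406.18602)))
  ms2$fA[[1]]$rt <- 10.61
  p <- tempfile(fileext = ".mgf")
  write_mgf(ms2, p)
  back <- read_mgf(p)
  expect_identical(sort(names(back)), c("fA", "fB"))
  expect_equal(back$fA[[1]]$peaks$mz, c(85.0283, 99.0440, 127.0389))
  expect_equal(back$fA[[1]]$rt, 10.61)
  expect_identical(length(back$fB), 2L)
  expect_equal(back$fB[[1]]$precursor_mz, 406.18602)
})
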