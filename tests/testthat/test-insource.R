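test_that("shared fragments are matched one-to-one, closest first", {
  frag3 <- c(85.0283, 99.0440, 127.0389)
  a <- spectrum(c(frag3, 169.0495), precursor = 187.06011)
  b <- spectrum(c(frag3, 197.0444), precursor = 215.05504)
  expect_equal(shared_fragments(a, b), frag3)
  disjoint <- spectrum(c(60.1, 70.2), precursor = 100)
  expect_identical(shared_fragments(a, disjoint), numeric(0))
  # each fragment used at most once even with near-duplicates
  c1 <- spectrum(c(100.000, 100.004), precursor = 200)
  c2 <- spectrum(100.002, precursor = 200)
  expect_identical(length(shared_fragments(c1, c2, mz_tol = 0.005)), 1L)
})

test_that("greedy matching count equals the brute-force optimum on random spectra", {
  set.seed(31)
  for (k in 1:60) {
    na <- sample(2:8, 1); nb <- sample(2:8, 1)
    ma <- stats::runif(na, 50, 300)
    mb <- stats::runif(nb, 50, 300)
    # plant a few near-coincidences so matches actually occur
    n_plant <- sample(0:min(na, nb), 1)
    if (n_plant > 0) {
      mb[seq_len(n_plant)] <- ma[seq_len(n_plant)] + stats::runif(n_plant, -4e-3, 4e-3)
    }
    got <- length(shared_fragments(spectrum(ma), spectrum(mb), mz_tol = 0.005))
    expect_identical(got, as.integer(oracle_match_count(sort(ma), sort(mb), 0.005)),
                     label = paste("case", k))
  }
})

test_that("precursor-as-fragment detection respects the m/z tolerance", {
  parent_ms2 <- list(spectrum(c(91.0542, 187.0753, 388.1755),
                              precursor = 406.18602))
  expect_true(precursor_in_fragments(parent_ms2, 187.07534))
  # within half a tolerance
  expect_true(precursor_in_fragments(parent_ms2, 187.0753 + 0.0025,
                                     mz_tol = 0.005))
  # beyond twice the tolerance
  expect_false(precursor_in_fragments(parent_ms2, 187.0753 + 0.010,
                                      mz_tol = 0.005))
  expect_false(precursor_in_fragments(list(spectrum(numeric(0), precursor = 406)),
                                      187.0753))
  expect_false(precursor_in_fragments(list(), 187.0753))
})

test_that("the worked example's 13 features collapse to eight chemicals", {
  zd <- zone_d_example()
  g <- group_insource(zd$feature_table)
  expect_identical(length(g$groups), 8L)
  sizes <- sort(vapply(g$groups, function(x) length(x$members), integer(1)))
  expect_identical(sizes, c(1L, 1L, 1L, 1L, 1L, 1L, 2L, 5L))
  members <- lapply(g$groups, `[[`, "members")
  expect_true(any(vapply(members, function(m)
    setequal(m, c("F02", "F03", "F04", "F05", "F06")), logical(1))))
  expect_true(any(vapply(members, function(m) setequal(m, c("F12", "F13")),
                         logical(1))))
  # representative of the linked pair is the higher-mass feature
  pair <- g$groups[[which(vapply(members, function(m)
    setequal(m, c("F12", "F13")), logical(1)))]]
  expect_identical(pair$representative, "F12")
  # without MS2 everything is a singleton
  bare <- zd$feature_table; bare$ms2 <- list()
  g0 <- group_insource(bare)
  expect_identical(length(g0$groups), 13L)
})

test_that("grouping equals brute-force connected components on random graphs", {
  set.seed(77)
  for (k in 1:40) {
    n <- sample(4:15, 1)
    ids <- sprintf("n%02d", seq_len(n))
    # random edge set; every node co-elutes (same rt), links are realized by
    # planting two unique fragment masses per edge in both endpoint spectra
    p_edge <- stats::runif(1, 0.05, 0.35)
    edges <- NULL
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      if (stats::runif(1) < p_edge) edges <- rbind(edges, c(i, j))
    }
    frag_sets <- replicate(n, numeric(0), simplify = FALSE)
    if (!is.null(edges)) {
      for (e in seq_len(nrow(edges))) {
        fr <- 100 + e * 5 + c(0, 2)  # unique, well separated per edge
        frag_sets[[edges[e, 1]]] <- c(frag_sets[[edges[e, 1]]], fr)
        frag_sets[[edges[e, 2]]] <- c(frag_sets[[edges[e, 2]]], fr)
      }
    }
    ms2 <- stats::setNames(lapply(seq_len(n), function(i) {
      filler <- 1000 + i * 10  # unique to the node, never shared
      list(spectrum(c(frag_sets[[i]], filler), precursor = 2000))
    }), ids)
    feats <- data.frame(feature_id = ids,
                        neutral_mass = 300 + seq_len(n),
                        mz = 300 + seq_len(n) + 1.007276,
                        adduct = "[M+H]+", rt = 10)
    ft <- feature_table(feats,
                        area_row(ids[1], "parent_r1", 1, 1e7),
                        make_samples(), ms2 = ms2)
    g <- group_insource(ft, rt_tol = 0.05, mz_tol = 0.005, min_shared = 2)
    edge_labels <- if (is.null(edges)) matrix(character(0), ncol = 2) else
      cbind(ids[edges[, 1]], ids[edges[, 2]])
    comps <- oracle_components(ids, edge_labels)
    got <- lapply(g$groups, `[[`, "members")
    got <- got[order(vapply(got, `[`, character(1), 1))]
    expect_identical(got, comps, label = paste("graph", k))
    # partition sanity: disjoint cover, representative has maximal mass
    expect_setequal(unlist(got), ids)
    for (gr in g$groups) {
      expect_identical(gr$representative,
                       gr$members[which.max(feats$neutral_mass[
                         match(gr$members, feats$feature_id)])])
    }
  }
})

test_that("grouping is invariant to input order", {
  zd <- zone_d_example()
  g1 <- group_insource(zd$feature_table, zd$feature_table$features$feature_id)
  g2 <- group_insource(zd$feature_table, rev(zd$feature_table$features$feature_id))
  expect_identical(lapply(g1$groups, `[[`, "members"),
                   lapply(g2$groups, `[[`, "members"))
})
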