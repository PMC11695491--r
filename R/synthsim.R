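# Seeded synthetic EDA study generator.
#
# Emulates the data a fractionation study produces downstream of vendor
# peak picking: a parent (unfractionated) extract of log-normally abundant
# features, HPTLC zone fractions with partial recoveries per elution
# method, blank-plate background features, injection triplicates with
# multiplicative noise, gap-filled (imputed) entries, in-source fragment
# clones sharing retention time and planted MS2 fragments, spiked known
# genotoxicants, suspect lists, molecular fingerprints whose genotoxicity
# is determined by a planted bit rule, and endpoint training datasets.
# Every emitted feature carries ground truth, so each pipeline stage is
# testable without any external data.

# fragment m/z planted in in-source clusters (recognizable polyol-type ions)
.default_cluster_fragments <- c(85.0283, 99.0440, 127.0389)

#' Specification of a spiked chemical
#'
#' @param name Chemical name (also its suspect-list entry).
#' @param formula Molecular formula string (Hill notation).
#' @param zone_id Zone the spike occupies on the plate.
#' @param recovery Fraction/parent area ratio achieved by fractionation,
#'   in (0, 1].
#' @param parent_area Mean area in the parent extract.
#' @param genotoxic Whether the chemical's fingerprint satisfies the
#'   planted activity rule.
#' @return A `spike_spec` list.
#' @export
spike_spec <- function(name, formula, zone_id, recovery, parent_area,
                       genotoxic = TRUE) {
  stopifnot(recovery > 0, recovery <= 1, parent_area > 0)
  structure(list(name = name, formula = formula, zone_id = zone_id,
                 recovery = recovery, parent_area = parent_area,
                 genotoxic = genotoxic), class = "spike_spec")
}

#' Synthetic study configuration
#'
#' Defaults reflect a printed-paperboard-scale study: ~2693 parent-extract
#' features, four bioactive zones, interface elution recovering about 10%
#' and manual scraping about 38% of parent abundance, log10-normal parent
#' areas (mu 6.8, sigma 0.6) so a realistic minority falls below the 1e6
#' picking threshold, and 10% injection-replicate CV.
#'
#' @param n_matrix_features Number of native matrix features in the parent
#'   extract.
#' @param n_blank_features Features originating from the blank plate only.
#' @param spikes List of [spike_spec()] entries.
#' @param zones Zone labels.
#' @param methods Elution methods to simulate fractions for.
#' @param recovery Named list, per method: a single recovery fraction or
#'   `c(shape1, shape2)` of a Beta distribution to draw from.
#' @param area_lognormal `c(mu, sigma)` of parent areas on the log10 scale.
#' @param replicate_cv Multiplicative (log-normal) CV of injection
#'   replicates.
#' @param zone_rate Probability that a matrix feature elutes into some zone.
#' @param blank_contamination_rate Probability that a matrix feature also
#'   shows a genuine peak in blank-plate fractions.
#' @param gap_fill_prob Probability that an absent (feature, sample) pair is
#'   emitted as a gap-filled (imputed) row below the threshold.
#' @param abundance_threshold Picking threshold used to scale gap-filled
#'   values.
#' @param insource_clusters List of `list(size =, n_shared =)`: each plants
#'   a co-eluting clone cluster on one zone feature; `n_shared >= 1` plants
#'   that many shared MS2 fragments, `n_shared = 0` links the pair by
#'   precursor-as-fragment instead.
#' @param ms2_rate Probability that an ordinary feature gets a random MS2
#'   spectrum.
#' @param fingerprint_length Bits per fingerprint.
#' @param planted_rule Bit indices whose OR determines genotoxic activity.
#' @param bit_density Background probability of a non-rule bit being set.
#' @param matrix_genotoxic_rate Probability that a matrix feature's true
#'   chemical is genotoxic.
#' @param n_structures Size of the shared candidate-structure library.
#' @param n_decoy_suspects Decoy entries in the emitted suspect list.
#' @param label_noise Label-flip probability for endpoint datasets.
#' @param endpoints Named list, per endpoint: `list(n =, active_fraction =)`.
#'   Defaults emulate the Tox21 priors 723/5953 (p53 activation) and
#'   257/3057 (DT40 DNA damage).
#' @param seed Integer seed; all outputs are reproducible from it.
#' @return A `study_config` list.
#' @export
study_config <- function(n_matrix_features = 2693,
                         n_blank_features = 50,
                         spikes = list(),
                         zones = c("A", "B", "C", "D"),
                         methods = c("interface", "manual_methanol",
                                     "manual_ethylacetate"),
                         recovery = list(interface = 0.10,
                                         manual_methanol = 0.38,
                                         manual_ethylacetate = 0.38),
                         area_lognormal = c(mu = 6.8, sigma = 0.6),
                         replicate_cv = 0.10,
                         zone_rate = 0.8,
                         blank_contamination_rate = 0.05,
                         gap_fill_prob = 0.5,
                         abundance_threshold = 1e6,
                         insource_clusters = list(),
                         ms2_rate = 0.3,
                         fingerprint_length = 2048,
                         planted_rule = c(17, 421, 1337),
                         bit_density = 0.1,
                         matrix_genotoxic_rate = 0.05,
                         n_structures = 300,
                         n_decoy_suspects = 50,
                         label_noise = 0.05,
                         endpoints = list(
                           p53_bla_ratio = list(n = 5953,
                                                active_fraction = 723 / 5953),
                           dt40_dna_damage = list(n = 3057,
                                                  active_fraction = 257 / 3057)),
                         seed = 1) {
  stopifnot(n_matrix_features >= 0, n_blank_features >= 0,
            replicate_cv >= 0, label_noise >= 0, label_noise < 0.5,
            all(planted_rule >= 1), all(planted_rule <= fingerprint_length))
  for (sp in spikes) {
    if (!sp$zone_id %in% zones) {
      stop("spike zone ", sp$zone_id, " not among study zones")
    }
  }
  stopifnot(all(methods %in% names(recovery)))
  structure(as.list(environment()), class = "study_config")
}

draw_recovery <- function(model) {
  if (length(model) == 1) return(as.numeric(model))
  stats::rbeta(1, model[1], model[2])
}

rep_noise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

random_spectrum <- function(mz, n_frag = sample(5:10, 1), extra = numeric(0)) {
  frag <- sort(c(extra, stats::runif(n_frag, 50, max(51, mz - 1))))
  frag <- frag[frag <= mz + 0.5]
  data.frame(mz = frag, intensity = stats::runif(length(frag), 1e3, 1e6))
}

#' Generate a complete synthetic EDA study
#'
#' @param cfg A [study_config()].
#' @return A `synthetic_study` list: `feature_table` (with MS2 attached),
#'   `feature_fingerprints` (matrix, one row per feature),
#'   `structure_fingerprints` (candidate library matrix),
#'   `structure_active` (named logical, truth under the planted rule),
#'   `suspects` (tibble), `endpoints` (list of [endpoint_dataset()]), and
#'   `truth` (per-feature tibble: chemical, zone, spike/blank origin,
#'   in-source group, genotoxicity).
#' @export
simulate_study <- function(cfg = study_config()) {
  stopifnot(inherits(cfg, "study_config"))
  set.seed(cfg$seed)
  thr <- cfg$abundance_threshold

  # ---- sample manifest ----
  samples <- list(tibble::tibble(
    sample_id = paste0("parent_r", 1:3), role = "parent",
    zone_id = NA_character_, method = NA_character_, replicate = 1:3))
  samples <- c(samples, list(tibble::tibble(
    sample_id = paste0("blank_r", 1:3), role = "blank_fraction",
    zone_id = NA_character_, method = NA_character_, replicate = 1:3)))
  for (z in cfg$zones) {
    for (m in cfg$methods) {
      samples <- c(samples, list(tibble::tibble(
        sample_id = paste0("zone", z, "_", m, "_r", 1:3),
        role = "zone_fraction", zone_id = z, method = m, replicate = 1:3)))
    }
  }
  samples <- do.call(rbind, samples)

  # ---- features and ground truth ----
  nM <- cfg$n_matrix_features
  feats <- list()
  truth <- list()
  if (nM > 0) {
    zone <- ifelse(stats::runif(nM) < cfg$zone_rate,
                   sample(cfg$zones, nM, replace = TRUE), NA_character_)
    feats[[1]] <- tibble::tibble(
      feature_id = sprintf("M%05d", seq_len(nM)),
      neutral_mass = stats::runif(nM, 100, 900),
      rt = stats::runif(nM, 1, 27),
      parent_area = 10^stats::rnorm(nM, cfg$area_lognormal[["mu"]],
                                    cfg$area_lognormal[["sigma"]]),
      zone_id = zone,
      is_spike = FALSE, is_blank_origin = FALSE,
      in_blank = stats::runif(nM) < cfg$blank_contamination_rate,
      recovery = NA_real_,
      genotoxic = stats::runif(nM) < cfg$matrix_genotoxic_rate,
      chemical = sprintf("chem_M%05d", seq_len(nM)))
  }
  for (k in seq_along(cfg$spikes)) {
    sp <- cfg$spikes[[k]]
    feats[[length(feats) + 1L]] <- tibble::tibble(
      feature_id = sprintf("SPK%02d", k),
      neutral_mass = monoisotopic_mass(sp$formula),
      rt = stats::runif(1, 1, 27),
      parent_area = sp$parent_area,
      zone_id = sp$zone_id,
      is_spike = TRUE, is_blank_origin = FALSE, in_blank = FALSE,
      recovery = sp$recovery,
      genotoxic = sp$genotoxic,
      chemical = sp$name)
  }
  nB <- cfg$n_blank_features
  if (nB > 0) {
    feats[[length(feats) + 1L]] <- tibble::tibble(
      feature_id = sprintf("B%04d", seq_len(nB)),
      neutral_mass = stats::runif(nB, 100, 900),
      rt = stats::runif(nB, 1, 27),
      parent_area = NA_real_,
      zone_id = NA_character_,
      is_spike = FALSE, is_blank_origin = TRUE, in_blank = TRUE,
      recovery = NA_real_,
      genotoxic = FALSE,
      chemical = sprintf("chem_B%04d", seq_len(nB)))
  }
  if (!length(feats)) {
    feats <- tibble::tibble(
      feature_id = character(0), neutral_mass = numeric(0), rt = numeric(0),
      parent_area = numeric(0), zone_id = character(0), is_spike = logical(0),
      is_blank_origin = logical(0), in_blank = logical(0),
      recovery = numeric(0), genotoxic = logical(0), chemical = character(0))
  } else {
    feats <- do.call(rbind, feats)
  }
  feats$insource_group <- NA_character_

  # ---- in-source clone clusters ----
  ms2 <- list()
  host_pool <- which(!is.na(feats$zone_id) & !feats$is_blank_origin)
  cluster_id <- 0L
  for (cl in cfg$insource_clusters) {
    if (!length(host_pool)) break
    cluster_id <- cluster_id + 1L
    host <- sample(host_pool, 1)
    host_pool <- setdiff(host_pool, host)
    gid <- sprintf("IS%02d", cluster_id)
    feats$insource_group[host] <- gid
    n_clone <- cl$size - 1L
    shared <- if (cl$n_shared >= 1) {
      c(.default_cluster_fragments,
        stats::runif(max(0, cl$n_shared - 3), 60, 140))[seq_len(cl$n_shared)]
    } else numeric(0)
    host_mz <- feats$neutral_mass[host] + 1.007276
    clones <- tibble::tibble(
      feature_id = sprintf("%s_C%d", gid, seq_len(n_clone)),
      neutral_mass = feats$neutral_mass[host] *
        stats::runif(n_clone, 0.3, 0.9),
      rt = feats$rt[host] + stats::runif(n_clone, -0.02, 0.02),
      parent_area = feats$parent_area[host] * stats::runif(n_clone, 0.2, 0.8),
      zone_id = feats$zone_id[host],
      is_spike = FALSE, is_blank_origin = FALSE, in_blank = FALSE,
      recovery = feats$recovery[host],
      genotoxic = feats$genotoxic[host],
      chemical = feats$chemical[host],
      insource_group = gid)
    if (cl$n_shared >= 1) {
      ms2[[feats$feature_id[host]]] <- list(list(
        precursor_mz = host_mz, rt = feats$rt[host],
        peaks = random_spectrum(host_mz, extra = shared)))
      for (i in seq_len(n_clone)) {
        cmz <- clones$neutral_mass[i] + 1.007276
        ms2[[clones$feature_id[i]]] <- list(list(
          precursor_mz = cmz, rt = clones$rt[i],
          peaks = random_spectrum(cmz, extra = shared[shared <= cmz + 0.5])))
      }
    } else {
      # precursor-as-fragment: clone ion m/z planted in the host's MS2
      clone_mz <- clones$neutral_mass + 1.007276
      ms2[[feats$feature_id[host]]] <- list(list(
        precursor_mz = host_mz, rt = feats$rt[host],
        peaks = random_spectrum(host_mz, extra = clone_mz)))
      for (i in seq_len(n_clone)) {
        ms2[[clones$feature_id[i]]] <- list(list(
          precursor_mz = clone_mz[i], rt = clones$rt[i],
          peaks = random_spectrum(clone_mz[i])))
      }
    }
    feats <- rbind(feats, clones)
  }
  feats$mz <- feats$neutral_mass + 1.007276
  feats$adduct <- "[M+H]+"

  # random MS2 for a subset of the remaining features
  no_ms2 <- setdiff(feats$feature_id, names(ms2))
  pick <- no_ms2[stats::runif(length(no_ms2)) < cfg$ms2_rate]
  for (fid in pick) {
    fmz <- feats$mz[feats$feature_id == fid]
    ms2[[fid]] <- list(list(precursor_mz = fmz,
                            rt = feats$rt[feats$feature_id == fid],
                            peaks = random_spectrum(fmz)))
  }

  # ---- per-sample areas ----
  n <- nrow(feats)
  areas <- list()
  in_parent <- !feats$is_blank_origin
  if (any(in_parent)) {
    fid <- feats$feature_id[in_parent]
    base <- feats$parent_area[in_parent]
    for (r in 1:3) {
      areas[[length(areas) + 1L]] <- tibble::tibble(
        feature_id = fid, sample_id = paste0("parent_r", r), replicate = r,
        area = base * rep_noise(length(base), cfg$replicate_cv),
        gap_filled = FALSE)
    }
  }
  # zone fractions
  for (m in cfg$methods) {
    rec_model <- cfg$recovery[[m]]
    in_zone <- !is.na(feats$zone_id) & !feats$is_blank_origin
    if (!any(in_zone)) next
    idx <- which(in_zone)
    rec <- vapply(idx, function(i) {
      if (!is.na(feats$recovery[i])) feats$recovery[i] else draw_recovery(rec_model)
    }, numeric(1))
    base <- feats$parent_area[idx] * rec
    for (r in 1:3) {
      areas[[length(areas) + 1L]] <- tibble::tibble(
        feature_id = feats$feature_id[idx],
        sample_id = paste0("zone", feats$zone_id[idx], "_", m, "_r", r),
        replicate = r,
        area = base * rep_noise(length(base), cfg$replicate_cv),
        gap_filled = FALSE)
    }
  }
  # blanks: blank-origin features and contaminated matrix features
  in_blk <- feats$in_blank | feats$is_blank_origin
  if (any(in_blk)) {
    idx <- which(in_blk)
    base <- ifelse(feats$is_blank_origin[idx],
                   10^stats::rnorm(length(idx), 6.2, 0.5),
                   10^stats::rnorm(length(idx), 5.8, 0.5))
    for (r in 1:3) {
      areas[[length(areas) + 1L]] <- tibble::tibble(
        feature_id = feats$feature_id[idx],
        sample_id = paste0("blank_r", r), replicate = r,
        area = base * rep_noise(length(idx), cfg$replicate_cv),
        gap_filled = FALSE)
    }
  }
  if (!length(areas)) {
    areas <- tibble::tibble(feature_id = character(0), sample_id = character(0),
                            replicate = integer(0), area = numeric(0),
                            gap_filled = logical(0))
  } else {
    areas <- do.call(rbind, areas)
  }

  # gap-filled rows for absent (feature, sample) pairs
  if (cfg$gap_fill_prob > 0 && n > 0) {
    present <- paste(areas$feature_id, areas$sample_id)
    grid <- expand.grid(feature_id = feats$feature_id,
                        sample_id = samples$sample_id,
                        stringsAsFactors = FALSE)
    absent <- grid[!paste(grid$feature_id, grid$sample_id) %in% present, ]
    keep <- stats::runif(nrow(absent)) < cfg$gap_fill_prob
    absent <- absent[keep, , drop = FALSE]
    if (nrow(absent)) {
      areas <- rbind(areas, tibble::tibble(
        feature_id = absent$feature_id,
        sample_id = absent$sample_id,
        replicate = samples$replicate[match(absent$sample_id,
                                            samples$sample_id)],
        area = stats::runif(nrow(absent), thr / 100, thr),
        gap_filled = TRUE))
    }
  }

  ft <- feature_table(
    feats[, c("feature_id", "neutral_mass", "mz", "adduct", "rt")],
    areas, samples, ms2 = ms2)

  # ---- fingerprints ----
  L <- cfg$fingerprint_length
  make_fp <- function(ids, genotoxic) {
    m <- matrix(stats::rbinom(length(ids) * L, 1, cfg$bit_density),
                nrow = length(ids), ncol = L)
    m[, cfg$planted_rule] <- 0L
    if (any(genotoxic)) {
      # an active chemical carries all planted bits; inactive carries none
      m[genotoxic, cfg$planted_rule] <- 1L
    }
    rownames(m) <- ids
    m
  }
  feature_fp <- make_fp(feats$feature_id, feats$genotoxic)
  struct_active <- stats::runif(cfg$n_structures) < 0.1
  struct_ids <- sprintf("S%04d", seq_len(cfg$n_structures))
  structure_fp <- make_fp(struct_ids, struct_active)
  names(struct_active) <- struct_ids

  # ---- suspect list ----
  susp <- list()
  for (sp in cfg$spikes) {
    susp[[length(susp) + 1L]] <- tibble::tibble(
      name = sp$name, formula = sp$formula,
      neutral_mass = monoisotopic_mass(sp$formula))
  }
  if (cfg$n_decoy_suspects > 0) {
    dc <- vapply(seq_len(cfg$n_decoy_suspects), function(i) {
      format(parse_formula(sprintf("C%dH%dO%d", sample(6:30, 1),
                                   sample(6:40, 1), sample(1:8, 1))))
    }, character(1))
    susp[[length(susp) + 1L]] <- tibble::tibble(
      name = sprintf("decoy_%03d", seq_along(dc)), formula = dc,
      neutral_mass = vapply(dc, monoisotopic_mass, numeric(1)))
  }
  suspects <- if (length(susp)) do.call(rbind, susp) else
    tibble::tibble(name = character(0), formula = character(0),
                   neutral_mass = numeric(0))

  # ---- endpoint training datasets ----
  eps <- list()
  for (nm in names(cfg$endpoints)) {
    e <- cfg$endpoints[[nm]]
    eps[[nm]] <- simulate_endpoint_data(
      n_chemicals = e$n, active_fraction = e$active_fraction,
      planted_rule = cfg$planted_rule, label_noise = cfg$label_noise,
      seed = cfg$seed + match(nm, names(cfg$endpoints)),
      fingerprint_length = L, bit_density = cfg$bit_density,
      endpoint_name = nm)
  }

  truth <- tibble::as_tibble(feats[, c(
    "feature_id", "chemical", "zone_id", "is_spike", "is_blank_origin",
    "in_blank", "recovery", "parent_area", "insource_group", "genotoxic")])

  structure(list(feature_table = ft,
                 feature_fingerprints = feature_fp,
                 structure_fingerprints = structure_fp,
                 structure_active = struct_active,
                 suspects = suspects,
                 endpoints = eps,
                 truth = truth,
                 config = cfg),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("<synthetic_study> seed ", x$config$seed, ": ",
      nrow(x$feature_table$features), " features (",
      sum(x$truth$is_spike), " spikes, ", sum(x$truth$is_blank_origin),
      " blank-origin), ", length(x$endpoints), " endpoint datasets\n",
      sep = "")
  invisible(x)
}

#' Simulate an endpoint training dataset with a planted activity rule
#'
#' Fingerprints are Bernoulli bit vectors; true activity is the OR of the
#' planted rule bits, whose per-bit probability is chosen so that the
#' post-noise label prior matches `active_fraction` in expectation;
#' labels are flipped with probability `label_noise`.
#'
#' @param n_chemicals Number of chemicals.
#' @param active_fraction Target active prior in (0, 1).
#' @param planted_rule Bit indices (>= 1) whose OR defines true activity.
#' @param label_noise Label flip probability in `[0, 0.5)`.
#' @param seed Integer seed.
#' @param fingerprint_length Bits per fingerprint.
#' @param bit_density Background bit probability.
#' @param endpoint_name Name for the resulting dataset.
#' @return An [endpoint_dataset()]; true (pre-noise) labels are attached as
#'   attribute `"true_active"`.
#' @export
simulate_endpoint_data <- function(n_chemicals, active_fraction, planted_rule,
                                   label_noise = 0.05, seed = 1,
                                   fingerprint_length = 2048,
                                   bit_density = 0.1,
                                   endpoint_name = "synthetic_endpoint") {
  stopifnot(active_fraction > 0, active_fraction < 1,
            label_noise >= 0, label_noise < 0.5)
  if (!length(planted_rule)) stop("planted rule must contain at least one bit")
  stopifnot(all(planted_rule >= 1), all(planted_rule <= fingerprint_length))
  if (active_fraction <= label_noise) {
    stop("active_fraction must exceed label_noise")
  }
  set.seed(seed)
  k <- length(planted_rule)
  # pre-noise rule prevalence q such that q(1-noise) + (1-q)noise = target
  q <- (active_fraction - label_noise) / (1 - 2 * label_noise)
  p_rule <- 1 - (1 - q)^(1 / k)
  m <- matrix(stats::rbinom(n_chemicals * fingerprint_length, 1, bit_density),
              nrow = n_chemicals)
  m[, planted_rule] <- stats::rbinom(n_chemicals * k, 1, p_rule)
  rownames(m) <- sprintf("chem_%05d", seq_len(n_chemicals))
  true_active <- rowSums(m[, planted_rule, drop = FALSE]) > 0
  flip <- stats::runif(n_chemicals) < label_noise
  lab <- xor(true_active, flip)
  d <- endpoint_dataset(endpoint_name, m,
                        stats::setNames(lab, rownames(m)))
  attr(d, "true_active") <- stats::setNames(true_active, rownames(m))
  d
}
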