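# Fingerprint-based genotoxicity endpoint models.
#
# Endpoints follow two Tox21 modes of action: p53 pathway activation and
# DNA damage in repair-deficient DT40 cell lines. DT40 activity is defined
# through sensitivity ratios of mutant lines to the wild-type control.
# Classifiers are gradient-boosted trees over binary molecular fingerprint
# bits, trained with a stratified 0.85/0.15 train/test split and
# positive-class weighting for the strongly imbalanced priors (~8-12%
# active). A feature is called potentially genotoxic when it is more likely
# than not (P > 0.5) active in at least one endpoint.

#' Read molecular fingerprints
#'
#' Delimited text `id, bitstring` where the bitstring is a fixed-length
#' 0/1 character string (one bit per molecular substructure).
#'
#' @param path CSV file.
#' @return Integer 0/1 matrix, one row per id (rownames), one column per bit.
#' @export
read_fingerprints <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c("character", "character"))
  lens <- nchar(d$bitstring)
  if (length(unique(lens)) > 1) stop("fingerprint bitstrings differ in length")
  m <- do.call(rbind, lapply(strsplit(d$bitstring, ""), as.integer))
  if (any(!m %in% c(0L, 1L))) stop("fingerprint bits must be 0 or 1")
  rownames(m) <- d$id
  m
}

#' Write molecular fingerprints
#'
#' @param fp Integer 0/1 matrix with rownames (ids).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_fingerprints <- function(fp, path) {
  bits <- apply(fp, 1, paste, collapse = "")
  utils::write.csv(data.frame(id = rownames(fp), bitstring = bits),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' DT40 ratio-to-control activity labels
#'
#' The DT40 DNA-damage readout compares cytotoxic potency (AC50) in
#' repair-deficient mutant lines against the wild-type control: a chemical
#' is genotoxic-active when a mutant line is at least
#' `sensitivity_threshold`-fold more sensitive than wild type
#' (`ac50_wt / ac50_mutant >= threshold`) in at least one mutant line.
#' Chemicals untested or inactive (no AC50) in all mutant lines are
#' inactive; a missing wild-type AC50 also yields inactive, since the ratio
#' is undefined.
#'
#' @param ac50_wt Named numeric vector of wild-type AC50s (chemical -> conc).
#' @param ac50_mutants Named numeric vector, or list of such vectors (one
#'   per mutant line, e.g. DT40_100 and DT40_657).
#' @param sensitivity_threshold Fold-change cutoff (> 1), default 2.
#' @return Named logical vector over all chemicals seen in any input.
#' @export
dt40_ratio_labels <- function(ac50_wt, ac50_mutants, sensitivity_threshold = 2) {
  stopifnot(sensitivity_threshold > 1)
  if (!is.list(ac50_mutants)) ac50_mutants <- list(ac50_mutants)
  all_conc <- c(ac50_wt, unlist(ac50_mutants))
  if (any(!is.na(all_conc) & all_conc <= 0)) {
    stop("AC50 concentrations must be positive")
  }
  chems <- sort(unique(c(names(ac50_wt), unlist(lapply(ac50_mutants, names)))))
  active <- stats::setNames(rep(FALSE, length(chems)), chems)
  for (mut in ac50_mutants) {
    common <- intersect(names(ac50_wt), names(mut))
    common <- common[!is.na(ac50_wt[common]) & !is.na(mut[common])]
    if (!length(common)) next
    ratio <- ac50_wt[common] / mut[common]
    active[common] <- active[common] | ratio >= sensitivity_threshold
  }
  active
}

#' Assemble an endpoint dataset
#'
#' @param endpoint_name Endpoint label (e.g. `"p53_bla_ratio"`).
#' @param fingerprints 0/1 matrix with chemical ids as rownames.
#' @param active Named logical vector of activity calls covering all rows.
#' @return An `endpoint_dataset` list with counts.
#' @export
endpoint_dataset <- function(endpoint_name, fingerprints, active) {
  ids <- rownames(fingerprints)
  if (anyDuplicated(ids)) stop("duplicate chemical ids")
  if (length(setdiff(ids, names(active)))) {
    stop("activity call missing for some chemicals")
  }
  act <- as.logical(active[ids])
  structure(list(endpoint_name = endpoint_name,
                 fingerprints = fingerprints,
                 active = stats::setNames(act, ids),
                 n_total = length(ids),
                 n_active = sum(act)),
            class = "endpoint_dataset")
}

#' @export
print.endpoint_dataset <- function(x, ...) {
  cat("<endpoint_dataset> ", x$endpoint_name, ": ", x$n_total,
      " chemicals, ", x$n_active, " active (",
      round_half_up(100 * x$n_active / x$n_total, 1), "%), ",
      ncol(x$fingerprints), " fingerprint bits\n", sep = "")
  invisible(x)
}

# stratified train/test index split, deterministic given seed
stratified_split <- function(active, test_fraction, seed) {
  idx_pos <- which(active)
  idx_neg <- which(!active)
  rng <- local({ set.seed(seed); list(pos = sample(idx_pos), neg = sample(idx_neg)) })
  n_test_pos <- max(1L, round(length(idx_pos) * test_fraction))
  n_test_neg <- max(1L, round(length(idx_neg) * test_fraction))
  test <- c(rng$pos[seq_len(n_test_pos)], rng$neg[seq_len(n_test_neg)])
  list(train = setdiff(seq_along(active), test), test = sort(test))
}

#' Train a genotoxicity endpoint classifier
#'
#' Gradient-boosted tree classifier (xgboost) over fingerprint bits, with a
#' stratified train/test split (default 0.85/0.15) and positive-class
#' weighting `n_inactive / n_active` to counter the low active prior.
#' Fixed shallow-tree settings (depth 4, eta 0.3, 80 rounds, no
#' subsampling, one thread) keep training deterministic given the seed.
#'
#' @param d An [endpoint_dataset()] containing both classes.
#' @param test_fraction Held-out fraction (default 0.15).
#' @param seed Integer seed controlling the split.
#' @param nrounds,max_depth,eta Boosting hyperparameters.
#' @return An `endpoint_model` with the fitted booster, held-out metrics
#'   (`balanced_accuracy`, `sensitivity`, `specificity`), the split
#'   indices, fingerprint length and training metadata.
#' @export
train_endpoint_model <- function(d, test_fraction = 0.15, seed = 1,
                                 nrounds = 80, max_depth = 4, eta = 0.3) {
  stopifnot(inherits(d, "endpoint_dataset"))
  if (d$n_active == 0 || d$n_active == d$n_total) {
    stop("endpoint dataset must contain both classes")
  }
  act <- unname(d$active)
  split <- stratified_split(act, test_fraction, seed)
  xtr <- d$fingerprints[split$train, , drop = FALSE]
  ytr <- as.numeric(act[split$train])
  xte <- d$fingerprints[split$test, , drop = FALSE]
  yte <- as.numeric(act[split$test])
  spw <- sum(ytr == 0) / sum(ytr == 1)
  dtrain <- xgboost::xgb.DMatrix(data = xtr, label = ytr)
  booster <- xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = max_depth,
                  eta = eta, nthread = 1, scale_pos_weight = spw,
                  eval_metric = "logloss"),
    data = dtrain, nrounds = nrounds, verbose = 0)
  p <- stats::predict(booster, xgboost::xgb.DMatrix(xte))
  pred <- p > 0.5
  sens <- if (any(yte == 1)) mean(pred[yte == 1]) else NA_real_
  spec <- if (any(yte == 0)) mean(!pred[yte == 0]) else NA_real_
  structure(list(
    endpoint_name = d$endpoint_name,
    booster = booster,
    fingerprint_length = ncol(d$fingerprints),
    seed = seed,
    test_fraction = test_fraction,
    params = list(nrounds = nrounds, max_depth = max_depth, eta = eta,
                  scale_pos_weight = spw),
    metrics = list(balanced_accuracy = (sens + spec) / 2,
                   sensitivity = sens, specificity = spec,
                   n_train = length(split$train), n_test = length(split$test))
  ), class = "endpoint_model")
}

#' @export
print.endpoint_model <- function(x, ...) {
  cat("<endpoint_model> ", x$endpoint_name, ": ", x$fingerprint_length,
      " bits; held-out balanced accuracy ",
      sprintf("%.3f", x$metrics$balanced_accuracy), "\n", sep = "")
  invisible(x)
}

#' Predict activity probability from a fingerprint
#'
#' @param model An `endpoint_model`.
#' @param fp A single 0/1 fingerprint vector, or a matrix of fingerprints
#'   (rows = ids).
#' @return Numeric probability in `[0, 1]` (vector, named by rownames when
#'   `fp` is a matrix).
#' @export
predict_probability <- function(model, fp) {
  stopifnot(inherits(model, "endpoint_model"))
  if (is.null(dim(fp))) fp <- matrix(fp, nrow = 1)
  if (ncol(fp) != model$fingerprint_length) {
    stop("fingerprint length ", ncol(fp), " does not match training length ",
         model$fingerprint_length)
  }
  p <- stats::predict(model$booster, xgboost::xgb.DMatrix(fp))
  stats::setNames(as.numeric(p), rownames(fp))
}

#' Any-endpoint activity rule
#'
#' A fingerprint is called potentially genotoxic when it is more likely
#' than not active in at least one endpoint model: strictly `P > 0.5` for
#' any endpoint.
#'
#' @param probs Named numeric vector (or list) of per-endpoint
#'   probabilities.
#' @return Logical.
#' @export
classify_any_endpoint <- function(probs) {
  probs <- unlist(probs)
  if (!length(probs)) stop("no endpoint probabilities given")
  stopifnot(all(probs >= 0 & probs <= 1))
  any(probs > 0.5)
}

#' Per-bit importance of a trained endpoint model
#'
#' @param model An `endpoint_model`.
#' @return Tibble `bit` (1-based index), `gain`, descending by gain.
#' @export
feature_importance <- function(model) {
  imp <- xgboost::xgb.importance(model = model$booster)
  bit <- as.integer(sub("^f", "", imp$Feature)) + 1L
  # named columns: if training matrix had colnames, map them through
  if (any(is.na(bit))) bit <- match(imp$Feature, paste0("bit", seq_len(model$fingerprint_length)))
  tibble::tibble(bit = bit, gain = imp$Gain)
}

#' Save an endpoint model to a self-describing file
#'
#' Writes a JSON artifact containing a schema version, the endpoint name,
#' fingerprint length, seed, training parameters, held-out metrics, and the
#' serialized booster, so that predictions are reproducible from the file.
#'
#' @param model An `endpoint_model`.
#' @param path Output path (`.json`).
#' @return `path`, invisibly.
#' @export
save_endpoint_model <- function(model, path) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  xgboost::xgb.save(model$booster, tmp)
  booster_json <- paste(readLines(tmp, warn = FALSE), collapse = "\n")
  jsonlite::write_json(list(
    schema_version = 1L,
    endpoint_name = model$endpoint_name,
    fingerprint_length = model$fingerprint_length,
    seed = model$seed,
    test_fraction = model$test_fraction,
    params = model$params,
    metrics = model$metrics,
    booster_json = booster_json
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load an endpoint model saved by [save_endpoint_model()]
#'
#' @param path Model artifact path.
#' @return An `endpoint_model`.
#' @export
load_endpoint_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$schema_version) || obj$schema_version != 1L) {
    stop("unsupported model artifact schema")
  }
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(obj$booster_json, tmp)
  booster <- xgboost::xgb.load(tmp)
  structure(list(
    endpoint_name = obj$endpoint_name,
    booster = booster,
    fingerprint_length = obj$fingerprint_length,
    seed = obj$seed,
    test_fraction = obj$test_fraction,
    params = obj$params,
    metrics = obj$metrics
  ), class = "endpoint_model")
}
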