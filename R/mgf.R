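# Minimal MGF (Mascot Generic Format) reader/writer for MS2 spectra.
# TITLE carries the feature id, PEPMASS the precursor m/z, RTINSECONDS the
# retention time. Peaks are "m/z intensity" pairs inside BEGIN/END IONS.

#' Read MS2 spectra from an MGF file
#'
#' @param path MGF file.
#' @return Named list keyed by feature id (the TITLE); each element is a
#'   list of spectra, each spectrum a list with `precursor_mz`, `rt`
#'   (minutes, from RTINSECONDS), and `peaks` (data frame `mz`, `intensity`
#'   sorted by `mz`).
#' @export
read_mgf <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  begin <- which(lines == "BEGIN IONS")
  end <- which(lines == "END IONS")
  if (length(begin) != length(end) || any(end < begin)) {
    stop("malformed MGF: unbalanced BEGIN IONS / END IONS")
  }
  out <- list()
  for (k in seq_along(begin)) {
    block <- lines[(begin[k] + 1):(end[k] - 1)]
    kv <- grepl("=", block, fixed = TRUE)
    meta <- block[kv]
    peaks_txt <- block[!kv & nzchar(block)]
    get <- function(key) {
      hit <- grep(paste0("^", key, "="), meta, value = TRUE)
      if (!length(hit)) return(NA_character_)
      sub(paste0("^", key, "="), "", hit[1])
    }
    title <- get("TITLE")
    if (is.na(title)) stop("MGF block ", k, " lacks TITLE")
    pep <- as.numeric(strsplit(get("PEPMASS"), "[[:space:]]+")[[1]][1])
    rts <- suppressWarnings(as.numeric(get("RTINSECONDS")))
    pk <- do.call(rbind, lapply(strsplit(peaks_txt, "[[:space:]]+"), function(p) {
      as.numeric(p[1:2])
    }))
    peaks <- if (is.null(pk)) {
      data.frame(mz = numeric(0), intensity = numeric(0))
    } else {
      data.frame(mz = pk[, 1], intensity = pk[, 2])
    }
    peaks <- peaks[order(peaks$mz), , drop = FALSE]
    rownames(peaks) <- NULL
    spec <- list(precursor_mz = pep,
                 rt = if (is.na(rts)) NA_real_ else rts / 60,
                 peaks = peaks)
    out[[title]] <- c(out[[title]], list(spec))
  }
  out
}

#' Write MS2 spectra to an MGF file
#'
#' Inverse of [read_mgf()].
#'
#' @param ms2 Named list of spectrum lists, as produced by [read_mgf()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(ms2, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (fid in names(ms2)) {
    for (spec in ms2[[fid]]) {
      writeLines("BEGIN IONS", con)
      writeLines(paste0("TITLE=", fid), con)
      writeLines(paste0("PEPMASS=", sprintf("%.17g", spec$precursor_mz)), con)
      if (!is.null(spec$rt) && !is.na(spec$rt)) {
        writeLines(paste0("RTINSECONDS=", sprintf("%.17g", spec$rt * 60)), con)
      }
      if (nrow(spec$peaks)) {
        writeLines(sprintf("%.17g %.17g", spec$peaks$mz, spec$peaks$intensity), con)
      }
      writeLines(c("END IONS", ""), con)
    }
  }
  invisible(path)
}
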