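#' Matching tolerances and thresholds
#'
#' Defaults follow the identification settings of the data-processing
#' step the pipeline emulates: 1 mDa accurate-mass tolerance in MS1,
#' 5 mDa in MS2, 0.1 min retention-time tolerance for alignment, a
#' spectral-similarity acceptance threshold of 0.80, and at least two
#' matched fragments.
#'
#' @param ms1_tol MS1 precursor tolerance, Da.
#' @param ms2_tol MS2 fragment tolerance, Da.
#' @param rt_tol Retention-time tolerance, minutes.
#' @param min_similarity Minimum spectral similarity for an accepted
#'   match (cosine on square-root intensities, in \[0, 1\]).
#' @param min_matched_fragments Minimum number of paired fragments.
#' @return List of class `"match_config"`.
#' @export
match_config <- function(ms1_tol = 0.001, ms2_tol = 0.005, rt_tol = 0.1,
                         min_similarity = 0.80, min_matched_fragments = 2L) {
  stopifnot(ms1_tol > 0, ms2_tol > 0, rt_tol > 0,
            min_similarity > 0, min_matched_fragments > 0)
  structure(list(ms1_tol = ms1_tol, ms2_tol = ms2_tol, rt_tol = rt_tol,
                 min_similarity = min_similarity,
                 min_matched_fragments = as.integer(min_matched_fragments)),
            class = "match_config")
}

#' Read a sample metadata table
#'
#' TSV with columns `sample_id`, `role` (`treated` / `control` / `QC`),
#' `matrix`, `timepoint` (days), `environment`.
#'
#' @param path TSV path.
#' @return Data frame.
#' @export
read_sample_metadata <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("sample_id", "role")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("sample metadata is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(df$sample_id)) {
    stop("sample ids must be unique", call. = FALSE)
  }
  df
}

# "mz:int mz:int" -> data.frame(mz, intensity); "" -> 0-row frame
parse_ms2_string <- function(x) {
  if (is.na(x) || !nzchar(trimws(x))) {
    return(data.frame(mz = numeric(0), intensity = numeric(0)))
  }
  parts <- strsplit(trimws(x), "[[:space:]]+")[[1]]
  pairs <- strsplit(parts, ":", fixed = TRUE)
  data.frame(
    mz = vapply(pairs, function(p) as.numeric(p[1]), numeric(1)),
    intensity = vapply(pairs, function(p) as.numeric(p[2]), numeric(1))
  )
}

format_ms2_string <- function(peaks) {
  if (nrow(peaks) == 0L) {
    return("")
  }
  paste(sprintf("%.5f:%.3f", peaks$mz, peaks$intensity), collapse = " ")
}

#' Read an aligned feature table
#'
#' TSV dialect modeled on an alignment export: columns `feature_id`,
#' `mz`, `rt`, `acquisition_mode`, `ms2` (peaks encoded as
#' `"mz:intensity"` pairs separated by spaces; may be empty), then one
#' area column per sample. Area columns must map to sample ids in the
#' metadata. Rows with unparseable m/z are rejected with their line
#' numbers; features outside the scan range are dropped with a message.
#'
#' @param path Feature-table TSV path.
#' @param metadata Sample metadata (data frame or path).
#' @param scan_range Length-2 numeric m/z scan range (default 60-800).
#' @return Data frame with a list column `ms2_peaks` of parsed peak
#'   frames and one numeric area column per sample.
#' @export
read_feature_table <- function(path, metadata, scan_range = c(60, 800)) {
  if (is.character(metadata)) metadata <- read_sample_metadata(metadata)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE, colClasses = "character")
  required <- c("feature_id", "mz", "rt", "acquisition_mode", "ms2")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("feature table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  area_cols <- setdiff(names(df), required)
  unknown <- setdiff(area_cols, metadata$sample_id)
  if (length(unknown) > 0L) {
    stop("area column(s) not present in sample metadata: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  mz <- suppressWarnings(as.numeric(df$mz))
  bad <- which(is.na(mz))
  if (length(bad) > 0L) {
    warning("dropping ", length(bad), " row(s) with unparseable m/z (line ",
            paste(bad + 1L, collapse = ", "), ")", call. = FALSE)
    df <- df[-bad, , drop = FALSE]
    mz <- mz[-bad]
  }
  df$mz <- mz
  df$rt <- as.numeric(df$rt)
  for (col in area_cols) df[[col]] <- as.numeric(df[[col]])
  in_range <- df$mz >= scan_range[1] & df$mz <= scan_range[2]
  if (any(!in_range)) {
    message("dropping ", sum(!in_range),
            " feature(s) outside the m/z scan range [",
            scan_range[1], ", ", scan_range[2], "]")
    df <- df[in_range, , drop = FALSE]
  }
  df$ms2_peaks <- I(lapply(df$ms2, parse_ms2_string))
  rownames(df) <- NULL
  df
}

#' Write a feature table in the aligned-export dialect
#'
#' @param features Feature data frame as returned by
#'   [read_feature_table()] or [simulate_feature_table()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path) {
  out <- features
  if (!is.null(out$ms2_peaks)) {
    out$ms2 <- vapply(out$ms2_peaks, format_ms2_string, character(1))
    out$ms2_peaks <- NULL
  }
  front <- c("feature_id", "mz", "rt", "acquisition_mode", "ms2")
  out <- out[, c(front, setdiff(names(out), front))]
  out$mz <- sprintf("%.5f", out$mz)
  out$rt <- sprintf("%.3f", out$rt)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Shortlist library records by precursor m/z
#'
#' @param feature_mz Observed feature m/z.
#' @param library A `"spectral_library"`.
#' @param config A [match_config()].
#' @return Data frame `candidate_id`, `precursor_mz`, `precursor_error`
#'   (observed minus library), sorted by absolute error.
#' @export
match_precursor <- function(feature_mz, library, config = match_config()) {
  if (length(library$records) == 0L) {
    return(data.frame(candidate_id = character(0), precursor_mz = numeric(0),
                      precursor_error = numeric(0)))
  }
  lib_mz <- vapply(library$records, function(r) r$precursor_mz, numeric(1))
  err <- feature_mz - lib_mz
  keep <- abs(err) <= config$ms1_tol
  out <- data.frame(
    candidate_id = vapply(library$records, function(r) r$compound_id,
                          character(1))[keep],
    precursor_mz = lib_mz[keep],
    precursor_error = err[keep],
    stringsAsFactors = FALSE
  )
  out[order(abs(out$precursor_error)), , drop = FALSE]
}

# greedy closest-first unique pairing of two peak lists within `tol`;
# ties broken by lower library (b) mz. Returns index pairs.
pair_fragments <- function(a, b, tol) {
  if (nrow(a) == 0L || nrow(b) == 0L) {
    return(cbind(a = integer(0), b = integer(0)))
  }
  diffs <- abs(outer(a$mz, b$mz, "-"))
  cand <- which(diffs <= tol, arr.ind = TRUE)
  if (nrow(cand) == 0L) {
    return(cbind(a = integer(0), b = integer(0)))
  }
  ord <- order(diffs[cand], b$mz[cand[, 2]], a$mz[cand[, 1]])
  cand <- cand[ord, , drop = FALSE]
  used_a <- logical(nrow(a))
  used_b <- logical(nrow(b))
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1]; j <- cand[k, 2]
    if (!used_a[i] && !used_b[j]) {
      used_a[i] <- TRUE
      used_b[j] <- TRUE
      keep[k] <- TRUE
    }
  }
  cbind(a = cand[keep, 1], b = cand[keep, 2])
}

#' Score MS2 similarity between a feature and a library record
#'
#' Fragments are paired greedily (closest mass difference first, each
#' peak used at most once) within the MS2 tolerance; the similarity is
#' the cosine of the square-root-intensity vectors over the union of
#' paired and unpaired peaks. An empty feature spectrum scores 0.
#'
#' @param feature_peaks,record_peaks Data frames with `mz`, `intensity`.
#' @param config A [match_config()].
#' @return List with `similarity` (in \[0, 1\]) and
#'   `matched_fragment_count`.
#' @export
score_ms2 <- function(feature_peaks, record_peaks, config = match_config()) {
  if (nrow(feature_peaks) == 0L || nrow(record_peaks) == 0L) {
    return(list(similarity = 0, matched_fragment_count = 0L))
  }
  pairs <- pair_fragments(feature_peaks, record_peaks, config$ms2_tol)
  npair <- nrow(pairs)
  x <- sqrt(feature_peaks$intensity)
  y <- sqrt(record_peaks$intensity)
  # union dimensions: paired peaks share a dimension; unpaired peaks
  # contribute a dimension where the other side is zero
  dot <- sum(x[pairs[, 1]] * y[pairs[, 2]])
  sim <- dot / (sqrt(sum(x^2)) * sqrt(sum(y^2)))
  list(similarity = as.numeric(sim), matched_fragment_count = npair)
}

#' Assign an identification confidence level
#'
#' Level 1: confirmed structure by reference standard. Level 2: probable
#' structure, library match against an exact-structure record. Level 3:
#' tentative structure, library match against a precursor-shifted
#' (tentative) record. Matches without MS2 support are not reported at
#' all (levels 4-5 are excluded).
#'
#' @param tentative Logical; was the matched record tentative?
#' @param has_experimental_ms2 Logical; does the feature carry MS2?
#' @param has_reference_standard Logical; reference-standard
#'   confirmation available?
#' @return Integer confidence level (1, 2 or 3), or `NA` if the match
#'   has no MS2 support.
#' @export
assign_confidence <- function(tentative, has_experimental_ms2 = TRUE,
                              has_reference_standard = FALSE) {
  if (!has_experimental_ms2) {
    return(NA_integer_)
  }
  if (has_reference_standard) {
    return(1L)
  }
  if (tentative) 3L else 2L
}

#' Retention-time difference between metabolite and parent feature
#'
#' Reported (not gated) alongside matches as a polarity-plausibility
#' check: hydrophilic conjugations (e.g. glucose) shift the metabolite to
#' earlier retention, lipophilic modifications (e.g. acetylation) to
#' later retention.
#'
#' @param feature_rt Metabolite feature retention time (min).
#' @param parent_rt Parent feature retention time (min), or `NA` when the
#'   parent feature is absent from the aligned table.
#' @return Signed minutes (metabolite minus parent), `NA` if unavailable.
#' @export
delta_rt <- function(feature_rt, parent_rt) {
  if (is.na(parent_rt)) {
    return(NA_real_)
  }
  feature_rt - parent_rt
}

#' Match a feature table against a spectral library
#'
#' For every feature whose acquisition polarity matches the library:
#' shortlist records within the MS1 tolerance, score MS2 similarity, and
#' keep matches that clear the similarity and matched-fragment
#' thresholds. Features without MS2 are never reported (no MS2 support).
#' When a parent table is supplied, the parent's own feature is located
#' by precursor m/z and the retention-time difference is reported.
#'
#' @param features Feature table from [read_feature_table()].
#' @param library A `"spectral_library"`.
#' @param config A [match_config()].
#' @param parents Optional parent table (adds `delta_rt`).
#' @param reference_standards Character vector of candidate ids with
#'   reference-standard confirmation (assigned level 1).
#' @return Data frame of match results: `feature_id`, `candidate_id`,
#'   `precursor_error`, `matched_fragment_count`, `similarity`,
#'   `confidence_level`, `tentative`, `acquisition_mode`, `delta_rt`.
#' @export
match_features <- function(features, library, config = match_config(),
                           parents = NULL, reference_standards = character(0)) {
  lib_tentative <- vapply(library$records, function(r) r$tentative,
                          logical(1))
  names(lib_tentative) <- vapply(library$records,
                                 function(r) r$compound_id, character(1))
  parent_rt <- rep(NA_real_, length.out = if (is.null(parents)) 0L else
                   nrow(parents))
  if (!is.null(parents) && nrow(parents) > 0L) {
    mz_col <- if (library$polarity == "positive") "mz_pos" else "mz_neg"
    for (p in seq_len(nrow(parents))) {
      d <- abs(features$mz - parents[[mz_col]][p])
      hit <- which(d <= config$ms1_tol)
      if (length(hit) > 0L) {
        parent_rt[p] <- features$rt[hit[which.min(d[hit])]]
      }
    }
    names(parent_rt) <- parents$id
  }
  rows <- list()
  for (i in seq_len(nrow(features))) {
    if (!identical(mode_polarity(features$acquisition_mode[i]),
                   library$polarity)) {
      next
    }
    peaks <- features$ms2_peaks[[i]]
    if (nrow(peaks) == 0L) next
    shortlist <- match_precursor(features$mz[i], library, config)
    for (j in seq_len(nrow(shortlist))) {
      cid <- shortlist$candidate_id[j]
      rec <- library$records[[cid]]
      sc <- score_ms2(peaks, rec$peaks, config)
      if (sc$similarity < config$min_similarity ||
          sc$matched_fragment_count < config$min_matched_fragments) {
        next
      }
      drt <- NA_real_
      if (!is.null(parents) && !is.na(rec$parent_id) &&
          rec$parent_id %in% names(parent_rt)) {
        drt <- delta_rt(features$rt[i], parent_rt[[rec$parent_id]])
      }
      rows[[length(rows) + 1L]] <- data.frame(
        feature_id = features$feature_id[i],
        candidate_id = cid,
        precursor_error = shortlist$precursor_error[j],
        matched_fragment_count = sc$matched_fragment_count,
        similarity = sc$similarity,
        confidence_level = assign_confidence(
          tentative = lib_tentative[[cid]],
          has_experimental_ms2 = TRUE,
          has_reference_standard = cid %in% reference_standards),
        tentative = lib_tentative[[cid]],
        acquisition_mode = features$acquisition_mode[i],
        delta_rt = drt,
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(
      feature_id = character(0), candidate_id = character(0),
      precursor_error = numeric(0), matched_fragment_count = integer(0),
      similarity = numeric(0), confidence_level = integer(0),
      tentative = logical(0), acquisition_mode = character(0),
      delta_rt = numeric(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
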