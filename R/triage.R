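# areas of `features` as a features x samples matrix, columns restricted
# to samples present in the metadata
area_matrix <- function(features, metadata) {
  cols <- intersect(metadata$sample_id, names(features))
  if (length(cols) == 0L) {
    stop("no sample area columns found in the feature table", call. = FALSE)
  }
  m <- as.matrix(features[, cols, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- features$feature_id
  m
}

# half of the smallest positive area in the table (zero-imputation unit)
half_min_positive <- function(areas) {
  pos <- areas[areas > 0]
  if (length(pos) == 0L) {
    return(1)
  }
  min(pos) / 2
}

#' Pooled-QC repeatability prefilter
#'
#' Classic quality prefilter for aligned feature tables: a feature is
#' retained only if (1) its pooled-QC peak-area relative standard
#' deviation is below `rsd_max` percent, (2) it is present in more than
#' `qc_presence_min` of the QC injections, and (3) it is present in more
#' than `group_presence_min` of the samples of at least one biological
#' group. All three comparisons are strict, and presence means an area
#' above `presence_floor`. An undefined RSD (zero QC mean) fails
#' criterion 1.
#'
#' @param features Feature table.
#' @param metadata Sample metadata with `role` (`treated` / `control` /
#'   `QC`); at least two QC samples are required.
#' @param rsd_max Maximum QC RSD in percent (default 30).
#' @param qc_presence_min Minimum QC presence fraction (default 0.5).
#' @param group_presence_min Minimum within-group presence fraction
#'   (default 0.7).
#' @param presence_floor Area above which a feature counts as present
#'   (default 0).
#' @return Data frame: `feature_id`, `qc_rsd` (percent), `qc_presence`,
#'   `max_group_presence`, `passes_prefilter`.
#' @export
qc_prefilter <- function(features, metadata, rsd_max = 30,
                         qc_presence_min = 0.5, group_presence_min = 0.7,
                         presence_floor = 0) {
  areas <- area_matrix(features, metadata)
  qc_ids <- metadata$sample_id[metadata$role == "QC"]
  if (length(qc_ids) < 2L) {
    stop("the QC prefilter needs at least two QC samples", call. = FALSE)
  }
  qc <- areas[, qc_ids, drop = FALSE]
  qc_mean <- rowMeans(qc)
  qc_sd <- apply(qc, 1, stats::sd)
  qc_rsd <- ifelse(qc_mean > 0, qc_sd / qc_mean * 100, NA_real_)
  qc_presence <- rowMeans(qc > presence_floor)
  groups <- unique(metadata$role[metadata$role != "QC"])
  group_presence <- sapply(groups, function(g) {
    ids <- metadata$sample_id[metadata$role == g]
    rowMeans(areas[, ids, drop = FALSE] > presence_floor)
  })
  group_presence <- matrix(group_presence, nrow = nrow(areas),
                           dimnames = list(rownames(areas), groups))
  max_presence <- apply(group_presence, 1, max)
  data.frame(
    feature_id = features$feature_id,
    qc_rsd = qc_rsd,
    qc_presence = qc_presence,
    max_group_presence = max_presence,
    passes_prefilter = !is.na(qc_rsd) & qc_rsd < rsd_max &
      qc_presence > qc_presence_min & max_presence > group_presence_min,
    stringsAsFactors = FALSE
  )
}

#' Volcano selection of treatment-elevated features
#'
#' Fold change is the ratio of raw group means (treated over control)
#' after replacing zero areas by half of the smallest positive area in
#' the table; the p-value comes from a Welch two-sample t-test on
#' log10-transformed areas (same half-minimum offset). A feature is
#' significant when `p < alpha` and `FC > fc_threshold` - the positive
#' direction only, since drug metabolites should be absent from control
#' samples. When prefilter results are supplied, significance also
#' requires passing the prefilter (the triage funnel is monotone).
#'
#' @param features Feature table.
#' @param metadata Sample metadata; must contain `treated` and `control`
#'   roles with at least two samples each.
#' @param alpha Significance level (default 0.05).
#' @param fc_threshold Minimum fold change, strict (default 3.0).
#' @param prefilter Optional output of [qc_prefilter()].
#' @param fdr Apply Benjamini-Hochberg adjustment to the p-values before
#'   thresholding (off by default, matching the raw-p criterion).
#' @return Data frame: `feature_id`, `p_value`, `fold_change`,
#'   `passes_prefilter`, `significant`.
#' @export
volcano_select <- function(features, metadata, alpha = 0.05,
                           fc_threshold = 3.0, prefilter = NULL,
                           fdr = FALSE) {
  areas <- area_matrix(features, metadata)
  for (role in c("treated", "control")) {
    n <- sum(metadata$role == role)
    if (n == 0L) {
      stop("no samples with role '", role, "' in the metadata",
           call. = FALSE)
    }
    if (n < 2L) {
      stop("need at least two '", role, "' samples for the volcano test",
           call. = FALSE)
    }
  }
  treated <- areas[, metadata$sample_id[metadata$role == "treated"],
                   drop = FALSE]
  control <- areas[, metadata$sample_id[metadata$role == "control"],
                   drop = FALSE]
  hm <- half_min_positive(areas)
  imp <- function(x) ifelse(x > 0, x, hm)
  fc <- rowMeans(imp(treated)) / rowMeans(imp(control))
  p <- vapply(seq_len(nrow(areas)), function(i) {
    a <- log10(treated[i, ] + hm)
    b <- log10(control[i, ] + hm)
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      return(if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0)
    }
    stats::t.test(a, b)$p.value
  }, numeric(1))
  if (fdr) p <- stats::p.adjust(p, method = "BH")
  passes <- if (is.null(prefilter)) {
    rep(TRUE, nrow(areas))
  } else {
    prefilter$passes_prefilter[match(features$feature_id,
                                     prefilter$feature_id)]
  }
  data.frame(
    feature_id = features$feature_id,
    p_value = p,
    fold_change = fc,
    passes_prefilter = passes,
    significant = passes & p < alpha & fc > fc_threshold,
    stringsAsFactors = FALSE
  )
}

#' PCA overview of the sample structure
#'
#' Areas are log10-transformed (half-minimum offset), constant features
#' are dropped with a warning, and the matrix is autoscaled (unit
#' variance per feature) before singular value decomposition. The sign
#' of each component is fixed by forcing its largest-magnitude loading
#' positive, so scores are deterministic.
#'
#' @param features Feature table (at least 2 features).
#' @param metadata Sample metadata (at least 3 samples).
#' @return List with `scores` (samples x components), `explained`
#'   (variance fractions) and `loadings`.
#' @export
pca_overview <- function(features, metadata) {
  areas <- area_matrix(features, metadata)
  if (ncol(areas) < 3L) stop("PCA needs at least 3 samples", call. = FALSE)
  x <- log10(t(areas) + half_min_positive(areas))  # samples x features
  keep <- apply(x, 2, stats::sd) > 0
  if (any(!keep)) {
    warning(sum(!keep), " constant feature(s) dropped before PCA",
            call. = FALSE)
    x <- x[, keep, drop = FALSE]
  }
  if (ncol(x) < 2L) stop("PCA needs at least 2 varying features",
                         call. = FALSE)
  fit <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  for (k in seq_len(ncol(fit$rotation))) {
    if (fit$rotation[which.max(abs(fit$rotation[, k])), k] < 0) {
      fit$rotation[, k] <- -fit$rotation[, k]
      fit$x[, k] <- -fit$x[, k]
    }
  }
  list(
    scores = fit$x,
    explained = fit$sdev^2 / sum(fit$sdev^2),
    loadings = fit$rotation
  )
}

#' Cross-reference significant features with library matches
#'
#' The identification report is the inner join of the volcano-significant
#' feature set with the library match report: a feature enters the report
#' only if it is both statistically elevated in treated samples and
#' matched against the metabolite library (significant-but-unmatched
#' features are metabolome changes, not drug metabolites; matched-but-
#' non-significant features lack the statistical support). One row is
#' emitted per (candidate, matrix, environment, timepoint) group in which
#' the feature is present in more than half of the treated samples.
#'
#' @param stats Output of [volcano_select()].
#' @param matches Output of [match_features()].
#' @param features Feature table (for per-sample areas).
#' @param metadata Sample metadata; `matrix`, `environment` and
#'   `timepoint` columns drive the report grouping (missing columns are
#'   treated as a single unnamed group).
#' @param presence_floor Area above which a compound counts as present.
#' @return Data frame: `candidate_id`, `feature_id`, `matrix`,
#'   `environment`, `timepoint`, `present`, `confidence_level`,
#'   `acquisition_mode`, `delta_rt`, `mean_treated_area`, `p_value`,
#'   `fold_change`.
#' @export
crossref_and_report <- function(stats, matches, features, metadata,
                                presence_floor = 0) {
  sig_ids <- stats$feature_id[stats$significant]
  hits <- matches[matches$feature_id %in% sig_ids, , drop = FALSE]
  empty <- data.frame(
    candidate_id = character(0), feature_id = character(0),
    matrix = character(0), environment = character(0),
    timepoint = numeric(0), present = logical(0),
    confidence_level = integer(0), acquisition_mode = character(0),
    delta_rt = numeric(0), mean_treated_area = numeric(0),
    p_value = numeric(0), fold_change = numeric(0),
    stringsAsFactors = FALSE)
  if (nrow(hits) == 0L) {
    return(empty)
  }
  md <- metadata[metadata$role == "treated", , drop = FALSE]
  if (is.null(md$matrix)) md$matrix <- "sample"
  if (is.null(md$environment)) md$environment <- "unspecified"
  if (is.null(md$timepoint)) md$timepoint <- NA_real_
  group_key <- paste(md$matrix, md$environment, md$timepoint, sep = "\r")
  groups <- unique(group_key)
  areas <- area_matrix(features, metadata)
  rows <- list()
  for (h in seq_len(nrow(hits))) {
    fid <- hits$feature_id[h]
    srow <- stats[stats$feature_id == fid, ][1, ]
    for (g in groups) {
      ids <- md$sample_id[group_key == g]
      a <- areas[fid, ids]
      present <- mean(a > presence_floor) > 0.5
      if (!present) next
      info <- md[match(ids[1], md$sample_id), ]
      rows[[length(rows) + 1L]] <- data.frame(
        candidate_id = hits$candidate_id[h], feature_id = fid,
        matrix = info$matrix, environment = info$environment,
        timepoint = info$timepoint, present = TRUE,
        confidence_level = hits$confidence_level[h],
        acquisition_mode = hits$acquisition_mode[h],
        delta_rt = hits$delta_rt[h],
        mean_treated_area = mean(a),
        p_value = srow$p_value, fold_change = srow$fold_change,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(empty)
  }
  out <- do.call(rbind, rows)
  out[order(out$candidate_id, out$matrix, out$timepoint), , drop = FALSE]
}

#' Acquisition-mode overlap of identifications
#'
#' Each (metabolite, sample-type) pair counts as one element; the
#' function reports how the elements distribute over the acquisition
#' modes (DDA/DIA, positive/negative) and all their intersections.
#'
#' @param report Identification report from [crossref_and_report()] (or
#'   any data frame with `candidate_id`, `matrix`, `acquisition_mode`).
#' @return List with `n_elements`, `per_mode` (element counts per mode)
#'   and `regions` (counts per exact mode combination, names joined
#'   with `&`).
#' @export
mode_venn <- function(report) {
  if (nrow(report) == 0L) {
    return(list(n_elements = 0L, per_mode = integer(0),
                regions = integer(0)))
  }
  element <- paste(report$candidate_id, report$matrix, sep = "\r")
  mode <- report$acquisition_mode
  sets <- tapply(mode, element, function(m) sort(unique(m)))
  combo <- vapply(sets, paste, character(1), collapse = "&")
  regions_tab <- table(combo)
  regions <- as.integer(regions_tab)
  names(regions) <- names(regions_tab)
  modes <- sort(unique(mode))
  per_mode_n <- vapply(modes, function(m) {
    sum(vapply(sets, function(s) m %in% s, logical(1)))
  }, integer(1))
  names(per_mode_n) <- modes
  list(n_elements = length(sets), per_mode = per_mode_n, regions = regions)
}
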