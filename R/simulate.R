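#' Packaged parent pharmaceuticals and their fragment ions
#'
#' The six study parents (atenolol, enrofloxacin, erythromycin,
#' ketoprofen, sulfamethoxazole, tetracycline) with their formulas and
#' reference fragment-ion sets in both electrospray polarities. The
#' fragment sets are the shared precursor/product ions reported for each
#' parent; the parent's own precursor ion is stored separately (as the
#' record precursor), not as a fragment, so that precursor-shift
#' synthesis adds exactly one peak.
#'
#' @return List with `parents` (parent table, see [read_parent_table()])
#'   and `fragments` (list `positive` / `negative` of per-parent peak
#'   data frames).
#' @export
packaged_parents <- function() {
  parents <- read_parent_table()
  fragments <- list(positive = list(), negative = list())
  for (polarity in names(fragments)) {
    path <- system.file(
      "extdata",
      paste0("parent_spectra_synthetic_",
             if (polarity == "positive") "pos" else "neg", ".msp"),
      package = "metidscreen")
    specs <- load_energy_resolved_spectra(path)
    fragments[[polarity]] <- lapply(specs, function(s) s$peaks)
  }
  list(parents = parents, fragments = fragments)
}

#' Collision-energy-merged parent spectra in one polarity
#'
#' Loads the packaged energy-resolved parent spectra and merges the
#' requested collision energies per parent.
#'
#' @param polarity `"positive"` or `"negative"`.
#' @param include Collision energies to merge (default 10 and 20 eV).
#' @return Named list of merged [spectrum_record()]s keyed by parent id.
#' @export
packaged_parent_spectra <- function(polarity = c("positive", "negative"),
                                    include = c(10, 20)) {
  polarity <- match.arg(polarity)
  path <- system.file(
    "extdata",
    paste0("parent_spectra_synthetic_",
           if (polarity == "positive") "pos" else "neg", ".msp"),
    package = "metidscreen")
  load_energy_resolved_spectra(path, include = include)
}

#' Simulation configuration
#'
#' Defines the simulated study design: a treated/control contrast with
#' pooled-QC injections, a lognormal background metabolome with no group
#' effect, and spiked metabolite features generated from library records.
#' The defaults mirror the exposure-study layout the pipeline targets
#' (small biological groups, eight pooled-QC injections, 15 percent
#' analytical variability) and keep m/z and MS2 errors well inside the
#' matching tolerances.
#'
#' @param seed Integer seed; mandatory, drives every random draw.
#' @param n_treated,n_control Biological replicates per group.
#' @param n_qc Pooled-QC injections.
#' @param n_background_features Null background features.
#' @param spike_list Data frame with columns `candidate_id`, `fc`
#'   (true fold change) and `base_area`, or `NULL` for none.
#' @param noise_cv Within-group biological+analytical CV, percent.
#' @param qc_cv Pooled-QC CV, percent.
#' @param mz_error_sd Gaussian m/z error of spiked features, Da.
#' @param rt_jitter_sd Retention-time jitter, minutes.
#' @param missing_rate Fraction of background areas set to zero.
#' @param n_decoys Number of decoy features (library precursor plus
#'   `decoy_offset`, shuffled intensities).
#' @param decoy_offset Decoy m/z offset, Da (must exceed twice the MS1
#'   tolerance to guarantee decoys fall outside the match window).
#' @param acquisition_mode Acquisition-mode tag written to every feature.
#' @return List of class `"sim_config"`.
#' @export
sim_config <- function(seed, n_treated = 3L, n_control = 3L, n_qc = 8L,
                       n_background_features = 150L, spike_list = NULL,
                       noise_cv = 15, qc_cv = 15, mz_error_sd = 0.0003,
                       rt_jitter_sd = 0.05, missing_rate = 0.1,
                       n_decoys = 0L, decoy_offset = 0.01,
                       acquisition_mode = "DDA+") {
  stopifnot(!missing(seed), is.numeric(seed), length(seed) == 1L)
  stopifnot(n_treated >= 0, n_control >= 0, n_qc >= 0,
            n_background_features >= 0, noise_cv >= 0, qc_cv >= 0,
            missing_rate >= 0, missing_rate <= 1)
  structure(list(
    seed = as.integer(seed), n_treated = as.integer(n_treated),
    n_control = as.integer(n_control), n_qc = as.integer(n_qc),
    n_background_features = as.integer(n_background_features),
    spike_list = spike_list, noise_cv = noise_cv, qc_cv = qc_cv,
    mz_error_sd = mz_error_sd, rt_jitter_sd = rt_jitter_sd,
    missing_rate = missing_rate, n_decoys = as.integer(n_decoys),
    decoy_offset = decoy_offset, acquisition_mode = acquisition_mode
  ), class = "sim_config")
}

# lognormal multiplicative noise around `mean_area` with the given CV (%)
rlnorm_cv <- function(n, mean_area, cv) {
  if (cv <= 0) {
    return(rep(mean_area, n))
  }
  sdlog <- sqrt(log(1 + (cv / 100)^2))
  mean_area * exp(stats::rnorm(n, mean = -sdlog^2 / 2, sd = sdlog))
}

# conjugation-dependent retention shift sign: hydrophilic sugar-type
# conjugates elute earlier, acyl/alkyl modifications later
rt_shift_for <- function(reaction_label) {
  if (is.na(reaction_label)) {
    return(stats::runif(1, -0.4, 0.4))
  }
  if (grepl("glucos|glucuron|galactose|hexos|pentose|deoxyhexose",
            reaction_label)) {
    return(-0.7)
  }
  if (grepl("acetyl|methyl", reaction_label)) {
    return(+0.8)
  }
  stats::runif(1, -0.4, 0.4)
}

#' Build decoy features from a spectral library
#'
#' Decoys probe the false-match rate: each decoy sits at a library
#' precursor plus a fixed offset (which must exceed twice the MS1
#' tolerance, so no decoy can fall inside any match window) and carries
#' the record's fragment m/z values with shuffled intensities.
#'
#' @param library A `"spectral_library"`.
#' @param offset m/z offset in Da.
#' @param ms1_tol MS1 tolerance the offset is validated against.
#' @param n Number of decoys (default: one per record, cycling).
#' @return Data frame `feature_id`, `mz`, `rt`, `ms2_peaks` (list
#'   column), `source_record`.
#' @export
make_decoys <- function(library, offset, ms1_tol = 0.001,
                        n = length(library$records)) {
  if (offset <= 2 * ms1_tol) {
    stop("decoy offset must exceed twice the MS1 tolerance (",
         2 * ms1_tol, " Da)", call. = FALSE)
  }
  if (length(library$records) == 0L || n == 0L) {
    return(data.frame(feature_id = character(0), mz = numeric(0),
                      rt = numeric(0), source_record = character(0)))
  }
  idx <- rep(seq_along(library$records), length.out = n)
  peaks <- vector("list", n)
  mz <- numeric(n)
  src <- character(n)
  for (k in seq_len(n)) {
    rec <- library$records[[idx[k]]]
    mz[k] <- rec$precursor_mz + offset
    p <- rec$peaks
    p$intensity <- sample(p$intensity)
    peaks[[k]] <- p
    src[k] <- rec$compound_id
  }
  out <- data.frame(
    feature_id = sprintf("D%04d", seq_len(n)),
    mz = mz,
    rt = stats::runif(n, 1, 12),
    source_record = src,
    stringsAsFactors = FALSE
  )
  out$ms2_peaks <- I(peaks)
  out
}

#' Simulate an aligned feature table with spiked metabolites
#'
#' Generates the full statistical structure the triage stage assumes:
#' background features with lognormal areas and no group effect, spiked
#' metabolite features whose treated-group areas are multiplied by the
#' true fold change, pooled-QC areas drawn around the pooled mean with
#' the QC CV, feature m/z equal to the library precursor plus Gaussian
#' error, MS2 peaks copied from the library with small jitter, and
#' optional decoys. Missingness is applied to background areas only
#' (pooled QCs contain every compound by construction). All draws come
#' from the seeded generator, so identical configurations reproduce
#' byte-identical tables.
#'
#' @param config A [sim_config()].
#' @param library A `"spectral_library"` providing the spiked records.
#' @param candidates Optional candidate table (adds reaction-dependent
#'   retention-time shifts relative to the parent).
#' @param parents Optional parent table with an `rt` column (defaults to
#'   the packaged parents); parent features are added to the table so
#'   retention-time differences can be reported.
#' @return List with `features` (feature table), `metadata` (sample
#'   metadata), `truth` (ground-truth ledger of spiked features) and
#'   `decoy_ids`.
#' @export
simulate_feature_table <- function(config, library, candidates = NULL,
                                   parents = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  if (is.null(parents)) parents <- read_parent_table()
  spikes <- config$spike_list
  if (!is.null(spikes) && nrow(spikes) > 0L) {
    unknown <- setdiff(spikes$candidate_id, names(library$records))
    if (length(unknown) > 0L) {
      stop("spike list references unknown candidate(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  sample_ids <- c(
    if (config$n_treated > 0) sprintf("T%02d", seq_len(config$n_treated)),
    if (config$n_control > 0) sprintf("C%02d", seq_len(config$n_control)),
    if (config$n_qc > 0) sprintf("QC%02d", seq_len(config$n_qc))
  )
  metadata <- data.frame(
    sample_id = sample_ids,
    role = c(rep("treated", config$n_treated),
             rep("control", config$n_control),
             rep("QC", config$n_qc)),
    matrix = "lettuce_root",
    timepoint = 14,
    environment = "hydroponic",
    stringsAsFactors = FALSE
  )
  n_t <- config$n_treated
  n_c <- config$n_control
  n_q <- config$n_qc
  mz_col <- if (library$polarity == "positive") "mz_pos" else "mz_neg"
  lib_mz <- vapply(library$records, function(r) r$precursor_mz, numeric(1))

  rows <- list()
  truth <- list()
  add_row <- function(feature_id, mz, rt, peaks, treated_mean,
                      control_mean, apply_missing = FALSE) {
    t_area <- rlnorm_cv(n_t, treated_mean, config$noise_cv)
    c_area <- rlnorm_cv(n_c, control_mean, config$noise_cv)
    pooled <- mean(c(rep(treated_mean, n_t), rep(control_mean, n_c)))
    q_area <- rlnorm_cv(n_q, pooled, config$qc_cv)
    areas <- c(t_area, c_area, q_area)
    if (apply_missing && config$missing_rate > 0) {
      areas[stats::runif(length(areas)) < config$missing_rate] <- 0
    }
    row <- data.frame(feature_id = feature_id, mz = mz, rt = rt,
                      acquisition_mode = config$acquisition_mode,
                      stringsAsFactors = FALSE)
    for (s in seq_along(sample_ids)) row[[sample_ids[s]]] <- areas[s]
    row$ms2_peaks <- I(list(peaks))
    row
  }

  # parent features: the parent drugs themselves are detectable in
  # treated samples (and in controls at trace level)
  parent_specs <- if (library$polarity == "positive") {
    packaged_parent_spectra("positive")
  } else {
    tryCatch(packaged_parent_spectra("negative"), error = function(e) list())
  }
  for (p in seq_len(nrow(parents))) {
    pid <- parents$id[p]
    spec <- parent_specs[[pid]]
    if (is.null(spec)) next
    rt <- if (!is.null(parents$rt)) parents$rt[p] else stats::runif(1, 1, 12)
    rows[[length(rows) + 1L]] <- add_row(
      feature_id = paste0("P_", pid),
      mz = parents[[mz_col]][p] + stats::rnorm(1, 0, config$mz_error_sd),
      rt = rt,
      peaks = spec$peaks,
      treated_mean = 5e5, control_mean = 5e5 / 50
    )
  }

  # spiked metabolite features
  if (!is.null(spikes) && nrow(spikes) > 0L) {
    for (k in seq_len(nrow(spikes))) {
      cid <- spikes$candidate_id[k]
      rec <- library$records[[cid]]
      base <- spikes$base_area[k]
      fid <- sprintf("S%03d", k)
      cand <- if (!is.null(candidates)) {
        candidates[match(cid, candidates$id), ]
      } else {
        NULL
      }
      parent_rt <- NA_real_
      shift <- stats::runif(1, -0.4, 0.4)
      if (!is.null(cand) && !is.na(cand$parent_id) &&
          cand$parent_id %in% parents$id && !is.null(parents$rt)) {
        parent_rt <- parents$rt[match(cand$parent_id, parents$id)]
        shift <- rt_shift_for(cand$reaction_label)
      }
      rt <- (if (is.na(parent_rt)) stats::runif(1, 1, 12) else
               parent_rt + shift) + stats::rnorm(1, 0, config$rt_jitter_sd)
      peaks <- rec$peaks
      peaks$mz <- peaks$mz + stats::rnorm(nrow(peaks), 0, 0.0005)
      peaks$intensity <- peaks$intensity *
        exp(stats::rnorm(nrow(peaks), 0, 0.1))
      peaks <- peaks[order(peaks$mz), , drop = FALSE]
      rows[[length(rows) + 1L]] <- add_row(
        feature_id = fid,
        mz = rec$precursor_mz + stats::rnorm(1, 0, config$mz_error_sd),
        rt = max(rt, 0.2),
        peaks = peaks,
        treated_mean = base * spikes$fc[k], control_mean = base
      )
      truth[[length(truth) + 1L]] <- data.frame(
        feature_id = fid, candidate_id = cid, true_fc = spikes$fc[k],
        base_area = base, stringsAsFactors = FALSE)
    }
  }

  # background metabolome: null features away from every library precursor
  if (config$n_background_features > 0L) {
    for (k in seq_len(config$n_background_features)) {
      repeat {
        mz <- stats::runif(1, 60, 800)
        if (length(lib_mz) == 0L || min(abs(mz - lib_mz)) > 0.005) break
      }
      b_area <- 10^stats::runif(1, 4, 6)
      rows[[length(rows) + 1L]] <- add_row(
        feature_id = sprintf("B%04d", k),
        mz = mz, rt = stats::runif(1, 0.5, 13),
        peaks = data.frame(mz = numeric(0), intensity = numeric(0)),
        treated_mean = b_area, control_mean = b_area,
        apply_missing = TRUE
      )
    }
  }

  decoy_ids <- character(0)
  if (config$n_decoys > 0L) {
    dec <- make_decoys(library, config$decoy_offset, n = config$n_decoys)
    for (k in seq_len(nrow(dec))) {
      rows[[length(rows) + 1L]] <- add_row(
        feature_id = dec$feature_id[k], mz = dec$mz[k], rt = dec$rt[k],
        peaks = dec$ms2_peaks[[k]],
        treated_mean = 1e5, control_mean = 1e5
      )
    }
    decoy_ids <- dec$feature_id
  }

  features <- do.call(rbind, rows)
  rownames(features) <- NULL
  truth <- if (length(truth) > 0L) {
    do.call(rbind, truth)
  } else {
    data.frame(feature_id = character(0), candidate_id = character(0),
               true_fc = numeric(0), base_area = numeric(0),
               stringsAsFactors = FALSE)
  }
  list(features = features, metadata = metadata, truth = truth,
       decoy_ids = decoy_ids)
}
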