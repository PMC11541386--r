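#' Pipeline configuration
#'
#' Collects every input path and threshold of the screening workflow.
#' All defaults are the study-design values the pipeline is built
#' around: QC RSD < 30 percent, QC presence > 0.5, group presence > 0.7,
#' p < 0.05 with fold change > 3.0, MS1/MS2 tolerances of 1/5 mDa,
#' retention-time tolerance 0.1 min, and an m/z 800 library cutoff.
#'
#' @param parent_table,reaction_table Paths to parent/reaction TSVs
#'   (default: packaged tables).
#' @param sp_table,ls_table Optional paths to software-predicted /
#'   literature candidate TSVs.
#' @param parent_spectra_pos,parent_spectra_neg Paths to
#'   collision-energy-resolved parent MSP files (default: packaged).
#' @param feature_table,sample_metadata Paths to the aligned feature
#'   table and its sample metadata.
#' @param out_dir Output directory for all artifacts.
#' @param polarity Library polarity to run (`"positive"` or
#'   `"negative"`).
#' @param ce_include Collision energies merged into library records.
#' @param mz_cutoff Upper adduct m/z cutoff for candidates.
#' @param ms1_tol,ms2_tol,rt_tol,min_similarity,min_matched_fragments
#'   Matching settings, see [match_config()].
#' @param rsd_max,qc_presence_min,group_presence_min Prefilter
#'   thresholds, see [qc_prefilter()].
#' @param alpha,fc_threshold Volcano thresholds, see [volcano_select()].
#' @param seed Integer seed recorded in the manifest and used by any
#'   stage that draws random numbers.
#' @return List of class `"pipeline_config"`.
#' @export
pipeline_config <- function(parent_table = NULL, reaction_table = NULL,
                            sp_table = NULL, ls_table = NULL,
                            parent_spectra_pos = NULL,
                            parent_spectra_neg = NULL,
                            feature_table = NULL, sample_metadata = NULL,
                            out_dir = "metidscreen_out",
                            polarity = "positive",
                            ce_include = c(10, 20),
                            mz_cutoff = 800,
                            ms1_tol = 0.001, ms2_tol = 0.005, rt_tol = 0.1,
                            min_similarity = 0.80,
                            min_matched_fragments = 2L,
                            rsd_max = 30, qc_presence_min = 0.5,
                            group_presence_min = 0.7,
                            alpha = 0.05, fc_threshold = 3.0,
                            seed = 1L) {
  default_file <- function(x, name) {
    if (!is.null(x)) x else system.file("extdata", name,
                                        package = "metidscreen")
  }
  cfg <- list(
    parent_table = default_file(parent_table, "parents.tsv"),
    reaction_table = default_file(reaction_table, "reactions_cmp.tsv"),
    sp_table = sp_table, ls_table = ls_table,
    parent_spectra_pos = default_file(parent_spectra_pos,
                                      "parent_spectra_synthetic_pos.msp"),
    parent_spectra_neg = default_file(parent_spectra_neg,
                                      "parent_spectra_synthetic_neg.msp"),
    feature_table = feature_table, sample_metadata = sample_metadata,
    out_dir = out_dir, polarity = polarity, ce_include = ce_include,
    mz_cutoff = mz_cutoff, ms1_tol = ms1_tol, ms2_tol = ms2_tol,
    rt_tol = rt_tol, min_similarity = min_similarity,
    min_matched_fragments = as.integer(min_matched_fragments),
    rsd_max = rsd_max, qc_presence_min = qc_presence_min,
    group_presence_min = group_presence_min,
    alpha = alpha, fc_threshold = fc_threshold, seed = as.integer(seed)
  )
  stopifnot(cfg$mz_cutoff > 0, cfg$alpha > 0, cfg$fc_threshold > 0,
            cfg$rsd_max > 0)
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [pipeline_config()]; unspecified keys
#' keep their defaults, so every deviation from the standard thresholds
#' is visible in the file (and echoed in the run manifest).
#'
#' @param path YAML file path.
#' @return A `"pipeline_config"`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0L) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(pipeline_config, vals)
}

#' Run the full screening pipeline
#'
#' Executes the stages in order - candidate prediction, library
#' building, feature matching, statistical triage, reporting - and
#' writes every artifact (candidate TSV, MSP library, match TSV, stats
#' TSV, report TSV, Venn JSON, run manifest, log) into the output
#' directory. Any stage failure aborts with the stage name and cause.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory artifacts (`candidates`,
#'   `library`, `matches`, `prefilter`, `volcano`, `report`,
#'   `mode_venn`, `source_venn`) and `paths` to the written files.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  log <- function(...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    paste0(...))
    log_lines <<- c(log_lines, line)
    message(line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  paths <- list()
  out <- function(name) file.path(config$out_dir, name)

  # -- predict ---------------------------------------------------------
  artifacts <- stage("predict", {
    parents <- read_parent_table(config$parent_table)
    reactions <- read_reaction_table(config$reaction_table)
    cmp <- enumerate_cmp(parents, reactions)
    rej <- attr(cmp, "rejections")
    sp <- if (!is.null(config$sp_table)) {
      ingest_candidate_table(config$sp_table, "SP")
    } else {
      cmp[0, ]
    }
    ls <- if (!is.null(config$ls_table)) {
      ingest_candidate_table(config$ls_table, "LS")
    } else {
      cmp[0, ]
    }
    candidates <- rbind(sp, ls, cmp)
    n_before <- nrow(candidates)
    candidates <- mz_cutoff_filter(candidates, config$mz_cutoff)
    log("predict: ", nrow(cmp), " CMP + ", nrow(sp), " SP + ", nrow(ls),
        " LS candidates (", nrow(rej), " rejections); ",
        n_before - nrow(candidates), " removed by m/z cutoff ",
        config$mz_cutoff)
    paths$candidates <- write_candidate_table(candidates,
                                               out("candidates.tsv"))
    list(parents = parents, reactions = reactions, candidates = candidates,
         sp = sp, ls = ls, cmp = cmp)
  })

  # -- buildlib --------------------------------------------------------
  library <- stage("buildlib", {
    spectra_path <- if (config$polarity == "positive") {
      config$parent_spectra_pos
    } else {
      config$parent_spectra_neg
    }
    parent_spectra <- load_energy_resolved_spectra(
      spectra_path, include = config$ce_include, tol = config$ms2_tol)
    lib <- build_library(artifacts$candidates, parent_spectra,
                         polarity = config$polarity)
    log("buildlib: ", length(lib$records), " records (",
        length(lib$skipped), " skipped, no spectrum source)")
    paths$library <- write_msp(lib, out(paste0(
      "library_", if (config$polarity == "positive") "pos" else "neg",
      ".msp")))
    lib
  })

  mcfg <- match_config(config$ms1_tol, config$ms2_tol, config$rt_tol,
                       config$min_similarity,
                       config$min_matched_fragments)

  # -- match / stats / report need a feature table ---------------------
  if (is.null(config$feature_table)) {
    log("no feature table configured; stopping after library build")
    manifest <- write_manifest(config, paths, out)
    writeLines(log_lines, out("run.log"))
    return(invisible(list(candidates = artifacts$candidates,
                          library = library, paths = paths,
                          manifest = manifest)))
  }
  if (!file.exists(config$feature_table)) {
    stop("pipeline stage 'match' failed: feature table not found: ",
         config$feature_table, call. = FALSE)
  }

  matches <- stage("match", {
    metadata <- read_sample_metadata(config$sample_metadata)
    features <- read_feature_table(config$feature_table, metadata)
    m <- match_features(features, library, mcfg,
                        parents = artifacts$parents)
    log("match: ", nrow(features), " features, ", nrow(m),
        " accepted matches")
    utils::write.table(m, out("matches.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths$matches <- out("matches.tsv")
    list(matches = m, features = features, metadata = metadata)
  })

  stats <- stage("stats", {
    pre <- qc_prefilter(matches$features, matches$metadata,
                        rsd_max = config$rsd_max,
                        qc_presence_min = config$qc_presence_min,
                        group_presence_min = config$group_presence_min)
    vol <- volcano_select(matches$features, matches$metadata,
                          alpha = config$alpha,
                          fc_threshold = config$fc_threshold,
                          prefilter = pre)
    merged <- merge(pre, vol[, c("feature_id", "p_value", "fold_change",
                                 "significant")], by = "feature_id")
    log("stats: ", sum(pre$passes_prefilter), "/", nrow(pre),
        " pass the QC prefilter; ", sum(vol$significant), " significant")
    utils::write.table(merged, out("feature_stats.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    paths$stats <- out("feature_stats.tsv")
    list(prefilter = pre, volcano = vol)
  })

  report <- stage("report", {
    rep <- crossref_and_report(stats$volcano, matches$matches,
                               matches$features, matches$metadata)
    venn_modes <- mode_venn(rep)
    src <- vapply(strsplit(rep$candidate_id, "-", fixed = TRUE),
                  function(x) x[1], character(1))
    log("report: ", nrow(rep), " identification rows, ",
        length(unique(rep$candidate_id)), " distinct metabolites")
    utils::write.table(rep, out("report.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths$report <- out("report.tsv")
    jsonlite::write_json(
      list(mode_venn = venn_modes,
           source_venn = venn_by_isomer_group(artifacts$sp, artifacts$ls,
                                              artifacts$cmp)),
      out("venn.json"), auto_unbox = TRUE, digits = NA)
    paths$venn <- out("venn.json")
    list(report = rep, mode_venn = venn_modes)
  })

  manifest <- write_manifest(config, paths, out)
  writeLines(log_lines, out("run.log"))
  paths$log <- out("run.log")
  invisible(list(
    candidates = artifacts$candidates, library = library,
    matches = matches$matches, prefilter = stats$prefilter,
    volcano = stats$volcano, report = report$report,
    mode_venn = report$mode_venn, paths = paths, manifest = manifest
  ))
}

write_manifest <- function(config, paths, out) {
  manifest <- list(
    package = "metidscreen",
    version = as.character(utils::packageVersion("metidscreen")),
    seed = config$seed,
    config = unclass(config),
    artifacts = paths
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  manifest
}
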