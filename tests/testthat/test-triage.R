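# minimal in-memory feature table: one row per entry of `areas`,
# columns named by the metadata sample ids
make_table <- function(areas, metadata) {
  df <- data.frame(feature_id = paste0("F", seq_len(nrow(areas))),
                   mz = 100 + seq_len(nrow(areas)), rt = 1,
                   acquisition_mode = "DDA+", stringsAsFactors = FALSE)
  for (j in seq_along(metadata$sample_id)) {
    df[[metadata$sample_id[j]]] <- areas[, j]
  }
  df$ms2_peaks <- I(replicate(nrow(areas),
                              data.frame(mz = numeric(0),
                                         intensity = numeric(0)),
                              simplify = FALSE))
  df
}

triage_metadata <- function(n_t = 3, n_c = 3, n_q = 4) {
  data.frame(
    sample_id = c(sprintf("T%02d", seq_len(n_t)),
                  sprintf("C%02d", seq_len(n_c)),
                  sprintf("QC%02d", seq_len(n_q))),
    role = c(rep("treated", n_t), rep("control", n_c), rep("QC", n_q)),
    matrix = "lettuce_root", timepoint = 14, environment = "hydroponic",
    stringsAsFactors = FALSE)
}

test_that("QC RSD uses the sample standard deviation", {
  md <- triage_metadata()
  areas <- rbind(rep(100, 10),
                 c(rep(100, 6), 90, 100, 110, 100))
  stats <- qc_prefilter(make_table(areas, md), md)
  expect_equal(stats$qc_rsd[1], 0)
  expect_equal(stats$qc_rsd[2], sd(c(90, 100, 110, 100)) / 100 * 100,
               tolerance = 1e-9)
  expect_equal(stats$qc_rsd[2], 8.1649658, tolerance = 1e-6)
  expect_true(all(stats$passes_prefilter))
})

test_that("prefilter thresholds are strict inequalities", {
  md <- triage_metadata(n_t = 10, n_c = 10, n_q = 10)
  base <- matrix(1000, nrow = 1, ncol = 30)
  # RSD straddle: construct QC areas with RSD exactly 29.9% / 30.1%
  make_rsd <- function(target) {
    x <- rep(c(-1, 1), 5)
    1000 + x * target / 100 * 1000 * sqrt(9 / 10)
  }
  a_lo <- base; a_lo[1, 21:30] <- make_rsd(29.9)
  a_hi <- base; a_hi[1, 21:30] <- make_rsd(30.1)
  expect_true(qc_prefilter(make_table(a_lo, md), md)$passes_prefilter)
  expect_false(qc_prefilter(make_table(a_hi, md), md)$passes_prefilter)
  # group presence straddle: 7/10 fails (not > 0.7), 8/10 passes
  a_07 <- base; a_07[1, c(1:3, 11:13)] <- 0   # 7/10 in both groups
  a_08 <- base; a_08[1, c(1:2, 11:13)] <- 0   # 8/10 treated
  s07 <- qc_prefilter(make_table(a_07, md), md)
  s08 <- qc_prefilter(make_table(a_08, md), md)
  expect_equal(s07$max_group_presence, 0.7)
  expect_false(s07$passes_prefilter)
  expect_true(s08$passes_prefilter)
  # QC presence straddle at exactly 0.5 fails
  a_qc <- base; a_qc[1, 21:25] <- 0
  expect_false(qc_prefilter(make_table(a_qc, md), md)$passes_prefilter)
  # all-zero QC areas: RSD undefined, criterion 1 fails
  a_z <- base; a_z[1, 21:30] <- 0
  s_z <- qc_prefilter(make_table(a_z, md), md)
  expect_true(is.na(s_z$qc_rsd))
  expect_false(s_z$passes_prefilter)
})

test_that("volcano selection keeps only treatment-elevated significant features", {
  md <- triage_metadata()
  areas <- rbind(
    c(1000, 1100, 900, 100, 110, 90, rep(500, 4)),   # FC 10, clear
    c(rep(500, 6), rep(500, 4)),                     # identical groups
    c(100, 110, 90, 1000, 1100, 900, rep(500, 4))    # elevated in control
  )
  vol <- volcano_select(make_table(areas, md), md)
  expect_true(vol$significant[1])
  expect_equal(vol$fold_change[1], 10, tolerance = 1e-9)
  expect_lt(vol$p_value[1], 0.05)
  expect_false(vol$significant[2])
  expect_equal(vol$fold_change[2], 1)
  # the control-elevated feature is excluded despite its small p
  expect_lt(vol$p_value[3], 0.05)
  expect_equal(vol$fold_change[3], 0.1, tolerance = 1e-9)
  expect_false(vol$significant[3])
})

test_that("volcano p-values agree with a direct Welch test on log areas", {
  md <- triage_metadata()
  set.seed(5)
  areas <- matrix(rlnorm(5 * 10, log(1e4), 0.4), nrow = 5)
  vol <- volcano_select(make_table(areas, md), md)
  hm <- min(areas[areas > 0]) / 2
  for (i in 1:5) {
    p_ref <- t.test(log10(areas[i, 1:3] + hm),
                    log10(areas[i, 4:6] + hm))$p.value
    expect_equal(vol$p_value[i], p_ref, tolerance = 1e-12)
  }
})

test_that("the triage funnel is monotone: significant implies prefilter pass", {
  exp <- simulated_experiment(seed = 77, n_spikes = 8, n_decoys = 0)
  pre <- qc_prefilter(exp$sim$features, exp$sim$metadata)
  vol <- volcano_select(exp$sim$features, exp$sim$metadata, prefilter = pre)
  expect_true(all(vol$passes_prefilter[vol$significant]))
  expect_true(all(vol$feature_id == pre$feature_id))
  expect_lte(sum(vol$significant), sum(pre$passes_prefilter))
})

test_that("null features show calibrated type-I error", {
  md <- triage_metadata(n_t = 6, n_c = 6, n_q = 2)
  set.seed(12)
  n <- 200
  areas <- matrix(rlnorm(n * 14, log(1e5), 0.3), nrow = n)
  vol <- volcano_select(make_table(areas, md), md)
  frac <- mean(vol$p_value < 0.05)
  expect_gte(frac, 0.03)
  expect_lte(frac, 0.07)
})

test_that("spiked features are recovered at high frequency across replicates", {
  # 10 replicates x 10 spiked features at FC 10, CV 15-20%, n = 3 + 3
  md <- triage_metadata()
  hits <- 0L
  total <- 0L
  set.seed(99)
  for (rep in 1:10) {
    fc <- 10
    cv <- 0.2
    sdl <- sqrt(log(1 + cv^2))
    areas <- cbind(
      matrix(1e5 * fc * exp(rnorm(10 * 3, -sdl^2 / 2, sdl)), nrow = 10),
      matrix(1e5 * exp(rnorm(10 * 3, -sdl^2 / 2, sdl)), nrow = 10),
      matrix(1e5 * exp(rnorm(10 * 4, 0, 0.1)), nrow = 10))
    vol <- volcano_select(make_table(areas, md), md)
    hits <- hits + sum(vol$significant)
    total <- total + 10L
  }
  expect_gte(hits / total, 0.95)
})

test_that("PCA separates groups, fixes signs, and drops constant features", {
  md <- triage_metadata()
  # rank-1 structure: two strongly correlated informative features
  set.seed(3)
  informative <- c(rep(1000, 3), rep(10, 3), rep(300, 4))
  informative2 <- informative * exp(rnorm(10, 0, 0.02))
  ft <- make_table(rbind(informative, informative2), md)
  res <- pca_overview(ft, md)
  expect_gt(res$explained[1], 0.9)
  t_scores <- res$scores[1:3, 1]
  c_scores <- res$scores[4:6, 1]
  expect_true(max(t_scores) < min(c_scores) ||
                min(t_scores) > max(c_scores))
  # deterministic up to the fixed sign rule
  res2 <- pca_overview(ft, md)
  expect_identical(res$scores, res2$scores)
  expect_gt(res$loadings[which.max(abs(res$loadings[, 1])), 1], 0)
  # constant features are dropped with a warning
  ft3 <- make_table(rbind(informative, informative2, rep(5, 10)), md)
  expect_warning(pca_overview(ft3, md), "constant")
})

test_that("QC injections cluster tighter than biological samples in PCA", {
  exp <- simulated_experiment(seed = 55, n_spikes = 6, n_decoys = 0)
  res <- suppressWarnings(pca_overview(exp$sim$features,
                                       exp$sim$metadata))
  roles <- exp$sim$metadata$role[match(rownames(res$scores),
                                       exp$sim$metadata$sample_id)]
  pair_dist <- function(scores) mean(dist(scores))
  qc_d <- pair_dist(res$scores[roles == "QC", 1:2])
  bio_d <- pair_dist(res$scores[roles != "QC", 1:2])
  expect_lt(qc_d, bio_d)
})

test_that("the identification report is the inner join of significance and matching", {
  md <- triage_metadata()
  areas <- rbind(
    c(1000, 1100, 900, 10, 11, 9, rep(400, 4)),  # significant + matched
    c(2000, 2100, 1900, 20, 21, 19, rep(800, 4)),# significant, unmatched
    c(rep(300, 6), rep(300, 4)))                 # matched, not significant
  ft <- make_table(areas, md)
  vol <- volcano_select(ft, md)
  matches <- data.frame(
    feature_id = c("F1", "F3"), candidate_id = c("DrugA-R1", "DrugA-R2"),
    precursor_error = 0, matched_fragment_count = 3L, similarity = 0.95,
    confidence_level = 3L, tentative = TRUE, acquisition_mode = "DDA+",
    delta_rt = -0.7, stringsAsFactors = FALSE)
  rep <- crossref_and_report(vol, matches, ft, md)
  expect_identical(unique(rep$candidate_id), "DrugA-R1")
  expect_identical(unique(rep$feature_id), "F1")
  expect_identical(rep$matrix[1], "lettuce_root")
  expect_identical(rep$confidence_level[1], 3L)
  # empty matches give an empty report
  expect_identical(nrow(crossref_and_report(vol, matches[0, ], ft, md)), 0L)
})

test_that("acquisition-mode Venn counts equal brute-force set algebra", {
  rep <- data.frame(
    candidate_id = c("M1", "M1", "M2", "M3", "M3", "M4", "M5"),
    matrix = c("root", "root", "root", "leaf", "leaf", "root", "leaf"),
    acquisition_mode = c("DDA+", "DIA+", "DDA+", "DDA-", "DIA-", "DIA+",
                         "DDA+"),
    stringsAsFactors = FALSE)
  v <- mode_venn(rep)
  expect_identical(v$n_elements, 5L)
  expect_identical(v$regions[["DDA+&DIA+"]], 1L)
  expect_identical(v$regions[["DDA+"]], 2L)
  expect_identical(v$regions[["DDA-&DIA-"]], 1L)
  expect_identical(v$per_mode[["DDA+"]], 3L)
  expect_identical(sum(v$regions), v$n_elements)
  empty <- mode_venn(rep[0, ])
  expect_identical(empty$n_elements, 0L)
})
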