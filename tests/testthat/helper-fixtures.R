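# Independent brute-force mass oracle: expands a formula atom by atom and
# accumulates single-atom masses from its own literal copy of the IUPAC
# monoisotopic table. Shares no code path with monoisotopic_mass().
oracle_masses <- c(
  C = 12.000000, H = 1.0078250, N = 14.0030740, O = 15.9949146,
  S = 31.9720707, F = 18.9984032, Cl = 34.9688527, P = 30.9737615,
  Na = 22.9897693, K = 38.9637065, Br = 78.9183376, I = 126.9044719
)

oracle_mass <- function(formula_string) {
  total <- 0
  rest <- formula_string
  while (nzchar(rest)) {
    m <- regmatches(rest, regexpr("^[A-Z][a-z]?[0-9]*", rest))[[1]]
    sym <- sub("[0-9]*$", "", m)
    n <- sub("^[A-Za-z]+", "", m)
    n <- if (nzchar(n)) as.integer(n) else 1L
    for (k in seq_len(n)) total <- total + oracle_masses[[sym]]
    rest <- substring(rest, nchar(m) + 1L)
  }
  total
}

random_formula <- function() {
  elements <- sample(names(oracle_masses), sample(2:6, 1))
  counts <- sample(1:30, length(elements), replace = TRUE)
  paste0(elements, counts, collapse = "")
}

# two-parent / three-reaction toy registry for exhaustive checks
toy_parents <- function() {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(c("id\tname\tformula",
               "drugA\tDrugA\tC6H6O",
               "drugB\tDrugB\tC2H6"), path)
  read_parent_table(path)
}

toy_reactions <- function(deltas = c("+O", "-H2O", "+C2H2O")) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(c("id\tlabel\tphase\tdelta",
               paste0("R", seq_along(deltas), "\trxn", seq_along(deltas),
                      "\tI\t", deltas)), path)
  read_reaction_table(path)
}

toy_spectrum <- function(id = "drugA", mz = c(51.0, 65.0, 77.0),
                         intensity = c(20, 50, 100), precursor = 95.04914,
                         energy = 10, adduct = "[M+H]+") {
  spectrum_record(id, adduct, precursor,
                  data.frame(mz = mz, intensity = intensity),
                  energy = energy)
}

# full positive-mode screening library from the packaged registry,
# built once per test run
packaged_library_pos <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      parents <- read_parent_table()
      cand <- enumerate_cmp(parents, cmp_reactions())
      cache <<- list(
        parents = parents,
        candidates = cand,
        library = build_library(cand, packaged_parent_spectra("positive"),
                                polarity = "positive")
      )
    }
    cache
  }
})

# simulated spike-in experiment shared by matching/pipeline tests
simulated_experiment <- function(seed, n_spikes = 26, fc = 10,
                                 n_decoys = 30, dir = NULL) {
  ctx <- packaged_library_pos()
  cand800 <- mz_cutoff_filter(ctx$candidates, 800)
  lib <- build_library(cand800, packaged_parent_spectra("positive"),
                       polarity = "positive")
  ids <- names(lib$records)
  by_parent <- split(ids, sub("-R[0-9]+$", "", ids))
  pick <- unlist(lapply(by_parent, head, ceiling(n_spikes / length(by_parent))))
  pick <- pick[seq_len(n_spikes)]
  spikes <- if (n_spikes > 0) {
    data.frame(candidate_id = unname(pick), fc = fc, base_area = 1e5)
  } else {
    NULL
  }
  cfg <- sim_config(seed = seed, spike_list = spikes, n_decoys = n_decoys,
                    noise_cv = 15, qc_cv = 15)
  sim <- simulate_feature_table(cfg, lib, candidates = cand800,
                                parents = ctx$parents)
  list(config = cfg, sim = sim, library = lib, candidates = cand800,
       parents = ctx$parents)
}
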