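test_that("collision-energy merging unions included levels and drops the rest", {
  ce10 <- toy_spectrum(mz = 100.0, intensity = 50, energy = 10,
                       precursor = 200)
  ce20 <- toy_spectrum(mz = c(100.0, 150.0), intensity = c(30, 80),
                       energy = 20, precursor = 200)
  ce40 <- toy_spectrum(mz = 50.0, intensity = 99, energy = 40,
                       precursor = 200)
  merged <- merge_energy_levels(list(ce10, ce20, ce40), include = c(10, 20))
  expect_equal(merged$peaks$mz, c(100.0, 150.0))
  expect_equal(merged$energy, c(10, 20))
  # the omitted high-energy level contributes nothing
  expect_false(50.0 %in% merged$peaks$mz)
  # identity: merging a single spectrum returns it unchanged
  solo <- merge_energy_levels(list(ce10), include = 10)
  expect_equal(solo$peaks, ce10$peaks)
})

test_that("peaks within the merge tolerance collapse to the most intense member", {
  a <- toy_spectrum(mz = 100.0000, intensity = 40, energy = 10,
                    precursor = 200)
  b <- toy_spectrum(mz = 100.0003, intensity = 90, energy = 20,
                    precursor = 200)
  merged <- merge_energy_levels(list(a, b), include = c(10, 20))
  expect_identical(nrow(merged$peaks), 1L)
  expect_equal(merged$peaks$mz, 100.0003)
  expect_equal(merged$peaks$intensity, 90)
})

test_that("merging rejects mismatched compounds", {
  a <- toy_spectrum(id = "drugA", energy = 10)
  b <- toy_spectrum(id = "drugB", energy = 20)
  expect_error(merge_energy_levels(list(a, b)), "share")
})

test_that("tentative synthesis reproduces the sulfamethoxazole glucose-conjugate spectrum", {
  smx <- spectrum_record(
    "sulfamethoxazole", "[M+H]+", 254.05994,
    data.frame(mz = c(92.04948, 94.06513, 156.01138),
               intensity = c(50, 30, 100)), energy = c(10, 20))
  ctx <- packaged_library_pos()
  cand <- ctx$candidates[ctx$candidates$id == "Sulfamethoxazole-R63", ]
  syn <- synthesize_tentative_spectrum(smx, cand)
  expect_identical(nrow(syn$peaks), 4L)
  expect_equal(syn$peaks$mz, c(92.04948, 94.06513, 156.01138, 254.05994))
  expect_equal(syn$precursor_mz, 416.11276, tolerance = 1e-5)
  expect_true(syn$tentative)
  # appended parent-precursor fragment carries the maximum intensity
  expect_equal(syn$peaks$intensity[4], 100)
})

test_that("ketoprofen glucose conjugation shifts the precursor to 417.15494", {
  ctx <- packaged_library_pos()
  cand <- ctx$candidates[ctx$candidates$id == "Ketoprofen-R63", ]
  rec <- packaged_parent_spectra("positive")[["ketoprofen"]]
  syn <- synthesize_tentative_spectrum(rec, cand)
  expect_equal(syn$precursor_mz, 417.15494, tolerance = 1e-5)
})

test_that("exact-structure candidates are refused by tentative synthesis", {
  rec <- packaged_parent_spectra("positive")[["atenolol"]]
  exact <- ingest_candidate_table(
    data.frame(name = "Atenolol-LS1", parent_id = "atenolol",
               formula = "C14H21NO4"), "LS")
  expect_error(synthesize_tentative_spectrum(rec, exact[1, ]),
               "exact structure")
  wrong <- packaged_library_pos()$candidates
  wrong <- wrong[wrong$parent_id == "ketoprofen", ][1, ]
  expect_error(synthesize_tentative_spectrum(rec, wrong),
               "does not belong")
})

test_that("library building covers all candidates and flags tentativeness by source", {
  ctx <- packaged_library_pos()
  lib <- ctx$library
  expect_identical(length(lib$records), nrow(ctx$candidates))  # 864
  expect_true(all(vapply(lib$records, function(r) r$tentative,
                         logical(1))))
  # mixed SP + CMP input: only CMP records are tentative
  exact <- ingest_candidate_table(
    data.frame(name = "Atenolol-LS1", parent_id = "atenolol",
               formula = "C14H21NO4"), "LS")
  mixed <- rbind(exact, ctx$candidates[1, ])
  lib2 <- build_library(
    mixed, packaged_parent_spectra("positive"),
    exact_spectra = list("Atenolol-LS1" = toy_spectrum("Atenolol-LS1",
      mz = c(74.06, 116.107), intensity = c(40, 100),
      precursor = 268.15437)),
    polarity = "positive")
  expect_false(lib2$records[["Atenolol-LS1"]]$tentative)
  expect_true(lib2$records[[2]]$tentative)
  # candidates with no spectrum source are skipped, not fatal
  orphan <- ingest_candidate_table(
    data.frame(name = "Orphan", parent_id = "nosuch", formula = "C2H6"),
    "SP")
  lib3 <- build_library(orphan, packaged_parent_spectra("positive"),
                        polarity = "positive")
  expect_identical(length(lib3$records), 0L)
  expect_identical(lib3$skipped, "Orphan")
})

test_that("every tentative record gains exactly one peak and shifts by the reaction delta", {
  ctx <- packaged_library_pos()
  parent_specs <- packaged_parent_spectra("positive")
  reactions <- cmp_reactions()
  delta <- stats::setNames(reactions$mass_delta, reactions$id)
  n_parent_peaks <- vapply(parent_specs, function(s) nrow(s$peaks),
                           integer(1))
  parent_prec <- vapply(parent_specs, function(s) s$precursor_mz,
                        numeric(1))
  for (rec in ctx$library$records) {
    cand <- ctx$candidates[match(rec$compound_id, ctx$candidates$id), ]
    expect_identical(nrow(rec$peaks),
                     n_parent_peaks[[cand$parent_id]] + 1L)
    expect_equal(rec$precursor_mz - parent_prec[[cand$parent_id]],
                 delta[[cand$reaction_id]], tolerance = 1e-5)
  }
})

test_that("positive and negative libraries have equal record counts when parent spectra exist in both", {
  ctx <- packaged_library_pos()
  neg_parents <- names(packaged_parent_spectra("negative"))
  cand <- ctx$candidates[ctx$candidates$parent_id %in% neg_parents, ]
  pos <- build_library(cand, packaged_parent_spectra("positive"),
                       polarity = "positive")
  neg <- build_library(cand, packaged_parent_spectra("negative"),
                       polarity = "negative")
  expect_identical(length(pos$records), length(neg$records))
  expect_gt(length(pos$records), 0L)
})

test_that("MSP round-trip preserves names, precursors, polarity and peaks", {
  ctx <- packaged_library_pos()
  lib <- ctx$library
  path <- withr::local_tempfile(fileext = ".msp")
  write_msp(lib, path)
  back <- read_msp(path)
  expect_identical(length(back$records), length(lib$records))
  expect_identical(back$polarity, "positive")
  for (id in c("Sulfamethoxazole-R63", "Ketoprofen-R63", "Atenolol-R1")) {
    a <- lib$records[[id]]
    b <- back$records[[id]]
    expect_equal(round(b$precursor_mz, 5), round(a$precursor_mz, 5))
    expect_equal(round(b$peaks$mz, 5), round(a$peaks$mz, 5))
    expect_identical(b$tentative, a$tentative)
    expect_identical(b$adduct$name, a$adduct$name)
  }
  # intensities are normalized to max 100 on write
  expect_true(all(vapply(back$records,
                         function(r) max(r$peaks$intensity) == 100,
                         logical(1))))
  # a full second round-trip is lossless
  path2 <- withr::local_tempfile(fileext = ".msp")
  write_msp(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("malformed MSP records are rejected with their line numbers", {
  path <- withr::local_tempfile(fileext = ".msp")
  writeLines(c("NAME: x", "PRECURSORMZ: 100.0", "Num Peaks: 3",
               "50.0\t10", "60.0\t20", "70.0\t30", "80.0\t40", ""), path)
  expect_error(read_msp(path), "Num Peaks")
  writeLines(c("NAME: x", "IONMODE: Positive", "Num Peaks: 1",
               "50.0\t10", ""), path)
  expect_error(read_msp(path), "PRECURSORMZ")
  # empty library writes an empty file that reads back empty
  empty <- structure(list(polarity = "positive", records = list(),
                          skipped = character(0)),
                     class = "spectral_library")
  write_msp(empty, path)
  expect_identical(length(read_msp(path)$records), 0L)
})
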