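#' Construct an MS2 spectrum record
#'
#' @param compound_id Library compound identifier (written as `NAME` in
#'   MSP output).
#' @param adduct Adduct name or [adduct_spec()].
#' @param precursor_mz Precursor m/z.
#' @param peaks Data frame with columns `mz`, `intensity`.
#' @param energy Numeric vector of collision energies (eV) the record was
#'   built from.
#' @param tentative Logical; `TRUE` for precursor-shifted spectra of
#'   tentative (formula-only) structures.
#' @param formula Optional formula string carried into MSP output.
#' @param parent_id Optional parent-compound id (set for records derived
#'   from a parent spectrum; used for retention-time reporting).
#' @param ms2_tol Tolerance (Da) used to validate that no fragment lies
#'   above the precursor.
#' @return An object of class `"ms2_spectrum"`.
#' @export
spectrum_record <- function(compound_id, adduct, precursor_mz, peaks,
                            energy = numeric(0), tentative = FALSE,
                            formula = NA_character_,
                            parent_id = NA_character_, ms2_tol = 0.005) {
  if (is.character(adduct)) adduct <- adduct_spec(adduct)
  stopifnot(is.data.frame(peaks), all(c("mz", "intensity") %in% names(peaks)))
  peaks <- peaks[order(peaks$mz), c("mz", "intensity")]
  rownames(peaks) <- NULL
  if (any(peaks$mz <= 0)) stop("peak m/z must be positive", call. = FALSE)
  if (any(peaks$intensity < 0)) {
    stop("peak intensities must be non-negative", call. = FALSE)
  }
  # fragments cannot exceed the precursor in a measured spectrum; the
  # check is skipped for tentative records, whose transplanted parent
  # fragments legitimately exceed the precursor under mass-loss reactions
  if (!isTRUE(tentative) && any(peaks$mz > precursor_mz + ms2_tol)) {
    stop("fragment m/z above precursor m/z in record '", compound_id, "'",
         call. = FALSE)
  }
  structure(
    list(compound_id = compound_id, adduct = adduct,
         polarity = adduct$polarity, precursor_mz = precursor_mz,
         peaks = peaks, energy = sort(unique(energy)),
         tentative = isTRUE(tentative), formula = formula,
         parent_id = parent_id),
    class = "ms2_spectrum"
  )
}

#' @export
print.ms2_spectrum <- function(x, ...) {
  cat(sprintf("<ms2_spectrum> %s %s precursor %.5f, %d peaks%s\n",
              x$compound_id, x$adduct$name, x$precursor_mz, nrow(x$peaks),
              if (x$tentative) " (tentative)" else ""))
  invisible(x)
}

# collapse peaks closer than `tol`, keeping the mz and intensity of the
# most intense member of each cluster
merge_peaks <- function(peaks, tol) {
  peaks <- peaks[order(peaks$mz), , drop = FALSE]
  if (nrow(peaks) <= 1L) {
    rownames(peaks) <- NULL
    return(peaks)
  }
  keep_mz <- numeric(0)
  keep_int <- numeric(0)
  for (i in seq_len(nrow(peaks))) {
    n <- length(keep_mz)
    if (n > 0L && peaks$mz[i] - keep_mz[n] < tol) {
      if (peaks$intensity[i] > keep_int[n]) {
        keep_mz[n] <- peaks$mz[i]
        keep_int[n] <- peaks$intensity[i]
      }
    } else {
      keep_mz <- c(keep_mz, peaks$mz[i])
      keep_int <- c(keep_int, peaks$intensity[i])
    }
  }
  data.frame(mz = keep_mz, intensity = keep_int)
}

#' Merge collision-energy levels of a predicted spectrum
#'
#' In silico fragmenters emit one spectrum per collision energy; library
#' records merge a chosen subset of energies (by default 10 and 20 eV,
#' emulating the collision-energy spread of DDA/DIA acquisition, while a
#' high-energy 40 eV level is left out to avoid unspecific low-mass
#' fragments). Peaks from the included levels are unioned; peaks closer
#' than `tol` collapse to the most intense member.
#'
#' @param spectra List of [spectrum_record()]s of the same compound and
#'   adduct at distinct collision energies.
#' @param include Numeric vector of collision energies to keep.
#' @param tol Peak-merge tolerance in Da (default 5 mDa, the MS2 match
#'   tolerance).
#' @return A single merged [spectrum_record()] with `energy = include`.
#' @export
merge_energy_levels <- function(spectra, include = c(10, 20), tol = 0.005) {
  stopifnot(length(spectra) > 0L)
  ids <- unique(vapply(spectra, function(s) s$compound_id, character(1)))
  adducts <- unique(vapply(spectra, function(s) s$adduct$name, character(1)))
  if (length(ids) != 1L || length(adducts) != 1L) {
    stop("all spectra must share compound_id and adduct", call. = FALSE)
  }
  kept <- Filter(function(s) any(s$energy %in% include), spectra)
  if (length(kept) == 0L) {
    stop("no spectrum at the requested collision energies", call. = FALSE)
  }
  peaks <- merge_peaks(do.call(rbind, lapply(kept, function(s) s$peaks)), tol)
  template <- kept[[1]]
  spectrum_record(
    compound_id = template$compound_id, adduct = template$adduct,
    precursor_mz = max(vapply(kept, function(s) s$precursor_mz, numeric(1))),
    peaks = peaks, energy = sort(include), tentative = template$tentative,
    formula = template$formula, parent_id = template$parent_id, ms2_tol = tol
  )
}

#' Synthesize the spectrum of a tentative-structure candidate
#'
#' Tentative candidates (known formula, unknown site of metabolism) have
#' no structure to fragment in silico. Their library spectrum is built by
#' fragment transplantation: the parent's fragments are kept verbatim,
#' the parent's own precursor ion is appended as an additional fragment
#' (conjugates commonly cleave the conjugated moiety, regenerating the
#' parent ion), and the record precursor is shifted to the candidate's
#' adduct m/z.
#'
#' @param parent_record Merged [spectrum_record()] of the candidate's
#'   parent compound.
#' @param candidate One candidate row (must have `source == "CMP"`).
#' @param adduct Adduct for the synthesized precursor (defaults to the
#'   parent record's adduct).
#' @return A tentative [spectrum_record()] with one extra peak.
#' @export
synthesize_tentative_spectrum <- function(parent_record, candidate,
                                          adduct = parent_record$adduct) {
  if (is.character(adduct)) adduct <- adduct_spec(adduct)
  if (!identical(candidate$source, "CMP")) {
    stop("candidate '", candidate$id, "' has an exact structure; ",
         "use its own predicted spectrum instead", call. = FALSE)
  }
  if (!identical(candidate$parent_id, parent_record$compound_id)) {
    stop("parent record '", parent_record$compound_id,
         "' does not belong to candidate '", candidate$id, "'",
         call. = FALSE)
  }
  frag_int <- if (nrow(parent_record$peaks) > 0L) {
    max(parent_record$peaks$intensity)
  } else {
    100
  }
  peaks <- rbind(parent_record$peaks,
                 data.frame(mz = parent_record$precursor_mz,
                            intensity = frag_int))
  spectrum_record(
    compound_id = candidate$id, adduct = adduct,
    precursor_mz = adduct_mz(candidate$neutral_mass, adduct),
    peaks = peaks, energy = parent_record$energy, tentative = TRUE,
    formula = candidate$formula, parent_id = candidate$parent_id
  )
}

#' Build a spectral library for one polarity
#'
#' Exact-structure candidates (SP/LS) use their own collision-energy
#' merged spectra; tentative candidates (CMP) use
#' [synthesize_tentative_spectrum()] from their parent's spectrum.
#' Candidates with no usable spectrum source are skipped and listed in
#' the `"skipped"` attribute.
#'
#' @param candidates Candidate data frame.
#' @param parent_spectra Named list, parent id to merged
#'   [spectrum_record()] in the requested polarity.
#' @param exact_spectra Named list, candidate id to merged
#'   [spectrum_record()] (for SP/LS candidates).
#' @param polarity `"positive"` or `"negative"`.
#' @return A `"spectral_library"`: list with `polarity` and `records`
#'   (named list of records, in candidate order).
#' @export
build_library <- function(candidates, parent_spectra,
                          exact_spectra = list(),
                          polarity = c("positive", "negative")) {
  polarity <- match.arg(polarity)
  adduct <- adduct_spec(if (polarity == "positive") "[M+H]+" else "[M-H]-")
  records <- list()
  skipped <- character(0)
  for (i in seq_len(nrow(candidates))) {
    cand <- candidates[i, ]
    rec <- NULL
    if (cand$source != "CMP" && !is.null(exact_spectra[[cand$id]])) {
      base <- exact_spectra[[cand$id]]
      rec <- spectrum_record(
        compound_id = cand$id, adduct = adduct,
        precursor_mz = adduct_mz(cand$neutral_mass, adduct),
        peaks = base$peaks, energy = base$energy, tentative = FALSE,
        formula = cand$formula, parent_id = cand$parent_id
      )
    } else if (cand$source == "CMP" &&
               !is.null(parent_spectra[[cand$parent_id]])) {
      rec <- synthesize_tentative_spectrum(parent_spectra[[cand$parent_id]],
                                           cand, adduct)
    }
    if (is.null(rec)) {
      skipped <- c(skipped, cand$id)
    } else {
      if (!is.null(records[[cand$id]])) {
        stop("duplicate compound id in library: '", cand$id, "'",
             call. = FALSE)
      }
      records[[cand$id]] <- rec
    }
  }
  structure(list(polarity = polarity, records = records,
                 skipped = skipped),
            class = "spectral_library")
}

#' @export
print.spectral_library <- function(x, ...) {
  cat(sprintf("<spectral_library> %s, %d records (%d tentative)\n",
              x$polarity, length(x$records),
              sum(vapply(x$records, function(r) r$tentative, logical(1)))))
  invisible(x)
}

#' Write a spectral library as MSP
#'
#' MSP dialect: `NAME`, `PRECURSORMZ`, `PRECURSORTYPE`, `IONMODE`,
#' `FORMULA`, `COMMENT`, `Num Peaks`, then tab-separated
#' `mz<TAB>intensity` lines, with a blank line between records.
#' Intensities are normalized to a maximum of 100 on write.
#'
#' @param library A `"spectral_library"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_msp <- function(library, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (rec in library$records) {
    peaks <- rec$peaks
    if (nrow(peaks) > 0L && max(peaks$intensity) > 0) {
      peaks$intensity <- peaks$intensity / max(peaks$intensity) * 100
    }
    comment <- paste0(
      if (rec$tentative) "Tentative=true" else "Tentative=false",
      if (length(rec$energy) > 0L) {
        paste0("; CE=", paste(rec$energy, collapse = ","))
      } else {
        ""
      })
    writeLines(c(
      paste0("NAME: ", rec$compound_id),
      sprintf("PRECURSORMZ: %.5f", rec$precursor_mz),
      paste0("PRECURSORTYPE: ", rec$adduct$name),
      paste0("IONMODE: ",
             if (rec$polarity == "positive") "Positive" else "Negative"),
      paste0("FORMULA: ",
             if (is.na(rec$formula)) "" else rec$formula),
      paste0("COMMENT: ", comment),
      paste0("Num Peaks: ", nrow(peaks)),
      if (nrow(peaks) > 0L) {
        sprintf("%.5f\t%.5f", peaks$mz, peaks$intensity)
      },
      ""
    ), con)
  }
  invisible(path)
}

#' Read an MSP spectral library
#'
#' Parses the dialect written by [write_msp()]. A `COMMENT: CE=<eV>` key
#' carries the collision energy of energy-resolved input spectra;
#' `Tentative=true` marks precursor-shifted records. Malformed records
#' (missing `PRECURSORMZ`, peak-count mismatch) are rejected with the
#' offending line number.
#'
#' @param path Path to an MSP file.
#' @param validate_unique Require compound id + adduct to be unique
#'   (disable for collision-energy-resolved inputs that repeat names).
#' @return A `"spectral_library"`; polarity is taken from the records
#'   (`"mixed"` if both occur).
#' @export
read_msp <- function(path, validate_unique = TRUE) {
  lines <- readLines(path)
  records <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    while (i <= n && !nzchar(trimws(lines[i]))) i <- i + 1L
    if (i > n) break
    start <- i
    fields <- list()
    peaks_expected <- NA_integer_
    while (i <= n && nzchar(trimws(lines[i]))) {
      line <- lines[i]
      if (grepl("^Num Peaks:", line, ignore.case = TRUE)) {
        peaks_expected <- as.integer(trimws(sub("^Num Peaks:", "", line,
                                                ignore.case = TRUE)))
        i <- i + 1L
        break
      }
      colon <- regexpr(":", line, fixed = TRUE)
      if (colon < 0L) {
        stop("malformed MSP header at line ", i, ": '", line, "'",
             call. = FALSE)
      }
      key <- toupper(trimws(substr(line, 1L, colon - 1L)))
      fields[[key]] <- trimws(substring(line, colon + 1L))
      i <- i + 1L
    }
    if (is.na(peaks_expected)) {
      stop("record starting at line ", start, " has no 'Num Peaks' header",
           call. = FALSE)
    }
    if (is.null(fields$PRECURSORMZ)) {
      stop("record starting at line ", start, " is missing PRECURSORMZ",
           call. = FALSE)
    }
    peak_lines <- character(0)
    while (i <= n && nzchar(trimws(lines[i]))) {
      peak_lines <- c(peak_lines, lines[i])
      i <- i + 1L
    }
    if (length(peak_lines) != peaks_expected) {
      stop("record starting at line ", start, ": 'Num Peaks: ",
           peaks_expected, "' but ", length(peak_lines),
           " peak line(s) found (near line ", i - 1L, ")", call. = FALSE)
    }
    parts <- strsplit(peak_lines, "[\t ]+")
    peaks <- data.frame(
      mz = vapply(parts, function(p) as.numeric(p[1]), numeric(1)),
      intensity = vapply(parts, function(p) as.numeric(p[2]), numeric(1))
    )
    if (anyNA(peaks)) {
      stop("unparseable peak line in record starting at line ", start,
           call. = FALSE)
    }
    adduct_name <- fields$PRECURSORTYPE
    if (is.null(adduct_name)) {
      ionmode <- toupper(fields$IONMODE %||% "POSITIVE")
      adduct_name <- if (startsWith(ionmode, "N")) "[M-H]-" else "[M+H]+"
    }
    comment <- fields$COMMENT %||% ""
    ce <- numeric(0)
    ce_match <- regmatches(comment, regexpr("CE=[0-9.,]+", comment))
    if (length(ce_match) == 1L) {
      ce <- as.numeric(strsplit(sub("CE=", "", ce_match), ",")[[1]])
    }
    tentative <- grepl("Tentative=true", comment, ignore.case = TRUE)
    records[[length(records) + 1L]] <- spectrum_record(
      compound_id = fields$NAME %||% paste0("record_", length(records) + 1L),
      adduct = adduct_name,
      precursor_mz = as.numeric(fields$PRECURSORMZ),
      peaks = peaks, energy = ce, tentative = tentative,
      formula = if (is.null(fields$FORMULA) || !nzchar(fields$FORMULA)) {
        NA_character_
      } else {
        fields$FORMULA
      }
    )
  }
  polarity <- unique(vapply(records, function(r) r$polarity, character(1)))
  if (length(polarity) != 1L) {
    polarity <- if (length(polarity) == 0L) "positive" else "mixed"
  }
  if (validate_unique) {
    keys <- vapply(records, function(r) {
      paste(r$compound_id, r$adduct$name)
    }, character(1))
    if (anyDuplicated(keys)) {
      stop("duplicate compound id + adduct in MSP file: ",
           keys[duplicated(keys)][1], call. = FALSE)
    }
    names(records) <- vapply(records, function(r) r$compound_id, character(1))
  }
  structure(list(polarity = polarity, records = records,
                 skipped = character(0)),
            class = "spectral_library")
}

#' Load collision-energy-resolved spectra and merge per compound
#'
#' Reads an MSP file holding one record per (compound, collision energy)
#' and returns one merged record per compound.
#'
#' @param path MSP path.
#' @param include Collision energies to merge (default 10 and 20 eV).
#' @param tol Peak-merge tolerance in Da.
#' @return Named list of merged [spectrum_record()]s.
#' @export
load_energy_resolved_spectra <- function(path, include = c(10, 20),
                                         tol = 0.005) {
  lib <- read_msp(path, validate_unique = FALSE)
  ids <- vapply(lib$records, function(r) r$compound_id, character(1))
  out <- lapply(split(lib$records, ids), merge_energy_levels,
                include = include, tol = tol)
  out[unique(ids)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
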