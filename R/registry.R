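#' Read a parent-compound table
#'
#' Parents are the administered drugs whose metabolites are screened for.
#' The table is UTF-8 TSV with a header; required columns `id`, `name`,
#' `formula` (Hill notation); optional `smiles`, `drug_class`, `rt`
#' (minutes, used by the simulator). The neutral monoisotopic mass and
#' both adduct m/z values are derived on read.
#'
#' @param path Path to the TSV file. Defaults to the packaged registry of
#'   the six study pharmaceuticals.
#' @return A data frame with one row per parent and derived columns
#'   `neutral_mass`, `mz_pos`, `mz_neg`.
#' @export
read_parent_table <- function(path = system.file("extdata", "parents.tsv",
                                                 package = "metidscreen")) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("id", "name", "formula")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("parent table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(df$id)) {
    stop("parent ids must be unique", call. = FALSE)
  }
  if (is.null(df$smiles)) df$smiles <- NA_character_
  if (is.null(df$drug_class)) df$drug_class <- NA_character_
  df$neutral_mass <- vapply(df$formula, monoisotopic_mass, numeric(1))
  df$mz_pos <- adduct_mz(df$neutral_mass, "[M+H]+")
  df$mz_neg <- adduct_mz(df$neutral_mass, "[M-H]-")
  df
}

#' Read a biotransformation reaction library
#'
#' Each reaction is a signed elemental-formula delta (e.g. `"+C6H10O5"`
#' for glucose conjugation, `"-H2O"` for dehydration, `"+C6H10O5 +C3H2O3"`
#' for glucose plus malonic acid). The packaged default library holds 144
#' pathways: phase I transformations, phase II conjugations, and pairwise
#' combinations.
#'
#' @param path Path to a TSV with columns `id`, `label`, `phase`, `delta`.
#'   Defaults to the packaged library.
#' @return A data frame with the derived signed `mass_delta` (Da).
#' @export
read_reaction_table <- function(path = system.file("extdata",
                                                   "reactions_cmp.tsv",
                                                   package = "metidscreen")) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("id", "label", "phase", "delta")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("reaction table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(df$id)) {
    stop("reaction ids must be unique", call. = FALSE)
  }
  df$mass_delta <- vapply(df$delta, monoisotopic_mass, numeric(1))
  df
}

#' The packaged common-metabolic-pathway library
#'
#' Convenience wrapper around [read_reaction_table()] for the packaged
#' 144-entry reaction library.
#'
#' @return Reaction data frame (144 rows).
#' @export
cmp_reactions <- function() {
  read_reaction_table()
}

empty_candidates <- function() {
  data.frame(
    id = character(0), parent_id = character(0), source = character(0),
    smiles = character(0), formula = character(0),
    neutral_mass = numeric(0), reaction_id = character(0),
    reaction_label = character(0), isomer_key = character(0),
    mz_pos = numeric(0), mz_neg = numeric(0), stringsAsFactors = FALSE)
}

candidate_row <- function(id, parent_id, source, smiles, counts,
                          neutral_mass, reaction_id = NA_character_,
                          reaction_label = NA_character_) {
  formula <- formula_string(counts)
  data.frame(
    id = id, parent_id = parent_id, source = source,
    smiles = if (is.na(smiles) || !nzchar(smiles)) NA_character_ else smiles,
    formula = formula, neutral_mass = neutral_mass,
    reaction_id = reaction_id, reaction_label = reaction_label,
    isomer_key = paste(parent_id, formula, sep = ":"),
    mz_pos = adduct_mz(neutral_mass, "[M+H]+"),
    mz_neg = adduct_mz(neutral_mass, "[M-H]-"),
    stringsAsFactors = FALSE
  )
}

#' Apply one reaction to one parent compound
#'
#' Forms a tentative-structure candidate metabolite: the candidate formula
#' is the elementwise sum of the parent formula and the reaction delta,
#' and the neutral mass is the parent mass plus the reaction mass delta.
#' A loss reaction that would remove atoms the parent does not carry
#' (any negative element count in the result) is rejected, not clamped.
#'
#' @param parent One row of a parent table (data frame or list).
#' @param reaction One row of a reaction table.
#' @return A one-row candidate data frame (source `"CMP"`, no SMILES).
#'   Rejections signal an error of class `"metidscreen_rejection"` naming
#'   the parent and reaction.
#' @export
apply_reaction <- function(parent, reaction) {
  counts <- formula_add(parse_formula(parent$formula),
                        parse_delta(reaction$delta))
  if (any(counts < 0L)) {
    neg <- names(counts)[counts < 0L]
    stop(structure(
      class = c("metidscreen_rejection", "error", "condition"),
      list(message = sprintf(
             "reaction %s (%s) is not applicable to parent %s: negative count for %s",
             reaction$id, reaction$label, parent$id,
             paste(neg, collapse = ", ")),
           call = NULL,
           parent_id = parent$id, reaction_id = reaction$id)))
  }
  mass <- parent$neutral_mass + reaction$mass_delta
  candidate_row(
    id = paste(parent$name, reaction$id, sep = "-"),
    parent_id = parent$id, source = "CMP", smiles = NA_character_,
    counts = counts, neutral_mass = mass,
    reaction_id = reaction$id, reaction_label = reaction$label
  )
}

#' Enumerate common-metabolic-pathway candidates
#'
#' Applies every reaction to every parent (parent order times reaction
#' order, deterministically). Pairs whose resulting formula would carry a
#' negative element count are skipped and recorded in the `"rejections"`
#' attribute of the result rather than aborting the enumeration.
#'
#' @param parents Parent table from [read_parent_table()].
#' @param reactions Reaction table from [read_reaction_table()].
#' @return Candidate data frame, one row per accepted (parent, reaction)
#'   pair; `attr(, "rejections")` is a data frame of skipped pairs.
#' @export
enumerate_cmp <- function(parents, reactions) {
  stopifnot(nrow(parents) > 0L)
  out <- vector("list", nrow(parents) * nrow(reactions))
  rej <- list()
  k <- 0L
  for (i in seq_len(nrow(parents))) {
    parent <- parents[i, ]
    for (j in seq_len(nrow(reactions))) {
      reaction <- reactions[j, ]
      cand <- tryCatch(apply_reaction(parent, reaction),
                       metidscreen_rejection = function(e) e)
      if (inherits(cand, "metidscreen_rejection")) {
        rej[[length(rej) + 1L]] <- data.frame(
          parent_id = cand$parent_id, reaction_id = cand$reaction_id,
          reason = conditionMessage(cand), stringsAsFactors = FALSE)
      } else {
        k <- k + 1L
        out[[k]] <- cand
      }
    }
  }
  candidates <- if (k > 0L) {
    do.call(rbind, out[seq_len(k)])
  } else {
    empty_candidates()
  }
  attr(candidates, "rejections") <- if (length(rej) > 0L) {
    do.call(rbind, rej)
  } else {
    data.frame(parent_id = character(0), reaction_id = character(0),
               reason = character(0), stringsAsFactors = FALSE)
  }
  candidates
}

#' Ingest an externally predicted or literature candidate table
#'
#' Software-predicted (SP) and literature-search (LS) candidates come
#' with exact structures. Each row needs `name`, `parent_id`, and either
#' a `formula` or a `smiles` (the formula is derived from the SMILES when
#' absent). Duplicated names receive distinct ids but share an isomer
#' group key.
#'
#' @param rows Data frame with columns `name`, `parent_id`, and
#'   `formula` and/or `smiles`.
#' @param source `"SP"` or `"LS"`.
#' @return Candidate data frame in the same layout as [enumerate_cmp()].
#' @export
ingest_candidate_table <- function(rows, source = c("SP", "LS")) {
  source <- match.arg(source)
  if (is.character(rows) && length(rows) == 1L) {
    rows <- utils::read.delim(rows, stringsAsFactors = FALSE)
  }
  if (nrow(rows) == 0L) {
    return(empty_candidates())
  }
  missing <- setdiff(c("name", "parent_id"), names(rows))
  if (length(missing) > 0L) {
    stop("candidate table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (is.null(rows$formula)) rows$formula <- NA_character_
  if (is.null(rows$smiles)) rows$smiles <- NA_character_
  ids <- make.unique(rows$name, sep = "_")
  out <- vector("list", nrow(rows))
  for (i in seq_len(nrow(rows))) {
    formula <- rows$formula[i]
    smiles <- rows$smiles[i]
    if (is.na(formula) || !nzchar(formula)) {
      if (is.na(smiles) || !nzchar(smiles)) {
        stop("candidate row ", i, " ('", rows$name[i],
             "') has neither a formula nor a SMILES", call. = FALSE)
      }
      formula <- smiles_to_formula(smiles)
    }
    counts <- parse_formula(formula)
    out[[i]] <- candidate_row(
      id = ids[i], parent_id = rows$parent_id[i], source = source,
      smiles = smiles, counts = counts,
      neutral_mass = monoisotopic_mass(counts)
    )
  }
  do.call(rbind, out)
}

#' Filter candidates by an upper adduct m/z cutoff
#'
#' Mirrors the scan-range decision of the study design: candidates whose
#' precursor would fall at or above the instrument's upper scan limit are
#' dropped before library building (default cutoff 800, the upper end of
#' the m/z 60-800 scan range).
#'
#' @param candidates Candidate data frame.
#' @param cutoff Upper m/z bound (exclusive).
#' @param adduct Adduct used for the comparison (default `"[M+H]+"`).
#' @return The retained candidate rows, order preserved.
#' @export
mz_cutoff_filter <- function(candidates, cutoff = 800, adduct = "[M+H]+") {
  if (is.character(adduct)) adduct <- adduct_spec(adduct)
  mz <- adduct_mz(candidates$neutral_mass, adduct)
  candidates[mz < cutoff, , drop = FALSE]
}

#' Three-source overlap by isomer group
#'
#' Exact-structure sources (SP, LS) distinguish structural isomers, while
#' tentative pathway candidates (CMP) do not; for a like-for-like Venn
#' comparison every candidate is collapsed to its isomer group key
#' (parent id plus canonical formula) before intersecting the sources.
#'
#' @param sp,ls,cmp Candidate data frames (any may be empty).
#' @return List with `regions` (named counts of the seven Venn regions),
#'   `structures` (raw per-source structure counts before grouping) and
#'   `groups` (per-source isomer-group counts).
#' @export
venn_by_isomer_group <- function(sp, ls, cmp) {
  key <- function(x) unique(x$isomer_key)
  s <- key(sp); l <- key(ls); c_ <- key(cmp)
  regions <- c(
    SP_only = length(setdiff(s, union(l, c_))),
    LS_only = length(setdiff(l, union(s, c_))),
    CMP_only = length(setdiff(c_, union(s, l))),
    SP_LS = length(setdiff(intersect(s, l), c_)),
    SP_CMP = length(setdiff(intersect(s, c_), l)),
    LS_CMP = length(setdiff(intersect(l, c_), s)),
    SP_LS_CMP = length(intersect(intersect(s, l), c_))
  )
  list(
    regions = regions,
    structures = c(SP = nrow(sp), LS = nrow(ls), CMP = nrow(cmp)),
    groups = c(SP = length(s), LS = length(l), CMP = length(c_))
  )
}

#' Write a candidate table to TSV
#'
#' @param candidates Candidate data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_candidate_table <- function(candidates, path) {
  out <- candidates[, c("id", "parent_id", "source", "formula", "smiles",
                        "neutral_mass", "mz_pos", "mz_neg")]
  out$neutral_mass <- sprintf("%.5f", out$neutral_mass)
  out$mz_pos <- sprintf("%.5f", out$mz_pos)
  out$mz_neg <- sprintf("%.5f", out$mz_neg)
  out$smiles[is.na(out$smiles)] <- ""
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
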