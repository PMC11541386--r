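# Mass of a hydrogen atom. Adduct shifts use the hydrogen-atom convention
# (no electron-mass correction): [M+H]+ = M + 1.00783, [M-H]- = M - 1.00783.
hydrogen_mass <- 1.0078250

#' Adduct specification
#'
#' The package works with singly charged protonated/deprotonated adducts,
#' the precursor species of electrospray suspect screening. Shifts follow
#' the hydrogen-atom-mass convention (1.00783 Da, no electron correction),
#' which is the arithmetic behind all library precursor values.
#'
#' @param name `"[M+H]+"` or `"[M-H]-"` (a Unicode minus is accepted).
#' @return A list with fields `name`, `polarity` (`"positive"` /
#'   `"negative"`), `shift` (Da, signed) and `charge` (+1 / -1), of class
#'   `"adduct_spec"`.
#' @export
#' @examples
#' adduct_spec("[M+H]+")$shift
adduct_spec <- function(name) {
  name <- gsub("−", "-", name)
  name <- gsub(" ", "", name)
  spec <- switch(name,
    "[M+H]+" = list(name = "[M+H]+", polarity = "positive",
                    shift = +hydrogen_mass, charge = +1L),
    "[M-H]-" = list(name = "[M-H]-", polarity = "negative",
                    shift = -hydrogen_mass, charge = -1L),
    stop("unsupported adduct: '", name,
         "' (expected \"[M+H]+\" or \"[M-H]-\")", call. = FALSE)
  )
  structure(spec, class = "adduct_spec")
}

#' Adduct m/z of a neutral mass
#'
#' @param neutral_mass Neutral monoisotopic mass in Da (non-negative).
#' @param adduct An [adduct_spec()] or an adduct name string.
#' @return m/z of the singly charged adduct ion.
#' @export
#' @examples
#' adduct_mz(253.05211, "[M+H]+")  # 254.05994
adduct_mz <- function(neutral_mass, adduct) {
  if (is.character(adduct)) adduct <- adduct_spec(adduct)
  stopifnot(inherits(adduct, "adduct_spec"))
  if (any(neutral_mass < 0)) {
    stop("neutral_mass must be non-negative", call. = FALSE)
  }
  neutral_mass + adduct$shift
}

# polarity ("positive"/"negative") implied by an acquisition-mode token
# such as "DDA+", "DIA-".
mode_polarity <- function(acquisition_mode) {
  mode <- gsub("−", "-", acquisition_mode)
  ifelse(endsWith(mode, "+"), "positive",
         ifelse(endsWith(mode, "-"), "negative", NA_character_))
}
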