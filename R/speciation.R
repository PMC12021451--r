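# Ionization-state math for weak acids and bases: fraction neutral at a
# given pH (Henderson-Hasselbalch) and the log D transform of log P.

.compound_classes <- c("PA", "PANO", "reference")
.ester_types <- c("monoester", "cyclic_diester", "open_chained_diester", "none")
.acid_base_classes <- c("acid", "base", "neutral", "zwitterion")

#' Construct an ionizable compound
#'
#' Bundles the identity and ionization properties of a compound: its class
#' (pyrrolizidine alkaloid `"PA"`, its N-oxide `"PANO"`, or `"reference"`),
#' ester type, acid/base character and, where the compound is ionizable,
#' its single most relevant pKa (the strongest basic or most acidic centre).
#'
#' @param name Compound name (scalar character).
#' @param compound_class One of `"PA"`, `"PANO"`, `"reference"`.
#' @param ester_type One of `"monoester"`, `"cyclic_diester"`,
#'   `"open_chained_diester"`, `"none"`.
#' @param acid_base One of `"acid"`, `"base"`, `"neutral"`, `"zwitterion"`.
#' @param pka Acid dissociation constant (dimensionless). Required for
#'   acids, bases and zwitterions; ignored (set to `NA`) for neutrals.
#'
#' @return An object of class `ionizable_compound`.
#' @examples
#' heliotrine_like <- ionizable_compound("example PA", "PA", "monoester",
#'                                       "base", pka = 6)
#' fraction_neutral(heliotrine_like, ph = 7.4)
#' @export
ionizable_compound <- function(name,
                               compound_class = c("reference", "PA", "PANO"),
                               ester_type = c("none", "monoester",
                                              "cyclic_diester",
                                              "open_chained_diester"),
                               acid_base = c("neutral", "acid", "base",
                                             "zwitterion"),
                               pka = NA_real_) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  compound_class <- match.arg(compound_class)
  ester_type <- match.arg(ester_type)
  acid_base <- match.arg(acid_base)
  pka <- suppressWarnings(as.numeric(pka))
  needs_pka <- acid_base %in% c("acid", "base", "zwitterion")
  if (needs_pka && (length(pka) != 1L || !is.finite(pka))) {
    pa_error(sprintf("pKa is required for %s '%s' but is missing",
                     acid_base, name),
             "papartition_config_error")
  }
  if (!needs_pka) pka <- NA_real_
  structure(
    list(name = name, compound_class = compound_class,
         ester_type = ester_type, acid_base = acid_base, pka = pka),
    class = "ionizable_compound"
  )
}

#' @export
print.ionizable_compound <- function(x, ...) {
  cat(sprintf("<ionizable_compound> %s (%s, %s)\n  acid/base: %s%s\n",
              x$name, x$compound_class, x$ester_type, x$acid_base,
              if (is.finite(x$pka)) sprintf(", pKa = %g", x$pka) else ""))
  invisible(x)
}

check_ph <- function(ph) {
  if (!is_scalar_number(ph) || ph < 0 || ph > 14) {
    pa_error("pH must be a single number in [0, 14]",
             "papartition_usage_error")
  }
  ph
}

check_compound <- function(compound) {
  if (!inherits(compound, "ionizable_compound")) {
    pa_error("expected an `ionizable_compound` object",
             "papartition_usage_error")
  }
  compound
}

#' Fraction of a compound in its neutral form at a given pH
#'
#' Henderson-Hasselbalch speciation of a monoprotic weak acid or base:
#' for a base the neutral fraction is \eqn{1 / (1 + 10^{pKa - pH})}, for
#' an acid \eqn{1 / (1 + 10^{pH - pKa})}; a declared-neutral compound is
#' entirely neutral at any pH. Zwitterions need a two-pKa treatment that
#' the single-pKa model cannot express and are rejected.
#'
#' @param compound An [ionizable_compound()].
#' @param ph pH of the aqueous phase, in \[0, 14\].
#'
#' @return An object of class `speciation_result`: a list with `ph`,
#'   `fraction_neutral` and `fraction_ionized` (the two fractions sum
#'   to one).
#' @examples
#' b <- ionizable_compound("weak base", acid_base = "base", pka = 6)
#' fraction_neutral(b, 7.4)$fraction_neutral  # ~0.96
#' @export
fraction_neutral <- function(compound, ph) {
  check_compound(compound)
  check_ph(ph)
  if (compound$acid_base == "zwitterion") {
    pa_error(sprintf(
      "speciation of zwitterion '%s' is unsupported (single-pKa model)",
      compound$name), "papartition_unsupported_error")
  }
  fn <- switch(compound$acid_base,
               neutral = 1,
               base = 1 / (1 + 10^(compound$pka - ph)),
               acid = 1 / (1 + 10^(ph - compound$pka)))
  structure(list(ph = ph, fraction_neutral = fn, fraction_ionized = 1 - fn),
            class = "speciation_result")
}

#' @export
print.speciation_result <- function(x, ...) {
  cat(sprintf("<speciation_result> pH %.2f: %.3f neutral, %.3f ionized\n",
              x$ph, x$fraction_neutral, x$fraction_ionized))
  invisible(x)
}

#' Distribution coefficient log D at a given pH
#'
#' Transforms the partition coefficient of the neutral species into the
#' pH-dependent distribution coefficient,
#' \deqn{\log D(pH) = \log P - \log_{10}(1 + 10^{(pH - pKa)\,\Delta i}),}
#' with \eqn{\Delta i = 1} for acids and \eqn{\Delta i = -1} for bases,
#' under the assumption that only the neutral species partitions into the
#' organic phase. For declared-neutral compounds log D equals log P at
#' every pH; zwitterions are rejected (see [fraction_neutral()]).
#'
#' @param log_p log10 n-octanol:water partition coefficient of the
#'   neutral species.
#' @inheritParams fraction_neutral
#'
#' @return Scalar log D (dimensionless).
#' @examples
#' b <- ionizable_compound("weak base", acid_base = "base", pka = 6)
#' log_d(-1.26, b, ph = 7.4)  # -1.277: nearly fully neutral
#' @export
log_d <- function(log_p, compound, ph) {
  if (!is_scalar_number(log_p)) {
    pa_error("`log_p` must be a single finite number",
             "papartition_usage_error")
  }
  check_compound(compound)
  check_ph(ph)
  if (compound$acid_base == "neutral") return(log_p)
  if (compound$acid_base == "zwitterion") {
    pa_error(sprintf(
      "log D of zwitterion '%s' is unsupported (single-pKa model)",
      compound$name), "papartition_unsupported_error")
  }
  delta_i <- if (compound$acid_base == "acid") 1 else -1
  log_p - log10(1 + 10^((ph - compound$pka) * delta_i))
}
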