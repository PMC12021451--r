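# In-silico blood-to-plasma ratio prediction: the acid/base
# classification rule and the mechanistic erythrocyte-composition model.

#' Blood composition parameters for the mechanistic Rb model
#'
#' Hematocrit plus the volume fractions of red-blood-cell water, lipids
#' and proteins and the water-protein partition constant. The defaults
#' are representative values for human erythrocytes (water 0.63, lipids
#' 0.005, protein 0.33, hematocrit 0.45) with a modest water-protein
#' partition constant of 0.2; all are plain numbers a user can override,
#' e.g. from a YAML file via [read_blood_params()].
#'
#' @param hct Hematocrit, volume fraction of whole blood in (0, 1).
#' @param f_rbc_water,f_rbc_lipids,f_rbc_prot Volume fractions of the
#'   red blood cell that are water, lipids and proteins; each in
#'   \[0, 1\], summing to at most 1.
#' @param k_prot Water-protein partition coefficient (>= 0).
#' @param ionization_correction If `TRUE`, the lipid term of
#'   [k_rbc_pla()] is scaled by the neutral fraction of the compound at
#'   the prediction pH (a physically motivated variant); the default
#'   `FALSE` uses the full `10^logP` lipid affinity.
#'
#' @return List of class `blood_params`.
#' @export
blood_params <- function(hct = 0.45, f_rbc_water = 0.63,
                         f_rbc_lipids = 0.005, f_rbc_prot = 0.33,
                         k_prot = 0.2, ionization_correction = FALSE) {
  for (nm in c("hct", "f_rbc_water", "f_rbc_lipids", "f_rbc_prot",
               "k_prot")) {
    v <- get(nm)
    if (!is_scalar_number(v) || v < 0) {
      pa_error(sprintf("`%s` must be a single nonnegative number", nm),
               "papartition_config_error")
    }
  }
  if (hct <= 0 || hct >= 1) {
    pa_error("`hct` must lie strictly between 0 and 1",
             "papartition_config_error")
  }
  if (f_rbc_water + f_rbc_lipids + f_rbc_prot > 1 + 1e-6) {
    pa_error("red-blood-cell volume fractions sum to more than 1",
             "papartition_config_error")
  }
  structure(list(hct = hct, f_rbc_water = f_rbc_water,
                 f_rbc_lipids = f_rbc_lipids, f_rbc_prot = f_rbc_prot,
                 k_prot = k_prot,
                 ionization_correction = isTRUE(ionization_correction)),
            class = "blood_params")
}

#' @export
print.blood_params <- function(x, ...) {
  cat(sprintf(
    "<blood_params> hct %.3g; rbc fractions water %.3g, lipids %.3g, protein %.3g; K_prot %.3g%s\n",
    x$hct, x$f_rbc_water, x$f_rbc_lipids, x$f_rbc_prot, x$k_prot,
    if (x$ionization_correction) "; ionization-corrected lipid term" else ""))
  invisible(x)
}

#' Read blood composition parameters from a YAML file
#'
#' @param path YAML file with any of the keys accepted by
#'   [blood_params()]; unspecified keys keep their defaults.
#'
#' @return A `blood_params` object.
#' @export
read_blood_params <- function(path) {
  if (!file.exists(path)) {
    pa_error(sprintf("blood-parameter file not found: %s", path),
             "papartition_io_error")
  }
  vals <- yaml::read_yaml(path)
  known <- names(formals(blood_params))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    warning(sprintf("ignoring unknown blood-parameter key(s): %s",
                    paste(unknown, collapse = ", ")))
    vals <- vals[intersect(names(vals), known)]
  }
  do.call(blood_params, vals)
}

#' Packaged default blood composition parameters
#'
#' Reads `extdata/blood_params.yaml`, which holds the package defaults
#' described in [blood_params()].
#'
#' @return A `blood_params` object.
#' @export
default_blood_params <- function() {
  read_blood_params(extdata_path("blood_params.yaml"))
}

#' Effective acid/base class of a compound at a given pH
#'
#' A declared base whose ionized fraction at `ph` falls below
#' `ionized_cutoff` (default 1%) behaves as a neutral for blood
#' partitioning purposes and is reclassified accordingly; every other
#' declaration stands. At physiological pH 7.4 this classifies the
#' weakly basic alkaloids as bases and their N-oxides (protonated only
#' under acidic conditions) as neutrals.
#'
#' @inheritParams fraction_neutral
#' @param ionized_cutoff Minimum ionized fraction for a base to remain
#'   classified as a base (default 0.01).
#'
#' @return One of `"acid"`, `"base"`, `"neutral"`, `"zwitterion"`.
#' @export
classify_at_ph <- function(compound, ph, ionized_cutoff = 0.01) {
  check_compound(compound)
  check_ph(ph)
  if (compound$acid_base != "base") return(compound$acid_base)
  sp <- fraction_neutral(compound, ph)
  if (sp$fraction_ionized < ionized_cutoff) "neutral" else "base"
}

#' Acid/base classification model for Rb
#'
#' In the absence of measurements, Rb is commonly taken as 1 for
#' neutrals and bases and as 1 - hematocrit = 0.55 for acids and
#' zwitterions (which are excluded from the red-blood-cell volume).
#'
#' @param cls Acid/base class, typically from [classify_at_ph()].
#'
#' @return Predicted Rb (1.0 or 0.55).
#' @export
rb_acid_base <- function(cls) {
  cls <- match.arg(cls, .acid_base_classes)
  if (cls %in% c("neutral", "base")) 1.0 else 0.55
}

#' Red-blood-cell to unbound-plasma partition coefficient
#'
#' Mechanistic composition model: the cell is approximated by its water,
#' lipid and protein constituents,
#' \deqn{K_{rbc,pla} = f_{water} + f_{lipids} 10^{\log P} +
#'   f_{prot} K_{prot},}
#' strictly increasing in log P whenever the lipid fraction is positive.
#' When `fraction_neutral < 1` the lipid term is scaled by it (used by
#' [predict_rb_table()] when `ionization_correction` is on).
#'
#' @param log_p log10 octanol:water partition coefficient.
#' @param params A [blood_params()] object.
#' @param fraction_neutral Scaling of the lipid term in \[0, 1\]
#'   (default 1: the neutral-species partition coefficient is used
#'   unmodified).
#'
#' @return Scalar partition coefficient (dimensionless, >= 0).
#' @export
k_rbc_pla <- function(log_p, params, fraction_neutral = 1) {
  stopifnot(inherits(params, "blood_params"))
  if (!is_scalar_number(log_p)) {
    pa_error("`log_p` must be a single finite number",
             "papartition_usage_error")
  }
  params$f_rbc_water +
    params$f_rbc_lipids * fraction_neutral * 10^log_p +
    params$f_rbc_prot * params$k_prot
}

#' Mechanistic blood-to-plasma ratio
#'
#' Whole-blood mass balance over plasma and red blood cells:
#' \deqn{R_b = 1 + hct\,(K_{rbc,pla}\, f_{u,p} - 1).}
#' The limits anchor the model: a compound fully excluded from the cells
#' (K = 0) gives \eqn{R_b = 1 - hct}; equal effective affinity
#' (\eqn{K f_{u,p} = 1}) gives \eqn{R_b = 1}.
#'
#' @param k Red-blood-cell to unbound-plasma partition coefficient,
#'   from [k_rbc_pla()] (>= 0).
#' @param fu_p Fraction unbound in plasma, in (0, 1.2\] (slightly above
#'   1 is tolerated for measured values).
#' @param params A [blood_params()] object (only `hct` is used).
#'
#' @return Predicted Rb (>= 1 - hct).
#' @export
rb_mechanistic <- function(k, fu_p, params) {
  stopifnot(inherits(params, "blood_params"))
  if (!is_scalar_number(k) || k < 0) {
    pa_error("`k` must be a single nonnegative number",
             "papartition_usage_error")
  }
  if (!is_scalar_number(fu_p) || fu_p <= 0 || fu_p > 1.2) {
    pa_error("`fu_p` must be a single number in (0, 1.2]",
             "papartition_usage_error")
  }
  1 + params$hct * (k * fu_p - 1)
}

#' Predict Rb for a set of compounds with both in-silico models
#'
#' Runs the acid/base classification model (needs only the effective
#' class at `ph`) and the mechanistic model (needs log P and fraction
#' unbound in plasma) for every compound. Missing inputs do not abort
#' the run: the affected compound/method pair is recorded in the
#' `errors` attribute and the remaining predictions are produced.
#'
#' @param compounds Registry tibble ([read_compound_registry()]) or a
#'   list of [ionizable_compound()] objects.
#' @param params A [blood_params()] object.
#' @param fu_p Named numeric vector of plasma fraction-unbound values.
#' @param logp Named numeric vector of log P values (typically the
#'   experimental means).
#' @param ph pH at which compounds are classified (default 7.4).
#'
#' @return Tibble with columns `compound`, `quantity` (`"rb"`),
#'   `method` (`"acid_base"` / `"mechanistic"`), `value`; per-compound
#'   failures are collected in `attr(, "errors")` (tibble `compound`,
#'   `method`, `message`).
#' @export
predict_rb_table <- function(compounds, params = default_blood_params(),
                             fu_p = pa_fu_p(), logp = NULL, ph = 7.4) {
  if (is.data.frame(compounds)) {
    compounds <- lapply(compounds$name, compound_from_registry,
                        registry = compounds)
  }
  rows <- list()
  errs <- list()
  for (cmp in compounds) {
    check_compound(cmp)
    cls <- tryCatch(classify_at_ph(cmp, ph), error = function(e) e)
    if (inherits(cls, "error")) {
      errs[[length(errs) + 1L]] <- tibble(
        compound = cmp$name, method = "acid_base",
        message = conditionMessage(cls))
    } else {
      rows[[length(rows) + 1L]] <- tibble(
        compound = cmp$name, quantity = "rb", method = "acid_base",
        value = rb_acid_base(cls))
    }
    lp <- unname(logp[cmp$name])
    fu <- unname(fu_p[cmp$name])
    mech_err <- NULL
    if (length(lp) != 1L || !is.finite(lp)) {
      mech_err <- "log P not available"
    } else if (length(fu) != 1L || !is.finite(fu)) {
      mech_err <- "fu,p not available"
    }
    if (is.null(mech_err)) {
      fn <- if (params$ionization_correction) {
        fraction_neutral(cmp, ph)$fraction_neutral
      } else 1
      val <- tryCatch(
        rb_mechanistic(k_rbc_pla(lp, params, fraction_neutral = fn),
                       fu, params),
        error = function(e) e)
      if (inherits(val, "error")) {
        mech_err <- conditionMessage(val)
      } else {
        rows[[length(rows) + 1L]] <- tibble(
          compound = cmp$name, quantity = "rb", method = "mechanistic",
          value = val)
      }
    }
    if (!is.null(mech_err)) {
      errs[[length(errs) + 1L]] <- tibble(
        compound = cmp$name, method = "mechanistic", message = mech_err)
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "errors") <- if (length(errs) > 0) dplyr::bind_rows(errs) else
    tibble(compound = character(), method = character(),
           message = character())
  out
}

#' Packaged plasma fraction-unbound values of the study compounds
#'
#' Fraction unbound in plasma for the four pyrrolizidine alkaloids and
#' their N-oxides (rapid-equilibrium-dialysis measurements or
#' predictions), as used by the mechanistic Rb model.
#'
#' @return Named numeric vector (names = compound names).
#' @export
pa_fu_p <- function() {
  df <- read.csv(extdata_path("fu_p.csv"), stringsAsFactors = FALSE)
  setNames(df$fu_p, df$compound)
}
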