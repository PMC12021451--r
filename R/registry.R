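# Compound registry: CSV-backed table of compound identities, ester types,
# acid/base character and pKa, with the packaged study compounds as fixture.

#' Read a compound registry CSV
#'
#' The registry holds one row per compound with columns `name`,
#' `compound_class` (`PA`/`PANO`/`reference`), `ester_type`, `acid_base`
#' and `pka` (empty for neutrals). An optional `logp_literature` column
#' carries literature log P values for reference substances. Every
#' N-oxide (`PANO`) must have its parent alkaloid in the registry,
#' resolvable by stripping the `" N-oxide"` suffix from its name.
#'
#' @param path Path to a UTF-8 CSV file with a header row.
#'
#' @return A tibble with one validated row per compound.
#' @seealso [pa_compounds()] for the packaged study compounds,
#'   [compound_from_registry()] to extract one compound as an object.
#' @export
read_compound_registry <- function(path) {
  if (!file.exists(path)) {
    pa_error(sprintf("registry file not found: %s", path),
             "papartition_io_error")
  }
  df <- read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  required <- c("name", "compound_class", "ester_type", "acid_base", "pka")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    pa_error(sprintf("registry is missing column(s): %s",
                     paste(missing_cols, collapse = ", ")),
             "papartition_io_error")
  }
  if (nrow(df) == 0) {
    pa_error("registry contains no compounds", "papartition_io_error")
  }
  df$pka <- suppressWarnings(as.numeric(df$pka))
  for (i in seq_len(nrow(df))) {
    row <- df[i, ]
    if (is.na(row$name) || !nzchar(row$name)) {
      pa_error(sprintf("registry row %d: empty compound name", i),
               "papartition_io_error")
    }
    if (!row$compound_class %in% .compound_classes) {
      pa_error(sprintf("registry row %d (%s): unknown compound_class '%s'",
                       i, row$name, row$compound_class),
               "papartition_io_error")
    }
    if (!row$ester_type %in% .ester_types) {
      pa_error(sprintf("registry row %d (%s): unknown ester_type '%s'",
                       i, row$name, row$ester_type),
               "papartition_io_error")
    }
    if (!row$acid_base %in% .acid_base_classes) {
      pa_error(sprintf("registry row %d (%s): unknown acid_base '%s'",
                       i, row$name, row$acid_base),
               "papartition_io_error")
    }
    if (row$acid_base %in% c("acid", "base", "zwitterion") &&
        !is.finite(row$pka)) {
      pa_error(sprintf("registry row %d: pKa missing for %s '%s'",
                       i, row$acid_base, row$name),
               "papartition_config_error")
    }
  }
  panos <- df$name[df$compound_class == "PANO"]
  parents <- pano_parent(panos)
  unresolved <- panos[!parents %in% df$name]
  if (length(unresolved) > 0) {
    pa_error(sprintf("parent alkaloid not in registry for N-oxide(s): %s",
                     paste(unresolved, collapse = ", ")),
             "papartition_config_error")
  }
  as_tibble(df)
}

# "X N-oxide" -> "X"; names without the suffix are returned unchanged.
pano_parent <- function(name) sub(" N-oxide$", "", name)

#' Packaged registry of the eight study compounds
#'
#' Four pyrrolizidine alkaloids (intermedine, lasiocarpine, monocrotaline,
#' retrorsine) and their N-oxides, with ester types and acid/base
#' character. The pKa column holds representative placeholder values
#' (6.0 for the alkaloids, 4.0 for the N-oxides), not measured constants:
#' they encode the qualitative speciation behaviour (alkaloids weakly
#' basic, still partly ionized at pH 7.4; N-oxides protonated only under
#' acidic conditions, neutral at pH 7.4) and can be overridden by
#' supplying a user registry to [read_compound_registry()].
#'
#' @return A tibble, as from [read_compound_registry()].
#' @export
pa_compounds <- function() {
  read_compound_registry(extdata_path("compounds_synthetic_pka.csv"))
}

#' Extract one compound from a registry as an object
#'
#' @param registry A tibble from [read_compound_registry()].
#' @param name Compound name to extract.
#'
#' @return An [ionizable_compound()].
#' @export
compound_from_registry <- function(registry, name) {
  hit <- which(registry$name == name)
  if (length(hit) != 1L) {
    pa_error(sprintf("compound '%s' not found (or duplicated) in registry",
                     name), "papartition_config_error")
  }
  row <- registry[hit, ]
  ionizable_compound(row$name, row$compound_class, row$ester_type,
                     row$acid_base, row$pka)
}
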