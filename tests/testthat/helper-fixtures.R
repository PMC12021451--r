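# Shared builders for hand-crafted measurement tables.

make_partition <- function(compound = "cmp", log_ratios,
                           direction = "from_organic", area_water = 100) {
  tibble::tibble(
    compound = compound,
    direction = direction,
    replicate_id = seq_along(log_ratios),
    area_octanol = area_water * 10^log_ratios,
    area_water = area_water
  )
}

make_depletion <- function(compound = "cmp", ratios, concentration = 1000,
                           area_eq = 100) {
  tibble::tibble(
    compound = compound,
    concentration = concentration,
    replicate_id = seq_along(ratios),
    area_reference_plasma = area_eq * ratios,
    area_equilibrated_plasma = area_eq
  )
}

base_compound <- function(pka = 6, name = "weak base") {
  ionizable_compound(name, acid_base = "base", pka = pka)
}

acid_compound <- function(pka = 4.5, name = "weak acid") {
  ionizable_compound(name, acid_base = "acid", pka = pka)
}
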