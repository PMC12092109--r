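#' Published strike-energy table for the Vienna specimen
#'
#' The published per-specimen energy grid, shipped as a fixture so the audit
#' functions can check its internal arithmetic without external files. Four
#' variants (columns of the original table) crossed with the quantities of
#' each row: bone-only vs soft-tissue-inclusive masses, with and without the
#' four imputed missing vertebrae.
#'
#' These are printed values, reproduced at their printed precision; they are
#' audit inputs, not outputs of this package.
#'
#' @return Data frame with one row per variant: `variant`, `tail_mass_kg`,
#'   `tail_length_m`, `whiplash_mass_kg`, `whiplash_length_m`,
#'   `whole_tail_energy_kJ`, `transferred_energy_kJ`,
#'   `quick_whiplash_energy_kJ`.
#' @export
printed_table1 <- function() {
  data.frame(
    variant = c("bone", "bone_imputed", "soft", "soft_imputed"),
    tail_mass_kg = c(26.5, 28.4, 76.5, 82.0),
    tail_length_m = c(1.958, 2.1, 1.958, 2.1),
    whiplash_mass_kg = c(0.3, 0.3, 0.7, 0.8),
    whiplash_length_m = c(0.597, 0.622, 0.597, 0.622),
    whole_tail_energy_kJ = c(56.136, 60.207, 162.234, 173.999),
    transferred_energy_kJ = c(47.716, 51.176, 137.899, 147.899),
    quick_whiplash_energy_kJ = c(0.537, 0.559, 1.553, 1.616),
    stringsAsFactors = FALSE)
}

#' Published comparative table across taxa
#'
#' Printed caudal counts, tail and whip lengths, whip percentages and
#' bone-only whole-tail strike energies for the five reference
#' specimens/taxa. Shipped for audit purposes at printed precision.
#'
#' @return Data frame with columns `specimen_id`, `taxon`, `n_caudals`,
#'   `total_tail_m`, `whip_length_m`, `whip_pct`, `energy_kJ`.
#' @export
printed_table2 <- function() {
  data.frame(
    specimen_id = c("IPUW 3480", "NHMW 1904/0004/0003", "Huene specimen",
                    "Frick Field no. 15.5", "NHMW-ZOO-HS-1680"),
    taxon = c("Varanus salvator", "Diplodocus carnegii",
              "Plateosaurus trossingensis", "Plateosaurus trossingensis",
              "Iguana iguana"),
    n_caudals = c(110, 70, 42, 42, 39),
    total_tail_m = c(1.03, 13.26, 2.55, 1.90, 0.64),
    whip_length_m = c(0.34, 7.28, 0.48, 0.60, 0.41),
    whip_pct = c(32.80, 54.90, 18.70, 31.50, 37.10),
    energy_kJ = c(0.03, 179.54, 82.51, 56.14, 0.01),
    stringsAsFactors = FALSE)
}

#' Direct-parameter presets for the comparative taxa
#'
#' Ready-made specimen entries for [comparative_table()], carrying the
#' published caudal counts, lengths, bone-only tail masses and strike
#' velocities of the reference taxa. Velocities for the extant taxa are the
#' upper bounds of the published ranges (water monitor ~13–20 m/s, green
#' iguana 5–10 m/s), matching the maximum-impact convention; the diplodocid
#' preset carries the modelled 33.2 kg bone-only tail mass and 104 m/s tip
#' velocity.
#'
#' @param which character vector choosing presets; any of `"diplodocus"`,
#'   `"varanus"`, `"iguana"`.
#' @return A named list of specimen entries.
#' @export
#' @examples
#' comparative_table(taxon_presets("diplodocus"))
taxon_presets <- function(which = c("diplodocus", "varanus", "iguana")) {
  which <- match.arg(which, several.ok = TRUE)
  all <- list(
    diplodocus = list(id = "NHMW 1904/0004/0003", taxon = "Diplodocus carnegii",
                      n_caudals = 70, total_length_m = 13.26,
                      whip_length_m = 7.28, mass_kg = 33.2,
                      velocity_m_s = 104),
    varanus = list(id = "IPUW 3480", taxon = "Varanus salvator",
                   n_caudals = 110, total_length_m = 1.03,
                   whip_length_m = 0.34, mass_kg = NULL,
                   velocity_m_s = 20),
    iguana = list(id = "NHMW-ZOO-HS-1680", taxon = "Iguana iguana",
                  n_caudals = 39, total_length_m = 0.64,
                  whip_length_m = 0.41, mass_kg = NULL,
                  velocity_m_s = 10))
  all[which]
}
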