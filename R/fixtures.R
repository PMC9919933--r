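#' Packaged study tables
#'
#' Paths to the plain-text tables shipped with the package: the UV standard
#' curve of the guest (`"calibration"`: 8 concentration/absorbance pairs,
#' 0.02-0.09 mM), the phase-solubility absorbances of the three host systems
#' (`"phase_solubility"`), the Hildebrand solubility parameters of the four
#' components (`"solubility_parameters"`) and the partial-charge atom-class
#' table used for hydrogen-bond typing (`"atom_classes"`).
#'
#' @param which which table.
#' @return file path of the CSV.
#' @examples
#' utils::read.csv(study_table("calibration"))
#' @export
study_table <- function(which = c("calibration", "phase_solubility",
                                  "solubility_parameters", "atom_classes")) {
  which <- match.arg(which)
  file <- c(calibration = "table1_calibration.csv",
            phase_solubility = "table2_phase_solubility.csv",
            solubility_parameters = "table3_solubility_parameters.csv",
            atom_classes = "table6_atom_classes.csv")[[which]]
  system.file("extdata", file, package = "hostguest", mustWork = TRUE)
}
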