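## Versioned physical-constant tables used by the mass-prediction module.
## Average (not monoisotopic) masses throughout: linear-mode MALDI-TOF of
## intact proteins resolves the average isotopic envelope only.

.MASS_CONSTANTS_VERSION <- "avg-1.0"

## Standard average residue (amino-acid minus water) masses, Da.
.AA_AVERAGE <- c(
  G =  57.0519, A =  71.0788, S =  87.0782, P =  97.1167, V =  99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132)

.WATER_AVERAGE <- 18.0153
.PROTON_MASS <- 1.00728

## Average-mass deltas of the built-in modification hypotheses, Da.
.MODIFICATION_DELTAS <- c(methylation = 14.0266,
                          acetylation = 42.0367,
                          beta_methylthiolation = 46.0916)

## Residues after which the initiator Met is excised (substrates of
## methionine aminopeptidase: the seven smallest side chains).
.MET_LOSS_RESIDUES <- c("G", "A", "S", "C", "T", "P", "V")

#' Mass constants
#'
#' The versioned constants table behind the mass-prediction module:
#' average residue masses for the 20 amino acids, the water and proton
#' masses, the average-mass deltas of the built-in modification
#' hypotheses (methylation +14.0266, acetylation +42.0367,
#' beta-methylthiolation +46.0916 Da), and the small-residue set of the
#' N-terminal Met-excision rule.  Pass a modified copy of
#' `$modifications` to [annotatePeaks()] to extend the hypothesis list.
#'
#' @return a list with elements `residues`, `water`, `proton`,
#'   `modifications`, `metLossResidues`, `version`.
#' @export
#' @examples
#' massConstants()$residues[["G"]]  # 57.0519
massConstants <- function() {
  list(residues = .AA_AVERAGE, water = .WATER_AVERAGE,
       proton = .PROTON_MASS, modifications = .MODIFICATION_DELTAS,
       metLossResidues = .MET_LOSS_RESIDUES,
       version = .MASS_CONSTANTS_VERSION)
}
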