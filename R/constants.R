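# Reference constant tables used by the physicochemical calculators and the
# classifier. All physicochemical constants follow the ExPASy ProtParam set
# (average residue masses, Bjellqvist pKa values, Kyte-Doolittle hydropathy,
# Guruprasad DIWV dipeptide instability weights).

#' @keywords internal
AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Average molecular weight of the free amino acid (Da); residue mass in a
# chain is this minus one water.
AA_MASS <- c(
  A = 89.0932,  C = 121.1582, D = 133.1027, E = 147.1293, F = 165.1891,
  G = 75.0666,  H = 155.1546, I = 131.1729, K = 146.1876, L = 131.1729,
  M = 149.2113, N = 132.1179, P = 115.1305, Q = 146.1445, R = 174.2010,
  S = 105.0926, T = 119.1192, V = 117.1463, W = 204.2252, Y = 181.1885
)

WATER_MASS <- 18.0153

# Kyte-Doolittle hydropathy values (GRAVY).
KD_HYDROPATHY <- c(
  A = 1.8,  C = 2.5,  D = -3.5, E = -3.5, F = 2.8,
  G = -0.4, H = -3.2, I = 4.5,  K = -3.9, L = 3.8,
  M = 1.9,  N = -3.5, P = -1.6, Q = -3.5, R = -4.5,
  S = -0.8, T = -0.7, V = 4.2,  W = -0.9, Y = -1.3
)

# Bjellqvist pKa set used by the ExPASy pI tool. Side chains plus termini;
# some residues modulate the terminal pKa when they sit at the terminus.
PK_POSITIVE <- c(Nterm = 7.5, K = 10.0, R = 12.0, H = 5.98)
PK_NEGATIVE <- c(Cterm = 3.55, D = 4.05, E = 4.45, C = 9.0, Y = 10.0)
PK_NTERM_BY_RESIDUE <- c(A = 7.59, M = 7.0, S = 6.93, P = 8.36, T = 6.82,
                         V = 7.44, E = 7.7)
PK_CTERM_BY_RESIDUE <- c(D = 4.55, E = 4.75)

# Atomic composition of amino-acid residues (amino acid minus one water).
# One extra water is added per chain.
AA_ATOMS <- matrix(c(
  # C   H   N  O  S
    3,  5,  1, 1, 0,  # A
    3,  5,  1, 1, 1,  # C
    4,  5,  1, 3, 0,  # D
    5,  7,  1, 3, 0,  # E
    9,  9,  1, 1, 0,  # F
    2,  3,  1, 1, 0,  # G
    6,  7,  3, 1, 0,  # H
    6, 11,  1, 1, 0,  # I
    6, 12,  2, 1, 0,  # K
    6, 11,  1, 1, 0,  # L
    5,  9,  1, 1, 1,  # M
    4,  6,  2, 2, 0,  # N
    5,  7,  1, 1, 0,  # P
    5,  8,  2, 2, 0,  # Q
    6, 12,  4, 1, 0,  # R
    3,  5,  1, 2, 0,  # S
    4,  7,  1, 2, 0,  # T
    5,  9,  1, 1, 0,  # V
   11, 10,  2, 1, 0,  # W
    9,  9,  1, 2, 0   # Y
), nrow = 20, byrow = TRUE,
  dimnames = list(AA_STANDARD, c("C", "H", "N", "O", "S")))

# Guruprasad et al. dipeptide instability weight values (DIWV). Row = first
# residue of the dipeptide, column = second.
DIWV <- matrix(c(
  1, 44.94, -7.49, 1, 1, 1, -7.49, 1, 1, 1, 1, 1, 20.26, 1, 1, 1, 1, 1, 1, 1,
  1, 1, 20.26, 1, 1, 1, 33.6, 1, 1, 20.26, 33.6, 1, 20.26, -6.54, 1, 1, 33.6, -6.54, 24.68, 1,
  1, 1, 1, 1, -6.54, 1, 1, 1, -7.49, 1, 1, 1, 1, 1, -6.54, 20.26, -14.03, 1, 1, 1,
  1, 44.94, 20.26, 33.6, 1, 1, -6.54, 20.26, 1, 1, 1, 1, 20.26, 20.26, 1, 20.26, 1, 1, -14.03, 1,
  1, 1, 13.34, 1, 1, 1, 1, 1, -14.03, 1, 1, 1, 20.26, 1, 1, 1, 1, 1, 1, 33.601,
  -7.49, 1, 1, -6.54, 1, 13.34, 1, -7.49, -7.49, 1, 1, -7.49, 1, 1, 1, 1, -7.49, 1, 13.34, -7.49,
  1, 1, 1, 1, -9.37, -9.37, 1, 44.94, 24.68, 1, 1, 24.68, -1.88, 1, 1, 1, -6.54, 1, -1.88, 44.94,
  1, 1, 1, 44.94, 1, 1, 13.34, 1, -7.49, 20.26, 1, 1, -1.88, 1, 1, 1, 1, -7.49, 1, 1,
  1, 1, 1, 1, 1, -7.49, 1, -7.49, 1, -7.49, 33.6, 1, -6.54, 24.64, 33.6, 1, 1, -7.49, 1, 1,
  1, 1, 1, 1, 1, 1, 1, 1, -7.49, 1, 1, 1, 20.26, 33.6, 20.26, 1, 1, 1, 24.68, 1,
  13.34, 1, 1, 1, 1, 1, 58.28, 1, 1, 1, -1.88, 1, 44.94, -6.54, -6.54, 44.94, -1.88, 1, 1, 24.68,
  1, -1.88, 1, 1, -14.03, -14.03, 1, 44.94, 24.68, 1, 1, 1, -1.88, -6.54, 1, 1, -7.49, 1, -9.37, 1,
  20.26, -6.54, -6.54, 18.38, 20.26, 1, 1, 1, 1, 1, -6.54, 1, 20.26, 20.26, -6.54, 20.26, 1, 20.26, -1.88, 1,
  1, -6.54, 20.26, 20.26, -6.54, 1, 1, 1, 1, 1, 1, 1, 20.26, 20.26, 1, 44.94, 1, -6.54, 1, -6.54,
  1, 1, 1, 1, 1, -7.49, 20.26, 1, 1, 1, 1, 13.34, 20.26, 20.26, 58.28, 44.94, 1, 1, 58.28, -6.54,
  1, 33.6, 1, 20.26, 1, 1, 1, 1, 1, 1, 1, 1, 44.94, 20.26, 20.26, 20.26, 1, 1, 1, 1,
  1, 1, 1, 20.26, 13.34, -7.49, 1, 1, 1, 1, 1, -14.03, 1, -6.54, 1, 1, 1, 1, -14.03, 1,
  1, 1, -14.03, 1, 1, -7.49, 1, 1, -1.88, 1, 1, 1, 20.26, 1, 1, 1, -7.49, 1, 1, -6.54,
  -14.03, 1, 1, 1, 1, -9.37, 24.68, 1, 1, 13.34, 24.68, 13.34, 1, 1, 1, 1, -14.03, -7.49, 1, 1,
  24.68, 1, 24.68, -6.54, 1, -7.49, 13.34, 1, 1, 1, 44.94, 1, 13.34, 1, -15.91, 1, -7.49, 1, -9.37, 13.34
), nrow = 20, byrow = TRUE, dimnames = list(AA_STANDARD, AA_STANDARD))

# Diagnostic motifs of the family classification.
MOTIF_QALGGH <- "QALGGH"
MOTIF_SATALL <- "SATALL"
MOTIF_SATALL_FULL <- "SATALLQKAAQMGS"
MOTIF_PCYCC <- "PCYCC"

#' Zinc-finger signature templates of the four A1 subsets
#'
#' The published spacing-signature templates for the four-finger A1 proteins:
#' per subset (A1a--A1d) the signatures of fingers 1--4 plus the diagnostic
#' non-finger motif carried by the subset, if any (SATALL block for A1a,
#' PCYCC for A1d).
#'
#' @return A data.frame with columns `subset`, `finger1`..`finger4`, `motif`.
#' @export
#' @examples
#' a1_templates()
a1_templates <- function() {
  data.frame(
    subset  = c("A1a", "A1b", "A1c", "A1d"),
    finger1 = rep("CX2CX12HX3H", 4),
    finger2 = c("CX4CX17HX4H", "CX4CX17HX4H", "CX4CX20HX4H", "CX4CX20HX4H"),
    finger3 = c("CX2CX12HX3C", "CX2CX12HX3C", "CX2CX13HX3C", "CX2CX12HX3C"),
    finger4 = c("CX1CX12HX3C", "CX1CX12HX3C", "CX1CX12HX6H", "CX1CX12HX7H"),
    motif   = c("SATALL", "", "", "PCYCC"),
    stringsAsFactors = FALSE
  )
}

#' Published water-stress enzyme panel reference (means and sds)
#'
#' Per-treatment (CK control; LS/MS/SS mild/moderate/severe water stress)
#' means and standard deviations of the six protective-enzyme / stress-marker
#' analytes measured in jujube leaves: SOD, POD and CAT activity (U/g), MDA
#' content (nmol/g), H2O2 content (umol/g) and proline content (g/kg),
#' n = 3 biological replicates per treatment. Used as the default simulation
#' truth by [make_enzyme_panel()] and as the worked-example input for
#' [percent_change()].
#'
#' @return A data.frame with columns `treatment`, `analyte`, `unit`, `mean`,
#'   `sd`, `n`.
#' @export
#' @examples
#' head(enzyme_reference())
enzyme_reference <- function() {
  trt <- c("CK", "LS", "MS", "SS")
  tab <- rbind(
    data.frame(treatment = trt, analyte = "SOD", unit = "U/g",
               mean = c(630.85, 794.60, 914.52, 1021.59),
               sd = c(19.01, 68.88, 42.69, 32.08)),
    data.frame(treatment = trt, analyte = "POD", unit = "U/g",
               mean = c(86931.97, 55909.43, 75926.12, 68229.46),
               sd = c(685.16, 678.79, 804.25, 498.09)),
    data.frame(treatment = trt, analyte = "CAT", unit = "U/g",
               mean = c(1385.92, 1255.08, 1423.33, 997.16),
               sd = c(10.92, 27.67, 52.94, 74.93)),
    data.frame(treatment = trt, analyte = "MDA", unit = "nmol/g",
               mean = c(59.94, 71.87, 70.05, 68.91),
               sd = c(1.06, 1.05, 1.73, 0.43)),
    data.frame(treatment = trt, analyte = "H2O2", unit = "umol/g",
               mean = c(5.73, 7.55, 8.41, 9.62),
               sd = c(0.24, 0.31, 0.22, 0.51)),
    data.frame(treatment = trt, analyte = "proline", unit = "g/kg",
               mean = c(0.175, 0.045, 0.035, 0.044),
               sd = c(0.0029, 0.0017, 0.001, 0.0012))
  )
  tab$n <- 3L
  tab
}
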