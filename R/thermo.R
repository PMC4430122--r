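## Nearest-neighbour duplex thermodynamics.
##
## Unified DNA/DNA nearest-neighbour parameters (SantaLucia 1998 unified set):
## enthalpy in kcal/mol, entropy in cal/(mol K), 1 M NaCl reference state.

.NN_DH <- c(
  AA = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, GT = -8.4,
  CT = -7.8, GA = -8.2, CG = -10.6, GC = -9.8, GG = -8.0,
  ## complements (duplex identity, e.g. TT/AA == AA/TT)
  TT = -7.9, TG = -8.5, AC = -8.4, AG = -7.8, TC = -8.2, CC = -8.0
)

.NN_DS <- c(
  AA = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, GT = -22.4,
  CT = -21.0, GA = -22.2, CG = -27.2, GC = -24.4, GG = -19.9,
  TT = -22.2, TG = -22.7, AC = -22.4, AG = -21.0, TC = -22.2, CC = -19.9
)

## duplex initiation with a terminal G.C vs A.T pair
.INIT_DH <- c(GC = 0.1, AT = 2.3)
.INIT_DS <- c(GC = -2.8, AT = 4.1)

.GAS_CONSTANT <- 1.987 # cal / (mol K)

#' Hybridization conditions for melting-temperature prediction
#'
#' Container for the solution conditions under which duplex melting
#' temperatures are evaluated. The nearest-neighbour parameter set is defined
#' at 1 M monovalent salt; lower salt is handled by an entropic correction and
#' formamide by a linear destabilisation of 0.65 degC per percent (v/v).
#'
#' @param monovalent_salt molar concentration of monovalent cations
#'   (e.g. 0.39 for 2x SSC, 1.0 for the NN reference state).
#' @param formamide_percent formamide, percent v/v in `[0, 100]`.
#' @param oligo_conc total oligonucleotide strand concentration, molar.
#' @return an object of class `thermo_conditions`.
#' @export
#' @examples
#' thermo_conditions()                      # NN reference state, no formamide
#' thermo_conditions(0.39, 50)              # FISH-like: 2x SSC + 50% formamide
thermo_conditions <- function(monovalent_salt = 1.0, formamide_percent = 0,
                              oligo_conc = 1e-6) {
  stopifnot(monovalent_salt > 0, oligo_conc > 0,
            formamide_percent >= 0, formamide_percent <= 100)
  structure(list(monovalent_salt = monovalent_salt,
                 formamide_percent = formamide_percent,
                 oligo_conc = oligo_conc),
            class = "thermo_conditions")
}

#' @export
print.thermo_conditions <- function(x, ...) {
  cat(sprintf("thermo_conditions: [Na+]=%g M, formamide=%g%%, C_T=%g M\n",
              x$monovalent_salt, x$formamide_percent, x$oligo_conc))
  invisible(x)
}

#' Nearest-neighbour duplex melting temperature
#'
#' Predicts the melting temperature of a perfect DNA/DNA duplex by summing
#' unified nearest-neighbour enthalpies and entropies over the dinucleotide
#' steps plus terminal initiation terms, then solving
#' Tm = dH / (dS + R ln(C_T / x)) with x = 4 for non-self-complementary
#' sequences (1 if the sequence equals its reverse complement). Salt is
#' corrected entropically, dS' = dS + 0.368 (N-1) ln`[Na+]`, and formamide
#' linearly at -0.65 degC per percent.
#'
#' @param sequence DNA string, alphabet ACGT, length >= 2. Vectorised.
#' @param conditions a [thermo_conditions()] object.
#' @return melting temperature(s) in degrees Celsius.
#' @export
#' @examples
#' tm_nearest_neighbor("ATGCATGCAT", thermo_conditions(0.05, 0))
tm_nearest_neighbor <- function(sequence, conditions = thermo_conditions()) {
  stopifnot(inherits(conditions, "thermo_conditions"))
  sequence <- toupper(sequence)
  if (any(nchar(sequence) < 2L))
    stop("invalid sequence: length must be >= 2", call. = FALSE)
  .check_dna(sequence)
  vapply(sequence, .tm_one, numeric(1), conditions = conditions,
         USE.NAMES = FALSE)
}

.tm_one <- function(seq, conditions) {
  n <- nchar(seq)
  chars <- strsplit(seq, "")[[1]]
  steps <- paste0(chars[-n], chars[-1])
  dh <- sum(.NN_DH[steps])
  ds <- sum(.NN_DS[steps])
  ends <- ifelse(chars[c(1L, n)] %in% c("G", "C"), "GC", "AT")
  dh <- dh + sum(.INIT_DH[ends])
  ds <- ds + sum(.INIT_DS[ends])
  ds <- ds + 0.368 * (n - 1L) * log(conditions$monovalent_salt)
  selfcomp <- seq == .revcomp1(seq)
  if (selfcomp) ds <- ds - 1.4  # duplex symmetry penalty
  x <- if (selfcomp) 1 else 4
  ct <- conditions$oligo_conc
  tm <- dh * 1000 / (ds + .GAS_CONSTANT * log(ct / x)) - 273.15
  tm - 0.65 * conditions$formamide_percent
}
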