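# Nearest-neighbor thermodynamics for DNA:RNA hybrid duplexes
# (Sugimoto et al. 1995 parameter set). Table is keyed by the RNA-strand
# doublet written 5'->3' (U encoded as T); values are (dH kcal/mol,
# dS cal/mol/K) for the doublet paired with its complementary DNA.
RNA_DNA_NN <- list(
  AA = c(-7.8, -21.9), AC = c(-5.9, -12.3), AG = c(-9.1, -23.5),
  AT = c(-8.3, -23.9), CA = c(-9.0, -26.1), CC = c(-9.3, -23.2),
  CG = c(-16.3, -47.1), CT = c(-7.0, -19.7), GA = c(-5.5, -13.5),
  GC = c(-8.0, -17.1), GG = c(-12.8, -31.9), GT = c(-7.8, -21.6),
  TA = c(-7.8, -23.2), TC = c(-8.6, -22.9), TG = c(-10.4, -28.4),
  TT = c(-11.5, -36.4)
)
RNA_DNA_INIT <- c(1.9, -3.9)
GAS_CONSTANT <- 1.987 # cal / (mol K)

#' Melting temperature of a DNA:RNA hybrid duplex
#'
#' Nearest-neighbor melting temperature for a DNA oligonucleotide hybridised
#' to a complementary RNA target, using the Sugimoto et al. (1995) RNA/DNA
#' parameter set. The reference condition is 1 M Na+; other sodium
#' concentrations apply an entropic salt correction of
#' 0.368 * (N - 1) * ln([Na+]) cal/mol/K. The total strand concentration
#' enters as CT/4 (non-self-complementary duplex, equal strand
#' concentrations).
#'
#' @param dna_probe DNA oligo 5'->3' (the probe).
#' @param rna_target RNA target 5'->3'; if missing, taken as the exact
#'   complement of `dna_probe`. Must be the reverse complement of the probe.
#' @param Na sodium concentration, mol/L (default 1).
#' @param ct total strand concentration, mol/L (default 5e-8, i.e. 50 nM).
#' @return melting temperature in degrees Celsius.
#' @export
melting_temperature <- function(dna_probe, rna_target = NULL, Na = 1.0,
                                ct = 5e-8) {
  check_alphabet(dna_probe, "DNA probe")
  dna_probe <- normalize_dna(dna_probe)
  if (is.null(rna_target)) {
    rna_target <- normalize_rna(revcomp_dna(dna_probe))
  }
  check_alphabet(rna_target, "RNA target")
  rna <- normalize_dna(normalize_rna(rna_target)) # U -> T for table lookup
  n <- nchar(rna)
  if (n < 8L) abort("duplex too short for nearest-neighbor Tm (need >= 8 nt)")
  if (nchar(dna_probe) != n || revcomp_dna(dna_probe) != rna) {
    abort("dna_probe and rna_target are not complementary")
  }
  ch <- seq_chars(rna)
  doublets <- paste0(ch[-n], ch[-1L])
  sums <- Reduce(`+`, RNA_DNA_NN[doublets])
  dH <- sums[1] + RNA_DNA_INIT[1]           # kcal/mol
  dS <- sums[2] + RNA_DNA_INIT[2]           # cal/mol/K
  dS <- dS + 0.368 * (n - 1) * log(Na)      # salt correction (1 M -> 0)
  dH * 1000 / (dS + GAS_CONSTANT * log(ct / 4)) - 273.15
}
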