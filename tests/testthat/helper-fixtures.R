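# Shared fixtures built in code.

# Photophysical table of the probe in six solvents of increasing polarity:
# two absorption maxima (pi-pi* short, n-pi* long) and one emission maximum.
table4 <- data.frame(
  solvent = c("toluene", "DCM", "THF", "ACN", "DMF", "DMSO"),
  abs1 = c(291, 268, 281, 250, 267, 263),
  abs2 = c(354, 367, 363, 358, 367, 370),
  emi  = c(430, 434, 445, 445, 457, 462),
  stringsAsFactors = FALSE)

# Product/reactant formulas of the Friedlander condensations: each monomer
# forms from 1 aminoketone + 1 dione (releasing 2 H2O), each dimer from
# 2 aminoketones + 1 dione (releasing 4 H2O).
friedlander_reactions <- list(
  `3a` = list(amine = "C13H11NO",    product = "C25H25NO",     n_amine = 1),
  `3b` = list(amine = "C13H10ClNO",  product = "C25H24ClNO",   n_amine = 1),
  `3c` = list(amine = "C13H9Cl2NO",  product = "C25H23Cl2NO",  n_amine = 1),
  `3d` = list(amine = "C13H10N2O3",  product = "C25H24N2O3",   n_amine = 1),
  `4a` = list(amine = "C13H11NO",    product = "C38H32N2",     n_amine = 2),
  `4b` = list(amine = "C13H10ClNO",  product = "C38H30Cl2N2",  n_amine = 2),
  `4c` = list(amine = "C13H9Cl2NO",  product = "C38H28Cl4N2",  n_amine = 2),
  `4d` = list(amine = "C13H10N2O3",  product = "C38H30N4O4",   n_amine = 2))

# Printed HRMS m/z for the isolated products (integer part used by the
# nominal-mass consistency test).
hrms_mz <- c(`3a` = 356.2014, `3b` = 390.1610, `3c` = 424.1235,
             `3d` = 401.1866, `3e` = 371.2079, `4a` = 517.2630,
             `4b` = 585.1867, `4c` = 653.1075, `4d` = 607.2345)
product_formulas <- c(`3a` = "C25H25NO", `3b` = "C25H24ClNO",
                      `3c` = "C25H23Cl2NO", `3d` = "C25H24N2O3",
                      `3e` = "C25H26N2O", `4a` = "C38H32N2",
                      `4b` = "C38H30Cl2N2", `4c` = "C38H28Cl4N2",
                      `4d` = "C38H30N4O4")

make_friedlander_spec <- function(id, with_masses = FALSE) {
  rx <- friedlander_reactions[[id]]
  reactants <- list(
    species("aminoketone", rx$amine, equivalents = rx$n_amine,
            mass_used = if (with_masses) rx$n_amine * 0.5),
    species("dione", "C12H18O2", equivalents = 1,
            mass_used = if (with_masses) 0.49))
  reaction_spec(reactants, product_formula = rx$product,
                product_mass = if (with_masses) 0.45)
}

# Noiseless solvatochromic series whose spectra peak exactly at the
# tabulated wavelengths (integer centers on a 1 nm grid).
make_table4_series <- function(noise_sd = 0, seed = 1) {
  base <- c(table4$abs1[1], table4$abs2[1])
  shifts <- lapply(seq_len(nrow(table4)), function(i) {
    c(table4$abs1[i] - base[1], table4$abs2[i] - base[2],
      table4$emi[i] - table4$emi[1])
  })
  names(shifts) <- table4$solvent
  simulate_solvatochromic_series(base, table4$emi[1], shifts,
                                 abs_amplitudes = c(0.6, 0.4),
                                 seed = seed, noise_sd = noise_sd)
}
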