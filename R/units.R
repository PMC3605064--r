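# Internal unit-conversion constants. Geometry is carried in micrometres,
# pressures in mmHg, flows in nl/min, viscosities in cP, shear stresses in
# dyn/cm2, oxygen amounts in cm3 O2 and oxygen fluxes in cm3 O2/s.

MMHG_TO_PA <- 133.322
MMHG_TO_DYN_CM2 <- 1333.22          # 1 mmHg in dyn/cm2
NLMIN_TO_CM3S <- 1e-6 / 60          # nl/min -> cm3/s
UM_TO_CM <- 1e-4

# Poiseuille resistance prefactor so that, with eta in cP, L and D in um,
# R = POISEUILLE_UNIT * 128 * eta * L / (pi * D^4) gives mmHg.min/nl.
POISEUILLE_UNIT <- local({
  r_si_per_cgs <- 1e15              # (cP um um^-4) -> Pa s m^-3
  q_si <- 1e-12 / 60                # nl/min -> m3/s
  r_si_per_cgs * q_si / (1 / 1)     # Pa per (nl/min)
}) / MMHG_TO_PA
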