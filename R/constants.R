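# Physical constants shared across modules.

# Gas constant (J mol^-1 K^-1) and body temperature (K).
.R_GAS <- 8.31446
.T_BODY <- 310.15

# Pa per mmHg.
.PA_PER_MMHG <- 101325 / 760

# Pressure-to-concentration ratio of an ideal gas at body temperature,
# expressed in mmHg m^3 mol^-1: P [mmHg] = .K_AIR * c [mol m^-3].
.K_AIR <- .R_GAS * .T_BODY / .PA_PER_MMHG

# Molar volume of an ideal gas at body temperature and 1 atm (m^3 mol^-1),
# used to convert metabolic demands given in mL O2 per kg per minute.
.V_MOLAR <- .R_GAS * .T_BODY / 101325

# Dynamic viscosity of air at body temperature (Pa s), used only by the
# optional Poiseuille link between geometry and hydrodynamic resistance.
.MU_AIR <- 1.8e-5
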