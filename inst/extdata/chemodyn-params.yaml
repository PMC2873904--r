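# Reference configuration for the dynamic MWC chemotaxis model.
# All numeric model constants live here, not in code.
# Units: concentrations mM, energies kT, time s, rates 1/s.
receptor:
  nu_a: 0.4166666666666667        # Tar fraction of dimers (Tar:Tsr = 1:1.4)
  nu_s: 0.5833333333333333        # Tsr fraction
  K_off_a: 0.02                   # MeAsp dissociation constant, Tar, off state [mM]
  K_on_a: 0.5                     # MeAsp dissociation constant, Tar, on state [mM]
  K_off_s: 100.0                  # MeAsp dissociation constant, Tsr, off state [mM]
  K_on_s: 1.0e+6                  # MeAsp dissociation constant, Tsr, on state [mM]
  fm_intercept: 1.0               # methylation free energy f(m) = intercept + slope*m [kT]
  fm_slope: -0.5                  # per methyl group [kT]; negative: methylation favours on
  size_intercept: 17.5            # complex size N(L0) = N0 + c*L0 [dimers]
  size_slope: 3.35                # [dimers/mM]
adaptation:
  g_R: 0.0069                     # methylation rate constant [methyl groups/s]
  a_wt1: 0.3333333333333333       # adapted activity, WT1
  a_wt2: 0.5                      # adapted activity, WT2 and CheB mutant
  K_R: 0.1                        # Michaelis constant, methylation (activity units)
  K_B: 0.1                        # Michaelis constant, demethylation (activity units)
  M_max: 3.3333333333333335       # max average methyl groups per dimer (8 sites * nu_a)
  m_c: 0.5                        # site-availability scale for reduced efficiency
flow:
  wt1:                            # fast flow (WT1 experiments)
    k_rise: 1.0                   # [1/s] exponential rise on addition
    k_fall: 1.3                   # [1/s] exponential fall on removal
  wt2:                            # slower flow (WT2 and CheB-mutant experiments)
    k_rise: 0.35
    k_fall: 0.45
fret:
  alpha: 0.43                     # fluorescence efficiency ratio
  dt_wt1: 0.2                     # sampling resolution [s], WT1
  dt_wt2: 1.0                     # sampling resolution [s], WT2 / CheB mutant
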