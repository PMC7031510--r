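# Reference parameterization of the single-compartment HVC_X model.
#
# Units: mV, ms, pA, pF, nS, uM.  Every voltage-dependent steady state is a
# Boltzmann sigmoid 1/(1 + exp(-(V - half)/slope)); a negative slope encodes
# inactivation (decreasing in V).  Time constants are
# base + amp / (1 + exp(-(V - half)/slope)).
#
# These constants are an explicit, versioned stand-in parameterization of the
# HVC_X current complement (Na, K, Ca-L, Ca-T, A, SK, h, leak); they were tuned
# once so that the reference conductance set reproduces the qualitative HVC_X
# phenotype (adapting spike train riding a depolarized plateau at +100 pA;
# sag and rebound firing at -140 pA when g_h and g_CaT are present; rest near
# -70 mV; input resistance in the low hundreds of megaohms).
version: 1
capacitance_pF:
  adult: 50
  juvenile: 75
conductances_nS:          # reference (mid-range) maximal conductances
  gNa: 900
  gK: 180
  gSK: 4
  gh: 3
  gCaT: 3
  gCaL: 2                 # fixed: indistinguishable from gSK in fits
  gA: 1                   # fixed: very small in HVC_X
  gL: 3.2
reversal_mV:
  ENa: 50
  EK: -90
  Eh: -43
  ECa: 120                # fixed Ca reversal, no GHK correction
  EL: -74
sodium:                   # I_Na = gNa * m_inf(V)^3 * h * (V - ENa)
  m_half: -35
  m_slope: 7
  h_half: -45
  h_slope: -7
  tauh_base_ms: 0.5
  tauh_amp_ms: 7
  tauh_half: -40.5
  tauh_slope: -6
potassium:                # I_K = gK * n^4 * (V - EK)
  n_half: -35
  n_slope: 10
  taun_base_ms: 0.2
  taun_amp_ms: 0.8
  taun_half: -27
  taun_slope: -15
calcium_T:                # I_CaT = gCaT * a_inf(V)^2 * b * (V - ECa)
  a_half: -59
  a_slope: 6
  b_half: -78
  b_slope: -5
  taub_base_ms: 50
  taub_amp_ms: 300        # slow deinactivation when hyperpolarized
  taub_half: -80
  taub_slope: -10
calcium_L:                # I_CaL = gCaL * s_inf(V)^2 * (V - ECa)
  s_half: -20
  s_slope: 8
a_type:                   # I_A = gA * e_inf(V) * (V - EK), instantaneous
  e_half: -45
  e_slope: 10
h_current:                # I_h = gh * r * (V - Eh)
  r_half: -75
  r_slope: -5.5
  taur_base_ms: 100
  taur_amp_ms: 300
  taur_half: -70
  taur_slope: 10
calcium_pool:             # Ca' = -kca*(I_CaT + I_CaL) - (Ca - ca0)/tau
  ks_uM: 0.4              # SK half-activation; I_SK = gSK * Ca^2/(Ca^2+ks^2) * (V-EK)
  kca_uM_per_pA_ms: 1.0e-4
  tau_ms: 150
  ca0_uM: 0.05
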