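# Default CA1-like membrane configuration.
#
# Passive constants follow the standard uniform CA1 parameterisation
# (tau_m = 28 ms, Rm = 28 kOhm cm^2, Ra = 150 Ohm cm, Vrest = -65 mV,
# hence Cm = 1 uF/cm^2). The active set covers fast sodium (axosomatic
# `na` and a dendritic variant `nad` with weaker, slower inactivation),
# delayed-rectifier potassium (kdr, n^4), transient A-type potassium (ka,
# a^4 b) concentrated in the dendrites, and a small hyperpolarization-
# activated mixed cation current (ih). Gate kinetics use Boltzmann steady
# states and bell-shaped time constants; temperature factors are folded
# into the constants.
name: ca1_default
passive:
  rm_kohm_cm2: 28
  ra_ohm_cm: 150
  cm_uf_cm2: 1.0
  vrest_mv: -65
  tau_m_ms: 28
channels:
- name: na
  erev_mv: 55
  gbar_s_cm2:
    axon: 0.3
    soma: 0.02
    basal_dendrite: 0.0
    apical_dendrite: 0.0
    connector: 0.01
  gates:
  - {name: m, exponent: 3, inf_vhalf_mv: -38, inf_k_mv: 6, tau_min_ms: 0.03,
     tau_amp_ms: 0.2, tau_vhalf_mv: -38, tau_ka_mv: 12, tau_kb_mv: 12}
  - {name: h, exponent: 1, inf_vhalf_mv: -60, inf_k_mv: -4, tau_min_ms: 0.3,
     tau_amp_ms: 40, tau_vhalf_mv: -70, tau_ka_mv: 5, tau_kb_mv: 1000}
- name: nad
  erev_mv: 55
  gbar_s_cm2:
    axon: 0.0
    soma: 0.0
    basal_dendrite: 0.12
    apical_dendrite: 0.09
    connector: 0.0
  gates:
  - {name: m, exponent: 3, inf_vhalf_mv: -46, inf_k_mv: 4.5, tau_min_ms: 3,
     tau_amp_ms: 0.0, tau_vhalf_mv: -45, tau_ka_mv: 20, tau_kb_mv: 20}
  - {name: h, exponent: 1, inf_vhalf_mv: -40, inf_k_mv: -8, tau_min_ms: 8,
     tau_amp_ms: 25, tau_vhalf_mv: -50, tau_ka_mv: 15, tau_kb_mv: 15}
- name: km
  erev_mv: -90
  gbar_s_cm2:
    axon: 0.0
    soma: 0.002
    basal_dendrite: 0.01
    apical_dendrite: 0.008
    connector: 0.0
  gates:
  - {name: u, exponent: 2, inf_vhalf_mv: -50, inf_k_mv: 4.5, tau_min_ms: 6,
     tau_amp_ms: 0.0, tau_vhalf_mv: -50, tau_ka_mv: 20, tau_kb_mv: 20}
- name: kdr
  erev_mv: -90
  gbar_s_cm2:
    axon: 0.06
    soma: 0.05
    basal_dendrite: 0.004
    apical_dendrite: 0.004
    connector: 0.01
  gates:
  - {name: "n", exponent: 4, inf_vhalf_mv: -45, inf_k_mv: 8, tau_min_ms: 0.5,
     tau_amp_ms: 2.5, tau_vhalf_mv: -45, tau_ka_mv: 15, tau_kb_mv: 15}
- name: ka
  erev_mv: -90
  gbar_s_cm2:
    axon: 0.002
    soma: 0.02
    basal_dendrite: 0.008
    apical_dendrite: 0.008
    connector: 0.005
  gates:
  - {name: a, exponent: 4, inf_vhalf_mv: -45, inf_k_mv: 9, tau_min_ms: 0.15,
     tau_amp_ms: 0.4, tau_vhalf_mv: -40, tau_ka_mv: 15, tau_kb_mv: 15}
  - {name: b, exponent: 1, inf_vhalf_mv: -60, inf_k_mv: -5, tau_min_ms: 4,
     tau_amp_ms: 20, tau_vhalf_mv: -65, tau_ka_mv: 15, tau_kb_mv: 15}
- name: km
  erev_mv: -90
  gbar_s_cm2:
    axon: 0.0
    soma: 0.002
    basal_dendrite: 0.01
    apical_dendrite: 0.008
    connector: 0.0
  gates:
  - {name: u, exponent: 2, inf_vhalf_mv: -50, inf_k_mv: 4.5, tau_min_ms: 6,
     tau_amp_ms: 0.0, tau_vhalf_mv: -50, tau_ka_mv: 20, tau_kb_mv: 20}
- name: kd
  erev_mv: -90
  gbar_s_cm2:
    axon: 0.22
    soma: 0.005
    basal_dendrite: 0.0
    apical_dendrite: 0.0
    connector: 0.0
  gates:
  - {name: a, exponent: 4, inf_vhalf_mv: -50, inf_k_mv: 5, tau_min_ms: 0.8,
     tau_amp_ms: 0.0, tau_vhalf_mv: -45, tau_ka_mv: 20, tau_kb_mv: 20}
  - {name: b, exponent: 1, inf_vhalf_mv: -65, inf_k_mv: -6, tau_min_ms: 300,
     tau_amp_ms: 0.0, tau_vhalf_mv: -60, tau_ka_mv: 20, tau_kb_mv: 20}
- name: ih
  erev_mv: -30
  gbar_s_cm2:
    axon: 0.0
    soma: 0.00005
    basal_dendrite: 0.00005
    apical_dendrite: 0.0001
    connector: 0.00005
  gates:
  - {name: q, exponent: 1, inf_vhalf_mv: -82, inf_k_mv: -8, tau_min_ms: 20,
     tau_amp_ms: 60, tau_vhalf_mv: -80, tau_ka_mv: 20, tau_kb_mv: 20}
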