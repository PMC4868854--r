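units: concentrations in M; rates in s^-1; half-saturations in uM; v_max in uM (M
  biomass)^-1 s^-1
provenance: reference (3 types)
types:
- name: Nitrospira
  strategy: K_chemolithotroph
  v_max_no2: 7.00000000000000089
  k_m_no2: 15.0
  k_m_o2: 10.0
  v_max_oc: 0.0
  k_m_oc: 100.0
  v_max_c: 0.70000000000000018
  k_m_c: 1.0
  mu_max: 6.99999999999999989e-06
  growth_yield: 0.10000000000000001
  mortality: 2.99999999999999986e-07
- name: Nitrobacter_chemolitho
  strategy: r_chemolithotroph
  v_max_no2: 40.0
  k_m_no2: 500.0
  k_m_o2: 60.0
  v_max_oc: 0.0
  k_m_oc: 100.0
  v_max_c: 0.80000000000000004
  k_m_c: 1.0
  mu_max: 1.59999999999999993e-05
  growth_yield: 0.02
  mortality: 2.99999999999999986e-07
- name: Nitrobacter_mixo
  strategy: r_mixotroph
  v_max_no2: 43.37500000000000711
  k_m_no2: 500.0
  k_m_o2: 25.10000000000000142
  v_max_oc: 52.24999999999999289
  k_m_oc: 100.0
  v_max_c: 1.91250000000000009
  k_m_c: 1.0
  mu_max: 6.90000000000000001e-06
  growth_yield: 0.02
  mortality: 2.99999999999999986e-07
  flexible_mu_max:
  - - 0.0
    - 6.90000000000000001e-06
  - - 0.005
    - 2.78000000000000015e-05
  flexible_k_m_o2:
  - - 0.0001
    - 25.10000000000000142
  - - 0.00625
    - 125.0
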