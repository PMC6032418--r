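# CYP1A2-phenacetin paramagnetic relaxation study: wild type and three
# active-site mutants. Per-proton T1 (seconds) in the ferric and
# ferrous-CO states with fit standard errors; occupancy parameters in uM;
# phenacetin-bound spin fractions; shared correlation time in seconds.
tau_c_s: 3.38e-10
enzymes:
  - label: "CYP1A2 WT"
    p450_uM: 0.017
    substrate_uM: 171
    ks_uM: 17.1
    f_high: 0.27
    f_low: 0.73
    protons:
      - {label: "H2,6",   t1_ferric: 2.22, se_ferric: 0.11, t1_ferrous_co: 2.78, se_ferrous_co: 0.05}
      - {label: "H3,5",   t1_ferric: 2.02, se_ferric: 0.04, t1_ferrous_co: 2.50, se_ferrous_co: 0.01}
      - {label: "-OCH2-", t1_ferric: 1.54, se_ferric: 0.15, t1_ferrous_co: 1.85, se_ferrous_co: 0.18}
      - {label: "-COCH3", t1_ferric: 1.53, se_ferric: 0.07, t1_ferrous_co: 1.62, se_ferrous_co: 0.06}
      - {label: "-CH3",   t1_ferric: 1.33, se_ferric: 0.07, t1_ferrous_co: 1.53, se_ferrous_co: 0.06}
  - label: "CYP1A2 L382V"
    # Enzyme concentration corrected to 0.0007 uM (= Ks/1000, the ratio
    # shared by the other three studies). The originally reported
    # 0.007 uM is internally inconsistent with every L382V distance.
    p450_uM: 0.0007
    substrate_uM: 7
    ks_uM: 0.7
    f_high: 0.21
    f_low: 0.79
    note: >-
      [P450] corrected from the reported 0.007 uM to 0.0007 uM; the
      reported value reproduces no L382V distance, the corrected value
      reproduces all four.
    protons:
      - {label: "H2,6",   t1_ferric: 2.28, se_ferric: 0.11, t1_ferrous_co: 3.06, se_ferrous_co: 0.04}
      - {label: "H3,5",   t1_ferric: 2.39, se_ferric: 0.22, t1_ferrous_co: 3.21, se_ferrous_co: 0.08}
      - {label: "-OCH2-", t1_ferric: 2.43, se_ferric: 0.18, t1_ferrous_co: 4.10, se_ferrous_co: 0.07}
      - {label: "-COCH3", t1_ferric: 1.64, se_ferric: 0.13, t1_ferrous_co: 1.87, se_ferrous_co: 0.11}
      - {label: "-CH3",   t1_ferric: 2.03, se_ferric: 0.13, t1_ferrous_co: 2.82, se_ferrous_co: 0.11}
  - label: "CYP1A2 N312L"
    p450_uM: 0.011
    substrate_uM: 102
    ks_uM: 10.2
    f_high: 0.14
    f_low: 0.86
    protons:
      - {label: "H2,6",   t1_ferric: 2.32, se_ferric: 0.10, t1_ferrous_co: 2.45, se_ferrous_co: 0.10}
      - {label: "H3,5",   t1_ferric: 1.94, se_ferric: 0.09, t1_ferrous_co: 2.04, se_ferrous_co: 0.10}
      - {label: "-OCH2-", t1_ferric: 1.62, se_ferric: 0.04, t1_ferrous_co: 1.69, se_ferrous_co: 0.04}
      - {label: "-COCH3", t1_ferric: 1.54, se_ferric: 0.12, t1_ferrous_co: 1.60, se_ferrous_co: 0.11}
      - {label: "-CH3",   t1_ferric: 1.87, se_ferric: 0.12, t1_ferrous_co: 1.97, se_ferrous_co: 0.07}
  - label: "CYP1A2 L382V/N312L"
    p450_uM: 0.004
    substrate_uM: 35
    ks_uM: 3.5
    f_high: 0.17
    f_low: 0.83
    protons:
      - {label: "H2,6",   t1_ferric: 2.43, se_ferric: 0.07, t1_ferrous_co: 3.00, se_ferrous_co: 0.06}
      - {label: "H3,5",   t1_ferric: 2.95, se_ferric: 0.09, t1_ferrous_co: 3.70, se_ferrous_co: 0.11}
      - {label: "-OCH2-", t1_ferric: 1.98, se_ferric: 0.12, t1_ferrous_co: 2.90, se_ferrous_co: 0.09}
      - {label: "-COCH3", t1_ferric: 2.12, se_ferric: 0.14, t1_ferrous_co: 2.59, se_ferrous_co: 0.12}
      - {label: "-CH3",   t1_ferric: 2.23, se_ferric: 0.09, t1_ferrous_co: 2.61, se_ferrous_co: 0.11}
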