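# Subgroup scenario, mismatch-repair-proficient (pMMR) population: lenvatinib + pembrolizumab (LP)
# versus physician's-choice chemotherapy in pretreated advanced endometrial
# cancer. Costs in 2021-December US dollars; ranges are the published
# sensitivity intervals (+/-25% unless clipped); transition probabilities
# are fixed monthly values fitted from the trial's survival curves.
label: "LP vs chemotherapy, pretreated advanced endometrial cancer (pMMR subgroup)"
population: pMMR
settings:
  horizon_cycles: 600
  cycle_length_months: 1
  annual_discount_rate: 0.03
  wtp_per_qaly: 100000
  half_cycle_correction: true
parameters:
  Lenvatinib:
    {base: 16166.98, low: 12125.24, high: 20208.73, distribution: Gamma}
  Pembrolizumab:
    {base: 16429.87, low: 12322.40, high: 20537.34, distribution: Gamma}
  Doxorubicin:
    {base: 164.16, low: 123.12, high: 205.20, distribution: Gamma}
  Paclitaxel:
    {base: 205.20, low: 153.90, high: 256.50, distribution: Gamma}
  Costs of administration per 10 mins:
    {base: 55.98, low: 41.99, high: 69.98, distribution: Gamma}
  Hypertension:
    {base: 7965.60, low: 5974.20, high: 9957.00, distribution: Gamma}
  Diarrhea:
    {base: 7795.80, low: 5846.85, high: 9744.75, distribution: Gamma}
  Anemia:
    {base: 14314.20, low: 10735.65, high: 17892.75, distribution: Gamma}
  Neutropenia:
    {base: 14429.73, low: 10822.30, high: 18037.16, distribution: Gamma}
  Neutrophil count decreased:
    {base: 14429.73, low: 10822.30, high: 18037.16, distribution: Gamma}
  WBC decreased:
    {base: 7071.65, low: 5303.74, high: 8839.56, distribution: Gamma}
  Costs of disease management:
    {base: 360.42, low: 270.32, high: 450.53, distribution: Gamma}
  Testing for dMMR/MSI-H status-one set:
    {base: 666.40, low: 499.80, high: 833.00, distribution: Gamma}
  Costs of palliative care-one set:
    {base: 11266.07, low: 8449.55, high: 14082.59, distribution: Gamma}
  Utility of PFS state:
    {base: 0.817, low: 0.613, high: 1.000, distribution: Beta}
  Utility of PD state:
    {base: 0.779, low: 0.584, high: 0.974, distribution: Beta}
arms:
- name: LP
  drugs: [Lenvatinib, Pembrolizumab]
  # the published acquisition total exceeds the two drug rows by $223.91,
  # expressed as administration time: $223.91 / $55.98 x 10 min (~40 min)
  administration_minutes_per_month: 39.99821365
  adverse_events:
    Hypertension: 0.379
    Diarrhea: 0.076
  subsequent_therapy_acceptance: 0.280
  transitions:
    {pfs_stay: 0.895, pfs_pd: 0.066, pfs_death: 0.039,
     pd_stay: 0.937, pd_death: 0.063}
  median_pfs: 6.6
  median_os: 17.4
- name: chemotherapy
  drugs: [Doxorubicin, Paclitaxel]
  # residual of the published acquisition total ($765.31) over the two drug
  # rows, expressed as administration time: $395.95 / $55.98 x 10 min
  administration_minutes_per_month: 70.73061808
  adverse_events:
    Anemia: 0.147
    Neutropenia: 0.258
    Neutrophil count decreased: 0.212
    WBC decreased: 0.103
  subsequent_therapy_acceptance: 0.481
  transitions:
    {pfs_stay: 0.809, pfs_pd: 0.135, pfs_death: 0.056,
     pd_stay: 0.904, pd_death: 0.096}
  median_pfs: 3.8
  median_os: 12.0
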