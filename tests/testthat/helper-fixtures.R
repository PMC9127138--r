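# Shared fixtures: the packaged trial scenarios are loaded once per run, and
# a minimal two-arm scenario list is built in code for schema-edit tests.

base_scenario <- keynote775_scenario("overall")
pmmr_scenario <- keynote775_scenario("pMMR")

# A small, fully explicit scenario list; tests copy and perturb it to probe
# the loader's validation.
minimal_scenario_list <- function() {
  list(
    label = "minimal",
    population = "overall",
    settings = list(horizon_cycles = 200L, annual_discount_rate = 0.03,
                    wtp_per_qaly = 1e5, half_cycle_correction = TRUE,
                    cycle_length_months = 1),
    parameters = list(
      "Drug X" = list(base = 1000, low = 750, high = 1250,
                      distribution = "Gamma"),
      "Costs of administration per 10 mins" =
        list(base = 50, low = 37.5, high = 62.5, distribution = "Gamma"),
      "Costs of disease management" =
        list(base = 300, low = 225, high = 375, distribution = "Gamma"),
      "Testing for dMMR/MSI-H status-one set" =
        list(base = 500, distribution = "Fixed"),
      "Costs of palliative care-one set" =
        list(base = 8000, low = 6000, high = 10000, distribution = "Gamma"),
      "Utility of PFS state" =
        list(base = 0.8, low = 0.6, high = 1.0, distribution = "Beta"),
      "Utility of PD state" =
        list(base = 0.6, low = 0.45, high = 0.75, distribution = "Beta")
    ),
    arms = list(
      list(name = "A", drugs = "Drug X",
           administration_minutes_per_month = 20,
           adverse_events = list(),
           subsequent_therapy_acceptance = 0.3,
           transitions = list(pfs_stay = 0.9, pfs_pd = 0.06,
                              pfs_death = 0.04, pd_stay = 0.92,
                              pd_death = 0.08)),
      list(name = "B", drugs = list(),
           administration_minutes_per_month = 0,
           adverse_events = list(),
           subsequent_therapy_acceptance = 0.5,
           transitions = list(pfs_stay = 0.8, pfs_pd = 0.13,
                              pfs_death = 0.07, pd_stay = 0.9,
                              pd_death = 0.1))
    )
  )
}
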