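Package: strokesim
Title: Monte Carlo Simulation of the Acute Stroke Thrombolysis Pathway
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Patient-flow simulation of the hyperacute stroke care chain, from
    symptom onset through prehospital referral (general practitioner, emergency
    call, self-referral or in-hospital onset) to intravenous thrombolysis (IVT).
    Activity durations are modelled as lognormal distributions fitted in closed
    form from published median/interquartile-range summaries, a scenario engine
    expresses service improvements as composable transformations of the pathway
    configuration (median rescaling, hard caps, delay elimination, referral-mix
    shifts), and outcome models translate simulated onset-to-treatment times
    into IVT utilisation, treatment-time band shares, attributable excellent
    functional outcome (modified Rankin Scale 0-1) and extra healthy-life days.
    Includes a synthetic patient-level cohort generator and a calibration
    routine that fixes unobserved pathway parameters against published cohort
    statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
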