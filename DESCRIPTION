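Package: virtualckd
Title: Virtual-Population Simulation of Calcium Channel Blockade in
    Hypertensive Chronic Kidney Disease
Version: 0.1.0
Authors@R:
    person("Virtualckd", "Developers", email = "virtualckd@example.org",
           role = c("aut", "cre"))
Description: A reduced-order whole-body cardiorenal model of hypertensive
    chronic kidney disease with pressure-threshold glomerulosclerosis,
    amlodipine pharmacokinetics/pharmacodynamics and renin-angiotensin
    system blockade, plus a virtual-population calibration algorithm that
    selects model parameterizations statistically indistinguishable from a
    patient-level clinical cohort (blood pressure and glomerular filtration
    rate before and after three years of amlodipine).  Includes a synthetic
    cohort generator emulating the calcium-channel-blocker arm of the AASK
    trial, in-silico trial protocols (control, CCB, CCB + RAS blockade),
    and the nonparametric statistical battery used for calibration and
    reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
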