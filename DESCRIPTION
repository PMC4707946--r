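Package: obesim
Title: Agent-Based Simulation of Childhood BMI Dynamics and School-Based
    Obesity Interventions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An individual-based simulation of body-mass-index dynamics in
    children aged 6 to 12. Simulated children move daily between home,
    school, and an after-school community program in three stylized town
    types, accumulate energy intake (as a multiple of Schofield resting
    metabolic rate) and MET-weighted energy expenditure, and convert the
    daily calorie gap into weight change at 7,700 kcal per kilogram.
    Initial BMI distributions are drawn with the LMS (Box-Cox) growth
    reference transform. Two multi-component obesity-prevention
    interventions -- in-school physical-activity programs and
    out-of-school-time dietary and activity components -- are modeled with
    explicit dose, reach, and retention. Includes a synthetic
    reference-bundle generator so the simulator runs without external
    growth-chart or survey data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
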