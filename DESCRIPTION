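Package: careseek
Title: Agent-Based Simulation of Care-Seeking Behaviour and Diabetes Diagnosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A seedable agent-based simulator of health-seeking behaviour and
    health-care provider choice for populations with undiagnosed diabetes.
    Individual decisions combine the theory of planned behaviour (attitude,
    perceived behavioural control, social norms), the health belief model
    (risk aversion, self-efficacy) and goal framing theory (hedonic and
    normative goals for provider choice), with trust and reputation dynamics
    propagating over a spatial social network. Includes a synthetic population
    generator driven by configurable demographic marginals, scenario and
    intervention tooling, replicated experiments with confidence intervals,
    one-factor-at-a-time sensitivity analysis, and summary-statistic
    calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
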