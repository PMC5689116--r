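Package: smbgpatterns
Title: Rule-Based Glycemic Pattern Detection for Self-Monitored Blood
    Glucose Logs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A configurable rule engine that screens self-monitored blood
    glucose, insulin bolus, carbohydrate and insulin-pump event logs for 19
    clinically defined glycemic patterns grouped in five blocks (glycemic
    variability, hypoglycemia, hyperglycemia, use of the system and
    treatment adherence), including the low/high blood-glucose risk indices
    and percentage coefficient of variation. Also provides the agreement
    statistics used to validate automated pattern detection against expert
    panels (percent agreement, Cohen's kappa with asymptotic confidence
    intervals and interpretation bands, evaluation-weighted pooling), a
    seeded synthetic log generator with per-pattern injection for
    end-to-end testing, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
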