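Package: kvagrade
Title: Keratopathy Visual Acuity (KVA) Grading with Precompiled Transition Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Computes the Keratopathy Visual Acuity (KVA) grade used to
    monitor belantamab mafodotin ocular toxicity. Provides a unit-agnostic
    visual-acuity layer (Snellen, logMAR, decimal) over a canonical acuity
    chart, a library of per-baseline finite-state transition models mapping
    any current reading to a best-corrected-visual-acuity change grade, a
    validated conditional question schema for the corneal examination, and
    the max-severity combination of both components across both eyes into
    an overall KVA grade. Includes a JSON session format, a command-line
    interface, deterministic report rendering, and a seeded synthetic
    exam-session generator for property testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    yaml,
    tools,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
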