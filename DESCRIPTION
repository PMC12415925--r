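Package: wildclockr
Title: Design and Stress-Test Epigenetic Clocks for Wildlife
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing and stress-testing DNA methylation age
    predictors ("epigenetic clocks") for wildlife species. Simulates
    age-associated CpG methylation with controllable class bias, age bias
    and ageing error; fits sparse elastic-net clocks; applies alignment-,
    variance- and association-based CpG feature selection; evaluates clocks
    with hold-out, k-fold and leave-one-out validation; and runs seeded
    replicate experiments quantifying how sampling design choices change
    clock accuracy.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    glmnet,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
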