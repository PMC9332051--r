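Package: ckdneeds
Title: Projecting Health Needs of Chronic Kidney Disease Secondary to Type 2 Diabetes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A five-state discrete-time Markov model of diabetic nephropathy
    (normoalbuminuria, microalbuminuria, macroalbuminuria, end-stage renal
    disease, cardiovascular death) used to project chronic kidney disease
    burden in a diabetic population over a multi-year horizon. Prevalent
    patients are initialized from age-group summaries of years since
    diagnosis via quantile-matched gamma fits or kernel density estimates;
    incident patients accrue yearly from a population projection and an
    incidence schedule. Provides analytic expectation propagation, an
    individual-level Monte-Carlo engine with a sample-size rule, a synthetic
    survey-data generator, and tidy projection tables with plotting and
    broom-style tidiers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
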