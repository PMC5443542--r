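Package: cohi
Title: Canadian Ocean Health Index Scoring and Goal Weighting
Version: 0.1.0
Authors@R: person("COHI", "Maintainers", email = "cohi@example.org", role = c("aut", "cre"))
Description: Tools to compute a national Ocean Health Index for Canada: the
    generic goal-scoring engine (status, trend, pressures and resilience
    combined into a likely future state and a 0-100 goal score, aggregated
    under arbitrary goal weights), customized goal calculators for Carbon
    Storage (subsea permafrost and methane clathrate habitats delimited by
    depth and latitude), Iconic Species (COSEWIC risk weights with
    range-based spatial weighting) and the Aboriginal Needs goal
    (food-to-fuel price ratios and sea-ice access relative to a 1979
    baseline), four survey-derived goal-weighting schemes (Equal, Likert,
    best-worst ranks and best-worst conditional-logit coefficients), a
    bootstrap group-comparison procedure, and seeded synthetic-data
    generators so the full pipeline can be exercised without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
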