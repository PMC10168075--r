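Package: innerbark
Title: Diurnal Inner Bark Thickness Dynamics and Phloem Turgor Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of diurnal inner-bark thickness dynamics in tree trunks
    from paired point-dendrometer and stem-psychrometer records. Derives inner
    bark thickness from dual dendrometers, removes the seasonal growth trend,
    extracts daily amplitude, extrema timing, and the lag relative to xylem
    water potential, fits a first-order xylem-phloem radial water-exchange
    (capacitor) model per day by AR(1) generalized least squares to isolate a
    phloem turgor-related signal, and estimates phloem hydrostatic pressure
    and its axial gradient from inner-bark sap osmolality via van 't Hoff.
    Includes a seeded synthetic field-campaign generator so every stage is
    verifiable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    zoo,
    jsonlite,
    yaml
Suggests:
    nlme,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
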