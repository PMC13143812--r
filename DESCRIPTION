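Package: mobair
Title: Mobility-Integrated Air Pollution Exposure Assessment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and compares residential, agent-based-mobility and
    GPS-track-based long-term NO2 and PM2.5 exposures. Provides a synthetic
    urban world generator (pollution surfaces, background-station series,
    transport network, origin-destination commuting matrices, agents, GPS
    tracks), diurnal rescaling of annual concentration surfaces to hourly
    weekday/weekend surfaces from background-station ratios, an agent-based
    mobility model with Monte Carlo work-location realizations, time-weighted
    exposure aggregation over activity diaries and GPS trajectories, and
    Bland-Altman and R-squared agreement analysis between exposure metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    yaml,
    xml2,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
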