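Package: melbreath
Title: Sleep Breathing-State Monitoring from Whole-Night Breathing Audio
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Segments whole-night breathing-sound recordings into breathing
    cycles by characteristic-moment-waveform analysis, extracts per-cycle
    Mel-scale spectral-occupancy indexes (MsL and N_MsL) from Yule-Walker
    autoregressive power spectra passed through a triangular Mel filter bank,
    and classifies each cycle as normal, abnormal or snoring with simple
    per-label threshold rules. Breathing stops between cycles are called as
    apnea (> 10 s) or hypopnea (6-10 s) events and the night is summarised by
    the normal-breathing ratio R_Sleep. A labelled synthetic-night generator
    is included so that the whole pipeline can be exercised and scored without
    clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    graphics,
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
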