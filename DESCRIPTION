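Package: envtrack
Title: Neural Envelope Tracking of Continuous Speech from EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify how strongly the EEG tracks the amplitude
    envelope of continuous speech. Implements gammatone power-law envelope
    extraction, EEG artifact handling (amplitude blanking and multichannel
    Wiener filtering of ocular artifacts), zero-phase Chebyshev type-II
    band-pass filtering and polyphase resampling, backward ridge decoders
    for stimulus reconstruction, forward temporal response functions with
    P1/N1/P2 peak extraction, bootstrapped Spearman tracking scores,
    psychometric speech-reception-threshold fitting, and a permutation
    statistics battery including cluster-based tests over channels and
    lags. A synthetic-study generator with known ground truth supports
    end-to-end validation without access to raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    Rcpp,
    signal,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    car,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
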