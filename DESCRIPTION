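Package: bivarcc
Title: Coupling and Causality Measures for Bivariate Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Time-domain, frequency-domain and information-theoretic measures
    of symmetric coupling and directional causality between two stationary
    time series. Implements linear parametric estimation via bivariate
    autoregressive (ARX) models, with restricted univariate models obtained
    through state-space/Riccati and Yule-Walker/Lyapunov routes, yielding
    Granger causality, total dependence and instantaneous causality together
    with their information-theoretic halves (transfer entropy, mutual
    information rate, instantaneous transfer). Frequency-domain profiles
    (coherence, directed coherence, Geweke spectral measures) are integrated
    over arbitrary bands via the spectral integration property. Model-free
    estimators (k-nearest-neighbour, binning, permutation) with uniform and
    non-uniform embedding, time-shift surrogate significance testing, a
    seeded benchmark simulator with known population measures, and a
    non-parametric weighted-covariance spectral estimator complete the
    toolkit.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    signal,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
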