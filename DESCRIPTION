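Package: strokesim
Title: Monte Carlo Simulation of Embolic Stroke in a Synthetic Cerebral
    Arterial Tree
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Three-dimensional Monte Carlo simulation of embolic stroke.
    Builds a parametric, mirror-symmetric brain phantom (grey/white matter,
    arterial perfusion territories) and a synthetic spatially embedded
    cerebral arterial tree obeying a Murray-type bifurcation law with
    exponent 3.2.  Single emboli are released at the circle of Willis and
    routed probabilistically through bifurcations according to relative
    Poiseuille flows; emboli lodge where both daughter vessels are narrower
    than the embolus, dissolve linearly in time, and starve terminal
    vessels of flow.  Terminals without flow for a threshold duration
    produce ischaemic lesions that are voxelised on the phantom.  In-silico
    cohort trials relate infarct volume to embolus diameter through an
    offset power law fitted by Levenberg-Marquardt nonlinear least squares,
    invert that law to size emboli from lesion volumes, and accumulate
    probabilistic lesion overlap maps written as NIfTI volumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    minpack.lm,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
NeedsCompilation: yes
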