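Package: spiral4d
Title: Retrospectively Gated Spiral 4D Flow MRI: Simulation, Reconstruction
    and Intracardiac Flow Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Acquisition-to-analysis chain for retrospectively cardiac-gated
    stack-of-spirals phase-contrast (4D flow) MRI. Designs slew- and
    gradient-limited variable-density spiral k-space trajectories, simulates
    velocity-encoded sampling of an analytic divergence-free beating-flow
    phantom with navigator respiratory gating, sorts readouts onto a
    normalized average cardiac cycle (systole kept constant, diastole
    stretched), reconstructs images by Kaiser-Bessel convolution gridding
    with Pipe-Menon density compensation, removes eddy-current background
    velocity offsets by a fourth-order polynomial fitted to static tissue,
    and quantifies flow: plane volume flow, peak flow rate and velocity, and
    four-component pathline decomposition of chamber flow (direct flow,
    retained inflow, delayed ejection, residual volume) with
    mass-conservation quality control, least-squares regression with F-test
    and Bland-Altman agreement statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    graphics
Suggests:
    testthat (>= 3.0.0),
    oro.nifti,
    withr,
    optparse
Config/testthat/edition: 3
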