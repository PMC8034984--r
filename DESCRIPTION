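Package: rigidISF
Title: Rigid-Body Intermediate Scattering Functions and Translation-Rotation
    Decoupling Analysis for Proteins in Solution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates Brownian motion of rigid coarse-grained protein models
    (a dissipative particle dynamics fluid with an embedded rigid body, and a
    fast overdamped rigid-body Brownian-dynamics surrogate with an anisotropic
    body-frame diffusion tensor) and computes the coherent intermediate
    scattering functions measured by Neutron Spin Echo, decomposed into total,
    center-of-mass, rotational, and structure-weighted translational parts.
    Extracts short-time effective diffusion coefficients Deff(Q), evaluates the
    orientationally weighted translational diffusion coefficient Dtrans(Q) by
    spherical quadrature, and quantifies the error of the widely used
    translation-rotation decoupling approximations used to interpret NSE data
    on anisotropic particles such as monoclonal antibodies.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    jsonlite,
    minpack.lm,
    pracma,
    rlang,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
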