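Package: condtensor
Title: Conductivity Tensor Reconstruction from Multi-b Diffusion MRI
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for reconstructing low-frequency electrical conductivity
    tensors of tissue from diffusion-weighted MRI. Implements five
    cross-property models that map water diffusion tensors to conductivity
    tensors (a linear eigenvalue model, a force equilibrium model, a volume
    constraint model, a volume fraction model, and conductivity tensor
    imaging driven by a high-frequency conductivity map), together with a
    synthetic phantom and brain simulator, single-tensor and bi-exponential
    multi-b diffusion fitting, NIfTI input/output, and the evaluation
    statistics used to compare the models (ROI summaries, relative errors,
    relative-difference maps, regressions and anisotropy ratios).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
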