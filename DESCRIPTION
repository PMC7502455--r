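Package: laosfit
Title: Fractional Viscoelastic Characterisation of Soft Tissue Under
    Combined Compression and Oscillatory Shear
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterising the nonlinear viscoelastic behaviour of
    soft tissue (liver, in particular) from rotational-rheometer torque traces
    acquired under combined compressive preload and large-amplitude oscillatory
    shear (LAOS).  Provides the exact compression-torsion kinematics of a
    cylindrical sample, three fractional viscoelastic constitutive models
    (a modified Mooney-Rivlin, an Ogden-type and a Fung-exponential form,
    each driven by a Caputo fractional derivative), a forward torque
    simulator, a synthetic-data generator emulating an 18-test compression /
    shear / frequency protocol with strain softening, and a model-fitting
    engine that sweeps the nonlinear parameters while solving the linear
    ones by nonnegative least squares under three error norms (L2,
    point-wise and parameter-scaling).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
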