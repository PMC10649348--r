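Package: implantflow
Title: Reduced-Order Multiphase Flow Model of Blood and Fibrinogen Infiltration Around Screw Implants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A two-dimensional volume-of-fluid simulator of early blood and
    fibrinogen infiltration into the peri-implant gap around screw-shaped
    bone implants. Couples an incompressible laminar projection solver with
    interface capturing, contact-angle wetting (explicit or Wenzel-effective
    roughness treatment), and passive fibrinogen transport, and reduces the
    fields to zone-wise statistics: per-zone fibrinogen mass, mean blood
    speed, infiltration ratios, and the fibrinogen recruitment/retention
    index. Includes analytic benchmark fixtures (plane Poiseuille flow,
    static droplet, sessile droplet, capillary infiltration, scalar
    transport) and a four-scenario study comparing smooth versus microrough
    and hydrophobic versus superhydrophilic implant surfaces.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    ggplot2,
    rlang,
    generics,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
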