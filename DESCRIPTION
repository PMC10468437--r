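Package: reactscope
Title: Simulation and Analysis of the Reactive Scope Model of Physiological Stress
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for simulating the reactive scope model of the
    physiological stress response as a switched system of ordinary
    differential equations. Provides stress-event kernels (box, ramp,
    Gaussian) and summed stress schedules, circadian/seasonal baseline
    mediator dynamics with a predictive-homeostasis threshold, an exact
    event-driven integrator for the Heaviside-switched wear-and-tear
    dynamics of the reactive-homeostasis threshold (with a smooth sigmoid
    switching variant), senescence extensions with closed-form solutions,
    detection of reactive/overload episodes in trajectories, recovery of
    the wear rate from episode geometry, named scenario fixtures, and a
    command-line interface for config-driven runs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
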