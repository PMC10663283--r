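Package: actspace
Title: Spatiotemporal Feasibility Analysis of Muscle Activation Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing the feasible activation space of
    tendon-driven limb models under temporal constraints. Builds the convex
    polytope of all muscle-activation trajectories that produce a prescribed
    sequence of isometric endpoint wrenches subject to per-step
    activation-contraction (Lipschitz) rate limits, samples it uniformly at
    random with a null-space Hit-and-Run Markov chain, and quantifies how rate
    limits and seed (initial-activation) choices shrink the reachable
    activation space: activation speeds, per-muscle occupancy, per-timestep
    principal-component projections, and seeded versus unseeded convex-hull
    area-reduction ratios.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    quadprog,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    arrow,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
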