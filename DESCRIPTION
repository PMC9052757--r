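Package: allostate
Title: Trajectory Analysis of Allosteric Activation in Heterodimeric Enzymes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis machinery for characterizing slow allosteric
    activation in molecular dynamics trajectories of the bienzyme
    imidazole glycerol phosphate synthase (IGPS, HisF + HisH).
    Computes backbone-dihedral, interface-angle and distance order
    parameters; classifies oxyanion-strand conformational states and
    substrate-binding phases by threshold rules; reconstructs free-energy
    landscapes from sampled populations and from multi-walker
    well-tempered metadynamics hill records; detects spontaneous binding
    events; and builds shortest-path-map (SPM) residue communication
    networks from displacement cross-correlations, including a sliding
    time-window (te-SPM) variant.  A synthetic-data module generates
    Langevin trajectories on analytic periodic multi-well potentials,
    metadynamics hill streams, binding-distance traces and correlated
    pseudo-C-alpha ensembles with planted communication paths, so the
    whole pipeline is exercisable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    igraph,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
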