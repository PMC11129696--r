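Package: wristsim
Title: Tendon-Driven Wrist Motion Simulation and Marker-Based Biplanar
    X-Ray Reconstruction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A virtual tendon-driven wrist motion simulator and the full
    marker-based reconstruction and analysis chain used with biplanar X-ray
    videoradiography. Builds a two-segment universal-joint wrist actuated by
    the five major flexor and extensor tendons, generates actuator
    displacement profiles and synthetic bead trajectories, simulates the
    rig's force-equalization, displacement-tracking and force-cap control
    loops, reconstructs bone poses by direct linear transform calibration,
    biplanar triangulation and orthogonal Procrustes fitting, decomposes
    wrist rotation into pronation, flexion and deviation angles in
    anatomical radius and third-metacarpal frames, and derives range of
    motion, dart thrower's motion plane, circumduction ellipse and
    inter-trial/inter-specimen repeatability statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    signal,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
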