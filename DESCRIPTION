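Package: rigkit
Title: Simulation-Backed Neurophysiology Acquisition Engine and Analysis Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A hardware-free engine for episodic neurophysiology acquisition
    and analysis. Models a rig as a hierarchy of optomechanical devices with
    3D affine transforms into a global sample coordinate system; executes
    declarative multi-device tasks with trigger-aware start ordering over
    simulated amplifiers, cameras, scan mirrors, stages and lasers; calibrates
    the galvanometric mirror voltage-to-position mapping; stores results in a
    hierarchical session with human-readable JSON indices; and provides
    analysis routines for patch-clamp membrane properties, current-step IV
    metrics, synaptic event detection, photostimulation map classification,
    and calcium-imaging ROI series.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    yaml,
    jsonlite,
    signal
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
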