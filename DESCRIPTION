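Package: armdyn
Title: Personalized Inverse Dynamics for Net Joint Forces of the Upper Extremity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes net joint forces and moments at the wrist, elbow and
    humerothoracic joint of a personalized rigid-body model of the upper
    extremity by distal-to-proximal Newton-Euler recursion.  Body segment
    parameters are estimated from subject anthropometry by linear regression;
    segment kinematics are reconstructed from labelled optoelectronic marker
    trajectories via static joint-center calibration, cluster-based technical
    frames and Euler-angle joint coordinate systems; results are expressed in
    world coordinates and in the anatomical axes of movement
    (flexion/extension, abduction/adduction, axial rotation).  A built-in
    forward-kinematic simulator generates isolated shoulder flexion/extension
    movements at prescribed internal-rotation positions, reproducing the
    increase and redirection of humerothoracic net joint forces associated
    with an internal shoulder rotation coping posture.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    deSolve,
    jsonlite,
    optparse
Config/testthat/edition: 3
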