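# armdyn — net joint forces of the upper extremity by inverse dynamics

`armdyn` is an R package for computing **net joint forces and moments at the
wrist, elbow and humerothoracic (shoulder) joint** of a personalized
rigid-body model of the arm, and for simulating how a pathological
**internal shoulder rotation position (IRO)** — the typical coping posture in
obstetric brachial plexus palsy — increases and redirects the humerothoracic
net joint force during shoulder flexion/extension.  It is aimed at movement
scientists and clinical gait/upper-limb laboratories working with
optoelectronic marker data and end-effector force sensors.

## The model

Body segment parameters (mass, centre of mass, moments of inertia) of hand,
forearm and upper arm are estimated from body mass *m*, stature *H* and
segment lengths by linear regression (Zatsiorsky–Seluyanov adult
coefficients by default, user-replaceable).  Inverse dynamics starts at the
most distal joint: with the 6-DoF end-effector load **F**<sub>ext</sub>, hand
mass *m<sub>h</sub>*, gravity **g** and hand CoM acceleration
**a**<sub>h</sub>, the wrist net joint force in the world coordinate system
(WCS) is

    F_w = diag(-1,-1,1) · F_ext + m_h · g − m_h · a_h

where the diagonal sign matrix maps the sensor convention into the WCS.
The recursion then carries the load proximally through forearm and upper
arm (F<sub>prox</sub> = F<sub>dist</sub> + m·g − m·a), terminating at the
humerothoracic joint.  Joint coordinate systems use the Euler sequence
R\* = R<sub>x</sub>(φ<sub>x</sub>)·R<sub>y</sub>(φ<sub>y</sub>)·R<sub>z</sub>(φ<sub>z</sub>)
(flexion/extension, abduction/adduction, axial rotation), chained as
R<sub>S</sub> = R\*<sub>S</sub>,
R<sub>E</sub> = R\*<sub>S</sub>·R<sub>z</sub>(90°)·R\*<sub>E</sub>,
R<sub>W</sub> = R<sub>E</sub>·R\*<sub>W</sub>; forces are expressed in the
anatomical axes of movement (body coordinate system, BCS) via
**F**<sub>body</sub> = Rᵀ·**F**<sub>wcs</sub>.

A forward-kinematic simulator generates isolated flexion/extension
movements (minimum-jerk profile, straight elbow and wrist) at a constant
IRO between 0° and 50°, including synthetic marker trajectories, so the
whole measurement pipeline — static joint-centre calibration, cluster
technical frames, joint angles, filtered numerical differentiation,
recursion — can be validated end to end.

## Worked example

Simulate the IRO experiment on the default child-like synthetic subject
(30 kg, 1.35 m, regression-derived segment parameters) and summarise the
humerothoracic force per anatomical axis:

```r
library(armdyn)
sub <- synthetic_subject()
sw  <- run_iro_experiment(subject = sub)   # IRO grid 0,10,...,50 deg
print(report(sw))
```

```
Internal-rotation sweep of humerothoracic net joint forces

 iro_deg peak_flexion_extension peak_abduction_adduction peak_rotation
       0                  0.000                   15.476        16.143
      10                  2.687                   15.241        16.143
      20                  5.293                   14.543        16.143
      30                  7.738                   13.403        16.143
      40                  9.948                   11.855        16.143
      50                 11.855                    9.948        16.143
 peak_norm
    18.093

flexion/extension-axis peak across the grid: monotone
peak-force direction rotates by 31.1 deg from first to last level
```

Reading the table: the same physical movement is performed at every IRO —
the overall force magnitude (`peak_norm`, 18.1 N) does not change — but an
increasing internal rotation re-expresses that force in the anatomical
axes: the flexion/extension-axis component grows strictly from 0 N to
11.9 N between 0° and 50° while the abduction/adduction component falls,
i.e. the force both grows along the axis loading the humeral head and
rotates direction (by 31°), the mechanism proposed to drive increased
coaptation and osseous malformation in the affected shoulder.  At the
typical pathological posture (40°) the flexion/extension-axis peak is
9.9 N versus 2.7 N at the 10° seen in healthy children.

Recorded trials are analysed the same way from files
(`analyze_trial("markers.csv", "static.csv", "subject.txt",
ext = "force.csv", output_dir = "out/")`), or from the shell via the thin
CLI in `inst/cli/armdyn` (`simulate`, `analyze`, `sweep`, `report`
subcommands).

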