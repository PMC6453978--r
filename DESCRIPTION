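Package: photoMOF
Title: Host-Guest Pairing and Topochemical Photodimerization Analysis in
    Porous Crystals
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis toolkit for guest nucleobases confined in the channels
    of a bio-derived metal-organic framework. Provides grid-based
    probe-accessible void volume and capacity arithmetic on periodic crystal
    structures, Watson-Crick adenine-thymine hydrogen-bond detection and
    pairing statistics over molecular trajectories, Schmidt/Woodward-Hoffmann
    screening of thymine pairs for [2+2] photodimerization readiness,
    solution-depletion uptake quantification via Beer-Lambert absorbance, BET
    and Dubinin-Radushkevich isotherm fits, and a seeded synthetic
    channel/trajectory generator with planted, recoverable ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'tables.R'
    'AllClasses.R'
    'structio.R'
    'voidspace.R'
    'pairing.R'
    'topochem.R'
    'uptake.R'
    'synthdata.R'
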