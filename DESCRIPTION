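Package: nephrosim
Title: Multi-Nephron Steady-State Model of Renal Solute and Water Transport
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: An epithelial-cell-based, steady-state model of solute and water
    transport along the nephrons of a human kidney. Six nephron classes
    (one superficial, five juxtamedullary) are represented as tubules lined
    by epithelial cells expressing segment-specific transporters (NHE3,
    SGLT2/SGLT1, GLUT1/GLUT2, NKCC2, NCC, ENaC, ROMK, Na/K-ATPase, K-Cl
    cotransport), with connecting tubules coalescing 10:1 into a shared
    collecting duct. The package ships declarative scenario overlays for
    moderate and severe diabetes and for pharmacological SGLT2 inhibition,
    a deterministic calibration stage that tunes under-determined transport
    capacities against whole-kidney anchors, and reporting utilities for
    filtered loads, segmental transport, urinary excretion, macula densa
    chloride, and the active/passive split of total sodium transport.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
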