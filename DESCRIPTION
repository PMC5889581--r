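Package: dockzones
Title: Contact-Zone Analysis of Protein-Protein Docking Ensembles
Version: 0.1.0
Authors@R: person("dockzones", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Filters, ranks and geometrically "opens" ensembles of
    protein-protein docking configurations. Reads docking poses from PDB
    files, detects residue-residue contact zones by minimum heavy-atom
    distance (default 3-5 Angstrom), aggregates them into a per-pair
    contact frequency matrix, filters configurations by required
    interacting pairs, scores each pose against a primary (e.g. crystal)
    configuration, builds comparative contact-zone list views, and emits
    rigid-body transforms realizing exploded and open-book layouts.
    Includes a synthetic-ensemble generator with exactly planted contacts
    for fully self-contained testing, deterministic SVG/TSV/JSON exports,
    and a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
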