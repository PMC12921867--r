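Package: photoforge
Title: Inverse Design of Organic Energy-Transfer Photocatalysts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A desk-scale workflow for the inverse design of organic
    triplet-energy-transfer photocatalysts. Provides multi-objective reward
    scoring of molecules with sigmoid/step property transforms, weighted
    geometric aggregation and hard structural-alert vetoes; a Hueckel
    pi-electron engine supplying HOMO-LUMO overlap, singlet-triplet gap and
    golden-rule intersystem-crossing proxies; a seedable genetic-algorithm
    generator with Bemis-Murcko scaffold diversity control; and a triage
    funnel of threshold filtering, Butina fingerprint clustering and
    combinatorial quinoxaline library enumeration with lead screening.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    ChemmineOB,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
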