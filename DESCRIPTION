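Package: netaggr
Title: Area Aggregation, Two-Time-Scale Reduction and Pinning
    Observability for Clustered Dynamical Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing sparse dynamical networks with densely
    connected clusters (areas). Builds the oriented incidence
    decomposition of a clustered connectivity matrix, computes the
    combinatorial node and area sparsity parameters, constructs the
    slow/fast coordinate transform and the associated singularly
    perturbed linear system, and derives the reduced slow subsystem,
    the fast subsystem and the rigid aggregate model together with
    their spectra. For networks of heterogeneous node dynamics it
    evaluates global and decoupled per-node pinning-observability
    criteria (Lyapunov matrix-definiteness tests), identifies the nodes
    that must be pinned for observer synchronization and searches
    minimal pinning gains. Includes seeded generators for clustered
    networks and heterogeneous dynamics, numerical integration of the
    full, reduced, nonlinear-flow and pinned systems, TSV/JSON input
    and output, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    deSolve,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'netaggr-package.R'
    'AllGenerics.R'
    'AllClasses.R'
    'networkCore.R'
    'timescale.R'
    'pinning.R'
    'simulate.R'
    'synthgen.R'
    'io.R'
    'cli.R'
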