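Package: rbmstack
Title: Energy-Based Generative Models: Restricted Boltzmann Machines,
    Deep Belief Nets and Factored Third-Order Extensions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reference implementations of a family of unsupervised
    energy-based learning modules for binary data: sigmoid belief nets with
    exact posterior enumeration (explaining away) and variational free
    energy; restricted Boltzmann machines with exact maximum-likelihood
    gradients and contrastive-divergence learning; greedy layerwise
    stacking of RBMs into deep belief nets; joint feature-label RBMs with
    free-energy classification and noisy-label inference; and factored
    third-order (gated) RBMs with damped mean-field reconstruction.  Every
    model small enough to enumerate comes with a brute-force oracle so the
    fast analytic paths can be verified exactly, and seeded synthetic-data
    generators (bars-and-stripes, oriented strokes, ground-truth model
    samples, noisy-label sets) make all experiments self-contained.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
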