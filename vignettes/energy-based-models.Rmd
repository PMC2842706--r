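---
title: "Energy-based generative models: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Energy-based generative models: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rbmstack)
```

`rbmstack` implements a family of unsupervised energy-based models of
binary data at desk scale, together with brute-force enumeration oracles
so that every analytic shortcut in the package can be verified exactly on
small instances.  This vignette records the models, the tunable
parameters, and the design decisions taken where the methods literature
leaves choices open.

## Sigmoid belief nets and explaining away

A sigmoid belief net is a directed, layered model of binary units.  In
the generative direction each unit turns on with probability
$\sigma(b_i + \sum_j w_{ij} h_j)$ given the sampled states $h_j$ of its
parents, with $\sigma(x) = 1/(1+e^{-x})$.  Sampling is by an ancestral
pass (`sbn_sample()`); inference is the hard part, because hidden causes
that are independent a priori become dependent once a common effect is
observed.  The package ships a three-unit fixture, `toy_jump_net()`: two
rare causes (bias $-10$ each) of one observed effect (bias $-20$, weight
$+20$ from each cause).  Enumerating its posterior (`sbn_posterior()`)
conditioned on the effect shows the two single-cause explanations
carrying probability $\approx 0.49995$ each while the both-causes
configuration keeps only $\approx 4.5\times10^{-5}$: observing the
effect makes the causes strongly anti-correlated.

For approximate inference the package supports a factorial posterior
$q(\mathbf h)$ and computes the variational objective
$-F = E_q[\log p(\mathbf v,\mathbf h)] + H(q) \le \log p(\mathbf v)$
exactly by enumeration (`sbn_free_energy()`), so the KL gap is measured
rather than assumed.  `sbn_fit_q()` maximizes $-F$ by exact coordinate
ascent: the objective is linear in each $q_i$ plus the concave entropy
term, so the coordinate optimum is a logistic of an exactly computed
expected log-odds.  Updates sweep units sequentially with damping 0.5;
because each coordinate objective is strictly concave, damped steps are
still ascent steps and the bound is monotone over sweeps.  On the
two-cause fixture the optimal factorial posterior collapses onto one
cause and leaves a residual gap of $\ln 2$ nats — the factorial family
cannot represent an anti-correlated two-mode posterior, which is exactly
why the fixture is instructive.  (A symmetric $q=(0.5,0.5)$ is sometimes
suggested as the natural compromise, but its bound, $-13.96$, is far
below the collapsed solution's $-10.69$; the collapse is the optimum,
not an artifact.)

## Restricted Boltzmann machines

An RBM is an undirected two-layer model with energy
$E(\mathbf v,\mathbf h) = -\mathbf v^\top\mathbf b - \mathbf h^\top\mathbf c
- \mathbf v^\top W \mathbf h$ and
$p(\mathbf v,\mathbf h) \propto e^{-E}$.  Within-layer independence
given the other layer makes Gibbs sampling and inference exact and
cheap.  Three computational paths coexist and are cross-checked:

* the analytic free energy
  $F(\mathbf v) = -\mathbf v^\top\mathbf b - \sum_k \log(1 + e^{c_k + (W^\top\mathbf v)_k})$,
* full enumeration of the joint (`rbm_joint()`, `rbm_partition()`),
  guarded at 24 total units — beyond that the oracles refuse rather than
  silently approximate,
* vectorized parallel Gibbs chains (`rbm_gibbs_step()`,
  `sample_rbm_data()`).

`rbm_ml_gradient()` returns the exact maximum-likelihood gradient, the
difference between data-side and model-side pair statistics, with the
model side computed from the enumerated marginal.  It is the oracle
against which contrastive divergence is compared.

### Contrastive divergence conventions

CD-1 replaces the model-side statistic with one driven by a single
sample–reconstruct–resample cycle.  The literature is silent on whether
each side of the statistic uses sampled binary states or real-valued
probabilities, and the choice matters.  The package's default
(`statistics = "sample"`): hidden probabilities on the data side, a
stochastic binary hidden sample to drive the chain, a stochastic binary
visible reconstruction, and negative-phase hidden probabilities computed
from that binary reconstruction.  The alternative
(`statistics = "mean_field"`) keeps real-valued visible probabilities in
the negative phase.  Both are unbiased about nothing — CD is biased
either way — but they have different fixed points: on the
bars-and-stripes benchmark below, the mean-field convention stalls at
roughly 45–50% KL reduction while the sampled convention reliably
reaches 60–75%.  The sampled convention is also the more literal reading
of the alternating Gibbs chain, so it is the default; the mean-field
variant is retained because its lower variance is occasionally useful on
very small batches.

Training (`train_rbm()`) is plain minibatch stochastic gradient: no
momentum, no weight decay, constant learning rate.  Weights initialize
from $N(0, 0.01^2)$, biases at zero.

### The bars-and-stripes benchmark

`make_bars_stripes(side)` draws an orientation uniformly and switches
each row (or column) on with probability 1/2;
`bars_stripes_distribution()` gives the generator's exact distribution,
so `rbm_kl()` can evaluate $KL(p_{\text{data}}\,\|\,p_{\text{model}})$
by enumeration.  The package's standing benchmark trains a 16-visible /
8-hidden RBM (8 hidden units is the most the 24-unit enumeration guard
allows at 16 visibles) on 500 cases of bars-and-stripes$(4\times4)$ for
500 epochs of CD-1 at learning rate 0.1, batch 50.  Across seeds this
cuts the initial KL (about 7.7 nats for a near-uniform initial model) by
60–75%.  The schedule matters: CD-1's bias makes the KL curve dip and
then creep back up, so the update count (epochs $\times$ batches) is
sized to land near the dip rather than far past it.

## Greedy stacking into deep belief nets

Writing the RBM as a prior over hidden vectors times a conditional of
visibles given hiddens shows that a second RBM can replace the prior.
`dbn_grow()` initializes the new top RBM as the transpose of the current
top (with swapped biases), which provably leaves the distribution over
visible vectors unchanged — `dbn_marginal_exact()` verifies this to
$10^{-10}$ — and then trains it on the propagated hidden activities
(stochastic binary samples by default, mean-field probabilities
optionally).  The composite model keeps the top pair of layers
undirected and all lower layers directed top-down; generation runs a
Gibbs chain in the top RBM followed by one directed pass down
(`dbn_generate()`), and fast bottom-up inference reuses the transposed
generative weights (`dbn_infer()`).

`dbn_bound()` evaluates the greedy-learning variational bound exactly on
small stacks.  At the transpose initialization the bound equals the base
RBM's log-likelihood; training the top layer can only improve it *if*
the top layer actually learns a better prior for the aggregated
posterior over the first hidden layer.  Two practical caveats, both
verified by the enumeration oracle: when the base RBM is already well
trained, the available headroom (often a few thousandths of a nat) is
smaller than CD-1's bias and the bound can drift down; the property is
therefore demonstrated on base models with sharp but mismatched priors
(random weights of standard deviation 2), where the headroom is large
and 20 of 20 seeded repetitions improve.

## Joint feature–label models and noisy labels

`labeled_rbm()` concatenates a feature block with a one-hot label block
in the visible layer of one RBM.  Because the free energy of a complete
visible vector is analytic, the exact class posterior costs one free
energy per class (`rbm_classify()`) — time linear in the number of
labels, no enumeration.  The exact gradient of
$\log p(\text{label}\mid\text{features})$ is likewise analytic
(`rbm_label_gradient()`) and can be mixed into the generative CD update
with a user-set weight (default 0, i.e. pure generative training; the
mixing coefficient is not specified by the method's sources, so it is
exposed rather than fixed).

During CD training of the joint model the label block of a
reconstruction goes through a softmax rather than independent logistics,
preserving the one-hot semantics; under the sampled convention one label
is drawn from that softmax.

When supervision is unreliable, the provided label is treated as a noisy
observation of the true label through a fixed row-stochastic confusion
matrix: `infer_true_label()` multiplies the feature-based posterior by
the confusion column of the observed label.  The identity matrix defers
entirely to the observation; a uniform matrix ignores it.  Whether the
noise model could itself be learned is out of scope; the matrix is a
fixed input.  The package's demonstration corrupts half of the labels of
a separable four-class prototype set (`make_noisy_labels()`: one
deterministic block prototype per class, 5% feature bit noise, flips
uniform over *all* classes so a quarter of flips restore the truth) and
still classifies held-out cases at $\ge 99\%$ against the true labels —
the clustering in the features, not the supervisor, defines the classes.

## Factored third-order (gated) models

Replacing the quadratic energy by three-way terms
$-\sum_{ijk} v_i v_j h_k w_{ijk}$ lets hidden units gate pairwise
interactions between visible units.  The full tensor
(`threeway_energy()`) has far too many parameters, so it is modelled as
a sum of rank-one factors, $w_{ijk} = \sum_f w_{if} w_{jf} w_{kf}$, with
the same visible weights in both visible-side sums
(`gated_rbm()`, `compose_tensor()`).  The sums run over all ordered
pairs including the diagonal, matching the algebra of the factored
form.  Factors are deterministic and send different messages to
different units (`factor_messages()`): the squared filter output
$(\sum_i v_i w_{if})^2$ to every hidden unit, and
$(\sum_j v_j w_{jf})(\sum_k h_k w_{kf})$ to every visible unit.  The
hidden-unit input assembled from these messages equals the energy drop
from turning that unit on — the package defines it that way, which
settles any ambiguity about factors of two from the symmetric pair sum —
so hidden units stay exactly conditionally independent
(`gated_sample_hidden()` matches enumeration to $10^{-12}$).

Given the hidden states the visible units are *not* independent (the
test suite exhibits an enumerated conditional that no product
distribution matches), so reconstruction uses a damped mean-field
iteration on real activities starting at the data vector:
$r \leftarrow (1-\lambda)\,r + \lambda\,\sigma(\text{field}(r))$, with
the field assembled from the factor-to-visible messages plus visible
biases.  Damping is applied to the probabilities, not the fields.
Defaults: $\lambda = 0.5$, 20 iterations, residual tolerance $10^{-6}$;
$\lambda$ must be large enough to move and small enough to prevent
oscillation, and 0.5 converged in every tested instance.  Hidden and
visible biases are included even though the minimal formulation omits
them.  CD learning (`gated_cd_update()`) updates factor-to-hidden
weights by differences of $\langle h_k (\mathbf v^\top w_f)^2\rangle$
statistics and visible-to-factor weights by differences of
$\langle v_i (\mathbf v^\top w_f)(\mathbf h^\top w_{\cdot f})\rangle$
statistics, with the mean-field activities standing in for the data in
the negative phase.  The explicit-tensor learning rule is implemented at
enumeration scale (`threeway_cd_update()`) purely as an oracle; the
factored path is the production path.

### Receptive fields from oriented strokes

`make_oriented_strokes()` draws one full-frame straight stroke per image
(orientation from $K$ equally spaced angles, uniform center, fixed
width), giving strong positive pixel correlations along the stroke
direction and negative ones orthogonally at stroke-width separation.
Training the factored model on such images should produce bar-shaped,
orientation-selective filters.  Two standard constraints make this
reliable (`train_gated_rbm()` options):

* `normalize_filters = TRUE` rescales each visible-to-factor column to
  unit norm after every update, preventing a few factors from absorbing
  all the energy;
* `gating = "tied"` fixes the factor-to-hidden matrix at the identity —
  one hidden unit per factor, i.e. the classical oriented-energy
  arrangement in which each complex cell pools the squared output of a
  single filter.

With free gating the pairwise statistics can be satisfied equally well
by symmetric mixtures of orientations, and the filters converge to
grid-like mixtures; with the tied topology each hidden unit's gating
feedback reinforces its own filter's current preference and the filters
specialize.  Selectivity is quantified by `orientation_selectivity()`,
the structure-tensor coherence of the filter image (0 for isotropic, 1
for perfectly oriented); the benchmark asks what fraction of learned
filters exceed the 95th percentile of 500 i.i.d. $N(0,1)$ filters.
Under the default conditions (8×8 images, 4 orientations, width 1, 2000
cases, 16 factors, 100 epochs, learning rate 0.05) that fraction is
0.9–1.0 across seeds.

## Randomness, sizes, and what the synthetic data does not show

All stochastic entry points take a `seed` argument and otherwise use R's
global RNG stream, the idiom of this language's modelling packages; a
fixed seed reproduces every result bit for bit, and long chains are run
as vectorized parallel chains (one independent chain per sample) rather
than one thinned chain.

Enumeration guards are hard limits: 24 total units for RBM oracles, 20
for belief-net posteriors, composite-stack marginals and gated joints.
The tests and the acceptance script size their problems accordingly —
KL benchmarks at 16+8 units, stack identities at 4+3(+4), gated
enumeration at 3+2 with 2 factors, Monte-Carlo checks at $10^4$–$10^6$
draws with 3-standard-error bands — sizes chosen so each check is
decisive at desk scale.

The generators emulate the *structure* the models are meant to exploit —
multimodality (bars-and-stripes), oriented covariance (strokes),
cluster-plus-noisy-naming (prototype classes) — but not the statistics
of natural images: no grey levels, no whitening, no occlusion, no scale
hierarchy, and class prototypes that are linearly separable by
construction.  Passing these tests shows the algorithms do what their
derivations claim under controlled conditions; it does not certify
performance on real image corpora.  Real-valued (Gaussian) visible
units, persistent chains, annealed importance sampling for large-model
partition functions, backprop fine-tuning of stacks, learning the label
confusion matrix, and stacking of gated models are all deliberately out
of scope.
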