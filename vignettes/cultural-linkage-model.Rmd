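---
title: "Package transmission of linked cultural traits: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Package transmission of linked cultural traits: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cultlink)
```

## The model

`cultlink` simulates cultural change in a well-mixed population of `N`
individuals. Each individual carries `h` discrete cultural traits (the
cultural analogue of loci), each taking one of `k` variants (alleles), and a
personal, symmetric graph of *links* between its own traits. Links are the
package's central object: when an individual learns from a demonstrator, the
demonstrator presents the chosen trait together with every trait connected
to it — directly or indirectly — in the demonstrator's own link graph. That
connected component is the transmitted *package*.

A timestep consists of four synchronous stages, all reading the
start-of-step state:

1. **Partner choice.** Every individual picks an interaction partner other
   than itself, under one of three regimes:
   * *unbiased*: uniform, probability `1/(N-1)` per candidate;
   * *pay-off-biased*: probability proportional to the candidate's pay-off
     `f_r = prod_i f_{i,j(r)}`, where the variant pay-off is linear in rank,
     `f_{i,j} = 1 - ((j-1)/(k-1)) s_i`. Variant 1 is always best, variant
     `k` worst, and `s_i in [0,1]` is the maximum pay-off difference at
     trait `i` (`s_i = 0` marks a neutral trait);
   * *conformist-biased* (single-trait model): probability proportional to
     `1 - s_kappa (1 - q_r)`, where `q_r` is the population frequency of the
     candidate's variant. The weight rises with frequency, so common
     variants are chosen disproportionately often; `s_kappa = 0` recovers
     unbiased choice exactly. We note the weight is sometimes typeset in a
     way that can be misread as the exponent form `1-(1-q)^s`; that form
     behaves pathologically here (it drives near-fixation at any small
     `s_kappa` and makes the conformity strength nearly irrelevant), whereas
     the multiplicative form produces the mild, tunable conformity the
     reference results display.
2. **Package transmission.** Each focal individual picks one of its `h`
   traits uniformly at random, builds the package from the *partner's* link
   graph, and attempts to copy every variant in the package independently
   with probability `c` (copying is blind to pay-offs — only whole-individual
   pay-offs and variant frequencies are observable). Its links are then
   updated by the transmission table: an in-package link held by both is
   kept; held only by the partner, acquired with probability `1-b`; held
   only by the focal, broken; and every focal link joining a package trait
   to a non-package trait is lost. Links entirely outside the package are
   untouched.
3. **Link formation.** Every unlinked trait pair of every individual gains
   a link independently with probability `a`.
4. **Innovation.** Every trait cell innovates with probability `mu`,
   switching to one of the other `k-1` variants uniformly (pairwise
   transition rate `mu/(k-1)`; an innovation never re-draws the current
   variant).

There is no demography: no birth, death or migration.

### Why links change diversity

Two mechanisms lower the pairwise difference
`pi = 1 - sum_j n_j (n_j - 1) / (N (N-1))` when links are present. First,
larger packages transmit more traits per interaction while innovation keeps
a fixed per-step rate, shifting the transmission-innovation balance; the
fixed-package-size control (`n_fixed`) isolates this effect, and the
single-trait Wright-Fisher expectation with the innovation rate rescaled by
`h/(n c)` (`scaled_wf_expectation()`) is its analytic reference. Second,
variable package sizes favour variants that happen to sit in large packages
(the probability a trait is transmitted grows with its component size), a
selection-like effect that is strongest at intermediate link frequencies
where `package_size_variance()` peaks.

## Scenarios

* `neutral` — all traits neutral, unbiased throughout; the baseline against
  the Wright-Fisher expectation `2 N mu (k-1) / (k-1 + 2 N mu k)`.
* `payoff` — unbiased burn-in, then pay-off-biased transmission at
  equilibrium (used for the equifinality references with `s1 = 0.07` and
  `s1 = 0.24`).
* `hitchhike_neutral` / `hitchhike_functional` — after the burn-in the
  population is put into the most conservative sweep configuration: one
  random innovator carries the best variant 1 at trait 1, everyone else the
  worst variant `k`; the innovator's trait-2 variant is set to the rarest in
  the population and labels are permuted so that this *associated variant*
  is `k` (rarest and, when `s2 > 0`, lowest pay-off). The post phase is
  pay-off-biased. `sweep_metrics()` then reports the sweep end (first
  timestep the swept variant's frequency does not increase), the associated
  variant's frequency at that moment, and how long it keeps an absolute
  majority (> 0.5, strictly).
* `conformist` — a single trait under conformist bias for the whole run (no
  burn-in phase is needed because there is no link structure to
  equilibrate).
* `fixed_package` — the control mode: each focal copies `n_fixed` randomly
  chosen distinct traits, link dynamics disabled.

## Defaults and units

All probabilities are per timestep. The default study conditions are
`N = 1000`, `h = 5`, `k = 4`, `mu = 0.01`, `c = 0.99`, `b = 0.1`, a 5000-step
unbiased burn-in and 2000 recorded post steps; the linked reference
condition uses `a = 0.01`. Selection strengths `s1 = 0.9` (sweeping trait)
and `s2 in {0, 0.1, 0.2}` (associated trait) define the hitchhiking
scenarios, and `s_kappa = 0.03` / `0.048` the two conformist references.
These are the conditions under which the reference results were produced;
they are defaults, not tuned values.

## Numerical and design choices

* **Snapshot semantics.** All reads within a timestep use the start-of-step
  state ("simultaneous" choice); each individual is the only writer of its
  own next state. The exact two-individual Markov oracle
  (`two_individual_markov_oracle()`) enumerates every RNG outcome of a step
  and is tested against the simulator, which pins these semantics down.
* **Package membership** is computed on the demonstrator's graph — the
  demonstrator can only demonstrate what its own links bundle. A shared
  in-package link is never subject to breakage (`b` applies to acquisition
  of links the focal lacks), and link acquisition is independent of whether
  the endpoint variants were successfully copied.
* **Shared-link breakage (sensitivity switch).** Whether a link held by
  *both* individuals should also break with probability `b` is a genuinely
  open modelling choice: the outcome-table reading keeps shared links
  unconditionally, which makes established fully-shared packages very
  stable and moves the high-link regime (where diversity returns to the
  Wright-Fisher expectation) to lower values of `a`; applying `b` to shared
  links keeps packages transient, lowers the equilibrium link frequency at
  a given `a`, deepens the diversity dip at larger `a`, but also weakens
  hitchhiking at low `a`. The package defaults to the outcome-table rule,
  which reproduces more of the reference statistics; the alternative is
  available as `sim_params(break_shared_links = TRUE)` for sensitivity
  analysis, and the exact two-individual oracle supports both rules.
* **Trait-2 relabeling at the sweep adjustment.** Rarest variant chosen with
  ties to the lowest label; remaining labels assigned by decreasing
  frequency. The innovator's previous variant is overwritten. With near-tied
  minimum counts the relabeled associated variant can exceed another count
  by one; at the default `N = 1000` burn-in states this does not occur in
  practice.
* **Sweep end** uses non-strict non-increase (`freq(t) <= freq(t-1)`),
  applied from the adjustment point. A sweep can therefore end at its first
  step if the innovator's variant fails to spread (or is lost) immediately;
  such early-stalled runs are retained, which gives the sweep-end
  distributions their long upper tail of equilibrium-like pairwise
  differences.
* **Censoring.** If the run ends while the swept variant is still rising
  (or the associated variant still holds its majority), the sweep end
  (resp. duration) is reported at the boundary and flagged `censored`;
  censored durations enter means as observed lower bounds with the censored
  fraction reported alongside. Mean majority durations are reported only
  when more than 5% of replicates hitchhiked.
* **Overlap estimation.** `area_of_overlap()` integrates the pointwise
  minimum of two density estimates on [0, 1]. The deterministic shared-bin
  histogram (100 bins) is the default for large samples; for the
  equifinality analysis at a few hundred replicates the kernel estimator is
  used instead (`equifinality_overlaps(method = "density")`), because with
  only one or two observations per bin the histogram minimum is severely
  biased towards zero. Both estimators are symmetric, bounded in [0, 1] and
  equal 1 on identical samples.
* **Wright-Fisher baseline.** `wf_replicate()` implements the standard
  single-trait multinomial resampling model with the same innovation scheme
  and is kept deliberately separate from the agent-based core. Note that a
  *multi-trait* linkless run is slower than Wright-Fisher per trait: a trait
  is only copied when chosen (rate `c/h` per individual per step), which is
  exactly the observation behind the `h/(n c)` rescaling; the unscaled
  Wright-Fisher expectation is therefore compared against single-trait
  (`h = 1`) unbiased runs, where simulation and the closed form agree to
  within Monte-Carlo error.
* **RNG.** The C++ core draws from an internal xoshiro256++ generator
  seeded from R's RNG at every entry point: `set.seed()` (or
  `params$seed`) makes any run bitwise reproducible. Sparse Bernoulli
  streams (link formation, innovation) use exact geometric gap sampling.
* **Problem sizes.** The packaged tests and the reproduction script run the
  full `N = 1000` conditions at 100-200 replicates per condition (the
  reference analyses used 700-1000), and the fixed-package control at
  `N = 200`; these sizes keep the whole suite in the tens of minutes on one
  core while leaving Monte-Carlo error well inside the comparison
  tolerances, and they are stated here as the package's chosen reproduction
  scale.

## What the synthetic conditions do and do not show

All inputs are generated by the simulator itself from the parameters above;
there is no empirical data in the package. Passing tests therefore
demonstrate internal consistency (exact small-state dynamics, closed-form
agreement, reproduction of the reference statistics at reduced replicate
counts) — they do not validate the model against any real cultural system.
In particular the model assumes a well-mixed population, no demography, no
synergistic pay-offs between linked traits, random link formation at a
fixed rate, and observable whole-individual pay-offs; none of these is
tested against data.

## Known limitations

* Conformist bias is defined for the single-trait model only (`h = 1`).
* The hitchhike scenarios require `k >= 2` functional structure on traits 1
  and 2 and at least one burn-in step to anchor the sweep clock.
* `area_of_overlap()` estimates depend on the density estimator at small
  sample sizes; the kernel and histogram variants can differ by several
  hundredths at 100-200 replicates.
* Full-scale reproduction (700-1000 replicates per condition) is a matter
  of CPU time only; all entry points accept the replicate count.
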