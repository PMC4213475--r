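---
title: "Modeling signaling circuit activity from gene expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling signaling circuit activity from gene expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathcircuits)
```

## The model in one page

A signaling pathway is read as a signed directed graph whose nodes are
proteins (or groups of proteins) and whose edges are activations or
inhibitions. Its functional units are **circuits**: a signal input node
(in-degree 0, the stimulus receptor) together with all loop-free linear
paths to one signal output node (out-degree 0, the effector). The package
estimates, per sample, the probability that each circuit transmits its
signal, in three stages:

1. **Node activation.** Each expression feature is assumed to live in one
   of two states. Across a reference compendium its values follow a
   two-component mixture with inactive proportion $\pi_0$ and active
   proportion $\pi_1$; the posterior for a new value $x$ is
   $P(\mathrm{active}\mid x) = \pi_1 p_1(x) / (\pi_0 p_0(x) + \pi_1 p_1(x))$.
   Probe posteriors aggregate to genes by the 90th percentile; alternatives
   nodes take the 90th percentile over all member probes, complexes the
   minimum over members.
2. **Signal propagation.** A linear path transmits iff all its nodes are
   active and every external inhibitor of an on-path node is inactive.
   Under node independence the probability of a path event is a product,
   and the circuit probability is the probability of the union of its path
   events, computed exactly by inclusion-exclusion with intersections
   evaluated on merged requirement sets (shared nodes therefore correlate
   paths exactly).
3. **Differential testing.** Circuit-by-circuit Wilcoxon rank-sum tests
   between two conditions, Hodges-Lehmann location estimates for direction,
   Benjamini-Hochberg FDR control within each pathway.

Assumptions worth keeping in mind: transcript abundance proxies protein
availability; node activations are independent events; a circuit's
biological effect is monotone in its transmission probability. None of
these is exactly true — which is why the intended readout is the
*comparison* of conditions, not the absolute probability of a single
sample.

## Pathway input and graph construction

KGML entries of type `gene` become nodes (`single` for one gene,
`alternatives` for several genes in one entry — redundant family members);
`group` entries and endpoints of binding/association relations merge into
`complex` nodes. Relation subtypes map to signs: inhibition, repression and
ubiquitination are inhibitory; phosphorylation, dephosphorylation,
expression, indirect effects and compound-mediated links are activating; a
relation carrying both a mechanism and an inhibitory label (e.g.
phosphorylation + inhibition) is an inhibition — the mechanism inhibits the
next node. Unknown subtypes default to activation with a warning, matching
the convention that relations are activations unless stated otherwise.
Compound entries are spliced out and replaced by a direct activation edge
between the flanking gene nodes; `map` entries (links to other pathways)
are dropped with a warning since pathways are modeled independently.
Cross-pathway collisions are avoided by namespacing node ids with the
pathway id.

### Inputs, outputs and loop removal

Inputs are nodes with no incoming interaction, outputs nodes with no
outgoing interaction; isolated nodes are neither. (Defining outputs by
*presence* of outgoing interactions would make nearly every node an output
and contradicts the receptor-to-effector picture, so the terminal-effector
reading is used.) Path discovery is exhaustive all-simple-paths
depth-first search with a per-circuit cap (`max_paths`, default 10,000;
hitting the cap flags the circuit `truncated`). A shortest-path algorithm
cannot produce "all possible sub-pathways", which is what the model needs —
every linear route contributes to the union. Circuits any of whose path
nodes lie on a directed cycle are removed outright (`removed_count` is
reported): feedback cannot be expressed as a union of linear path events,
and silently breaking cycles would misstate the topology.

## Mixture estimation choices

* **Families.** Two candidate pairs are fitted — normal+normal and
  gamma+normal (gamma inactive component, generalising the exponential
  shape of absent transcripts) — and the better log-likelihood wins, with
  BIC as tie-break. Both pairs have five parameters, so the criterion
  reduces to likelihood; the gamma pair is skipped when values are
  non-positive. On data whose inactive component is truly normal, the
  gamma pair's shape flexibility can absorb sampling skew and win by a
  small margin, pulling the inactive mean slightly upward; when the
  inactive family is known, pass `families = "normal-normal"`.
* **Initialisation.** At the two highest peaks of a kernel-density
  estimate of the values (falling back to the quartiles when the KDE is
  unimodal), mirroring the idea of starting EM from the two dominant
  expression modes.
* **Iteration control.** At most 500 EM iterations, relative
  log-likelihood tolerance $10^{-8}$. The gamma M-step uses weighted
  moment matching (shape $= m^2/v$, scale $= v/m$) — the weighted gamma
  shape update has no closed form.
* **Orientation and degeneracy.** The lower-mean component is labeled
  inactive. Fits are flagged `degenerate` when EM fails to converge, a
  proportion collapses below 0.02, or the means separate by less than half
  a pooled SD — single-population features carry no on/off information and
  their posteriors should be treated with suspicion. Inputs with fewer
  than 30 finite values or zero variance are rejected.
* **Tail underflow.** Where both component densities underflow to zero the
  posterior is resolved by side of the active mean (1 above, 0 below).

At separation 3 pooled SDs and $n = 2000$ the maximum-likelihood estimate
of $\pi_1$ itself has sampling SD around 0.03, so single-fit recovery
errors of that order are expected; the test suite asserts unbiasedness
over replicates rather than single-draw exactness.

## Propagation choices

* **Requirement sets.** Every on-path node is required active; every
  off-path source of an inhibition edge into an on-path node is required
  inactive. A node required active that also inhibits the same path is a
  contradiction: the event has probability 0.
* **In-path inhibitions.** The original description specifies repression
  transmission only in an unprinted figure panel, so the package adopts a
  documented parity convention: an inhibition edge along the path requires
  its source active (it must act) and inverts the downstream signal; a
  path delivers a *net-activating* signal iff it carries an even number of
  in-path inhibitions, and only net-activating paths count toward the
  circuit's transmission probability. The convention is isolated in
  `path_requirements()` so an alternative semantics can be swapped in
  wholesale.
* **Exact-vs-sampled union.** Inclusion-exclusion enumerates $2^n - 1$
  subsets; up to `max_exact_paths = 20` paths this is exact. Beyond the
  cap a Monte-Carlo estimator samples independent node states
  (`mc_draws = 1e5` by default) and the result is flagged `approximate`.
  Alternating sums are clipped to $[0, 1]$ after accumulation to absorb
  floating-point residue.
* **Missing genes.** A node none of whose genes are measured gets `NA`
  activation and is treated as non-informative: it is dropped from every
  requirement set and the affected circuits are flagged `incomplete`.
  Imputing 0 would veto every circuit through the node, imputing 1 would
  hard-wire it open; both force circuit states the data cannot support.
  Circuits with no measured node at all are dropped with a warning.

## Testing choices

The Wilcoxon rank-sum test is exact when both groups have at most 25
samples and the data are tie-free, otherwise the tie-corrected normal
approximation applies (the `wilcox.test` convention). Constant, identical
groups return $p = 1$ and location 0. The location parameter is the
Hodges-Lehmann estimate of the condition-2 minus condition-1 shift; its
sign sets the reported direction for circuits passing the FDR threshold.
FDR control is applied within each pathway's circuit set by default —
circuits of one pathway form the natural family for the correction — with
`fdr_scope = "global"` available for multi-pathway screens where a single
family is preferred. Note that FDR control bounds the expected fraction of
false calls among discoveries; it does not preclude individual false
positives in any given run.

## What the synthetic generator does and does not emulate

`toy_pathways()` provides fixed fixtures covering every modeled topology
(a bifurcating worked-example pathway with three receptors, three
effectors and five circuits; a complex-and-alternatives chain; an external
inhibitor; a cycle that forces loop removal) plus seeded random DAGs.
`simulate_null_probes()` implements the type-I-error design: every probe
carries the same activation probability, a base value in
$\{0.1, 0.3, 0.5, 0.7, 0.9\}$ plus $N(0, 0.05)$ noise clipped to
$[0, 1]$, for $n \in \{10, 20, 50, 100\}$ samples; each dataset is split
in half and compared, so every positive is false. Noise is drawn per probe
*and sample* (a per-probe-only reading would make datasets constant and
the experiment vacuous). The default replication is 100 datasets per cell,
a scaled-down version of the original thousand; pass a larger
`n_datasets` for the full design.

`simulate_study()` exercises the whole stack: probes follow a
normal+normal mixture (means 5 and 9, SD 1 — roughly the log2-scale
separation between absent and present transcripts on expression arrays;
3 probes per gene), a reference compendium is drawn at activation
probability 0.5, and study samples at base probability 0.3 with the
designated circuits' genes shifted by `effect` in condition 2. Ground
truth honestly includes every circuit sharing a shifted node. What this
does **not** emulate: probe-level measurement error and cross-
hybridisation, correlated co-regulation of genes outside the perturbed
circuit, batch effects, platform-specific intensity distributions, and
RNA-seq counts. Passing tests therefore demonstrate correctness of the
machinery and calibration under idealised sampling, not performance on
any particular real platform.

Simulation scales (100 datasets per cell; 20 seeded study repetitions;
200 random graphs against a $10^6$-draw Monte-Carlo oracle) were chosen so
the whole suite exercises the full stated designs while remaining
comfortably desk-scale.

## Known limitations

* Node-event independence ignores co-regulation; correlated nodes make
  the union formula an approximation whose error the comparison between
  conditions largely cancels but does not eliminate.
* The parity convention for in-path repressions is an explicit assumption,
  not a reproduction of the original (unprinted) formula.
* Loop-containing circuits are discarded, so feedback-dominated pathways
  are only partially covered.
* The per-pathway loop-removal counts and circuit inventories of any given
  KEGG release depend on that release's KGML files.
* Absolute transmission probabilities inherit every approximation above;
  only their between-condition comparison is recommended for
  interpretation.
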