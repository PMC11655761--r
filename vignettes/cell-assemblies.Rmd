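---
title: "Emergent cell assemblies and working-memory superposition in multi-area Hebbian networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Emergent cell assemblies and working-memory superposition in multi-area Hebbian networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The model

`hebbnet` simulates a chain of `areas` (default six) cortical-like areas,
each a 25 x 25 sheet of excitatory graded-response cells paired with a
matched 25 x 25 sheet of inhibitory cells. Excitatory cells are wired by
three families of sparse, random, topographic projections: a within-area
recurrent projection, and forward/backward projections between each adjacent
pair of areas (next-neighbour, reciprocal). A synapse from a cell at grid
position $(r, c)$ can only target cells within a square Chebyshev
neighbourhood of half-width $k$ (default 6) around the same position in the
target grid; within that window each potential synapse exists independently
with probability `density` (default 0.35). With these defaults a cell
receives on the order of $10^2$ synapses — sparse relative to the 625 cells
of an area, which is the regime in which distinct memory circuits can remain
segregated.

Each excitatory cell $i$ is a leaky integrator with a piecewise-linear
output squash:

$$
V_i \leftarrow V_i + \frac{1}{\tau_m}\Big(\text{ext}_i + \textstyle\sum_k w_{ik} O_k
  - k_L\, O^{\mathrm{inh}}_i - k_G\, G_{a(i)} - k_A\, A_i + \xi_i - V_i\Big),
\qquad
O_i = \big[V_i - \varphi\big]_0^1
$$

where $[x]_0^1$ clips to $[0,1]$, $\varphi = 0.5$ is the output threshold,
$\xi_i$ is additive uniform noise on $[-a, a]$ (default $a = 0.15$, present
during training and testing), $A_i$ is a slow adaptation variable
(low-passed own output, weak gain $k_A = 0.02$ by default), $O^{\mathrm{inh}}_i$
is the output of the cell's matched local inhibitory cell, and $G_a$ is a
slow area-level estimate of total excitatory output. Inhibitory cells pool
excitatory output over a 7 x 7 neighbourhood through their own leaky
integrator and the same squash. All time constants are in simulation steps
(synchronous update, unit step).

Two design points deserve emphasis, because the formation of *separate*
assemblies depends on them:

* **The output threshold is high** ($\varphi = 0.5$). Cells with weak,
  subthreshold drive are output-silent, so the area-activity estimate $G$
  tracks assemblies, not background murmur. During exploration of this
  design we found that when subthreshold activity leaks into the output, $G$
  rises before any circuit has formed and recruitment is strangled; when
  initial weights are instead made large enough to overcome this, the random
  graph contains dense "k-core" subsets whose members receive two to three
  times the mean random drive, and these ignite as a single item-unspecific
  standing state that Hebbian learning then cements into one global
  assembly. Small initial weights (uniform on $[0, 0.25]$) plus a high
  output threshold make *unlearned* reverberation impossible: only circuits
  whose links have been driven to saturation can sustain activity.

* **Area-level inhibition is the size- and number-regulator.** With
  $k_G = 0.12$ an area comfortably supports one fully active assembly
  (about 15-30 cells per area); a second co-active assembly exceeds the
  budget unless it receives external input. This is what closes recruitment
  as an assembly grows, prevents two circuits from being co-active during
  single-item training (which would merge them), and produces the
  winner-take-all resolution used by the superposition protocol below.

# The plasticity rule

Every excitatory projection is plastic. For each existing synapse $s \to t$
the rule compares the presynaptic output $O_s$ against $\theta_{\mathrm{pre}}$
and the postsynaptic *sustained* depolarisation $\bar V_t$ (a low-pass of
the membrane potential with time constant $\tau_p = 4$ steps) against two
thresholds $\theta_- < \theta_+$:

* $O_s \ge \theta_{\mathrm{pre}}$ and $\bar V_t \ge \theta_+$: potentiation,
  $w \mathrel{+}= \Delta w$ (LTP), up to the saturation weight $w_{\max}$;
* $O_s \ge \theta_{\mathrm{pre}}$ and $\theta_- \le \bar V_t < \theta_+$:
  homosynaptic depression, $w \mathrel{-}= \Delta w_{\mathrm{ltd}}$;
* $O_s < \theta_{\mathrm{pre}}$ and $\bar V_t \ge \theta_+$: heterosynaptic
  depression, $w \mathrel{-}= \Delta w_{\mathrm{het}}$;
* otherwise the weight is unchanged, exactly. Weights are clipped to
  $[0, w_{\max}]$.

Four threshold/rate choices, each of which we adopted after the
corresponding failure mode appeared in simulation:

1. **The postsynaptic signal is the low-passed potential.** Brief ignition
   transients (and burst/suppress limit cycles) depolarise many
   item-unspecific cells for a few steps each; gating plasticity on
   sustained depolarisation confines learning to the stimulus-specific
   steady state. The related `plasticity_lag` (default 5 steps) keeps
   learning off during the onset transient of each presentation.
2. **$\theta_+$ (0.25) sits below the output threshold.** Recruitment into
   an assembly is depolarisation-gated: a cell is potentiated towards an
   assembly as soon as strong presynaptic drivers depolarise it
   persistently, before it fires strongly itself. With $\theta_+$ above the
   saturated output range, no central-area cell is ever eligible before
   learning and no assembly can form (the sparse 19-of-625 stimuli deliver
   sub-threshold drive through random sparse projections). Area-level
   inhibition rising with assembly size is what closes recruitment again.
3. **$\theta_{\mathrm{pre}}$ (0.75) is high.** Only near-saturated cells act
   as Hebbian drivers. Mid-active cells (halo, partially ignited foreign
   members) can be recruited *to*, but cannot recruit others; this breaks
   the absorption chains through which two circuits sharing a few cells
   would otherwise ignite and annex each other.
4. **Depression is slower than potentiation**
   ($\Delta w_{\mathrm{ltd}} = \Delta w / 5$), except for the heterosynaptic
   branch ($\Delta w_{\mathrm{het}} = \Delta w$). While an upstream area
   matures, downstream candidate cells pass through the homosynaptic
   depression window; with equal rates their pathways are erased before
   they can potentiate and assemblies never span more than one central
   area. The heterosynaptic branch never touches a synapse whose
   presynaptic cell is driving its target, so it can be fast — it is the
   main force cutting links between cells claimed by different items, and
   it alone suffices to drive the connecting weight of two anti-correlated
   cells to zero.

We deliberately use fixed-size weight steps with hard clipping and no
homeostatic weight scaling or sliding thresholds; the temporal competition
between items is carried entirely by the interplay of the LTP/LTD branches
and inhibition. The end state is a bimodal weight distribution: within-item
synapses pile up near $w_{\max}$, cross-item synapses near zero.

# Stimuli and training schedule

Stimuli are binary pattern pairs: each item activates 19 of the 625 cells
in the first area and 19 of 625 in the last area, drawn uniformly without
replacement and independently across items, subject to a dissimilarity
constraint (`min_hamming_active`, default `n_active - 1`): two items share
at most one active cell per area. Fully unconstrained draws
(`min_hamming_active = 0`) leave chance collisions of 3-6 cells between
some item pairs; because those cells are driven by both items, their
outgoing links into both circuits saturate, and in long training runs such
a bridge can occasionally ignite the partner circuit during the wrong
item's trials often enough to fuse the two assemblies — a qualitatively
different outcome from the emergence of distinct circuits that the
single-item design is about. Near-disjoint stimuli realize the distinct,
independently presented items the segregation argument presumes;
the unconstrained setting remains available as a stress test of halo
growth and fusion.
Active cells receive a constant external drive of 5 for 16 steps, followed
by an 8-step inter-stimulus interval with zero input; learning remains on
throughout (ISI activity is near zero, so the no-learning zone of the rule
dominates there).

Each presentation presents exactly one item, and every item occurs equally
often (default 3000 presentations per item; the schedule can be randomized
or round-robin). Independence of items is the premise that makes the
activities of different items' cells anti-correlated, which is what the
depression branches convert into segregation. Dynamic state (not weights)
is reset at each presentation onset. This models long inter-trial
intervals: once circuits become reverberation-capable, activity from the
previous presentation would otherwise persist into the next one and
co-activate two items — exactly the co-presentation the single-item design
is meant to exclude. The decay-to-baseline that motivates the interval
length is asserted in the test suite for the stimulus-driven regime.

# Assembly extraction and overlap

After training, each item is probed with learning off: state is reset, the
pattern pair applied for `probe_steps` (20) steps, and each cell's output
averaged over the last half of the window (excluding the ignition
transient). A cell belongs to item $i$'s assembly at threshold $\gamma$ iff
its response reaches $\gamma \cdot M_i$, where $M_i$ is the maximal
response of any cell in the network for that item (global across areas).
Membership therefore depends only on response relative to $M$, is
scale-invariant, and is nested across $\gamma$. The kernel is the subset at
the fixed higher threshold `gamma_kernel` (0.8); the remainder is the halo.

Pairwise overlap at each $\gamma$ is
$100\,|C_i \cap C_j| / \min(|C_i|, |C_j|)$ by default — the most
conservative denominator (it yields the largest percentages); union and
mean-cardinality denominators are selectable. The $\gamma$ grid defaults to
0.50-0.90 in steps of 0.05.

Overlap can be computed over all areas or a subset. The reproduction
protocol in `scripts/acceptance.R` (and the `reproduce-overlap` command)
evaluates the emergent circuits in the four central areas A2-A5: that is
where the assembly-forming cells live, whereas membership in the two
peripheral (stimulated) areas is partly imposed by the binary patterns
themselves — two items whose random patterns happen to share several input
cells share those cells by construction, regardless of what learning does.
With the default dissimilarity constraint this stimulus-imposed sharing is
at most one cell per area, and under the unconstrained stress setting it
occasionally reaches 3-6 of 19 cells for a pair; counting only the central
areas measures the property the architecture is responsible for. The mean
overlap of whole assemblies (all areas) is reported alongside — it is what
the "on average" summary refers to, and stays near 1% regardless of pattern
collisions. Both conventions are available via the `areas` argument of
`overlap_report()`.

Quasi-orthogonality is summarised separately as the pairwise cosine
similarity of the steady-state response vectors; in trained default
networks the mean off-diagonal similarity is around 0.01, far below the
0.2 bound we use as the quasi-orthogonality criterion.

# Working-memory experiments

*Ignition*: reset, stimulate an item briefly (12 steps), remove input. The
assembly counts as "on" when at least `theta_frac` (0.5) of its kernel
cells have output at least `theta_on` (0.5). Trained items ignite; an
all-zero stimulus or a novel random pattern of the same sparsity fully
ignites no learned assembly — responses are all-or-none.

*Persistence*: after ignition and input removal, the kernel's summed
activity must stay at or above `theta_on` times its post-ignition level
for the whole observation window (>= 500 steps). In the default regime the
fixed-point reverberation shows only minor fluctuations (drift well below
the 10% band we assert). Raising `adapt_strength` moves the model into a
fading regime.

*Superposition* (nine phases $t_0$-$t_8$): ignite a sustained item and let
it stabilise; from $t_1$ stimulate a second, never-co-trained item — by
default at `probe_strength_frac` (0.9) of the training drive — so that by
$t_4$ both assemblies are "on" and the decoded on-set among all learned
items equals exactly the stimulated pair; remove input at $t_5$ and observe
through $t_8$. In the default regime the probed assembly is
stimulus-dependent: with the external drive gone and the sustained
assembly still claiming the area-level inhibition budget, the probed
circuit collapses, while the sustained one — which never depended on the
input — survives with a small kernel-activity change, and the network
returns to its pre-probe state (relative L2 distance below
`epsilon_return` = 0.05). Driving the probed item at full strength
instead produces the variant in which it, too, persists (or, at full
training strength, displaces the incumbent).

The working-memory experiments in the test suite probe a network trained
with 300 presentations per item: circuits are fully formed there (all six
persist input-free for 500+ steps), but remain in the regime where a
stimulus-driven partial sub-circuit cannot survive on its own. After much
longer training some circuits become so strong that a probed assembly can
leave behind a self-sustaining central fragment, which coexists with the
sustained item under the shared inhibition budget — the both-persist
variant of the protocol. Which item pairs display the textbook
stimulate-decode-fade-return sequence depends on the realised connectivity
(circuits differ in strength, exactly as heterogeneous assemblies should);
the suite therefore scans pairs and requires at least three clean ones.

Superposing three assemblies simultaneously requires head-room in the
area-level inhibition; the multi-way check lowers `global_inhib_gain` to
0.04 for that experiment, as the coupling between the inhibition budget
and the number of co-active circuits predicts.

# Determinism and problem sizes

All randomness derives from `master_seed` through named substreams
(connectivity, patterns, schedule, noise, probe, experiment), so any result
is bit-reproducible from a configuration alone, and a saved run container
(`save_network()`) plus the config regenerates every figure and table. The
compiled core draws its noise from R's RNG, so R-level seeding governs it.

The acceptance script trains the full condition — 12 items x 3000
presentations, six areas of 625 + 625 cells — in about six minutes on one
CPU (the activity-gated sparse engine makes step cost proportional to the
number of active cells). The test suite uses the same architecture with 6
items and 300-500 presentations (under a minute per training), plus small
2-area networks for dynamics-level checks against an independent plain-R
implementation of the update equations.

# What the synthetic stimuli do and do not show

The pattern generator produces sparse, uncorrelated binary stimuli. This
matches the modelling assumption under which the segregation argument is
formulated (independent items, anti-correlated activities) and suffices to
demonstrate the mechanism: emergence of quasi-disjoint circuits and their
interference-free co-activation. It does not emulate structured natural
input — correlated features, overlapping categories, graded intensities or
temporal structure — so passing these tests says nothing about, e.g.,
category formation under correlated experience, where halo competition
would be far more severe. Other known limitations: inhibitory wiring is
fixed and non-plastic; there are no conduction delays; the rate model has
no spike timing, so oscillatory/phase phenomena are out of scope; and the
superposition capacity question (how many circuits can be co-active as
depth grows) is configurable but not part of the validated claims.
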