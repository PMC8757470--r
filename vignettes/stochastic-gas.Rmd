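---
title: "Stochastic GAS-CI: models, parameters, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stochastic GAS-CI: models, parameters, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gasci)
```

## The model

A generalized active space (GAS) calculation solves the configuration
interaction problem over a *truncated* determinant space.  The active
spatial orbitals are partitioned into $k$ subspaces of sizes
$n_1, \dots, n_k$; an electron distribution $x = (x_1, \dots, x_k)$ with
$\sum_i x_i = N$ is a *composition*, and it is a *supergroup* when it
satisfies the occupation constraints — either local,
$N_i^{\min} \le x_i \le N_i^{\max}$, or cumulative,
$\tilde N_i^{\min} \le \sum_{j \le i} x_j \le \tilde N_i^{\max}$.
A determinant belongs to the GAS space exactly when its supergroup is
allowed.  Whether an excitation $(A, B \leftarrow I, J)$ stays inside the
space depends only on the supergroup of the starting determinant and on the
subspaces the four orbitals belong to — not on the determinant itself.  That
single observation makes precomputed excitation generation possible:
weights can be tabulated per supergroup instead of per determinant.

Two constraint families are supported because they are genuinely different:
not every cumulative constraint set has a local equivalent and vice versa.
`convert_constraints()` applies the interconversion relations
($N_i^{\min} = \tilde N_i^{\min} - \tilde N_{i-1}^{\max}$,
$N_i^{\max} = \tilde N_i^{\max} - \tilde N_{i-1}^{\min}$, and running sums in
the other direction) and then decides equivalence *constructively*, by
building both supergroup tables and comparing them.  We chose the
constructive test deliberately: the algebraic conditions under which the
conversion is faithful are existential (they quantify over compositions) and
testing them directly is both awkward and no cheaper than enumerating the
two tables at desk scale.

### Occupation bands

Applications usually constrain a *number of interspace excitations*
$n_\mathrm{exc}$ relative to a neutral filling.  `band_constraints()` builds
either form: the local band clips $[\,\mathrm{neutral}_i - n_\mathrm{exc},\,
\mathrm{neutral}_i + n_\mathrm{exc}\,]$ to the spin-orbital capacity
$2 n_i$ (the capacity clip matters: without it the bands can formally exceed
the Pauli limit), and the cumulative band constrains each partial sum to
within $n_\mathrm{exc}$ of the neutral partial sum, with the last space tied
exactly to $N$.  For a five-fragment $(6,6)$ stack these give 51 (local) and
81 (cumulative) supergroups at $n_\mathrm{exc} = 1$; the cumulative band
grows as $(2 n_\mathrm{exc} + 1)^{k-1}$ (81, 625, 2401, … for $k = 5$).
For the four-site $(3,3)$ model the bands reported by `count` are the local
ones (19 and 85 supergroups at one and two excitations); we provide both
constructors and the choice is explicit in every interface, because the two
families differ precisely in cases like multiple simultaneous single
excitations from neighboring fragments.

### Indexing

Supergroups are kept in decreasing lexicographic order.  The position of a
composition in that order has the closed form
$i_C = 1 + \sum_j \binom{\mathrm{rem}_j - x_j - 1 + k - j}{\,k - j\,}$
("jump over all compositions with a larger leading term"), so mapping a
determinant to its supergroup index costs one $O(N)$ per-space tally, one
$O(k)$ index evaluation from a cached binomial triangle, and one binary
search over the stored composition indices.  The index is cached per
occupied determinant in the walker store and computed once per newly
occupied determinant.

## Exact counting

All counting is exact integer arithmetic on a base-$10^7$ digit
representation (`bigint`), because the interesting counts exceed the exact
range of a double: the $(30e, 30o)$ complete space at $m_s = 0$ holds
$2.41 \times 10^{16}$ determinants and is *counted, never materialized*.
GAS counts convolve, per supergroup, the per-space generating polynomials
$\sum_a \binom{n_i}{a}\binom{n_i}{x_i - a} z^a$ and read off the coefficient
with the required total $\alpha$ count.  Spin-adapted counts use the van
Vleck–Sherman branching formula
$\Omega(n_o, s) = \binom{n_o}{n_o/2 - s} - \binom{n_o}{n_o/2 - s - 1}$,
validated in the tests against explicit diagonalization of $\hat S^2$ over
open-shell determinants for $n_o \le 6$; for 20 open shells it peaks at
$s = 2$, which is why low-spin states of exchange-coupled clusters are the
expensive ones in a determinant basis.

## GAS-PCHB excitation generation

Double excitations: two occupied spin orbitals $(I, J)$ are drawn uniformly;
the hole pair $(A, B)$ is drawn from a precomputed alias table with weights
$|H^{AB}_{IJ}|$ — the double-excitation matrix element, which does not
depend on the parent determinant.  One table set is stored per supergroup,
with GAS-forbidden and spin-forbidden moves carrying weight exactly zero.
If a sampled hole is occupied in the parent, the attempt is *discarded*; the
rejection is a normal outcome and its probability mass is part of the
bookkeeping (the tests verify that generation probabilities over all
children plus the rejection mass sum to one).  Single excitations cannot be
importance-sampled from determinant-independent tables, so holes are drawn
uniformly over the same-spin unoccupied orbitals whose target subspace keeps
the composition allowed, implemented as per-(supergroup, source-space)
orbital bitmasks; the generation probability carries the per-determinant
normalizer.

Full-CI PCHB is literally the single-supergroup special case (`gas = FALSE`
and one-space GAS tables produce identical alias tables and identical event
streams under the same seed).  The *discarding* baseline proposes from
full-CI tables and rejects forbidden children after the fact; conditional on
the particle pair and acceptance, its hole distribution equals the GAS-PCHB
one, so both dynamics converge to the same energy (tested).  The discarding
scheme wastes proposals and spreads its generation probabilities over
forbidden moves, which in production use forces a smaller time step and
tends to degrade efficiency; at the desk-scale fixtures used here the two
generators' blocking errors are comparable and their ordering depends on the
time step, so the package asserts the agreement of the estimates and the
positive rejection fraction, not an efficiency inequality.

Memory is the price: tables scale as (spin-orbital pairs)$^2 \times
n_\mathrm{sg}$.  `memory_estimate()` implements this with a default entry
width of 8 bytes (float probability + int alias); `build_pchb_tables()`
refuses to build above a configurable cap instead of thrashing.  Production
configurations (e.g. 30 orbitals at 2401 supergroups, tens of GB) are out of
desk-scale reach by design; the spatial-orbital indexing variant, which
reduces the pair count by about four, is documented in the estimator but not
implemented in the sampler.

## FCIQMC dynamics

The propagator $1 - \Delta\tau (K - S)$, $K = H - E_\mathrm{ref}\mathbf 1$,
is applied stochastically to signed integer walker populations:

* **spawning** with acceptance $\Delta\tau |K_{ij}| / p_\mathrm{gen}$
  (multiplicity above one allowed), child sign
  $-\operatorname{sign}(K_{ij})\operatorname{sign}(c_i)$;
* **death/cloning** with probability $\Delta\tau (K_{jj} - S)$, sampled
  binomially per determinant;
* **annihilation** by signed summation per determinant.

$E_\mathrm{ref}$ is the diagonal element of the initial reference (the
lowest-diagonal determinant of the space), so at stationarity the shift
equals the correlation energy.  Choices a user should know about:

* **Time step** — default $0.9 / \max(|K|/p_\mathrm{gen})$ over a 500-event
  warm-up scan from the reference, capped at 0.05, then frozen.  The cap
  keeps death probabilities well below one on the desk-scale fixtures.
* **Population control** — the shift is held at zero until the walker count
  reaches `target_population`, is then *initialized to the instantaneous
  growth rate* (an undamped first update), and afterwards follows the damped
  update $S \leftarrow S - \frac{\zeta}{A\Delta\tau}\ln N_w(\tau)/N_w(\tau -
  A\Delta\tau)$ with $\zeta = 0.05$, $A = 5$.  The undamped initialization
  is what prevents the multi-fold population overshoot a purely damped
  controller produces when the growth phase is fast; the default initial
  population is one fifth of the target so the measured growth rate reflects
  the relaxed wave function rather than the early spreading transient.
* **Initiator** — spawns from parents with $|c_i| <$ `n_add` (default 3)
  onto unoccupied determinants are vetoed.
* **Adaptive shift** — each determinant gets
  $S_i = \Delta + f_i (S - \Delta)$, with $f_i$ the ratio of
  initiator-accepted to total spawn weight, weights $|H_{ji}| / (H_{jj} -
  E)$ (first-order perturbation theory; the denominator is floored at 0.5 to
  guard near-degeneracies).  $f_i$ uses exponential forgetting with a
  configurable half-life (default 200 iterations) because a prescription for
  the accumulation window is not uniquely determined by the two limits that
  pin the scheme down: $\Delta = S$ must reproduce conventional initiator
  dynamics (tested seed-for-seed) and $\Delta = 0$ with $f_i = 1$ must give
  $S_i = S$.  The offset is configured as a fraction of the current shift;
  0.5 is the recommended midpoint.  Death applies $S$ to initiators and
  $S_i$ to non-initiators — the scheme's purpose is to extend non-initiator
  lifetimes, and the two pinned limits do not distinguish the alternatives.
* **Semistochastic core** — the `core_space_size` most-populated
  determinants (ties broken by determinant key, so runs are reproducible)
  are propagated exactly under the dense core Hamiltonian; core→core
  stochastic spawns are dropped so that block is applied exactly once.
  With the core equal to the whole space the dynamics degenerates to exact
  power iteration, which is tested against the eigensolver.
* **Reference switching** — when another determinant's population exceeds
  the reference's by a factor 1.5 for 100 consecutive iterations, the
  projector is re-pointed at it and the energy accumulation restarts.  The
  thresholds are ours; switching only changes the estimator, never $K$.

The projected energy $E = H_{00} + \sum_t \mathrm{num}_t / \sum_t
\mathrm{den}_t$ keeps numerator ($\sum_{j \ne 0} H_{0j} c_j$) and
denominator ($c_0$) as separate series; its error comes from a
Flyvbjerg–Petersen blocking analysis of the per-iteration ratio, with
plateau detection and an explicit flag (plus the maximum over levels) when
no plateau exists.  Injecting an exact eigenvector reproduces the eigenvalue
identically, which pins the estimator's algebra.

Randomness: a single R RNG stream drives everything (the compiled proposal
kernel draws from the same stream), so any run is reproducible from
`set.seed()`.  Per-determinant RNG substreams, which matter only for
parallel annihilation, are intentionally not implemented in this
single-threaded code.

## Reduced density matrices

Exact RDMs contract an eigenvector with the one- and two-body excitation
operators.  Stochastic RDMs accumulate diagonal contributions from squared
walker populations and off-diagonal contributions from the same spawn events
that drive propagation, reweighted by $1/p_\mathrm{gen}$; the 1-RDM trace is
normalized to $N$ exactly and the same factor scales the 2-RDM.  Because the
off-diagonal estimator reuses the propagation events, it carries the known
same-walker bias; the tests bound it against oracle RDMs on fixtures, and
replica sampling is a noted extension, not implemented.  GAS-forbidden index
blocks are exactly zero by construction — the generator cannot emit the
events that would populate them — which the disconnected-space tests assert
as identity, not as a tolerance.

Storage is spin-blocked in chemists' pair ordering
($\Gamma^{\sigma\sigma'}[p,q,r,s] = \langle a^\dagger_{p\sigma}
a^\dagger_{r\sigma'} a_{s\sigma'} a_{q\sigma}\rangle$), so
$E = E_\mathrm{core} + \sum h\gamma + \tfrac12 \sum (pq|rs)\Gamma$ directly.
Mixed-spin pair slots are redundant images under antisymmetry and are
dropped at accumulation time — double-counting them is the natural bug of
this representation, which is why the test suite compares every block
against a brute-force second-quantized oracle.  $\langle \hat S^2 \rangle =
m_s(m_s+1) + N_\beta - \sum_{pq} \Gamma^{\alpha\beta}[p,q,q,p]$ (the
spin-flip contraction); the working equation is validated against explicit
$\hat S^2$ matrices rather than assumed.  Pseudonatural orbitals
block-diagonalize the spin-summed 1-RDM per subspace; for disconnected
spaces the 1-RDM is block diagonal and they coincide with natural orbitals,
which is tested.

## Fermionic conventions

Spin orbitals are numbered $1..n$ ($\alpha$ block) then $n{+}1..2n$
($\beta$), ascending spatial index; kets are ordered products of creation
operators in that order.  A single excitation picks up
$(-1)^{\#\text{occupied strictly between } I \text{ and } A}$; a double is
evaluated as two sequential singles on the intermediate occupation.  No
convention is "right" in isolation — what is tested is that the full matrix
over a $(4e, 4o)$ basis equals a brute-force second-quantized construction
to $10^{-10}$, which fixes every sign.  Orbitals and composition/supergroup
indices are 1-based throughout (the natural R convention; tabulated
supergroup examples are 1-based as well).  Point-group symmetry is accepted
in FCIDUMP headers but not exploited: it is orthogonal to the constraint
algebra and the sampling machinery implemented here.

## What the synthetic generators do and do not emulate

`synthetic_integrals()` produces a symmetry-complete random integral table
with well-separated orbital energies (diagonally dominant $h$, spacing 0.5
hartree, random noise of scale 0.1) and a modest positive on-site repulsion,
giving a single-reference-like ground state with weak correlation — the
regime where a small walker population suffices and exact diagonalization is
available as the oracle.  `hubbard_integrals()` gives the standard
nearest-neighbor chain, whose small instances have closed-form or
tight-binding-reducible energies.  Neither reproduces features of real
molecular integrals — point-group symmetry, shell structure, integral decay,
near-degenerate open-shell manifolds, strong static correlation — so passing
tests demonstrate the correctness of the algorithms (constraint algebra,
unbiased sampling, estimator identities), not the chemical accuracy of any
application.  The cluster-scale applications this method targets
(fragment stacks, metal clusters, uncontracted MRCI with ~100 correlated
electrons) need molecular integrals and walker counts far beyond desk scale;
what carries over is exactly what is tested: counts, constraint handling,
the a-priori guarantee of the generator, and the unbiasedness of the
estimators.

## Problem sizes used by the test suite

Deterministic checks run on 2–8 orbital systems where full enumeration is
trivial.  The stochastic end-to-end checks use a $(6e, 6o)$ random table
(400-determinant basis) with $10^5$ walkers and ~2200 iterations for the
exact-diagonalization comparison (about a minute each for full CI and for a
two-subspace band truncation), $10^6$ sampled events for the
zero-forbidden-children assertion, $10^5$ draws for the chi-squared
generator calibration, and smaller $(4e, 4o)$ runs for RDM sampling.  These
sizes were chosen as the smallest at which the stochastic assertions have
comfortable statistical power.

## Known limitations

* Single-threaded; walker counts beyond ~$10^6$ are impractical.
* Determinant (not spin-adapted) basis: for antiferromagnets, spin-pure
  states are reachable by choosing $m_s$, but ferromagnetically ordered
  systems collapse to the highest-spin state regardless of $m_s$, and
  disconnected-space spin ladders are not meaningful in this basis.
* No orbital optimization: the package consumes fixed integrals.
* Stochastic RDMs use single-run sampling (same-walker bias, bounded on
  fixtures but not removed).
* At most 16 spatial orbitals for determinant-resolved work (bit-mask
  representation); counting and constraint algebra have no such limit.
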