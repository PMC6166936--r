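---
title: "Laplacian mixture models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Laplacian mixture models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lapmix)
```

## The model

A finite mixture `f(x) = sum_k a_k f_k(x)` can equivalently be written as a
*partition of unity*: `m` nonnegative conditional probabilities `p_k(x)`
summing to one at every point, with `a_k = sum_x p_k(x) f(x)` and
`f_k = p_k f / a_k`. A Laplacian mixture model estimates the partition of
unity directly from the leading eigenspace of a graph Laplacian
`Delta = D - A`, without assuming any parametric form for the components.

Write `phi_0, ..., phi_{m-1}` for the orthonormal eigenvectors of the
(symmetric) Laplacian with the `m` smallest-magnitude eigenvalues, `phi_0`
the nonnegative Perron–Frobenius eigenvector, and
`omega_k = phi_k / phi_0` (entrywise). Any candidate partition in the span of
the eigenbasis is `p(x) = M omega(x)` for an `m x m` coefficient matrix `M`,
and feasibility is linear: `t(M) e = e_1` makes the components sum to one
(because `omega_0` is identically one), and `(M omega)(x) >= 0` at every data
point keeps them nonnegative.

The fitted model minimizes the expected squared classifier error
(fuzziness)

```
L(M) = 1 - sum_k < p_k(x)^2 >_w ,
```

with expectations taken under the weight `w = phi_0^2` (normalized to sum
one). That weight is the unique choice under which orthonormality of the
eigenvectors collapses the objective to the closed form
`L = 1 - tr(t(M) M) = 1 - ||M||_F^2`; on graph inputs it reduces to the
uniform weight, and on the density path it is the stationary distribution of
the discretized operator. `L` is zero exactly for binary (crisp) partitions
and `1 - 1/m` at the uniform one, and our tests assert the identity between
the Frobenius form and the direct weighted sum to `1e-10` on every solved
model.

Minimizing a *concave* quadratic over a polytope is NP-hard in general; all
optima sit at polytope vertices. The solver is therefore a heuristic with a
certificate-free outcome — see "Optimizer" below for what is and is not
guaranteed.

## Input paths

**Graphs.** A weighted undirected adjacency matrix (weights in `[0, 1]`, no
self-loops) goes straight into `Delta = D - A`. For network data whose raw
weights are unevenly scaled, `adjacency_preprocess()` mirrors the standard
practice: strengthen each vertex's top `k_min` connections to the 0.99
quantile of all weights, apply a `k_nn` nearest-neighbour cutoff, normalize
rows to unit sum, symmetrize by elementwise maximum, zero the diagonal.

**Feature tables.** `similarity_graph()` converts items-by-features data to
a sparse graph: Gaussian kernel of the Euclidean distance (an unbounded
inverse-quadratic kernel is available behind `kernel = "invquad"`), with
bandwidth `kernel_scale = "auto"` set to the median distance to the
`k_nn`-th neighbour; then the same floor/strengthen/cutoff/normalize/
symmetrize pipeline. The per-item floor guarantees every item keeps at least
one non-trivial connection.

**Densities.** Nonnegative values sampled on a regular Cartesian grid define
a lattice Smoluchowski (drift-diffusion) generator: nearest neighbours `i`,
`j` exchange probability at rates `q(i <- j) = (f_i / f_j)^(beta/2)` with
reflecting boundaries, so the stationary distribution is `f^beta` and the
diagonally-conjugated symmetric operator annihilates `f^(beta/2)`. We fixed
the ratio orientation by *requiring detailed balance with stationary
`f^beta`* rather than by reading any particular typography of the rate
formula; that choice reproduces the continuum relation in which the ground
state of the symmetrized operator is the square root of the Boltzmann
distribution. `beta` acts as an inverse temperature: larger values sharpen
the metastable structure of `f`, and `beta_search()` scans it on a grid.

## Optimizer

The constraint polytope in `M` has `m` equalities and `N * m` inequalities.
`lapmix_solve()` runs a seeded multi-start modified Frank–Wolfe procedure:

1. **Search direction.** Restarts alternate between an *anchor* direction —
   `m` rows of `omega` chosen by farthest-point sampling, mapped to the
   corner of the polytope where each anchor owns one component — and an
   isotropic Gaussian direction. Both are driven by `search_params(seed=)`.
2. **Vertex hopping.** The first linear program maximizes the direction over
   the polytope, landing on a vertex; Frank–Wolfe then repeatedly maximizes
   the linearization `tr(t(M_t) M)` of the concave objective, each step a
   linear program whose optimum is again a vertex. The objective is
   non-increasing and the iteration terminates at a vertex no linearization
   improves (tolerance `tol_obj = 1e-10`, cap `max_fw_iters = 100`).
3. **Candidate pool and degeneracy check.** *Every* LP iterate is a polytope
   vertex and is treated as a model candidate. A candidate whose
   hard-thresholded labels (argmax per item, ties to the lowest component
   index) leave any component empty is assigned infinite loss — this is the
   practical stand-in for the non-invertibility exclusion, since a model
   whose component owns no item is useless as a mixture. The minimum-loss
   nondegenerate candidate over all restarts wins; if none exists the fit
   reports status `"degenerate"` ("no m-component solution"), which is an
   informative outcome, not an error.

Keeping all iterates in the pool matters: on noisy graphs the plain
Frank–Wolfe fixed point from *every* start can be the same degenerate global
vertex, while the best nondegenerate model sits at vertices the descent
passes through. We observed exactly this on noisy interpolating cluster
graphs; pooling the iterates recovers the planted structure where the
fixed-point-only variant finds nothing.

Defaults: `n_restarts = 32 * m`, `tol_feas = 1e-9`. Output probabilities are
clipped to `[0, 1]` after the feasibility check; the largest clip applied is
recorded on the fit (`fit$clip`, at the `1e-9` feasibility scale).

**Linear programming.** The inequality right-hand sides are all zero, so
every basic feasible solution is massively degenerate. The bundled dense
two-phase simplex uses Dantzig pivoting with an automatic permanent switch
to Bland's rule when the objective stalls, which is immune to cycling; it is
validated in the test suite against exhaustive vertex enumeration of the
same polytopes. Before solving, the constraint rows are reduced exactly: the
nonnegativity of an affine function on a point cloud is equivalent to its
nonnegativity on the extremes, so for `m = 2` only the min/max ratio rows
are kept, for `m = 3` the 2-D convex hull, and for larger `m` the unique
rows. Solutions are always re-verified against the full constraint set.

**Rotation invariance.** Interpolating cluster graphs have a Fiedler
eigenvalue of multiplicity `K - 1`, so the computed eigenbasis is an
arbitrary rotation of the degenerate eigenspace. The solver's output is
invariant to such rotations up to component permutation (tested explicitly
by randomly rotating the eigenspace before solving).

## Eigencomputation

Systems up to 1200 vertices are decomposed densely; larger systems use the
ARPACK iterative solver (via `igraph::arpack`) on the spectrally shifted
operator `cI - L` (`c` a Gershgorin bound), so that the small-magnitude end
of the spectrum becomes the well-separated large end. Signs are fixed
deterministically: `phi_0` entrywise positive, higher eigenvectors flipped
so their largest-magnitude entry is positive. `phi_0` entries below
`1e-12 * max(phi_0)` abort with a disconnection diagnostic; use
`largest_connected_component()` first.

## Synthetic generators and what they (do not) show

`interpolating_cluster_graph(sizes, epsilon)` interpolates between a union
of complete blocks (`epsilon = 1`) and the complete graph (`epsilon = 0`);
within-block weights are 1 and cross-block weights `1 - epsilon`. Its
Laplacian eigenstructure and the optimal model are available in closed form
(`cluster_graph_eigenvectors()`, `cluster_graph_solution()`): the optimum is
the binary block indicator with loss exactly zero, for any block count,
sizes, and `0 <= epsilon < 1` — including when no spectral gap separates the
Fiedler eigenvalue from the rest. This makes the family a genuine oracle for
the numerical solver, which the tests exploit throughout. The printed
eigenvector convention (value 1 on the reference block, `-N_1/N_j` on block
`j`, 0 elsewhere) is validated numerically at construction rather than
trusted.

`add_graph_noise()` applies `b_ij <- (1 - alpha) b_ij + alpha u` with a
fresh uniform draw per unordered pair, keeping weights in `[0, 1]`, and can
prepend fully connected `U(0,1)`-weighted outlier vertices (the outlier
mechanism is our choice; a worst-case hub-like contaminant that degrades
small-cluster recovery, which is the behaviour such a control is meant to
probe).

`radial_mixture_density()` builds mixtures whose components are sums of
anisotropic radial basis functions with Gaussian, Laplace, or hyperbolic
secant profiles and randomized covariance transforms, returning the true
components for scoring. Default layout is a 200-point-per-axis grid; the
two-Gaussian configuration used in tests places unit-width components at
`±4` on `[-8, 8]`, which is well separated (8 standard deviations) on a
200-point grid.

These generators emulate planted block structure, uniform edge
contamination, and smooth separable densities. They do not emulate heavy-
tailed degree distributions, sampling noise in density estimates, dropout or
count noise of real expression data, or non-metric similarity structure —
passing the suite shows solver correctness on the idealized families with
known ground truth, not performance on any particular real dataset.

## Evaluation and selection

* `labeling_errors()` is the minimum Hamming distance over one-to-one
  component-to-cluster matchings (exhaustive over permutations up to 8
  classes, greedy beyond); `matched_labels()` exposes the matching.
* `relative_error()` averages per-component relative 2-norms after optimal
  matching (a stacked-norm variant sits behind `aggregate = "stacked"`).
  The formula is our choice of normalization; the matching makes it
  permutation invariant.
* `silhouette_profile()` averages Euclidean silhouette widths of the hard
  labels over seeded subsamples (defaults 10 draws of 2000 items).
  Silhouettes are computed in the normalized feature space, the natural
  space when the similarity graph was built from Euclidean distances.
* `select_model()` fits a robust line (IRLS, Tukey bisquare — the default
  weight function of `MASS::rlm`) of score against optimal objective value
  and returns the highest-dimensional model whose residual is positive
  beyond numerical noise (`tol = 1e-8`); with no positive residual it falls
  back to the smallest model with a warning.
* `beta_search()` and `knn_grid_search()` scan the inverse temperature and
  the sparsification parameters, recording per-cell model status rather than
  failing on degenerate cells.

Per-component fuzziness is reported as `c_k = 1 - <p_k^2>_w / <p_k>_w`, the
per-component normalization of the global objective: it lies in `[0, 1)`,
vanishes exactly for binary components, and equals `1 - 1/m` under the
uniform partition. The normalization (rather than, say, an unnormalized
second moment) is our design choice and is flagged as such.

## Numerical choices and degenerate inputs

* Feasibility tolerance `1e-9`; partition rows sum to one within `1e-8`;
  clipping to `[0, 1]` happens after the tolerance check and is reported.
* The k-NN cutoff is *tie-inclusive*: every edge tied with the `k`-th
  largest weight survives. For continuous weights this changes nothing; on
  exactly tied weights (e.g. noise-free planted graphs where all cross-block
  weights coincide) a first-occurrence cutoff would split ties by index
  order and can disconnect the graph.
* `adjacency_preprocess()`/`similarity_graph()` are deterministic but not
  idempotent at the weight level: max-symmetrization can push a row sum
  above one, which a second pass renormalizes. Re-running on own output
  preserves structure in the tested configurations but not exact weights.
* Argmax ties in hard thresholding resolve to the lowest component index;
  with `m = 1` the fit is flagged `"trivial"` (`p = 1`, `L = 0`).
* Empty components in `component_losses()` report 1; components with
  vanishing weight in `mixture_components()` are reported in `empty` rather
  than dividing by ~0.

## Problem sizes

The test suite and the acceptance script run, by design, on: cluster graphs
up to 260 vertices (blocks 10/50/200, three noise levels, five replicates),
exhaustive-enumeration oracles at `N <= 8`, density grids of 80–200 points
(plus a generation-only check of the 200 x 200 layout), and a 1400-vertex
path graph for the iterative eigensolver against its closed-form spectrum.
These sizes keep every loop exact or exhaustively verifiable; the
implementation itself is sparse end-to-end and scales to much larger inputs
through the ARPACK path.

## Known limitations

* No global-optimality certificate exists for the concave QP; the multi-start
  heuristic is validated against exhaustive enumeration only at small sizes
  and by the closed-form cluster-graph solutions elsewhere.
* A `"degenerate"` outcome for some `m` is data-dependent and expected —
  e.g. featureless random dense graphs frequently admit no nondegenerate
  three-component model; sequences truncate at the first such order.
* The dense LP tableau bounds the practical per-iteration constraint count;
  constraint reduction keeps `m <= 3` cheap at any `N`, while `m > 3` on
  very large `N` pays for `N * m` inequality rows per LP.
* The density path requires strictly positive density values on the grid;
  zeros must be floored or the support cropped by the caller.
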