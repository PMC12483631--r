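# chaoslearn

Quantitative prediction from data embedded in coupled chaotic oscillator
networks.

Structural and omics data are usually summarised by static descriptors.
`chaoslearn` takes the opposite route: every data point — a C&alpha; atom of
a protein, a single cell, a signal channel, an image vector — becomes a node
of a weighted network, every node is given a three-variable chaotic
oscillator (Lorenz or Rossler), and the nodes are coupled diffusively
through the network.  A *Laplacian filtration* thresholds the weighted
connectivity at `p` evenly spaced levels, producing a nested family of
graph Laplacians `L_1 ⊇ … ⊇ L_p`; at each scale the coupled system

&nbsp;&nbsp;&nbsp;&nbsp;`ds_i/dt = f(s_i) + ε Σ_j C_ij Γ s_j`,&nbsp;&nbsp; `C = −L_k`

is integrated (RK4, `h = 10⁻³`), and statistics of each node's trajectory
across all scales become its feature vector.  Depending on the filtration
scale the dynamics is chaotic, partially synchronized or fully
synchronized, and the way each node joins (or resists) synchronization
encodes its embedded environment.  Features feed per-protein linear
regression of crystallographic B-factors or cross-validated classification
(cell types, signal categories, images) with balanced accuracy as the
headline metric.

A companion module computes full simplicial persistent Laplacians over
Vietoris–Rips filtrations,
`L_q^{t,p} = B_{q+1}^{t,p} (B_{q+1}^{t,p})ᵀ + (B_q^t)ᵀ B_q^t`:
the multiplicity of its zero eigenvalues recovers the persistent Betti
number `β_q^{t,p}`, and its smallest nonzero eigenvalue tracks geometric
evolution invisible to homology.

The package is self-contained: seeded generators reproduce the geometric
and statistical structure of each input class (regular polygons,
folded/unfolded 120-node chains, correlated signal bundles, clustered
expression counts, elastic-chain pseudo-proteins with known flexibility),
so everything is testable without downloads.

## Worked example

```r
library(chaoslearn)

# a 100-residue elastic-chain pseudo-protein with 5 % B-factor noise
pr  <- synthetic_protein(100, noise_sd = 0.05, seed = 1)
rep <- run_bfactor(pr, pipeline_config(steps = 1000L, seed = 1))
rep
#> B-factor pipeline: 100 residues, PCC = 0.9631 (ols fit)

# synchronization regimes on the 16-node polygon
demo <- run_pointcloud_demo(polygon_cloud(16), pipeline_config(seed = 11),
                            scales = c(1, 10), steps = 1e5,
                            record_every = 20)
demo[, c("scale", "edges", "global_error", "regime")]
#>   scale edges global_error         regime
#> 1     1    80      0.00000           full
#> 2    10     0     30.48537 unsynchronized
```

The protein run builds the exponential-kernel connectivity (κ = 1, σ = 3)
over C&alpha; distances, filters it into 10 scales, integrates one
perturbative Lorenz trajectory per residue and scale (α = 10, γ = 60,
β = 8/3, ε = 13.6), reduces the 240 trajectory statistics to the 30 of
largest variance, and fits ordinary least squares against the experimental
B-factors; the printed PCC is the Pearson correlation between fitted and
experimental values.  In the demo, the dense scale couples every node and
the global synchronization error collapses to numerical zero ("full"),
while the empty scale leaves 16 independent chaotic orbits spread over the
attractor ("unsynchronized").

Real proteins work the same way:

```r
chain <- read_pdb_calpha("1cll.pdb", chain = "A")
run_bfactor(chain, pipeline_config())
```

A thin command-line front end over these functions ships in
`inst/scripts/chaoslearn-cli.R`
(`connect | pl | simulate | features | bfactor | classify | demo | synth`).

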