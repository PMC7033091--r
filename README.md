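# evibnet

Residue-level analysis of allosteric communication as vibrational-energy
diffusion on a Markov chain.

Type II allosteric modulators change a receptor's behaviour without a
conformational rearrangement: what changes is how fast vibrational energy
flows between distant functional regions. `evibnet` is for computational
biophysicists and structural bioinformaticians who have residue-pair
energy-exchange times (typically estimated from equilibrium MD of each
liganded state, e.g. a GPCR with agonist only versus agonist plus
modulator) and want to turn them into interpretable statistics: which
residue groups form metastable energy reservoirs, how large the energy
current between them is, and which residues a modulator acts through.

## The model

The fraction of total vibrational energy per residue, $p(t)$, diffuses on
the residue network under the master equation

$$\frac{dp(t)}{dt} = p(t)\,L, \qquad
  L_{ij} = \frac{1}{\tau^{ij}}\ (i \ne j), \quad
  L_{ii} = -\sum_{k \ne i} L_{ik},$$

where $\tau^{ij}$ is the characteristic time to exchange energy between
residues $i$ and $j$. On this chain the package computes:

1. **Metastable clusters** by robust Perron cluster analysis (PCCA+):
   grades of membership $w_m^{(s)}$ from the dominant eigenvectors of
   $L$, the quality score $\theta = \min w$, a spectral-gap-based
   recommendation of the cluster number, and an assignment at a
   membership cutoff (default 0.7).
2. **Reactive currents** between two clusters $A$ and $B$ by transition
   path theory: forward/backward committors $q^\pm$, reactive density
   $m^R_i = p^\infty_i q^-_i q^+_i$, edge flux
   $f_{ij} = p^\infty_i q^-_i L_{ij} q^+_j$, net flux, and the total
   current $F = \sum_{i\in A}\sum_{j\notin A} f_{ij}$.
3. **Modulation statistics** comparing the binary and ternary states:
   $\Delta F = (F_{all} - F_{ag})/F_{ag}\cdot 100$ overall and
   $\Delta F_X$ per residue, ranking hotspots above a threshold
   (default 70%).

A synthetic-data module generates exchange-time matrices with planted
metastable blocks, noise, an excluded residue range (emulating a mobile
loop such as ICL3) and planted modulator hotspots, plus Monte-Carlo
jump-chain oracles, so the entire pipeline is testable without MD data.
See the vignette `vignettes/energy-diffusion-networks.Rmd` for the
methods account.

## Worked example

```r
library(evibnet)

# a two-block network, 40 residues, separation ratio 100, log-noise 0.3
sys <- generate_block_tau(n = 40, blocks = 2, ratio = 100, noise = 0.3,
                          seed = 1)

# a "modulator" accelerating inter-block exchange 5-fold at 4 residues
hot <- sys$tau$labels[sys$clusters == 1][1:4]   # "D1" "E2" "A3" "R4"
mod <- apply_modulator(sys, hot, gamma = 5)

report <- compare_states(sys$tau, mod$tau)
report
#> modulation_report: F_ag = 0.102699, F_all = 0.183441
#>   delta F = 78.62% (gross), 78.62% (net)
#>   clusters: |A| = 20, |B| = 20, unassigned = 0
#>   hotspots (delta F_X > 70 %): D1 E2 A3 R4 I30 K23 ...

head(rank_residues(report, threshold = 70), 4)
#> [1] "D1" "E2" "A3" "R4"
```

Reading the numbers: the total reactive energy current between the two
metastable clusters rises from 0.103 to 0.183 (arbitrary inverse-time
units — only ratios are meaningful), i.e. the modulator speeds up
inter-cluster energy exchange by 78.6%. The four planted hotspot residues
show the largest per-residue changes ($\Delta F_X = 400\%$ each, exactly
the 5-fold rate acceleration on their boundary edges) and top the hotspot
ranking; boundary residues of the opposite cluster pick up smaller
secondary increases.

For real receptor data the same call takes two `read_tau()` matrices
(after `mask_residues()` for unreliable segments) instead of the
generated ones.

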