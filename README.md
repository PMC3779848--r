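# centropy

Cluster entropy of long-range correlated sequences and DNA walks.

Many complex signals — and nucleotide sequences in particular — are
long-range correlated: their fluctuations follow power laws governed by a
Hurst exponent H > 0.5 rather than decaying exponentially.  `centropy`
implements an information measure built on a *generating partition* of such
a signal: the series y(x) (for DNA, the walk obtained by coding purines A,G
as +1 and pyrimidines C,T as −1 and summing) is cut into **clusters** at its
crossings with its own moving average ỹₙ of window n.  The cluster lengths
ℓ follow

    P(ℓ, n) ~ ℓ^(−D) e^(−ℓ/n),          D = 2 − H,

and the Shannon entropy of the partition decomposes per length bin as

    S(ℓ, n) = S₀ + D log ℓ + ℓ/n.

The logarithmic term is intrinsic (n-invariant) and describes *ordered*,
power-law correlated clusters; the linear term is the excess entropy
injected by the partition and dominates for *disordered*, exponentially
distributed clusters (ℓ > n).  The large-ℓ slope is the source entropy
rate s(n) ≈ 1/n.  For genomes, each cluster is a block of bases whose
composition can be read off: ordered clusters carry the composition of the
whole sequence, disordered ones fluctuate around it, and the fluctuation
spread σ_C per chromosome can be correlated with supplied genomic features.

The package is aimed at researchers analyzing scaling and compositional
heterogeneity in genomic (or any symbolic/numeric) sequences: it provides
exact fractional-Gaussian-noise and synthetic-DNA generators, the DMA
(detrending moving average) Hurst estimator, the cluster partition with
bit-exact crossing arithmetic on integer walks, the entropy decomposition,
and per-cluster composition statistics — all behind one model-fitting
function in the classic R idiom.

## Worked example

```r
library(centropy)

y   <- rfbm(2^18, hurst = 0.6, seed = 1)          # fractional Brownian walk
fit <- cluster_entropy(y, windows = c(500, 1000, 2000))
summary(fit)
```

```
Cluster-entropy fit: S(l, n) = S0 + D log l + s(n) l

    n clusters    S0     D    slope   1/n
  500     3464 1.109 1.336 0.001270 2e-03
 1000     2092 1.213 1.342 0.000956 1e-03
 2000     1370 1.501 1.255 0.000187 5e-04

Hurst (DMA variance scaling): H = 0.6033, D = 2 - H = 1.3967
Power-law regime of P(l, n): D = 1.2548 (H = 0.7452)
Source entropy rate: regression of s(n) on 1/n, R^2 = 0.8276
```

Reading the output: each window n yields a cluster partition whose entropy
curve is fitted as S₀ + D log ℓ + slope·ℓ.  The fitted D per window sits
near the theoretical 2 − H = 1.4, the linear slopes track 1/n, and the DMA
estimate recovers the generating H = 0.6 to half a percent.  (Per-window D
and the rate regression tighten considerably when replicate series are
pooled — pass a list of walks; the single-series run above is the smallest
honest example.)

For a sequence instead of a series:

```r
rec <- simulate_dna(1e6, hurst = 0.6,
                    composition = c(A = .30, C = .20, G = .20, T = .30),
                    seed = 7)
w   <- dna_walk(rec)                     # purine/pyrimidine +-1 walk
cs  <- extract_clusters(w, moving_average(w, 4))
sig <- composition_sigma(cluster_composition(rec, cs), id = rec$id)
print(sig)
```

`run_full_analysis(run_config(...))` drives the whole pipeline
(FASTA/series/simulation input → clusters, distribution, entropy, fits,
Hurst, composition, σ_C, feature-correlation TSVs plus a manifest), and
`inst/exec/centropy` is a thin command-line front end over it
(`centropy simulate ...`, `centropy report ...`).

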