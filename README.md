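# corowave

Wave reflection and scaling laws at coronary bifurcations.

## The problem

The branching pattern of a coronary network is classically summarized by a
scaling law linking mother and daughter vessel calibres,
`(d_d1/d_m)^τ + (d_d2/d_m)^τ = 1` (Murray's law τ = 3, Huo–Kassab τ = 7/3).
Independently, the pulse waves that shape coronary pressure and flow are
partially reflected at every junction, with forward reflection coefficient
`R_f = (Y_m − Y_d1 − Y_d2)/(Y_m + Y_d1 + Y_d2)` in terms of vessel
admittances `Y = A·c` (area × pulse wave speed). Recasting both frameworks
in the area ratio `σ = (A_d1 + A_d2)/A_m` and symmetry ratio
`γ = A_d2/A_d1 ∈ (0,1]` shows they are the same theory: a network obeys a
scaling law with exponent τ exactly when every junction is *well matched* —
reflection-free for forward waves — under the wave-speed coupling
`c ∝ A^(τ/2−1)`, on the closed-form locus

    σ(γ; τ) = (1 + γ) · (1 + γ^(τ/2))^(−2/τ).

Backward waves then see `R_d1 = −γ^(τ/2)/(1+γ^(τ/2))` and
`R_d2 = −1/(1+γ^(τ/2))`: junctions are one-way valves that increasingly
suppress backward waves from the smaller daughter. At coronary Womersley
numbers (α ≈ 0.01–10) the viscous oscillatory-flow factors M₀′ and ε₀ enter
the impedance, and each scaling law corresponds to a *band* of σ–γ curves
rather than one curve, rising as α falls.

The package is for physiologists and modelers who want to analyze branching
morphometry in wave-propagation terms: it provides the tree data model,
the closed forms, the Womersley extension (complex Bessel evaluation, no
table interpolation), wave-speed parametrizations (uniform speed, uniform
wall stiffness β\*, uniform β, exponential empirical wall law), a synthetic
coronary-tree generator emulating published branching statistics, and the
analysis pipeline (clustering, 50-restart exponent fitting, rank tests,
reflection-coefficient and band-coverage summaries).

## Worked example

```r
library(corowave)

tr <- generate_tree(synthetic_config(seed = 1, r_min = 0.25))
bs <- extract_bifurcations(tr)
bs
#> <bifurcation_set> 2030 bifurcations
#>   census: 2183 terminal, 0 unary, 2030 bifurcation, 76 n-furcation

rec <- cluster_bifurcations(bs$records,
                            cluster_spec(bin_edges = c(0.25, 0.5, 1, 3)))
summarize_clusters(rec, fit = TRUE, seed = 1)
#>      cluster    n mean_sigma sem_sigma mean_gamma sem_gamma frac_asymmetric tau_hat
#> 1 [0.25,0.5] 1810       1.29  0.000608      0.657   0.00353           0.160    3.33
#> 2    (0.5,1]  190       1.27  0.002956      0.539   0.01210           0.395    3.32
#> 3      (1,3]   30       1.20  0.008868      0.366   0.02494           0.900    3.11

band_coverage(bs$records, tau = 7/3, alpha_range = c(0.01, 10))
#> [1] 0.968
```

Reading the numbers: moving distally (smaller mother radius), the mean
symmetry ratio rises (0.37 → 0.66) and the asymmetric fraction (γ < 0.5)
falls (0.90 → 0.16), as in measured coronary networks. The *steady-regime*
exponent fit returns τ̂ ≈ 3.1–3.3 even though the tree was generated
well-matched under the Huo–Kassab law (τ = 7/3) — the signature of ignoring
pulsatility, which inflates the apparent exponent at low Womersley number.
Comparing the same (σ, γ) points against the pulsatile Huo–Kassab *band*
instead covers 97% of them: with pulsatility accounted for, the HK law
explains the cloud.

Desk-scale identities:

```r
100 * wave_transmission(-0.3)   # 70: amplitude % surviving a junction at R = -0.3
transit_time(14, 20)            # 7e-04 s: a 14 mm segment at 20 m/s, under 1 ms
fit_tau(generate_matched_cloud(exponent_s = 0,   n = 50))$tau_hat  # 2   (uniform c)
fit_tau(generate_matched_cloud(exponent_s = 1/4, n = 50))$tau_hat  # 2.5 (uniform beta)
```

## Command line

```sh
Rscript inst/cli/corowave generate --config cfg.yaml -o tree.csv
Rscript inst/cli/corowave analyze tree.csv --cluster radius \
        --material uniform_beta_star --report out/
Rscript inst/cli/corowave curves --tau 2.3333 --alpha-range 0.01,10 -o band.txt
Rscript inst/cli/corowave fit tree.csv --cluster radius
```

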