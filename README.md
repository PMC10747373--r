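# scintopt

Optimal non-local-means smoothing for thin-scintillator radiographs.

## The problem

X-ray detectors built on a thin scintillator (e.g. a 96 µm Gd₂O₂S:Tb screen
in front of a CMOS sensor) resolve fine structure well but produce noisy
images; a thick screen (e.g. 140 µm) converts more X-rays to light and is
cleaner, but the extra optical spread blurs the image. Software denoising can
give a thin detector thick-detector noise behavior — *if* the smoothing
strength is chosen well. Too little smoothing leaves the noise; too much
destroys the resolution advantage that motivated the thin screen in the first
place.

`scintopt` selects the smoothing factor *h* of non-local-means (NLM)
denoising by sweeping it over a grid and tracking two scores of the denoised
thin-detector image NL(h):

* **EPI(h)** — the edge preservation index against the thin-detector image
  itself: the normalized cross-correlation of mean-subtracted Laplacian
  responses over an edge-bearing ROI,
  `EPI = Γ(Δp₁−Δp̄₁, Δp₂−Δp̄₂) / √(Γ(Δp₁−Δp̄₁, Δp₁−Δp̄₁)·Γ(Δp₂−Δp̄₂, Δp₂−Δp̄₂))`
  with `Γ(a,b) = Σ_ROI a·b`. EPI starts at 1 and falls as smoothing eats
  edges.
* **SNR̂(h)** — the ROI signal-to-noise ratio (mean/standard deviation over a
  homogeneous ROI) of NL(h), normalized by the same ROI's SNR in the
  thick-detector image. It starts well below 1 and rises with smoothing.

The selected *h\** is the crossing of the two curves: the point where the
gain in noise quality (measured on the thick detector's scale) balances the
loss of sharpness. The NLM denoiser itself replaces each pixel by a weighted
average of its search-window neighbors, with weights
`w(i,j) = exp(−‖p_i − p_j‖² / 2h²) / Z(i)` driven by patch similarity.

The package also ships the measurement stack used to verify the choice —
the normalized noise power spectrum (NNPS) from flat-field stacks with
overlapping-ROI averaging, and the slanted-edge presampled MTF with the
10%-MTF frequency — plus a parameterized scintillator + sensor simulator
("thin" and "thick" presets) so the whole pipeline runs, and is tested,
without physical detector data.

## Worked example

```r
library(scintopt)

# a matched pair: one tilted-edge scene exposed through both presets
pair <- simulate_study_pair(seed = 1, shape = c(256, 256))

cfg <- sweep_config(h_min = 1e-3, h_max = 1e-1, n_steps = 25,
                    epi_roi = pair$epi_roi, snr_roi = pair$snr_roi)
res <- run_sweep(pair$thin, pair$thick, cfg)
res
#> <sweep_result> 25 steps on [0.001, 0.1] (log), status crossed, optimal h = 0.00415

den <- apply_optimal(pair$thin, res)
c(thin = compute_mtf(pair$thin, pair$mtf_roi)$f10,
  denoised = compute_mtf(den, pair$mtf_roi)$f10,
  thick = compute_mtf(pair$thick, pair$mtf_roi)$f10)
#>     thin denoised    thick
#> 8.271488 8.221178 5.578135
```

The sweep crosses at `h* ≈ 0.0042`: below it the EPI curve (≈1) dominates,
above it the normalized SNR (→ ≈3 at full smoothing) dominates. The 10%-MTF
frequencies (lp/mm) confirm the intended trade: the denoised thin image keeps
nearly all of the thin detector's resolution (8.22 vs 8.28 lp/mm) while the
thick detector sits far below (5.58 lp/mm); the NNPS of the denoised image,
in turn, never exceeds the thin detector's.

A shell interface wraps the same functions:

```sh
exec/radioptim simulate --scene edge --detector thin --frames 1 --seed 1 \
    --rows 256 --cols 256 --out thin_edge.tif
exec/radioptim sweep --thin thin.tif --thick thick.tif \
    --epi-roi 32,87,192,82 --snr-roi 32,173,192,79 --out sweep.csv
```

Every command writes a JSON sidecar with its effective parameters, so runs
are reproducible from their outputs.

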