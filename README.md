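# tubularity

Multiscale Hessian-based enhancement of tubular structures (blood vessels,
airways, neural fibres) in 3D gray-scale volumes, with fully automatic
selection of the background noise-suppression parameter.

## The problem and the method

Vascular and neural networks span tube diameters from micrometres to
centimetres, so a useful enhancement filter must respond to every width at
once. The classical answer observes the volume through Gaussian apertures of
increasing scale σ, forms at each scale the γ-normalized Hessian (second
derivatives scaled by σ^2γ so responses are comparable across scales), and
scores each voxel from the magnitude-ordered eigenvalues
|λ₁| ≤ |λ₂| ≤ |λ₃| with the Frangi vesselness

    ν = (1 − exp(−Ra²/2a²)) · exp(−Rb²/2b²) · (1 − exp(−S²/2c²)),

    Ra = |λ₂|/|λ₃|,   Rb = |λ₁|/√|λ₂λ₃|,   S = √(λ₁²+λ₂²+λ₃²),

zero whenever λ₂ > 0 or λ₃ > 0 for bright structures, and the per-voxel
maximum over scales is kept together with the scale achieving it. The shape
ratios Ra, Rb are intensity-invariant, so for tubular targets a = b = 0.5
can be fixed once; only the noise-suppression scale c depends on the
acquisition. This package automates that last parameter: c is set to one
tenth of the maximum image Laplacian (the Hessian trace λ₁+λ₂+λ₃),
evaluated with the same normalized derivatives over the same scale list —
everything the filter needs is then read from the image being processed.

The package also provides the Sato two-eigenvalue line measure, a
synthetic phantom generator with ground truth (curved/straight tubes with
Gaussian or bar cross-sections, blob/plate distractors, polynomial
backgrounds, seeded Gaussian noise), MSE/PSNR quality metrics, maximum
intensity projection, volume I/O (multi-page TIFF, NRRD, MetaImage), an
end-to-end pipeline driver with stage logging, and a command-line script
(`inst/scripts/tubeness.R`).

## Worked example

Enhance three curved tubes of distinct widths hidden among blob distractors
and Gaussian noise, in fully automatic mode:

```r
library(tubularity)

ph <- makeCurvedTubePhantom(seed = 1, shape = c(64L, 64L, 64L), noiseSd = 25)
ph$degraded
#> Volume: 64 x 64 x 64 voxels, spacing (1, 1, 1), origin (0, 0, 0)
#>   intensity range [-122.1, 1058]

result <- multiscaleObjectness(ph$degraded,
                               ScaleSpec(1, 8, 10, "logarithmic"),
                               ObjectnessParams())
result
#> ResponseVolume: 64 x 64 x 64 voxels, 10 scales in [1, 8]
#>   c = 16.1068 (automatic), response range [0, 0.8645]

resp <- voxelData(responseVolume(result))
mean(resp[ph$centerlineIdx])    # response on the true centerlines
#> [1] 0.852
median(resp[!ph$mask])          # background suppressed to zero
#> [1] 0
```

The derived c = 16.1 is the phantom's maximum normalized Laplacian divided
by 10; tube centerlines score ≈ 0.85 (the measure's ceiling for an ideal
tube is 1 − e⁻² ≈ 0.865) while the median background voxel scores 0 — the
blobs and noise are rejected by the shape and energy factors. The
per-voxel `bestScaleVolume(result)` maps each centerline to a scale near
its true width. Against the clean reference,
`qualityReport(Volume(voxelData(ph$ideal)/1000), responseVolume(result))`
prints

```
QualityReport: MSE = 0.0150313, PSNR = 18.2300 dB (L = 1, n = 262144)
```

For file-based workflows the same run is
`runPipeline(runConfig("vessels.nrrd", outputDir = "out", sigmaMin = 1,
sigmaMax = 30, nSteps = 20))`, which writes the response and best-scale
volumes, MIPs along each axis, and a log recording every parameter and the
derived c.

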