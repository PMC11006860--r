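# phaseseg

Multiphase image segmentation with a scalar phase field and a piecewise-cubic
("bi-cubic spline") transition potential.

Segmenting an image into K regions of roughly constant intensity is a core
preprocessing step in biological and medical image analysis (character
extraction, tumor delineation in MRI slices, object detection).  `phaseseg`
implements a phase-field approach: a single scalar field φ encodes all K
phases through its integer plateaus, and is evolved by the explicit gradient
descent flow of the energy

    E(φ) = ∫ BiC(⟨φ⟩)/ε² + |∇φ|²/2 + (λ/2) Σₖ (C_k − I₀)² sinc²(φ − k) dx

where ⟨φ⟩ is the fractional part of φ, BiC is a periodic multi-well
piecewise-cubic potential (every integer level is a well), I₀ is the min–max
normalized intensity, sinc(u) = sin(πu)/(πu), and

    C_k = ∫ I₀ sinc²(φ−k) dx / ∫ sinc²(φ−k) dx

are sinc²-weighted region means — the optimal piecewise-constant fit values.
The field is initialized as φ = K·I₀, evolved for a few explicit
finite-difference steps (five-point Laplacian, mirrored Neumann boundary),
and segments are read off the half-integer bands of φ; the level sets
φ = 1/2, …, K − 1/2 are the segment contours.  Interface cells can be
refined on an m×m subgrid via bicubic interpolation through cell centers
when evaluating the stiff potential force.  See the methods vignette
(`vignettes/phase-field-segmentation.Rmd`) for the discretization, the
stability analysis, and every numerical choice.

## Worked example

Segment a synthetic two-phase disk phantom (the generator ships with the
package, with ground-truth labels):

```r
library(phaseseg)

ph  <- generate_phantom(phantom_spec("disk", N = 256, K = 2))
res <- run_segmentation(ph$image$values,
                        params = solver_params(K = 2, dt = 2e-6))
print(res)
#> <segmentation_result> K = 2, 256 x 256, 10 step(s)
#>   energy: 31022.9 -> 16710
#>   phase sizes: 39872, 25664
label_accuracy(res$labels, ph$labels)
#> [1] 0.993103
```

The energy drops steeply as the interface relaxes from the sharp
initialization (the trace `res$energy_trace` starts at 31022.9 and settles
near 16700 within three steps), the two phases cover 39872 and 25664 of the
65536 cells, and 99.3 % of the pixels agree with the generator's ground
truth.  `res$labels` is the 0-based label map, `res$masks` the per-phase
masks, and `res$means_trace` the per-step region means.  Passing
`out_dir = "seg_out"` additionally writes `labels.png` (byte value = phase
index), per-phase masks, a contour overlay, the energy trace as TSV and a
config echo.

The same pipeline runs from the shell:

```sh
Rscript inst/scripts/make-phantom.R --shape glyph --n 256 --out phantom_dir
Rscript inst/scripts/segment.R phantom_dir/phantom.png --k 2 --dt 2e-6 --out seg_out
```

Note on the time step: the reference protocol value `dt = 5e-6` on a
256×256 grid sits slightly beyond the explicit stability bound of the stiff
potential term (dt·BiC″(0)/ε² ≈ 2.8 > 2); noiseless piecewise-constant
images still segment, but for noisy data use `dt ≤ 2ε²` (≈ 2e-6 here).  The
vignette derives the bound.

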