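# histonorm

Reference-free brightness and contrast normalization for stacks of
serial-section micrographs.

## The problem

Three-dimensional reconstruction of an organ from hundreds of stained serial
sections inherits every imperfection of the staining and scanning workflow:
section-to-section differences in stain uptake and illumination produce
severe, irregular brightness and contrast changes through the stack. Virtual
reslices through such a volume show strong horizontal striping, and
segmentation or tracing across sections becomes unreliable. Reference-based
histogram specification (pick one "good" section, force every other
histogram onto it) fails when tissue content genuinely changes along the
stack — and over hundreds of sections it always does.

`histonorm` implements *sequential histogram fitting*: a reference-free
method that separates the **smooth structural drift** of the histogram
(real anatomy changing slowly at micron-scale section spacing) from the
**irregular per-section corruption** (staining variation), and removes only
the latter.

## The algorithm

For each section image *I<sub>i</sub>* (i = 1…N) with gray-value histogram
*H<sub>i</sub>*:

1. **Landmark setup.** Detect the dynamic range [*L<sub>i1</sub>*,
   *L<sub>im</sub>*] — from the darkest steadily occupied gray value to the
   bright-background peak — and place interior landmarks
   *L<sub>i2</sub> … L<sub>i,m−1</sub>* at equal steps of cumulative
   frequency *T(r)*, so the row {*L<sub>i0</sub>* = 0, *L<sub>i1</sub>*, …,
   *L<sub>i,m+1</sub>* = 255} summarizes the histogram shape (default
   m = 9). Histograms are computed on block-subsampled thumbnails.
2. **Trajectory fitting.** For each ordinate j, fit the trajectory
   {*L<sub>1j</sub>*, …, *L<sub>Nj</sub>*} with a least-squares cubic (or
   quartic) polynomial *C<sub>j</sub>(i)*. The fitted curves are the
   structural drift; the residuals are the staining corruption.
3. **Desired landmarks.** Anchor the output dynamic range at constant gray
   values (defaults *L′<sub>i1</sub>* = 64, *L′<sub>im</sub>* = 228), remap
   the interior fitted values onto that band, and repair any curve
   crossings to a strictly increasing row.
4. **Piecewise-linear warp.** With scale factors
   *s<sub>ij</sub>* = (*L′<sub>i,j+1</sub>* − *L′<sub>ij</sub>*) /
   (*L<sub>i,j+1</sub>* − *L<sub>ij</sub>*), map
   *x′* = *L′<sub>ij</sub>* + *s<sub>ij</sub>* (x − *L<sub>ij</sub>*) inside
   the dynamic range, extrapolate beyond it with the nearest interior scale
   factor, clip to [0, 255], and apply the resulting 256-entry lookup table
   to the full-resolution image. RGB sections are recolored by the
   per-pixel intensity ratio so hue is preserved.

The package also provides the two standard comparison baselines (classic
global equalization, and histogram specification to a reference section),
the evaluation metrics used to judge them — Kullback–Leibler divergence
KLD(P‖Q) = Σ P ln(P/Q) between original and processed histograms, and
contrast per pixel (CPP), the mean absolute difference between each pixel
and its 3×3 neighbors — plus orthogonal reslicing with a stripe-variance
statistic, and a synthetic serial-section generator with known ground
truth.

## Worked example

```r
library(histonorm)

# A 120-section synthetic stack: smooth structural drift, corrupted by
# per-section affine brightness/contrast changes (ground truth returned).
s <- generate_stack(synth_config(seed = 42))
s$corrupted
#> <image_stack> 120 sections, 128 x 128, 8-bit

fit <- run_shfa(s$corrupted)   # m = 9, cubic trajectories, anchors 64/228
generics::glance(fit)
#> # A tibble: 1 × 6
#>   n_images     m degree anchor_low anchor_high n_degenerate
#>      <int> <int>  <int>      <dbl>       <dbl>        <int>
#> 1      120     9      3         64         228            0

metric_report(s$corrupted, fit$stack)$blocks
#> # A tibble: 2 × 6
#>   block  from    to mean_kld mean_cpp_before mean_cpp_after
#>   <dbl> <int> <int>    <dbl>           <dbl>          <dbl>
#> 1     1     1   100     9.38            46.4           58.7
#> 2     2   101   120     8.85            45.3           58.1

stripe_variance(reslice_stack(s$corrupted, "xz", 64))  # 286.06
stripe_variance(reslice_stack(fit$stack, "xz", 64))    #   8.47
```

Contrast rises (CPP 46 → 59) without the over-stretching of global
equalization, and the reslice stripe variance collapses (286 → 8.5):
section brightness is now even through the stack. `autoplot(fit)` shows the
detected landmark trajectories against the fitted targets, and
`generics::tidy(fit)` returns them as a table.

A command-line interface wraps the same functions:

```sh
Rscript inst/cli/histonorm.R synth   --output data --seed 1
Rscript inst/cli/histonorm.R enhance --input data/corrupted --output out --method shfa
Rscript inst/cli/histonorm.R metrics --original data/corrupted --processed out/processed --output reports
Rscript inst/cli/histonorm.R reslice --input out/processed --output reslice.png --plane xz
```

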