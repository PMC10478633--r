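# sxrobust

Robust Gaussian fitting for serial crystallography (SX) image analysis.

Most per-pixel decisions in SX data reduction — *is this pixel part of a
Bragg peak? is this detector pixel defective?* — come down to modelling a
dominant Gaussian-noise structure (the local background, or the population
of healthy pixels) in the presence of outliers that are precisely the
objects of interest. Sample means and standard deviations are biased by
those outliers. `sxrobust` provides:

* **MSSE** — a noise-scale estimator that walks the sorted squared
  residuals $r_{(1)}^2 \le r_{(2)}^2 \le \dots$ and stops at the first
  index $k$ where $r_{(k+1)}^2 > \lambda^2 \sigma_k^2$, with
  $\sigma_k^2 = \sum_{j\le k} r_{(j)}^2/(k-p)$ and cutoff $\lambda = 3$ by
  default (plus a weighted/masked variant);
* **FLkOS** — a guided-sampling optimizer that repeatedly least-squares
  fits the block of points ranked just below the $k$-th order statistic of
  the residuals ($k = \lceil 0.5\,N \rceil$ by default), giving robust
  fits of constants, lines and planes without knowing the inlier count
  (`fit_value`, `fit_line`, `fit_plane`, `median_of_fits`);
* **`fit_background`** — per-pixel background mean/scale maps from robust
  tilted-plane fits in sliding windows with stride averaging;
* **`find_peaks`** — the robust Bragg-peak finder: local-maximum
  candidates, robust local plane background, SNR threshold (default 6),
  flood-fill peak growth, hit classification (`is_hit`);
* **`make_mask`** — the robust bad-pixel mask maker: temporal feature maps
  of calibration stacks, windowed abnormality SNR maps, 8-bit coded masks
  (hot / flickering / dead classes);
* seeded synthetic generators with ground truth for every component
  (`gen_1d_dataset`, `gen_line_dataset`, `gen_plane_dataset`,
  `gen_diffraction_pattern`, `gen_frame_stack`);
* CSV/TIFF/JSON I/O, an order-preserving `parallel_map` over frames, and a
  command-line front end (`inst/cli/sxrobust`) with `simulate`, `fit`,
  `background`, `find-peaks` and `make-mask` subcommands.

The signal-to-noise ratio used throughout is statistical separability,
$\mathrm{SNR} = (x_p - \mu_B)/\sigma_B$, signed so dead pixels come out
negative.

## Worked example

Seventy percent of the data are draws from N(10, 2²); thirty percent are
uniform clutter on [40, 100]:

```r
library(sxrobust)

d <- gen_1d_dataset(1000, inlier_frac = 0.7, mu = 10, sigma = 2,
                    outlier_low = 40, outlier_high = 100, seed = 42)
fit_value(d$data)
#> Robust value fit (FLkOS + MSSE)
#>   params   : value = 9.93205
#>   sigma    : 1.92056
#>   inliers  : 696 of 1000 (threshold 5.762)
mean(d$data)
#> [1] 27.7
```

The robust mean lands on the planted 10 (the plain mean is pulled to 27.7
by the clutter), the scale on the planted 2, and 696 of the 700 planted
inliers fall inside the reported acceptance band `threshold` = λ·σ.

Peak finding on a synthetic diffraction pattern — a tilted background with
ten planted spots at ten times the noise scale:

```r
pat <- gen_diffraction_pattern(seed = 42)    # 256 x 256, 10 spots
peaks <- find_peaks(pat$image)
head(as.data.frame(peaks), 3)
#>   seed_row seed_col centroid_row centroid_col n_pixels total_intensity    snr
#> 1      218       37        217.3        37.96      141           933.8 11.173
#> 2      218       98        218.2        97.13      142           855.5 10.777
#> 3      158       98        159.7        97.70      222          1092.8  9.889
nrow(peaks); is_hit(peaks, 5)
#> [1] 10
#> [1] TRUE
```

All ten planted spots are found, each with a measured SNR near the nominal
10, and the frame is classified a hit. Bad-pixel masking from a
calibration stack:

```r
st <- gen_frame_stack(shape = c(128, 128), n_frames = 50,
                      n_hot = 5, n_dead = 3, n_flicker = 4, seed = 42)
make_mask(st$stack, win = 64)
#> Bad-pixel mask: 128 x 128 pixels, 12 flagged
#>   temporal_mean  (bit 1): 9
#>   temporal_std   (bit 2): 7
#>   dead           (bit 4): 3
```

Exactly the 12 planted defects are flagged: hot pixels by the mean
feature, flickering pixels by the std feature, and the dead pixels by
mean, std and the derived dead bit together (code 7).

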