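# priorseg

Sequential, prior-guided segmentation of an organ through a CT image volume
from a single manually delineated slice.

Organ delineation in abdominal CT is hard for purely edge-driven or purely
statistical methods: boundaries against adjacent soft tissue are weak, and
shape and intensity vary too much for population priors. priorseg exploits
the one prior that is almost always reliable — *adjacent slices of the same
volume look alike*. One seed slice is delineated by hand; each further slice
is segmented from its neighbour's result, and every new result immediately
sharpens the prior for the next slice. The package is aimed at method
developers and image-analysis practitioners who need a transparent,
dependency-light reference implementation with a built-in phantom generator
and evaluation tools.

## The method

From the previous slice's mask the pipeline derives, per slice:

1. a **search region** (mask dilated by `n_dilate` px) outside which all
   forces vanish;
2. an **initial contour** (mask eroded by `k_erode` px), guaranteed to start
   inside the object, encoded as a binary-step level-set field
   φ₀ = ∓c (c = 2, interior negative);
3. a **probability density map** s(x) over the search region, from the
   growing feature set F = {(uᵢ, σᵢ)} of per-slice region statistics:
   each entry scores intensity x as

       p(x) = exp(−(x−u)²/2σ²)   if x ∈ [u−2σ, u+2σ]
       p(x) = −|x−u| / 2σ        otherwise

   and a committee vote resolves the scores — strict majority inside the
   2σ intervals takes max P, tie or minority takes min P.

The field then evolves by a distance-regularized level-set equation,

    ∂φ/∂t = μ div(d_p(|∇φ|)∇φ) + α s(x) δ_ε(φ) + λ δ_ε(φ) div(g ∇φ/|∇φ|),

with edge indicator g = 1/(1+|∇(G∗I)|²), in two phases: a balloon phase
(α = −1, λ = 3) in which positive s expands the interior and negative s
repels it, then a refinement phase (α = 0, λ = 2) in which the edge force
finalizes the contour. No reinitialization is ever needed. Accuracy is
reported as Dice similarity (SI), false positive error (FPE = |O∩B|/|G|)
and false negative error (FNE = (|G|−|O∩G|)/|G|).

## Worked example

```r
library(priorseg)

# a 20-slice 128x128 phantom with drifting shape and intensity, known truth
ph  <- generate_phantom(phantom_preset("drift"), seed = 1)

# segment the whole volume from one seed slice (index 10, truth as seed)
res <- segment_sequence(ph$slices, seed_index = 10, seed_mask = ph$truth[[10]])
res
#> priorseg_result: 20 slice mask(s), seed at slice 10

# evaluate against ground truth on the non-seed slices
ns  <- setdiff(1:20, 10)
rep <- batch_report(res$masks[as.character(ns)], ph$truth[ns])
rep
#> priorseg_report over 19 slice(s)
#>   mean FPE 0.0000  mean FNE 0.0723  mean SI 0.9625
```

Mean SI 0.9625 means the propagated masks overlap the ground truth at a
Dice coefficient of ~0.96 averaged over the 19 propagated slices; FPE 0
means no pixel was segmented outside the true object, and FNE 0.07 reflects
a thin undershoot ring at the blurred object boundary (see the methods
vignette). `multi_seed_segment()` accepts several seed slices for volumes
with abrupt shape changes, and `read_volume()` / `write_masks()` handle
NIfTI volumes and PNG/TIFF stacks. A command-line front end is installed at
`inst/scripts/priorseg` (subcommands `segment`, `evaluate`, `simulate`,
`show-config`).

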