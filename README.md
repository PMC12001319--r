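# ddlseg — prior-guided difference meta-learning for contouring-style adaptation

Radiotherapy structures (clinical target volumes, organs-at-risk) are
contoured to institution- and clinician-specific **styles** — a CTV capped
at a fixed depth into the bladder, a rectum drawn only on slices that also
contain the prostate, only the superficial parotid lobe. A segmentation
model trained elsewhere disagrees *systematically* with the local style,
and that systematic part is learnable from the first few locally corrected
patients.

`ddlseg` implements a **prior-guided deep difference learner**: a frozen,
meta-trained 3D network that corrects a general segmentation model's
output toward a new style, conditioned on `k` "prior" patients with
approved styled contours — **no parameter updates at adaptation time**.
The style signal is a feature-space difference, averaged over priors:

    DDLBlock({P_i}, {M_i}) = (1/n) · Σ_i tanh( Conv3D_θ( f(P_i) − f(M_i) ) )

where `f` is a shared 3D encoder (3×3×3 convs, ReLU, group norm, parallel
atrous convs at rates 6/12/24, two max-pool steps, channels
`base → 2·base → 4·base`), `P_i`/`M_i` are each prior's approved and
general-model contours (paired with the image as a 2-channel input), and
the decoder merges the averaged style signal with the query's features to
produce the stylized segmentation. Training is episodic over *simulated*
styles (morphology, slice selection against reference structures,
mm-depth extension into or trimming inside neighbours, aspect splits)
with a combined soft-Dice + distance-transform Hausdorff loss whose
weighting ramps once training DSC passes 70%.

Everything runs without clinical data: the package ships a seeded 3D
anatomy phantom, a simulated "pre-trained general model" calibrated to the
high-80s DSC regime, and a style library with sixteen training styles and
four held-out evaluation styles.

## Worked example

```r
library(ddlseg)

## meta-train the reference model (8 base features, 24^3 phantoms,
## 1500 episodic iterations; ~12 min on one core)
cfg <- train_config(seed = 101)
run <- meta_train(cfg)

## adapt to a *held-out* style from a varying number of prior patients
lib    <- style_library()
test   <- make_subjects(cfg, n = 10, offset = 7)   # unseen subjects
priors <- make_subjects(cfg, n = 10, offset = 8)   # disjoint prior pool
cv <- sweep_priors(run$state, lib$superior_half, test, priors,
                   n_values = c(0, 1, 3, 5, 10))
cv$summary
```

On the fixed reference seed this prints (mean Dice and Hausdorff in mm
over the ten test subjects; `n_priors = 0` is the no-adaptation
baseline):

```
  n_priors mean_dsc sd_dsc mean_hd sd_hd
1        0    0.598  0.064    9.60  1.26
2        1    0.504  0.154    4.47  1.07
3        3    0.545  0.151    3.96  1.16
4        5    0.604  0.140    3.66  1.08
5       10    0.707  0.094    2.91  0.74
```

Reading it: the superior aspect split is the hardest held-out style —
its truth is the top half of the target with no anatomical landmark at
the cut. The no-adaptation pass reconstructs an (anatomically correct)
whole target, which gives a deceptively high Dice floor and a 9.6 mm
Hausdorff error from the spurious inferior half. Priors immediately fix
the *stylistic* error — the Hausdorff distance more than halves with 3
priors because the inferior half is cut away — while the Dice overlap
only overtakes the baseline once enough priors (here ~10, +0.11 over
baseline) pin down the exact cut height. Easier held-out styles show the
classic few-prior gain directly: for the deeper posterior extension
(`into_post_9mm`) the same model moves from 0.773 (no adaptation) to
0.871 mean DSC with 3 priors. All of this happens with frozen weights —
`sweep_priors()` asserts the parameter digest never changes.

`simulate_workflow()` replays the deployment loop (first corrected
patient seeds the prior bank, later patients are predicted, scored, and
banked), and `adapt_segment()` is the single-patient entry point. A thin
command-line wrapper over these functions is installed at
`inst/cli/ddl.R` (`phantom`, `train`, `adapt`, `sweep`,
`baseline-transfer`, `metrics` subcommands).

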