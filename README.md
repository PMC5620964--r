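# tuns

Non-rigid structure from motion with a kernelized low-rank representation,
for articulated bodies. Given monocular 2D joint tracks `W` (2NF x NP) and
the per-frame orthographic camera rotations, `tuns` recovers the per-frame
3D joint positions `X` (3NP x NF) of a moving skeleton. It is aimed at
motion-capture and biomechanics work where a calibrated multi-camera rig is
unavailable: marker tracks (or 2D joint-detector heightmaps, in the
marker-less mode) from a single RGB view are enough.

## The model

Monocular reconstruction is ill-posed — each frame leaves the camera-depth
direction of every joint unobserved. `tuns` resolves it for *complex*
motion (sequences composed of several primitive actions) by assuming the 3D
shapes lie on a union of nonlinear low-dimensional manifolds:

```
min_{X,Z,E,l}  ||Z||* + λ1 ||X||* + λ2 ||E||_1
               + λ3 tr((I−Z)ᵀ K(X) (I−Z)) + λ4 R(X,l)
        s.t.   W = R X# + E
```

with `K(X)` an RBF kernel on the frame columns of `X` (self-expressiveness
in feature space; the coefficient matrix `Z` doubles as a frame affinity for
action clustering), `||X||*` a low-rank shape prior, `||E||_1` a sparse
model of gross tracking errors, and `R(X,l) = Σ_f Σ_bones (||x_fp − x_fq||
− l_pq)²` a soft bone-inextensibility penalty with the nominal lengths `l`
estimated alongside. The problem is solved by an augmented Lagrangian
(ALM) scheme: singular-value thresholding and shrinkage proximal steps for
the convex blocks, a bounded L-BFGS inner loop for `X`, closed forms for
`C` and `l`, and dual ascent with a geometric penalty schedule. A
marker-less variant consumes per-joint detector heightmaps instead of
tracks. Details, parameter guidance and design notes are in the methods
vignette (`vignettes/tuns-methods.Rmd`).

## Worked example

Everything below is synthetic and self-contained: the package ships a
forward-kinematics generator that builds an articulated stick figure, a
multi-action motion with exactly conserved bone lengths, and a camera that
orbits the body.

```r
library(tuns)

scene <- make_scene(actions = c("swing", "reach"), n_frames = c(60, 60),
                    deg_per_frame = 1.5, seed = 7)
fit <- reconstruct(scene$W_clean, scene$cams, scene$skeleton,
                   tuns_params(center_tracks = FALSE))
fit
#> <tuns_fit: 13 joints x 120 frames, 113 iterations, converged>
#>   final residuals: reprojection 8.903e-07, affinity 1.997e-07, shape 6.388e-07

emean(fit$X, scene$X_gt)
#> <error_report: e_mean = 0.0980, e_med = 0.0083 (sigma = 0.2592, flip +1)>

labels <- affinity_to_clusters(fit$Z, n_clusters = 2, seed = 1)
label_accuracy(labels, scene$action_labels)
#> [1] 0.9666667
temporal_consistency(labels)
#> [1] 0.9747899
```

`e_mean` is the mean 3D joint error normalized by the ground-truth shape's
average coordinate standard deviation (`sigma`), after resolving the
orthographic depth-flip; `0.098` means the average joint is off by about a
tenth of the body's spatial spread, and the median error (`0.0083`) shows
most joints are recovered an order of magnitude better. The clustering
calls recover which frames belong to which action purely from the affinity
matrix `Z` produced during reconstruction.

The same pipeline is available from the shell:

```sh
tuns simulate --preset stick13 --actions swing,reach --frames 60,60 \
     --deg-per-frame 1.5 --seed 7 --outdir scene/
tuns reconstruct --tracks scene/tracks.csv --rotations scene/rotations.csv \
     --skeleton scene/skeleton.json --out scene/X.csv --report scene/report.json
tuns evaluate --est scene/X.csv --gt scene/gt_motion.csv --out scene/eval.json
```

(`tuns` is the launcher installed under `exec/`; `Rscript -e
'tuns::run_cli()' --args ...` works identically.)

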