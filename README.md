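# negvol

Negative-volume segmentation and left–right symmetry morphometry for
ball-and-socket joints in 3D CT.

## The problem

The empty space inside a joint — between the condylar "ball" and its socket
— is where joint disease shows first: the space widens, narrows, or wears
unevenly between the left and the right side.  The space itself has no
intensity signature in CT and cannot be segmented directly; clinical
practice falls back on a handful of 2D linear measurements.  `negvol`
extracts the joint space as a solid ("negative volume") by a geometric
construction, with the temporomandibular joint (TMJ) between the mandibular
condyle (MC) and the temporal bone (TB) as the motivating anatomy:

1. coarse low-resolution segmentation localizes the two joints and yields a
   volume of interest (VOI) per side;
2. a volumetric convolutional network segments the condyle; the socket bone
   comes from a network heatmap fused with a classical image-processing
   route (median denoising, minimum-method thresholding, morphology,
   slice-wise Canny edges linked in 3D);
3. marching tetrahedra reconstruct triangle meshes from the masks;
4. the condyle mesh is *inflated* along its vertex normals under Laplacian
   regularization until the socket surface stops it; the mandibular neck is
   clipped with a plane; subtracting the original condyle solid leaves the
   negative volume;
5. left–right symmetry of the two negative volumes is quantified with the
   Hausdorff cloud-to-cloud distance and the surface-area ratio

   H_LR = max{ sup_l inf_r d(l,r), sup_r inf_l d(l,r) },
   S_LR = max{S_L, S_R} / min{S_L, S_R} >= 1.

Everything is testable without patient data through a synthetic
ball-and-socket phantom whose joint space is an upper hemispherical shell
with closed-form volume `(2/3)π[(r+g)³ − r³]` and surface area.  The three
segmentation architectures (V-Net, 3D U-Net, attention-gated 3D U-Net) are
implemented natively — forward and backward passes, Adam, augmentation —
plus an analytic FLOPs counter over the same computation graph.

See the methods vignette for models, parameters and design choices:
`vignettes/negative-volume-methods.Rmd`.

## Worked example

Generate a two-sided phantom whose right joint space is 20% wider, extract
both negative volumes from the ground-truth bone meshes, and compare the
sides:

```r
library(negvol)

spec <- phantom_spec(condyle_radius = 6, gap = 2, asymmetry_factor = 1.2,
                     grid_shape = c(52, 52, 56), noise_sd = 0)
head <- make_head_phantom(spec)

params <- inflation_params(step = 0.2, max_iters = 20)
neg <- lapply(c("left", "right"), function(side) {
  joint <- head[[side]]
  negative_volume(joint$mc_mesh, joint$tb_mesh, joint$clip_plane,
                  params, resolution = 112)
})

report <- symmetry_report(neg[[1]]$mesh, neg[[2]]$mesh,
                          mid_plane = head$mid_plane, s_lr_flag = 1.05,
                          seed = 1)
report
#> <symmetry report>  S_LR = 1.094   H_LR = 1.431 mm (subsampled 1.43 +/- 0.00)
#>   S_L 851.7 mm^2, S_R 932.1 mm^2; V_L 596.3 mm^3, V_R 772.2 mm^3
#>   asymmetric (S_LR > 1.05): TRUE
```

The analytic joint-space volumes of this phantom are 619.9 mm³ (left) and
789.0 mm³ (right) — the reconstruction recovers both within ~4% — and the
analytic surface ratio is 1.086, against the measured `S_LR = 1.094`.  The
wider right space is correctly flagged.  `H_LR = 1.43 mm` is the largest
distance from either negative volume to its mirrored counterpart; for a
perfectly symmetric pair it is essentially zero (mesh resolution), and it
grows with the gap difference.

The scaled-down end-to-end study — cohort generation, network training,
localization, segmentation, reconstruction, inflation and flagging in one
call — is `phantom_study(n = 10, seed = 11)`; a thin command-line wrapper
for it and the other entry points is `inst/cli/negvol.R`
(`Rscript negvol.R {phantom|train|report|pipeline|study} ...`).

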