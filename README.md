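# bonefe

Image-based whole-bone biomechanics in R: voxel micro-finite-element
(micro-FE) simulation of a three-point bending test from micro-CT volumes,
destructive load-displacement curve analysis, back-calculation of the bone
tissue Young's modulus, and paired treated-versus-control statistics — with
a synthetic femur-phantom generator supplying ground-truth data for every
stage.

## Who this is for

Bone biomechanics groups that combine ex-vivo mechanical testing of small
animal bones (rat femora) with micro-CT based finite-element modeling.  A
typical application: quantifying whether an intervention (for example a
thermal ablation of the marrow cavity and cortex) changes whole-bone
stiffness or the intrinsic stiffness of the mineralized tissue.

## The computational chain

1. **Preprocessing** (`preprocessVolume`): reorient the scan to the
   bending-test frame, reduce the resolution from the scan voxel (25 um)
   to 50 um by block averaging, segment mineralized bone with a single
   threshold at 500 per mille of the maximum possible intensity, crop to
   the span between the bottom rollers plus 0.5 mm per side, and keep the
   largest connected component.
2. **Voxel micro-FE** (`buildModel`, `solveFE`): every bone voxel becomes
   a cubic 8-node trilinear element with tissue modulus E = 10 GPa and
   Poisson ratio 0.3.  Bottom rollers are idealized as vertical-only
   supports on the bottom-surface node bands; a vertical displacement
   delta is prescribed on the top-surface band at the load position.  The
   system is solved matrix-free with an element-by-element
   Jacobi-preconditioned conjugate-gradient method (all element products
   batched into one BLAS call per iteration), and the FE bending
   stiffness is

   k_FE = |sum of vertical reactions at the load nodes| / |delta|.

3. **Curve analysis** (`analyzeCurve`): elastic stiffness k_exp as the
   least-squares slope of the detected linear range (max-R² window inside
   the 10-60% force band), ultimate load as the force maximum, yield load
   at the first relative departure from the extrapolated elastic line.
4. **Tissue-modulus calibration** (`backCalculateTissueModulus`): the
   model is linear in E, so

   E_tissue = (k_exp / k_FE) x E_ref,  E_ref = 10 GPa.

5. **Statistics** (`wilcoxonSignedRank`, `twoSidedTTest`,
   `cohortReport`): Wilcoxon signed-rank for all paired
   treated-versus-control comparisons (normal approximation without
   continuity correction, matching the convention that yields two-sided
   p = 0.109 / 0.285 / 0.593 for T = 0 / 1 / 2 at n = 3; exact
   enumeration available), and two-sided t tests for across-timepoint
   comparisons of the treated/control ratios.

Validation is against closed-form Timoshenko beam theory
(`timoshenkoRectStiffness`, `timoshenkoAnnulusStiffness`): the solver's
bending stiffness for a voxelized square beam (1.2 mm edge, 9.6 mm span)
converges monotonically toward the closed form as the mesh is refined
from 100 to 50 to 25 um.

## Worked example

```r
library(bonefe)

# synthetic femur mid-shaft: hollow cortical cylinder at 50 um
spec <- phantomSpec(lengthMm = 8, outerRadiusMm = 1.0,
                    corticalThicknessMm = 0.5, voxelSizeUm = 50,
                    blurSigmaUm = 0, noiseSd = 0)
img  <- generateFemurPhantom(spec)
crop <- spanCrop(c(0.5, 7.5), marginMm = 0.25)   # 7 mm span, load at 4 mm
mask <- preprocessVolume(img, crop, targetUm = 50)
model <- buildModel(mask, material(10, 0.3), crop)
sol <- solveFE(model, tol = 1e-5)
sol
#> FESolution: stiffness 824.8 N/mm (reaction -8.248 N), 812 iterations,
#>   relative residual 9.83e-06 (converged: TRUE)

timoshenkoAnnulusStiffness(7, material(10, 0.3), 1.0, 0.5)
#> [1] 780.128        # closed form; FE agrees within ~6% at 50 um

# a simulated destructive test and the tissue-modulus back-calculation
crv <- generateLoadCurve(curveSpec(stiffnessNPerMm = 1154,
                                   yieldLoadN = 115, ultimateLoadN = 150,
                                   sampleIntervalS = 5))
summ <- analyzeCurve(crv)
backCalculateTissueModulus(elasticStiffness(summ), feStiffness(sol))
#> TissueModulusResult: E_tissue = 13.99 GPa (k_exp 1154 / k_fe 824.8 x 10)

# the paired-statistics anchor at n = 3
wilcoxonSignedRank(c(1, 2, 3))$p.value    # T = 0
#> [1] 0.1088094                            # rounds to 0.11
```

An end-to-end demonstration on a synthetic paired cohort (two timepoints,
control vs treated bones with woven-bone and periosteal shells):

```r
runDemo("demo-out", seed = 1)    # writes moduli.csv, report.json, ...
```

or from the shell: `inst/scripts/bonefe demo --seed 1 --out demo-out`.

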