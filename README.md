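# faceMorph

Quantitative dissection of three-dimensional facial morphology, for
anthropologists and geneticists asking whether subpopulations differ in
facial shape — and in *which* of thousands of facial measurements.

Facial surfaces are scanned as triangle meshes and annotated with 26
Farkas-convention soft-tissue landmarks, each placed twice by an operator.
`faceMorph` turns these raw inputs into a phenotype library and runs the
population statistics on it:

* **Alignment** — replicate averaging; generalized Procrustes analysis
  removing translation and rotation but deliberately *not* scale (face
  size is biology, not nuisance); landmarking reproducibility SDs and
  two-way mixed-effects consistency ICC, ICC(3,1) = (MS_S − MS_E)/(MS_S +
  (k−1)MS_E).
* **Landmark phenotypes** — principal curvatures from local quadric fits
  (MC = (k_max + k_min)/2, GC = k_max·k_min); all 325 pairwise Euclidean
  (d = √((a−b)ᵀ(a−b))), Manhattan (Σ|a_k − b_k|) and on-surface geodesic
  distances (fast-marching solution of the unit-speed Eikonal equation
  |∇U| = 1); 32 proportion indices (smaller distance as % of larger);
  7800 angles (θ = cos⁻¹(⟨A,B⟩/|A||B|)); 2600 Heron triangle areas
  (A = √(s(s−a)(s−b)(s−c))); convex-hull volumes and surface areas of 10
  facial regions.
* **Global-to-local segmentation** — dense displacement fields in the
  consensus frame, RV-coefficient vertex similarity, recursive spectral
  bipartition to 7 levels (127 facial segments), per-segment PCA with
  parallel-analysis retention, segment surface areas, and Moran's I
  (I = n/Σw · Σw_ij z_i z_j / Σz_i²) of z, mean and Gaussian curvature.
* **Population statistics** — Spearman screening against ordered regions
  with Bonferroni control (heterogeneous vs homogeneous phenotypes),
  chi-square design balance, NIPALS PLS-DA with VIP selection
  (ΣVIP² = p; VIP > 1 selects), PERMANOVA/Adonis (pseudo-F, R², permutation
  p), and linear age adjustment.
* **Synthetic populations** — a procedural face template and a generative
  population model with known regional gradients, so every stage is
  testable without cohort data.

## Worked example

Simulate 90 individuals (30 per region) under the default model — eight
landmark coordinates carry a 1–1.5 mm north-to-south gradient — then run
both phenotyping tracks and the statistics:

```r
library(faceMorph)

tpl <- buildTemplate()
pop <- simulatePopulation(tpl, populationModel(), nPerRegion = 30, seed = 42)

rp <- reproducibility(pop)
sum(rp$class == "moderate_or_high")   # 78 of 78 coordinates with SD <= 1 mm

ph  <- extractPhenotypes(pop)          # landmark track: 11557 phenotypes
seg <- segmentPhenotypes(pop, nNull = 50, seed = 1)
all <- bindPhenotypes(ph, seg$phenotypes)
dim(phenotypeValues(all))
#> [1]    90 12516

scr <- regionScreen(all, factor(pop@sampleData$region,
                                levels = c("north", "central", "south")))
table(scr$label)
#> heterogeneous   homogeneous
#>          2155         10247
head(scr[order(scr$p), c("phenotype", "rho", "p")], 3)
#>                           phenotype    rho            p
#> 9259  Tri_pronasale-gnathion-zygion_R -0.906 1.50e-34
#> 11170                     Vol_midface -0.888 1.68e-31
#> 11180                    Surf_midface -0.885 5.32e-31

permanova(all, pop@sampleData$region, nPerm = 999, seed = 1)[c("F", "R2", "p")]
#> $F 5.47   $R2 0.112   $p 0.001

m <- plsda(phenotypeValues(ph)[, phenotypeCategories(ph) %in%
                                 c("Point", "Euclidean", "Index")],
           pop@sampleData$region, seed = 1)
head(sort(vip(m), decreasing = TRUE), 3)
#> Euc_zygion_L-zygion_R   Euc_nasion-gnathion     Point_pronasale_z
#>              2.43                  2.37                  2.32
```

The screen's top heterogeneous phenotypes are triangles and hull measures
built on the gradient landmarks (nose projection, face width/height), the
highest-VIP variables are the face-width and face-height distances and the
nose-tip z coordinate — i.e. the statistics point straight back at the
structure the generator injected — and PERMANOVA attributes about 11% of
phenotypic variance to region at this effect size.

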