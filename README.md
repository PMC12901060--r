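# gradalign

Orthogonal Procrustes alignment of functional connectivity gradients, and
what the *number of gradients used in alignment* does to the aligned
principal gradient.

## The problem

Functional connectivity (FC) gradients are low-dimensional spectral
embeddings of a parcellated FC matrix: each brain parcel gets a coordinate
along axes of connectivity variation, and the first ("principal") gradient
is the workhorse feature of individual-level gradient analyses. Gradients
extracted per subject and session are not directly comparable — their signs
are arbitrary and their eigenvalue ordering unstable — so they are aligned
to a group reference with orthogonal Procrustes rotation before any
comparison. The analyst must choose how many gradients *n* enter the
alignment, and because the transformation mixes all *n* of them into the
aligned principal gradient, this choice silently changes what the
"principal gradient" downstream actually is: its subject specificity, its
coupling to head motion, and its behaviour in prediction pipelines.

`gradalign` is for researchers who want to quantify those effects, audit an
existing gradient pipeline, or stress-test methodological choices on a
fully synthetic cohort before touching real data.

## What it computes

Given a subject gradient matrix **A** (parcels × n) and reference **B**,
the orthogonal Procrustes solution is

    C = A'B,   C = U Σ V',   T = U V',   A' = A T

which minimizes ‖AT − B‖_F over orthogonal T (no centering, no scaling, no
iterative reference update). On top of the fit, the package reports:

* **correspondence** c = max|t·1| / Σ|t·1| over the first column of T —
  how much the aligned principal gradient is still "the" unaligned one;
* **Trans_Total, Trans_PG** — Σ|t_ij| over the matrix / its first column,
  heuristic transformation magnitudes;
* **‖w‖₂** — ℓ2 norm of the singular values of C, and **‖Θ‖₂** — ℓ2 norm
  of the principal angles between the column spans: opposing descriptors
  of subspace similarity;
* **fingerprinting** — identification accuracy and differential
  identifiability I_diff = (I_self − I_other) × 100, raw and Fisher-z;
* **motion metrics** — framewise displacement (Power formulation, 50 mm
  radius) and typicality of functional connectivity
  TFC = (1 + r(FC_i, FC̄))/2 — and their correlation sweeps against the
  alignment diagnostics with Benjamini–Hochberg FDR control;
* **prediction** — 10× repeated 5-fold nested CV (ridge, SVMs, random
  forest) with CV-consistent confound removal.

Gradient extraction supports row sparsification, five affinity kernels
(normalized angle by default) and three spectral reductions (diffusion map
embedding, PCA, Laplacian eigenmaps). A deterministic synthetic cohort
generator provides multi-session subjects with stable individual gradient
bases, per-session sign/order/rotation instability, and a motion level
that perturbs connectivity — so the whole study runs end to end without
any data download.

## Worked example

```r
library(gradalign)

spec <- cohort_spec(seed = 7)          # 60 subjects, 2 sessions, 100 parcels
records <- generate_cohort(spec)

fc <- list()
for (r in records)
  fc[[r$subject_id]][[r$session_id]] <- pearson_fc(r$time_series)

split <- holdout_split(names(fc), fraction = 0.2, seed = 7)
holdout_fc <- unlist(lapply(split$holdout, function(s) fc[[s]]),
                     recursive = FALSE)
reference <- build_reference(holdout_fc)   # group gradients, holdout only

gradients <- list()
for (s in split$analysis) for (ses in names(fc[[s]]))
  gradients[[s]][[ses]] <- extract_gradients(fc[[s]][[ses]],
                                             subject_id = s, session_id = ses)

sweep <- alignment_sweep(gradients, reference, c(2, 10, 20))
round(tapply(sweep$diagnostics$correspondence,
             sweep$diagnostics$n_align, mean), 3)
#>     2    10    20
#> 0.715 0.490 0.440

ident <- sweep_identifiability(gradients, reference, c(1, 10, 20))
subset(ident, variant == "z",
       select = c(n_align, accuracy, i_self, i_other, i_diff))
#>   n_align  accuracy   i_self  i_other   i_diff
#> 2       1 0.3437500 1.261650 1.009073 25.25764
#> 4      10 0.5937500 1.907052 1.528215 37.88373
#> 6      20 0.6458333 1.946675 1.563728 38.29469
```

Reading the output: as more gradients enter the alignment, the mean
correspondence falls from 0.72 to 0.44 — the aligned principal gradient
increasingly mixes in lower gradients — while subject identification
accuracy rises from 0.34 to 0.65 and z-transformed differential
identifiability from 25 to 38: the alignment is absorbing per-session
sign/order instability, at the price of a principal gradient that is no
longer a single component. `run_full_study()` orchestrates this plus the
motion-correlation and prediction stages from a directory of TSV inputs
and writes tidy CSVs and a JSON run manifest; the same pipeline is
available from the shell via `inst/cli/gradalign.R` (`simulate`,
`run-all`).

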