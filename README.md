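# chondrostage

Image-based staging of chondrocyte dedifferentiation.

Autologous chondrocyte therapies depend on cell quality, but passage
number alone does not tell how far a culture has dedifferentiated.
Dedifferentiation is biphasic: an early, still-rescuable stage in which
the antioxidative markers **RBP4** and **SOD3** peak, and a late,
dysfunctional stage in which **IFITM3** and **F-actin** rise while cells
and nuclei enlarge. `chondrostage` turns that biology into a staging
system for anyone who can immunostain a coverslip: it quantifies the six
visual indicators per cell from confocal images, assembles them into a
normalized feature matrix, and places unknown donor samples against a
staged reference model.

## The method

For each sample, 20 randomly selected cells ("detection rounds") are
measured per indicator, giving a rounds × (sample, indicator) matrix
over the panel {RBP4, SOD3, IFITM3, F-actin, cell size, nucleus size}.
Per indicator, values are min–max normalized to integers in
[0, 14 000]:

    x' = round( (x − min) / (max − min) × 14000 )

A staged reference (passages P0, P2, P4, P8) freezes these
normalization parameters. Each sample is represented by its
concatenated, **round-sorted** 6 × 20 = 120-dimensional vector; rounds
are exchangeable cells, so sorting makes every downstream result exactly
invariant to the order in which cells were measured. A query is assigned
the stage of its nearest reference under Euclidean distance, with a
two-nearest-stage confidence

    c = d_other / (d_other + d_assigned)  ∈ (0.5, 1]  when unambiguous,

PCA coordinates in the reference-fitted space, and flags for ambiguous
ties and out-of-model samples ("not close to any group"). A companion
sub-pipeline implements the single-cell QC filters (≥ 500 genes/cell,
≥ 10 cells/gene, total counts within mean ± 2 sd) and classifies gene
trajectories along pseudotime into five temporal archetypes (immediate
down, gradual down, delayed up, gradual up, tide wave) plus a flat
rejection class. A synthetic-data generator encoding the biphasic
structure (marker dynamics, size growth, renderable images with
ground-truth masks, archetype gene trajectories) backs every claim with
testable ground truth.

## Worked example

Build a synthetic staged reference, stage an unknown donor sample, and
run the full evaluation study:

```r
library(chondrostage)

refs <- lapply(seq_along(stage_levels()), function(i)
  simulate_sample_profile(make_stage_params(stage_levels()[i]),
                          paste0("ref_", stage_levels()[i]), seed = 100 + i))
model <- build_reference(refs)

donor <- simulate_sample_profile(make_stage_params("P2"), "donor_1", seed = 7)
donor$stage <- "UNKNOWN"
assign_stage(donor, model)
#> <staging_result> donor_1 -> stage P2 (confidence 0.836)

run_evaluation(run_config(seed = 21, write_figures = FALSE))
#> <evaluation_report>
#>   stage assignment accuracy: 100.0% (n = 40 queries)
#>   per stage: P0 100%, P2 100%, P4 100%, P8 100%
#>   P2 queries assigned early: 100%; P8 assigned late: 100%
```

The donor's distances to the references (`ref_P0` 38307, `ref_P2` 7171,
`ref_P4` 36653, `ref_P8` 74360, on the normalized 0–14 000 scale) show
why it lands at P2 with confidence 0.836: the next-nearest stage is five
times farther. The evaluation report stages 40 queries (10 per stage)
against a fresh 4-sample reference and summarizes recovery of the
generating stages.

Images work the same way end to end:

```r
cells <- sample_cell_measurements(make_stage_params("P2"), 24, seed = 50)
img   <- render_image(cells, image_config(), seed = 51)   # 5-channel 16-bit
meas  <- quantify_image(img$channels)                      # segment + measure
sel   <- select_cells(meas, k = 20, seed = 52)             # 20 rounds
query <- measurements_to_profile(sel, "donor_img")
```

A thin CLI over these functions lives at `inst/cli/chondrostage.R`
(`simulate`, `quantify`, `stage`, `patterns`, `evaluate`).

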