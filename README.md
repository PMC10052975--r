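# ViTLV

Left-ventricle (LV) detection in cardiac MR relaxometry sequences with a
Vision Transformer.

Quantitative myocardial tissue characterization (T2\*, T2 and T1 mapping)
starts from short-axis multi-echo acquisitions that cover the whole chest,
while every downstream step — segmental analysis, signal fitting,
segmentation — only concerns the left ventricle. Locating the LV
automatically is harder in relaxometry than in cine imaging because *every*
tissue's signal changes across frames (with the echo time), the LV sits at a
variable off-centre position, coil sensitivity shades the field, and other
bright, similarly shaped structures are present. `ViTLV` implements a
transformer-based detector for this problem, together with everything needed
to exercise it end to end at desk scale: a synthetic multi-echo phantom
generator with exact ground truth, reference-standard construction
(bounding boxes, blood-pool centres, equiangular AHA segmental T2\*
analysis), the training protocol and the full evaluation metric suite.

## The model

The detector is a standard pre-norm Vision Transformer regressing four
numbers. An input stack `x ∈ R^{R×C×Nf}` (rows × columns × frames; the
first, fifth and ninth echoes of a ten-echo T2\* train by default) is split
into non-overlapping `P×P` patches, giving `N = RC/P²` tokens

    x_p ∈ R^{N×(P²·Nf)},   X = x_p W_E + E_pos ∈ R^{N×D}.

Each encoder block applies multi-head self-attention and an MLP, both
wrapped in residual connections around layer normalisation:

    U  = X + MHSA(LN(X)),        X' = U + MLP(LN(U)),
    head_i: A_i = softmax(Q_i K_iᵀ / s),   Z_i = A_i V_i,
    MHSA = [Z_0, …, Z_{h−1}] W_O,

with `Q_i = X W_Q^i`, etc. on per-head column slices. The encoder output is
flattened and a dense regression head emits `(x1, y1, x2, y2)` — the
normalized top-left and bottom-right corners of the LV bounding box.
Training minimises `1 − DICE` between the predicted and ground-truth boxes
with Adam under an exponentially decaying learning rate, ±20 px random-shift
augmentation, and subject-grouped k-fold splits (all three slices of a
subject — basal, middle, apical — stay in one partition, so no subject leaks
across sets). The forward pass, the backward pass and the optimizer are
implemented in base R on BLAS; gradient correctness is pinned against finite
differences in the test suite.

Evaluation reports, per image and aggregated by slice position: IoU
(Jaccard), DICE, the centre-point absolute error ε_CP,A (pixels), the
epicardial/endocardial fractional errors (ε_CP,A divided by the radius of
the equal-area circle of each mask) and the Correct Identification Rate —
the rate at which the predicted box centre falls inside the endocardial
mask.

## Worked example

Simulate a 100-subject cohort of 64×64 ten-echo phantoms (three slices per
subject), train the reduced detector on one subject-grouped fold for 30
epochs, and evaluate the held-out subjects:

```r
library(ViTLV)

co   <- simulateCohort(100, imageRows = 64, seed = 1)
data <- detectionDataset(co)                      # echoes 1, 5, 9
plan <- makeSplits(unique(data$index$subject_id), k = 5, seed = 1)
fold <- plan@folds[[1]]
trainIdx <- which(data$index$subject_id %in% fold$train)
valIdx   <- which(data$index$subject_id %in% fold$validation)
testIdx  <- which(data$index$subject_id %in% fold$test)

model <- vitModel(reducedViTConfig(), seed = 2)
model
#> ViTConfig: 64x64x3 input, P=16 (N=16 patches), D=32, h=4 heads, 2 encoder block(s)
#>   encoder MLP: 64/32 (dropout 0.10)
#>   head MLP: 512/128/32 -> 4 (dropout 0.30)
#>   374,852 trainable parameters

fit  <- trainDetector(model, data, trainIdx, valIdx,
                      trainConfig(batchSize = 32, maxEpochs = 30,
                                  initialLr = 1e-3, shiftRange = 5L,
                                  seed = 3))
pred <- predictBoxes(fit$model, data$images[testIdx])
rec  <- evaluateDetections(pred, data$boxes[testIdx],
                           data$index$slice_type[testIdx],
                           masks = data$masks[testIdx])
s <- aggregateMetrics(rec)
s[, c("slice", "n", "iou_mean", "iou_sd", "dice_mean",
      "eps_cp_a_mean", "cir_mean")]
#>    slice  n iou_mean iou_sd dice_mean eps_cp_a_mean cir_mean
#> 1  basal 20    0.765  0.109     0.863          1.27    1.000
#> 2 middle 20    0.766  0.107     0.863          1.20    1.000
#> 3 apical 20    0.602  0.148     0.742          1.51    0.750
#> 4 Global 60    0.711  0.143     0.823          1.33    0.917
```

Sixty held-out images are localised with a mean IoU of 0.71, the box centre
falls inside the blood pool in 92% of them, and — as expected from their
smaller size — apical slices are the hardest. The ground-truth side of the
pipeline works the same way on a single phantom:

```r
p <- generatePhantom(phantomSpec("middle", imageRows = 64,
                                 noiseSigma = 0, coilGradient = 0), seed = 7)
p
#> PhantomSample (middle slice): 64 x 64 x 10, myocardial T2* 56.82 ms
#>   GT box: (0.391, 0.516) -- (0.578, 0.703)
sa <- segmentalT2Star(imageSequenceOf(p), contourMasksOf(p), 6)
round(sa$segmentT2, 3)
#> [1] 56.819 56.819 56.819 56.819 56.819 56.819
```

A thin CLI over the same functions lives at `inst/scripts/vitlv`
(`simulate`, `train`, `predict`, `evaluate` subcommands on NIfTI stacks,
PNG masks and CSV annotations).

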