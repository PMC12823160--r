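# camtrapnet

Build robust plant–animal interaction datasets from camera-trap **video**
surveys assisted by computer vision, and quantify what the computer vision
step costs you.

Camera traps aimed at fruiting plants record short (≈10 s) motion-triggered
videos of animal visitors. Wind makes most triggers empty, so an object
detector (MegaDetector-format output) is used to discard blank videos before
human review. That filter loses information: videos whose animal scores
below the confidence threshold (false negatives, FN) silently disappear from
the interaction record, unevenly across plant species. `camtrapnet` is for
ecologists who run such surveys and want (i) a standardized pipeline from
frame-level detector output to weighted bipartite interaction networks, and
(ii) an explicit audit of the FN information loss and its effect on network
structure.

## What the package computes

* **Three-table data standard** (CamTrap-DP–style): `deployment.csv` (one
  camera on one focal plant), `video.csv` (media), `observation.csv`
  (reviewed content), with referential-integrity checking, flagged — never
  dropped — violations, and expert-consensus species labels (≥3 agreeing
  reviewers, otherwise `"unidentified"`).
* **Video-level classification.** Frame-level detections are aggregated per
  video by the *maximum* confidence over its frames; a video is selected for
  review when max confidence > τ (default τ = 0.8), else blank.
* **Independent interaction events.** Consecutive videos of the same animal
  species at the same deployment within a 5-min window collapse into one
  event (gap/chain rule; a fixed-interval mode is also provided). Event
  counts fill the plant × animal adjacency matrix **W**, and the
  probability of interspecific encounter is the row-normalized

  PIE<sub>ij</sub> = w<sub>ij</sub> / Σ<sub>j</sub> w<sub>ij</sub>,

  optionally diet-weighted per animal species.
* **Sampling effort** per deployment revision: (last − first media
  timestamp) in decimal trap-days, anchored by sentinel recordings.
* **Detector validation.** Stratified proportional review samples; confusion
  matrices per plant species / individual; the 12 standard metrics (TPR,
  TNR, FPR, FNR, PPV, NPV, FDR, FOR, ACC, ERR, F1 and MCC =
  (TP·TN − FP·FN)/√((TP+FP)(TP+FN)(TN+FP)(TN+FN)), the metric of choice for
  imbalanced video sets); FP/FN calibration curves over a threshold grid
  with per-species optimal thresholds (argmin of FPR + FNR).
* **Information-loss audit.** Events, species and unique pairwise
  interactions lost per plant stratum when FN are excluded, plus direct FN
  imputation (unscaled union of reviewed FN records).
* **Network comparison.** Valued Hamming distance Σ|a<sub>ij</sub> −
  b<sub>ij</sub>|, graph correlation (product-moment over cells), and a
  **two-mode QAP test** that permutes plant and animal labels independently,
  with add-one p-values.
* **Synthetic studies.** A generator with known ground truth (Poisson
  visits, exponential durations, 10 s trigger cascades, wind false
  triggers, Beta-distributed frame confidences thinned by per-species
  detectability) plus closed-form FN/FP rate oracles, so the whole pipeline
  is testable without any field data.

## Worked example

A fully synthetic 14-day survey: 3 plant species × 2 individuals, five
frugivore species with visit rates 0.1–2 visits/day and detectabilities
0.6–0.9, heavy wind triggering.

```r
library(camtrapnet)

cfg <- scenario_config(study_days = 14)
sc  <- generate_scenario(cfg, seed = 42)
sc$tables
#> camtrap_tables: 6 deployments, 5068 media, 1626 observations; 0 integrity issue(s)

det  <- parse_detections(sc$detections)
idx  <- aggregate_to_video(det, sc$manifest)     # max confidence per video
part <- partition_videos(idx, threshold = 0.8)   # strict >, ties -> blank
length(part$selected); length(part$blank)
#> [1] 1388
#> [1] 3680

rec    <- join_observation_media(filter_interaction_records(sc$tables$observations),
                                 sc$tables$media)
rec_cv  <- rec[rec$media_id %in% part$selected, ]
ev_cv   <- collapse_events(rec_cv, window_s = 300)   # CV-filtered events
ev_full <- collapse_events(rec,    window_s = 300)   # with the FN included
nrow(ev_cv); nrow(ev_full)
#> [1] 234
#> [1] 243

net_cv <- interaction_matrix(ev_cv, sc$tables$deployments)
net_cv
#> bipartite_network: 3 plants x 5 animals, total weight 234
round(pie_matrix(net_cv), 3)
#>                  Erithacus rubecula Pica pica Sturnus unicolor Sylvia atricapilla Turdus merula
#> Plantus species1              0.247     0.000            0.104              0.143         0.506
#> Plantus species2              0.182     0.039            0.078              0.169         0.532
#> Plantus species3              0.250     0.038            0.062              0.112         0.537

eff <- compute_effort(sc$tables$media)
sum(eff$effort_days)
#> [1] 84    # 6 deployments x 14 trap-days
```

Each PIE row is the probability distribution of a plant's visitors:
*Turdus merula*, the common and conspicuous visitor, carries ≈53% of every
plant's interactions, while the rare *Pica pica* (0.1 visits/day,
detectability 0.6) is entirely absent from one plant's CV-filtered row.

How much did the detector cost us? Validating against the generator's truth:

```r
truth <- setNames(sc$truth$contains_animal, sc$truth$media_id)
round(compute_metrics(confusion_matrix(truth, idx, threshold = 0.8))[,
      c("ACC", "TPR", "FNR", "F1", "MCC")], 3)
#>     ACC   TPR   FNR   F1   MCC
#> 1 0.953 0.853 0.147 0.92 0.893

lost <- lost_information_report(add_plant_labels(ev_full, sc$tables$deployments),
                                add_plant_labels(ev_cv,  sc$tables$deployments))
format_lost_info(lost)[, c("stratum", "n_events", "events_lost", "pct_lost")]
#>            stratum n_events events_lost pct_lost
#> 1 Plantus species1       81           4      4.9
#> 2 Plantus species2       80           3      3.8
#> 3 Plantus species3       82           2      2.4

qap_test(net_cv, interaction_matrix(ev_full, sc$tables$deployments),
         statistic = "gcor", n_perm = 1000, seed = 42)
#> QAP test (gcor, alternative = greater): observed = 0.998758, p = 0.002997 (1000 permutations)

select_optimal_threshold(threshold_curves(truth, idx))
#> [1] 0.62
```

Reading: at τ = 0.8 the detector misses 14.7% of occupied videos, costing
2.4–4.9% of interaction events depending on the plant; yet the CV network is
structurally indistinguishable from the FN-imputed one (graph correlation
0.999, far above its label-permutation null), and calibration suggests a
community-level threshold near 0.62 would balance FP against FN better than
the conservative 0.8.

## Further reading

The methods vignette (`vignettes/camtrap-interaction-networks.Rmd`) documents
the model assumptions, the parameters that matter and their defaults, the
numerical conventions (strict-greater thresholding, tie handling, undefined
metrics), what the synthetic generator does and does not emulate, and known
limitations.
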