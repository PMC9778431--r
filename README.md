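# noduleseg

Boundary-aware segmentation of pulmonary nodules on 2-D CT patches, in R.

Accurate nodule delineation is central to lung-cancer screening, but
ground-glass, wall-attached and vessel-attached nodules share their
intensity with the surrounding tissue and defeat plain encoder-decoders.
`noduleseg` implements a *features-complementary* network that mirrors how a
radiologist reads a nodule -- locate it, outline its coarse area, then
refine the boundary -- and lets the three information streams reinforce each
other:

* a five-level Res2Net50-style backbone whose 7x7 stem is replaced by three
  3x3 conv+ReLU layers (taps at strides 2, 4, 8, 16, 32);
* **MF** multi-receptive-field blocks refining each high-level feature
  through four cascade branches (1x1; factorized 1x(2m+1)/(2m+1)x1; 3x3 with
  dilation 2m+1) with effective receptive fields 1, 9, 15, 21 pixels;
* an **MD** cross-scale decoder, `f_i'' = f_i' * prod_k Conv(Up(f_k'))`,
  aggregating into a coarse nodule map `f_g`;
* an **LE** edge decoder, `f_E = f_2 + f_1 * f_2`, at stride 4;
* a complementary module: location fusion
  `f_E^ = Conv(f_E + Up(f_4' * sigma(Up(Conv(Convs(f_5'))))))` and edge
  fusion `P_s = sigma(f_E^ + Up(Conv(Convs(f_g))))`;
* the edge-weighted hybrid loss
  `L = L_edge + (wBCE + wIoU)/2`, with per-pixel weights
  `W = alpha + beta |G_s - meanpool(G_s)|` (alpha = 1, beta = 5)
  emphasizing boundary pixels, plus deep supervision of the coarse map;
* the full structural evaluation suite: DSC, Jaccard, HD95, sensitivity,
  specificity, S-measure, E-measure, MAE, with mean +/- SD (95% CI)
  reporting.

There is no deep-learning framework dependency: the convolutional core
(conv2d, batch norm, bilinear resizing, reverse-mode autograd, Adam) is
implemented in C++/R inside the package, and its gradients are verified
against finite differences in the test suite. A deterministic synthetic
CT-phantom generator (isolated, juxta-pleural, juxta-vascular, ground-glass,
cavitary, calcified nodules; five non-centered non-square crops per nodule,
resized to 96x96) makes the entire pipeline testable without clinical data.

## Worked example

Build a 10-patient synthetic dataset, split it 9:1 by patient, train a
desk-scale network for two epochs, and evaluate on the held-out patient:

```r
library(noduleseg)

td  <- tempfile()
man <- build_dataset(synth_config(n_patients = 10, seed = 77), td)  # 50 patches
sp  <- split_patients(man, seed = 5)                                # 9 / 1 patients

fit <- fit_model(sp$train, sp$test, data_dir = td,
                 config = train_config(lr0 = 1e-3, max_epochs = 2,
                                       width = 1/16, blocks = c(1, 1, 1, 1),
                                       seed = 9))
#> epoch   1  lr 1.00e-03  loss 1.6785  val DSC 0.704
#> epoch   2  lr 1.00e-03  loss 0.9576  val DSC 0.811
```

Predicting the held-out patches and scoring them:

```r
rep <- evaluate_dataset(pred_probability_dir, heldout_mask_dir)
rep
#> <metrics_report> 5 images
#>   DSC   0.8111 +/- 0.0563 (0.7618-0.8605)
#>   JA    0.6853 +/- 0.0788 (0.6162-0.7544)
#>   HD95  4.1052 +/- 1.5600 (2.7378-5.4727)
#>   SE    0.7660 +/- 0.1171 (0.6633-0.8687)
#>   SP    0.9834 +/- 0.0058 (0.9783-0.9885)
#>   Sm    0.8580 +/- 0.0845 (0.7840-0.9321)
#>   Em    0.9306 +/- 0.0709 (0.8684-0.9927)
#>   MAE   0.0672 +/- 0.0528 (0.0210-0.1135)
```

After two epochs on a 1/16-width network the held-out-patient Dice is
already 0.81 with a sub-5-pixel HD95: the edge-weighted loss pulls the
predicted boundary onto the phantom boundary quickly. `tidy(rep)` returns
the per-image rows, `glance(rep)` the aggregate row, `autoplot(rep)` the
per-metric distributions; fits support `tidy()`/`glance()`/`autoplot()` the
same way.

A command-line front end mirrors the API:

```sh
exec/noduleseg synth   --config cfg.yaml --out data/
exec/noduleseg train   --config cfg.yaml --data data/ --ckpt best.rds
exec/noduleseg predict --ckpt best.rds --in data/images --out pred/
exec/noduleseg eval    --pred pred/prob --gt data/masks --out report.csv
```

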