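# dgntrace

Unsupervised extraction of hidden fluorophore-count state paths from noisy
single-molecule fluorescence intensity traces, with a discriminator–generator
network (DGN) of paired bidirectional LSTMs.

## What problem this solves, and for whom

Single-molecule TIRF experiments reduce each tracked spot to an intensity
time trace (one value per frame). Behind the trace sits an integer hidden
process — the number of emitting fluorophores: a decreasing staircase under
photobleaching (subunit counting / stoichiometry), a switching staircase
under association–dissociation dynamics (occupancies, transition rates,
dwell times). Recovering that path is hard when the step height is
comparable to the noise and when reversible photoblinking mimics bleaching
steps. This package is for single-molecule biophysicists who want
per-frame state paths from such traces without hand-labelling data or
fixing a state count in advance.

The estimator at the core:

* a **discriminator** biLSTM (32 units/direction) maps the normalized trace
  `x = {x_1..x_T}` to a per-frame posterior `h_t` over fluorophore counts
  `0..s_max` (softmax head);
* a **generator** biLSTM (16 units/direction, linear head) reconstructs
  `x̂_t` from `(h_t, x̂_{t-1})`;
* both are trained jointly on the quadratic reconstruction loss
  `L = (1/2T) Σ (x̂_t − x_t)²` — label-free — blended with a hidden-space
  cross-entropy `L_h` on synthetic, labelled traces:
  labelled traces contribute `(1−α) L + α L_h`, with the annealing weight
  `α = 0.5 e^(−2k/K)` over epochs `k = 0..K`.

After training, the discriminator alone yields the state path (per-frame
argmax). The package also ships the calibrated trace simulator (shot noise,
Gaussian noise, per-fluorophore blinking, aSNR targeting), the
photobleaching and kinetics analytics, bootstrap summaries, and a
from-scratch Gaussian-HMM baseline (Baum–Welch + Viterbi) for comparison.

## Worked example

Simulate a photobleaching cohort at a realistic noise level, train a DGN,
and score the recovered paths:

```r
library(dgntrace)

# training cohort: initial counts weighted toward full staircases, so the
# rare high-count states get enough frames to learn from
train <- synthesize_dataset("photobleach", n_traces = 1000,
                            target_asnr = 4.74,
                            state_mix = c(1:9, 25) / 70,
                            split = c(0.85, 0.15, 0), seed = 401)
train
#> <trace_dataset> 1000 traces (photobleach), s_max = 10
#>   split: 850 train / 150 val / 0 test
#>   target aSNR 4.74, achieved 4.744

fit <- dgn(train, epochs = 60, seed = 1)
fit
#> Discriminator-generator network (photobleach mode)
#>   states 0..10; discriminator biLSTM 32/dir + softmax, generator biLSTM 16/dir + linear
#>   trained 60 epochs on 850 traces; final train loss 0.00307, val loss 0.00327

# evaluation cohort: the standard equal 10% initial-state mix
test <- synthesize_dataset("photobleach", n_traces = 300,
                           target_asnr = 4.74, split = c(0, 0, 1),
                           seed = 402)
test <- dataset_split(test, "test")
rep <- state_confusion(predict(fit, test, type = "states"),
                       lapply(test$records, `[[`, "states"), s_max = 10)
rep
#> <confusion_report> 120000 frames, 11 represented states
#>   overall accuracy 0.9890, minimum per-state accuracy 0.7493
#>      0      1      2      3      4      5      6      7      8      9     10
#> 0.9989 0.9860 0.9708 0.9724 0.9551 0.9363 0.9077 0.8727 0.8569 0.7493 0.7591
```

The headline figure is the *minimum* per-state accuracy over the
fluorophore-count states (background excluded): here 74.9%, sitting at
state 9, whose geometric dwell under per-fluorophore bleaching lasts only
~6 frames; overall frame accuracy is 98.9%. Step counts and kinetics come
from the same predicted paths:

```r
paths <- predict(fit, test, type = "states")
round(population_distribution(paths), 3)  # bleaching-step fractions
#>     0     1     2     3     4     5     6     7     8     9    10
#> 0.017 0.103 0.087 0.103 0.110 0.100 0.107 0.090 0.107 0.040 0.137
fit_dwell_exp(dwell_durations(paths, state = 1, 0.1))
#> [1] 5.017  # seconds; the generating state-1 dwell mean is 5.0 s
state_occupancy(paths)              # fraction of frames per state
transition_rates(paths, 0.1)        # per-second rate matrix
```

The estimated step-count fractions sit near the true 10% per class, with
the residual error concentrated in the 9/10-step classes (initial-plateau
identification of the shortest-lived states), and the state-1 dwell
constant recovers the generating value.

A command-line front end wrapping the same functions is installed at
`inst/cli/dgntrace.R` (`simulate`, `train`, `predict`, `evaluate`,
`dynamics`, `baseline-hmm`).

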