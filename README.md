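# decklanding

Affordance-based modelling of helicopter ship-deck landing decisions.

Landing a helicopter on the deck of a frigate tossed by the sea is safe
only if the touchdown velocity relative to the deck stays below a critical
value, V_crt = 3 m/s. Whether that is achievable with the lift a helicopter
can develop is an *affordance* — a possibility for action emerging from the
relation between the vehicle's action capabilities and the heaving deck.
For a deck heaving sinusoidally (amplitude A, frequency f, phase φ) and a
helicopter of mass m under a constant lift L, the relative velocity at the
first contact, a time Δt after the lift is applied, is

    V_td = V_current + (L/m − g)·Δt − A·2πf·cos(φ_current + 2πf·Δt)

and the dimensionless affordance ratio of committing to the landing at
time t is π(t) = |V_td(t)| / V_crt: π = 1 is the critical point between
safe and unsafe, contiguous spans with π ≤ 1 are safe deck-landing
windows, and the minimum over the response window, π_optimal, marks the
optimal moment to commit. The package implements this model end to end:

* closed-form heave/descent kinematics, a contact-time solver and the
  touchdown-velocity equation (`contact_time()`, `touchdown_velocity()`);
* deck-landing-ability landscapes over (trigger time × lift), fixed-lift
  slices π(t), safe windows and per-condition optima (`build_landscape()`,
  `pi_timeline()`, `extract_safe_windows()`, `pi_optimal()`, `pi_table()`);
* the two-group (low-lifter 80,000 N / heavy-lifter 90,000 N) judgment
  trial protocol over 8 conditions of initial altitude × heave phase
  (`build_condition_grid()`, `run_trial()`, `experiment_block()`);
* the ecological head-up display that renders the future touchdown
  velocity in V_crt units (`compute_frame()`, `animate()`,
  `write_frame_png()`);
* synthetic noisy-threshold observers standing in for human participants
  (`observer_params()`, `decide()`, `generate_cohort()`, `fit_observer()`);
* the decision-analysis pipeline: attempt frequencies and sigmoid fits,
  touchdown-velocity distributions and unsafe-attempt rates, timing
  errors, landscape overlays (`attempt_frequency()`, `fit_sigmoid()`,
  `velocity_distributions()`, `timing_errors()`, `landscape_overlay()`).

See `vignettes/deck-landing-affordance.Rmd` for the model, the response
window reconstruction, numerical choices and the observer calibration.

## Worked example

The per-condition optima of the affordance model under the study
constants:

```r
library(decklanding)
pt <- pi_table()
pt[pt$z_init == 9 & pt$phi_init == 0, c("group", "pi_optimal", "t_optimal")]
#>   group pi_optimal t_optimal
#> 1    LL      0.703      8.47
#> 2    HL      0.325      7.51
```

From 9 m with the deck starting at its mean plane moving up, the
low-lifter's best attempt (committed 8.47 s into the descent) touches down
at 0.70·V_crt = 2.1 m/s; the heavy lifter, decelerating less violently,
can do 0.32·V_crt ≈ 1.0 m/s. The heavy lifter's safe window for that
condition:

```r
extract_safe_windows(pi_timeline(9, 0, "HL"))
#>   onset offset depth_pi t_optimal
#> 1  6.09   8.77    0.325      7.51
```

A full synthetic experiment and its headline analysis:

```r
log <- generate_cohort(n_ll = 15, n_hl = 14, master_seed = 1)
velocity_distributions(log)$rates
#>   group augmented                rate   mean     sd n_participants
#> 1    HL     FALSE unsafe_attempt_rate 0.2835 0.0550             14
#> 2    HL      TRUE unsafe_attempt_rate 0.0922 0.0538             14
#> 3    LL     FALSE unsafe_attempt_rate 0.3882 0.0938             15
#> 4    LL      TRUE unsafe_attempt_rate 0.1346 0.0494             15
#> ...
```

Without the display augmentation the synthetic observers attempt unsafe
landings on roughly a third of their attempts; with it, under 15% — the
directional effect the display is designed to produce. Augmentation in
the simulator works by sharpening perception (smaller perceptual noise
and timing jitter), so attempt timing also concentrates on the optimum:

```r
fit_sigmoid(attempt_frequency(log), "HL", augmented = TRUE)
#> <sigmoid_fit> midpoint pi = 0.9766, slope = 0.0592, SSE = 0.00809
```

i.e. the augmented psychometric function steps down almost exactly at the
critical point π = 1.

## Command line

A thin CLI over the same functions lives at `inst/cli/decklanding.R`
(installed under `system.file("cli", "decklanding.R", package =
"decklanding")`), with subcommands `pi-table`, `slice`, `landscape`,
`simulate`, `analyze` and `render`.
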