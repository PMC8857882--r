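# imuRehab

Movement-quality metrics for home-based physiotherapy from a single
shank-worn inertial measurement unit (IMU).

Tele-rehabilitation depends on patients performing prescribed exercises
correctly without supervision. `imuRehab` evaluates recordings from one
9-DoF sensor strapped to the shank: it finds the section of a trial that
contains the exercise repetitions, delimits the individual repetitions
from the periodicity of the acceleration signal, and computes eight
metrics of movement duration, smoothness, intensity, regularity and
control. It is aimed at researchers in rehabilitation biomechanics and
digital health who need an automated, unbiased pipeline for lab-vs-home
exercise comparison — plus a synthetic-recording generator with ground
truth, so every step is testable without access to recorded subjects.

## The metrics

For a recording with active window [t₁, t₂] and per-repetition
boundaries:

| Metric | Definition | Units |
|---|---|---|
| Cycle duration | boundary span / number of cycles | s |
| LDLJ | −ln((t₂−t₁)/a²peak · ∫ ẍ′²+ÿ′²+z̈′² dt), 6 Hz zero-phase Butterworth prefilter | — |
| MI mean / MIV | mean and SD of ‖a(t)‖/g (raw signal) | g |
| RAV | mean over repetitions of max−min of ‖ω(t)‖ | rad/s |
| Kinetic value | (∫ resultant acceleration dt)²/2 | J/kg |
| Regularity Ad1 | first non-zero-lag peak of the max-normalised biased autocorrelation, first 5 repetitions | — |
| DTW | mean path-length-normalised DTW distance of consecutive repetitions | m/s² |

LDLJ values closer to zero mean smoother movement; Ad1 close to 1 means
repetitions executed consistently; smaller DTW means better movement
control.

## Worked example

```r
library(imuRehab)

out <- generateRecording(exerciseTemplate("half_squat", cycleDuration = 3.5),
                         defaultPerturbation("half_squat", seed = 3))
seg <- segmentRecording(out$recording)
seg
#> SegmentationResult: axis x, window [2.44, 27.78] s
#>   7 cycles, mean duration 3.486 s (dominant period 3.459 s)

computeMetricSet(out$recording, seg)
#> MetricSet:
#>   cycle duration     3.486 s      (n = 7 cycles)
#>   LDLJ              -9.235
#>   MI mean / var      1.000 / 0.030 g
#>   RAV                0.381 rad/s
#>   kinetic value     18.822 J/kg
#>   regularity Ad1     0.786
#>   DTW distance       0.035 m/s^2
```

The segmentation recovered all 7 simulated repetitions and their
jittered 3.46 s realised pace to within 1%; movement intensity sits at
1 g (the sensor mostly
re-orients in the gravity field), and the regularity coefficient is near
the 0.8 ceiling of the biased five-repetition estimator, as expected for
a consistent execution.

Cohort-level use mirrors a study design — every subject performs five
exercises in a lab and a home session:

```r
coh <- generateCohort(nSubjects = 30, seed = 1)    # 300 recordings
tab <- runBatch(coh)$metrics                       # tidy table, 1 row per recording
summarizeSessions(tab)                             # mean ± SD per exercise x session
compareSessions(tab, "cycle_duration_s", "knee_extension", seed = 1)
#> $pValue: 1e-04  -- the simulated home pace reduction is detected
```

A thin command-line wrapper with `simulate` / `run` / `summarize` /
`compare` subcommands is installed at `inst/scripts/imurehab-cli.R`.

Real recordings load through a configurable column map
(`readRecording(path, readColumnMap("map.yml"))`), which handles file
schemas with different column names, g vs m/s² accelerometer units, dps
vs rad/s gyroscope units, and missing time columns.

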