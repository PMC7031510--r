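# On-disk formats

All files are plain text. Units follow the package convention: mV, ms, pA,
pF, nS, MΩ.

## Voltage trace (`*.csv` + `*.meta.json`)

CSV header: `time_ms,voltage_mV,current_pA`; one row per sample, uniform
time grid starting at 0. The sidecar `<name>.meta.json` holds:

```json
{
  "neuron_id": "bird01_n01",
  "bird_id": "bird01",
  "dt_ms": 0.05,
  "protocol": {
    "kind": "step",
    "amplitude_pA": 100,
    "pre_ms": 200, "stim_ms": 200, "post_ms": 200,
    "holding_mV": -70,
    "seed": null
  },
  "provenance": "simulated | synthetic-cohort | external"
}
```

Written/read by `writeTraceCsv()` / `readTraceCsv()`.

## Fits table (`fits.csv`)

One row per neuron:
`neuron_id,bird_id,gNa,gK,gSK,gh,gCaT,error,disregarded_count`
(conductances in nS; `error` is the unitless fitting error at the
canonical +100 pA pulse; `disregarded_count` the number of grid candidates
removed by the spike-count rule). `writeFitsCsv()` / `readFitsCsv()`.

## Features table (`features.csv`)

One row per neuron: `neuron_id,bird_id,n_spikes,spike_rate_hz,isi1_ms,
isi2_ms,isi3_ms,spike_amplitude_mv,spike_threshold_mv,spike_duration_ms,
plateau_amplitude_mv,resting_potential_mv,sag_ratio,rebound_spikes,
input_resistance_mohm`. Missing (not computable) values are empty/NA,
never zero. Produced by `featuresTable()`.

## Song-similarity matrix (`similarity.csv`)

Square matrix with bird ids as the header row and the first column
(`bird_id`); values are percent-like similarities in (0, 100], diagonal
100. `writeSimilarityCsv()` / `readSimilarityCsv()`.

## Reference parameters (`inst/extdata/reference_parameters.yaml`)

One block per ionic current with all Boltzmann midpoints/slopes (mV) and
time-constant parameters (ms) explicit; capacitance per age class (pF);
calcium-pool constants (µM, ms). Loaded by `referenceParameters()`.

## Pipeline report (`report.json`, `report.md`)

`report.json` holds the config snapshot and its hash, per-bird volumes,
pairwise Euclidean/Mahalanobis distance matrices, MANOVA results, the
similarity correlation and the parameter-recovery summary. `report.md` is
the human-readable digest of the same numbers. Written by `writeReport()`;
reruns with an unchanged config are byte-identical.
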